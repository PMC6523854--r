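#' Package configuration defaults
#'
#' Every physical default carries its value, unit and a provenance note.
#' These are the model's standard settings: 0.004 ps step, 15 A cutoff,
#' Nose-Hoover times f = 0.5 ps (NVT) and f1 = 0.5 ps / f2 = 3.0 ps (NPT),
#' Ewald convergence parameter 0.18520 1/A with kmax (8, 8, 16), and the
#' lattice-quench protocol starting at 100 K with an 800 ps cold
#' equilibration.
#'
#' @return Named list; each entry has `value`, `unit` and `note`.
#' @export
cg_defaults <- function() {
  d <- function(value, unit, note) list(value = value, unit = unit, note = note)
  list(
    dt        = d(0.004, "ps", "integration time step of the coarse-grained model"),
    cutoff    = d(15, "angstrom", "nonbonded cutoff radius of the model"),
    f         = d(0.5, "ps", "Nose-Hoover thermostat coupling time (NVT)"),
    f1        = d(0.5, "ps", "Nose-Hoover thermostat coupling time (NPT)"),
    f2        = d(3.0, "ps", "Nose-Hoover barostat coupling time (NPT)"),
    alpha     = d(0.18520, "angstrom^-1", "Ewald convergence parameter"),
    kmax      = d(c(8L, 8L, 16L), "", "reciprocal-lattice limits of the Ewald sum"),
    initial_T = d(100, "K", "lattice equilibration temperature before the quench"),
    equil_span = d(800, "ps", "cold-equilibration span of the lattice-quench protocol"),
    production_T = d(298.15, "K", "default production temperature"),
    production_span = d(100, "ps", "default production span"),
    P         = d(1, "atm", "pressure setpoint for atmospheric-density runs"),
    scale14   = d(1.0, "", "scaling of 1-4 intramolecular nonbonded pairs")
  )
}

unit_table <- list(
  time = c(ps = 1, fs = 1e-3, ns = 1e3),
  length = c(angstrom = 1, A = 1, "Å" = 1, nm = 10),
  temperature = c(K = 1),
  pressure = c(atm = 1, bar = 0.98692327),
  inv_length = c("angstrom^-1" = 1, "A^-1" = 1, "1/A" = 1),
  density = c("g/cm^3" = 1, "g/cm3" = 1),
  none = c(none = 1)
)

# Parse "0.004 ps" style annotated quantities. Bare numbers are rejected for
# physical keys: units in config files are explicit.
parse_quantity <- function(x, dim, key) {
  if (is.numeric(x)) {
    if (dim == "none") return(as.numeric(x))
    stop("config error at '", key, "': physical values need a unit string, ",
         "e.g. \"", x, " ", names(unit_table[[dim]])[1], "\"")
  }
  parts <- strsplit(trimws(as.character(x)), "\\s+")[[1]]
  if (length(parts) != 2)
    stop("config error at '", key, "': expected \"<value> <unit>\", got '", x, "'")
  val <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(val)) stop("config error at '", key, "': non-numeric value '", parts[1], "'")
  fac <- unit_table[[dim]][parts[2]]
  if (is.na(fac))
    stop("config error at '", key, "': unit '", parts[2],
         "' is not a recognised ", dim, " unit")
  unname(val * fac)
}

config_dims <- c(
  dt = "time", cutoff = "length", f = "time", f1 = "time", f2 = "time",
  alpha = "inv_length", initial_T = "temperature", equil_span = "time",
  production_T = "temperature", production_span = "time", P = "pressure",
  T = "temperature", target_density = "density", shell = "length",
  spacing = "length", skin = "length"
)

#' Parse a run configuration file
#'
#' YAML with sections `forcefield` (path or "default"), `build`, `ensemble`,
#' `ewald`, `protocol`, plus `seed`, `output` and `log_level`. Physical
#' values are unit-annotated strings (`"0.004 ps"`); bare numbers for
#' physical keys are rejected. Missing values resolve to [cg_defaults()],
#' each of which carries a provenance note in the returned `meta`.
#'
#' @param path config file path.
#' @return A `run_config` object.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- yaml::read_yaml(path) %||% list()
  known_top <- c("forcefield", "build", "ensemble", "ewald", "protocol",
                 "seed", "output", "log_level")
  bad <- setdiff(names(doc), known_top)
  if (length(bad))
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "))
  defs <- cg_defaults()
  getq <- function(section, key, dim = config_dims[[key]] %||% "none") {
    x <- doc[[section]][[key]]
    if (is.null(x)) {
      dv <- defs[[key]]
      if (is.null(dv)) return(NULL)
      return(dv$value)
    }
    parse_quantity(x, dim, paste0(section, ".", key))
  }
  ff_path <- doc$forcefield %||% "default"
  if (!identical(ff_path, "default") && !file.exists(ff_path))
    stop("config error: force-field file not found: ", ff_path)

  kmax <- doc$ewald$kmax %||% defs$kmax$value
  kmax <- as.integer(rep(unlist(kmax), length.out = 3))
  if (any(kmax < 1)) stop("config error at 'ewald.kmax': components must be >= 1")

  ens_kind <- toupper(doc$ensemble$kind %||% "NPT")
  if (!ens_kind %in% c("NVE", "NVT", "NPT"))
    stop("config error at 'ensemble.kind': ", ens_kind)
  ensemble <- ensemble_config(
    kind = ens_kind,
    T = getq("ensemble", "T") %||% defs$production_T$value,
    P = getq("ensemble", "P"),
    f = getq("ensemble", "f"), f1 = getq("ensemble", "f1"),
    f2 = getq("ensemble", "f2"),
    dt = getq("ensemble", "dt"), cutoff = getq("ensemble", "cutoff"))

  protocol <- protocol_spec(
    initial_T = getq("protocol", "initial_T"),
    equil_span = getq("protocol", "equil_span"),
    production_T = getq("protocol", "production_T") %||% ensemble$T,
    production_span = getq("protocol", "production_span"),
    stride = doc$protocol$stride %||% 25L,
    frame_stride = doc$protocol$frame_stride %||% 0L,
    minimize_steps = doc$protocol$minimize_steps %||% 200L)

  build <- doc$build %||% list()
  if (!is.null(build$target_density))
    build$target_density <- parse_quantity(build$target_density, "density",
                                           "build.target_density")

  structure(list(
    forcefield = ff_path,
    build = build,
    ensemble = ensemble,
    ewald = list(alpha = getq("ewald", "alpha"), kmax = kmax),
    protocol = protocol,
    seed = as.integer(doc$seed %||% 1L),
    output = doc$output %||% "cgmie_out",
    log_level = doc$log_level %||% "info",
    meta = defs,
    path = path
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("run_config: %s ensemble, T = %g K, dt = %g ps, seed %d\n",
              x$ensemble$kind, x$ensemble$T, x$ensemble$dt, x$seed))
  invisible(x)
}

load_forcefield_from_config <- function(config) {
  if (identical(config$forcefield, "default")) default_forcefield()
  else read_forcefield(config$forcefield)
}
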