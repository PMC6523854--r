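#' Construct a force field programmatically
#'
#' Mirrors the YAML registry schema as R lists; used by the fixture
#' generator and available for small bespoke systems.
#'
#' @param site_types named list; each entry a list(mass, charge, epsilon,
#'   n, m, r0 or sigma), epsilon 0 for vdW-silent sites.
#' @param molecules named list of molecule blocks (sites, coords, bonds,
#'   bends, dihedrals, species, rigid), same shape as the YAML file.
#' @param mixing,exclusions,water_model optional overrides.
#' @return A `cg_forcefield`.
#' @export
make_forcefield <- function(site_types, molecules,
                            mixing = list(exponent_rule = "arithmetic",
                                          fixed_exponents = c(9, 6)),
                            exclusions = list(policy = "1-3", scale14 = 1.0),
                            water_model = list(dOH = 1.0, dHH = 1.6329932)) {
  sites <- list()
  for (nm in names(site_types)) {
    st <- site_types[[nm]]
    sp <- NULL
    if (!is.null(st$epsilon) && st$epsilon > 0)
      sp <- mie_params(st$epsilon, st$n, st$m, r0 = st$r0, sigma = st$sigma)
    sites[[nm]] <- site_type(nm, st$mass, st$charge %||% 0, sp)
  }
  ff <- structure(list(
    sites = sites, mixing = mixing, exclusions = exclusions,
    molecules = lapply(molecules, compile_molecule_template, sites = sites),
    water_model = water_model, species_masses = NULL,
    meta = list(name = "programmatic"), path = NA_character_
  ), class = "cg_forcefield")
  ff$pair_table <- build_pair_table(ff)
  ff
}

monatomic_molecule <- function(type, species = type) {
  list(species = species, sites = list(list(id = type, type = type)),
       coords = stats::setNames(list(c(0, 0, 0)), type))
}

#' Generate a deterministic test fixture
#'
#' Small systems exercising one physical ingredient each:
#' \describe{
#'   \item{ideal_gas}{n non-interacting sites on a jittered grid (RDF and
#'     barostat limiting cases).}
#'   \item{nacl_lattice}{8 alternating +1/-1 ions on a rock-salt cubic cell
#'     (Ewald versus the Madelung constant).}
#'   \item{harmonic_dimer}{two bonded sites, optionally stretched
#'     (integrator versus the closed-form oscillator).}
#'   \item{mie_fluid}{n identical 9-6 Mie sites at a given density
#'     (NVE conservation, thermostat contract).}
#'   \item{il_box}{[bmim][Cl] lattice of n_pairs pairs at an expanded
#'     density (scaled-down equilibrium-density runs).}
#'   \item{mini_fiber}{4 cellulose chains solvated by 200 ionic-liquid
#'     pairs and 270 waters, preserving the water:IL molecule ratio of the
#'     full solvated-fiber system (scaled-down RDF runs).}
#' }
#'
#' @param kind fixture name, see above.
#' @param seed RNG seed; identical (kind, parameters, seed) give identical
#'   fixtures.
#' @param ... size overrides per kind (`n`, `density`, `n_pairs`, `a`,
#'   `spring_k`, `r0`, `stretch`, `n_chains`, `n_units`, `n_il`, `n_water`,
#'   `box`, ...). Note `spring_k`, not `k`, for the dimer force constant:
#'   a bare `k` would partially match the `kind` argument.
#' @return List with `topology`, `ff` and `kind`.
#' @export
generate_fixture <- function(kind = c("ideal_gas", "nacl_lattice",
                                      "harmonic_dimer", "mie_fluid",
                                      "il_box", "mini_fiber"),
                             seed = 1L, ...) {
  kind <- match.arg(kind)
  args <- list(...)
  set.seed(seed)
  out <- switch(kind,
    ideal_gas = {
      n <- args$n %||% 1000L
      box <- rep(args$box %||% 40, length.out = 3)
      ff <- make_forcefield(
        list(ID = list(mass = 40, charge = 0, epsilon = 0)),
        list(ideal = monatomic_molecule("ID", "ideal")))
      tpls <- rep(list(ff$molecules$ideal), n)
      top <- assemble_topology(place_on_grid(tpls, box, jitter = args$jitter %||% 0.3),
                               box, ff)
      list(topology = top, ff = ff)
    },
    nacl_lattice = {
      a <- args$a %||% 5.64
      ff <- make_forcefield(
        list("NA" = list(mass = 22.990, charge = 1, epsilon = 0),
             CL = list(mass = 35.453, charge = -1, epsilon = 0)),
        list(na = monatomic_molecule("NA", "na"),
             cl = monatomic_molecule("CL", "cl")))
      frac <- as.matrix(expand.grid(0:1, 0:1, 0:1)) / 2
      parity <- rowSums(frac * 2) %% 2
      stamps <- lapply(seq_len(8), function(i)
        stamp_template(if (parity[i] == 0) ff$molecules$na else ff$molecules$cl,
                       frac[i, ] * a))
      top <- assemble_topology(stamps, rep(a, 3), ff)
      list(topology = top, ff = ff, nn_dist = a / 2)
    },
    harmonic_dimer = {
      k <- args$spring_k %||% 10; r0 <- args$r0 %||% 3.0
      stretch <- args$stretch %||% 0.3
      mass <- args$mass %||% 15
      box <- rep(args$box %||% 50, 3)
      ff <- make_forcefield(
        list(DA = list(mass = mass, charge = 0, epsilon = 0)),
        list(dimer = list(
          species = "dimer",
          sites = list(list(id = "A", type = "DA"), list(id = "B", type = "DA")),
          coords = list(A = c(0, 0, 0), B = c(r0, 0, 0)),
          bonds = list(list(ij = list("A", "B"), k = k)))))
      st <- stamp_template(ff$molecules$dimer, box / 2)
      top <- assemble_topology(list(st), box, ff)
      # stretch along the bond
      top$pos[2, 1] <- top$pos[2, 1] + stretch
      list(topology = top, ff = ff, k = k, r0 = r0, mass = mass,
           stretch = stretch)
    },
    mie_fluid = {
      n <- args$n %||% 100L
      density <- args$density %||% 0.008  # number density, sites per A^3
      ff <- make_forcefield(
        list(LJ = list(mass = 50, charge = 0, epsilon = args$epsilon %||% 0.3,
                       n = 9, m = 6, r0 = args$r0 %||% 4.7)),
        list(lj = monatomic_molecule("LJ", "lj")))
      box <- rep(args$box %||% (n / density)^(1 / 3), length.out = 3)
      tpls <- rep(list(ff$molecules$lj), n)
      top <- assemble_topology(place_on_grid(tpls, box), box, ff)
      list(topology = top, ff = ff)
    },
    il_box = {
      n_pairs <- args$n_pairs %||% 64L
      dens <- args$density %||% 0.80
      ff <- args$ff %||% default_forcefield()
      top <- build_lattice(c(bmim = n_pairs, chloride = n_pairs), ff,
                           target_density = dens, seed = seed)
      list(topology = top, ff = ff)
    },
    mini_fiber = {
      n_chains <- args$n_chains %||% 4L
      n_units <- args$n_units %||% 4L
      n_il <- args$n_il %||% 200L
      n_water <- args$n_water %||% 270L
      dens <- args$density %||% 0.62
      ff <- args$ff %||% default_forcefield()
      mass <- n_chains * n_units * 324.28 + n_il * 174.673 + n_water * 18.015
      edge <- (mass / (cg_constants$avogadro_dens * dens))^(1 / 3)
      fib <- build_fiber(n_chains, n_units, ff = ff)
      top <- solvate(fib, n_il, n_water, rep(edge, 3), ff = ff, seed = seed)
      list(topology = top, ff = ff,
           counts = c(chains = n_chains, il = n_il, water = n_water))
    })
  out$kind <- kind
  out$seed <- seed
  structure(out, class = "cg_fixture")
}
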