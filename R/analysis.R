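#' Time series of a scalar observable
#'
#' @param times sample times, ps, strictly increasing.
#' @param values observable values (volume, energy, density, ...).
#' @param label observable name.
#' @return An `observable_series` object.
#' @export
observable_series <- function(times, values, label = "observable") {
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values, label = label),
            class = "observable_series")
}

#' Detect the equilibration point of an observable series
#'
#' Scans candidate production starts (a grid over the first half of the
#' series) and returns the first index after which the remaining data are
#' statistically flat: the two halves of the remaining window have means
#' closer than `threshold` times the standard deviation of the later
#' (reference) half. Using the later half as the scale keeps a residual
#' transient in the earlier half from inflating the tolerance. A series
#' that drifts to the end is flagged, not an error.
#'
#' @param series an [observable_series()], or a numeric vector.
#' @param threshold flatness threshold in reference-block standard deviations.
#' @return Integer index (1-based) of the first production sample, with
#'   attribute `equilibrated` (logical). For a never-flat series the index
#'   is `length(series)` and `equilibrated` is FALSE.
#' @export
detect_equilibration <- function(series, threshold = 1.0) {
  x <- if (inherits(series, "observable_series")) series$values else series
  n <- length(x)
  if (n < 20) stop("need at least 20 samples to detect equilibration")
  starts <- unique(pmax(1L, as.integer(floor(seq(0, 0.5, by = 0.025) * n)) + 1L))
  for (s in starts) {
    rest <- x[s:n]
    h <- length(rest) %/% 2
    a <- rest[seq_len(h)]; b <- rest[(h + 1):length(rest)]
    sd_ref <- stats::sd(b)
    if (!is.finite(sd_ref)) sd_ref <- 0
    if (abs(mean(a) - mean(b)) <= threshold * sd_ref + 1e-300) {
      return(structure(s, equilibrated = TRUE))
    }
  }
  structure(n, equilibrated = FALSE)
}

#' Average density with uncertainty from an NPT run
#'
#' Density is total mass over the average volume after equilibration; the
#' uncertainty is propagated from the standard deviation of the volumes.
#'
#' @param observables data.frame with a `V` column (Angstrom^3), e.g. from
#'   [run_md()]; rows before `eq_index` are discarded.
#' @param topology the simulated [cg_topology] (for the total mass).
#' @param eq_index first production row (e.g. from [detect_equilibration()]).
#' @param T_label temperature attached to the report (default: mean of the
#'   `T` column if present).
#' @param rho_ref optional reference density, g/cm^3; adds an `mabd` field.
#' @return A `density_report`: list(T, rho_md, rho_err, rho_ref, mabd).
#' @export
average_density <- function(observables, topology, eq_index = 1L,
                            T_label = NULL, rho_ref = NULL) {
  V <- observables$V
  if (is.null(V)) stop("observables must contain a V column")
  if (eq_index < 1 || eq_index > length(V))
    stop("empty post-equilibration window")
  V <- V[eq_index:length(V)]
  mass <- sum(topology$mass)
  rho <- mass / (cg_constants$avogadro_dens * mean(V))
  rho_err <- rho * stats::sd(V) / mean(V)
  if (is.na(rho_err)) rho_err <- 0
  if (is.null(T_label))
    T_label <- if (!is.null(observables$T))
      mean(observables$T[eq_index:nrow(observables)]) else NA_real_
  rep <- structure(list(T = T_label, rho_md = rho, rho_err = rho_err,
                        rho_ref = rho_ref, mabd = NULL),
                   class = "density_report")
  if (!is.null(rho_ref)) rep$mabd <- mabd(rho, rho_ref)
  rep
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("density_report: T = %.2f K, rho = %.4f +/- %.4f g/cm^3",
              x$T, x$rho_md, x$rho_err))
  if (!is.null(x$rho_ref))
    cat(sprintf(", ref = %.4f (MABD %.2f%%)", x$rho_ref, x$mabd))
  cat("\n")
  invisible(x)
}

#' Mean absolute percentage deviation between simulated and reference values
#'
#' Per-element deviation is `100 * |md - ref| / md` (note the simulated value
#' in the denominator, which makes the measure intentionally asymmetric);
#' vectors are averaged.
#'
#' @param rho_md simulated value(s), > 0.
#' @param rho_ref reference value(s), > 0.
#' @return Percentage (scalar).
#' @export
mabd <- function(rho_md, rho_ref) {
  if (any(rho_md <= 0) || any(rho_ref <= 0)) stop("mabd: inputs must be > 0")
  mean(100 * abs(rho_md - rho_ref) / rho_md)
}

#' Site-site radial distribution function
#'
#' Standard pair-count estimator: per-frame pair separations within `rmax`
#' are histogrammed and normalised by the ideal-gas shell expectation
#' `N_a N_b / V * 4/3 pi (r2^3 - r1^3)` (`N (N-1) / 2` for identical types,
#' with unordered pairs counted once) and the number of frames. Distinct
#' type pairs are counted once per unordered pair.
#'
#' @param frames list of frames (`list(pos, box, ...)`) from [run_md()] /
#'   [run_protocol()] / [read_trajectory()].
#' @param topology the matching [cg_topology].
#' @param type_a,type_b site type labels.
#' @param dr bin width, Angstrom.
#' @param rmax maximum distance (default: half the smallest box edge of the
#'   first frame).
#' @return An `rdf_result`: list(pair, r, g, counts, n_frames, dr, rmax).
#' @export
rdf <- function(frames, topology, type_a, type_b, dr = 0.1, rmax = NULL) {
  if (!length(frames)) stop("no frames")
  sel_a <- which(topology$type == type_a)
  sel_b <- which(topology$type == type_b)
  if (!length(sel_a)) stop("no sites of type ", type_a)
  if (!length(sel_b)) stop("no sites of type ", type_b)
  same <- identical(type_a, type_b)
  if (is.null(rmax)) rmax <- min(frames[[1]]$box) / 2
  if (rmax > min(frames[[1]]$box) / 2 + 1e-9)
    stop("rmax exceeds half the smallest box edge")
  nbin <- floor(rmax / dr)
  edges <- (0:nbin) * dr
  counts <- numeric(nbin)
  ideal <- numeric(nbin)
  npair <- if (same) length(sel_a) * (length(sel_a) - 1) / 2
           else length(sel_a) * length(sel_b)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  for (f in frames) {
    d <- cg_pair_distances(f$pos, f$box, sel_a - 1L, sel_b - 1L,
                           nbin * dr, same)
    if (length(d))
      counts <- counts + tabulate(pmin(nbin, floor(d / dr) + 1L), nbins = nbin)
    ideal <- ideal + npair / prod(f$box) * shell_vol
  }
  structure(list(pair = c(type_a, type_b),
                 r = edges[-1] - dr / 2,
                 g = ifelse(ideal > 0, counts / ideal, 0),
                 counts = counts, n_frames = length(frames),
                 dr = dr, rmax = nbin * dr),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  pk <- which.max(x$g)
  cat(sprintf("rdf_result %s-%s: %d bins to %.1f A over %d frames; first max g = %.2f at r = %.2f A\n",
              x$pair[1], x$pair[2], length(x$r), x$rmax, x$n_frames,
              x$g[pk], x$r[pk]))
  invisible(x)
}

#' Height and position of the first RDF peak
#'
#' @param x an `rdf_result`.
#' @param r_window optional c(min, max) search window, Angstrom.
#' @return Named vector c(r, g).
#' @export
rdf_first_peak <- function(x, r_window = NULL) {
  sel <- if (is.null(r_window)) seq_along(x$r)
         else which(x$r >= r_window[1] & x$r <= r_window[2])
  k <- sel[which.max(x$g[sel])]
  c(r = x$r[k], g = x$g[k])
}

#' Tabulate densities across temperatures
#'
#' @param reports list of `density_report` objects (>= 2 temperatures).
#' @return data.frame sorted by temperature with columns T, rho_md, rho_err,
#'   rho_ref, mabd; attribute `monotonic_decreasing` flags whether the MD
#'   densities decrease with temperature.
#' @export
density_vs_temperature <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 temperatures")
  Ts <- vapply(reports, function(r) r$T, 0)
  if (anyDuplicated(Ts)) stop("duplicate temperatures")
  o <- order(Ts)
  df <- data.frame(
    T = Ts[o],
    rho_md = vapply(reports, function(r) r$rho_md, 0)[o],
    rho_err = vapply(reports, function(r) r$rho_err, 0)[o],
    rho_ref = vapply(reports, function(r) r$rho_ref %||% NA_real_, 0)[o]
  )
  df$mabd <- ifelse(is.na(df$rho_ref), NA_real_,
                    100 * abs(df$rho_md - df$rho_ref) / df$rho_md)
  attr(df, "monotonic_decreasing") <- all(diff(df$rho_md) < 0)
  df
}

#' Reference liquid densities of [bmim][Cl]
#'
#' The packaged comparison table: reported coarse-grained simulation
#' densities and experimental literature densities (g/cm^3) at four
#' temperatures, as shipped in `extdata/bmimcl_density_reference.csv`.
#'
#' @return data.frame with columns T, rho_md_reported, rho_exp.
#' @export
reference_densities <- function() {
  utils::read.csv(system.file("extdata", "bmimcl_density_reference.csv",
                              package = "cgmie", mustWork = TRUE))
}
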