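#' Mie n-m pair potential parameters
#'
#' The Mie potential generalises the Lennard-Jones form to arbitrary repulsive
#' (n) and attractive (m) exponents:
#' \deqn{U(r) = \frac{\epsilon}{n-m}\left(m\,(r_0/r)^n - n\,(r_0/r)^m\right)}
#' where \eqn{\epsilon} is the well depth and \eqn{r_0} the position of the
#' minimum, so that \eqn{U(r_0) = -\epsilon} exactly. The collision diameter
#' \eqn{\sigma} (where U crosses zero) is related to \eqn{r_0} by
#' \eqn{r_0 = \sigma (n/m)^{1/(n-m)}}.
#'
#' Exactly one of `r0` and `sigma` must be given; the other is derived.
#'
#' @param epsilon well depth, kcal/mol (> 0).
#' @param n repulsive exponent (> m).
#' @param m attractive exponent (>= 1).
#' @param r0 distance of the minimum, Angstrom.
#' @param sigma collision diameter, Angstrom.
#' @return An object of class `mie_params`.
#' @examples
#' p <- mie_params(0.375, 9, 6, r0 = 4.693)
#' mie_energy(p$r0, p)   # -epsilon
#' @export
mie_params <- function(epsilon, n, m, r0 = NULL, sigma = NULL) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L)
  if (epsilon <= 0) stop("mie_params: epsilon must be > 0")
  if (!(n > m && m >= 1)) stop("mie_params: require n > m >= 1")
  if (is.null(r0) == is.null(sigma))
    stop("mie_params: give exactly one of r0, sigma")
  if (is.null(r0)) r0 <- r0_from_sigma(sigma, n, m)
  if (is.null(sigma)) sigma <- sigma_from_r0(r0, n, m)
  if (r0 <= 0) stop("mie_params: r0 must be > 0")
  # consistency of the pair (guards hand-constructed objects)
  if (abs(r0 - r0_from_sigma(sigma, n, m)) > 1e-10 * r0)
    stop("mie_params: r0/sigma inconsistent with the exponents")
  structure(list(epsilon = epsilon, n = n, m = m, r0 = r0, sigma = sigma),
            class = "mie_params")
}

#' @export
print.mie_params <- function(x, ...) {
  cat(sprintf("Mie %g-%g: epsilon = %g kcal/mol, r0 = %g A (sigma = %g A)\n",
              x$n, x$m, x$epsilon, x$r0, x$sigma))
  invisible(x)
}

#' Position of the Mie minimum from the collision diameter
#'
#' \eqn{r_0 = \sigma (n/m)^{1/(n-m)}}. Inverse of [sigma_from_r0()].
#'
#' @param sigma collision diameter, Angstrom (> 0).
#' @param n,m Mie exponents, n != m, both > 0.
#' @return r0 in Angstrom.
#' @export
r0_from_sigma <- function(sigma, n, m) {
  check_exponents(n, m)
  stopifnot(all(sigma > 0))
  sigma * (n / m)^(1 / (n - m))
}

#' Collision diameter from the position of the Mie minimum
#'
#' @param r0 distance of the minimum, Angstrom (> 0).
#' @inheritParams r0_from_sigma
#' @return sigma in Angstrom.
#' @export
sigma_from_r0 <- function(r0, n, m) {
  check_exponents(n, m)
  stopifnot(all(r0 > 0))
  r0 / (n / m)^(1 / (n - m))
}

check_exponents <- function(n, m) {
  if (any(n == m)) stop("degenerate Mie exponents: n must differ from m")
  if (any(n <= 0) || any(m <= 0)) stop("Mie exponents must be > 0")
  invisible(TRUE)
}

#' Mie pair energy
#'
#' Vectorised over `r`.
#'
#' @param r separation(s), Angstrom, all > 0.
#' @param p a [mie_params()] object.
#' @return Energy in kcal/mol.
#' @export
mie_energy <- function(r, p) {
  if (any(r <= 0)) stop("mie_energy: r must be > 0")
  with(p, epsilon / (n - m) * (m * (r0 / r)^n - n * (r0 / r)^m))
}

#' Mie pair energy and analytic radial force
#'
#' The force is \eqn{-dU/dr}; positive values push the pair apart.
#'
#' @inheritParams mie_energy
#' @return List with `energy` and `force` (kcal/mol/Angstrom), both vectorised.
#' @export
mie_energy_force <- function(r, p) {
  if (any(r <= 0)) stop("mie_energy_force: r must be > 0")
  sn <- (p$r0 / r)^p$n
  sm <- (p$r0 / r)^p$m
  C <- p$epsilon / (p$n - p$m)
  list(energy = C * (p$m * sn - p$n * sm),
       force  = C * p$n * p$m * (sn - sm) / r)
}

#' Lorentz-Berthelot mixing for Mie site types
#'
#' Cross parameters between two site types: arithmetic mean of the collision
#' diameters, geometric mean of the well depths. Lorentz-Berthelot does not
#' define cross exponents; for unlike exponent pairs the rule is selectable:
#' `"arithmetic"` (default) takes the arithmetic mean of each exponent rounded
#' to the nearest integer not below m+1, `"fixed"` uses `fixed_exponents`.
#' The returned `r0` is recomputed from the mixed sigma and exponents.
#'
#' @param a,b [site_type()] objects (or `mie_params` directly).
#' @param rule `"arithmetic"` or `"fixed"`.
#' @param fixed_exponents length-2 c(n, m) used when `rule = "fixed"`.
#' @return A `mie_params` object for the cross interaction.
#' @export
mix_params <- function(a, b, rule = c("arithmetic", "fixed"),
                       fixed_exponents = c(9, 6)) {
  rule <- match.arg(rule)
  pa <- if (inherits(a, "site_type")) a$self_params else a
  pb <- if (inherits(b, "site_type")) b$self_params else b
  if (is.null(pa) || is.null(pb))
    stop("mix_params: a site without Mie interaction cannot be mixed")
  sigma <- (pa$sigma + pb$sigma) / 2
  eps <- sqrt(pa$epsilon * pb$epsilon)
  if (rule == "arithmetic") {
    m <- round((pa$m + pb$m) / 2)
    n <- max(round((pa$n + pb$n) / 2), m + 1)
  } else {
    n <- fixed_exponents[1]; m <- fixed_exponents[2]
  }
  mie_params(eps, n, m, sigma = sigma)
}
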