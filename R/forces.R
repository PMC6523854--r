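#' Ewald summation configuration
#'
#' @param alpha convergence (screening) parameter, 1/Angstrom.
#' @param kmax three integers: reciprocal-lattice limits per axis.
#' @param real_cutoff real-space cutoff, Angstrom.
#' @return An `ewald_config` object.
#' @export
ewald_config <- function(alpha = 0.18520, kmax = c(8L, 8L, 16L),
                         real_cutoff = 15) {
  if (alpha <= 0) stop("ewald_config: alpha must be > 0")
  kmax <- as.integer(rep(kmax, length.out = 3))
  if (any(kmax < 1)) stop("ewald_config: kmax components must be >= 1")
  structure(list(alpha = alpha, kmax = kmax, real_cutoff = real_cutoff),
            class = "ewald_config")
}

# kmax sufficient for relative reciprocal truncation ~delta at this box
auto_kmax <- function(alpha, box, delta = 1e-5) {
  kcut <- 2 * alpha * sqrt(log(1 / delta))
  pmax(1L, as.integer(ceiling(kcut * box / (2 * pi))))
}

#' Ewald electrostatic energy and forces
#'
#' Splits the periodic Coulomb sum into a short-range erfc-screened real-space
#' part, a reciprocal-space sum over k-vectors and the self-energy. The
#' system must be charge-neutral and the real-space cutoff must fit the box.
#'
#' @param pos N x 3 positions, Angstrom.
#' @param charges length-N charges, e.
#' @param box length-3 box edges.
#' @param cfg an [ewald_config()].
#' @return List with `real`, `recip`, `self`, `total` energies (kcal/mol),
#'   `forces` (N x 3, kcal/mol/Angstrom) and `virial`.
#' @export
ewald_energy_forces <- function(pos, charges, box, cfg = ewald_config()) {
  box <- rep(as.numeric(box), length.out = 3)
  if (abs(sum(charges)) > 1e-8)
    stop("Ewald requires a charge-neutral system (net charge ",
         signif(sum(charges), 3), ")")
  if (cfg$real_cutoff > min(box) / 2)
    stop("real-space cutoff exceeds half the shortest box edge")
  n <- nrow(pos)
  if (all(charges == 0)) {
    return(list(real = 0, recip = 0, self = 0, total = 0,
                forces = matrix(0, n, 3), virial = 0))
  }
  zero1 <- matrix(0, 1, 1)
  pairs <- cg_nblist(pos, box, cfg$real_cutoff)
  pr <- cg_pair_forces(pos, box, integer(n), charges,
                       zero1, zero1 + 9, zero1 + 6, zero1 + 1, zero1, zero1,
                       cfg$real_cutoff, 0L, pairs,
                       matrix(0L, 0, 2), matrix(0L, 0, 2), 1.0,
                       TRUE, cfg$alpha, cg_constants$coulomb, 1e-6)
  rec <- cg_ewald_recip(pos, charges, box, cfg$alpha, cfg$kmax,
                        cg_constants$coulomb)
  e_self <- -cg_constants$coulomb * cfg$alpha / sqrt(pi) * sum(charges^2)
  list(real = pr$e_real, recip = rec$energy, self = e_self,
       total = pr$e_real + rec$energy + e_self,
       forces = pr$forces + rec$forces,
       virial = pr$virial + rec$virial)
}

# ---- nonbonded exclusions ---------------------------------------------------

# 1-2/1-3 exclusions (policy "1-3") or 1-2 only, plus full exclusion of the
# three intramolecular pairs of each rigid water; 1-4 pairs listed separately
# for scaling. Returns 1-based pair matrices.
bonded_exclusions <- function(topology, policy = "1-3") {
  n <- nrow(topology$pos)
  adj <- vector("list", n)
  b <- topology$bonds
  if (nrow(b)) for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  pairs12 <- pairs13 <- pairs14 <- NULL
  add <- function(store, i, j) rbind(store, cbind(pmin(i, j), pmax(i, j)))
  for (i in seq_len(n)) {
    n1 <- adj[[i]]
    if (is.null(n1)) next
    n2 <- setdiff(unique(unlist(adj[n1])), c(i, n1))
    n3 <- setdiff(unique(unlist(adj[c(n1, n2)])), c(i, n1, n2))
    pairs12 <- add(pairs12, i, n1[n1 > i])
    pairs13 <- add(pairs13, i, n2[n2 > i])
    pairs14 <- add(pairs14, i, n3[n3 > i])
  }
  excl <- switch(policy,
    "1-2" = pairs12,
    "1-3" = rbind(pairs12, pairs13),
    stop("unknown exclusion policy: ", policy))
  # rigid waters: exclude all three intramolecular pairs
  w <- topology$waters
  if (nrow(w)) {
    excl <- rbind(excl,
                  cbind(pmin(w[, 1], w[, 2]), pmax(w[, 1], w[, 2])),
                  cbind(pmin(w[, 1], w[, 3]), pmax(w[, 1], w[, 3])),
                  cbind(pmin(w[, 2], w[, 3]), pmax(w[, 2], w[, 3])))
  }
  dedupe <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(matrix(0L, 0, 2))
    m <- unique(m)
    matrix(as.integer(m), ncol = 2)
  }
  excl <- dedupe(excl)
  pairs14 <- dedupe(pairs14)
  # a pair both excluded and 1-4 (rings): exclusion wins
  if (nrow(pairs14) && nrow(excl)) {
    ke <- excl[, 1] * (n + 1) + excl[, 2]
    k4 <- pairs14[, 1] * (n + 1) + pairs14[, 2]
    pairs14 <- pairs14[!(k4 %in% ke), , drop = FALSE]
  }
  list(excl = excl, pairs14 = pairs14)
}

# ---- system compilation -----------------------------------------------------

#' Compile a topology + force field into a simulation-ready system
#'
#' Precomputes mixed pair tables, truncation shifts, exclusion lists, Ewald
#' settings, long-range (tail) correction coefficients and the Verlet
#' neighbour-list bookkeeping.
#'
#' @param topology a [cg_topology].
#' @param ff force field registry.
#' @param cutoff nonbonded cutoff, Angstrom (default 15).
#' @param ewald use Ewald electrostatics (default: TRUE if any site charged).
#' @param alpha Ewald convergence parameter, 1/Angstrom; `NULL` picks
#'   `2.78 / cutoff` (0.185 at the default 15 Angstrom cutoff), keeping the
#'   real-space truncation error uniform across cutoffs.
#' @param kmax reciprocal limits; `NULL` sizes them from alpha and the box.
#' @param truncation Mie truncation scheme: `"shift"` (energy shifted to
#'   zero at the cutoff, the default), `"shift-force"` (energy and force both
#'   continuous at the cutoff; use for strict NVE energy-conservation work) or
#'   `"none"` (plain truncation).
#' @param tail_correction add analytic Mie tail corrections to energy and
#'   virial (default TRUE; assumes a homogeneous fluid beyond the cutoff).
#' @param skin Verlet-list skin, Angstrom.
#' @return A `cg_system` object used by [total_energy_forces()] and the
#'   integrators.
#' @export
compile_system <- function(topology, ff = default_forcefield(),
                           cutoff = 15, ewald = NULL,
                           alpha = NULL, kmax = NULL,
                           truncation = c("shift", "shift-force", "none"),
                           tail_correction = TRUE,
                           skin = 2.0) {
  truncation <- match.arg(truncation)
  if (cutoff > min(topology$box) / 2)
    stop("cutoff ", cutoff, " A exceeds half the shortest box edge (",
         round(min(topology$box) / 2, 2), " A)")
  pt <- ff$pair_table
  tidx <- match(topology$type, pt$names)
  if (anyNA(tidx)) stop("topology uses site types absent from the force field")
  if (is.null(ewald)) ewald <- any(topology$charge != 0)
  if (is.null(alpha)) alpha <- 2.78 / cutoff
  if (ewald && abs(sum(topology$charge)) > 1e-8)
    stop("Ewald requires charge neutrality; net charge = ",
         signif(sum(topology$charge), 4))
  if (is.null(kmax)) kmax <- auto_kmax(alpha, topology$box)
  ex <- bonded_exclusions(topology, ff$exclusions$policy)

  # tail-correction coefficients: U_tail = K_U / V, W_tail = K_W / V
  K_U <- K_W <- 0
  if (tail_correction) {
    cnt <- table(factor(topology$type, levels = pt$names))
    nz <- which(cnt > 0)
    for (a in nz) for (b in nz) {
      eps <- pt$eps[a, b]
      if (eps <= 0) next
      nn <- pt$n[a, b]; mm <- pt$m[a, b]; r0 <- pt$r0[a, b]
      C <- eps / (nn - mm)
      In <- r0^nn * cutoff^(3 - nn) / (nn - 3)
      Im <- r0^mm * cutoff^(3 - mm) / (mm - 3)
      I_u <- C * (mm * In - nn * Im)
      J <- -C * nn * mm * (In - Im)
      K_U <- K_U + 2 * pi * cnt[a] * cnt[b] * I_u
      K_W <- K_W - 2 * pi * cnt[a] * cnt[b] * J
    }
  }

  nb <- new.env(parent = emptyenv())
  nb$pairs <- NULL; nb$ref_pos <- NULL

  structure(list(
    topology = topology, ff = ff,
    type0 = tidx - 1L,
    charges = topology$charge,
    pt = pt, shiftM = pair_shift_matrix(pt, cutoff),
    fshiftM = pair_fshift_matrix(pt, cutoff),
    cutoff = cutoff,
    trunc_mode = match(truncation, c("none", "shift", "shift-force")) - 1L,
    use_ewald = ewald, alpha = alpha, kmax = as.integer(kmax),
    excl0 = ex$excl - 1L, pairs14_0 = ex$pairs14 - 1L,
    scale14 = ff$exclusions$scale14,
    K_U = as.numeric(K_U), K_W = as.numeric(K_W),
    skin = skin, nb = nb,
    bonds0 = shift_index(topology$bonds, 2),
    bends0 = shift_index(topology$bends, 3),
    dihs0 = shift_index(topology$dihedrals, 4),
    waters0 = if (nrow(topology$waters)) topology$waters - 1L else
      matrix(0L, 0, 3),
    ndof = n_dof(topology)
  ), class = "cg_system")
}

shift_index <- function(m, k) {
  if (nrow(m) == 0) return(m)
  m[, seq_len(k)] <- m[, seq_len(k)] - 1
  m
}

update_nblist <- function(sys, pos, box) {
  nb <- sys$nb
  rebuild <- is.null(nb$pairs)
  if (!rebuild) {
    disp <- abs(pos - nb$ref_pos)
    if (max(disp) > sys$skin / 2) rebuild <- TRUE
  }
  if (rebuild) {
    nb$pairs <- cg_nblist(pos, box, sys$cutoff + sys$skin)
    nb$ref_pos <- pos
  }
  nb$pairs
}

#' Total potential energy and forces with decomposition
#'
#' Evaluates every term of the force field at the given configuration:
#' Mie pairs (with cutoff, optional shift and tail correction), Ewald
#' electrostatics (real, reciprocal, self) and bonded terms. The forces are
#' the exact analytic negative gradient of the returned total energy, and the
#' decomposition sums to the total exactly.
#'
#' @param sys a compiled `cg_system` from [compile_system()].
#' @param pos positions (defaults to the topology's build positions).
#' @param box box edges (defaults to the topology's box).
#' @return List with `energies` (named: mie, coulomb_real, coulomb_recip,
#'   coulomb_self, bond, bend, dihedral), `total`, `forces` (N x 3) and the
#'   scalar `virial` (Tr of the virial tensor, so P = (2K + W)/(3V)).
#' @export
total_energy_forces <- function(sys, pos = sys$topology$pos,
                                box = sys$topology$box) {
  if (sys$cutoff > min(box) / 2)
    stop("cutoff exceeds half the shortest box edge during evaluation")
  pairs <- update_nblist(sys, pos, box)
  pr <- cg_pair_forces(pos, box, sys$type0, sys$charges,
                       sys$pt$eps, sys$pt$n, sys$pt$m, sys$pt$r0, sys$shiftM,
                       sys$fshiftM,
                       sys$cutoff, sys$trunc_mode, pairs,
                       sys$excl0, sys$pairs14_0, sys$scale14,
                       sys$use_ewald, sys$alpha, cg_constants$coulomb, 1e-6)
  V <- prod(box)
  e_tail <- sys$K_U / V
  w_tail <- sys$K_W / V
  if (sys$use_ewald) {
    rec <- cg_ewald_recip(pos, sys$charges, box, sys$alpha, sys$kmax,
                          cg_constants$coulomb)
    e_self <- -cg_constants$coulomb * sys$alpha / sqrt(pi) *
      sum(sys$charges^2)
  } else {
    rec <- list(energy = 0, forces = 0, virial = 0)
    e_self <- 0
  }
  bd <- cg_bonded(pos, box, sys$bonds0, sys$bends0, sys$dihs0)
  energies <- c(
    mie = pr$e_mie + e_tail,
    coulomb_real = pr$e_real + pr$e_corr,
    coulomb_recip = rec$energy,
    coulomb_self = e_self,
    bond = bd$e_bond, bend = bd$e_bend, dihedral = bd$e_dih
  )
  forces <- pr$forces + bd$forces
  if (sys$use_ewald) forces <- forces + rec$forces
  list(energies = energies, total = sum(energies),
       forces = forces,
       virial = pr$virial + rec$virial + bd$virial + w_tail)
}

#' Bonded energy and forces only
#'
#' Harmonic bonds and bends, cosine dihedrals; forces are analytic gradients.
#'
#' @param topology a [cg_topology].
#' @param pos positions (defaults to topology positions).
#' @return List with `e_bond`, `e_bend`, `e_dih`, `forces`, `virial`.
#' @export
bonded_energy_forces <- function(topology, pos = topology$pos) {
  cg_bonded(pos, topology$box,
            shift_index(topology$bonds, 2),
            shift_index(topology$bends, 3),
            shift_index(topology$dihedrals, 4))
}
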