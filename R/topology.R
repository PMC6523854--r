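#' Coarse-grained topology
#'
#' A `cg_topology` bundles everything static about a system: site types,
#' masses, charges, molecule membership, positions, the orthorhombic box and
#' the bonded term lists. Builders ([build_bmimcl()], [build_cellulose_chain()],
#' [build_fiber()], [solvate()], [build_lattice()]) return this class.
#'
#' Fields: `type` (character, per site), `mass`, `charge` (numeric, per site),
#' `mol_id` (integer, per site), `mol_species` (character, per molecule),
#' `pos` (N x 3), `box` (length 3), `bonds` (i, j, k, r0), `bends`
#' (i, j, k, ktheta, theta0), `dihedrals` (i, j, k, l, amp, mult, delta),
#' `waters` (nw x 3 matrix of O, H1, H2 site indices). All indices 1-based.
#'
#' @name cg_topology
NULL

new_topology <- function(type, mass, charge, mol_id, mol_species, pos, box,
                         bonds, bends, dihedrals, waters) {
  structure(list(
    type = type, mass = mass, charge = charge,
    mol_id = as.integer(mol_id), mol_species = mol_species,
    pos = pos, box = as.numeric(box),
    bonds = bonds, bends = bends, dihedrals = dihedrals,
    waters = waters
  ), class = "cg_topology")
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(paste0("cg_topology: %d sites, %d molecules, box %.2f x %.2f x",
                     " %.2f A\n  bonds %d, bends %d, dihedrals %d, waters %d\n"),
              nrow(x$pos), length(x$mol_species),
              x$box[1], x$box[2], x$box[3],
              NROW(x$bonds), NROW(x$bends), NROW(x$dihedrals), NROW(x$waters)))
  tab <- table(x$mol_species)
  cat("  composition:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Total charge of a topology
#' @param topology a `cg_topology`.
#' @return Sum of site charges, elementary charges.
#' @export
total_charge <- function(topology) sum(topology$charge)

empty_terms <- function() list(
  bonds = matrix(0, 0, 4, dimnames = list(NULL, c("i", "j", "k", "r0"))),
  bends = matrix(0, 0, 5, dimnames = list(NULL, c("i", "j", "k", "ktheta", "theta0"))),
  dihedrals = matrix(0, 0, 7, dimnames = list(NULL, c("i", "j", "k", "l", "amp", "mult", "delta")))
)

# ---- template expansion and stamping ---------------------------------------

# Expand a repeat template into a single-molecule chain template of n_units.
# Spanning terms of the last unit (those that reference the next unit) are
# dropped; every interior unit owns the full 7/4/8 bonded-term template.
make_chain_template <- function(tpl, n_units) {
  if (!isTRUE(tpl$repeats)) stop("template is not a repeat unit")
  if (n_units < 1) stop("n_units must be >= 1")
  ns <- tpl$n_sites
  types <- rep(tpl$site_types, n_units)
  coords <- do.call(rbind, lapply(seq_len(n_units), function(u)
    sweep(tpl$coords, 2, c(0, 0, (u - 1) * tpl$z_period), "+")))
  remap <- function(term_mat, n_idx) {
    if (is.null(term_mat)) return(NULL)
    out <- NULL
    for (u in seq_len(n_units)) {
      for (r in seq_len(nrow(term_mat))) {
        row <- term_mat[r, ]
        spans <- row[["spans"]] > 0
        if (spans && u == n_units) next
        idx <- row[seq_len(n_idx)]
        idx <- ifelse(idx > ns, u * ns + (idx - ns), (u - 1) * ns + idx)
        out <- rbind(out, c(idx, row[(n_idx + 1):(length(row) - 1)]))
      }
    }
    out
  }
  list(species = tpl$species, rigid = tpl$rigid,
       site_types = types, n_sites = ns * n_units,
       coords = coords, repeats = FALSE,
       bonds = remap(tpl$bonds, 2),
       bends = remap(tpl$bends, 3),
       dihedrals = remap(tpl$dihedrals, 4))
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Stamp one molecule template at `shift` with rotation R and geometry scale.
stamp_template <- function(tpl, shift, R = diag(3), scale = 1) {
  ctr <- colMeans(tpl$coords)
  pos <- scale * sweep(tpl$coords, 2, ctr, "-") %*% t(R)
  pos <- sweep(pos, 2, shift, "+")
  list(tpl = tpl, pos = pos)
}

# Assemble a list of stamped molecules (+ per-molecule species) into a topology.
assemble_topology <- function(stamps, box, ff) {
  n_tot <- sum(vapply(stamps, function(s) nrow(s$pos), 0L))
  type <- character(n_tot); mol_id <- integer(n_tot)
  pos <- matrix(0, n_tot, 3)
  mol_species <- character(length(stamps))
  terms <- empty_terms()
  bonds_l <- list(); bends_l <- list(); dihs_l <- list(); waters_l <- list()
  off <- 0L
  for (mi in seq_along(stamps)) {
    s <- stamps[[mi]]; tpl <- s$tpl
    ns <- nrow(s$pos)
    idx <- off + seq_len(ns)
    type[idx] <- tpl$site_types
    mol_id[idx] <- mi
    pos[idx, ] <- s$pos
    mol_species[mi] <- tpl$species
    if (!is.null(tpl$bonds))
      bonds_l[[length(bonds_l) + 1L]] <-
        cbind(tpl$bonds[, 1:2, drop = FALSE] + off, tpl$bonds[, 3:4, drop = FALSE])
    if (!is.null(tpl$bends))
      bends_l[[length(bends_l) + 1L]] <-
        cbind(tpl$bends[, 1:3, drop = FALSE] + off, tpl$bends[, 4:5, drop = FALSE])
    if (!is.null(tpl$dihedrals))
      dihs_l[[length(dihs_l) + 1L]] <-
        cbind(tpl$dihedrals[, 1:4, drop = FALSE] + off, tpl$dihedrals[, 5:7, drop = FALSE])
    if (!is.na(tpl$rigid) && identical(tpl$rigid, "water"))
      waters_l[[length(waters_l) + 1L]] <- off + c(1L, 2L, 3L)
    off <- off + ns
  }
  props <- site_properties(ff, type)
  bonds <- if (length(bonds_l)) do.call(rbind, bonds_l) else terms$bonds
  bends <- if (length(bends_l)) do.call(rbind, bends_l) else terms$bends
  dihs <- if (length(dihs_l)) do.call(rbind, dihs_l) else terms$dihedrals
  colnames(bonds) <- c("i", "j", "k", "r0")
  colnames(bends) <- c("i", "j", "k", "ktheta", "theta0")
  colnames(dihs) <- c("i", "j", "k", "l", "amp", "mult", "delta")
  waters <- if (length(waters_l)) do.call(rbind, waters_l) else
    matrix(0L, 0, 3)
  new_topology(type, props$mass, props$charge, mol_id, mol_species, pos, box,
               bonds, bends, dihs, waters)
}

# Grid placement of whole molecules: molecules in `tpl_list` (one entry per
# molecule, in placement order) are dropped on a jittered cubic grid of
# centroids, with per-molecule random orientation. Template geometry is
# compressed when the grid pitch cannot accommodate the full molecule; the
# initial configuration only needs to respect the minimum separation, the
# equilibration stage relaxes it.
place_on_grid <- function(tpl_list, box, jitter = 0.3, min_sep = 0.8,
                          points = NULL) {
  M <- length(tpl_list)
  if (is.null(points)) {
    nc <- pmax(1L, as.integer(ceiling((M / prod(box))^(1 / 3) * box)))
    while (prod(nc) < M) {
      w <- which.max(box / nc)   # grow the dimension with the largest pitch
      nc[w] <- nc[w] + 1L
    }
    gx <- (seq_len(nc[1]) - 0.5) / nc[1] * box[1]
    gy <- (seq_len(nc[2]) - 0.5) / nc[2] * box[2]
    gz <- (seq_len(nc[3]) - 0.5) / nc[3] * box[3]
    points <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  }
  if (nrow(points) < M)
    stop("packing error: ", M, " molecules do not fit on ", nrow(points),
         " grid points")
  pitch <- min(dist_nearest_grid(points, box))
  stamps <- vector("list", M)
  for (k in seq_len(M)) {
    tpl <- tpl_list[[k]]
    rad <- max(sqrt(rowSums(sweep(tpl$coords, 2, colMeans(tpl$coords), "-")^2)))
    # compress so that even jittered nearest neighbours keep min_sep clearance
    scale <- if (rad > 0)
      min(1, (pitch - min_sep - 2 * jitter) / (2 * rad)) else 1
    if (scale <= 0.05)
      stop("packing error: grid pitch ", round(pitch, 2),
           " A too small for molecule of radius ", round(rad, 2), " A")
    shift <- points[k, ] + stats::runif(3, -jitter, jitter)
    stamps[[k]] <- stamp_template(tpl, shift, random_rotation(), scale)
  }
  stamps
}

# nearest-neighbour pitch of a centroid grid (min over a sample, PBC-aware)
dist_nearest_grid <- function(points, box) {
  m <- min(nrow(points), 20L)
  sel <- seq_len(m)
  out <- numeric(m)
  for (q in sel) {
    d <- sweep(points, 2, points[q, ], "-")
    d <- sweep(d, 2, box, function(x, L) x - L * round(x / L))
    r <- sqrt(rowSums(d^2))
    out[q] <- min(r[r > 1e-9], Inf)
  }
  out
}

# ---- builders ---------------------------------------------------------------

#' Build a box of [bmim][Cl] ion pairs
#'
#' Five sites per pair: a four-site connected cation (I3 methyl - I1 ring -
#' I2 ring - CT butyl tail) plus a single chloride site. Pairs are placed on
#' a jittered grid with alternating cation/anion assignment so every grid
#' neighbourhood is near-neutral.
#'
#' @param n_pairs number of ion pairs (>= 1).
#' @param box length-3 box edges in Angstrom.
#' @param ff force field (defaults to the packaged registry).
#' @param seed RNG seed for orientations and jitter.
#' @return A [cg_topology] with `5 * n_pairs` sites and zero net charge.
#' @export
build_bmimcl <- function(n_pairs, box, ff = default_forcefield(), seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  box <- rep(as.numeric(box), length.out = 3)
  set.seed(seed)
  tpls <- rep(list(ff$molecules$bmim, ff$molecules$chloride), n_pairs)
  stamps <- place_on_grid(tpls, box)
  top <- assemble_topology(stamps, box, ff)
  audit_min_separation(top)
  top
}

#' Build a linear coarse-grained cellulose chain
#'
#' Six sites per cellobiose repeat unit (C11, C14, C16 on the first glucose,
#' C21, C24, C26 on the second, named by the mapped ring carbon). Each
#' interior repeat unit owns 7 bonds, 4 bends and 8 dihedrals including the
#' glycosidic linkage into the next unit; the terminal unit drops the
#' unit-spanning terms.
#'
#' @param n_units number of cellobiose units (>= 1).
#' @param ff force field registry.
#' @param box optional box; defaults to the chain extent plus a 40 A margin.
#' @param origin chain start position.
#' @return A [cg_topology] with `6 * n_units` sites in one molecule.
#' @export
build_cellulose_chain <- function(n_units, ff = default_forcefield(),
                                  box = NULL, origin = NULL) {
  if (n_units < 1) stop("n_units must be >= 1")
  chain <- make_chain_template(ff$molecules$cellobiose, n_units)
  extent <- n_units * ff$molecules$cellobiose$z_period
  if (is.null(box)) box <- c(40, 40, extent + 40)
  if (is.null(origin)) origin <- box / 2
  st <- stamp_template(chain, origin)
  top <- assemble_topology(list(st), box, ff)
  audit_min_separation(top)
  top
}

#' Build a multi-chain cellulose fiber
#'
#' Parallel chains on a staggered two-row lattice ("I-alpha-like" packing:
#' the coarse-grained model keeps the chain packing motif, not the
#' crystallographic unit cell).
#'
#' @param n_chains number of chains (default 36).
#' @param n_units cellobiose units per chain (default 10).
#' @param spacing lattice spacing between chain axes, Angstrom.
#' @param ff force field registry.
#' @param box optional box (default sized to the fiber plus margin).
#' @return A [cg_topology] with `6 * n_units * n_chains` sites.
#' @export
build_fiber <- function(n_chains = 36, n_units = 10, spacing = 6.0,
                        ff = default_forcefield(), box = NULL) {
  if (n_chains < 1 || n_units < 1) stop("counts must be >= 1")
  chain <- make_chain_template(ff$molecules$cellobiose, n_units)
  extent <- n_units * ff$molecules$cellobiose$z_period
  nx <- ceiling(sqrt(n_chains))
  ny <- ceiling(n_chains / nx)
  width <- (nx + 0.5) * spacing
  height <- ny * spacing * sqrt(3) / 2
  if (is.null(box)) box <- c(width + 30, height + 30, extent + 30)
  ctr <- box / 2
  stamps <- list()
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (k >= n_chains) break
    k <- k + 1L
    x <- (ix - (nx + 1) / 2) * spacing + (iy %% 2) * spacing / 2
    y <- (iy - (ny + 1) / 2) * spacing * sqrt(3) / 2
    stamps[[k]] <- stamp_template(chain, ctr + c(x, y, 0))
  }
  top <- assemble_topology(stamps, box, ff)
  audit_min_separation(top)
  top
}

#' Solvate a fiber with ionic liquid and water
#'
#' The fiber is centred in the box; ionic-liquid pairs and water molecules
#' are placed on jittered grid positions outside an exclusion shell around
#' fiber sites, interleaved so the mixture is spatially uniform.
#'
#' @param fiber a [cg_topology] (typically from [build_fiber()]).
#' @param n_il_pairs number of [bmim][Cl] pairs.
#' @param n_water number of water molecules.
#' @param box length-3 box, Angstrom (must contain the fiber with margin).
#' @param shell exclusion shell radius around fiber sites, Angstrom.
#' @param ff force field registry.
#' @param seed RNG seed.
#' @return A [cg_topology] combining fiber, ionic liquid and water.
#' @export
solvate <- function(fiber, n_il_pairs, n_water, box,
                    shell = 3.0, ff = default_forcefield(), seed = 1L) {
  box <- rep(as.numeric(box), length.out = 3)
  if (any(apply(fiber$pos, 2, function(x) diff(range(x))) > box))
    stop("fiber does not fit the requested box")
  set.seed(seed)
  # recentre fiber
  shift <- box / 2 - colMeans(fiber$pos)
  fiber_pos <- sweep(fiber$pos, 2, shift, "+")

  n_solvent <- 2L * n_il_pairs + n_water
  if (n_solvent > 0) {
    # grid fine enough to host all solvent molecules outside the shell
    pitch <- (prod(box) / max(n_solvent * 1.7, 1))^(1 / 3)
    repeat {
      nc <- pmax(1L, as.integer(floor(box / pitch)))
      gx <- (seq_len(nc[1]) - 0.5) / nc[1] * box[1]
      gy <- (seq_len(nc[2]) - 0.5) / nc[2] * box[2]
      gz <- (seq_len(nc[3]) - 0.5) / nc[3] * box[3]
      pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
      keep <- outside_shell(pts, fiber_pos, box, shell)
      if (sum(keep) >= n_solvent || pitch < 2.0) break
      pitch <- pitch * 0.9
    }
    if (sum(keep) < n_solvent)
      stop("packing error: cannot place ", n_solvent,
           " solvent molecules outside the fiber shell")
    pts <- pts[keep, , drop = FALSE][sample.int(sum(keep), n_solvent), , drop = FALSE]
    tpls <- c(rep(list(ff$molecules$bmim, ff$molecules$chloride), n_il_pairs),
              rep(list(ff$molecules$water), n_water))
    stamps <- place_on_grid(tpls, box, points = pts)
  } else stamps <- list()

  solv <- if (length(stamps)) assemble_topology(stamps, box, ff) else NULL
  top <- bind_topologies(shift_topology(fiber, shift, box), solv, ff)
  audit_min_separation(top)
  top
}

outside_shell <- function(pts, ref, box, shell) {
  keep <- rep(TRUE, nrow(pts))
  s2 <- shell^2
  # chunked to bound memory
  idx <- split(seq_len(nrow(ref)), ceiling(seq_len(nrow(ref)) / 500))
  for (ch in idx) {
    sub <- ref[ch, , drop = FALSE]
    for (d in 1:3) {
      dd <- outer(pts[, d], sub[, d], "-")
      dd <- dd - box[d] * round(dd / box[d])
      if (d == 1) acc <- dd^2 else acc <- acc + dd^2
    }
    keep <- keep & (rowSums(acc < s2) == 0)
    if (!any(keep)) break
  }
  keep
}

shift_topology <- function(top, shift, box = top$box) {
  top$pos <- sweep(top$pos, 2, shift, "+")
  top$box <- box
  top
}

bind_topologies <- function(a, b, ff) {
  if (is.null(b)) { a$box <- a$box; return(a) }
  off <- nrow(a$pos); moff <- length(a$mol_species)
  shift_terms <- function(m, ncol_idx, off) {
    if (nrow(m) == 0) return(m)
    m[, seq_len(ncol_idx)] <- m[, seq_len(ncol_idx)] + off
    m
  }
  new_topology(
    c(a$type, b$type), c(a$mass, b$mass), c(a$charge, b$charge),
    c(a$mol_id, b$mol_id + moff), c(a$mol_species, b$mol_species),
    rbind(a$pos, b$pos), a$box,
    rbind(a$bonds, shift_terms(b$bonds, 2, off)),
    rbind(a$bends, shift_terms(b$bends, 3, off)),
    rbind(a$dihedrals, shift_terms(b$dihedrals, 4, off)),
    rbind(a$waters, if (nrow(b$waters)) b$waters + off else b$waters)
  )
}

#' Build a lattice of molecules at a target density
#'
#' Molecular centroids on a simple cubic lattice with seeded random
#' orientations; the starting point of the lattice-quench protocol.
#'
#' @param counts named integer vector of molecule counts, names matching
#'   molecule templates in the force field (e.g. `c(bmim = 64, chloride = 64)`).
#' @param ff force field registry.
#' @param target_density g/cm^3; used to size a cubic box unless `box` given.
#' @param box explicit box edges (overrides `target_density`).
#' @param seed RNG seed.
#' @return A [cg_topology].
#' @export
build_lattice <- function(counts, ff = default_forcefield(),
                          target_density = NULL, box = NULL, seed = 1L) {
  if (any(counts < 0) || sum(counts) < 1) stop("counts must be >= 1 in total")
  bad <- setdiff(names(counts), names(ff$molecules))
  if (length(bad)) stop("unknown molecule templates: ", paste(bad, collapse = ", "))
  set.seed(seed)
  tpls <- list()
  # interleave species for charge/composition uniformity
  order_idx <- order(unlist(lapply(seq_along(counts), function(i)
    seq_len(counts[i]) / (counts[i] + 1) + i * 1e-9)))
  expanded <- unlist(lapply(seq_along(counts), function(i)
    rep(names(counts)[i], counts[i])))[order_idx]
  tpls <- lapply(expanded, function(nm) ff$molecules[[nm]])
  if (is.null(box)) {
    if (is.null(target_density)) stop("give target_density or box")
    mass <- sum(vapply(tpls, function(t)
      sum(site_properties(ff, t$site_types)$mass), 0))
    V <- mass / (cg_constants$avogadro_dens * target_density)
    box <- rep(V^(1 / 3), 3)
  }
  box <- rep(as.numeric(box), length.out = 3)
  stamps <- place_on_grid(tpls, box)
  top <- assemble_topology(stamps, box, ff)
  audit_min_separation(top)
  top
}

# ---- audits -----------------------------------------------------------------

audit_min_separation <- function(top, min_sep = 0.5) {
  d <- cg_min_distance(top$pos, top$box)
  if (d < min_sep)
    stop("packing error: minimum site separation ", round(d, 3),
         " A below ", min_sep, " A")
  invisible(d)
}

#' Mass fraction of a species in a topology
#'
#' Site masses come from the force-field registry via the topology. Species
#' labels are molecule species (`"water"`, `"bmim"`, `"chloride"`,
#' `"cellulose"`) plus the composite `"bmimcl"` (cation + anion). The
#' denominator can be restricted, e.g. cellulose relative to cellulose + IL.
#'
#' @param topology a [cg_topology].
#' @param species species label.
#' @param relative_to `"total"` or a character vector of species labels
#'   forming the denominator.
#' @return Mass fraction in `[0, 1]`.
#' @export
mass_fraction <- function(topology, species, relative_to = "total") {
  expand <- function(s) if ("bmimcl" %in% s)
    unique(c(setdiff(s, "bmimcl"), "bmim", "chloride")) else s
  species_set <- expand(species)
  known <- unique(topology$mol_species)
  if (!any(species_set %in% known))
    stop("species not present in topology: ", species)
  site_species <- topology$mol_species[topology$mol_id]
  num <- sum(topology$mass[site_species %in% species_set])
  den <- if (identical(relative_to, "total")) sum(topology$mass)
         else sum(topology$mass[site_species %in% expand(relative_to)])
  num / den
}

#' Bonded-term counts per molecule and per template
#'
#' Returns the actual per-molecule counts in a topology together with the
#' per-repeat-unit template counts of the force field (for the cellulose
#' repeat unit the template owns the unit-spanning linkage terms, so the
#' per-unit convention counts 7 bonds, 4 bends, 8 dihedrals even though a
#' finite chain's terminal unit drops the spanning ones).
#'
#' @param topology a [cg_topology].
#' @return data.frame with one row per molecule: species, n_sites, bonds,
#'   bends, dihedrals.
#' @export
count_bonded_terms <- function(topology) {
  nmol <- length(topology$mol_species)
  count_by_mol <- function(m, idx_cols) {
    if (nrow(m) == 0) return(integer(nmol))
    tabulate(topology$mol_id[m[, 1]], nbins = nmol)
  }
  data.frame(
    molecule = seq_len(nmol),
    species = topology$mol_species,
    n_sites = tabulate(topology$mol_id, nbins = nmol),
    bonds = count_by_mol(topology$bonds, 2),
    bends = count_by_mol(topology$bends, 3),
    dihedrals = count_by_mol(topology$dihedrals, 4)
  )
}

#' Per-repeat-unit term counts of a repeat template
#'
#' @param ff force field registry.
#' @param molecule template name (default `"cellobiose"`).
#' @return Named integer vector: bonds, bends, dihedrals, sites.
#' @export
template_term_counts <- function(ff, molecule = "cellobiose") {
  tpl <- ff$molecules[[molecule]]
  if (is.null(tpl)) stop("unknown molecule template: ", molecule)
  c(sites = tpl$n_sites,
    bonds = NROW(tpl$bonds), bends = NROW(tpl$bends),
    dihedrals = NROW(tpl$dihedrals))
}
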