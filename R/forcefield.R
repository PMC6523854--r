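#' Coarse-grained site type
#'
#' A named interaction site: mass, partial charge and (optionally) the Mie
#' parameters for its self interaction. Sites such as SPC/E hydrogens carry
#' charge and mass but no van-der-Waals interaction (`self_params = NULL`).
#'
#' @param name label, unique within a force field (e.g. "I1", "CI", "OW").
#' @param mass g/mol, must be > 0.
#' @param charge elementary charges.
#' @param self_params a [mie_params()] object or NULL for a vdW-silent site.
#' @return An object of class `site_type`.
#' @export
site_type <- function(name, mass, charge, self_params = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(mass) || mass <= 0) stop("site_type: mass must be > 0")
  if (!is.null(self_params) && !inherits(self_params, "mie_params"))
    stop("site_type: self_params must be mie_params or NULL")
  structure(list(name = name, mass = mass, charge = charge,
                 self_params = self_params),
            class = "site_type")
}

#' Read a force-field registry file
#'
#' The registry is a YAML document declaring site types (mass, charge, Mie
#' epsilon/n/m and one of r0 or sigma), molecule templates (site list,
#' template coordinates and bonded force constants), mixing options, the
#' nonbonded exclusion policy and the rigid-water geometry. Reference bond
#' lengths, angles and dihedral phases are derived from the template
#' coordinates, so each molecule template sits at its bonded minimum.
#'
#' @param path path to a YAML force-field file.
#' @return An object of class `cg_forcefield`.
#' @seealso [default_forcefield()]
#' @export
read_forcefield <- function(path) {
  if (!file.exists(path)) stop("force-field file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (key in c("site_types", "molecules"))
    if (is.null(doc[[key]])) stop("force-field file missing section: ", key)

  sites <- list()
  for (nm in names(doc$site_types)) {
    st <- doc$site_types[[nm]]
    sp <- NULL
    if (!is.null(st$epsilon) && st$epsilon > 0) {
      sp <- mie_params(st$epsilon, st$n, st$m,
                       r0 = st$r0, sigma = st$sigma)
    }
    sites[[nm]] <- site_type(nm, st$mass, st$charge %||% 0, sp)
  }
  if (anyDuplicated(names(sites))) stop("duplicate site type names")

  mixing <- list(
    exponent_rule = (doc$mixing$exponent_rule %||% "arithmetic"),
    fixed_exponents = unlist(doc$mixing$fixed_exponents %||% c(9, 6))
  )
  exclusions <- list(
    policy  = doc$exclusions$policy %||% "1-3",
    scale14 = doc$exclusions$scale14 %||% 1.0
  )
  if (!exclusions$policy %in% c("1-2", "1-3"))
    stop("unsupported exclusion policy: ", exclusions$policy)

  molecules <- lapply(doc$molecules, compile_molecule_template, sites = sites)

  ff <- structure(list(
    sites = sites,
    mixing = mixing,
    exclusions = exclusions,
    molecules = molecules,
    water_model = list(dOH = doc$water_model$dOH %||% 1.0,
                       dHH = doc$water_model$dHH %||% 1.6329932),
    species_masses = doc$species_masses,
    meta = doc$meta,
    path = path
  ), class = "cg_forcefield")
  ff$pair_table <- build_pair_table(ff)
  ff
}

#' Packaged default force field
#'
#' Reads the registry shipped with the package (five-site [bmim][Cl], SPC/E
#' water, six-site-per-cellobiose cellulose).
#'
#' @return A `cg_forcefield`.
#' @export
default_forcefield <- function() {
  read_forcefield(system.file("forcefield", "bmimcl_cg.yaml",
                              package = "cgmie", mustWork = TRUE))
}

#' @export
print.cg_forcefield <- function(x, ...) {
  cat(sprintf("cg_forcefield '%s': %d site types, %d molecule templates\n",
              x$meta$name %||% "?", length(x$sites), length(x$molecules)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- molecule templates -----------------------------------------------------

# Turn the YAML molecule block into an indexed template with derived
# reference geometry. Sites referencing the next repeat unit carry a "+"
# suffix and are resolved to index + n_sites with coordinates shifted by
# z_period along z.
compile_molecule_template <- function(mol, sites) {
  ids <- vapply(mol$sites, function(s) s$id, "")
  types <- vapply(mol$sites, function(s) s$type, "")
  if (anyDuplicated(ids)) stop("duplicate site ids in molecule template")
  if (!all(types %in% names(sites)))
    stop("molecule template references unknown site types: ",
         paste(setdiff(types, names(sites)), collapse = ", "))
  ns <- length(ids)
  coords <- t(vapply(ids, function(id) {
    xyz <- mol$coords[[id]]
    if (is.null(xyz) || length(xyz) != 3L)
      stop("missing/invalid template coordinates for site ", id)
    as.numeric(xyz)
  }, numeric(3)))
  zp <- mol$z_period %||% 0

  resolve <- function(ref) {
    plus <- grepl("\\+$", ref)
    id <- sub("\\+$", "", ref)
    k <- match(id, ids)
    if (is.na(k)) stop("unknown site id in bonded term: ", ref)
    list(index = k + if (plus) ns else 0L, spans = plus)
  }
  site_pos <- function(res) {
    p <- coords[(res$index - 1L) %% ns + 1L, ]
    if (res$spans) p <- p + c(0, 0, zp)
    p
  }

  bonds <- bends <- dihedrals <- NULL
  for (b in mol$bonds %||% list()) {
    r1 <- resolve(b$ij[[1]]); r2 <- resolve(b$ij[[2]])
    r0 <- sqrt(sum((site_pos(r1) - site_pos(r2))^2))
    if (r0 <= 0) stop("bond with zero reference length")
    bonds <- rbind(bonds, c(r1$index, r2$index, b$k, r0,
                            spans = r1$spans || r2$spans))
  }
  for (b in mol$bends %||% list()) {
    rr <- lapply(b$ijk, resolve)
    p <- lapply(rr, site_pos)
    u <- p[[1]] - p[[2]]; v <- p[[3]] - p[[2]]
    th0 <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    bends <- rbind(bends, c(sapply(rr, `[[`, "index"), b$k, th0,
                            spans = any(sapply(rr, `[[`, "spans"))))
  }
  for (d in mol$dihedrals %||% list()) {
    rr <- lapply(d$ijkl, resolve)
    p <- lapply(rr, site_pos)
    phi0 <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    mult <- d$mult %||% 1
    # choose the phase so the template geometry is a minimum of A(1+cos(mult*phi-delta))
    delta <- mult * phi0 - pi
    dihedrals <- rbind(dihedrals, c(sapply(rr, `[[`, "index"),
                                    d$amp, mult, delta,
                                    spans = any(sapply(rr, `[[`, "spans"))))
  }
  list(
    species = mol$species,
    rigid = mol$rigid %||% NA_character_,
    site_ids = ids, site_types = types, n_sites = ns,
    coords = coords, z_period = zp, repeats = isTRUE(mol[["repeat"]]),
    bonds = bonds, bends = bends, dihedrals = dihedrals
  )
}

# Signed dihedral angle (radians) of four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- mixed pair tables ------------------------------------------------------

# Precompute ntype x ntype matrices of mixed Mie parameters (and the energy
# shift at an arbitrary cutoff, filled in at compile time). Rows/columns follow
# names(ff$sites); vdW-silent sites get epsilon 0.
build_pair_table <- function(ff) {
  nm <- names(ff$sites)
  nt <- length(nm)
  eps <- nmat <- mmat <- r0 <- matrix(0, nt, nt, dimnames = list(nm, nm))
  nmat[] <- 9; mmat[] <- 6; r0[] <- 1   # placeholders where eps = 0
  for (i in seq_len(nt)) for (j in i:nt) {
    a <- ff$sites[[i]]$self_params; b <- ff$sites[[j]]$self_params
    if (is.null(a) || is.null(b)) next
    p <- if (i == j) a else
      mix_params(a, b, rule = ff$mixing$exponent_rule,
                 fixed_exponents = ff$mixing$fixed_exponents)
    eps[i, j] <- eps[j, i] <- p$epsilon
    nmat[i, j] <- nmat[j, i] <- p$n
    mmat[i, j] <- mmat[j, i] <- p$m
    r0[i, j] <- r0[j, i] <- p$r0
  }
  list(names = nm, eps = eps, n = nmat, m = mmat, r0 = r0)
}

# Mie energy at the cutoff for every type pair (used as the truncation shift).
pair_shift_matrix <- function(pt, cutoff) {
  C <- pt$eps / (pt$n - pt$m)
  C * (pt$m * (pt$r0 / cutoff)^pt$n - pt$n * (pt$r0 / cutoff)^pt$m)
}

# dU/dr at the cutoff (used by the shifted-force truncation).
pair_fshift_matrix <- function(pt, cutoff) {
  C <- pt$eps / (pt$n - pt$m)
  -C * pt$n * pt$m * ((pt$r0 / cutoff)^pt$n - (pt$r0 / cutoff)^pt$m) / cutoff
}

#' Site masses and charges for a vector of type names
#'
#' @param ff a `cg_forcefield`.
#' @param types character vector of site type names.
#' @return data.frame with columns `mass` and `charge`.
#' @export
site_properties <- function(ff, types) {
  bad <- setdiff(unique(types), names(ff$sites))
  if (length(bad)) stop("unknown site types: ", paste(bad, collapse = ", "))
  data.frame(
    mass = vapply(types, function(t) ff$sites[[t]]$mass, 0),
    charge = vapply(types, function(t) ff$sites[[t]]$charge, 0),
    row.names = NULL
  )
}
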