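test_that("ionic-liquid builds have the right counts, connectivity and neutrality", {
  ff <- default_forcefield()
  top1 <- build_bmimcl(1, 25, ff)
  expect_equal(nrow(top1$pos), 5L)
  expect_equal(total_charge(top1), 0)
  top <- build_bmimcl(256, 41, ff)
  expect_equal(nrow(top$pos), 1280L)          # 256 pairs x 5 sites
  expect_equal(total_charge(top), 0, tolerance = 1e-12)
  # per-molecule bonded terms match the cation template exactly
  counts <- count_bonded_terms(top)
  cat_counts <- counts[counts$species == "bmim", ]
  expect_true(all(cat_counts$bonds == 3))
  expect_true(all(cat_counts$bends == 2))
  expect_true(all(cat_counts$dihedrals == 1))
  expect_true(all(counts$bonds[counts$species == "chloride"] == 0))
})

test_that("cellulose chains follow the six-site / 7-4-8 per-unit convention", {
  ff <- default_forcefield()
  expect_error(build_cellulose_chain(0), ">= 1")
  # per-repeat-unit template owns 7 bonds, 4 bends, 8 dihedrals
  expect_equal(template_term_counts(ff, "cellobiose"),
               c(sites = 6L, bonds = 7L, bends = 4L, dihedrals = 8L))
  ch10 <- build_cellulose_chain(10, ff)
  expect_equal(nrow(ch10$pos), 60L)           # 10 units x 6 sites
  # finite chain drops the unit-spanning terms of the terminal unit
  expect_equal(nrow(ch10$bonds), 7 * 10 - 1)
  expect_equal(nrow(ch10$bends), 4 * 10 - 1)
  expect_equal(nrow(ch10$dihedrals), 8 * 10 - 4)
  # unique unordered pair combinations of the 6 cellulose site types
  types <- c("C11", "C14", "C16", "C21", "C24", "C26")
  combos <- unique(t(apply(expand.grid(types, types), 1, sort)))
  expect_equal(nrow(combos), choose(6, 2) + 6)   # 21
})

test_that("fiber builds are consistent and chains keep their lattice spacing", {
  ff <- default_forcefield()
  fib <- build_fiber(36, 10, spacing = 6, ff = ff)
  expect_equal(nrow(fib$pos), 2160L)
  expect_equal(length(fib$mol_species), 36L)
  expect_true(all(fib$mol_species == "cellulose"))
  # minimum distance between sites of different chains >= spacing - pendant extent
  ids <- fib$mol_id
  d <- Inf
  for (m in 1:4) {
    a <- fib$pos[ids == m, ]
    b <- fib$pos[ids != m, ]
    for (r in seq_len(nrow(a)))
      d <- min(d, sqrt(min(colSums((t(b) - a[r, ])^2))))
  }
  expect_gte(d, 6 - 5.7)  # pendant beads extend ~2.8 A toward each neighbour
  # single chain build equals the chain builder's placement
  one <- build_fiber(1, 5, ff = ff)
  expect_equal(nrow(one$pos), nrow(build_cellulose_chain(5, ff)$pos))
})

test_that("solvated fiber reproduces the reference composition arithmetic", {
  ff <- default_forcefield()
  fib <- build_fiber(36, 10, ff = ff, box = c(70, 62, 104))
  top <- solvate(fib, 2826, 3809, c(100, 100, 106), ff = ff, seed = 4)
  expect_equal(nrow(top$pos), 2160 + 5 * 2826 + 3 * 3809)
  tab <- table(top$mol_species)
  expect_equal(unname(tab[c("bmim", "chloride", "water", "cellulose")]),
               c(2826L, 2826L, 3809L, 36L), ignore_attr = TRUE)
  expect_equal(total_charge(top), 0, tolerance = 1e-10)
  # water mass fraction rounds to 10% w/w
  expect_equal(round(100 * mass_fraction(top, "water")), 10)
  # cellulose fraction: ~19% relative to IL, ~17% of the total mixture
  cel_in_il <- mass_fraction(top, "cellulose",
                             relative_to = c("cellulose", "bmimcl"))
  expect_equal(cel_in_il, 0.19, tolerance = 0.02)
  expect_equal(mass_fraction(top, "cellulose"), 0.17, tolerance = 0.02)
})

test_that("mass fractions follow registry masses", {
  ff <- default_forcefield()
  # one water + one chloride
  w <- cgmie:::stamp_template(ff$molecules$water, c(10, 10, 10))
  cl <- cgmie:::stamp_template(ff$molecules$chloride, c(15, 10, 10))
  top <- cgmie:::assemble_topology(list(w, cl), c(20, 20, 20), ff)
  expect_equal(mass_fraction(top, "water"), frozen$water_cl_frac,
               tolerance = 1e-10)
  # pure water
  top2 <- cgmie:::assemble_topology(list(w), c(20, 20, 20), ff)
  expect_identical(mass_fraction(top2, "water"), 1)
  expect_error(mass_fraction(top2, "cellulose"), "not present")
})

test_that("lattice builder sizes the box from mass and density", {
  ff <- default_forcefield()
  # 8 molecules -> 2 x 2 x 2 centroid lattice
  top8 <- build_lattice(c(chloride = 8), ff, box = c(12, 12, 12))
  expect_equal(nrow(top8$pos), 8L)
  # centroids sit on a 2 x 2 x 2 lattice (planes at 3 and 9) up to jitter
  for (d in 1:3) {
    off <- pmin(abs(top8$pos[, d] - 3), abs(top8$pos[, d] - 9))
    expect_lt(max(off), 0.35)
  }
  # 256 IL pairs at ~1.1 g/cm^3: cubic edge from mass/density arithmetic
  top <- build_lattice(c(bmim = 256, chloride = 256), ff,
                       target_density = 1.1)
  mass <- 256 * 174.673
  edge_expect <- (mass / (cg_constants$avogadro_dens * 1.1))^(1 / 3)
  expect_equal(top$box[1], edge_expect, tolerance = 1e-10)
  expect_true(edge_expect > 40 && edge_expect < 41)
  expect_error(build_lattice(c(bmim = 2), ff), "target_density or box")
})

test_that("builds are deterministic given a seed and respect minimum separation", {
  ff <- default_forcefield()
  a <- build_bmimcl(16, 28, ff, seed = 42)
  b <- build_bmimcl(16, 28, ff, seed = 42)
  expect_identical(a$pos, b$pos)
  c2 <- build_bmimcl(16, 28, ff, seed = 43)
  expect_false(identical(a$pos, c2$pos))
  expect_gte(cgmie:::audit_min_separation(a), 0.5)
  # packing error surfaces when the request cannot fit
  expect_error(build_bmimcl(64, 10, ff), "packing error")
})
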