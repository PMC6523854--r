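make_bond_top <- function(pos, bonds, box = c(50, 50, 50)) {
  n <- nrow(pos)
  terms <- cgmie:::empty_terms()
  b <- terms$bonds
  for (bb in bonds) b <- rbind(b, bb)
  colnames(b) <- c("i", "j", "k", "r0")
  cgmie:::new_topology(rep("X", n), rep(10, n), rep(0, n), rep(1L, n), "x",
                       pos, box, b, terms$bends, terms$dihedrals,
                       matrix(0L, 0, 3))
}

test_that("a bond at its reference length stores no energy and no force", {
  top <- make_bond_top(rbind(c(0, 0, 0), c(3, 0, 0)),
                       list(c(1, 2, 100, 3)))
  bd <- bonded_energy_forces(top)
  expect_identical(bd$e_bond, 0)
  expect_true(all(bd$forces == 0))
})

test_that("harmonic bond energy is k/2 dr^2", {
  top <- make_bond_top(rbind(c(0, 0, 0), c(3.1, 0, 0)),
                       list(c(1, 2, 100, 3)))
  bd <- bonded_energy_forces(top)
  expect_equal(bd$e_bond, 0.5, tolerance = 1e-12)
  # restoring force of magnitude k*dr on each site, opposite directions
  expect_equal(bd$forces[2, 1], -10, tolerance = 1e-10)
  expect_equal(bd$forces[1, 1], 10, tolerance = 1e-10)
})

test_that("bonded terms respect the minimum-image convention", {
  # bond across the periodic boundary: separation is 3, not 47
  top <- make_bond_top(rbind(c(1, 25, 25), c(48, 25, 25)),
                       list(c(1, 2, 100, 3)), box = c(50, 50, 50))
  bd <- bonded_energy_forces(top)
  expect_equal(bd$e_bond, 0, tolerance = 1e-12)
})

test_that("analytic bonded forces match finite differences on a cellulose chain", {
  ff <- default_forcefield()
  top <- build_cellulose_chain(3, ff)
  set.seed(21)
  pos <- top$pos + matrix(rnorm(length(top$pos), sd = 0.15), nrow(top$pos))
  bd <- bonded_energy_forces(top, pos)
  etot <- function(p) {
    r <- bonded_energy_forces(top, p)
    r$e_bond + r$e_bend + r$e_dih
  }
  fscale <- max(abs(bd$forces))
  set.seed(22)
  probes <- cbind(sample(nrow(pos), 12), sample(3, 12, replace = TRUE))
  for (k in seq_len(nrow(probes))) {
    i <- probes[k, 1]; d <- probes[k, 2]
    fd <- -fd_gradient(function(x) { p <- pos; p[i, d] <- x; etot(p) },
                       pos[i, d])
    expect_equal(bd$forces[i, d] / fscale, fd / fscale, tolerance = 1e-6)
  }
  # deformed chain stores energy in every term class
  expect_gt(bd$e_bond, 0); expect_gt(bd$e_bend, 0); expect_gt(bd$e_dih, 0)
  # Newton's third law
  expect_equal(colSums(bd$forces), c(0, 0, 0), tolerance = 1e-9)
})

test_that("total energy decomposition sums exactly and forces vanish in equilibrium", {
  ff <- default_forcefield()
  fx <- generate_fixture("il_box", n_pairs = 8, density = 0.5, seed = 9)
  sys <- compile_system(fx$topology, ff, cutoff = 8)
  r <- total_energy_forces(sys)
  expect_identical(r$total, sum(r$energies))
  expect_named(r$energies, c("mie", "coulomb_real", "coulomb_recip",
                             "coulomb_self", "bond", "bend", "dihedral"))
  expect_equal(colSums(r$forces), c(0, 0, 0), tolerance = 1e-8)
})

test_that("analytic total forces match finite differences on a charged IL box", {
  fx <- generate_fixture("il_box", n_pairs = 8, density = 0.5, seed = 2)
  sys <- compile_system(fx$topology, fx$ff, cutoff = 7)
  set.seed(5)
  err <- cgmie:::force_fd_error(sys, fx$topology$pos, fx$topology$box,
                                n_probe = 10)
  expect_lt(err, 1e-6)
})

test_that("overlapping sites trigger the singularity guard", {
  fx <- generate_fixture("mie_fluid", n = 20, seed = 2)
  sys <- compile_system(fx$topology, fx$ff, cutoff = 6)
  pos <- fx$topology$pos
  pos[2, ] <- pos[1, ] + 1e-8
  expect_error(total_energy_forces(sys, pos), "overlapping sites")
})
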