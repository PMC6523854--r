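test_that("equilibration detection handles constant, step and drifting series", {
  # constant series: production starts at the first sample
  idx <- detect_equilibration(rep(5, 50))
  expect_identical(as.integer(idx), 1L)
  expect_true(attr(idx, "equilibrated"))
  # step series: detected start at or after the change point
  set.seed(31)
  x <- c(rnorm(40, 10, 0.1), rnorm(60, 2, 0.1))
  idx <- detect_equilibration(x)
  expect_gte(as.integer(idx), 41L)
  expect_true(attr(idx, "equilibrated"))
  # monotone drift to the end: flagged, not an exception
  idx <- detect_equilibration(seq(0, 10, length.out = 100))
  expect_false(attr(idx, "equilibrated"))
  expect_error(detect_equilibration(1:10), "at least 20")
})

test_that("observable_series validates its invariants", {
  expect_silent(observable_series(1:5, rnorm(5)))
  expect_error(observable_series(c(1, 2, 2), 1:3), "strictly increasing")
  expect_error(observable_series(1:3, 1:4), "length mismatch")
})

test_that("average density reproduces hand-computed values", {
  ff <- default_forcefield()
  top <- build_lattice(c(bmim = 256, chloride = 256), ff, box = rep(40, 3))
  obs <- data.frame(V = rep(40^3, 30), T = rep(298.15, 30))
  rep1 <- average_density(obs, top, 1L)
  rho_hand <- 256 * 174.673 / (0.602214076 * 64000)
  expect_equal(rep1$rho_md, rho_hand, tolerance = 1e-10)
  expect_equal(rep1$rho_err, 0)
  # doubling all masses doubles the density
  top2 <- top; top2$mass <- 2 * top$mass
  expect_equal(average_density(obs, top2, 1L)$rho_md, 2 * rep1$rho_md)
  # error propagates from the volume standard deviation
  set.seed(2)
  obs2 <- data.frame(V = rnorm(200, 64000, 500))
  rep2 <- average_density(obs2, top, 1L)
  expect_equal(rep2$rho_err / rep2$rho_md, sd(obs2$V) / mean(obs2$V),
               tolerance = 1e-10)
  expect_error(average_density(obs, top, 40L), "empty post-equilibration")
})

test_that("density averages are invariant under integer-stride subsampling", {
  ff <- default_forcefield()
  top <- build_lattice(c(chloride = 10), ff, box = rep(20, 3))
  obs <- data.frame(V = rep(8000, 120))
  full <- average_density(obs, top, 1L)$rho_md
  sub <- average_density(obs[seq(1, 120, by = 5), , drop = FALSE], top, 1L)$rho_md
  expect_identical(full, sub)
})

test_that("deviation statistic uses the simulated-value denominator", {
  expect_identical(mabd(1.2, 1.2), 0)
  expect_equal(mabd(1.157, 1.067), 100 * 0.09 / 1.157, tolerance = 1e-12)
  # asymmetry is intentional
  expect_false(isTRUE(all.equal(mabd(1.157, 1.067), mabd(1.067, 1.157))))
  # vector form averages per-temperature deviations
  expect_equal(mabd(printed_density_table$MD, printed_density_table$EXP),
               mean(frozen$mabd_rows), tolerance = 1e-10)
  expect_error(mabd(-1, 1), "> 0")
})

test_that("density table sorts, flags monotonicity and recomputes deviations", {
  reps <- lapply(c(3, 1, 4, 2), function(i)
    structure(list(T = printed_density_table$T[i],
                   rho_md = printed_density_table$MD[i],
                   rho_err = 0.001,
                   rho_ref = printed_density_table$EXP[i], mabd = NULL),
              class = "density_report"))
  df <- density_vs_temperature(reps)
  expect_equal(df$T, printed_density_table$T)
  expect_true(attr(df, "monotonic_decreasing"))   # MD column decreases with T
  # per-row deviations match the printed column within one-unit rounding slack
  expect_true(all(abs(df$mabd - printed_density_table$MABD) <= 0.06))
  expect_error(density_vs_temperature(reps[1]), "at least 2")
  expect_error(density_vs_temperature(reps[c(1, 1)]), "duplicate")
})

test_that("ideal-gas radial distribution is flat at unity", {
  frames <- lapply(1:8, function(i) {
    fx <- generate_fixture("ideal_gas", n = 1000, box = 40, seed = i,
                           jitter = 2.2)
    list(pos = fx$topology$pos, box = fx$topology$box)
  })
  fx <- generate_fixture("ideal_gas", n = 1000, box = 40)
  res <- rdf(frames, fx$topology, "ID", "ID", dr = 0.25)
  sel <- res$r > 5 & res$r < 20     # away from the jittered-grid short range
  expect_lt(max(abs(res$g[sel] - 1)), 0.05)
  # fluctuations shrink with more frames
  res2 <- rdf(frames[1:2], fx$topology, "ID", "ID", dr = 0.25)
  expect_lt(sd(res$g[sel]), sd(res2$g[sel]))
  # pair-count bookkeeping: binned counts equal all pairs within rmax
  brute <- cgmie:::cg_pair_distances(frames[[1]]$pos, frames[[1]]$box,
                                     seq_len(1000) - 1L, seq_len(1000) - 1L,
                                     res$rmax, TRUE)
  res1 <- rdf(frames[1], fx$topology, "ID", "ID", dr = 0.25)
  expect_equal(sum(res1$counts), length(brute))
})

test_that("two fixed sites give a single peak with closed-form normalization", {
  ff <- make_forcefield(
    list(A = list(mass = 1, charge = 0, epsilon = 0),
         B = list(mass = 1, charge = 0, epsilon = 0)),
    list(a = cgmie:::monatomic_molecule("A", "a"),
         b = cgmie:::monatomic_molecule("B", "b")))
  box <- c(30, 30, 30)
  d <- 6.1
  sa <- cgmie:::stamp_template(ff$molecules$a, c(10, 10, 10))
  sb <- cgmie:::stamp_template(ff$molecules$b, c(10 + d, 10, 10))
  top <- cgmie:::assemble_topology(list(sa, sb), box, ff)
  frames <- rep(list(list(pos = top$pos, box = box)), 25)
  res <- rdf(frames, top, "A", "B", dr = 0.2)
  k <- floor(d / 0.2) + 1
  expect_equal(sum(res$counts > 0), 1L)
  shell <- 4 / 3 * pi * (( (k) * 0.2)^3 - ((k - 1) * 0.2)^3)
  g_hand <- prod(box) / shell    # N_a = N_b = 1
  expect_equal(res$g[k], g_hand, tolerance = 1e-10)
})

test_that("rdf validates selections and range", {
  fx <- generate_fixture("ideal_gas", n = 50, box = 30)
  frames <- list(list(pos = fx$topology$pos, box = fx$topology$box))
  expect_error(rdf(frames, fx$topology, "ZZ", "ID"), "no sites of type")
  expect_error(rdf(frames, fx$topology, "ID", "ID", rmax = 16),
               "half the smallest box edge")
})

test_that("packaged reference densities match the printed comparison table", {
  refs <- reference_densities()
  expect_equal(refs$T, printed_density_table$T)
  expect_equal(refs$rho_md_reported, printed_density_table$MD)
  expect_equal(refs$rho_exp, printed_density_table$EXP)
})
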