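test_that("force-free motion is exact straight-line propagation", {
  fx <- generate_fixture("ideal_gas", n = 8, box = 30)
  st <- init_state(fx$topology, fx$ff, T = 300, seed = 3, cutoff = 3,
                   tail_correction = FALSE)
  p0 <- st$pos; v0 <- st$vel
  for (i in 1:100) st <- nve_step(st, 0.004)
  expect_equal(st$pos, p0 + 100 * 0.004 * v0, tolerance = 1e-12)
  expect_equal(st$vel, v0, tolerance = 1e-14)
})

test_that("harmonic dimer follows the closed-form oscillator at small step", {
  fx <- generate_fixture("harmonic_dimer")   # defaults: k = 10, r0 = 3, stretch = 0.3
  st <- init_state(fx$topology, fx$ff, T = 0, cutoff = 9,
                   tail_correction = FALSE)
  nstep <- 1000
  x <- numeric(nstep)
  for (i in seq_len(nstep)) {
    st <- nve_step(st, 0.004)
    x[i] <- st$pos[2, 1] - st$pos[1, 1]
  }
  ref <- dimer_oscillator(10, 15, 3, 0.3, (1:nstep) * 0.004)
  # phase agreement over ~15 periods at omega*dt ~ 0.09
  expect_lt(max(abs(x - ref$x)), 0.02)
  expect_equal(range(x), c(2.7, 3.3), tolerance = 1e-3)
})

test_that("momentum is conserved to round-off on an interacting Mie gas", {
  fx <- generate_fixture("mie_fluid", n = 50, density = 0.006, seed = 8)
  st <- init_state(fx$topology, fx$ff, T = 300, cutoff = 9,
                   tail_correction = FALSE)
  m <- fx$topology$mass
  p0 <- colSums(st$vel * m)
  for (i in 1:2000) st <- nve_step(st, 0.004)
  expect_equal(colSums(st$vel * m), p0, tolerance = 1e-9)
})

test_that("NVE with shifted-force truncation conserves energy (block means)", {
  fx <- generate_fixture("mie_fluid", n = 40, seed = 5)
  st <- init_state(fx$topology, fx$ff, T = 300, cutoff = 8,
                   tail_correction = FALSE, truncation = "shift-force")
  nrec <- 500
  e <- numeric(nrec)
  for (b in seq_len(nrec)) {
    for (i in 1:10) st <- nve_step(st, 0.004)
    e[b] <- total_energy_of(st)
  }
  K_scale <- kinetic_energy(st$vel, fx$topology$mass)
  drift <- abs(mean(tail(e, 50)) - mean(head(e, 50))) / K_scale
  expect_lt(drift, 1e-4)
})

test_that("Nose-Hoover NVT holds the kinetic-temperature setpoint", {
  fx <- generate_fixture("mie_fluid", n = 60, density = 0.006, seed = 12)
  cfg <- ensemble_config("NVT", T = 300, dt = 0.004, cutoff = 9)
  st <- init_state(fx$topology, fx$ff, T = 250, cutoff = 9,
                   tail_correction = FALSE)
  r <- run_md(st, cfg, 10000, stride = 20)
  o <- r$observables
  expect_equal(mean(tail(o$T, 300)), 300, tolerance = 0.05)
  # extended-system conserved quantity is stable on the kinetic-energy scale
  expect_lt(diff(range(tail(o$conserved, 400))) / mean(o$e_kin), 5e-2)
})

test_that("infinite thermostat mass recovers NVE trajectories", {
  fx <- generate_fixture("mie_fluid", n = 20, seed = 4)
  cfg <- ensemble_config("NVT", T = 300, f = Inf, dt = 0.004, cutoff = 6)
  a <- init_state(fx$topology, fx$ff, T = 300, cutoff = 6,
                  tail_correction = FALSE)
  b <- init_state(fx$topology, fx$ff, T = 300, cutoff = 6,
                  tail_correction = FALSE)
  for (i in 1:200) { a <- nvt_step(a, cfg); b <- nve_step(b, 0.004) }
  expect_equal(a$pos, b$pos, tolerance = 1e-12)
})

test_that("NPT on an ideal gas reproduces PV = N kB T", {
  fx <- generate_fixture("ideal_gas", n = 100, box = 21)
  cfg <- ensemble_config("NPT", T = 300, P = 500, dt = 0.004, cutoff = 3)
  st <- init_state(fx$topology, fx$ff, T = 300, cutoff = 3,
                   tail_correction = FALSE)
  r <- run_md(st, cfg, 30000, stride = 50)
  o <- r$observables[-(1:120), ]
  V_theory <- (100 - 1) * cg_constants$kB * 300 / (500 / cg_constants$press_atm)
  expect_equal(mean(o$V), V_theory, tolerance = 0.03)
  expect_equal(mean(o$T), 300, tolerance = 0.03)
  expect_equal(mean(o$P), 500, tolerance = 0.10)
})

test_that("frozen barostat at the same state reduces NPT to NVT scaling", {
  # with veps pinned at zero the NPT velocity update equals the NVT one; here
  # checked operationally: an NPT step from P = Pint leaves the box nearly
  # unchanged over a short span
  fx <- generate_fixture("mie_fluid", n = 30, seed = 6)
  st <- init_state(fx$topology, fx$ff, T = 100, cutoff = 7,
                   tail_correction = FALSE)
  st <- cgmie:::ensure_forces(st)
  K <- kinetic_energy(st$vel, fx$topology$mass)
  Pint <- (2 * K + st$fcache$virial) / (3 * prod(st$box)) *
    cg_constants$press_atm
  cfg <- ensemble_config("NPT", T = 100, P = Pint, f2 = 50, dt = 0.004,
                         cutoff = 7)
  V0 <- prod(st$box)
  for (i in 1:50) st <- npt_step(st, cfg)
  expect_equal(prod(st$box) / V0, 1, tolerance = 5e-3)
})

test_that("rigid water constraints restore geometry and do no work", {
  ff <- default_forcefield()
  w <- lapply(1:20, function(i)
    cgmie:::stamp_template(ff$molecules$water,
                           c(5 + (i %% 4) * 5, 5 + (i %/% 4) * 5, 10),
                           cgmie:::random_rotation()))
  top <- cgmie:::assemble_topology(w, c(25, 25, 25), ff)
  st <- init_state(top, ff, T = 300, seed = 2, cutoff = 10)
  # perturb and restore
  set.seed(9)
  st$pos <- st$pos + matrix(rnorm(length(st$pos), sd = 0.05), nrow(st$pos))
  st2 <- constrain_water(st)
  dOH <- ff$water_model$dOH; dHH <- ff$water_model$dHH
  wv <- st2$sys$waters0 + 1L
  dists <- function(pos) c(
    sqrt(rowSums((pos[wv[, 1], ] - pos[wv[, 2], ])^2)),
    sqrt(rowSums((pos[wv[, 1], ] - pos[wv[, 3], ])^2)),
    sqrt(rowSums((pos[wv[, 2], ] - pos[wv[, 3], ])^2)))
  expect_equal(dists(st2$pos), rep(c(dOH, dOH, dHH), each = 20),
               tolerance = 1e-7)
  # velocities have no component along constraints
  relv <- rowSums((st2$vel[wv[, 1], ] - st2$vel[wv[, 2], ]) *
                  (st2$pos[wv[, 1], ] - st2$pos[wv[, 2], ]))
  expect_lt(max(abs(relv)), 1e-7)
  # already-satisfied geometry is left untouched
  st3 <- constrain_water(st2)
  expect_equal(st3$pos, st2$pos, tolerance = 1e-9)
})

test_that("water geometry stays rigid through thermostatted dynamics", {
  ff <- default_forcefield()
  set.seed(14)
  w <- lapply(1:27, function(i) {
    grid <- c(i %% 3, (i %/% 3) %% 3, i %/% 9) * 6 + 4
    cgmie:::stamp_template(ff$molecules$water, grid, cgmie:::random_rotation())
  })
  top <- cgmie:::assemble_topology(w, c(19, 19, 19), ff)
  cfg <- ensemble_config("NVT", T = 300, dt = 0.004, cutoff = 9)
  st <- init_state(top, ff, T = 300, seed = 5, cutoff = 9)
  r <- run_md(st, cfg, 1500, stride = 100)
  wv <- st$sys$waters0 + 1L
  pos <- r$state$pos
  doh <- c(sqrt(rowSums((pos[wv[, 1], ] - pos[wv[, 2], ])^2)),
           sqrt(rowSums((pos[wv[, 1], ] - pos[wv[, 3], ])^2)))
  expect_lt(max(abs(doh - ff$water_model$dOH)), 1e-6)
  # temperature estimator uses the constrained dof count: 3N - 3 - 3 n_water
  expect_equal(st$sys$ndof, 3 * 81 - 3 - 3 * 27)
  expect_equal(mean(tail(r$observables$T, 10)), 300, tolerance = 0.15)
})

test_that("protocol runs are reproducible bit-for-bit from (spec, seed)", {
  fx <- generate_fixture("il_box", n_pairs = 8, density = 0.6, seed = 3)
  prot <- protocol_spec(initial_T = 100, equil_span = 0.4,
                        production_T = 200, production_span = 0.4,
                        stride = 10, minimize_steps = 50)
  cfg <- ensemble_config("NVT", T = 200, dt = 0.004, cutoff = 7)
  r1 <- run_protocol(fx$topology, prot, cfg, fx$ff, seed = 11)
  r2 <- run_protocol(fx$topology, prot, cfg, fx$ff, seed = 11)
  expect_identical(r1$observables, r2$observables)
  expect_identical(r1$state$pos, r2$state$pos)
  expect_setequal(unique(r1$observables$stage),
                  c("equilibration", "production"))
  # production span 0: only equilibration output
  prot0 <- protocol_spec(initial_T = 100, equil_span = 0.2,
                         production_span = 0, stride = 10,
                         minimize_steps = 10)
  r0 <- run_protocol(fx$topology, prot0, cfg, fx$ff, seed = 11)
  expect_identical(unique(r0$observables$stage), "equilibration")
})

test_that("instability diagnostics name the failing site", {
  fx <- generate_fixture("mie_fluid", n = 10, seed = 2)
  st <- init_state(fx$topology, fx$ff, T = 300, cutoff = 5)
  st$pos[3, 1] <- NaN
  st$fcache <- NULL
  expect_error(nve_step(st, 0.004), "site 3")
})
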