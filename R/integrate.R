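#' Ensemble configuration
#'
#' Integration settings for NVE, Nose-Hoover NVT or isotropic Nose-Hoover
#' NPT. Defaults follow the coarse-grained model's standard settings:
#' 0.004 ps time step, thermostat time f = 0.5 ps, thermo-barostat times
#' f1 = 0.5 ps and f2 = 3.0 ps, 15 Angstrom cutoff, 1 atm.
#'
#' @param kind "NVE", "NVT" or "NPT".
#' @param T target temperature, K.
#' @param P target pressure, atm (NPT only).
#' @param f thermostat coupling time, ps (NVT).
#' @param f1 thermostat coupling time, ps (NPT).
#' @param f2 barostat coupling time, ps (NPT).
#' @param dt time step, ps.
#' @param cutoff nonbonded cutoff, Angstrom.
#' @return An `ensemble_config` object.
#' @export
ensemble_config <- function(kind = c("NVT", "NVE", "NPT"), T = 300, P = 1,
                            f = 0.5, f1 = 0.5, f2 = 3.0,
                            dt = 0.004, cutoff = 15) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("dt must be > 0")
  if (any(c(f, f1, f2) <= 0)) stop("coupling times must be > 0")
  structure(list(kind = kind, T = T, P = P, f = f, f1 = f1, f2 = f2,
                 dt = dt, cutoff = cutoff),
            class = "ensemble_config")
}

#' Initialise a simulation state
#'
#' Compiles the system, assigns Maxwell-Boltzmann velocities at `T` (net
#' momentum zeroed, kinetic temperature rescaled exactly, water constraints
#' projected out) and evaluates the initial forces.
#'
#' @param topology a [cg_topology].
#' @param ff force field registry.
#' @param T initial temperature, K.
#' @param seed RNG seed (all randomness in a run flows from here).
#' @param ... passed to [compile_system()] (cutoff, ewald, alpha, ...).
#' @return A `cg_state` object.
#' @export
init_state <- function(topology, ff = default_forcefield(), T = 100,
                       seed = 1L, ...) {
  sys <- compile_system(topology, ff, ...)
  state <- structure(list(
    sys = sys, pos = topology$pos, box = topology$box,
    vel = matrix(0, nrow(topology$pos), 3),
    xi = 0, vxi = 0, veps = 0,
    step = 0L, time = 0, seed = as.integer(seed),
    fcache = NULL
  ), class = "cg_state")
  state <- init_velocities(state, T, seed)
  state
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf("cg_state: %d sites, step %d (t = %.3f ps), T = %.1f K\n",
              nrow(x$pos), x$step, x$time,
              kinetic_temperature(x$vel, x$sys$topology$mass, x$sys$ndof)))
  invisible(x)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param state a `cg_state`.
#' @param T temperature, K.
#' @param seed RNG seed.
#' @return The state with fresh velocities.
#' @export
init_velocities <- function(state, T, seed = state$seed) {
  set.seed(seed)
  m <- state$sys$topology$mass
  n <- length(m)
  sd <- sqrt(cg_constants$kB * T / (m * cg_constants$mv2_to_kcal))
  vel <- matrix(stats::rnorm(3 * n), n, 3) * sd
  # zero net momentum
  p <- colSums(vel * m)
  vel <- sweep(vel, 2, p / sum(m), "-")
  # project out constrained components, then rescale to T exactly
  if (nrow(state$sys$waters0)) {
    vel <- cg_rattle_vel(state$pos, vel, state$sys$waters0, m, state$box,
                         1e-10, 500)$vel
  }
  if (T > 0) {
    Tk <- kinetic_temperature(vel, m, state$sys$ndof)
    if (Tk > 0) vel <- vel * sqrt(T / Tk)
  } else vel[] <- 0
  state$vel <- vel
  state
}

ensure_forces <- function(state) {
  if (is.null(state$fcache)) {
    if (any(!is.finite(state$pos))) {
      bad <- which(!is.finite(rowSums(state$pos)))[1]
      stop("instability: non-finite coordinate on site ", bad,
           " (type ", state$sys$topology$type[bad], ") at step ", state$step)
    }
    state$fcache <- total_energy_forces(state$sys, state$pos, state$box)
    if (any(!is.finite(state$fcache$forces))) {
      bad <- which(!is.finite(rowSums(state$fcache$forces)))[1]
      stop("instability: non-finite force on site ", bad,
           " (type ", state$sys$topology$type[bad], ") at step ", state$step)
    }
  }
  state
}

sinhx <- function(x) ifelse(abs(x) < 1e-4, 1 + x^2 / 6, sinh(x) / x)

apply_shake <- function(state, pos_new, vel, dt) {
  if (nrow(state$sys$waters0) == 0)
    return(list(pos = pos_new, vel = vel, virial = 0))
  wm <- state$sys$ff$water_model
  sh <- cg_shake_waters(pos_new, state$pos, vel, state$sys$waters0,
                        state$sys$topology$mass, state$box,
                        wm$dOH, wm$dHH, 1e-8, 500L, dt, cg_constants$acc)
  if (!sh$converged)
    stop("constraint error: SHAKE did not converge in 500 iterations")
  list(pos = sh$pos, vel = sh$vel, virial = sh$virial)
}

apply_rattle <- function(state, vel) {
  if (nrow(state$sys$waters0) == 0) return(vel)
  rt <- cg_rattle_vel(state$pos, vel, state$sys$waters0,
                      state$sys$topology$mass, state$box, 1e-10, 500L)
  if (!rt$converged)
    stop("constraint error: RATTLE velocity stage did not converge")
  rt$vel
}

#' One velocity-Verlet NVE step
#'
#' @param state a `cg_state` (forces are computed if not cached).
#' @param dt time step, ps.
#' @return The advanced state.
#' @export
nve_step <- function(state, dt = 0.004) {
  state <- ensure_forces(state)
  m <- state$sys$topology$mass
  acc <- state$fcache$forces / m * cg_constants$acc
  vel <- state$vel + 0.5 * dt * acc
  pos_new <- state$pos + dt * vel
  sh <- apply_shake(state, pos_new, vel, dt)
  state$pos <- sh$pos; vel <- sh$vel
  state$w_constr <- sh$virial
  state$fcache <- NULL
  state <- ensure_forces(state)
  acc <- state$fcache$forces / m * cg_constants$acc
  vel <- vel + 0.5 * dt * acc
  state$vel <- apply_rattle(state, vel)
  state$step <- state$step + 1L
  state$time <- state$time + dt
  state
}

# Nose-Hoover half-update of the thermostat variable; scales particle
# velocities (and the barostat velocity when coupled). f_time is the
# coupling time constant; Inf recovers NVE.
nh_half <- function(state, T, f_time, dt, with_baro = FALSE, W_baro = 0) {
  ndof <- state$sys$ndof
  kT <- cg_constants$kB * T
  Q <- ndof * kT * f_time^2
  if (!is.finite(Q)) return(state)
  n_target <- if (with_baro) (ndof + 1) * kT else ndof * kT
  twoK <- 2 * kinetic_energy(state$vel, state$sys$topology$mass)
  baro <- if (with_baro) W_baro * state$veps^2 else 0
  G <- (twoK + baro - n_target) / Q
  state$vxi <- state$vxi + dt / 4 * G
  s <- exp(-state$vxi * dt / 2)
  state$vel <- state$vel * s
  if (with_baro) state$veps <- state$veps * s
  twoK <- twoK * s^2
  baro <- if (with_baro) W_baro * state$veps^2 else 0
  G <- (twoK + baro - n_target) / Q
  state$vxi <- state$vxi + dt / 4 * G
  state$xi <- state$xi + dt / 2 * state$vxi
  state
}

#' One Nose-Hoover NVT step
#'
#' Single-chain Nose-Hoover thermostat with coupling time `cfg$f` wrapped
#' around a velocity-Verlet core. The extended-system conserved quantity is
#' available from [conserved_quantity()].
#'
#' @param state a `cg_state`.
#' @param cfg an [ensemble_config()] with `kind = "NVT"`.
#' @return The advanced state.
#' @export
nvt_step <- function(state, cfg) {
  dt <- cfg$dt
  state <- ensure_forces(state)
  state <- nh_half(state, cfg$T, cfg$f, dt)
  state <- nve_step(state, dt)
  state <- nh_half(state, cfg$T, cfg$f, dt)
  state
}

#' One isotropic Nose-Hoover NPT step
#'
#' Martyna-Tobias-Klein style splitting: a single Nose-Hoover chain couples
#' to the particles and the barostat; the barostat strain rate scales box
#' and positions isotropically. Instantaneous pressure comes from the
#' kinetic term plus the pair/bonded/Ewald virial (with tail correction).
#'
#' @param state a `cg_state`.
#' @param cfg an [ensemble_config()] with `kind = "NPT"`.
#' @return The advanced state.
#' @export
npt_step <- function(state, cfg) {
  dt <- cfg$dt
  m <- state$sys$topology$mass
  ndof <- state$sys$ndof
  kT <- cg_constants$kB * cfg$T
  W <- (ndof + 3) * kT * cfg$f2^2
  Pext <- cfg$P / cg_constants$press_atm

  state <- ensure_forces(state)
  state <- nh_half(state, cfg$T, cfg$f1, dt, with_baro = TRUE, W_baro = W)

  baro_G <- function(state) {
    V <- prod(state$box)
    twoK <- 2 * kinetic_energy(state$vel, m)
    Pint <- (twoK + state$fcache$virial + (state$w_constr %||% 0)) / (3 * V)
    (3 * V * (Pint - Pext) + (3 / ndof) * twoK) / W
  }
  state$veps <- state$veps + dt / 2 * baro_G(state)

  # velocity half-kick with barostat scaling
  alpha <- (1 + 3 / ndof) * state$veps
  acc <- state$fcache$forces / m * cg_constants$acc
  state$vel <- state$vel * exp(-alpha * dt / 2) +
    0.5 * dt * acc * exp(-alpha * dt / 4) * sinhx(alpha * dt / 4)

  # position and box update
  sc <- exp(state$veps * dt)
  pos_new <- state$pos * sc +
    dt * state$vel * exp(state$veps * dt / 2) * sinhx(state$veps * dt / 2)
  state$box <- state$box * sc
  if (min(state$box) < 2 * 0.5)
    stop("instability: box collapsed (edge ", round(min(state$box), 2), " A)")
  if (state$sys$cutoff > min(state$box) / 2)
    stop("instability: box shrank below twice the cutoff")
  sh <- apply_shake(state, pos_new, state$vel, dt)
  state$pos <- sh$pos; state$vel <- sh$vel
  state$w_constr <- sh$virial

  state$fcache <- NULL
  state <- ensure_forces(state)
  acc <- state$fcache$forces / m * cg_constants$acc
  alpha <- (1 + 3 / ndof) * state$veps
  state$vel <- state$vel * exp(-alpha * dt / 2) +
    0.5 * dt * acc * exp(-alpha * dt / 4) * sinhx(alpha * dt / 4)
  state$vel <- apply_rattle(state, state$vel)

  state$veps <- state$veps + dt / 2 * baro_G(state)
  state <- nh_half(state, cfg$T, cfg$f1, dt, with_baro = TRUE, W_baro = W)
  state$step <- state$step + 1L
  state$time <- state$time + dt
  state
}

#' Project water geometry back onto the rigid SPC/E constraints
#'
#' Iteratively restores the two O-H distances and the H-H distance of every
#' water, then removes any velocity component along the constraints so the
#' constraint forces do no work.
#'
#' @param state a `cg_state`.
#' @param tol convergence tolerance on distances, Angstrom.
#' @param maxit maximum iterations (error on non-convergence).
#' @return The constrained state.
#' @export
constrain_water <- function(state, tol = 1e-8, maxit = 500L) {
  if (nrow(state$sys$waters0) == 0) return(state)
  wm <- state$sys$ff$water_model
  sh <- cg_shake_waters(state$pos, state$pos, state$vel, state$sys$waters0,
                        state$sys$topology$mass, state$box,
                        wm$dOH, wm$dHH, tol, maxit, 0, cg_constants$acc)
  if (!sh$converged)
    stop("constraint error: no convergence in ", maxit, " iterations")
  state$pos <- sh$pos
  state$vel <- apply_rattle(state, state$vel)
  state$fcache <- NULL
  state
}

#' Extended-system conserved quantity
#'
#' NVE: total energy. NVT: adds the thermostat terms; NPT: adds barostat
#' kinetic energy and the P V term.
#'
#' @param state a `cg_state` (forces must be current or computable).
#' @param cfg the [ensemble_config()] in force.
#' @return Conserved quantity, kcal/mol.
#' @export
conserved_quantity <- function(state, cfg) {
  state <- ensure_forces(state)
  ndof <- state$sys$ndof
  kT <- cg_constants$kB * cfg$T
  E <- state$fcache$total + kinetic_energy(state$vel, state$sys$topology$mass)
  if (cfg$kind == "NVE") return(E)
  Q <- ndof * kT * (if (cfg$kind == "NVT") cfg$f else cfg$f1)^2
  nt <- if (cfg$kind == "NPT") ndof + 1 else ndof
  E <- E + 0.5 * Q * state$vxi^2 + nt * kT * state$xi
  if (cfg$kind == "NPT") {
    W <- (ndof + 3) * kT * cfg$f2^2
    E <- E + 0.5 * W * state$veps^2 +
      cfg$P / cg_constants$press_atm * prod(state$box)
  }
  E
}

#' Steepest-descent energy minimisation
#'
#' Removes builder overlaps before dynamics; displacement per step is capped.
#'
#' @param state a `cg_state`.
#' @param n_steps iterations.
#' @param max_disp displacement cap per site per step, Angstrom.
#' @return The relaxed state.
#' @export
minimize <- function(state, n_steps = 200L, max_disp = 0.2) {
  state <- ensure_forces(state)
  gamma <- 1e-4
  for (k in seq_len(n_steps)) {
    f <- state$fcache$forces
    e0 <- state$fcache$total
    step_vec <- f * gamma
    mag <- sqrt(rowSums(step_vec^2))
    cap <- max(mag)
    if (cap > max_disp) step_vec <- step_vec * (max_disp / cap)
    pos_new <- state$pos + step_vec
    if (nrow(state$sys$waters0)) {
      sh <- apply_shake(state, pos_new, state$vel, 0)
      pos_new <- sh$pos
    }
    fc <- total_energy_forces(state$sys, pos_new, state$box)
    if (fc$total < e0) {
      state$pos <- pos_new
      state$fcache <- fc
      gamma <- gamma * 1.2
    } else {
      gamma <- gamma / 2
      if (gamma < 1e-10) break
    }
  }
  state
}

#' Run constant-ensemble dynamics
#'
#' Advances `n_steps` under the configured ensemble, sampling observables
#' every `stride` steps and storing a snapshot every `frame_stride` steps.
#'
#' @param state a `cg_state`.
#' @param cfg an [ensemble_config()].
#' @param n_steps number of steps.
#' @param stride observable sampling interval, steps.
#' @param frame_stride snapshot interval, steps (0 = no frames).
#' @param stage label recorded with each observable row.
#' @return List: `state`, `observables` (data.frame), `frames` (list of
#'   `list(pos, box, time, obs)`).
#' @export
run_md <- function(state, cfg, n_steps, stride = 25L, frame_stride = 0L,
                   stage = cfg$kind) {
  stepper <- switch(cfg$kind,
    NVE = function(s) nve_step(s, cfg$dt),
    NVT = function(s) nvt_step(s, cfg),
    NPT = function(s) npt_step(s, cfg))
  n_samp <- floor(n_steps / stride)
  obs <- vector("list", n_samp + 1L)
  frames <- list()
  snap <- function(state) {
    state <- ensure_forces(state)
    m <- state$sys$topology$mass
    K <- kinetic_energy(state$vel, m)
    V <- prod(state$box)
    e <- state$fcache$energies
    data.frame(
      step = state$step, time = state$time, stage = stage,
      T = kinetic_temperature(state$vel, m, state$sys$ndof),
      P = (2 * K + state$fcache$virial + (state$w_constr %||% 0)) /
        (3 * V) * cg_constants$press_atm,
      V = V,
      rho = sum(m) / (cg_constants$avogadro_dens * V),
      e_pot = state$fcache$total, e_kin = K,
      conserved = conserved_quantity(state, cfg),
      t(e)
    )
  }
  obs[[1]] <- snap(state)
  si <- 1L
  for (k in seq_len(n_steps)) {
    state <- stepper(state)
    if (k %% stride == 0L) {
      si <- si + 1L
      obs[[si]] <- snap(state)
    }
    if (frame_stride > 0L && k %% frame_stride == 0L) {
      state <- ensure_forces(state)
      frames[[length(frames) + 1L]] <- list(
        pos = state$pos, box = state$box, time = state$time,
        obs = c(T = kinetic_temperature(state$vel, state$sys$topology$mass,
                                        state$sys$ndof),
                V = prod(state$box), e_pot = state$fcache$total))
    }
  }
  list(state = state,
       observables = do.call(rbind, obs[seq_len(si)]),
       frames = frames)
}

#' Protocol specification: lattice, equilibrate cold, quench, produce
#'
#' The standard workflow: the system starts from a lattice, equilibrates at
#' a low initial temperature (default 100 K, 800 ps), is quenched to the
#' production temperature by an instantaneous thermostat setpoint change,
#' and then runs production.
#'
#' @param initial_T K (default 100).
#' @param equil_span ps (default 800).
#' @param equil_kind ensemble for the cold equilibration stage: `NULL` uses
#'   the run ensemble; `"NVT"` is useful to relax dense builder output at
#'   fixed volume before handing the box to the barostat.
#' @param production_T K.
#' @param production_span ps.
#' @param stride observable sampling interval, steps.
#' @param frame_stride snapshot interval, steps.
#' @param minimize_steps pre-equilibration minimisation iterations.
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(initial_T = 100, equil_span = 800,
                          production_T = 298.15, production_span = 100,
                          stride = 25L, frame_stride = 0L,
                          minimize_steps = 200L, equil_kind = NULL) {
  if (equil_span < 0 || production_span < 0) stop("spans must be >= 0")
  structure(list(initial_T = initial_T, equil_span = equil_span,
                 production_T = production_T,
                 production_span = production_span,
                 stride = as.integer(stride),
                 frame_stride = as.integer(frame_stride),
                 minimize_steps = as.integer(minimize_steps),
                 equil_kind = equil_kind),
            class = "protocol_spec")
}

#' Run the lattice-equilibrate-quench protocol
#'
#' @param topology a [cg_topology] (typically a lattice build).
#' @param protocol a [protocol_spec()].
#' @param cfg an [ensemble_config()] (its `T` is overridden stage by stage).
#' @param ff force field registry.
#' @param seed master seed for velocities.
#' @param ... passed to [compile_system()].
#' @return List: `state`, `observables` (with a `stage` column), `frames`.
#' @export
run_protocol <- function(topology, protocol, cfg, ff = default_forcefield(),
                         seed = 1L, ...) {
  state <- init_state(topology, ff, T = protocol$initial_T, seed = seed,
                      cutoff = cfg$cutoff, ...)
  if (protocol$minimize_steps > 0) {
    state <- minimize(state, protocol$minimize_steps)
    state <- init_velocities(state, protocol$initial_T, seed)
  }
  n_eq <- round(protocol$equil_span / cfg$dt)
  n_pr <- round(protocol$production_span / cfg$dt)
  cfg_eq <- cfg; cfg_eq$T <- protocol$initial_T
  if (!is.null(protocol$equil_kind)) cfg_eq$kind <- protocol$equil_kind
  eq <- run_md(state, cfg_eq, n_eq, protocol$stride,
               protocol$frame_stride, stage = "equilibration")
  state <- eq$state
  frames <- eq$frames
  obs <- eq$observables
  if (n_pr > 0) {
    cfg_pr <- cfg; cfg_pr$T <- protocol$production_T
    # quench: instantaneous setpoint change
    pr <- run_md(state, cfg_pr, n_pr, protocol$stride,
                 protocol$frame_stride, stage = "production")
    state <- pr$state
    frames <- c(frames, pr$frames)
    obs <- rbind(obs, pr$observables)
  }
  list(state = state, observables = obs, frames = frames,
       topology = topology)
}
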