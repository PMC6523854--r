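# Independent oracles used across the suite. These deliberately avoid the
# package's own evaluation paths: plain-R direct sums and finite differences.

# Direct Coulomb lattice sum over explicit image shells (conditionally
# convergent; adequate for the isolated-pair limit where images are a small
# correction). Energy in kcal/mol with the same Coulomb constant.
direct_coulomb_sum <- function(pos, q, box, nshell = 4) {
  kc <- 332.063713
  n <- nrow(pos)
  e <- 0
  for (sx in -nshell:nshell) for (sy in -nshell:nshell) for (sz in -nshell:nshell) {
    shift <- c(sx * box[1], sy * box[2], sz * box[3])
    central <- all(c(sx, sy, sz) == 0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (central && i >= j) next
      d <- pos[j, ] + shift - pos[i, ]
      r <- sqrt(sum(d^2))
      w <- if (central) 1 else 0.5
      e <- e + w * kc * q[i] * q[j] / r
    }
  }
  e
}

# Evjen-style direct sum for the rock-salt Madelung constant: cubic shells
# with fractional weights for sites on the shell boundary. Converges fast.
evjen_madelung <- function(nmax = 8) {
  acc <- 0
  for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax) {
    if (i == 0 && j == 0 && k == 0) next
    w <- prod(ifelse(abs(c(i, j, k)) == nmax, 0.5, 1))
    acc <- acc + w * (-1)^(i + j + k) / sqrt(i^2 + j^2 + k^2)
  }
  -acc
}

# Central finite difference of a scalar function of one coordinate.
fd_gradient <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Closed-form 1-D harmonic oscillator for the dimer fixture: relative
# coordinate x(t) = r0 + A cos(omega t), omega^2 = k / mu * acc.
dimer_oscillator <- function(k, mass, r0, stretch, times) {
  mu <- mass / 2
  omega <- sqrt(k / mu * cgmie::cg_constants$acc)
  list(x = r0 + stretch * cos(omega * times), omega = omega)
}

# Frozen high-precision expected values (computed independently with
# arbitrary-precision arithmetic before the implementation was written).
frozen <- list(
  mie_I1_r4       = 0.224952442110445,    # Table-row (0.375, 9, 6, 4.693) at r = 4
  r0_sigma_9_6    = 1.14471424255333187,  # (3/2)^(1/3)
  r0_sigma_12_6   = 1.12246204830937298,  # 2^(1/6)
  eps_I1_CT       = 0.419374534276939615, # sqrt(0.375 * 0.469)
  water_cl_frac   = 0.336930500486272163, # 18.015 / (18.015 + 35.453)
  madelung_nacl   = 1.747565,
  mabd_rows       = c(7.44225834046193, 7.77873811581677,
                      7.46924428822496, 7.52212389380531)
)

# Small shared fixtures -------------------------------------------------------

table2_rows <- data.frame(
  site = c("I1", "I2", "I3", "CT", "CI"),
  eps = c(0.375, 0.345, 0.199, 0.469, 0.148),
  n = c(9, 9, 9, 9, 12),
  m = c(6, 6, 6, 6, 6),
  r0 = c(4.693, 4.693, 4.120, 5.249, 4.232)
)

printed_density_table <- data.frame(
  T = c(298.15, 323.15, 348.15, 363.15),
  MD = c(1.169, 1.157, 1.138, 1.130),
  EXP = c(1.082, 1.067, 1.053, 1.045),
  MABD = c(7.49, 7.77, 7.47, 7.51)
)

total_energy_of <- function(state) {
  state <- cgmie:::ensure_forces(state)
  state$fcache$total + kinetic_energy(state$vel, state$sys$topology$mass)
}
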