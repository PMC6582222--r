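# Independent oracles used across the suite.

R_GAS <- 1.9872041e-3
RT298 <- R_GAS * 298.15

# central-difference gradient of the potential, the reference for forces()
fd_forces <- function(system, positions, h = 1e-6) {
  g <- matrix(0, nrow(positions), 3)
  for (i in seq_len(nrow(positions))) for (d in 1:3) {
    pp <- positions; pp[i, d] <- pp[i, d] + h
    pm <- positions; pm[i, d] <- pm[i, d] - h
    g[i, d] <- -(potential_energy(system, pp) -
                 potential_energy(system, pm)) / (2 * h)
  }
  g
}

# brute-force enumeration of all cumulative levels of a step list
brute_levels <- function(steps) {
  base <- 0
  ts <- stat <- numeric(0)
  for (i in seq_len(nrow(steps))) {
    ts <- c(ts, base + steps$dG_TS[i])
    base <- base + steps$dG_step[i]
    stat <- c(stat, base)
  }
  list(ts = ts, stat = stat)
}

# plain velocity-Verlet reference integrator (deterministic, no thermostat)
vv_reference <- function(system, n_steps, dt) {
  x <- system$positions
  mobile <- !system$fixed
  m <- system$masses
  kf <- thermo_constants()$accel
  v <- matrix(0, nrow(x), 3)
  xs <- vector("list", n_steps + 1)
  xs[[1]] <- x
  f <- forces(system, x)
  for (s in seq_len(n_steps)) {
    v[mobile, ] <- v[mobile, ] + 0.5 * dt * f[mobile, , drop = FALSE] *
      kf / m[mobile]
    x[mobile, ] <- x[mobile, ] + dt * v[mobile, , drop = FALSE]
    f <- forces(system, x)
    v[mobile, ] <- v[mobile, ] + 0.5 * dt * f[mobile, , drop = FALSE] *
      kf / m[mobile]
    xs[[s + 1]] <- x
  }
  xs
}

# small LJ dimer used in several engine tests
lj_dimer <- function(eps = 0.25, displace = 0) {
  A <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  rmin <- 2^(1 / 6)
  A[1, 2] <- A[2, 1] <- eps * 4   # A = 4*eps for the sigma = 1 LJ form
  B[1, 2] <- B[2, 1] <- eps * 4
  toy_system(c(16, 16), rbind(c(0, 0, 0), c(rmin + displace, 0, 0)),
             lj_A = A, lj_B = B)
}
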