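## Toy steered Langevin-dynamics engine.
##
## Few-atom systems with pairwise LJ(12-6-1) nonbonded interactions
##   U_nb = sum_pairs A_ij / r^12 - B_ij / r^6 + C q_i q_j / r
## (C = 332.0636 kcal A / mol e^2, direct sums, no cutoff, no periodicity),
## harmonic bonds/angles, and optional per-axis positional restraints. A
## moving harmonic restraint V = k/2 (xi - lambda(t))^2 on a distance or
## distance-difference reaction coordinate drags the system between states;
## the accumulated external work feeds the Jarzynski estimator.
##
## Units: kcal/mol, angstrom, amu, fs, K; friction gamma in 1/ps. The
## integrator is the BAOAB Langevin splitting, which reduces to velocity
## Verlet when gamma = 0 and T = 0.

#' Define a toy few-atom system
#'
#' @param masses numeric vector of atomic masses, amu (> 0)
#' @param positions n x 3 matrix of Cartesian coordinates, angstrom
#' @param charges per-atom partial charges, e (default 0)
#' @param lj_A,lj_B symmetric n x n matrices of pairwise LJ coefficients
#'   (kcal A^12/mol and kcal A^6/mol; default all zero)
#' @param bonds data frame \code{i, j, k_b, r0} of harmonic bonds
#'   (kcal/mol/A^2, A); bonded pairs are excluded from the nonbonded sum
#' @param angles optional data frame \code{i, j, k, k_theta, theta0} of
#'   harmonic angles (kcal/mol/rad^2, radians; \code{j} is the vertex)
#' @param restraints optional data frame \code{atom, axis, k, x0} of
#'   per-axis harmonic positional restraints (\code{axis} in 1:3)
#' @param fixed logical vector marking atoms frozen in place
#' @return object of class \code{toy_system}
#' @export
toy_system <- function(masses, positions, charges = NULL,
                       lj_A = NULL, lj_B = NULL, bonds = NULL,
                       angles = NULL, restraints = NULL, fixed = NULL) {
  n <- length(masses)
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (n < 1L || any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive and finite")
  if (!is.matrix(positions) || nrow(positions) != n || ncol(positions) != 3 ||
      any(!is.finite(positions)))
    stop("positions must be a finite n x 3 matrix")
  if (is.null(charges)) charges <- numeric(n)
  if (is.null(lj_A)) lj_A <- matrix(0, n, n)
  if (is.null(lj_B)) lj_B <- matrix(0, n, n)
  if (!isSymmetric(unname(lj_A)) || !isSymmetric(unname(lj_B)))
    stop("LJ coefficient matrices must be symmetric")
  if (any(lj_A < 0) || any(lj_B < 0))
    stop("LJ coefficients must be nonnegative")
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  stopifnot(length(charges) == n, length(fixed) == n)
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "k_b", "r0") %in% names(bonds)))
    if (any(bonds$i == bonds$j)) stop("a bond must join two distinct atoms")
  }
  if (!is.null(angles)) {
    angles <- as.data.frame(angles)
    stopifnot(all(c("i", "j", "k", "k_theta", "theta0") %in% names(angles)))
  }
  if (!is.null(restraints)) {
    restraints <- as.data.frame(restraints)
    stopifnot(all(c("atom", "axis", "k", "x0") %in% names(restraints)),
              all(restraints$axis %in% 1:3))
  }
  # nonbonded pair list: i < j, bonded pairs excluded
  excl <- matrix(FALSE, n, n)
  if (!is.null(bonds) && nrow(bonds)) {
    excl[cbind(bonds$i, bonds$j)] <- TRUE
    excl[cbind(bonds$j, bonds$i)] <- TRUE
  }
  pi_ <- integer(0); pj_ <- integer(0)
  if (n >= 2L) {
    cmb <- utils::combn(n, 2)
    keep <- !excl[cbind(cmb[1, ], cmb[2, ])]
    pi_ <- cmb[1, keep]; pj_ <- cmb[2, keep]
  }
  structure(list(masses = as.numeric(masses), positions = positions,
                 charges = as.numeric(charges), lj_A = lj_A, lj_B = lj_B,
                 bonds = bonds, angles = angles, restraints = restraints,
                 fixed = as.logical(fixed),
                 pairs = list(i = pi_, j = pj_,
                              A = lj_A[cbind(pi_, pj_)],
                              B = lj_B[cbind(pi_, pj_)],
                              qq = .const$coulomb *
                                   charges[pi_] * charges[pj_])),
            class = "toy_system")
}

#' @export
print.toy_system <- function(x, ...) {
  cat(sprintf("Toy system: %d atom%s, %d nonbonded pair%s, %d bond%s\n",
              length(x$masses), if (length(x$masses) == 1) "" else "s",
              length(x$pairs$i), if (length(x$pairs$i) == 1) "" else "s",
              if (is.null(x$bonds)) 0 else nrow(x$bonds),
              if (!is.null(x$bonds) && nrow(x$bonds) == 1) "" else "s"))
  invisible(x)
}

# potential energy and forces in one pass; positions is an n x 3 matrix
.energy_forces <- function(system, positions) {
  n <- nrow(positions)
  U <- 0
  F <- matrix(0, n, 3)
  p <- system$pairs
  if (length(p$i)) {
    d  <- positions[p$i, , drop = FALSE] - positions[p$j, , drop = FALSE]
    r2 <- rowSums(d * d)
    if (any(r2 < 1e-12)) stop("coincident nonbonded atom pair")
    r   <- sqrt(r2)
    ir6 <- 1 / (r2 * r2 * r2)
    U <- U + sum(p$A * ir6 * ir6 - p$B * ir6 + p$qq / r)
    # dU/dr terms: -12 A r^-13 + 6 B r^-7 - qq r^-2; force = -dU/dr * unit
    coef <- (12 * p$A * ir6 * ir6 - 6 * p$B * ir6 + p$qq / r) / r2
    fp <- d * coef
    for (k in seq_along(p$i)) {
      F[p$i[k], ] <- F[p$i[k], ] + fp[k, ]
      F[p$j[k], ] <- F[p$j[k], ] - fp[k, ]
    }
  }
  b <- system$bonds
  if (!is.null(b) && nrow(b)) {
    for (k in seq_len(nrow(b))) {
      d <- positions[b$i[k], ] - positions[b$j[k], ]
      r <- sqrt(sum(d * d))
      if (r < 1e-12) stop("coincident bonded atom pair")
      U <- U + b$k_b[k] * (r - b$r0[k])^2
      f <- -2 * b$k_b[k] * (r - b$r0[k]) * d / r
      F[b$i[k], ] <- F[b$i[k], ] + f
      F[b$j[k], ] <- F[b$j[k], ] - f
    }
  }
  a <- system$angles
  if (!is.null(a) && nrow(a)) {
    for (k in seq_len(nrow(a))) {
      rij <- positions[a$i[k], ] - positions[a$j[k], ]
      rkj <- positions[a$k[k], ] - positions[a$j[k], ]
      nij <- sqrt(sum(rij^2)); nkj <- sqrt(sum(rkj^2))
      cth <- sum(rij * rkj) / (nij * nkj)
      cth <- min(1, max(-1, cth))
      th  <- acos(cth)
      U <- U + a$k_theta[k] * (th - a$theta0[k])^2
      sth <- sqrt(max(1e-12, 1 - cth^2))
      dU  <- 2 * a$k_theta[k] * (th - a$theta0[k])
      di <- (rkj / (nij * nkj) - cth * rij / nij^2) / (-sth)
      dk <- (rij / (nij * nkj) - cth * rkj / nkj^2) / (-sth)
      F[a$i[k], ] <- F[a$i[k], ] - dU * di
      F[a$k[k], ] <- F[a$k[k], ] - dU * dk
      F[a$j[k], ] <- F[a$j[k], ] + dU * (di + dk)
    }
  }
  rs <- system$restraints
  if (!is.null(rs) && nrow(rs)) {
    for (k in seq_len(nrow(rs))) {
      dx <- positions[rs$atom[k], rs$axis[k]] - rs$x0[k]
      U <- U + 0.5 * rs$k[k] * dx^2
      F[rs$atom[k], rs$axis[k]] <- F[rs$atom[k], rs$axis[k]] - rs$k[k] * dx
    }
  }
  list(U = U, F = F)
}

#' Potential energy of a toy system
#'
#' Direct pairwise LJ(12-6-1) sum over the nonbonded pair list plus
#' harmonic bond, angle and positional-restraint terms.
#'
#' @param system a \code{toy_system}
#' @param positions optional n x 3 matrix overriding the stored coordinates
#' @return potential energy in kcal/mol
#' @export
potential_energy <- function(system, positions = system$positions) {
  stopifnot(inherits(system, "toy_system"))
  .energy_forces(system, as.matrix(positions))$U
}

#' Forces on all atoms
#'
#' Analytic gradient of \code{\link{potential_energy}}; obeys Newton's
#' third law pairwise and sums to zero when no positional restraint is
#' present.
#'
#' @inheritParams potential_energy
#' @return n x 3 matrix of forces, kcal/mol/A
#' @export
forces <- function(system, positions = system$positions) {
  stopifnot(inherits(system, "toy_system"))
  .energy_forces(system, as.matrix(positions))$F
}

#' Define a reaction coordinate
#'
#' Either a plain interatomic distance d(a, b) or a distance difference
#' d(a, b) - d(a, c), the two coordinate families used to steer the
#' pulling simulations.
#'
#' @param kind \code{"distance"} or \code{"distance_difference"}
#' @param atoms integer vector of atom indices: \code{c(a, b)} for a
#'   distance, \code{c(a, b, c)} for d(a, b) - d(a, c)
#' @return object of class \code{reaction_coordinate}
#' @export
reaction_coordinate <- function(kind = c("distance", "distance_difference"),
                                atoms) {
  kind <- match.arg(kind)
  atoms <- as.integer(atoms)
  need <- if (kind == "distance") 2L else 3L
  if (length(atoms) != need || anyDuplicated(atoms))
    stop(sprintf("%s coordinate needs %d distinct atom indices", kind, need))
  structure(list(kind = kind, atoms = atoms), class = "reaction_coordinate")
}

#' Value and analytic gradient of a reaction coordinate
#'
#' @param rc a \code{reaction_coordinate}
#' @param positions n x 3 coordinate matrix, angstrom
#' @return list with \code{value} (angstrom) and \code{grad} (n x 3); for a
#'   distance the per-atom gradient blocks are unit vectors, for a
#'   difference the signed sum of unit vectors
#' @export
rc_value_and_gradient <- function(rc, positions) {
  stopifnot(inherits(rc, "reaction_coordinate"))
  positions <- as.matrix(positions)
  g <- matrix(0, nrow(positions), 3)
  a <- rc$atoms
  dab <- positions[a[1], ] - positions[a[2], ]
  rab <- sqrt(sum(dab^2))
  if (rab < 1e-12) stop("coincident atoms in reaction coordinate")
  uab <- dab / rab
  if (rc$kind == "distance") {
    g[a[1], ] <- uab; g[a[2], ] <- -uab
    return(list(value = rab, grad = g))
  }
  dac <- positions[a[1], ] - positions[a[3], ]
  rac <- sqrt(sum(dac^2))
  if (rac < 1e-12) stop("coincident atoms in reaction coordinate")
  uac <- dac / rac
  g[a[1], ] <- uab - uac
  g[a[2], ] <- -uab
  g[a[3], ] <- uac
  list(value = rab - rac, grad = g)
}

#' Define a pulling protocol
#'
#' A harmonic restraint of stiffness \code{k_spring} on the reaction
#' coordinate whose centre moves linearly from \code{lambda_start} to
#' \code{lambda_end} over \code{n_steps} integration steps, preceded by
#' \code{n_equil} equilibration steps at \code{lambda_start}.
#'
#' @param rc a \code{reaction_coordinate}
#' @param lambda_start,lambda_end restraint-centre endpoints, angstrom
#' @param n_steps number of pulling steps (>= 1)
#' @param k_spring restraint stiffness, kcal/mol/A^2 (>= 0)
#' @param dt time step, fs
#' @param gamma Langevin friction, 1/ps (0 gives deterministic dynamics)
#' @param T temperature, K (0 switches the thermostat noise off)
#' @param seed integer seed for the thermostat noise
#' @param n_equil equilibration steps before work accumulation
#' @return object of class \code{pulling_protocol}
#' @export
pulling_protocol <- function(rc, lambda_start, lambda_end, n_steps,
                             k_spring, dt = 0.5, gamma = 1,
                             T = .const$T_default, seed = 1, n_equil = 0) {
  stopifnot(inherits(rc, "reaction_coordinate"),
            is.finite(lambda_start), is.finite(lambda_end))
  if (n_steps < 1) stop("n_steps must be at least 1")
  if (dt <= 0) stop("dt must be positive")
  if (k_spring < 0) stop("k_spring must be nonnegative")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (T < 0) stop("temperature must be nonnegative")
  structure(list(rc = rc, lambda_start = lambda_start,
                 lambda_end = lambda_end, n_steps = as.integer(n_steps),
                 k_spring = k_spring, dt = dt, gamma = gamma, T = T,
                 seed = as.integer(seed), n_equil = as.integer(n_equil)),
            class = "pulling_protocol")
}

#' Run one steered Langevin pull
#'
#' BAOAB integration with the moving harmonic restraint. During each
#' pulling step the restraint centre sits at the midpoint of its schedule
#' segment and the work increment is
#' \code{-k_spring (xi - lambda_mid) dlambda} (midpoint rule), which is
#' exact for a static system.
#'
#' @param system a \code{toy_system}
#' @param protocol a \code{pulling_protocol}
#' @param record keep the per-step trajectory table (default TRUE); with
#'   FALSE only the endpoints are recorded, which is faster for ensembles
#' @return object of class \code{work_trajectory}: list with
#'   \code{records} (data frame: time fs, lambda, xi, restraint_energy,
#'   work), \code{final_work} (kcal/mol), \code{final_positions}
#' @export
run_pull <- function(system, protocol, record = TRUE) {
  stopifnot(inherits(system, "toy_system"),
            inherits(protocol, "pulling_protocol"))
  .with_seed(protocol$seed,
             .run_pull_impl(system, protocol, record))
}

.run_pull_impl <- function(system, protocol, record) {
  x <- system$positions
  n <- nrow(x)
  mobile <- !system$fixed
  m  <- system$masses
  dt <- protocol$dt
  k  <- protocol$k_spring
  rc <- protocol$rc
  kf <- .const$accel                       # (kcal/mol/A)/amu -> A/fs^2
  inv_m <- kf / m
  c1 <- exp(-protocol$gamma * dt * 1e-3)   # gamma is 1/ps, dt fs
  kT <- .RT(max(protocol$T, 0))
  c2 <- sqrt((1 - c1^2) * kT * kf / m)     # A/fs
  v <- matrix(0, n, 3)
  if (protocol$T > 0) {
    v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(kT * kf / m)
    v[!mobile, ] <- 0
  }

  # the physical force and the rc value/gradient depend only on positions;
  # cache them so a change of restraint centre between steps costs nothing
  phys_rc <- function(pos) {
    r <- rc_value_and_gradient(rc, pos)
    list(Fp = .energy_forces(system, pos)$F, xi = r$value, grad = r$grad)
  }
  with_restraint <- function(pc, lam) pc$Fp - k * (pc$xi - lam) * pc$grad

  N  <- protocol$n_steps
  lam_path <- protocol$lambda_start +
    (protocol$lambda_end - protocol$lambda_start) * (0:N) / N
  n_eq <- protocol$n_equil
  tot  <- n_eq + N

  W <- 0
  if (record) {
    rec_t <- rec_lam <- rec_xi <- rec_re <- rec_W <- numeric(N + 1)
  }
  pc <- phys_rc(x)
  if (record) {
    rec_t[1] <- 0; rec_lam[1] <- lam_path[1]; rec_xi[1] <- pc$xi
    rec_re[1] <- 0.5 * k * (pc$xi - lam_path[1])^2; rec_W[1] <- 0
  }
  for (step in seq_len(tot)) {
    pulling <- step > n_eq
    if (pulling) {
      i   <- step - n_eq
      lam <- 0.5 * (lam_path[i] + lam_path[i + 1])   # mid-schedule centre
      dl  <- lam_path[i + 1] - lam_path[i]
    } else {
      lam <- lam_path[1]; dl <- 0
    }
    # B: half kick (restraint re-centred at this step's lambda; the cached
    # physical force and rc gradient are still valid at these positions)
    fr <- with_restraint(pc, lam)
    v[mobile, ] <- v[mobile, ] + 0.5 * dt * fr[mobile, , drop = FALSE] *
      inv_m[mobile]
    # A: half drift
    x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
    # O: thermostat
    if (protocol$gamma > 0) {
      v[mobile, ] <- c1 * v[mobile, , drop = FALSE] +
        c2[mobile] * matrix(stats::rnorm(3 * sum(mobile)), sum(mobile), 3)
    }
    # A: half drift
    x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
    if (any(abs(x) > 1e6))
      stop(sprintf("integration failure: coordinate blow-up at step %d", step))
    # B: half kick at the new positions
    pc <- phys_rc(x)
    fr <- with_restraint(pc, lam)
    v[mobile, ] <- v[mobile, ] + 0.5 * dt * fr[mobile, , drop = FALSE] *
      inv_m[mobile]
    if (pulling) {
      W <- W - k * (pc$xi - lam) * dl
      if (record) {
        i <- step - n_eq
        rec_t[i + 1]   <- i * dt
        rec_lam[i + 1] <- lam_path[i + 1]
        rec_xi[i + 1]  <- pc$xi
        rec_re[i + 1]  <- 0.5 * k * (pc$xi - lam_path[i + 1])^2
        rec_W[i + 1]   <- W
      }
    }
  }
  records <- if (record) {
    data.frame(time = rec_t, lambda = rec_lam, xi = rec_xi,
               restraint_energy = rec_re, work = rec_W)
  } else NULL
  structure(list(records = records, final_work = W, final_positions = x,
                 protocol = protocol),
            class = "work_trajectory")
}

#' @export
print.work_trajectory <- function(x, ...) {
  p <- x$protocol
  cat(sprintf(
    "Steered pull: lambda %.3f -> %.3f A in %d steps (k = %g kcal/mol/A^2)\n",
    p$lambda_start, p$lambda_end, p$n_steps, p$k_spring))
  cat(sprintf("  final work W = %.4f kcal/mol\n", x$final_work))
  invisible(x)
}

#' Run an ensemble of independent steered pulls
#'
#' Replica r runs with seed \code{seed + r} (a deterministic split of the
#' master seed), so the ensemble is reproducible as a whole and each
#' replica individually.
#'
#' @param system a \code{toy_system}
#' @param protocol a \code{pulling_protocol} (its own seed is ignored)
#' @param n_replicas number of independent pulls (>= 1)
#' @param seed master integer seed
#' @return a \code{\link{work_sample}} of the final work values, at the
#'   protocol's temperature
#' @export
run_pull_ensemble <- function(system, protocol, n_replicas, seed = 1) {
  if (n_replicas < 1) stop("n_replicas must be at least 1")
  works <- vapply(seq_len(n_replicas), function(r) {
    pr <- protocol
    pr$seed <- as.integer(seed + r)
    tryCatch(run_pull(system, pr, record = FALSE)$final_work,
             error = function(e)
               stop(sprintf("replica %d: %s", r, conditionMessage(e))))
  }, numeric(1))
  work_sample(works, T = if (protocol$T > 0) protocol$T else .const$T_default,
              protocol_id = sprintf("ensemble[n=%d,seed=%d]", n_replicas, seed))
}

#' Unbiased Langevin sampling with kinetic-energy statistics
#'
#' Runs plain (unsteered) BAOAB dynamics and records the kinetic energy of
#' the mobile atoms, mainly to check thermalization: at equilibrium the
#' mean kinetic energy per degree of freedom is RT/2.
#'
#' @param system a \code{toy_system}
#' @param n_steps number of integration steps
#' @param dt time step, fs
#' @param gamma friction, 1/ps
#' @param T temperature, K
#' @param seed integer seed
#' @param sample_every record energies every this many steps
#' @return list with \code{kinetic} and \code{potential} (vectors of
#'   sampled energies, kcal/mol), \code{n_dof} (mobile degrees of freedom)
#'   and \code{final_positions}
#' @export
run_langevin <- function(system, n_steps, dt = 0.5, gamma = 1,
                         T = .const$T_default, seed = 1, sample_every = 10) {
  stopifnot(inherits(system, "toy_system"), n_steps >= 1, dt > 0, gamma >= 0)
  .with_seed(seed, {
    x <- system$positions
    n <- nrow(x)
    mobile <- which(!system$fixed)
    nm <- length(mobile)
    m  <- system$masses
    kf <- .const$accel
    inv_m <- kf / m
    c1 <- exp(-gamma * dt * 1e-3)
    kT <- .RT(max(T, 0))
    c2 <- sqrt((1 - c1^2) * kT * kf / m)
    v <- matrix(0, n, 3)
    if (T > 0) {
      v <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(kT * kf / m)
      v[-mobile, ] <- 0
    }
    ke <- pe <- numeric(n_steps %/% sample_every)
    kidx <- 0L
    ef <- .energy_forces(system, x)
    fr <- ef$F
    for (step in seq_len(n_steps)) {
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fr[mobile, , drop = FALSE] *
        inv_m[mobile]
      x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
      if (gamma > 0)
        v[mobile, ] <- c1 * v[mobile, , drop = FALSE] +
          c2[mobile] * matrix(stats::rnorm(3 * nm), nm, 3)
      x[mobile, ] <- x[mobile, ] + 0.5 * dt * v[mobile, , drop = FALSE]
      if (any(abs(x) > 1e6))
        stop(sprintf("integration failure: coordinate blow-up at step %d", step))
      fr <- .energy_forces(system, x)$F
      v[mobile, ] <- v[mobile, ] + 0.5 * dt * fr[mobile, , drop = FALSE] *
        inv_m[mobile]
      if (step %% sample_every == 0L) {
        kidx <- kidx + 1L
        ke[kidx] <- 0.5 * sum(m[mobile] *
                              rowSums(v[mobile, , drop = FALSE]^2)) / kf
        pe[kidx] <- .energy_forces(system, x)$U
      }
    }
    list(kinetic = ke, potential = pe, n_dof = 3L * nm, final_positions = x)
  })
}
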