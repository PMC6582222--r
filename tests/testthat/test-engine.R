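test_that("LJ(12-6-1) energies match closed forms", {
  # LJ minimum: U(r_min) = -B^2/(4A)
  d <- lj_dimer(eps = 0.25)
  expect_equal(potential_energy(d), -0.25, tolerance = 1e-12)
  # independent 1-D minimization oracle
  u1d <- function(r) 1 / r^12 - 1 / r^6    # A = B = 1
  opt <- optimize(u1d, c(0.8, 3))
  A <- matrix(c(0, 1, 1, 0), 2); B <- A
  sys1 <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(opt$minimum, 0, 0)),
                     lj_A = A, lj_B = B)
  expect_equal(potential_energy(sys1), opt$objective, tolerance = 1e-9)

  # pure Coulomb: C q1 q2 / r with C = 332.0636
  sq <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(3.320636, 0, 0)),
                   charges = c(1, -1))
  expect_equal(potential_energy(sq), -100, tolerance = 1e-12)

  # single atom has no pairs
  expect_equal(potential_energy(toy_system(1, matrix(0, 1, 3))), 0)
  # coincident nonbonded pair is a domain error
  expect_error(potential_energy(toy_system(c(1, 1), matrix(0, 2, 3))),
               "coincident")
})

test_that("bonded pairs are excluded from the nonbonded sum", {
  A <- matrix(1e6, 2, 2); diag(A) <- 0
  sys <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                    lj_A = A, lj_B = matrix(0, 2, 2),
                    bonds = data.frame(i = 1, j = 2, k_b = 10, r0 = 1.2))
  expect_equal(potential_energy(sys), 10 * 0.3^2, tolerance = 1e-12)
})

test_that("analytic forces match finite differences and conserve momentum", {
  expect_lt(max(abs(forces(lj_dimer()))), 1e-8)   # stationary point
  set.seed(21)
  for (rep in 1:5) {
    pos <- matrix(rnorm(12, sd = 3), 4)
    A <- matrix(runif(16, 0, 2), 4); A <- A + t(A); diag(A) <- 0
    B <- matrix(runif(16, 0, 4), 4); B <- B + t(B); diag(B) <- 0
    sys <- toy_system(c(12, 16, 14, 1), pos,
                      charges = c(0.4, -0.3, -0.2, 0.1),
                      lj_A = A, lj_B = B,
                      bonds = data.frame(i = 1, j = 2, k_b = 250, r0 = 1.4),
                      angles = data.frame(i = 1, j = 2, k = 3,
                                          k_theta = 35, theta0 = 2.0))
    f <- forces(sys)
    expect_equal(f, fd_forces(sys, pos), tolerance = 1e-5)
    expect_lt(max(abs(colSums(f))), 1e-9)   # translation invariance
  }
})

test_that("reaction coordinates evaluate exactly with finite-difference gradients", {
  pos <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  rc <- reaction_coordinate("distance", c(1, 2))
  out <- rc_value_and_gradient(rc, pos)
  expect_equal(out$value, 5)
  expect_equal(sqrt(rowSums(out$grad[1:2, ]^2)), c(1, 1))   # unit vectors

  # symmetric difference coordinate vanishes
  poss <- rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0))
  rcd <- reaction_coordinate("distance_difference", c(1, 2, 3))
  expect_equal(rc_value_and_gradient(rcd, poss)$value, 0)

  set.seed(33)
  for (rep in 1:5) {
    p <- matrix(rnorm(9, sd = 2), 3)
    for (rcx in list(rc, rcd)) {
      an <- rc_value_and_gradient(rcx, p)
      h <- 1e-6
      fd <- matrix(0, 3, 3)
      for (i in 1:3) for (dd in 1:3) {
        pp <- p; pp[i, dd] <- pp[i, dd] + h
        pm <- p; pm[i, dd] <- pm[i, dd] - h
        fd[i, dd] <- (rc_value_and_gradient(rcx, pp)$value -
                      rc_value_and_gradient(rcx, pm)$value) / (2 * h)
      }
      expect_equal(an$grad, fd, tolerance = 1e-6)
    }
  }
  expect_error(reaction_coordinate("distance", c(1, 1)), "distinct")
  expect_error(rc_value_and_gradient(rc, matrix(0, 2, 3)), "coincident")
})

test_that("uncoupled or unscheduled pulls do no work", {
  bm <- gen_pull_benchmark("flat")
  rc <- bm$protocol$rc
  p0 <- pulling_protocol(rc, 2.5, 4.5, n_steps = 200, k_spring = 0,
                         dt = 0.5, gamma = 2, seed = 4)
  expect_equal(run_pull(bm$system, p0)$final_work, 0)
  p1 <- pulling_protocol(rc, 2.5, 2.5, n_steps = 200, k_spring = 50,
                         dt = 0.5, gamma = 2, seed = 4)
  expect_equal(run_pull(bm$system, p1)$final_work, 0, tolerance = 1e-12)
})

test_that("deterministic limit reproduces an independent velocity-Verlet integration", {
  # gamma = 0, T = 0, no restraint: particle oscillating in a harmonic bond
  sys <- toy_system(c(16, 16), rbind(c(0, 0, 0), c(1.8, 0, 0)),
                    fixed = c(TRUE, FALSE),
                    bonds = data.frame(i = 1, j = 2, k_b = 150, r0 = 1.5))
  rc <- reaction_coordinate("distance", c(2, 1))
  prot <- pulling_protocol(rc, 1.8, 1.8, n_steps = 400, k_spring = 0,
                           dt = 0.5, gamma = 0, T = 0, seed = 1)
  tr <- run_pull(sys, prot)
  ref <- vv_reference(sys, 400, 0.5)
  ref_xi <- vapply(ref, function(x) sqrt(sum((x[2, ] - x[1, ])^2)),
                   numeric(1))
  expect_equal(tr$records$xi, ref_xi, tolerance = 1e-8)
  expect_lt(max(abs(tr$records$xi - ref_xi)), 1e-6)
})

test_that("work on a frozen system matches the static closed form", {
  bm <- gen_pull_benchmark("flat")
  sys <- bm$system
  sys$fixed <- c(TRUE, TRUE)             # freeze the pulled particle too
  rc <- reaction_coordinate("distance", c(2, 1))
  # xi is frozen at 2.5; W = k/2 [(xi-l1)^2 - (xi-l0)^2] exactly
  for (k in c(5, 50)) {
    pr <- pulling_protocol(rc, 2.5, 4.5, n_steps = 137, k_spring = k,
                           dt = 0.5, gamma = 0, T = 0)
    expect_equal(run_pull(sys, pr)$final_work, k / 2 * 4, tolerance = 1e-12)
  }
  # symmetric endpoints about the frozen coordinate: equal work both ways
  fwd <- pulling_protocol(rc, 1.5, 3.5, n_steps = 80, k_spring = 20,
                          dt = 0.5, gamma = 0, T = 0)
  rev <- pulling_protocol(rc, 3.5, 1.5, n_steps = 80, k_spring = 20,
                          dt = 0.5, gamma = 0, T = 0)
  expect_equal(run_pull(sys, fwd)$final_work, run_pull(sys, rev)$final_work,
               tolerance = 1e-12)
})

test_that("pull ensembles are deterministic with split replica seeds", {
  bm <- gen_pull_benchmark("flat")
  pr <- bm$protocol
  pr$n_steps <- 150L; pr$n_equil <- 50L
  s1 <- run_pull_ensemble(bm$system, pr, 4, seed = 42)
  s2 <- run_pull_ensemble(bm$system, pr, 4, seed = 42)
  expect_identical(s1$works, s2$works)
  expect_identical(length(unique(s1$works)), 4L)
  # one replica reproduces a single pull at the derived seed
  pr1 <- pr; pr1$seed <- 43L
  expect_equal(run_pull_ensemble(bm$system, pr, 1, seed = 42)$works,
               run_pull(bm$system, pr1)$final_work)
})

test_that("microcanonical dynamics conserve energy over 1e4 steps", {
  sys <- lj_dimer(eps = 0.25, displace = 0.05)
  out <- run_langevin(sys, n_steps = 1e4, dt = 0.5, gamma = 0, T = 0,
                      seed = 1, sample_every = 10)
  etot <- out$kinetic + out$potential
  e0 <- potential_energy(sys)
  expect_lt(max(abs(etot - e0)) / abs(e0), 1e-4)
})

test_that("Langevin sampling satisfies equipartition", {
  sys <- toy_system(c(16, 16), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                    fixed = c(TRUE, FALSE),
                    bonds = data.frame(i = 1, j = 2, k_b = 100, r0 = 1.5))
  out <- run_langevin(sys, n_steps = 2e5, dt = 0.5, gamma = 20, T = 298.15,
                      seed = 17, sample_every = 10)
  ke_per_dof <- mean(out$kinetic) / out$n_dof
  expect_equal(ke_per_dof, RT298 / 2, tolerance = 0.05)
})

test_that("mean work dominates the Jarzynski estimate and the analytic limit", {
  bm <- gen_pull_benchmark("flat")
  pr <- bm$protocol
  pr$n_steps <- 500L; pr$n_equil <- 200L
  s <- run_pull_ensemble(bm$system, pr, 30, seed = 7)
  dg <- jarzynski_dG(s)
  expect_gte(mean(s$works), dg)           # Jensen
  # second law: dissipation is nonnegative up to statistical error
  expect_gte(mean(s$works), bm$dF - 0.1)
  expect_gte(dg, bm$dF - 0.25)
})

test_that("slower pulling dissipates less work", {
  bm <- gen_pull_benchmark("flat")
  diss <- vapply(c(250L, 1000L, 4000L), function(n) {
    pr <- bm$protocol
    pr$n_steps <- n; pr$n_equil <- 200L
    mean(run_pull_ensemble(bm$system, pr, 30, seed = 13)$works) - bm$dF
  }, numeric(1))
  expect_gt(diss[1], diss[2])
  expect_gt(diss[2], diss[3])
})

test_that("numerical blow-ups are reported with the failing step", {
  sys <- toy_system(c(1, 1), rbind(c(0, 0, 0), c(1, 0, 0)),
                    charges = c(2, 2))   # strong repulsion, light atoms
  rc <- reaction_coordinate("distance", c(2, 1))
  pr <- pulling_protocol(rc, 1, 2, n_steps = 5000, k_spring = 0,
                         dt = 200, gamma = 0, T = 0)
  expect_error(run_pull(sys, pr), "blow-up at step")
})
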