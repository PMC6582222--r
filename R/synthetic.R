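## Synthetic inputs with known ground truth: Gaussian work ensembles (the
## near-equilibrium regime of repeated steered pulls, where the Jarzynski
## average has the closed form mu - sigma^2/(2RT)), toy pulling benchmarks
## whose free-energy difference is computable by quadrature, and the bundled
## reference step-energetics tables for the adenine-to-guanine transition.

#' Free energy implied by a Gaussian work distribution
#'
#' For normally distributed work the Jarzynski average evaluates in closed
#' form to \code{mu - sigma2 / (2 RT)}.
#'
#' @param mu mean work, kcal/mol
#' @param sigma2 work variance, kcal^2/mol^2
#' @param T temperature, K
#' @return implied free-energy difference, kcal/mol
#' @export
implied_dG <- function(mu, sigma2, T = .const$T_default) {
  .check_T(T)
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  mu - sigma2 / (2 * .RT(T))
}

#' Generate a Gaussian work ensemble
#'
#' @param mu mean work, kcal/mol
#' @param sigma2 work variance, kcal^2/mol^2 (>= 0)
#' @param n sample size (>= 1)
#' @param T temperature, K
#' @param seed integer seed; the draw is a pure function of the arguments
#' @return a \code{\link{work_sample}} carrying the analytic
#'   \code{implied_dG} as an attribute
#' @examples
#' s <- gen_gaussian_works(10, 1.18497, n = 1000, seed = 7)
#' attr(s, "implied_dG")        # 9.0 at 298.15 K
#' @export
gen_gaussian_works <- function(mu, sigma2, n, T = .const$T_default, seed = 1) {
  if (n < 1) stop("n must be at least 1")
  if (sigma2 < 0) stop("sigma2 must be nonnegative")
  w <- .with_seed(seed, stats::rnorm(n, mu, sqrt(sigma2)))
  s <- work_sample(w, T, sprintf("gaussian(mu=%g,sigma2=%g,seed=%d)",
                                 mu, sigma2, seed))
  attr(s, "implied_dG") <- implied_dG(mu, sigma2, T)
  s
}

#' Analytic pulling benchmarks for the steered-dynamics chain
#'
#' Builds a toy system, a pulling protocol, and the exact free-energy
#' difference between the restrained end states, so the full
#' pull -> work -> Jarzynski chain can be validated.
#'
#' \describe{
#'   \item{flat}{a single mobile particle with no internal potential,
#'     tethered to the pulling axis by stiff transverse positional
#'     restraints; the restrained free energy is independent of the
#'     restraint centre, so \code{dF = 0} between any endpoints.}
#'   \item{two_state}{a mobile particle between two fixed Lennard-Jones
#'     anchors with different well depths, giving an asymmetric double-well
#'     potential along the axis; \code{dF} is computed by trapezoidal
#'     quadrature of the Boltzmann factor of
#'     \code{U(x) + k/2 (x - lambda)^2} along the effective 1-D
#'     coordinate.}
#' }
#'
#' The transverse tethers make the motion effectively one-dimensional, which
#' is what renders the quadrature oracle exact for the sampled system (up to
#' the residual transverse coupling of the LJ terms, far below the
#' statistical resolution of a pulling ensemble).
#'
#' @param kind \code{"flat"} or \code{"two_state"}
#' @param lambda_start,lambda_end restraint-centre endpoints, angstrom
#' @param k_spring pulling-restraint stiffness, kcal/mol/A^2
#' @param n_steps,dt,gamma,T,n_equil integrator settings, see
#'   \code{\link{pulling_protocol}}
#' @param eps1,eps2 anchor LJ well depths, kcal/mol (two_state only)
#' @param r_min LJ minimum distance of both anchors, angstrom
#' @param separation distance between the two anchors, angstrom
#' @param k_tether transverse positional-restraint stiffness, kcal/mol/A^2
#' @param n_quad quadrature grid points for the oracle
#' @return list with \code{system}, \code{protocol}, \code{dF} (kcal/mol),
#'   and for \code{two_state} also \code{U_1d}, the effective 1-D
#'   potential function of x
#' @export
gen_pull_benchmark <- function(kind = c("flat", "two_state"),
                               lambda_start = 2.5, lambda_end = 4.5,
                               k_spring = 100, n_steps = 6000, dt = 0.5,
                               gamma = 5, T = .const$T_default,
                               n_equil = 1000,
                               eps1 = 2.0, eps2 = 1.0, r_min = 2.5,
                               separation = 7.0, k_tether = 1000,
                               n_quad = 10000) {
  kind <- match.arg(kind)
  rt <- .RT(T)
  if (kind == "flat") {
    sys <- toy_system(
      masses = c(16, 16),
      positions = rbind(c(0, 0, 0), c(lambda_start, 0, 0)),
      fixed = c(TRUE, FALSE),
      restraints = data.frame(atom = c(2, 2), axis = c(2, 3),
                              k = k_tether, x0 = 0))
    rc <- reaction_coordinate("distance", c(2, 1))
    prot <- pulling_protocol(rc, lambda_start, lambda_end, n_steps,
                             k_spring, dt, gamma, T, seed = 1,
                             n_equil = n_equil)
    return(list(system = sys, protocol = prot, dF = 0))
  }
  # two_state: anchors at x = 0 and x = separation, mobile in between
  ljA <- matrix(0, 3, 3); ljB <- matrix(0, 3, 3)
  ljA[1, 3] <- ljA[3, 1] <- eps1 * r_min^12
  ljB[1, 3] <- ljB[3, 1] <- 2 * eps1 * r_min^6
  ljA[2, 3] <- ljA[3, 2] <- eps2 * r_min^12
  ljB[2, 3] <- ljB[3, 2] <- 2 * eps2 * r_min^6
  sys <- toy_system(
    masses = c(16, 16, 14),
    positions = rbind(c(0, 0, 0), c(separation, 0, 0),
                      c(lambda_start, 0, 0)),
    lj_A = ljA, lj_B = ljB,
    fixed = c(TRUE, TRUE, FALSE),
    restraints = data.frame(atom = c(3, 3), axis = c(2, 3),
                            k = k_tether, x0 = 0))
  rc <- reaction_coordinate("distance", c(3, 1))
  prot <- pulling_protocol(rc, lambda_start, lambda_end, n_steps,
                           k_spring, dt, gamma, T, seed = 1,
                           n_equil = n_equil)
  lj <- function(eps, r) eps * ((r_min / r)^12 - 2 * (r_min / r)^6)
  U_1d <- function(x) lj(eps1, x) + lj(eps2, separation - x)
  f_restr <- function(lambda) {
    # restrained 1-D configurational free energy at this restraint centre
    xs <- seq(0.8 * r_min, separation - 0.8 * r_min, length.out = n_quad)
    u <- U_1d(xs) + 0.5 * k_spring * (xs - lambda)^2
    m <- min(u)
    -rt * (log(sum(exp(-(u - m) / rt)) * (xs[2] - xs[1])) - m / rt)
  }
  list(system = sys, protocol = prot,
       dF = f_restr(lambda_end) - f_restr(lambda_start),
       U_1d = U_1d)
}

#' Reference step energetics for the adenine-to-guanine transition
#'
#' The bundled table of activation and reaction free energies (kcal/mol,
#' 298.15 K) for every elementary step, composed process and global row of
#' the water/formic-acid-assisted adenine -> hypoxanthine -> xanthine ->
#' guanine transformation, in gas and aqueous solution phases, together
#' with the published equilibrium constants, forward rate constants and
#' product lifetimes.
#'
#' The free energies are the primary quantities; K, k and tau are derived
#' via the transition-state-theory formulas (see
#' \code{\link{annotate_steps}}). The logical columns \code{K_ok},
#' \code{k_ok} and \code{tau_ok} record whether each published derived
#' value is internally consistent with the free energies of its own row
#' (within 5\% for K and 15\% for k and tau, the propagation of the tables'
#' 0.01 kcal/mol rounding through the exponentials); \code{consistent} is
#' their conjunction. A minority of published rows fail this check (e.g. a
#' likely exponent typo in one lifetime and one rate constant that was
#' evidently computed from a cumulative rather than per-step barrier), and
#' those values are flagged rather than silently corrected.
#'
#' @param phase optionally restrict to \code{"gas"} or \code{"solution"}
#' @return data frame with columns \code{phase}, \code{process},
#'   \code{label}, \code{dG_act}, \code{dG_rxn}, \code{K_printed},
#'   \code{k_printed}, \code{tau_printed}, \code{K_ok}, \code{k_ok},
#'   \code{tau_ok}, \code{consistent}; 16 rows per phase
#' @examples
#' head(ag_energetics("gas"))
#' @export
ag_energetics <- function(phase = NULL) {
  path <- system.file("extdata", "ag_step_energetics.csv",
                      package = "smdkin", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$consistent <- x$K_ok & x$k_ok & x$tau_ok
  if (!is.null(phase)) {
    phase <- match.arg(phase, c("gas", "solution"))
    x <- x[x$phase == phase, , drop = FALSE]
    rownames(x) <- NULL
  }
  x
}

#' Elementary steps of the deamination-oxidation-amination pathway
#'
#' Returns the step table for the lowest-cost route through the three
#' processes (A-pathway deamination, C oxidation, E-pathway amination),
#' ready for \code{\link{compose_profile}} / \code{\link{pathway_global}}.
#'
#' At \code{level = "step"} each process contributes its two elementary
#' steps; at \code{level = "process"} each process enters as a single
#' composed step carrying the published process-level activation and
#' reaction free energies, labelled by the transition structure at which
#' the composed barrier is reached.
#'
#' @param phase \code{"gas"} or \code{"solution"}
#' @param level \code{"step"} or \code{"process"}
#' @return data frame with columns \code{name}, \code{dG_TS},
#'   \code{dG_step}, \code{ts_label}, \code{product_label}, \code{process}
#' @examples
#' steps <- ag_pathway("gas", "process")
#' pathway_global(lapply(split(steps, steps$process), compose_profile))
#' @export
ag_pathway <- function(phase = c("gas", "solution"),
                       level = c("step", "process")) {
  phase <- match.arg(phase)
  level <- match.arg(level)
  tab <- ag_energetics(phase)
  pick <- function(labels) {
    i <- match(labels, tab$label)
    data.frame(name = tab$label[i], dG_TS = tab$dG_act[i],
               dG_step = tab$dG_rxn[i], stringsAsFactors = FALSE)
  }
  if (level == "step") {
    out <- pick(c("1A-step", "2A-step", "3C-step", "4C-step",
                  "5E-step", "6E-step"))
    out$ts_label <- paste0("TS", 1:6)
    out$product_label <- paste0("I", 1:6)
    out$process <- factor(rep(c("A", "C", "E"), each = 2),
                          levels = c("A", "C", "E"))
  } else {
    out <- pick(c("A-process", "C-process", "E-process"))
    # label each composed barrier by the transition structure at which the
    # cumulative maximum is reached in the step-level profile
    out$ts_label <- c("TS2", "TS4", "TS6")
    out$product_label <- c("I2", "I4", "I6")
    out$process <- factor(c("A", "C", "E"), levels = c("A", "C", "E"))
  }
  out
}
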