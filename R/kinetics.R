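## Transition-state-theory kinetics from step free energies.
##
## Every derived quantity comes from the activation free energy dG_act
## (transition state above the step's own reactant level) and the reaction
## free energy dG_rxn (product above reactant), both in kcal/mol:
##   K    = exp(-dG_rxn / RT)
##   k_f  = (kB T / h) exp(-dG_act / RT)
##   k_r  = (kB T / h) exp(-(dG_act - dG_rxn) / RT)
##   tau  = 1 / k_r
## All exponents are formed in log space and exponentiated last so that
## barriers up to |dG| ~ 200 kcal/mol neither overflow nor underflow.

.check_T <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be finite and positive")
}

#' Equilibrium constant from a reaction free energy
#'
#' @param dG_rxn reaction free energy in kcal/mol (product minus reactant)
#' @param T temperature in K
#' @return dimensionless equilibrium constant exp(-dG_rxn/RT); strictly
#'   decreasing in \code{dG_rxn}
#' @examples
#' equilibrium_constant(0)                 # 1
#' equilibrium_constant(-5.76)             # about 1.68e4
#' @export
equilibrium_constant <- function(dG_rxn, T = .const$T_default) {
  .check_T(T)
  if (!is.numeric(dG_rxn) || any(!is.finite(dG_rxn)))
    stop("dG_rxn must be finite")
  exp(-dG_rxn / .RT(T))
}

#' Eyring forward rate constant from an activation free energy
#'
#' @param dG_act activation free energy in kcal/mol; negative values are
#'   accepted with a warning (they can arise from composed, rounded inputs)
#' @param T temperature in K
#' @return rate constant in 1/s, (kB T/h) exp(-dG_act/RT)
#' @examples
#' eyring_rate(74.15)                      # about 2.8e-42 s^-1
#' @export
eyring_rate <- function(dG_act, T = .const$T_default) {
  .check_T(T)
  if (!is.numeric(dG_act) || any(!is.finite(dG_act)))
    stop("dG_act must be finite")
  if (any(dG_act < 0))
    warning("negative activation free energy; rate exceeds the Eyring prefactor")
  # log-space: log k = log(kB T / h) - dG_act / RT, exponentiated last
  exp(log(.const$kB * T / .const$h) - dG_act / .RT(T))
}

#' Reverse barrier of a step
#'
#' Height of the transition state above the product level,
#' \code{dG_act - dG_rxn}; it controls the reverse rate and hence the
#' product's lifetime.
#'
#' @param dG_act activation free energy, kcal/mol
#' @param dG_rxn reaction free energy, kcal/mol
#' @return reverse barrier in kcal/mol; a negative result (product above the
#'   transition state) triggers a warning, not an error
#' @export
reverse_barrier <- function(dG_act, dG_rxn) {
  if (!is.numeric(dG_act) || !is.numeric(dG_rxn) ||
      any(!is.finite(dG_act)) || any(!is.finite(dG_rxn)))
    stop("free energies must be finite")
  out <- dG_act - dG_rxn
  if (any(out < 0))
    warning("negative reverse barrier: product lies above the transition state")
  out
}

#' Lifetime of a step's product
#'
#' \code{tau = 1 / k_r} where the reverse rate constant is the Eyring rate
#' over the reverse barrier.
#'
#' @inheritParams reverse_barrier
#' @param T temperature in K
#' @return lifetime in seconds
#' @examples
#' lifetime(52.52, 3.87)                   # about 7.7e22 s
#' @export
lifetime <- function(dG_act, dG_rxn, T = .const$T_default) {
  1 / eyring_rate(reverse_barrier(dG_act, dG_rxn), T)
}

#' Derive the full kinetic description of a table of elementary steps
#'
#' Takes a data frame with one row per step (or per composed process) holding
#' at least \code{label}, \code{dG_act} and \code{dG_rxn} columns in kcal/mol
#' and appends the derived columns \code{K}, \code{k_f}, \code{k_r},
#' \code{tau} and \code{dG_rev}. Unknown columns are passed through
#' untouched and row order is preserved.
#'
#' @param steps data frame with columns \code{label}, \code{dG_act},
#'   \code{dG_rxn} (a \code{phase} column, if present, is carried along)
#' @param T temperature in K shared by all rows
#' @return the input data frame with the five derived columns appended, of
#'   class \code{step_kinetics}; zero rows in, zero rows out
#' @examples
#' annotate_steps(data.frame(label = "1A-step", dG_act = 61.11, dG_rxn = 21.72))
#' @export
annotate_steps <- function(steps, T = .const$T_default) {
  .check_T(T)
  stopifnot(is.data.frame(steps))
  need <- c("label", "dG_act", "dG_rxn")
  miss <- setdiff(need, names(steps))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- steps
  if (nrow(steps) == 0L) {
    out$K <- out$k_f <- out$k_r <- out$tau <- out$dG_rev <- numeric(0)
  } else {
    if (any(!nzchar(as.character(steps$label))))
      stop("step labels must be nonempty")
    out$K      <- equilibrium_constant(steps$dG_rxn, T)
    out$k_f    <- eyring_rate(steps$dG_act, T)
    out$dG_rev <- reverse_barrier(steps$dG_act, steps$dG_rxn)
    out$k_r    <- eyring_rate(out$dG_rev, T)
    out$tau    <- 1 / out$k_r
  }
  attr(out, "temperature") <- T
  class(out) <- c("step_kinetics", "data.frame")
  out
}

#' @export
print.step_kinetics <- function(x, digits = 3, ...) {
  cat(sprintf("Step kinetics at T = %.2f K (%d row%s)\n",
              attr(x, "temperature"), nrow(x), if (nrow(x) == 1) "" else "s"))
  y <- as.data.frame(x)
  for (cl in intersect(c("K", "k_f", "k_r", "tau"), names(y)))
    y[[cl]] <- format_sci(y[[cl]], digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
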