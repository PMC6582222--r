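## Free-energy profile composition.
##
## An elementary step contributes two numbers relative to its own reactant
## level: dG_TS (transition-state height) and dG_step (product minus
## reactant). Chaining n steps produces a profile of 2n + 1 alternating
## stationary/transition levels, all cumulative relative to the first
## stationary point. The activation free energy of the composed segment is
## the maximum cumulative transition level; its reaction free energy is the
## final stationary level.

.norm_steps <- function(steps) {
  stopifnot(is.data.frame(steps))
  need <- c("name", "dG_TS", "dG_step")
  miss <- setdiff(need, names(steps))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(steps) == 0L) stop("at least one elementary step is required")
  if (anyDuplicated(steps$name)) stop("step names must be unique")
  if (any(!is.finite(steps$dG_TS)) || any(!is.finite(steps$dG_step)))
    stop("step free energies must be finite")
  if (is.null(steps$ts_label)) steps$ts_label <- paste0("TS_", steps$name)
  if (is.null(steps$product_label)) steps$product_label <- paste0("P_", steps$name)
  steps
}

#' Compose elementary steps into a cumulative free-energy profile
#'
#' @param steps data frame with columns \code{name}, \code{dG_TS},
#'   \code{dG_step} (kcal/mol, each relative to that step's own reactant
#'   level) and optional \code{ts_label} / \code{product_label} columns
#'   naming the transition states and product minima
#' @param start cumulative level (kcal/mol) of the initial stationary point;
#'   0 for a profile anchored at the reactants
#' @param start_label label of the initial stationary point
#' @return an object of class \code{fe_profile}: a data frame with columns
#'   \code{label}, \code{kind} (\code{"stationary"} or \code{"transition"})
#'   and \code{dG} (cumulative, kcal/mol), with \code{2 n + 1} rows for
#'   \code{n} steps, strictly alternating kinds and first row at
#'   \code{start}
#' @examples
#' compose_profile(data.frame(name = "s1", dG_TS = 10, dG_step = 2))
#' @export
compose_profile <- function(steps, start = 0, start_label = "R") {
  steps <- .norm_steps(steps)
  n <- nrow(steps)
  label <- character(2 * n + 1)
  kind  <- character(2 * n + 1)
  dG    <- numeric(2 * n + 1)
  label[1] <- start_label; kind[1] <- "stationary"; dG[1] <- start
  base <- start
  for (i in seq_len(n)) {
    dG[2 * i]       <- base + steps$dG_TS[i]
    label[2 * i]    <- steps$ts_label[i]
    kind[2 * i]     <- "transition"
    base            <- base + steps$dG_step[i]
    dG[2 * i + 1]   <- base
    label[2 * i + 1] <- steps$product_label[i]
    kind[2 * i + 1] <- "stationary"
  }
  out <- data.frame(label = label, kind = kind, dG = dG,
                    stringsAsFactors = FALSE)
  class(out) <- c("fe_profile", "data.frame")
  out
}

.check_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("label", "kind", "dG") %in% names(profile)))
  n <- nrow(profile)
  if (n < 1L || n %% 2L == 0L)
    stop("a profile must have an odd number of levels (2 steps + 1)")
  exp_kind <- rep(c("stationary", "transition"), length.out = n)
  if (!identical(as.character(profile$kind), exp_kind))
    stop("profile kinds must strictly alternate stationary, transition, ...")
  invisible(profile)
}

#' Activation and reaction free energy of a composed profile
#'
#' @param profile an \code{fe_profile}
#' @return named numeric vector \code{c(dG_act =, dG_rxn =)}: the maximum
#'   cumulative transition level and the final stationary level, both
#'   relative to the profile's first level
#' @examples
#' p <- compose_profile(data.frame(name = c("a", "b"),
#'                                 dG_TS = c(54.69, 52.52),
#'                                 dG_step = c(4.54, 3.87)))
#' process_summary(p)     # dG_act 57.06, dG_rxn 8.41
#' @export
process_summary <- function(profile) {
  .check_profile(profile)
  ref <- profile$dG[1]
  ts <- profile$dG[profile$kind == "transition"]
  c(dG_act = if (length(ts)) max(ts) - ref else NA_real_,
    dG_rxn = profile$dG[nrow(profile)] - ref)
}

#' Rate-determining transition state of a profile
#'
#' @param profile an \code{fe_profile}
#' @return label of the transition level with the highest cumulative free
#'   energy; ties are broken in favour of the earliest occurrence
#' @export
rate_determining_step <- function(profile) {
  .check_profile(profile)
  ts <- profile[profile$kind == "transition", , drop = FALSE]
  if (nrow(ts) == 0L) stop("profile has no transition level")
  ts$label[which.max(ts$dG)]
}

#' Concatenate process profiles into one pathway profile
#'
#' Each successive process is offset by the cumulative free energy reached
#' at the end of the previous one; the duplicated junction level (end of one
#' process, start of the next) is kept once.
#'
#' @param processes list of \code{fe_profile} objects, in pathway order
#' @return a single \code{fe_profile}
#' @export
concat_profiles <- function(processes) {
  if (!is.list(processes) || length(processes) == 0L)
    stop("at least one process profile is required")
  lapply(processes, .check_profile)
  out <- as.data.frame(processes[[1]])
  for (p in processes[-1]) {
    p <- as.data.frame(p)
    offset <- out$dG[nrow(out)] - p$dG[1]
    p$dG <- p$dG + offset
    out <- rbind(out, p[-1, , drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("fe_profile", "data.frame")
  out
}

#' Global energetics and kinetics of a composed pathway
#'
#' Concatenates the process profiles, reads off the global activation free
#' energy (highest cumulative transition level), global reaction free energy
#' (final level) and the rate-determining transition state, and derives the
#' equilibrium constant, Eyring rate constant and product lifetime for the
#' overall transformation.
#'
#' @param processes list of \code{fe_profile} objects in pathway order (a
#'   single profile may be passed directly)
#' @param T temperature in K
#' @return object of class \code{pathway_result}: a list with elements
#'   \code{dG_act_global}, \code{dG_rxn_global}, \code{rds_label},
#'   \code{kinetics} (one-row \code{step_kinetics}) and \code{profile}
#' @examples
#' gas <- lapply(split(ag_pathway("gas", "process"),
#'                     seq_len(3)), compose_profile)
#' pathway_global(gas)$dG_act_global      # 74.15
#' @export
pathway_global <- function(processes, T = .const$T_default) {
  if (inherits(processes, "fe_profile")) processes <- list(processes)
  prof <- concat_profiles(processes)
  s <- process_summary(prof)
  kin <- annotate_steps(
    data.frame(label = "global", dG_act = s[["dG_act"]],
               dG_rxn = s[["dG_rxn"]]), T)
  out <- list(dG_act_global = s[["dG_act"]],
              dG_rxn_global = s[["dG_rxn"]],
              rds_label     = rate_determining_step(prof),
              kinetics      = kin,
              profile       = prof,
              temperature   = T)
  class(out) <- "pathway_result"
  out
}

#' @export
print.pathway_result <- function(x, ...) {
  cat("Composed pathway at T =", format(x$temperature), "K\n")
  cat(sprintf("  global dG_act = %.2f kcal/mol (rate-determining TS: %s)\n",
              x$dG_act_global, x$rds_label))
  cat(sprintf("  global dG_rxn = %.2f kcal/mol\n", x$dG_rxn_global))
  k <- x$kinetics
  cat(sprintf("  K = %s   k = %s s^-1   tau = %s s\n",
              format_sci(k$K), format_sci(k$k_f), format_sci(k$tau)))
  invisible(x)
}

#' Tabular serialization of a profile
#'
#' @param profile an \code{fe_profile}
#' @return a plain data frame with columns \code{label}, \code{kind},
#'   \code{cumulative_dG}; \code{profile_from_table} inverts it losslessly
#' @export
profile_to_table <- function(profile) {
  .check_profile(profile)
  data.frame(label = profile$label, kind = profile$kind,
             cumulative_dG = profile$dG, stringsAsFactors = FALSE)
}

#' @rdname profile_to_table
#' @param table a data frame as produced by \code{profile_to_table}
#' @export
profile_from_table <- function(table) {
  out <- data.frame(label = table$label, kind = table$kind,
                    dG = table$cumulative_dG, stringsAsFactors = FALSE)
  class(out) <- c("fe_profile", "data.frame")
  .check_profile(out)
  out
}

#' Recover per-step energetics from a profile
#'
#' Inverse of \code{\link{compose_profile}} up to labelling:
#' \code{compose_profile(profile_steps(p))} reproduces the levels of
#' \code{p} exactly.
#'
#' @param profile an \code{fe_profile}
#' @return data frame of \code{name}, \code{dG_TS}, \code{dG_step},
#'   \code{ts_label}, \code{product_label}
#' @export
profile_steps <- function(profile) {
  .check_profile(profile)
  n <- (nrow(profile) - 1L) %/% 2L
  if (n == 0L) stop("profile has no steps")
  i <- seq_len(n)
  stat <- profile$dG[2 * i - 1]
  data.frame(name = profile$label[2 * i],
             dG_TS = profile$dG[2 * i] - stat,
             dG_step = profile$dG[2 * i + 1] - stat,
             ts_label = profile$label[2 * i],
             product_label = profile$label[2 * i + 1],
             stringsAsFactors = FALSE)
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf("Free-energy profile: %d level%s (%d step%s)\n", nrow(x),
              if (nrow(x) == 1) "" else "s", (nrow(x) - 1) %/% 2,
              if ((nrow(x) - 1) %/% 2 == 1) "" else "s"))
  print(as.data.frame(x), row.names = FALSE, ...)
  invisible(x)
}

#' Plot a free-energy profile as a level diagram
#'
#' @param x an \code{fe_profile}
#' @param ... further arguments passed to \code{plot.default}
#' @export
plot.fe_profile <- function(x, ...) {
  .check_profile(x)
  n <- nrow(x)
  xs <- seq_len(n)
  graphics::plot(xs, x$dG, type = "n", xaxt = "n",
                 xlab = "reaction progress", ylab = "dG (kcal/mol)", ...)
  graphics::segments(xs - 0.35, x$dG, xs + 0.35, x$dG,
                     lwd = ifelse(x$kind == "stationary", 3, 1.5),
                     lty = ifelse(x$kind == "stationary", 1, 2))
  for (i in seq_len(n - 1))
    graphics::segments(xs[i] + 0.35, x$dG[i], xs[i + 1] - 0.35, x$dG[i + 1],
                       col = "grey60")
  graphics::axis(1, at = xs, labels = x$label, las = 2, cex.axis = 0.7)
  invisible(x)
}
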