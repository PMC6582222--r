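## Jarzynski free-energy estimation from nonequilibrium work ensembles.
##
## The exponential estimator
##   dG = -RT log( (1/N) sum_i exp(-W_i / RT) )
## is evaluated through a log-sum-exp scheme so that work values of either
## sign up to ~1e4 kcal/mol neither overflow nor underflow. The
## second-cumulant estimator mean(W) - var(W)/(2 RT) is exact for Gaussian
## work distributions and serves as a near-equilibrium diagnostic.

#' Bundle nonequilibrium work values into a work sample
#'
#' @param works numeric vector of work values, kcal/mol (at least one,
#'   all finite)
#' @param T temperature of the pulling ensemble, K
#' @param protocol_id free-form provenance label
#' @return object of class \code{work_sample}
#' @export
work_sample <- function(works, T = .const$T_default, protocol_id = "") {
  .check_T(T)
  works <- as.numeric(works)
  if (length(works) < 1L || any(!is.finite(works)))
    stop("works must contain at least one finite value")
  structure(list(works = works, T = T, protocol_id = as.character(protocol_id)),
            class = "work_sample")
}

.as_work_sample <- function(x, T) {
  if (inherits(x, "work_sample")) x else work_sample(x, T)
}

#' @export
print.work_sample <- function(x, ...) {
  cat(sprintf("Work sample: n = %d, T = %.2f K%s\n", length(x$works), x$T,
              if (nzchar(x$protocol_id)) paste0(" [", x$protocol_id, "]") else ""))
  cat(sprintf("  mean W = %.4f  sd W = %.4f kcal/mol\n",
              mean(x$works), stats::sd(x$works)))
  invisible(x)
}

# log( mean(exp(x)) ), overflow-safe
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski exponential free-energy estimator
#'
#' @param sample a \code{work_sample}, or a numeric vector of works
#' @param T temperature in K (ignored when \code{sample} carries its own)
#' @return Gibbs free-energy difference in kcal/mol; never exceeds the
#'   sample mean (Jensen's inequality)
#' @examples
#' jarzynski_dG(work_sample(c(5, 5, 5)))   # 5
#' @export
jarzynski_dG <- function(sample, T = .const$T_default) {
  s <- .as_work_sample(sample, T)
  rt <- .RT(s$T)
  -rt * .log_mean_exp(-s$works / rt)
}

#' Second-cumulant (Gaussian) free-energy estimator
#'
#' \code{mean(W) - var(W) / (2 RT)} with the unbiased (n - 1) variance.
#'
#' @inheritParams jarzynski_dG
#' @return free-energy difference in kcal/mol; requires at least two works
#' @export
cumulant2_dG <- function(sample, T = .const$T_default) {
  s <- .as_work_sample(sample, T)
  if (length(s$works) < 2L) stop("cumulant estimator needs at least two works")
  mean(s$works) - stats::var(s$works) / (2 * .RT(s$T))
}

# Run code under a private RNG stream, restoring global state afterwards.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap confidence interval for a work-based free-energy estimate
#'
#' Percentile bootstrap (2.5/97.5) over \code{B} resamples with
#' replacement; fully deterministic for a given \code{seed} and leaving the
#' global RNG state untouched.
#'
#' @param sample a \code{work_sample} (n >= 2)
#' @param method \code{"exponential"} (Jarzynski) or \code{"cumulant2"}
#' @param B number of bootstrap resamples (>= 100)
#' @param seed integer seed
#' @return object of class \code{fe_estimate}: list with \code{dG},
#'   \code{method}, \code{n}, \code{ci_low}, \code{ci_high}, \code{seed},
#'   \code{T}
#' @export
bootstrap_ci <- function(sample, method = c("exponential", "cumulant2"),
                         B = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(sample, "work_sample"))
  if (length(sample$works) < 2L) stop("bootstrap needs at least two works")
  if (!is.numeric(B) || B < 100) stop("B must be at least 100")
  est <- switch(method, exponential = jarzynski_dG, cumulant2 = cumulant2_dG)
  w <- sample$works
  n <- length(w)
  boot <- .with_seed(seed, {
    vapply(seq_len(B),
           function(b) est(work_sample(w[sample.int(n, n, replace = TRUE)],
                                       sample$T)),
           numeric(1))
  })
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(dG = est(sample), method = method, n = n,
                 ci_low = ci[1], ci_high = ci[2],
                 seed = seed, T = sample$T),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("dG = %.4f kcal/mol (%s estimator, n = %d, seed = %d)\n",
              x$dG, x$method, x$n, x$seed))
  cat(sprintf("  95%% bootstrap CI [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Finite-sample bias curve of the exponential estimator
#'
#' Averages the Jarzynski estimate over random subsamples of increasing
#' size. For near-equilibrium (Gaussian) work the mean estimate approaches
#' the true free energy from above as the subsample grows.
#'
#' @param sample a \code{work_sample}
#' @param subsample_sizes integer vector of subsample sizes (each <= n)
#' @param n_rep random subsamples drawn per size
#' @param seed integer seed
#' @return data frame with columns \code{n} and \code{dG_mean}
#' @export
bias_curve <- function(sample, subsample_sizes, n_rep = 50, seed = 1) {
  stopifnot(inherits(sample, "work_sample"))
  sizes <- as.integer(subsample_sizes)
  n <- length(sample$works)
  if (any(sizes < 1L) || any(sizes > n))
    stop("subsample sizes must lie in [1, n]")
  means <- .with_seed(seed, {
    vapply(sizes, function(sz) {
      mean(vapply(seq_len(n_rep), function(r) {
        jarzynski_dG(work_sample(sample$works[sample.int(n, sz)], sample$T))
      }, numeric(1)))
    }, numeric(1))
  })
  data.frame(n = sizes, dG_mean = means)
}
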