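#' Posterior update for a rating tally
#'
#' Conjugate beta-binomial update: with a `Beta(alpha0, beta0)` prior on the
#' probability that a volunteer rates the task positive, and a tally of
#' `n_pos` positive and `n_neg` negative ratings, the posterior is
#' `Beta(alpha0 + n_pos, beta0 + n_neg)`. 'maybe' ratings are
#' non-informative and must never enter a tally.
#'
#' @param n_pos,n_neg Non-negative integer counts of positive and negative
#'   ratings.
#' @param prior A [prior_spec()].
#' @return Named list with elements `alpha` and `beta`, the posterior
#'   beta parameters.
#' @examples
#' update_posterior(4, 1)   # Beta(4.5, 1.5)
#' @export
update_posterior <- function(n_pos, n_neg, prior = prior_spec()) {
  check_tally(n_pos, n_neg)
  stopifnot(inherits(prior, "prior_spec"))
  list(alpha = prior$alpha0 + as.numeric(n_pos),
       beta = prior$beta0 + as.numeric(n_neg))
}

check_tally <- function(n_pos, n_neg) {
  for (v in list(n_pos, n_neg)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        v < 0 || v != as.integer(v))
      stop("rating counts must be single non-negative integers",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Posterior mean disagreement rate
#'
#' The expected share of ratings on the minority side of the current
#' majority: `min(alpha, beta) / (alpha + beta)` for posterior parameters
#' `(alpha, beta)`. Reported as descriptive metadata alongside decisions;
#' the stopping rule itself is quantile-based and never thresholds this
#' mean.
#'
#' @param alpha,beta Positive posterior beta parameters, e.g. from
#'   [update_posterior()].
#' @return A value in `[0, 0.5]`; equals 0.5 exactly when `alpha == beta`.
#' @examples
#' mean_disagreement(4.5, 1.5)   # 0.25
#' @export
mean_disagreement <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, beta > 0)
  pmin(alpha, beta) / (alpha + beta)
}

# outcome codes shared by every module; CONTINUE deliberately 0 so that
# "any terminal" is a nonzero test
.OUTCOMES <- c(CONTINUE = 0L, POSITIVE = 1L, NEGATIVE = 2L, DEADLOCK = 3L,
               CAPPED = 4L, UNRESOLVED = 5L, CENSORED = 6L)

outcome_label <- function(code) {
  names(.OUTCOMES)[match(code, .OUTCOMES)]
}

# Vectorised decision rule on raw counts. Returns integer codes
# 0 = CONTINUE, 1 = POSITIVE, 2 = NEGATIVE, 3 = DEADLOCK.
#
# With F the posterior Beta CDF of the positive-rating probability:
#   NEGATIVE  iff F(D)   >= gamma          (gamma-quantile at or below D)
#   POSITIVE  iff F(1-D) <= 1 - gamma      ((1-gamma)-quantile at or above 1-D)
#   DEADLOCK  iff F(D) < (1-gamma)/2 and F(1-D) > 1-(1-gamma)/2
#             (central gamma interval strictly inside (D, 1-D))
# Classification inequalities are non-strict, deadlock strict. For D < 0.5
# the three terminal conditions are mutually exclusive. The CDF form
# (pbeta, the regularized incomplete beta function) is preferred over
# quantile inversion: algebraically equivalent, better conditioned near
# the tails.
decide_codes <- function(n_pos, n_neg, config,
                         method = c("cdf", "quantile")) {
  method <- match.arg(method)
  D <- config$disagreement_threshold
  g <- config$certainty
  alpha <- config$prior$alpha0 + n_pos
  beta <- config$prior$beta0 + n_neg
  out <- integer(length(alpha))
  if (method == "cdf") {
    FD <- stats::pbeta(D, alpha, beta)
    F1D <- stats::pbeta(1 - D, alpha, beta)
    out[FD >= g] <- .OUTCOMES[["NEGATIVE"]]
    pos <- out == 0L & F1D <= 1 - g
    out[pos] <- .OUTCOMES[["POSITIVE"]]
    dl <- out == 0L & FD < (1 - g) / 2 & F1D > 1 - (1 - g) / 2
    out[dl] <- .OUTCOMES[["DEADLOCK"]]
  } else {
    q_hi <- stats::qbeta(g, alpha, beta)
    q_lo <- stats::qbeta(1 - g, alpha, beta)
    q_c_lo <- stats::qbeta((1 - g) / 2, alpha, beta)
    q_c_hi <- stats::qbeta(1 - (1 - g) / 2, alpha, beta)
    out[q_hi <= D] <- .OUTCOMES[["NEGATIVE"]]
    pos <- out == 0L & q_lo >= 1 - D
    out[pos] <- .OUTCOMES[["POSITIVE"]]
    dl <- out == 0L & q_c_lo > D & q_c_hi < 1 - D
    out[dl] <- .OUTCOMES[["DEADLOCK"]]
  }
  out
}

#' Three-way sequential stopping decision for one tally
#'
#' Evaluates the retirement rule for a task with `n_pos` positive and
#' `n_neg` negative ratings. Writing `F` for the posterior Beta CDF of the
#' positive-rating probability `p` and `D`, `gamma` for the configured
#' thresholds, the outcome is:
#'
#' * `NEGATIVE` if `F(D) >= gamma` — at least `gamma` posterior probability
#'   that `p <= D`;
#' * `POSITIVE` if `F(1 - D) <= 1 - gamma` — at least `gamma` posterior
#'   probability that `p >= 1 - D`;
#' * `DEADLOCK` if the central `gamma` credible interval lies strictly
#'   inside `(D, 1 - D)`: `F(D) < (1 - gamma)/2` and
#'   `F(1 - D) > 1 - (1 - gamma)/2`;
#' * `CONTINUE` otherwise — more ratings are needed.
#'
#' The three terminal outcomes are mutually exclusive whenever `D < 0.5`.
#' Any `rating_cap` in the config is ignored here; cap semantics belong to
#' the replay engine and simulator.
#'
#' @inheritParams update_posterior
#' @param config A [stopping_config()].
#' @param method `"cdf"` (default) evaluates the rule through the posterior
#'   CDF; `"quantile"` through the inverse CDF. The two are equivalent and
#'   `"quantile"` exists mainly for cross-checking.
#' @return An object of class `crowdstop_decision`: a list with `outcome`
#'   (one of `"POSITIVE"`, `"NEGATIVE"`, `"DEADLOCK"`, `"CONTINUE"`),
#'   `posterior` (`alpha`, `beta`), `mean_disagreement`, and `evidence`
#'   (the posterior CDF values at `D` and `1 - D`, plus the quantiles the
#'   rule compares against the thresholds).
#' @examples
#' decide(9, 0)    # unanimous: POSITIVE at the default thresholds
#' decide(5, 5)    # evenly split: DEADLOCK
#' decide(4, 1)    # the canonical 20%-disagreement tally: too few votes yet
#' @export
decide <- function(n_pos, n_neg, config = stopping_config(),
                   method = c("cdf", "quantile")) {
  check_tally(n_pos, n_neg)
  stopifnot(inherits(config, "stopping_config"))
  method <- match.arg(method)
  post <- update_posterior(n_pos, n_neg, config$prior)
  D <- config$disagreement_threshold
  g <- config$certainty
  code <- decide_codes(n_pos, n_neg, config, method = method)
  evidence <- list(
    cdf_at_D = stats::pbeta(D, post$alpha, post$beta),
    cdf_at_1mD = stats::pbeta(1 - D, post$alpha, post$beta),
    q_certainty = stats::qbeta(g, post$alpha, post$beta),
    q_one_minus_certainty = stats::qbeta(1 - g, post$alpha, post$beta),
    q_central_lo = stats::qbeta((1 - g) / 2, post$alpha, post$beta),
    q_central_hi = stats::qbeta(1 - (1 - g) / 2, post$alpha, post$beta))
  structure(list(outcome = outcome_label(code),
                 posterior = post,
                 mean_disagreement = mean_disagreement(post$alpha, post$beta),
                 evidence = evidence,
                 config = config),
            class = "crowdstop_decision")
}

#' @export
print.crowdstop_decision <- function(x, ...) {
  cat(sprintf("Decision: %s\n", x$outcome))
  cat(sprintf("  posterior Beta(%g, %g); mean disagreement %.3f\n",
              x$posterior$alpha, x$posterior$beta, x$mean_disagreement))
  cat(sprintf("  P(p <= D) = %.4g, P(p <= 1-D) = %.4g\n",
              x$evidence$cdf_at_D, x$evidence$cdf_at_1mD))
  invisible(x)
}
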