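#' Beta prior on the positive-rating probability
#'
#' Encodes pre-data belief about the probability that a volunteer rates a
#' task as the positive class, as pseudo-counts of positive (`alpha0`) and
#' negative (`beta0`) ratings. The default `Beta(0.5, 0.5)` (Jeffreys) prior
#' is weak: it treats the two classes as equally likely and is swamped by a
#' handful of real ratings.
#'
#' @param alpha0 Positive pseudo-count of positive ratings.
#' @param beta0 Positive pseudo-count of negative ratings.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()          # Jeffreys prior
#' prior_spec(2, 2)      # mildly informative, symmetric
#' @export
prior_spec <- function(alpha0 = 0.5, beta0 = 0.5) {
  stopifnot(is.numeric(alpha0), length(alpha0) == 1L, is.finite(alpha0),
            is.numeric(beta0), length(beta0) == 1L, is.finite(beta0))
  if (alpha0 <= 0 || beta0 <= 0)
    stop("prior pseudo-counts 'alpha0' and 'beta0' must be strictly positive",
         call. = FALSE)
  structure(list(alpha0 = as.numeric(alpha0), beta0 = as.numeric(beta0)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Beta prior: alpha0 = %g, beta0 = %g\n", x$alpha0, x$beta0))
  invisible(x)
}

#' Stopping-rule configuration
#'
#' Bundles the tunable parameters of the sequential retirement rule:
#' the maximum acceptable disagreement rate `D`, the required posterior
#' certainty `gamma`, the beta prior, and an optional hard cap on ratings
#' per task.
#'
#' A task is retired as classified once the posterior probability that the
#' disagreement rate is below `D` reaches `gamma`; it is retired as
#' deadlocked once the central `gamma` credible interval for the
#' positive-rating probability lies strictly inside `(D, 1 - D)`.
#'
#' @param disagreement_threshold Maximum acceptable disagreement rate `D`,
#'   in `(0, 0.5)`. Default 0.2.
#' @param certainty Required certainty level `gamma`, in `(0.5, 1)`.
#'   Default 0.95.
#' @param prior A [prior_spec()]. Default Jeffreys `Beta(0.5, 0.5)`.
#' @param rating_cap Optional positive integer: maximum informative ratings
#'   a task may accumulate before being withdrawn undecided. `NULL` (the
#'   default) disables the cap. The cap is consulted by the replay engine
#'   and simulator, never by [decide()] itself.
#' @return An object of class `stopping_config`.
#' @examples
#' stopping_config()                      # D = 20%, gamma = 95%
#' stopping_config(rating_cap = 34)       # early-withdrawal variant
#' @export
stopping_config <- function(disagreement_threshold = 0.2,
                            certainty = 0.95,
                            prior = prior_spec(),
                            rating_cap = NULL) {
  D <- disagreement_threshold
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(certainty), length(certainty) == 1L,
            is.finite(certainty))
  if (D <= 0 || D >= 0.5)
    stop("'disagreement_threshold' must lie strictly in (0, 0.5)",
         call. = FALSE)
  if (certainty <= 0.5 || certainty >= 1)
    stop("'certainty' must lie strictly in (0.5, 1)", call. = FALSE)
  if (!inherits(prior, "prior_spec"))
    stop("'prior' must be a prior_spec object", call. = FALSE)
  if (!is.null(rating_cap)) {
    if (!is.numeric(rating_cap) || length(rating_cap) != 1L ||
        !is.finite(rating_cap) || rating_cap < 1 ||
        rating_cap != as.integer(rating_cap))
      stop("'rating_cap' must be NULL or a positive integer", call. = FALSE)
    rating_cap <- as.integer(rating_cap)
  }
  structure(list(disagreement_threshold = as.numeric(D),
                 certainty = as.numeric(certainty),
                 prior = prior,
                 rating_cap = rating_cap),
            class = "stopping_config")
}

#' @export
print.stopping_config <- function(x, ...) {
  cat(sprintf("Sequential stopping rule: D = %g, gamma = %g\n",
              x$disagreement_threshold, x$certainty))
  cat(sprintf("  prior Beta(%g, %g); rating cap: %s\n",
              x$prior$alpha0, x$prior$beta0,
              if (is.null(x$rating_cap)) "none" else x$rating_cap))
  invisible(x)
}

# flat named list used when echoing a config into JSON/CSV metadata
config_as_list <- function(config) {
  list(disagreement_threshold = config$disagreement_threshold,
       certainty = config$certainty,
       alpha0 = config$prior$alpha0,
       beta0 = config$prior$beta0,
       rating_cap = config$rating_cap)
}
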