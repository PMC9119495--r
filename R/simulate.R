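#' Monte-Carlo sweep configuration
#'
#' Settings for the error-rate study of the stopping rule as a function of
#' the latent positive-rating probability `theta`. The default grid runs
#' from 0.01 to 0.99 in steps of 0.01 but omits the two decision
#' thresholds `D` and `1 - D` themselves: immediately at a threshold the
#' posterior can take astronomically long to commit to either side, and
#' the cell is uninformative for campaign design.
#'
#' @param theta_grid Numeric vector of latent probabilities in (0, 1);
#'   values equal to `D` or `1 - D` are rejected.
#' @param reps Replicates per `theta` value.
#' @param stopping A [stopping_config()].
#' @param max_ratings Safety bound per replicate; a replicate that reaches
#'   it undecided is recorded as `CENSORED`.
#' @param master_seed Integer; per-replicate seeds are derived
#'   deterministically from it (see [run_sweep()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(theta_grid = NULL, reps = 1000L,
                       stopping = stopping_config(),
                       max_ratings = 1e6, master_seed = 1L) {
  stopifnot(inherits(stopping, "stopping_config"),
            is.numeric(reps), reps >= 1,
            is.numeric(max_ratings), max_ratings >= 1)
  D <- stopping$disagreement_threshold
  if (is.null(theta_grid)) {
    idx <- setdiff(1:99, c(round(100 * D), round(100 * (1 - D))))
    theta_grid <- idx / 100
  }
  stopifnot(all(theta_grid > 0), all(theta_grid < 1))
  if (any(abs(theta_grid - D) < 1e-12 | abs(theta_grid - (1 - D)) < 1e-12))
    stop("theta_grid must not contain the decision thresholds D or 1 - D",
         call. = FALSE)
  structure(list(theta_grid = as.numeric(theta_grid),
                 reps = as.integer(reps),
                 stopping = stopping,
                 max_ratings = as.numeric(max_ratings),
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# counter-based seed derivation: any (theta index, replicate) cell can be
# re-run in isolation; all products stay below 2^53 so the double
# arithmetic is exact, and the result fits a 32-bit R integer
derive_seed <- function(master_seed, theta_index, rep_index) {
  s <- (as.double(master_seed) %% 2147483629) * 1048573 +
    as.double(theta_index) * 9973 + as.double(rep_index)
  as.integer(s %% 2147483629)
}

# theta-implied truth under the rule's thresholds: theta below D should
# conclude NEGATIVE, above 1-D POSITIVE, strictly between them DEADLOCK
theta_truth <- function(theta, config) {
  D <- config$disagreement_threshold
  ifelse(theta < D, "NEGATIVE", ifelse(theta > 1 - D, "POSITIVE",
                                       "DEADLOCK"))
}

#' Simulate one task to conclusion
#'
#' Draws iid Bernoulli(`theta`) ratings, updating the tally and consulting
#' the decision rule after every draw, until the task is retired as
#' POSITIVE, NEGATIVE or DEADLOCK — or `CENSORED` once `max_ratings` is
#' reached undecided. Ratings are generated and the rule evaluated in
#' growing blocks, and tallies covered by the optional decision grid are
#' resolved by table lookup, so long runs near the thresholds stay cheap;
#' the stopping point is identical to a draw-by-draw evaluation.
#'
#' @param theta Latent probability of a positive rating. The degenerate
#'   values 0 and 1 are allowed (useful for checking the unanimous-ratings
#'   boundary).
#' @param stopping A [stopping_config()].
#' @param seed Optional integer seed; when given, the replicate is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param max_ratings Safety bound on the number of ratings.
#' @param grid Optional [decision_grid()] for `stopping`.
#' @return A list with `n_ratings` (integer) and `outcome` (one of
#'   `"POSITIVE"`, `"NEGATIVE"`, `"DEADLOCK"`, `"CENSORED"`).
#' @examples
#' simulate_task(1, seed = 1)   # nine unanimous ratings, POSITIVE
#' @export
simulate_task <- function(theta, stopping = stopping_config(), seed = NULL,
                          max_ratings = 1e6, grid = NULL) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta >= 0, theta <= 1)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  n_pos <- 0L; n_neg <- 0L; n <- 0L
  block <- 16L
  while (n < max_ratings) {
    k <- as.integer(min(block, max_ratings - n))
    x <- stats::rbinom(k, 1L, theta)
    cp <- n_pos + cumsum(x)
    cn <- n_neg + (seq_len(k) - cumsum(x))
    codes <- decide_codes_fast(cp, cn, stopping, grid)
    hit <- which(codes != 0L)
    if (length(hit)) {
      i <- hit[1L]
      return(list(n_ratings = n + i, outcome = outcome_label(codes[i])))
    }
    n_pos <- cp[k]; n_neg <- cn[k]; n <- n + k
    block <- min(block * 2L, 8192L)
  }
  list(n_ratings = as.integer(max_ratings), outcome = "CENSORED")
}

#' Monte-Carlo sweep of the stopping rule across theta
#'
#' For every `theta` in the grid, runs `reps` independent tasks to
#' conclusion with [simulate_task()] and aggregates the outcome counts,
#' the median ratings-to-conclusion (over concluded replicates only), and
#' the misclassification rate against the theta-implied truth (`theta < D`
#' should end NEGATIVE, `theta > 1 - D` POSITIVE, anything strictly
#' between DEADLOCK). Each replicate's seed is derived deterministically
#' from `master_seed` and its (theta index, replicate index) pair, so any
#' single cell — or single replicate — can be reproduced in isolation.
#' `CENSORED` replicates are counted separately and excluded from both
#' the numerator and denominator of the misclassification rate.
#'
#' @param config A [sim_config()].
#' @param grid_max Size of the internal [decision_grid()] lookup table.
#' @param progress Emit a progress message per theta cell (to stderr).
#' @return A `data.frame` with one row per theta: `theta`, `truth`,
#'   `n_positive`, `n_negative`, `n_deadlock`, `n_censored`,
#'   `misclass_rate` (in \[0, 1\]), `median_n`; run metadata (config echo,
#'   seed scheme) in attribute `"metadata"`.
#' @export
run_sweep <- function(config = sim_config(), grid_max = 400L,
                      progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  grid <- decision_grid(config$stopping, grid_max)
  rows <- vector("list", length(config$theta_grid))
  for (ti in seq_along(config$theta_grid)) {
    theta <- config$theta_grid[ti]
    n_rat <- integer(config$reps)
    out <- character(config$reps)
    for (r in seq_len(config$reps)) {
      res <- simulate_task(theta, config$stopping,
                           seed = derive_seed(config$master_seed, ti, r),
                           max_ratings = config$max_ratings, grid = grid)
      n_rat[r] <- res$n_ratings
      out[r] <- res$outcome
    }
    truth <- theta_truth(theta, config$stopping)
    concluded <- out != "CENSORED"
    mis <- if (any(concluded)) mean(out[concluded] != truth) else NA_real_
    rows[[ti]] <- data.frame(
      theta = theta, truth = truth,
      n_positive = sum(out == "POSITIVE"),
      n_negative = sum(out == "NEGATIVE"),
      n_deadlock = sum(out == "DEADLOCK"),
      n_censored = sum(out == "CENSORED"),
      misclass_rate = mis,
      median_n = if (any(concluded)) stats::median(n_rat[concluded])
                 else NA_real_,
      stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("theta = %.2f: misclass %.3f, median n %.0f",
                      theta, mis, rows[[ti]]$median_n))
  }
  sweep <- do.call(rbind, rows)
  attr(sweep, "metadata") <- list(
    tool = "crowdstop",
    version = as.character(utils::packageVersion("crowdstop")),
    config = config_as_list(config$stopping),
    reps = config$reps,
    max_ratings = config$max_ratings,
    master_seed = config$master_seed,
    seed_scheme = paste("seed(theta_i, rep_j) = (master %% 2147483629) *",
                        "1048573 + theta_i * 9973 + rep_j, mod 2147483629"),
    censoring = "CENSORED replicates excluded from misclass_rate and median_n")
  sweep
}

#' Write a sweep table and its metadata
#'
#' @param sweep Result of [run_sweep()].
#' @param csv_path Output CSV path.
#' @param json_path Metadata JSON path; default replaces the CSV extension.
#' @return Invisibly, the metadata list.
#' @export
write_sweep <- function(sweep, csv_path,
                        json_path = sub("\\.[^.]*$", ".json", csv_path)) {
  utils::write.csv(sweep, csv_path, row.names = FALSE, quote = FALSE)
  meta <- attr(sweep, "metadata")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(meta)
}
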