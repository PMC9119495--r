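#' Minimum majority ratings needed to classify, given a dissent count
#'
#' Scans majority counts `m = 1, 2, ...` and returns the smallest `m` for
#' which a tally of `m` majority and `d` dissenting ratings is retired as
#' the majority class. With a symmetric prior the answer is the same
#' whichever class holds the majority. Tasks close to the disagreement
#' threshold may need arbitrarily many ratings, so the scan is bounded by
#' `search_limit` and `NA` means "not classifiable within the limit".
#'
#' @param d Non-negative integer count of dissenting (minority) ratings.
#' @param config A [stopping_config()].
#' @param search_limit Upper bound on the scan over majority counts.
#' @return The minimum majority count as an integer, or `NA_integer_` if
#'   classification is not reached within `search_limit`.
#' @examples
#' min_majority_for_classification(0)   # 9 at the default thresholds
#' min_majority_for_classification(4)   # 36
#' @export
min_majority_for_classification <- function(d, config = stopping_config(),
                                            search_limit = 10000L) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 0, d == as.integer(d),
            inherits(config, "stopping_config"),
            is.numeric(search_limit), search_limit >= 1)
  d <- as.integer(d)
  # block the scan so the pbeta calls vectorise
  lo <- 1L
  majority_code <- .OUTCOMES[["POSITIVE"]]
  while (lo <= search_limit) {
    hi <- min(lo + 1023L, as.integer(search_limit))
    m <- lo:hi
    codes <- decide_codes(m, rep(d, length(m)), config)
    hit <- which(codes == majority_code)
    if (length(hit)) return(m[hit[1L]])
    lo <- hi + 1L
  }
  NA_integer_
}

#' Minimum evenly split ratings that trigger a deadlock
#'
#' Scans even splits `(k, k)` for `k = 1, 2, ...` and returns the total
#' number of ratings `2k` at which the rule first declares a deadlock.
#'
#' @inheritParams min_majority_for_classification
#' @return Total ratings (an even integer), or `NA_integer_` if no even
#'   split deadlocks within `search_limit` ratings per side.
#' @examples
#' min_even_split_for_deadlock()   # 10 at the default thresholds
#' @export
min_even_split_for_deadlock <- function(config = stopping_config(),
                                        search_limit = 10000L) {
  stopifnot(inherits(config, "stopping_config"))
  lo <- 1L
  while (lo <= search_limit) {
    hi <- min(lo + 1023L, as.integer(search_limit))
    k <- lo:hi
    codes <- decide_codes(k, k, config)
    hit <- which(codes == .OUTCOMES[["DEADLOCK"]])
    if (length(hit)) return(2L * k[hit[1L]])
    lo <- hi + 1L
  }
  NA_integer_
}

#' Dissent count that forces early retirement under a rating cap
#'
#' If every task is withdrawn after at most `cap` ratings, a task holding
#' `d` dissenting votes can still be classified only if
#' `d + min_majority_for_classification(d) <= cap`. This returns the
#' smallest `d` for which that fails, i.e. the dissent count at which a
#' task can be retired immediately because classification has become
#' unreachable within the cap.
#'
#' @param cap Positive integer rating cap.
#' @inheritParams min_majority_for_classification
#' @return The smallest disqualifying dissent count (a non-negative
#'   integer).
#' @examples
#' dissent_threshold_under_cap(34)   # 4: with four dissents, 36 + 4 > 34
#' @export
dissent_threshold_under_cap <- function(cap, config = stopping_config(),
                                        search_limit = 10000L) {
  stopifnot(is.numeric(cap), length(cap) == 1L, cap >= 1,
            cap == as.integer(cap))
  cap <- as.integer(cap)
  d <- 0L
  repeat {
    m <- min_majority_for_classification(d, config, search_limit)
    if (is.na(m) || d + m > cap) return(d)
    d <- d + 1L
  }
}

#' Precomputed decision-boundary table
#'
#' Materialises the decision rule's integer boundaries for a given
#' configuration: the minimum majority count needed to classify at each
#' dissent count `0..max_dissent`, and the full decision code for every
#' tally on a `grid_max x grid_max` grid (the deadlock region is not
#' characterised by a single per-dissent threshold, so it is stored
#' densely). The table is a cache of [decide()], never a re-derivation:
#' every cell is produced by the same rule.
#'
#' @inheritParams min_majority_for_classification
#' @param max_dissent Largest dissent count tabulated for the
#'   minimum-majority map.
#' @param grid_max Tallies `(n_pos, n_neg)` with both counts `<= grid_max`
#'   are stored in the dense decision grid.
#' @return An object of class `boundary_table`: a list with `config`,
#'   `min_majority` (integer vector indexed by dissent count `0..max_dissent`,
#'   `NA` = unreachable within `search_limit`), and `grid` (integer matrix,
#'   `grid[i, j]` the decision code for tally `(i - 1, j - 1)`; codes as in
#'   `CONTINUE = 0, POSITIVE = 1, NEGATIVE = 2, DEADLOCK = 3`).
#' @examples
#' bt <- boundary_table(max_dissent = 4, grid_max = 50)
#' bt$min_majority   # named by dissent count: 9, 17, 24, 30, 36
#' @export
boundary_table <- function(config = stopping_config(), max_dissent = 20L,
                           grid_max = 200L, search_limit = 10000L) {
  stopifnot(inherits(config, "stopping_config"),
            max_dissent >= 0, grid_max >= 1)
  max_dissent <- as.integer(max_dissent)
  grid_max <- as.integer(grid_max)
  mm <- vapply(0:max_dissent, min_majority_for_classification,
               integer(1L), config = config, search_limit = search_limit)
  names(mm) <- 0:max_dissent
  grid <- decision_grid(config, grid_max)
  structure(list(config = config, min_majority = mm, grid = grid,
                 max_dissent = max_dissent, grid_max = grid_max,
                 search_limit = as.integer(search_limit)),
            class = "boundary_table")
}

#' Dense decision grid for fast lookup
#'
#' Evaluates the decision rule once for every tally with
#' `n_pos, n_neg <= grid_max` and returns the codes as a matrix, so the
#' simulator and replay engine can replace repeated posterior-CDF
#' evaluations with an O(1) lookup. `grid[n_pos + 1, n_neg + 1]` holds the
#' code for tally `(n_pos, n_neg)`.
#'
#' @inheritParams boundary_table
#' @return Integer matrix of dimension `(grid_max + 1) x (grid_max + 1)`.
#' @export
decision_grid <- function(config = stopping_config(), grid_max = 200L) {
  grid_max <- as.integer(grid_max)
  n <- grid_max + 1L
  np <- rep(0:grid_max, times = n)
  nn <- rep(0:grid_max, each = n)
  matrix(decide_codes(np, nn, config), nrow = n, ncol = n)
}

# grid-accelerated vectorised decision: lookup where the grid covers the
# tally, direct rule otherwise; identical to decide_codes everywhere
decide_codes_fast <- function(n_pos, n_neg, config, grid = NULL) {
  if (is.null(grid)) return(decide_codes(n_pos, n_neg, config))
  gmax <- nrow(grid) - 1L
  out <- integer(length(n_pos))
  covered <- n_pos <= gmax & n_neg <= gmax
  if (any(covered))
    out[covered] <- grid[cbind(n_pos[covered] + 1L, n_neg[covered] + 1L)]
  if (any(!covered))
    out[!covered] <- decide_codes(n_pos[!covered], n_neg[!covered], config)
  out
}

#' @export
print.boundary_table <- function(x, ...) {
  cat(sprintf("Decision boundary table (D = %g, gamma = %g, prior Beta(%g, %g))\n",
              x$config$disagreement_threshold, x$config$certainty,
              x$config$prior$alpha0, x$config$prior$beta0))
  cat("  minimum majority ratings by dissent count:\n")
  print(x$min_majority)
  cat(sprintf("  dense decision grid: tallies up to (%d, %d)\n",
              x$grid_max, x$grid_max))
  invisible(x)
}

#' Export a boundary table to delimited text and JSON
#'
#' Writes the minimum-majority map as a two-column CSV
#' (`dissent_count, min_majority`) and, alongside it, a JSON header that
#' carries the configuration (and any per-cap dissent thresholds), so the
#' exported table is self-describing.
#'
#' @param table A [boundary_table()].
#' @param csv_path Output path for the CSV.
#' @param json_path Output path for the JSON header; default replaces the
#'   CSV extension with `.json`.
#' @param caps Optional integer vector of rating caps; for each, the
#'   dissent threshold under that cap is included in the JSON.
#' @return Invisibly, the list written to JSON.
#' @export
write_boundary_table <- function(table, csv_path,
                                 json_path = sub("\\.[^.]*$", ".json",
                                                 csv_path),
                                 caps = NULL) {
  stopifnot(inherits(table, "boundary_table"))
  df <- data.frame(dissent_count = as.integer(names(table$min_majority)),
                   min_majority = unname(table$min_majority))
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(tool = "crowdstop",
               version = as.character(utils::packageVersion("crowdstop")),
               config = config_as_list(table$config),
               search_limit = table$search_limit,
               min_majority = as.list(stats::setNames(
                 unname(table$min_majority), names(table$min_majority))))
  if (!is.null(caps)) {
    meta$dissent_threshold_under_cap <- lapply(
      stats::setNames(as.integer(caps), caps),
      dissent_threshold_under_cap, config = table$config,
      search_limit = table$search_limit)
  }
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(meta)
}
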