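#' Read a per-image rating stream from delimited text
#'
#' Parses a CSV/TSV file of volunteer ratings (delimiter autodetected by
#' `data.table::fread`, or set explicitly) into the normalised layout the
#' replay engine consumes: one row per rating with columns `image_id`,
#' `rater_id` (may be `NA`), `order_key` and `rating` in
#' `{"positive", "negative", "maybe"}`. Rows are sorted within image by
#' `order_key`, with input file order as the stable tie-break; 'maybe'
#' ratings are retained but flagged non-informative downstream.
#'
#' @param path Path to the delimited text file (must have a header).
#' @param image_col,rating_col Column names holding the image identifier
#'   and the rating label.
#' @param order_col Optional column name holding a sortable order key
#'   (timestamp or sequence number); if `NULL`, file order is used.
#' @param rater_col Optional column name holding the rater identifier.
#' @param vocabulary Named list mapping the three canonical labels to the
#'   vocabulary used in the file, e.g.
#'   `list(positive = "cropland", negative = "non-cropland", maybe = "maybe")`.
#'   Each entry may be a vector of accepted labels.
#' @param sep Field delimiter; `"auto"` (default) lets `fread` detect it.
#' @return A `data.frame` with columns `image_id` (character), `rater_id`
#'   (character or `NA`), `order_key`, `rating` (character, canonical
#'   labels), ordered by image and then by `order_key`.
#' @export
read_ratings <- function(path,
                         image_col = "image_id",
                         rating_col = "rating",
                         order_col = "order",
                         rater_col = NULL,
                         vocabulary = list(positive = "positive",
                                           negative = "negative",
                                           maybe = "maybe"),
                         sep = "auto") {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  stopifnot(all(c("positive", "negative", "maybe") %in% names(vocabulary)))
  header <- names(data.table::fread(path, sep = sep, header = TRUE,
                                    nrows = 0L, showProgress = FALSE))
  for (col in c(image_col, rating_col, order_col, rater_col)) {
    if (!is.null(col) && !col %in% header)
      stop(sprintf("required column '%s' not present in %s", col, path),
           call. = FALSE)
  }
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = c(image_col,
                                                          rating_col)),
                          data.table = TRUE, showProgress = FALSE)
  raw <- dt[[rating_col]]
  lut <- c(stats::setNames(rep("positive", length(vocabulary$positive)),
                           as.character(vocabulary$positive)),
           stats::setNames(rep("negative", length(vocabulary$negative)),
                           as.character(vocabulary$negative)),
           stats::setNames(rep("maybe", length(vocabulary$maybe)),
                           as.character(vocabulary$maybe)))
  rating <- unname(lut[raw])
  if (anyNA(rating)) {
    bad <- which(is.na(rating))[1L]
    stop(sprintf(
      "unknown rating label '%s' at data line %d of %s (known labels: %s)",
      raw[bad], bad, path, paste(names(lut), collapse = ", ")),
      call. = FALSE)
  }
  out <- data.frame(
    image_id = dt[[image_col]],
    rater_id = if (is.null(rater_col)) NA_character_
               else as.character(dt[[rater_col]]),
    order_key = if (is.null(order_col)) seq_len(nrow(dt))
                else dt[[order_col]],
    rating = rating,
    stringsAsFactors = FALSE)
  # stable sort: order_key within image, file order breaking ties
  out <- out[order(out$image_id, out$order_key, seq_len(nrow(out)),
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replay the stopping rule over one image's rating stream
#'
#' Consumes the informative (non-'maybe') ratings of a single image in
#' order, re-evaluating the decision rule after each one, and stops at the
#' first terminal outcome — the moment the task would have been retired.
#' If `config$rating_cap` is set and reached with no decision the stop is
#' `CAPPED`; if the stream ends undecided it is `UNRESOLVED`. The replay
#' then continues hypothetically through the remaining ratings to measure
#' how often early retirement would have been regretted:
#'
#' * `rewidened` — some later cumulative tally no longer satisfies the
#'   condition that triggered the stop (the credible interval drifted back
#'   out of spec);
#' * `changed` — some later cumulative tally satisfies a *different*
#'   terminal condition; `change_type` is `"strong"` for a
#'   POSITIVE/NEGATIVE swap and `"weak"` for a swap between a classified
#'   outcome and DEADLOCK;
#' * `final_outcome` — the first such different terminal outcome, or the
#'   stop outcome if none occurs;
#' * `end_state` — the rule's verdict on the complete tally at the literal
#'   end of the stream (possibly `CONTINUE`).
#'
#' `rewidened`, `changed` and `change_type` are `NA`/`"none"` for `CAPPED`
#' and `UNRESOLVED` stops, which have no triggering condition; for those,
#' `final_outcome` reports the first terminal outcome the continuation
#' reaches, if any.
#'
#' @param ratings Character vector of ratings in presentation order, each
#'   one of `"positive"`, `"negative"`, `"maybe"`.
#' @param config A [stopping_config()].
#' @param grid Optional [decision_grid()] for the same config, used to
#'   accelerate the per-prefix decisions.
#' @return A one-row `data.frame` with columns `n_informative`, `n_used`,
#'   `stop_outcome`, `final_outcome`, `end_state`, `rewidened`, `changed`,
#'   `change_type`, `first_agrees` (first informative rating equals the
#'   simple majority over all informative ratings; `NA` on a tie or empty
#'   stream).
#' @examples
#' replay_image(rep("positive", 12))        # stops at 9, POSITIVE
#' replay_image(rep(c("positive", "negative"), 5))   # stops at 10, DEADLOCK
#' @export
replay_image <- function(ratings, config = stopping_config(), grid = NULL) {
  stopifnot(is.character(ratings), inherits(config, "stopping_config"))
  bad <- setdiff(unique(ratings), c("positive", "negative", "maybe"))
  if (length(bad))
    stop("unknown rating label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  info <- ratings[ratings != "maybe"]
  n_info <- length(info)
  if (n_info == 0L) {
    return(data.frame(n_informative = 0L, n_used = 0L,
                      stop_outcome = "UNRESOLVED",
                      final_outcome = "UNRESOLVED",
                      end_state = "CONTINUE",
                      rewidened = NA, changed = NA, change_type = "none",
                      first_agrees = NA, stringsAsFactors = FALSE))
  }
  x <- as.integer(info == "positive")
  cum_pos <- cumsum(x)
  cum_neg <- seq_len(n_info) - cum_pos
  codes <- decide_codes_fast(cum_pos, cum_neg, config, grid)

  cap <- config$rating_cap
  horizon <- if (is.null(cap)) n_info else min(n_info, cap)
  hit <- which(codes[seq_len(horizon)] != 0L)
  if (length(hit)) {
    n_used <- hit[1L]
    stop_code <- codes[n_used]
    stop_outcome <- outcome_label(stop_code)
  } else if (!is.null(cap) && n_info >= cap) {
    n_used <- as.integer(cap)
    stop_code <- NA_integer_
    stop_outcome <- "CAPPED"
  } else {
    n_used <- n_info
    stop_code <- NA_integer_
    stop_outcome <- "UNRESOLVED"
  }

  later <- if (n_used < n_info) codes[(n_used + 1L):n_info] else integer(0)
  if (!is.na(stop_code)) {
    rewidened <- any(later != stop_code)
    diff_term <- later != stop_code & later != 0L
    changed <- any(diff_term)
    if (changed) {
      first_code <- later[which(diff_term)[1L]]
      final_outcome <- outcome_label(first_code)
      both_classified <- all(c(stop_code, first_code) %in% c(1L, 2L))
      change_type <- if (both_classified) "strong" else "weak"
    } else {
      final_outcome <- stop_outcome
      change_type <- "none"
    }
  } else {
    rewidened <- NA
    changed <- NA
    change_type <- "none"
    term <- which(later != 0L)
    final_outcome <- if (length(term)) outcome_label(later[term[1L]])
                     else stop_outcome
  }
  end_state <- outcome_label(codes[n_info])
  maj <- sign(sum(x) - (n_info - sum(x)))  # 1 pos majority, -1 neg, 0 tie
  first_agrees <- if (maj == 0L) NA else (x[1L] == 1L) == (maj > 0L)
  data.frame(n_informative = n_info, n_used = n_used,
             stop_outcome = stop_outcome, final_outcome = final_outcome,
             end_state = end_state, rewidened = rewidened, changed = changed,
             change_type = change_type, first_agrees = first_agrees,
             stringsAsFactors = FALSE)
}

#' Replay a whole campaign of rating streams
#'
#' Applies [replay_image()] to every image in a normalised ratings table
#' (as produced by [read_ratings()] or [generate_synthetic_campaign()]).
#'
#' @param ratings A `data.frame` with columns `image_id`, `rating`, already
#'   ordered within image (as [read_ratings()] guarantees).
#' @param config A [stopping_config()].
#' @param grid_max Size of the internal [decision_grid()] used to speed up
#'   the per-prefix decisions.
#' @return A `data.frame` with one row per image: `image_id` plus all
#'   [replay_image()] columns.
#' @export
replay_campaign <- function(ratings, config = stopping_config(),
                            grid_max = 200L) {
  stopifnot(is.data.frame(ratings),
            all(c("image_id", "rating") %in% names(ratings)))
  grid <- decision_grid(config, grid_max)
  dt <- data.table::as.data.table(ratings)
  res <- dt[, replay_image(rating, config, grid), by = "image_id"]
  as.data.frame(res)
}

#' Campaign-level efficiency and reliability summary
#'
#' Aggregates per-image replay results into the campaign statistics used
#' to judge the stopping rule: how much volunteer effort it saves, how
#' fast each outcome class concludes, and how often early retirement would
#' later have looked premature.
#'
#' Savings are defined over informative (non-'maybe') ratings only: the
#' denominator is the total informative ratings collected, and an image's
#' saving is `n_informative - n_used`. The efficiency multiplier
#' `1 / (1 - fraction_ratings_eliminated)` estimates how many times more
#' tasks the same labor could have processed. Percentiles of the discrete
#' ratings-to-conclusion counts use the "smallest n covering at least the
#' stated fraction of cases" convention.
#'
#' @param results A `data.frame` of replay results from
#'   [replay_campaign()] (or `rbind`-ed [replay_image()] rows).
#' @param config The [stopping_config()] used for the replay (consulted
#'   for the minimum-ratings-to-conclude reference counts).
#' @return An object of class `campaign_summary`: a list with counts,
#'   `fraction_images_removed` (stop outcome other than UNRESOLVED),
#'   `fraction_ratings_eliminated`, `efficiency_multiplier`, per-outcome
#'   ratings-to-conclusion statistics (`mean`, `p95`, `p99`),
#'   `min_ratings_conclusion_fraction` (share of concluded images that
#'   stopped at the theoretical minimum for their outcome),
#'   `first_agreement_rate`, and per-outcome `rewidened` / `changed` rates.
#' @export
summarize_campaign <- function(results, config = stopping_config()) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("n_informative", "n_used", "stop_outcome") %in%
                  names(results)))
  n_images <- nrow(results)
  n_total <- sum(results$n_informative)
  n_used <- sum(results$n_used)
  frac_elim <- if (n_total > 0) 1 - n_used / n_total else 0
  concluded <- results$stop_outcome %in% c("POSITIVE", "NEGATIVE", "DEADLOCK")
  removed <- results$stop_outcome != "UNRESOLVED"

  q_disc <- function(x, q) {            # smallest n covering >= q of cases
    if (!length(x)) return(NA_real_)
    sort(x)[ceiling(q * length(x))]
  }
  per_outcome <- lapply(
    stats::setNames(nm = c("POSITIVE", "NEGATIVE", "DEADLOCK")),
    function(oc) {
      n <- results$n_used[results$stop_outcome == oc]
      list(n_images = length(n),
           mean = if (length(n)) mean(n) else NA_real_,
           p95 = q_disc(n, 0.95), p99 = q_disc(n, 0.99))
    })

  min_classify <- min_majority_for_classification(0L, config)
  min_deadlock <- min_even_split_for_deadlock(config)
  min_for <- c(POSITIVE = min_classify, NEGATIVE = min_classify,
               DEADLOCK = min_deadlock)
  at_min <- concluded &
    results$n_used == unname(min_for[results$stop_outcome])
  rate <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  per_outcome_rates <- lapply(
    stats::setNames(nm = c("POSITIVE", "NEGATIVE", "DEADLOCK")),
    function(oc) {
      sel <- results$stop_outcome == oc
      list(rewidened_rate = rate(results$rewidened[sel]),
           changed_rate = rate(results$changed[sel]))
    })

  structure(list(
    n_images = n_images,
    n_ratings_total = n_total,
    n_ratings_needed = n_used,
    n_ratings_eliminated = n_total - n_used,
    fraction_images_removed = mean(removed),
    fraction_ratings_eliminated = frac_elim,
    efficiency_multiplier = 1 / (1 - frac_elim),
    ratings_to_conclusion = per_outcome,
    min_ratings_conclusion_fraction =
      if (any(concluded)) sum(at_min) / sum(concluded) else NA_real_,
    first_agreement_rate = rate(results$first_agrees),
    reliability = per_outcome_rates,
    n_unresolved = sum(results$stop_outcome == "UNRESOLVED"),
    n_capped = sum(results$stop_outcome == "CAPPED"),
    config = config_as_list(config)),
    class = "campaign_summary")
}

#' @export
print.campaign_summary <- function(x, ...) {
  cat(sprintf("Campaign summary: %d images, %d informative ratings\n",
              x$n_images, x$n_ratings_total))
  cat(sprintf("  ratings needed %d; eliminated %d (%.1f%%); multiplier %.2fx\n",
              x$n_ratings_needed, x$n_ratings_eliminated,
              100 * x$fraction_ratings_eliminated, x$efficiency_multiplier))
  cat(sprintf("  images removed from circulation: %.1f%% (%d unresolved, %d capped)\n",
              100 * x$fraction_images_removed, x$n_unresolved, x$n_capped))
  for (oc in names(x$ratings_to_conclusion)) {
    s <- x$ratings_to_conclusion[[oc]]
    if (s$n_images > 0)
      cat(sprintf("  %s: %d images, mean %.1f ratings (95%%: %d, 99%%: %d)\n",
                  oc, s$n_images, s$mean, s$p95, s$p99))
  }
  if (!is.na(x$first_agreement_rate))
    cat(sprintf("  first rating agreed with final majority: %.1f%%\n",
                100 * x$first_agreement_rate))
  invisible(x)
}

#' Write replay outputs to disk
#'
#' @param results Per-image replay table from [replay_campaign()].
#' @param summary A [summarize_campaign()] object.
#' @param out_prefix Path prefix; writes `<prefix>_replay.csv` and
#'   `<prefix>_summary.json`.
#' @return Invisibly, the two paths written.
#' @export
write_replay <- function(results, summary, out_prefix) {
  csv <- paste0(out_prefix, "_replay.csv")
  js <- paste0(out_prefix, "_summary.json")
  utils::write.csv(results, csv, row.names = FALSE, quote = FALSE)
  payload <- unclass(summary)
  payload$tool <- "crowdstop"
  payload$version <- as.character(utils::packageVersion("crowdstop"))
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
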