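write_ratings_file <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

test_that("rating files parse, group and order correctly", {
  p <- write_ratings_file(c("image_id,order,rating",
                            "a,1,positive", "a,2,positive", "a,3,maybe"))
  r <- read_ratings(p)
  expect_equal(nrow(r), 3L)
  expect_equal(sum(r$rating != "maybe"), 2L)

  # interleaved images come back grouped, each internally ordered
  p2 <- write_ratings_file(c("image_id,order,rating",
                             "b,2,negative", "a,1,positive",
                             "b,1,positive", "a,2,maybe"))
  r2 <- read_ratings(p2)
  expect_equal(r2$image_id, c("a", "a", "b", "b"))
  expect_equal(r2$order_key, c(1L, 2L, 1L, 2L))
  expect_equal(r2$rating, c("positive", "maybe", "positive", "negative"))
})

test_that("alternate label vocabularies map onto the canonical labels", {
  p <- write_ratings_file(c("img,seq,vote",
                            "x,1,yes", "x,2,no", "x,3,unsure"))
  r <- read_ratings(p, image_col = "img", rating_col = "vote",
                    order_col = "seq",
                    vocabulary = list(positive = "yes", negative = "no",
                                      maybe = "unsure"))
  expect_equal(r$rating, c("positive", "negative", "maybe"))
})

test_that("parse errors name the offending line or column", {
  p <- write_ratings_file(c("image_id,order,rating",
                            "a,1,positive", "a,2,banana"))
  expect_error(read_ratings(p), "banana.*line 2")
  expect_error(read_ratings(p, rating_col = "nope"), "column 'nope'")
  expect_error(read_ratings(tempfile()), "not found")
})

test_that("replay stops at the first terminal decision", {
  # nine unanimous positives conclude at nine even with ratings to spare
  r <- replay_image(rep("positive", 14))
  expect_equal(r$stop_outcome, "POSITIVE")
  expect_equal(r$n_used, 9L)
  expect_equal(r$n_informative, 14L)

  # strict alternation reaches the five-five deadlock at ten
  r <- replay_image(rep(c("positive", "negative"), 5))
  expect_equal(r$stop_outcome, "DEADLOCK")
  expect_equal(r$n_used, 10L)

  # 'maybe' ratings are non-informative and invisible to the rule
  r <- replay_image(c("maybe", rep("positive", 9), "maybe"))
  expect_equal(r$stop_outcome, "POSITIVE")
  expect_equal(r$n_used, 9L)
  r <- replay_image(rep("maybe", 5))
  expect_equal(r$stop_outcome, "UNRESOLVED")
  expect_equal(r$n_used, 0L)

  # too short a stream ends unresolved with everything consumed
  r <- replay_image(rep("positive", 4))
  expect_equal(r$stop_outcome, "UNRESOLVED")
  expect_equal(r$n_used, 4L)
})

test_that("post-stop continuation detects rewidening and weak changes", {
  # nine positives classify; nine following negatives drag the posterior
  # back into deadlock territory: a weak change, never a strong one
  stream <- c(rep("positive", 9), rep("negative", 9))
  expect_equal(decide(9, 9)$outcome, "DEADLOCK")
  r <- replay_image(stream)
  expect_equal(r$stop_outcome, "POSITIVE")
  expect_true(r$rewidened)
  expect_true(r$changed)
  expect_equal(r$change_type, "weak")
  expect_equal(r$final_outcome, "DEADLOCK")

  # a stop followed only by confirming ratings neither rewidens nor changes
  r <- replay_image(rep("positive", 20))
  expect_false(r$rewidened)
  expect_false(r$changed)
  expect_equal(r$change_type, "none")
  expect_equal(r$final_outcome, "POSITIVE")
  expect_equal(r$end_state, "POSITIVE")
})

test_that("a rating cap withdraws undecided tasks as CAPPED", {
  cfg <- stopping_config(rating_cap = 8)
  r <- replay_image(rep(c("positive", "negative"), 10), cfg)
  expect_equal(r$stop_outcome, "CAPPED")
  expect_equal(r$n_used, 8L)
  # the continuation still reports the eventual deadlock
  expect_equal(r$final_outcome, "DEADLOCK")
  expect_true(is.na(r$rewidened))
  # a task that concludes before the cap is unaffected by it
  r <- replay_image(rep("positive", 12), cfg)
  expect_equal(r$stop_outcome, "CAPPED")  # 9 > 8: cannot classify in 8
  cfg34 <- stopping_config(rating_cap = 34)
  r <- replay_image(rep("positive", 12), cfg34)
  expect_equal(r$stop_outcome, "POSITIVE")
})

test_that("first-rating agreement compares against the stream majority", {
  expect_true(replay_image(c(rep("positive", 9), "negative"))$first_agrees)
  expect_false(replay_image(c("negative", rep("positive", 9)))$first_agrees)
  expect_true(is.na(replay_image(c("positive", "negative"))$first_agrees))
})

test_that("campaign summaries reproduce hand-computed totals", {
  streams <- list(
    a = rep("positive", 14),                        # stops at 9 of 14
    b = rep(c("positive", "negative"), 5),          # deadlock at 10 of 10
    c = rep("negative", 9),                         # stops at 9 of 9
    d = c(rep("maybe", 3), rep("positive", 2)),     # unresolved, 2 informative
    e = c(rep("positive", 9), rep("negative", 9)))  # stops at 9 of 18
  res <- replay_campaign(as_campaign_df(streams))
  expect_equal(nrow(res), 5L)
  s <- summarize_campaign(res)
  expect_equal(s$n_images, 5L)
  expect_equal(s$n_ratings_total, 14L + 10L + 9L + 2L + 18L)
  expect_equal(s$n_ratings_needed, 9L + 10L + 9L + 2L + 9L)
  expect_equal(s$n_ratings_eliminated, 5L + 0L + 0L + 0L + 9L)
  expect_equal(s$fraction_images_removed, 4 / 5)
  expect_equal(s$fraction_ratings_eliminated, 14 / 53)
  expect_equal(s$efficiency_multiplier, 53 / 39)
  # three of four concluded images stopped at their class minimum (a, c at
  # 9; b at 10; e at 9 -> all four), so the fraction is 1
  expect_equal(s$min_ratings_conclusion_fraction, 1)
  expect_equal(s$ratings_to_conclusion$DEADLOCK$n_images, 1L)
  expect_equal(s$ratings_to_conclusion$POSITIVE$mean, 9)
})

test_that("the published savings fraction implies the published multiplier", {
  # two images, each 500 informative ratings, 203 needed: exactly 59.4%
  # of ratings eliminated
  res <- data.frame(n_informative = c(500L, 500L), n_used = c(203L, 203L),
                    stop_outcome = c("POSITIVE", "NEGATIVE"),
                    rewidened = FALSE, changed = FALSE,
                    first_agrees = TRUE)
  s <- summarize_campaign(res)
  expect_equal(s$fraction_ratings_eliminated, 0.594)
  expect_equal(round(s$efficiency_multiplier, 2), 2.46)
})

test_that("a campaign with no conclusions saves nothing", {
  res <- data.frame(n_informative = c(3L, 4L), n_used = c(3L, 4L),
                    stop_outcome = "UNRESOLVED", rewidened = NA,
                    changed = NA, first_agrees = NA)
  s <- summarize_campaign(res)
  expect_equal(s$fraction_ratings_eliminated, 0)
  expect_equal(s$efficiency_multiplier, 1)
  expect_equal(s$fraction_images_removed, 0)
})

test_that("synthetic campaigns are deterministic and honor their spec", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  generate_synthetic_campaign(100, seed = 5, path = f1)
  generate_synthetic_campaign(100, seed = 5, path = f2)
  expect_equal(tools::md5sum(f1), tools::md5sum(f2), ignore_attr = TRUE)
  generate_synthetic_campaign(100, seed = 6, path = f2)
  expect_false(tools::md5sum(f1) == tools::md5sum(f2))

  # a forced theta = 1 image is all positive and replays to nine
  camp <- generate_synthetic_campaign(1, theta_sampler = 1,
                                      ratings_per_image = 12,
                                      maybe_rate = 0, seed = 3)
  expect_equal(camp$rating, rep("positive", 12))
  r <- replay_image(camp$rating)
  expect_equal(r$n_used, 9L)

  # written files round-trip through read_ratings
  rt <- read_ratings(f1, order_col = "order")
  camp1 <- generate_synthetic_campaign(100, seed = 5)
  expect_equal(rt$rating, camp1$rating)
  expect_equal(rt$image_id, camp1$image_id)
  unlink(c(f1, f2))
})

test_that("ambiguous imagery deadlocks almost surely", {
  camp <- generate_synthetic_campaign(60, theta_sampler = 0.5,
                                      ratings_per_image = 80,
                                      maybe_rate = 0, seed = 9)
  res <- replay_campaign(camp)
  expect_gte(mean(res$stop_outcome == "DEADLOCK"), 0.9)
})

test_that("replay conserves ratings and stops consistently", {
  camp <- generate_synthetic_campaign(300, seed = 17)
  res <- replay_campaign(camp)
  # conservation: used plus saved is exactly what was collected
  expect_equal(sum(res$n_used) + sum(res$n_informative - res$n_used),
               sum(res$n_informative))
  expect_true(all(res$n_used <= res$n_informative))
  # determinism: an identical replay gives identical results
  expect_identical(res, replay_campaign(camp))
  # stopping consistency: the stop tally decides, the one before does not
  info <- camp[camp$rating != "maybe", ]
  for (i in which(res$stop_outcome %in% c("POSITIVE", "NEGATIVE",
                                          "DEADLOCK"))) {
    x <- info$rating[info$image_id == res$image_id[i]] == "positive"
    k <- res$n_used[i]
    expect_equal(decide(sum(x[1:k]), k - sum(x[1:k]))$outcome,
                 res$stop_outcome[i])
    if (k > 1) {
      x1 <- x[1:(k - 1)]
      expect_equal(decide(sum(x1), length(x1) - sum(x1))$outcome,
                   "CONTINUE")
    }
  }
})

test_that("no classification ever flips between the two classes", {
  # seed-pinned synthetic campaign spanning the whole theta range
  camp <- generate_synthetic_campaign(
    20000, theta_sampler = function(n) runif(n, 0.01, 0.99),
    seed = 2024)
  res <- replay_campaign(camp)
  expect_equal(sum(res$change_type == "strong", na.rm = TRUE), 0L)
})
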