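#' Mixture sampler for latent per-image rating probabilities
#'
#' Draws per-image latent probabilities `theta` of a positive rating from
#' a three-component beta mixture: a component concentrated near 0
#' (clear negatives), one near 1 (clear positives), and a minority
#' mid-range component (genuinely ambiguous imagery). The defaults mimic
#' a typical binary geo-classification campaign in which most images are
#' easy and volunteers converge quickly, while a modest fraction hovers
#' near an even split.
#'
#' @param n Number of draws.
#' @param weights Mixture weights for the (negative-leaning, positive-
#'   leaning, ambiguous) components; normalised internally.
#' @param shapes List of three `c(alpha, beta)` pairs, one per component.
#' @return Numeric vector of `n` values in (0, 1).
#' @export
rtheta_mixture <- function(n,
                           weights = c(0.45, 0.45, 0.10),
                           shapes = list(c(2, 18), c(18, 2), c(6, 6))) {
  stopifnot(length(weights) == length(shapes), all(weights >= 0),
            sum(weights) > 0)
  weights <- weights / sum(weights)
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  theta <- numeric(n)
  for (k in seq_along(shapes)) {
    idx <- comp == k
    if (any(idx))
      theta[idx] <- stats::rbeta(sum(idx), shapes[[k]][1], shapes[[k]][2])
  }
  theta
}

#' Generate a synthetic rating campaign
#'
#' Emulates a crowdsourced binary classification campaign: each image gets
#' a latent probability `theta` of receiving a positive rating, volunteers
#' rate it independently as Bernoulli(`theta`), and each informative
#' rating is independently replaced by 'maybe' at rate `maybe_rate`. The
#' number of ratings per image is drawn from `ratings_per_image`. Output is
#' deterministic given `seed`, and when `path` is supplied the standard
#' rating-file dialect (`image_id, rater_id, order, rating`) is written so
#' the file round-trips through [read_ratings()].
#'
#' @param n_images Number of images to simulate.
#' @param theta_sampler Function of `n` returning `n` latent probabilities;
#'   default [rtheta_mixture()]. A single number is also accepted and used
#'   for every image.
#' @param ratings_per_image Function of `n` returning `n` positive integer
#'   rating counts; default a negative-binomial with mean 23 (size 5),
#'   floored at 1, giving the right-skewed per-image effort profile typical
#'   of such campaigns. A single number is also accepted.
#' @param maybe_rate Probability that any one rating is 'maybe' instead of
#'   an informative vote, in `[0, 1)`.
#' @param seed Integer seed; the same seed reproduces the campaign (and
#'   file) exactly.
#' @param path Optional output path; when given, the campaign is written
#'   as CSV and the path returned invisibly.
#' @param vocabulary Labels to write, as in [read_ratings()]; the first
#'   element of each entry is used.
#' @return A `data.frame` of ratings in the normalised dialect, with the
#'   per-image latent `theta` attached as attribute `"theta"`. If `path`
#'   is given the data frame is returned invisibly after writing.
#' @examples
#' camp <- generate_synthetic_campaign(5, theta_sampler = 1,
#'                                     ratings_per_image = 12, seed = 1)
#' table(camp$rating)   # all positive
#' @export
generate_synthetic_campaign <- function(n_images,
                                        theta_sampler = rtheta_mixture,
                                        ratings_per_image = NULL,
                                        maybe_rate = 0.05,
                                        seed = 1L,
                                        path = NULL,
                                        vocabulary = list(
                                          positive = "positive",
                                          negative = "negative",
                                          maybe = "maybe")) {
  stopifnot(is.numeric(n_images), n_images >= 1,
            is.numeric(maybe_rate), maybe_rate >= 0, maybe_rate < 1)
  n_images <- as.integer(n_images)
  if (is.numeric(theta_sampler)) {
    th0 <- theta_sampler
    stopifnot(length(th0) == 1L, th0 >= 0, th0 <= 1)
    theta_sampler <- function(n) rep(th0, n)
  }
  if (is.null(ratings_per_image)) {
    ratings_per_image <- function(n) pmax(1L, stats::rnbinom(n, size = 5,
                                                             mu = 23))
  } else if (is.numeric(ratings_per_image)) {
    k0 <- as.integer(ratings_per_image)
    stopifnot(length(k0) == 1L, k0 >= 1)
    ratings_per_image <- function(n) rep(k0, n)
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  theta <- theta_sampler(n_images)
  stopifnot(length(theta) == n_images, all(theta >= 0), all(theta <= 1))
  k <- as.integer(ratings_per_image(n_images))
  stopifnot(length(k) == n_images, all(k >= 1))

  image_id <- sprintf("img%05d", seq_len(n_images))
  total <- sum(k)
  img <- rep(image_id, times = k)
  th <- rep(theta, times = k)
  vote <- stats::rbinom(total, 1L, th)
  is_maybe <- stats::runif(total) < maybe_rate
  rating <- ifelse(is_maybe, "maybe",
                   ifelse(vote == 1L, "positive", "negative"))
  ord <- sequence(k)
  out <- data.frame(
    image_id = img,
    rater_id = sprintf("r%04d",
                       sample.int(max(100L, n_images %/% 2L), total,
                                  replace = TRUE)),
    order_key = ord,
    rating = rating,
    stringsAsFactors = FALSE)
  attr(out, "theta") <- stats::setNames(theta, image_id)

  if (!is.null(path)) {
    lab <- c(positive = as.character(vocabulary$positive[1]),
             negative = as.character(vocabulary$negative[1]),
             maybe = as.character(vocabulary$maybe[1]))
    file_df <- data.frame(image_id = out$image_id,
                          rater_id = out$rater_id,
                          order = out$order_key,
                          rating = unname(lab[out$rating]),
                          stringsAsFactors = FALSE)
    # fixed formatting so the determinism contract is byte-level
    con <- file(path, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines("image_id,rater_id,order,rating", con, sep = "\n")
    writeLines(sprintf("%s,%s,%d,%s", file_df$image_id, file_df$rater_id,
                       file_df$order, file_df$rating), con, sep = "\n")
    return(invisible(out))
  }
  out
}
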