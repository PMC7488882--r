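# Multirater agreement for the visual DWI/FLAIR mismatch reading.

#' Free-marginal multirater kappa
#'
#' Chance-corrected agreement for raters who are not constrained to fixed
#' category quotas: `kappa = (Po - 1/k) / (1 - 1/k)` where `Po` is the
#' overall observed agreement (mean over items of the proportion of agreeing
#' rater pairs) and `k` the number of rating categories. The CI is a normal
#' approximation using the between-item variance of the per-item agreement.
#'
#' Supply either a ratings table, or `po` directly (with `k`) to evaluate the
#' formula on an externally computed agreement.
#'
#' @param ratings items x raters matrix or data.frame of categorical ratings;
#'   NA entries are treated as an explicit "no response" category.
#' @param k number of categories (default: distinct observed ratings).
#' @param po overall observed agreement in `[0, 1]`, alternative to `ratings`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `kappa_result`: `po`, `k`, `kappa`, `ci` (NA when
#'   only `po` is supplied), `n_items`, `n_raters`.
#' @export
free_marginal_kappa <- function(ratings = NULL, k = NULL, po = NULL,
                                conf_level = 0.95) {
  if (is.null(ratings) && is.null(po))
    stop_strokeclock("bad_input", "supply a ratings table or an observed agreement po")
  if (!is.null(po)) {
    if (is.null(k)) stop_strokeclock("bad_input", "k is required with po")
    if (k < 2) stop_strokeclock("bad_input", "need at least 2 categories")
    kap <- (po - 1 / k) / (1 - 1 / k)
    return(structure(list(po = po, k = k, kappa = kap,
                          ci = c(lower = NA_real_, upper = NA_real_),
                          n_items = NA_integer_, n_raters = NA_integer_),
                     class = "kappa_result"))
  }
  m <- as.matrix(ratings)
  m[is.na(m)] <- "no_response"
  n_items <- nrow(m); r <- ncol(m)
  if (r < 2L) stop_strokeclock("bad_input", "need at least 2 raters")
  if (n_items < 1L) stop_strokeclock("bad_input", "need at least 1 item")
  if (is.null(k)) k <- length(unique(as.vector(m)))
  if (k < 2) stop_strokeclock("bad_input", "need at least 2 categories")
  p_item <- apply(m, 1, function(row) {
    cnt <- table(row)
    sum(cnt * (cnt - 1)) / (r * (r - 1))
  })
  po <- mean(p_item)
  kap <- (po - 1 / k) / (1 - 1 / k)
  se_po <- if (n_items > 1) stats::sd(p_item) / sqrt(n_items) else 0
  se_k <- se_po / (1 - 1 / k)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(po = po, k = k, kappa = kap,
         ci = c(lower = kap - z * se_k, upper = kap + z * se_k),
         n_items = n_items, n_raters = r),
    class = "kappa_result"
  )
}

#' Majority adjudication of mismatch ratings
#'
#' Final match/mismatch classification per item: the majority vote of the
#' non-abstaining raters; an arbitrator decides exact ties (including items
#' on which every rater abstained).
#'
#' @param ratings items x raters matrix/data.frame with values `"match"`,
#'   `"mismatch"`, or NA / `"no_response"` for abstention.
#' @param arbitrator character vector of arbitrator decisions per item
#'   (needed only where the vote ties).
#' @return character vector of final labels.
#' @export
majority_adjudicate <- function(ratings, arbitrator = NULL) {
  m <- as.matrix(ratings)
  n <- nrow(m)
  if (is.null(arbitrator)) arbitrator <- rep(NA_character_, n)
  out <- character(n)
  for (i in seq_len(n)) {
    v <- m[i, ]
    v <- v[!is.na(v) & v != "no_response"]
    n_match <- sum(v == "match"); n_mis <- sum(v == "mismatch")
    if (n_match > n_mis) out[i] <- "match"
    else if (n_mis > n_match) out[i] <- "mismatch"
    else {
      if (is.na(arbitrator[i]))
        stop_strokeclock("missing_arbitrator",
                         "tied vote on item %d with no arbitrator decision", i)
      out[i] <- arbitrator[i]
    }
  }
  out
}

#' Simulate visual DWI/FLAIR mismatch ratings (synthetic)
#'
#' Stand-in for the human reading: each rater judges whether the lesion is
#' visible on FLAIR. The probability of visibility rises with onset time via
#' a logistic in (onset - 270)/scale; a visible lesion yields "match", an
#' invisible one "mismatch", and each rater abstains ("no response") with a
#' fixed probability. The arbitrator follows the noise-free visibility rule.
#'
#' @param onset_minutes onset times of the rated patients.
#' @param n_raters number of raters (default 4).
#' @param scale steepness of the visibility transition in minutes (default 60).
#' @param uncertain_rate per-rating abstention probability (default 0.15).
#' @return list with `ratings` (items x raters character matrix) and
#'   `arbitrator` (character vector).
#' @export
simulate_mismatch_ratings <- function(onset_minutes, n_raters = 4L,
                                      scale = 60, uncertain_rate = 0.15) {
  n <- length(onset_minutes)
  p_vis <- stats::plogis((onset_minutes - 270) / scale)
  ratings <- matrix(NA_character_, n, n_raters,
                    dimnames = list(NULL, paste0("rater", seq_len(n_raters))))
  for (j in seq_len(n_raters)) {
    visible <- stats::runif(n) < p_vis
    r <- ifelse(visible, "match", "mismatch")
    r[stats::runif(n) < uncertain_rate] <- "no_response"
    ratings[, j] <- r
  }
  arbitrator <- ifelse(p_vis > 0.5, "match", "mismatch")
  list(ratings = ratings, arbitrator = arbitrator)
}
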