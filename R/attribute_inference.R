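#' Observer sets
#'
#' For each roster member, the set of respondents who placed that member in
#' the recognized (not close) bin. The size of a member's observer set is the
#' number of binomial trials behind every attribute test for that member.
#'
#' @param rs a [report_set()].
#' @return named list mapping member id to a character vector of respondent
#'   ids; members never recognized map to an empty vector.
#' @export
observer_sets <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  rec <- rs$reports[rs$reports$bin == "recognized", ]
  out <- split(rec$respondent_id, factor(rec$member_id, levels = rs$roster$member_id))
  lapply(out, as.character)
}

#' Ascribe a perceived attribute from opinion counts
#'
#' Exact one-sided binomial test of the affirmation count `f` against the null
#' rate `beta_a` over `o_size` observers. If `f` exceeds the null expectation
#' `beta_a * o_size`, a right-tailed test is performed and `+1` ("have")
#' returned when `P[Z >= f] <= 1 - level` under `Z ~ Bin(o_size, beta_a)`;
#' if `f` falls below the expectation, a left-tailed test returns `-1`
#' ("not have") when `P[Z <= f] <= 1 - level`. Otherwise (including `f` equal
#' to the expectation or no observers) the result is `0` ("inconclusive").
#' The tails are exact, with no normal approximation, so the test is well
#' defined at small observer counts.
#'
#' @param f affirmation count(s), `0 <= f <= o_size`.
#' @param o_size observer count(s).
#' @param beta_a null affirmation probability.
#' @param level confidence level (default 0.95).
#' @return integer vector in `{-1, 0, 1}` (vectorized over `f`, `o_size`).
#' @export
ascribe_attribute <- function(f, o_size, beta_a, level = 0.95) {
  if (!is_prob(beta_a) || length(beta_a) != 1L) stopf("beta_a must be a probability")
  if (!is_prob(level) || length(level) != 1L) stopf("level must be a probability")
  if (any(f < 0) || any(f > o_size)) stopf("need 0 <= f <= o_size")
  tails <- attribute_tails(f, o_size, beta_a)
  decide_attribute(f, o_size, beta_a, tails$right, tails$left, level)
}

attribute_tails <- function(f, o_size, beta_a) {
  list(right = stats::pbinom(f - 1, o_size, beta_a, lower.tail = FALSE),
       left = stats::pbinom(f, o_size, beta_a))
}

decide_attribute <- function(f, o_size, beta_a, right, left, level) {
  expct <- beta_a * o_size
  out <- integer(length(f))
  out[o_size > 0 & f > expct & right <= 1 - level] <- 1L
  out[o_size > 0 & f < expct & left <= 1 - level] <- -1L
  out
}

#' Ascribe all perceived attributes
#'
#' Applies [ascribe_attribute()] to every (member, attribute) combination,
#' using the observer-set sizes as trial counts and the affirmation counts
#' recorded in the opinion table. Members never recognized by any respondent
#' are inconclusive for every attribute.
#'
#' @param rs a [report_set()].
#' @param beta named vector of null affirmation rates; estimated from the
#'   data via [estimate_beta()] when `NULL`.
#' @param level confidence level (default 0.95).
#' @return an object of class `attribute_estimate` with elements `q_tilde`
#'   (member x attribute matrix in `{-1, 0, 1}`), `f` (affirmation counts),
#'   `o_size` (observer counts per member), `tail` (the p-value of the tested
#'   tail, `NA` where no test applies), `beta`, `level`, and `summary`
#'   (per-attribute counts of have / not-have / inconclusive over all `n`
#'   members).
#' @export
ascribe_all <- function(rs, beta = NULL, level = 0.95) {
  stopifnot(inherits(rs, "report_set"))
  atts <- rs$attributes$attribute_id
  if (!length(atts)) stopf("report set has no attribute catalog")
  if (is.null(beta)) beta <- estimate_beta(rs)
  if (is.null(names(beta))) names(beta) <- atts
  if (!all(atts %in% names(beta))) stopf("beta must cover every cataloged attribute")

  members <- rs$roster$member_id
  o_size <- lengths(observer_sets(rs))[members]
  f <- matrix(0L, length(members), length(atts), dimnames = list(members, atts))
  op <- rs$opinions
  if (nrow(op)) {
    agg <- rowsum(op$opinion, paste(op$member_id, op$attribute_id, sep = "\r"))
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    f[cbind(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))] <- as.integer(agg)
  }

  q_tilde <- f * 0L
  tail_p <- matrix(NA_real_, length(members), length(atts), dimnames = dimnames(f))
  for (a in atts) {
    tails <- attribute_tails(f[, a], o_size, beta[[a]])
    dec <- decide_attribute(f[, a], o_size, beta[[a]], tails$right, tails$left, level)
    q_tilde[, a] <- dec
    tested_right <- o_size > 0 & f[, a] > beta[[a]] * o_size
    tested_left <- o_size > 0 & f[, a] < beta[[a]] * o_size
    tail_p[tested_right, a] <- tails$right[tested_right]
    tail_p[tested_left, a] <- tails$left[tested_left]
  }

  summary <- data.frame(
    attribute_id = atts,
    have = colSums(q_tilde == 1L),
    not_have = colSums(q_tilde == -1L),
    inconclusive = colSums(q_tilde == 0L),
    row.names = NULL
  )
  structure(list(q_tilde = q_tilde, f = f, o_size = o_size, tail = tail_p,
                 beta = beta[atts], level = level, summary = summary),
            class = "attribute_estimate")
}

#' @export
print.attribute_estimate <- function(x, ...) {
  cat(sprintf("<attribute_estimate> %d members x %d attributes at level %.3f\n",
              nrow(x$q_tilde), ncol(x$q_tilde), x$level))
  print(x$summary)
  invisible(x)
}
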