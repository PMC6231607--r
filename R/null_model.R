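#' Null-model parameters
#'
#' The blind-respondent null model: each of `m` sampled respondents is shown a
#' uniform random `k`-subset of the `n`-member roster, recognizes each shown
#' non-self member independently with probability `gamma`, sorts each
#' recognized member into one of `B` clusters uniformly at random, and affirms
#' attribute `a` for each recognized member with probability `beta[a]`. The
#' model has `M + 5` free parameters: `n`, `m`, `k`, `B`, `gamma` and the
#' `beta` vector.
#'
#' @param n population (roster) size.
#' @param m number of respondents.
#' @param k photos shown per respondent.
#' @param B number of clusters.
#' @param gamma recognition probability in `[0, 1]`.
#' @param beta vector of attribute affirmation probabilities (may be empty).
#' @param sig_level significance/confidence level used for tie thresholds and
#'   attribute tests (default 0.95).
#' @return an object of class `null_params`.
#' @export
null_params <- function(n, m, k, B, gamma, beta = numeric(), sig_level = 0.95) {
  stopifnot(is_count(n), is_count(m), is_count(k), is_count(B))
  if (k < 2 || k > n) stopf("need 2 <= k <= n")
  if (m < 1) stopf("need m >= 1")
  if (B < 2) stopf("need B >= 2 clusters")
  if (!is_prob(gamma) || length(gamma) != 1L) stopf("gamma must be a probability")
  if (length(beta) && !is_prob(beta)) stopf("beta entries must be probabilities")
  if (!is_prob(sig_level) || length(sig_level) != 1L) stopf("sig_level must be a probability")
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 B = as.integer(B), gamma = gamma, beta = beta,
                 sig_level = sig_level),
            class = "null_params")
}

#' @export
print.null_params <- function(x, ...) {
  cat(sprintf("<null_params> n = %d, m = %d, k = %d, B = %d, gamma = %.4f, M = %d, level = %.3f\n",
              x$n, x$m, x$k, x$B, x$gamma, length(x$beta), x$sig_level))
  invisible(x)
}

#' Calibrate the recognition probability from data
#'
#' The recognition rate is set so that the null model's expected recognition
#' count matches the data: `gamma = sum_i d(s_i) / (m * k)`, with `d(s_i)` the
#' recognition degree and `k` the nominal number of photos shown.
#'
#' @param rs a [report_set()].
#' @param k nominal shown count; defaults to the report set's `k`.
#' @return estimated probability.
#' @export
estimate_gamma <- function(rs, k = NULL) {
  stopifnot(inherits(rs, "report_set"))
  k <- k %||% rs$params$k
  m <- rs$params$m
  if (m < 1L || k < 1L) stopf("gamma is undefined for an empty report set")
  g <- sum(recognition_degree(rs)) / (m * k)
  if (g > 1) warnf("estimated gamma exceeds 1; check the nominal k")
  g
}

#' Calibrate attribute affirmation probabilities from data
#'
#' For each attribute, the affirmation rate is the fraction of affirmative
#' opinions among all recorded opinions on that attribute, matching the null
#' model's expected number of positive assertions to the data.
#'
#' @param rs a [report_set()].
#' @param attribute a single attribute id, or `NULL` for all cataloged
#'   attributes.
#' @return named numeric vector of estimates (or a single value when
#'   `attribute` is given).
#' @export
estimate_beta <- function(rs, attribute = NULL) {
  stopifnot(inherits(rs, "report_set"))
  op <- rs$opinions
  ids <- attribute %||% rs$attributes$attribute_id
  if (!length(ids)) stopf("no attributes cataloged")
  out <- vapply(ids, function(a) {
    o <- op$opinion[op$attribute_id == a]
    if (!length(o)) stopf("no opinions recorded for attribute '%s'; beta is undefined", a)
    mean(o)
  }, numeric(1))
  if (!is.null(attribute) && length(attribute) == 1L) unname(out) else out
}

#' Null distribution of a respondent's recognition count
#'
#' Under the null model a respondent recognizes each of the other `n - 1`
#' members independently with probability `gamma`, so the recognition count
#' over the whole roster is binomial with `n - 1` trials.
#'
#' @param params a [null_params()].
#' @return numeric vector of probabilities over counts `0 .. n-1`.
#' @export
recognition_pmf <- function(params) {
  stopifnot(inherits(params, "null_params"))
  stats::dbinom(0:(params$n - 1L), params$n - 1L, params$gamma)
}

#' Per-respondent co-cluster and split probabilities under the null model
#'
#' For a uniformly random pair of roster members, `p` is the probability that
#' a single blind respondent recognizes both and places them in the same
#' cluster, and `q` the probability of recognizing both and splitting them:
#' `p` marginalizes the recognition count `r ~ Bin(n-1, gamma)` against the
#' hypergeometric count of recognized members among the `k` shown and the
#' chance `C(l,2)/C(n,2)` that the pair falls inside the recognized-shown set,
#' with a final factor `1/B` (same cluster) or `(B-1)/B` (different clusters),
#' so `q = (B-1) p`. All combinatorial terms are accumulated in log space.
#'
#' @param params a [null_params()].
#' @return list with elements `p` and `q`.
#' @export
copair_probabilities <- function(params) {
  stopifnot(inherits(params, "null_params"))
  n <- params$n; k <- params$k; B <- params$B; gamma <- params$gamma
  if (gamma == 0) return(list(p = 0, q = 0))
  lognk <- lchoose(n, k)
  logn2 <- lchoose(n, 2)
  log_terms <- c()
  for (r in 0:(n - 1L)) {
    lo <- max(2L, k + r - n); hi <- min(r, k)
    if (hi < lo) next
    lz <- stats::dbinom(r, n - 1L, gamma, log = TRUE)
    l <- lo:hi
    log_terms <- c(log_terms,
                   lz + lchoose(r, l) + lchoose(n - r, k - l) - lognk +
                     lchoose(l, 2) - logn2)
  }
  if (!length(log_terms)) return(list(p = 0, q = 0))
  # sum of exp(log_terms), shifted by the running maximum for stability
  mx <- max(log_terms)
  s <- exp(mx) * sum(exp(log_terms - mx))
  list(p = s / B, q = s * (B - 1) / B)
}

#' Null distributions of pairwise co-cluster and split counts
#'
#' Aggregated over the `m` respondents, the number `X` of respondents who
#' recognize a fixed pair and co-cluster it is binomial `Bin(m, p)`, and the
#' split count `Y` is `Bin(m, q)`. Includes the significance thresholds at the
#' configured level.
#'
#' @param params a [null_params()].
#' @param level significance level; defaults to `params$sig_level`.
#' @return an object of class `pair_null` with elements `p`, `q`, `x_pmf`,
#'   `y_pmf` (probability vectors over counts `0..m`), `delta_plus`,
#'   `delta_minus`, `level`, `m`.
#' @export
pair_count_distributions <- function(params, level = params$sig_level) {
  stopifnot(inherits(params, "null_params"))
  pq <- copair_probabilities(params)
  m <- params$m
  x_pmf <- stats::dbinom(0:m, m, pq$p)
  y_pmf <- stats::dbinom(0:m, m, pq$q)
  structure(list(p = pq$p, q = pq$q, x_pmf = x_pmf, y_pmf = y_pmf,
                 delta_plus = threshold_from_pmf(x_pmf, level),
                 delta_minus = threshold_from_pmf(y_pmf, level),
                 level = level, m = m),
            class = "pair_null")
}

#' @export
print.pair_null <- function(x, ...) {
  cat(sprintf("<pair_null> m = %d, p = %.6g, q = %.6g\n", x$m, x$p, x$q))
  cat(sprintf("  delta_plus = %d, delta_minus = %d at level %.3f\n",
              x$delta_plus, x$delta_minus, x$level))
  invisible(x)
}

# minimum integer w with Prob[count < w] >= level, the strict lower tail
threshold_from_pmf <- function(pmf, level) {
  cdf_strict <- c(0, cumsum(pmf))   # cdf_strict[w + 1] = Prob[count < w]
  w <- which(cdf_strict >= level - 1e-12)[1] - 1L
  if (is.na(w)) length(pmf) else w
}

#' Significance thresholds for tie ascription
#'
#' `delta_plus` is the minimum integer `w` such that `Prob[X < w] >= level`
#' under the null model; an observed co-cluster count `>= delta_plus` is
#' significant evidence of a perceived tie. `delta_minus` is the analogous
#' cutoff for the split count `Y`, giving "robust intransitive" (perceived
#' non-) ties.
#'
#' @param params a [null_params()].
#' @param level significance level in `[0, 1]`.
#' @return list with integer elements `delta_plus` and `delta_minus`.
#' @export
thresholds <- function(params, level = params$sig_level) {
  stopifnot(inherits(params, "null_params"))
  if (!is_prob(level) || length(level) != 1L) stopf("level must be a probability")
  d <- pair_count_distributions(params, level)
  list(delta_plus = d$delta_plus, delta_minus = d$delta_minus)
}
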