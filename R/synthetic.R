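#' Configuration for the blind-respondent (null) report simulator
#'
#' Defaults reproduce the study conditions of the motivating field deployment:
#' a roster of 393 photographed community members, 172 respondents each shown
#' 40 photos sorted into 5 clusters, recognition rate 0.7622. The attribute
#' affirmation rates are not published per attribute, so the default spreads
#' 16 attributes over a plausible range of community-opinion base rates.
#'
#' @param n roster size.
#' @param m number of respondents.
#' @param k photos shown per respondent.
#' @param B number of clusters.
#' @param gamma recognition probability.
#' @param beta named or unnamed vector of attribute affirmation rates (empty
#'   for no opinion data).
#' @param seed integer seed.
#' @return object of class `null_sim_config`.
#' @export
null_sim_config <- function(n = 393L, m = 172L, k = 40L, B = 5L,
                            gamma = 0.7622,
                            beta = round(seq(0.10, 0.70, length.out = 16), 4),
                            seed = 1L) {
  stopifnot(is_count(n), is_count(m), is_count(k), is_count(B), is_count(seed))
  if (k > n) stopf("need k <= n")
  if (m > n) stopf("need m <= n (respondents are roster members)")
  if (!is_prob(gamma) || (length(beta) && !is_prob(beta)))
    stopf("gamma and beta must be probabilities")
  if (length(beta) && is.null(names(beta)))
    names(beta) <- sprintf("A%d", seq_along(beta))
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 B = as.integer(B), gamma = gamma, beta = beta,
                 seed = as.integer(seed)),
            class = "null_sim_config")
}

roster_ids <- function(n) sprintf("p%04d", seq_len(n))

#' Simulate respondent reports under the null model
#'
#' Each respondent is shown a uniform random `k`-subset of the roster (their
#' own photo may be drawn, in which case it yields no record), recognizes each
#' shown non-self member independently with probability `gamma`, places each
#' recognized member into a uniform random cluster among the `B`, and affirms
#' each attribute for each recognized member with the attribute's `beta` rate.
#' Randomness is split into one stream per respondent (derived from the
#' configuration seed), so enlarging `m` does not reshuffle earlier
#' respondents; the output is byte-identical for identical configurations.
#'
#' @param config a [null_sim_config()].
#' @return a validated [report_set()].
#' @export
simulate_null_reports <- function(config) {
  stopifnot(inherits(config, "null_sim_config"))
  with(config, {
    roster <- roster_ids(n)
    set.seed(seed)
    respondents <- sample(roster, m)
    atts <- names(beta)
    rep_rows <- vector("list", m)
    op_rows <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(derive_seed(seed, i))
      shown <- sample(roster, k)
      shown <- shown[shown != respondents[i]]
      rec <- stats::runif(length(shown)) < gamma
      cluster <- rep(NA_integer_, length(shown))
      cluster[rec] <- sample.int(B, sum(rec), replace = TRUE)
      rep_rows[[i]] <- data.frame(
        respondent_id = respondents[i], member_id = shown,
        bin = ifelse(rec, "recognized", "unknown"), cluster = cluster)
      if (length(atts) && any(rec)) {
        rm <- shown[rec]
        op_rows[[i]] <- data.frame(
          respondent_id = respondents[i],
          member_id = rep(rm, times = length(atts)),
          attribute_id = rep(atts, each = length(rm)),
          opinion = stats::rbinom(length(rm) * length(atts), 1L,
                                  rep(beta, each = length(rm))))
      }
    }
    report_set(
      roster = roster,
      attributes = if (length(atts)) atts else NULL,
      reports = do.call(rbind, rep_rows),
      opinions = if (length(atts)) do.call(rbind, op_rows) else NULL,
      k = k, B = B
    )
  })
}

#' Configuration for the planted-community report simulator
#'
#' A deliberately simple perception model used as ground truth for recovery
#' tests: the roster is split into `K_true` communities, each mapped to a
#' distinct cluster bin; an observer files a recognized member under the
#' member's community bin with probability `lambda` and under a uniform random
#' bin otherwise, where `lambda^2 = B (theta_in - theta_out) / (B - 1)`
#' (capped at 1). This induces same-bin placement with probability
#' `lambda^2 + (1 - lambda^2)/B` for same-community pairs and
#' `(1 - lambda^2)/B` for cross-community pairs, so `theta_in = theta_out`
#' reduces exactly to the blind null model. Each member holds attribute `a`
#' (`Q = +1`) with probability `role_prob[community, a]`; observers affirm
#' with rate `opinion_tp` for holders and `opinion_fp` for non-holders. A
#' recognized member is diverted to the "close" bin (and so excluded from
#' cluster sorting and opinions) with probability `close_prob`.
#'
#' Defaults define a recoverable regime: 4 equal communities of 30, every
#' member interviewed, strong co-clustering signal, and one marker attribute
#' per community.
#'
#' @param n,m,k,B,gamma,seed as in [null_sim_config()].
#' @param K_true number of planted communities (`<= B`).
#' @param sizes community sizes summing to `n`; defaults to near-equal.
#' @param theta_in,theta_out target same-bin placement probabilities for
#'   same-community and cross-community recognized pairs.
#' @param role_prob `K_true x M` matrix of `P(Q = +1 | community)`; defaults
#'   to one marker attribute per community (0.9 within, 0.1 elsewhere).
#' @param opinion_tp,opinion_fp affirmation probabilities given `Q = +1` /
#'   `Q = -1`.
#' @param close_prob probability a recognized member is binned "close".
#' @return object of class `planted_config`.
#' @export
planted_config <- function(n = 120L, m = 120L, k = 40L, B = 5L, K_true = 4L,
                           sizes = NULL, gamma = 0.7622,
                           theta_in = 0.9, theta_out = 0.1,
                           role_prob = NULL, opinion_tp = 0.9,
                           opinion_fp = 0.1, close_prob = 0.1, seed = 1L) {
  stopifnot(is_count(n), is_count(m), is_count(k), is_count(B),
            is_count(K_true), is_count(seed))
  if (K_true > B) stopf("K_true communities cannot exceed B bins")
  if (k > n || m > n) stopf("need k <= n and m <= n")
  if (!is_prob(c(gamma, theta_in, theta_out, opinion_tp, opinion_fp, close_prob)))
    stopf("all rates must be probabilities")
  if (is.null(sizes)) {
    sizes <- rep(n %/% K_true, K_true)
    sizes[seq_len(n %% K_true)] <- sizes[seq_len(n %% K_true)] + 1L
  }
  if (sum(sizes) != n || length(sizes) != K_true)
    stopf("community sizes must sum to n with one entry per community")
  if (is.null(role_prob)) {
    role_prob <- matrix(0.1, K_true, K_true,
                        dimnames = list(NULL, sprintf("A%d", seq_len(K_true))))
    diag(role_prob) <- 0.9
  }
  if (!is_prob(role_prob)) stopf("role_prob entries must be probabilities")
  if (is.null(colnames(role_prob)))
    colnames(role_prob) <- sprintf("A%d", seq_len(ncol(role_prob)))

  lambda2 <- min(1, max(0, B * (theta_in - theta_out) / (B - 1)))
  s_in <- lambda2 + (1 - lambda2) / B
  s_out <- (1 - lambda2) / B
  if (theta_in > theta_out && (s_in < theta_in - 1e-9 || s_out > theta_out + 1e-9))
    warnf("declared theta bounds not representable (induced same-bin rates: %.3f within, %.3f across)",
          s_in, s_out)
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 B = as.integer(B), K_true = as.integer(K_true),
                 sizes = as.integer(sizes), gamma = gamma,
                 theta_in = theta_in, theta_out = theta_out,
                 lambda = sqrt(lambda2), role_prob = role_prob,
                 opinion_tp = opinion_tp, opinion_fp = opinion_fp,
                 close_prob = close_prob, seed = as.integer(seed)),
            class = "planted_config")
}

#' Simulate respondent reports with planted community and role structure
#'
#' See [planted_config()] for the generative model. Returns the report set
#' together with the planted ground truth, enabling end-to-end recovery tests
#' of the tie-inference, balance-partitioning and attribute-ascription stages.
#'
#' @param config a [planted_config()].
#' @return list with elements `reports` (a [report_set()]), `communities`
#'   (named integer vector over the roster) and `Q` (member x attribute
#'   ground-truth matrix in `{-1, +1}`).
#' @export
simulate_planted_reports <- function(config) {
  stopifnot(inherits(config, "planted_config"))
  with(config, {
    roster <- roster_ids(n)
    comm <- stats::setNames(rep(seq_len(K_true), times = sizes), roster)
    atts <- colnames(role_prob)
    M <- length(atts)

    set.seed(derive_seed(seed, 0L))
    Q <- matrix(ifelse(stats::runif(n * M) < role_prob[comm, , drop = FALSE], 1L, -1L),
                n, M, dimnames = list(roster, atts))
    respondents <- sample(roster, m)

    rep_rows <- vector("list", m)
    op_rows <- vector("list", m)
    for (i in seq_len(m)) {
      set.seed(derive_seed(seed, i))
      shown <- sample(roster, k)
      shown <- shown[shown != respondents[i]]
      rec <- stats::runif(length(shown)) < gamma
      close <- rec & stats::runif(length(shown)) < close_prob
      c2 <- rec & !close
      bin <- ifelse(close, "close", ifelse(c2, "recognized", "unknown"))
      cluster <- rep(NA_integer_, length(shown))
      if (any(c2)) {
        n2 <- sum(c2)
        use_comm <- stats::runif(n2) < lambda
        cl <- sample.int(B, n2, replace = TRUE)
        cl[use_comm] <- comm[shown[c2][use_comm]]
        cluster[c2] <- cl
      }
      rep_rows[[i]] <- data.frame(
        respondent_id = respondents[i], member_id = shown,
        bin = bin, cluster = cluster)
      if (M && any(c2)) {
        rm <- shown[c2]
        affirm_p <- ifelse(Q[rm, , drop = FALSE] == 1L, opinion_tp, opinion_fp)
        op_rows[[i]] <- data.frame(
          respondent_id = respondents[i],
          member_id = rep(rm, times = M),
          attribute_id = rep(atts, each = length(rm)),
          opinion = stats::rbinom(length(rm) * M, 1L, as.vector(affirm_p)))
      }
    }
    rs <- report_set(
      roster = roster,
      attributes = if (M) atts else NULL,
      reports = do.call(rbind, rep_rows),
      opinions = if (M) do.call(rbind, op_rows) else NULL,
      k = k, B = B
    )
    list(reports = rs, communities = comm, Q = Q)
  })
}
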