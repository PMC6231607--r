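#' Structural-balance score of a partition
#'
#' `R = alpha_w * N_c + (1 - alpha_w) * P_c`, where `N_c` counts negative
#' edges inside classes and `P_c` counts positive edges between classes. A
#' perfectly balanced partition scores 0.
#'
#' @param network a `signed_network`.
#' @param assignment named integer vector (node -> class index) covering every
#'   network node, or an unnamed vector aligned with `network$nodes`.
#' @param alpha_w balance weight in `[0, 1]` (default 0.5, giving negative
#'   within-class and positive between-class inconsistencies equal weight).
#' @return list with elements `r`, `n_c`, `p_c`.
#' @export
balance_score <- function(network, assignment, alpha_w = 0.5) {
  el <- network_edge_index(network)
  cls <- align_assignment(assignment, network$nodes)
  same <- cls[el$ui] == cls[el$vi]
  n_c <- sum(el$sign < 0L & same)
  p_c <- sum(el$sign > 0L & !same)
  list(r = alpha_w * n_c + (1 - alpha_w) * p_c, n_c = n_c, p_c = p_c)
}

align_assignment <- function(assignment, nodes) {
  if (!is.null(names(assignment))) {
    miss <- setdiff(nodes, names(assignment))
    if (length(miss)) stopf("assignment lacks node(s): %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    assignment <- assignment[nodes]
  } else if (length(assignment) != length(nodes)) {
    stopf("unnamed assignment must have one entry per network node")
  }
  as.integer(assignment)
}

network_edge_index <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  ed <- network$edges
  list(ui = match(ed$u, network$nodes), vi = match(ed$v, network$nodes),
       sign = as.integer(ed$sign))
}

# canonical labeling: classes numbered by order of first appearance
canonical_partition <- function(cls) {
  match(cls, unique(cls))
}

# random start: deal min_size nodes to each class round-robin, rest uniform
random_feasible_partition <- function(n, K, min_size) {
  cls <- integer(n)
  perm <- sample.int(n)
  base <- K * min_size
  if (base > 0L) cls[perm[seq_len(base)]] <- rep(seq_len(K), each = min_size)
  if (base < n) cls[perm[(base + 1L):n]] <- sample.int(K, n - base, replace = TRUE)
  cls
}

#' Partition a signed network by minimizing the balance score
#'
#' Local search over partitions into exactly `K` classes of at least
#' `min_size` nodes. Each repetition starts from a fresh random feasible
#' partition and applies steepest-descent moves — single-node relocations and
#' two-node exchanges, restricted to moves that preserve the class-size floor
#' — until no move strictly decreases `R`. The minimum `R` over all
#' repetitions is returned together with every distinct optimal partition
#' found (class labels canonicalized before comparison), which supports the
#' uniqueness accounting used for model selection.
#'
#' @param network a `signed_network`.
#' @param K number of classes.
#' @param min_size minimum class size (default 3, a minimal sociologically
#'   meaningful group).
#' @param repetitions number of random restarts (default 100).
#' @param alpha_w balance weight (default 0.5).
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param method `"steepest"` (default) applies the best improving move each
#'   step; `"first"` applies the first improving move found.
#' @return an object of class `balance_trial`: `K`, `r` (best score), `n_c`,
#'   `p_c`, `partitions` (list of distinct optimal assignments, named integer
#'   vectors), `n_solutions`, `unique` (exactly one optimum found),
#'   `repetitions`, `min_size`, `alpha_w`.
#' @export
optimize_partition <- function(network, K, min_size = 3L, repetitions = 100L,
                               alpha_w = 0.5, seed = NULL,
                               method = c("steepest", "first")) {
  method <- match.arg(method)
  el <- network_edge_index(network)
  n <- length(network$nodes)
  stopifnot(is_count(K), is_count(min_size), is_count(repetitions))
  min_size <- max(as.integer(min_size), 1L)  # classes must stay non-empty
  if (K < 1L || K * min_size > n) stopf("infeasible: K * min_size exceeds node count")
  if (repetitions < 1L) stopf("repetitions must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  adj <- build_signed_adjacency(n, el)
  best_r <- Inf
  best_counts <- NULL
  seen <- new.env(parent = emptyenv())
  partitions <- list()

  for (rep_i in seq_len(repetitions)) {
    cls <- random_feasible_partition(n, K, min_size)
    cls <- local_search_balance(cls, n, K, min_size, alpha_w, el, adj, method)
    sc <- score_from_index(el, cls, alpha_w)
    if (sc$r < best_r - 1e-9) {
      best_r <- sc$r
      best_counts <- sc
      seen <- new.env(parent = emptyenv())
      partitions <- list()
    }
    if (sc$r <= best_r + 1e-9) {
      canon <- canonical_partition(cls)
      key <- paste(canon, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        partitions[[length(partitions) + 1L]] <-
          stats::setNames(canon, network$nodes)
      }
    }
  }

  structure(list(K = as.integer(K), r = best_r, n_c = best_counts$n_c,
                 p_c = best_counts$p_c, partitions = partitions,
                 n_solutions = length(partitions),
                 unique = length(partitions) == 1L,
                 repetitions = as.integer(repetitions),
                 min_size = as.integer(min_size), alpha_w = alpha_w),
            class = "balance_trial")
}

#' @export
print.balance_trial <- function(x, ...) {
  cat(sprintf("<balance_trial> K = %d: best R = %g (N_c = %d, P_c = %d), %d distinct optimum%s over %d repetitions\n",
              x$K, x$r, x$n_c, x$p_c, x$n_solutions,
              if (x$n_solutions == 1L) "" else "a", x$repetitions))
  if (x$n_solutions >= 1L) {
    sizes <- tabulate(x$partitions[[1]])
    cat(sprintf("  class sizes: %s\n", paste(sizes, collapse = ", ")))
  }
  invisible(x)
}

score_from_index <- function(el, cls, alpha_w) {
  same <- cls[el$ui] == cls[el$vi]
  n_c <- sum(el$sign < 0L & same)
  p_c <- sum(el$sign > 0L & !same)
  list(r = alpha_w * n_c + (1 - alpha_w) * p_c, n_c = n_c, p_c = p_c)
}

build_signed_adjacency <- function(n, el) {
  pos <- vector("list", n); neg <- vector("list", n)
  for (e in seq_along(el$sign)) {
    u <- el$ui[e]; v <- el$vi[e]
    if (el$sign[e] > 0L) {
      pos[[u]] <- c(pos[[u]], v); pos[[v]] <- c(pos[[v]], u)
    } else {
      neg[[u]] <- c(neg[[u]], v); neg[[v]] <- c(neg[[v]], u)
    }
  }
  list(pos = pos, neg = neg)
}

# steepest-descent / first-improvement local search; every accepted move
# strictly decreases R, so termination is guaranteed
local_search_balance <- function(cls, n, K, min_size, alpha_w, el, adj, method) {
  # W*[i, c]: number of positive / negative edges from node i into class c
  Wpos <- matrix(0L, n, K); Wneg <- matrix(0L, n, K)
  for (e in seq_along(el$sign)) {
    u <- el$ui[e]; v <- el$vi[e]
    if (el$sign[e] > 0L) {
      Wpos[u, cls[v]] <- Wpos[u, cls[v]] + 1L
      Wpos[v, cls[u]] <- Wpos[v, cls[u]] + 1L
    } else {
      Wneg[u, cls[v]] <- Wneg[u, cls[v]] + 1L
      Wneg[v, cls[u]] <- Wneg[v, cls[u]] + 1L
    }
  }
  sizes <- tabulate(cls, K)
  idx <- seq_len(n)
  tol <- 1e-9

  # exchange correction for adjacent pairs: relocation deltas double-count the
  # shared edge, which in fact stays cross-class under an exchange
  n_edges <- length(el$sign)
  corr_val <- ifelse(el$sign > 0L, 2 * (1 - alpha_w), -2 * alpha_w)

  repeat {
    own <- cbind(idx, cls)
    D <- alpha_w * (Wneg - Wneg[own]) + (1 - alpha_w) * (Wpos[own] - Wpos)
    D[own] <- 0

    # relocations: forbidden out of classes at the size floor
    Drel <- D
    Drel[sizes[cls] <= min_size, ] <- Inf
    Drel[own] <- Inf

    # exchanges: EX[i, j] = D[i, cls_j] + D[j, cls_i] (+ shared-edge correction)
    M1 <- D[, cls, drop = FALSE]
    EX <- M1 + t(M1)
    if (n_edges) {
      eidx <- cbind(el$ui, el$vi)
      EX[eidx] <- EX[eidx] + corr_val
      EX[eidx[, 2:1, drop = FALSE]] <- EX[eidx[, 2:1, drop = FALSE]] + corr_val
    }
    EX[outer(cls, cls, "==")] <- Inf

    if (method == "first") {
      hit <- which(Drel < -tol)
      if (length(hit)) {
        i <- ((hit[1] - 1L) %% n) + 1L
        b <- ((hit[1] - 1L) %/% n) + 1L
        apply_move <- list(type = "rel", i = i, b = b)
      } else {
        hit <- which(EX < -tol)
        if (!length(hit)) break
        i <- ((hit[1] - 1L) %% n) + 1L
        j <- ((hit[1] - 1L) %/% n) + 1L
        apply_move <- list(type = "ex", i = i, j = j)
      }
    } else {
      best_rel <- min(Drel)
      best_ex <- min(EX)
      if (min(best_rel, best_ex) >= -tol) break
      if (best_rel <= best_ex) {
        w <- which.min(Drel)
        apply_move <- list(type = "rel", i = ((w - 1L) %% n) + 1L,
                           b = ((w - 1L) %/% n) + 1L)
      } else {
        w <- which.min(EX)
        apply_move <- list(type = "ex", i = ((w - 1L) %% n) + 1L,
                           j = ((w - 1L) %/% n) + 1L)
      }
    }

    move_node <- function(i, b) {
      a <- cls[i]
      for (u in adj$pos[[i]]) {
        Wpos[u, a] <<- Wpos[u, a] - 1L
        Wpos[u, b] <<- Wpos[u, b] + 1L
      }
      for (u in adj$neg[[i]]) {
        Wneg[u, a] <<- Wneg[u, a] - 1L
        Wneg[u, b] <<- Wneg[u, b] + 1L
      }
      sizes[a] <<- sizes[a] - 1L
      sizes[b] <<- sizes[b] + 1L
      cls[i] <<- b
    }
    if (apply_move$type == "rel") {
      move_node(apply_move$i, apply_move$b)
    } else {
      bi <- cls[apply_move$j]; bj <- cls[apply_move$i]
      move_node(apply_move$i, bi)
      move_node(apply_move$j, bj)
    }
  }
  cls
}

#' Exhaustive optimum of the balance score (test oracle)
#'
#' Enumerates every partition of the network's nodes into exactly `K` classes
#' meeting the size floor and returns the global minimum of the balance score
#' with all partitions attaining it. Guarded to at most 14 nodes.
#'
#' @inheritParams optimize_partition
#' @return list with elements `r` (global optimum), `n_c`, `p_c`,
#'   `partitions` (list of canonical optimal assignments).
#' @export
exhaustive_optimum <- function(network, K, min_size = 1L, alpha_w = 0.5) {
  n <- length(network$nodes)
  if (n > 14L) stopf("exhaustive enumeration guarded to networks of <= 14 nodes")
  stopifnot(is_count(K), K >= 1L)
  if (K * min_size > n) stopf("infeasible: K * min_size exceeds node count")
  el <- network_edge_index(network)

  # level-wise expansion of restricted growth strings with < K class labels
  A <- matrix(0L, 1L, 1L)
  mx <- 0L
  for (i in seq_len(n)[-1]) {
    blocks <- lapply(0:(K - 1L), function(v) {
      keep <- mx >= v - 1L
      if (!any(keep)) return(NULL)
      list(A = cbind(A[keep, , drop = FALSE], v), mx = pmax(mx[keep], v))
    })
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    A <- do.call(rbind, lapply(blocks, `[[`, "A"))
    mx <- unlist(lapply(blocks, `[[`, "mx"), use.names = FALSE)
    if (nrow(A) > 2e7) stopf("enumeration too large; reduce n or K")
  }
  keep <- mx == K - 1L
  A <- A[keep, , drop = FALSE]
  if (min_size > 1L) {
    ok <- rep(TRUE, nrow(A))
    for (c in 0:(K - 1L)) ok <- ok & rowSums(A == c) >= min_size
    A <- A[ok, , drop = FALSE]
  }
  if (!nrow(A)) stopf("no feasible partition for the given K and min_size")

  r_vec <- numeric(nrow(A))
  nc_vec <- integer(nrow(A)); pc_vec <- integer(nrow(A))
  for (e in seq_along(el$sign)) {
    same <- A[, el$ui[e]] == A[, el$vi[e]]
    if (el$sign[e] < 0L) nc_vec <- nc_vec + same
    else pc_vec <- pc_vec + !same
  }
  r_vec <- alpha_w * nc_vec + (1 - alpha_w) * pc_vec
  r_star <- min(r_vec)
  opt <- which(r_vec <= r_star + 1e-12)
  parts <- lapply(opt, function(i) stats::setNames(A[i, ] + 1L, network$nodes))
  list(r = r_star, n_c = nc_vec[opt[1]], p_c = pc_vec[opt[1]], partitions = parts)
}

#' Sweep the number of balance classes
#'
#' Runs [optimize_partition()] for every `K` in `K_range`, `trials` times per
#' `K` (trial `t` uses seed `base_seed + t`; the same trial-seed sequence is
#' reused across `K` values). Reports per-trial results plus the per-`K`
#' summaries used for model selection: median best `R`, outlier trials (those
#' whose repetitions found more than one distinct optimum), the mean number of
#' optima among outliers, and the smallest/largest class sizes.
#'
#' @inheritParams optimize_partition
#' @param K_range integer vector of class counts to try (default `3:9`).
#' @param trials independent optimization trials per `K` (default 10).
#' @param base_seed base RNG seed.
#' @return an object of class `balance_sweep` with elements `results`
#'   (per-trial data frame), `summary` (per-`K` data frame) and `params`.
#' @export
sweep_classes <- function(network, K_range = 3:9, trials = 10L,
                          repetitions = 100L, min_size = 3L, alpha_w = 0.5,
                          base_seed = 1L) {
  rows <- list()
  trial_objs <- list()
  for (K in K_range) {
    for (t in seq_len(trials)) {
      tr <- optimize_partition(network, K = K, min_size = min_size,
                               repetitions = repetitions, alpha_w = alpha_w,
                               seed = base_seed + t)
      sizes <- tabulate(tr$partitions[[1]], K)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, trial = t, seed = base_seed + t, r = tr$r,
        n_solutions = tr$n_solutions, unique = tr$unique,
        smallest_class = min(sizes), largest_class = max(sizes))
      trial_objs[[sprintf("K%d_t%d", K, t)]] <- tr
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$K), function(d) {
    out_trials <- d[!d$unique, , drop = FALSE]
    data.frame(K = d$K[1],
               median_r = stats::median(d$r),
               min_r = min(d$r),
               n_outliers = nrow(out_trials),
               mean_solutions_outliers = if (nrow(out_trials)) mean(out_trials$n_solutions) else 0,
               median_smallest_class = stats::median(d$smallest_class))
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, trials = trial_objs,
                 params = list(K_range = K_range, trials = trials,
                               repetitions = repetitions, min_size = min_size,
                               alpha_w = alpha_w, base_seed = base_seed)),
            class = "balance_sweep")
}

#' @export
print.balance_sweep <- function(x, ...) {
  cat(sprintf("<balance_sweep> K in {%s}, %d trials x %d repetitions\n",
              paste(x$params$K_range, collapse = ", "),
              x$params$trials, x$params$repetitions))
  print(x$summary)
  invisible(x)
}

#' Recommend a class count from a sweep
#'
#' Picks the `K` with the lowest median balance score, breaking ties by the
#' fewest outlier (non-unique) trials and then by the smaller `K`. The full
#' ranked criteria table is returned; the choice is advisory.
#'
#' @param sweep a `balance_sweep`.
#' @return list with elements `K` (recommended class count) and `criteria`
#'   (the summary table in ranked order).
#' @export
select_model <- function(sweep) {
  stopifnot(inherits(sweep, "balance_sweep"))
  s <- sweep$summary
  if (!nrow(s)) stopf("empty sweep")
  ord <- order(s$median_r, s$n_outliers, s$K)
  list(K = s$K[ord[1]], criteria = s[ord, ])
}
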