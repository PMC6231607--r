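#' Tally pairwise co-cluster and split evidence from reports
#'
#' For every unordered pair of roster members that at least one respondent
#' placed in the recognized bin together, counts the respondents who put both
#' in the same cluster (`x_obs`) and in different clusters (`y_obs`). Only
#' recognized-bin members contribute: "close" and "unknown" placements count
#' toward neither total. In lenient mode, recognized members lacking a cluster
#' are dropped from the pair tallies entirely.
#'
#' @param rs a [report_set()].
#' @return a data frame of class `pair_evidence` with columns `u`, `v`
#'   (`u < v` lexicographically), `n_corecognized`, `x_obs`, `y_obs`, and an
#'   attribute `recognized_members` (members placed in the recognized bin by
#'   at least one respondent).
#' @export
tally_pair_evidence <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  rec <- rs$reports[rs$reports$bin == "recognized", c("respondent_id", "member_id", "cluster")]
  recognized_members <- sort(unique(rec$member_id))
  rec <- rec[!is.na(rec$cluster), ]

  us <- vs <- character(0); same <- logical(0)
  if (nrow(rec)) {
    by_resp <- split(rec[, c("member_id", "cluster")], rec$respondent_id)
    pieces <- lapply(by_resp, function(d) {
      nr <- nrow(d)
      if (nr < 2L) return(NULL)
      o <- order(d$member_id)
      mem <- d$member_id[o]; cl <- d$cluster[o]
      ij <- utils::combn(nr, 2L)
      list(u = mem[ij[1, ]], v = mem[ij[2, ]], same = cl[ij[1, ]] == cl[ij[2, ]])
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) {
      us <- unlist(lapply(pieces, `[[`, "u"), use.names = FALSE)
      vs <- unlist(lapply(pieces, `[[`, "v"), use.names = FALSE)
      same <- unlist(lapply(pieces, `[[`, "same"), use.names = FALSE)
    }
  }

  if (!length(us)) {
    out <- data.frame(u = character(), v = character(), n_corecognized = integer(),
                      x_obs = integer(), y_obs = integer())
  } else {
    key <- paste(us, vs, sep = "\r")
    agg <- rowsum(cbind(n = 1L, x = as.integer(same), y = as.integer(!same)), key)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    out <- data.frame(u = vapply(parts, `[[`, "", 1L),
                      v = vapply(parts, `[[`, "", 2L),
                      n_corecognized = as.integer(agg[, "n"]),
                      x_obs = as.integer(agg[, "x"]),
                      y_obs = as.integer(agg[, "y"]))
    out <- out[order(out$u, out$v), ]
    rownames(out) <- NULL
  }
  attr(out, "recognized_members") <- recognized_members
  class(out) <- c("pair_evidence", class(out))
  out
}

empty_edge_table <- function() {
  data.frame(u = character(), v = character(), sign = integer(),
             x_obs = integer(), y_obs = integer(), n_corecognized = integer())
}

new_signed_network <- function(nodes, edges, contested = empty_edge_table(),
                               evidence = NULL, delta_plus = NA_integer_,
                               delta_minus = NA_integer_, policy = NA_character_) {
  structure(list(nodes = nodes, edges = edges, contested = contested,
                 evidence = evidence, delta_plus = delta_plus,
                 delta_minus = delta_minus, policy = policy),
            class = "signed_network")
}

#' Ascribe the signed perceived network from pair evidence
#'
#' A pair receives a positive tie when at least `delta_plus` respondents
#' co-clustered it, and a negative ("robust intransitive") tie when at least
#' `delta_minus` respondents split it. Pairs meeting both thresholds are
#' recorded in a contested ledger and resolved by `policy`: under the default
#' `contested_null` they carry no edge; `positive_wins` / `negative_wins`
#' force the corresponding sign. All remaining pairs carry no edge.
#'
#' @param evidence a `pair_evidence` table from [tally_pair_evidence()].
#' @param delta_plus,delta_minus integer thresholds (>= 1), see [thresholds()].
#' @param policy resolution for pairs meeting both thresholds.
#' @param nodes node universe; defaults to the evidence table's
#'   `recognized_members` attribute (members recognized by at least one
#'   respondent), falling back to the members appearing in evidence pairs.
#' @return an object of class `signed_network` with elements `nodes`, `edges`
#'   (`u`, `v`, `sign`, evidence counts), `contested`, `evidence`,
#'   `delta_plus`, `delta_minus`, `policy`.
#' @export
infer_signed_network <- function(evidence, delta_plus, delta_minus,
                                 policy = c("contested_null", "positive_wins", "negative_wins"),
                                 nodes = NULL) {
  policy <- match.arg(policy)
  stopifnot(is_count(delta_plus), is_count(delta_minus))
  if (delta_plus < 1L || delta_minus < 1L) stopf("thresholds must be >= 1")
  nodes <- nodes %||% attr(evidence, "recognized_members") %||%
    sort(unique(c(evidence$u, evidence$v)))

  pos <- evidence$x_obs >= delta_plus
  neg <- evidence$y_obs >= delta_minus
  both <- pos & neg
  contested <- as.data.frame(evidence[both, , drop = FALSE])

  sign_of <- integer(nrow(evidence))
  sign_of[pos & !both] <- 1L
  sign_of[neg & !both] <- -1L
  sign_of[both] <- switch(policy, contested_null = 0L, positive_wins = 1L,
                          negative_wins = -1L)
  keep <- sign_of != 0L
  edges <- data.frame(u = evidence$u[keep], v = evidence$v[keep],
                      sign = sign_of[keep],
                      x_obs = evidence$x_obs[keep], y_obs = evidence$y_obs[keep],
                      n_corecognized = evidence$n_corecognized[keep])
  rownames(edges) <- NULL
  new_signed_network(nodes, edges, contested, evidence = as.data.frame(evidence),
                     delta_plus = as.integer(delta_plus),
                     delta_minus = as.integer(delta_minus), policy = policy)
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d edges (%d positive, %d negative), %d contested pair%s (policy %s)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == 1L),
              sum(x$edges$sign == -1L), nrow(x$contested),
              if (nrow(x$contested) == 1L) "" else "s", x$policy))
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param network a `signed_network`.
#' @param sign `NULL` for the full signed graph (edge attribute `sign`), or
#'   `+1` / `-1` for the single-sign subgraph.
#' @param drop_isolates drop nodes with no incident edge of the requested
#'   sign (the convention for single-sign summary statistics).
#' @return an igraph object.
#' @export
as_igraph_signed <- function(network, sign = NULL, drop_isolates = FALSE) {
  stopifnot(inherits(network, "signed_network"))
  ed <- network$edges
  if (!is.null(sign)) ed <- ed[ed$sign == sign, , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  if (drop_isolates) g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  g
}

#' Summary statistics of a single-sign network
#'
#' Computes the node and edge counts, mean degree, diameter of the largest
#' connected component, mean geodesic distance (within components),
#' transitivity, and mean closeness, eigenvector and betweenness centralities
#' of the undirected simple graph formed by the edges of the requested sign.
#' Nodes with no edge of that sign are not part of the single-sign network.
#'
#' @param network a `signed_network`.
#' @param sign `+1` or `-1`.
#' @return a one-row data frame of statistics, or `NULL` when the sub-network
#'   is empty.
#' @export
network_summary <- function(network, sign) {
  stopifnot(sign %in% c(-1L, 1L))
  g <- as_igraph_signed(network, sign = sign, drop_isolates = TRUE)
  if (igraph::vcount(g) == 0L) return(NULL)
  comps <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comps$membership == which.max(comps$csize)))
  data.frame(
    sign = sign,
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = mean(igraph::degree(g)),
    diameter = igraph::diameter(giant, unconnected = FALSE),
    mean_distance = igraph::mean_distance(g),
    transitivity = igraph::transitivity(g, type = "global"),
    mean_closeness = mean(igraph::closeness(g), na.rm = TRUE),
    mean_eigenvector = mean(eigencentrality_dense(g)),
    mean_betweenness = mean(igraph::betweenness(g))
  )
}

# principal-eigenvector centrality via a dense symmetric eigendecomposition,
# scaled to a maximum of 1; deterministic, unlike iterative ARPACK starts
eigencentrality_dense <- function(g) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ev <- eigen(A, symmetric = TRUE)$vectors[, 1]
  ev <- abs(ev)
  if (max(ev) > 0) ev <- ev / max(ev)
  ev
}

#' Correlation of positive and negative degrees
#'
#' Pearson correlation, over the network's node universe, between each node's
#' number of positive edges and number of negative edges (zero when a node
#' carries no edge of a sign).
#'
#' @param network a `signed_network`.
#' @return correlation coefficient, or `NA` when either degree sequence has
#'   zero variance.
#' @export
signed_degree_correlation <- function(network) {
  stopifnot(inherits(network, "signed_network"))
  if (length(network$nodes) < 2L) stopf("need at least 2 nodes")
  ed <- network$edges
  deg <- function(s) {
    ends <- c(ed$u[ed$sign == s], ed$v[ed$sign == s])
    tab <- table(factor(ends, levels = network$nodes))
    as.numeric(tab)
  }
  dp <- deg(1L); dn <- deg(-1L)
  if (stats::sd(dp) == 0 || stats::sd(dn) == 0) return(NA_real_)
  stats::cor(dp, dn)
}
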