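# Hand-built three-respondent fixture over a five-member roster.
# Respondents p1, p4, p5; recognition degrees 3, 2, 2 (hand count).
# Pair (p2, p3): co-recognized by p1 (same cluster), p4 (same), p5 (split)
#   => n_corecognized = 3, x_obs = 2, y_obs = 1.
# Observer sets: O(p2) = O(p3) = {p1, p4, p5}; O(p1) = {} (close/unknown only).
tiny_tables <- function() {
  list(
    roster = data.frame(member_id = paste0("p", 1:5),
                        label = paste("Person", 1:5)),
    attributes = data.frame(attribute_id = c("A1", "A2"),
                            description = c("helps elders", "shares food")),
    reports = data.frame(
      respondent_id = c(rep("p1", 4), rep("p4", 4), rep("p5", 4)),
      member_id = c("p2", "p3", "p4", "p5",
                    "p1", "p2", "p3", "p5",
                    "p1", "p2", "p3", "p4"),
      bin = c("recognized", "recognized", "recognized", "unknown",
              "close", "recognized", "recognized", "unknown",
              "unknown", "recognized", "recognized", "close"),
      cluster = c(1L, 1L, 2L, NA,
                  NA, 2L, 2L, NA,
                  NA, 1L, 3L, NA)),
    opinions = data.frame(
      respondent_id = c("p1", "p1", "p1", "p4", "p5"),
      member_id = c("p2", "p3", "p2", "p3", "p2"),
      attribute_id = c("A1", "A1", "A2", "A1", "A1"),
      opinion = c(1L, 0L, 1L, 1L, 1L))
  )
}

tiny_report_set <- function(mode = "strict") {
  tt <- tiny_tables()
  report_set(tt$roster, tt$attributes, tt$reports, tt$opinions,
             k = 4, B = 3, mode = mode)
}

write_tiny_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_reports(tiny_report_set(), dir)
  dir
}

# build an arbitrary signed network through the public evidence interface
signed_net_from_edges <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$u, edges$v)))
  ev <- data.frame(u = edges$u, v = edges$v,
                   n_corecognized = 1L,
                   x_obs = as.integer(edges$sign > 0),
                   y_obs = as.integer(edges$sign < 0))
  infer_signed_network(ev, delta_plus = 1L, delta_minus = 1L, nodes = nodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random signed Erdos-Renyi graph for oracle comparisons
random_signed_network <- function(n, p_edge = 0.45, p_neg = 0.5) {
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  ids <- sprintf("v%02d", 1:n)
  edges <- data.frame(u = ids[pairs[, 1]], v = ids[pairs[, 2]],
                      sign = ifelse(stats::runif(nrow(pairs)) < p_neg, -1L, 1L))
  signed_net_from_edges(edges, nodes = ids)
}

# two positive cliques joined by all-negative cross edges: perfectly balanced
balanced_two_clique_network <- function(n1 = 5, n2 = 5) {
  ids <- sprintf("v%02d", 1:(n1 + n2))
  grp <- rep(1:2, c(n1, n2))
  pairs <- t(utils::combn(n1 + n2, 2))
  edges <- data.frame(u = ids[pairs[, 1]], v = ids[pairs[, 2]],
                      sign = ifelse(grp[pairs[, 1]] == grp[pairs[, 2]], 1L, -1L))
  list(network = signed_net_from_edges(edges, nodes = ids),
       truth = stats::setNames(grp, ids))
}

make_zip <- function(zipfile, files, workdir) {
  old <- setwd(workdir); on.exit(setwd(old))
  res <- system2("python", c("-m", "zipfile", "-c", shQuote(zipfile),
                             shQuote(basename(files))), stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(zipfile))
  zipfile
}
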