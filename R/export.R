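#' Export a signed network to standard graph formats
#'
#' Supported formats: `pajek_net` (a `*Vertices`/`*Edges` NET file with edge
#' weights +1/-1), `graphml` (sign and evidence counts carried as edge
#' attributes), and `edge_csv` (`u,v,sign,x_obs,y_obs`). Re-importing with
#' [import_signed_network()] reproduces the node set, edge set and signs
#' exactly.
#'
#' @param network a [signed_network][infer_signed_network()].
#' @param format one of `"pajek_net"`, `"graphml"`, `"edge_csv"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
export_signed_network <- function(network, format = c("pajek_net", "graphml", "edge_csv"),
                                  path) {
  stopifnot(inherits(network, "signed_network"))
  if (length(network$nodes) == 0L) stopf("cannot export an empty network")
  format <- match.arg(format)
  ed <- network$edges
  switch(format,
    pajek_net = {
      idx <- stats::setNames(seq_along(network$nodes), network$nodes)
      lines <- c(
        sprintf("*Vertices %d", length(network$nodes)),
        sprintf('%d "%s"', seq_along(network$nodes), network$nodes),
        "*Edges",
        if (nrow(ed)) sprintf("%d %d %d", idx[ed$u], idx[ed$v], ed$sign)
      )
      writeLines(lines, path)
    },
    graphml = {
      g <- as_igraph_signed(network)
      igraph::write_graph(g, path, format = "graphml")
    },
    edge_csv = {
      utils::write.csv(ed[, c("u", "v", "sign", "x_obs", "y_obs")], path,
                       row.names = FALSE)
    }
  )
  invisible(path)
}

#' Import a signed network written by [export_signed_network()]
#'
#' Evidence counts are restored where the format carries them (`edge_csv`,
#' `graphml`); the Pajek NET format preserves nodes, edges and signs only.
#'
#' @param path file path.
#' @param format one of `"pajek_net"`, `"graphml"`, `"edge_csv"`.
#' @return a [signed_network][infer_signed_network()].
#' @export
import_signed_network <- function(path, format = c("pajek_net", "graphml", "edge_csv")) {
  format <- match.arg(format)
  switch(format,
    pajek_net = {
      lines <- readLines(path)
      nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
      vlines <- lines[2:(1 + nv)]
      nodes <- sub('^\\s*\\d+\\s+"(.*)"\\s*$', "\\1", vlines)
      estart <- grep("^\\*Edges", lines, ignore.case = TRUE)[1]
      elines <- if (estart < length(lines)) lines[(estart + 1):length(lines)] else character()
      elines <- elines[nzchar(trimws(elines))]
      if (length(elines)) {
        parts <- do.call(rbind, lapply(strsplit(trimws(elines), "\\s+"), as.numeric))
        ed <- data.frame(u = nodes[parts[, 1]], v = nodes[parts[, 2]],
                         sign = as.integer(parts[, 3]),
                         x_obs = NA_integer_, y_obs = NA_integer_,
                         n_corecognized = NA_integer_)
      } else {
        ed <- empty_edge_table()
      }
      new_signed_network(nodes, ed)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      nodes <- igraph::V(g)$name
      if (igraph::ecount(g)) {
        endp <- igraph::as_edgelist(g, names = TRUE)
        grab <- function(a) {
          v <- igraph::edge_attr(g, a)
          if (is.null(v)) rep(NA_integer_, nrow(endp)) else as.integer(v)
        }
        ed <- data.frame(u = endp[, 1], v = endp[, 2],
                         sign = as.integer(igraph::E(g)$sign),
                         x_obs = grab("x_obs"), y_obs = grab("y_obs"),
                         n_corecognized = grab("n_corecognized"))
      } else ed <- empty_edge_table()
      new_signed_network(nodes, ed)
    },
    edge_csv = {
      ed <- utils::read.csv(path, colClasses = c(u = "character", v = "character"))
      ed$n_corecognized <- ed$x_obs + ed$y_obs
      new_signed_network(sort(unique(c(ed$u, ed$v))), ed)
    }
  )
}

#' Write / read a Pajek CLU partition file
#'
#' The CLU format lists one class index per node, in the node order of the
#' network it accompanies.
#'
#' @param assignment named integer vector (node -> class) or a
#'   `balance_trial` from [optimize_partition()] (its first optimal partition
#'   is written).
#' @param path file path.
#' @return `write_pajek_clu`: invisibly, `path`. `read_pajek_clu`: an integer
#'   vector of class indices.
#' @export
write_pajek_clu <- function(assignment, path) {
  if (inherits(assignment, "balance_trial")) assignment <- assignment$partitions[[1]]
  writeLines(c(sprintf("*Vertices %d", length(assignment)),
               as.character(as.integer(assignment))), path)
  invisible(path)
}

#' @rdname write_pajek_clu
#' @export
read_pajek_clu <- function(path) {
  lines <- readLines(path)
  as.integer(lines[-1][nzchar(trimws(lines[-1]))])
}
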