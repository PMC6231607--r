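#' Pipeline run configuration
#'
#' @param reports a [report_set()], or `NULL` when `paths` point at canonical
#'   CSVs.
#' @param paths named list of input files (`roster`, `attributes`, `reports`,
#'   `opinions`), used when `reports` is `NULL`.
#' @param k,B nominal study parameters (inferred from the data when `NULL`).
#' @param sig_level significance level for ties and attributes.
#' @param policy contested-pair policy, see [infer_signed_network()].
#' @param K class count for the clustering stage; when `NULL`, a sweep over
#'   `K_range` is run and the recommendation of [select_model()] used.
#' @param K_range sweep range (default `3:9`).
#' @param min_size,alpha_w,trials,repetitions balance-clustering parameters.
#' @param reference_class baseline class for the association stage (`NULL`
#'   for the largest class).
#' @param seed base seed for every stochastic stage.
#' @param out_dir output directory.
#' @param stages subset of
#'   `c("calibrate", "edges", "attributes", "cluster", "associate")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(reports = NULL, paths = NULL, k = NULL, B = NULL,
                       sig_level = 0.95, policy = "contested_null",
                       K = NULL, K_range = 3:9, min_size = 3L, alpha_w = 0.5,
                       trials = 10L, repetitions = 100L,
                       reference_class = NULL, seed = 1L, out_dir,
                       stages = c("calibrate", "edges", "attributes",
                                  "cluster", "associate")) {
  if (is.null(reports) && is.null(paths))
    stopf("supply either a report_set or input file paths")
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(reports = reports, paths = paths, k = k, B = B,
                 sig_level = sig_level, policy = policy, K = K,
                 K_range = K_range, min_size = min_size, alpha_w = alpha_w,
                 trials = trials, repetitions = repetitions,
                 reference_class = reference_class, seed = as.integer(seed),
                 out_dir = out_dir, stages = stages),
            class = "run_config")
}

#' Run the full perceptual-tomography pipeline
#'
#' Executes, in order: calibration of the null model from the data (gamma,
#' beta, the pairwise count distributions and significance thresholds), signed
#' tie inference, attribute ascription, balance clustering (a single `K` or a
#' sweep plus model selection), and class-attribute association. Every stage
#' writes its artifacts under `config$out_dir`, and a `manifest.json` records
#' the parameters, seed, package version and MD5 checksum of every output, so
#' any number can be reproduced from the manifest alone. A stage failure
#' aborts with the stage name; artifacts of completed stages are retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  res <- list()

  rs <- stage("input", {
    config$reports %||% read_reports(config$paths$roster, config$paths$attributes,
                                     config$paths$reports, config$paths$opinions,
                                     k = config$k, B = config$B)
  })

  if ("calibrate" %in% config$stages) {
    res$calibration <- stage("calibrate", {
      gamma <- estimate_gamma(rs)
      beta <- if (nrow(rs$opinions)) estimate_beta(rs) else numeric()
      params <- null_params(rs$params$n, rs$params$m, rs$params$k, rs$params$B,
                            gamma, beta, config$sig_level)
      dist <- pair_count_distributions(params)
      emit(data.frame(count = 0:params$m, x_pmf = dist$x_pmf, y_pmf = dist$y_pmf),
           "null_pmfs.csv")
      emit(data.frame(
        quantity = c("n", "m", "k", "B", "gamma", "p", "q", "delta_plus",
                     "delta_minus", "sig_level",
                     if (length(beta)) paste0("beta_", names(beta))),
        value = c(params$n, params$m, params$k, params$B, gamma, dist$p, dist$q,
                  dist$delta_plus, dist$delta_minus, config$sig_level, unname(beta))),
        "calibration.csv")
      list(params = params, dist = dist)
    })
  }

  if ("edges" %in% config$stages) {
    res$network <- stage("edges", {
      dist <- res$calibration$dist
      if (is.null(dist)) stopf("edges stage requires the calibrate stage")
      ev <- tally_pair_evidence(rs)
      net <- infer_signed_network(ev, dist$delta_plus, dist$delta_minus,
                                  policy = config$policy)
      emit(net$edges, "edges.csv")
      p <- file.path(config$out_dir, "network.net")
      export_signed_network(net, "pajek_net", p); outputs <<- c(outputs, p)
      p <- file.path(config$out_dir, "network.graphml")
      export_signed_network(net, "graphml", p); outputs <<- c(outputs, p)
      summ <- rbind(network_summary(net, 1L), network_summary(net, -1L))
      if (!is.null(summ)) emit(summ, "network_summary.csv")
      net
    })
  }

  if ("attributes" %in% config$stages) {
    res$attributes <- stage("attributes", {
      if (!nrow(rs$opinions)) stopf("no opinion data available")
      est <- ascribe_all(rs, level = config$sig_level)
      qt <- data.frame(member_id = rownames(est$q_tilde), est$q_tilde,
                       check.names = FALSE)
      emit(qt, "attributes.csv")
      emit(est$summary, "attribute_summary.csv")
      est
    })
  }

  if ("cluster" %in% config$stages) {
    res$clustering <- stage("cluster", {
      net <- res$network
      if (is.null(net)) stopf("cluster stage requires the edges stage")
      if (is.null(config$K)) {
        sw <- sweep_classes(net, K_range = config$K_range, trials = config$trials,
                            repetitions = config$repetitions,
                            min_size = config$min_size, alpha_w = config$alpha_w,
                            base_seed = config$seed)
        emit(sw$results, "sweep.csv")
        emit(sw$summary, "sweep_summary.csv")
        K <- select_model(sw)$K
      } else K <- config$K
      trial <- optimize_partition(net, K = K, min_size = config$min_size,
                                  repetitions = config$repetitions,
                                  alpha_w = config$alpha_w, seed = config$seed)
      p <- file.path(config$out_dir, "partition.clu")
      write_pajek_clu(trial, p); outputs <<- c(outputs, p)
      emit(data.frame(node = names(trial$partitions[[1]]),
                      class = unname(trial$partitions[[1]])), "partition.csv")
      trial
    })
  }

  if ("associate" %in% config$stages) {
    res$association <- stage("associate", {
      if (is.null(res$clustering)) stopf("associate stage requires the cluster stage")
      if (is.null(res$attributes)) stopf("associate stage requires the attributes stage")
      rows <- list()
      for (a in colnames(res$attributes$q_tilde)) {
        design <- build_design(res$clustering, res$attributes, a,
                               reference_class = config$reference_class)
        if (attr(design, "degenerate") || nlevels(droplevels(design$outcome)) < 2L) {
          rows[[a]] <- data.frame(attribute_id = a, outcome = NA, term = NA,
                                  estimate = NA, std_error = NA, aic = NA,
                                  converged = NA, separation = NA,
                                  note = "degenerate")
          next
        }
        fitted <- fit_multinomial(design)
        cf <- fitted$coefficients
        rows[[a]] <- data.frame(
          attribute_id = a,
          outcome = rep(rownames(cf), times = ncol(cf)),
          term = rep(colnames(cf), each = nrow(cf)),
          estimate = as.vector(cf),
          std_error = as.vector(fitted$std_errors),
          aic = fitted$aic, converged = fitted$converged,
          separation = fitted$separation, note = "")
      }
      tab <- do.call(rbind, rows)
      emit(tab, "associations.csv")
      tab
    })
  }

  manifest <- list(
    package = "tomonet",
    version = as.character(utils::packageVersion("tomonet")),
    seed = config$seed,
    parameters = config[c("k", "B", "sig_level", "policy", "K", "K_range",
                          "min_size", "alpha_w", "trials", "repetitions")],
    stages = config$stages,
    checksums = as.list(tools::md5sum(sort(unique(outputs))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}
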