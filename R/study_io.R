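#' Bin labels used in canonical report files
#'
#' Respondents sort each shown photo into one of three bins: people they are
#' close to, people they recognize but are not close to, and people they do
#' not recognize. Only the "recognized" bin feeds the sociometric analysis.
#'
#' @export
BIN_LEVELS <- c("close", "recognized", "unknown")

#' Assemble and validate a set of respondent reports
#'
#' A report set bundles the population roster, the attribute catalog, one row
#' per (respondent, shown member) with the bin assignment and (for recognized
#' members) a cluster index in `1..B`, and one row per recorded binary opinion.
#' All downstream inference (tie tallies, null-model calibration, attribute
#' ascription) starts from this container.
#'
#' Validation is total: every malformed row produces one diagnostic naming the
#' table and row, and all diagnostics are reported together. A respondent's
#' own photo, if present among the shown rows, is silently dropped (a
#' respondent never bins themself).
#'
#' @param roster character vector of member identifiers, or a data frame with
#'   columns `member_id` and optionally `label`.
#' @param attributes character vector of attribute identifiers, or a data
#'   frame with columns `attribute_id` and optionally `description`. May be
#'   `NULL` when no opinions are supplied.
#' @param reports data frame with columns `respondent_id`, `member_id`,
#'   `bin` (one of [BIN_LEVELS]) and `cluster` (integer or `NA`).
#' @param opinions data frame with columns `respondent_id`, `member_id`,
#'   `attribute_id`, `opinion` (0/1), or `NULL` for no opinion data.
#' @param k nominal number of photos shown per respondent. Inferred as the
#'   maximum shown count when `NULL`.
#' @param B number of clusters available in the sorting task. Inferred as the
#'   maximum observed cluster index when `NULL`.
#' @param mode `"strict"` requires every recognized member to carry a cluster
#'   and a constant shown count of `k` (or `k - 1`, covering a respondent
#'   whose own photo was drawn); `"lenient"` tolerates varying shown counts
#'   and unclustered recognized members (which are excluded from pair tallies
#'   but still count as recognition).
#' @return An object of class `report_set` with elements `roster`,
#'   `attributes`, `reports`, `opinions` and `params` (`n`, `m`, `k`, `B`,
#'   `M`, `mode`).
#' @export
report_set <- function(roster, attributes = NULL, reports, opinions = NULL,
                       k = NULL, B = NULL, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  roster <- as_roster(roster)
  attributes <- as_attribute_catalog(attributes)
  reports <- normalize_reports(reports)
  opinions <- normalize_opinions(opinions)

  # a respondent never bins their own photo; drop such rows silently
  self_rows <- reports$respondent_id == reports$member_id
  n_self <- sum(self_rows)
  reports <- reports[!self_rows, , drop = FALSE]
  rownames(reports) <- NULL

  if (is.null(B)) {
    B <- if (any(!is.na(reports$cluster))) max(reports$cluster, na.rm = TRUE) else 2L
  }
  B <- as.integer(B)
  shown_counts <- if (nrow(reports)) table(reports$respondent_id) else integer()
  if (is.null(k)) {
    k <- if (length(shown_counts)) max(shown_counts) else 0L
  }
  k <- as.integer(k)

  diags <- validate_report_tables(roster, attributes, reports, opinions,
                                  k = k, B = B, mode = mode)
  if (nrow(diags)) {
    shown <- utils::head(diags, 20L)
    stopf("invalid report data (%d problem%s):\n%s%s",
          nrow(diags), if (nrow(diags) > 1L) "s" else "",
          paste(sprintf("  %s row %s: %s", shown$table, shown$row, shown$message),
                collapse = "\n"),
          if (nrow(diags) > 20L) sprintf("\n  ... and %d more", nrow(diags) - 20L) else "")
  }

  structure(
    list(
      roster = roster,
      attributes = attributes,
      reports = reports,
      opinions = opinions,
      params = list(
        n = nrow(roster),
        m = length(unique(reports$respondent_id)),
        k = k,
        B = B,
        M = nrow(attributes),
        mode = mode,
        self_rows_dropped = n_self
      )
    ),
    class = "report_set"
  )
}

as_roster <- function(roster) {
  if (is.character(roster)) roster <- data.frame(member_id = roster, label = roster)
  roster <- as.data.frame(roster)
  if (!"member_id" %in% names(roster)) stopf("roster needs a 'member_id' column")
  if (!"label" %in% names(roster)) roster$label <- roster$member_id
  roster$member_id <- as.character(roster$member_id)
  roster$label <- as.character(roster$label)
  if (anyDuplicated(roster$member_id))
    stopf("roster member identifiers must be unique (duplicate: %s)",
          roster$member_id[duplicated(roster$member_id)][1])
  if (nrow(roster) < 2L) stopf("roster must contain at least 2 members")
  roster[, c("member_id", "label")]
}

as_attribute_catalog <- function(attributes) {
  if (is.null(attributes))
    return(data.frame(attribute_id = character(), description = character()))
  if (is.character(attributes))
    attributes <- data.frame(attribute_id = attributes, description = attributes)
  attributes <- as.data.frame(attributes)
  if (!"attribute_id" %in% names(attributes))
    stopf("attribute catalog needs an 'attribute_id' column")
  if (!"description" %in% names(attributes))
    attributes$description <- attributes$attribute_id
  attributes$attribute_id <- as.character(attributes$attribute_id)
  attributes$description <- as.character(attributes$description)
  if (anyDuplicated(attributes$attribute_id))
    stopf("attribute identifiers must be unique")
  attributes[, c("attribute_id", "description")]
}

normalize_reports <- function(reports) {
  reports <- as.data.frame(reports)
  need <- c("respondent_id", "member_id", "bin")
  miss <- setdiff(need, names(reports))
  if (length(miss)) stopf("reports table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"cluster" %in% names(reports)) reports$cluster <- NA_integer_
  reports$respondent_id <- as.character(reports$respondent_id)
  reports$member_id <- as.character(reports$member_id)
  reports$bin <- tolower(as.character(reports$bin))
  cl <- reports$cluster
  cl[!is.na(cl) & cl == ""] <- NA
  reports$cluster <- suppressWarnings(as.integer(cl))
  reports[, c("respondent_id", "member_id", "bin", "cluster")]
}

normalize_opinions <- function(opinions) {
  if (is.null(opinions))
    return(data.frame(respondent_id = character(), member_id = character(),
                      attribute_id = character(), opinion = integer()))
  opinions <- as.data.frame(opinions)
  need <- c("respondent_id", "member_id", "attribute_id", "opinion")
  miss <- setdiff(need, names(opinions))
  if (length(miss)) stopf("opinions table lacks column(s): %s", paste(miss, collapse = ", "))
  opinions$respondent_id <- as.character(opinions$respondent_id)
  opinions$member_id <- as.character(opinions$member_id)
  opinions$attribute_id <- as.character(opinions$attribute_id)
  opinions$opinion <- suppressWarnings(as.integer(opinions$opinion))
  opinions[, need]
}

validate_report_tables <- function(roster, attributes, reports, opinions, k, B, mode) {
  diags <- list()
  add <- function(table, rows, message) {
    if (length(rows))
      diags[[length(diags) + 1L]] <<- data.frame(table = table, row = rows,
                                                 message = message)
  }
  ids <- roster$member_id

  add("reports", which(!reports$respondent_id %in% ids), "unknown respondent id")
  add("reports", which(!reports$member_id %in% ids), "unknown member id")
  add("reports", which(!reports$bin %in% BIN_LEVELS),
      sprintf("bin must be one of %s", paste(BIN_LEVELS, collapse = "/")))
  dup <- duplicated(reports[, c("respondent_id", "member_id")])
  add("reports", which(dup), "duplicate (respondent, member) row")

  rec <- reports$bin == "recognized"
  bad_cluster <- !is.na(reports$cluster) & (reports$cluster < 1L | reports$cluster > B)
  add("reports", which(bad_cluster), sprintf("cluster outside 1..%d", B))
  add("reports", which(!rec & !is.na(reports$cluster)),
      "cluster given for a member not in the recognized bin")
  if (mode == "strict")
    add("reports", which(rec & is.na(reports$cluster)),
        "recognized member lacks a cluster (strict mode)")

  if (mode == "strict" && nrow(reports)) {
    counts <- table(reports$respondent_id)
    bad <- names(counts)[counts != k & counts != k - 1L]
    if (length(bad))
      add("reports", match(bad, reports$respondent_id),
          sprintf("respondent shown-count differs from nominal k = %d", k))
  }

  if (nrow(opinions)) {
    add("opinions", which(!opinions$respondent_id %in% ids), "unknown respondent id")
    add("opinions", which(!opinions$member_id %in% ids), "unknown member id")
    if (nrow(attributes))
      add("opinions", which(!opinions$attribute_id %in% attributes$attribute_id),
          "unknown attribute id")
    else
      add("opinions", seq_len(nrow(opinions)), "opinions supplied without an attribute catalog")
    add("opinions", which(!opinions$opinion %in% c(0L, 1L)), "opinion must be 0 or 1")
    dup <- duplicated(opinions[, c("respondent_id", "member_id", "attribute_id")])
    add("opinions", which(dup), "duplicate (respondent, member, attribute) row")
    rec_key <- paste(reports$respondent_id[rec], reports$member_id[rec])
    op_key <- paste(opinions$respondent_id, opinions$member_id)
    add("opinions", which(!op_key %in% rec_key),
        "opinion recorded for a member the respondent did not place in the recognized bin")
  }

  if (length(diags)) do.call(rbind, diags)
  else data.frame(table = character(), row = integer(), message = character())
}

#' Recognition degree of each respondent
#'
#' The recognition degree `d(s_i)` is the number of shown photos the
#' respondent placed in the "recognized but not close" bin.
#'
#' @param rs a [report_set()].
#' @return named integer vector over respondents.
#' @export
recognition_degree <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  resp <- unique(rs$reports$respondent_id)
  rec <- rs$reports[rs$reports$bin == "recognized", ]
  d <- table(factor(rec$respondent_id, levels = resp))
  stats::setNames(as.integer(d), resp)
}

#' @export
print.report_set <- function(x, ...) {
  p <- x$params
  cat(sprintf("<report_set> n = %d members, m = %d respondents, k = %d shown, B = %d clusters, M = %d attributes (%s mode)\n",
              p$n, p$m, p$k, p$B, p$M, p$mode))
  cat(sprintf("  %d report rows, %d opinion rows\n", nrow(x$reports), nrow(x$opinions)))
  invisible(x)
}

#' Read respondent reports from canonical CSV files
#'
#' The canonical files are: `roster.csv` (`member_id,label`), `attributes.csv`
#' (`attribute_id,description`), `reports.csv`
#' (`respondent_id,member_id,bin,cluster`) with `bin` in
#' `close`/`recognized`/`unknown` and `cluster` an integer in `1..B` or empty,
#' and `opinions.csv` (`respondent_id,member_id,attribute_id,opinion`) with
#' `opinion` in 0/1.
#'
#' @param roster_file,attributes_file,reports_file,opinions_file paths to the
#'   canonical CSVs. `attributes_file`/`opinions_file` may be `NULL`.
#' @inheritParams report_set
#' @return a validated [report_set()].
#' @export
read_reports <- function(roster_file, attributes_file = NULL, reports_file,
                         opinions_file = NULL, k = NULL, B = NULL,
                         mode = c("strict", "lenient")) {
  read1 <- function(path) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) stopf("file not found: %s", path)
    utils::read.csv(path, colClasses = "character")
  }
  report_set(
    roster = read1(roster_file),
    attributes = read1(attributes_file),
    reports = read1(reports_file) %||%
      data.frame(respondent_id = character(), member_id = character(),
                 bin = character(), cluster = character()),
    opinions = read1(opinions_file),
    k = k, B = B, mode = match.arg(mode)
  )
}

#' Write a report set to canonical CSV files
#'
#' Inverse of [read_reports()]; the round trip is lossless.
#'
#' @param rs a [report_set()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(rs, dir) {
  stopifnot(inherits(rs, "report_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("roster.csv", "attributes.csv", "reports.csv", "opinions.csv"))
  utils::write.csv(rs$roster, paths[1], row.names = FALSE)
  utils::write.csv(rs$attributes, paths[2], row.names = FALSE)
  rep_out <- rs$reports
  rep_out$cluster <- ifelse(is.na(rep_out$cluster), "", as.character(rep_out$cluster))
  utils::write.csv(rep_out, paths[3], row.names = FALSE)
  utils::write.csv(rs$opinions, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Read respondent reports from a deposited study archive
#'
#' Ingests a zip archive of study tables via a user-supplied mapping
#' configuration (YAML) that names, for each canonical table, the source file
#' inside the archive and the source column for each canonical field:
#'
#' ```yaml
#' roster:     {file: roster.csv, member_id: id, label: name}
#' attributes: {file: attributes.csv, attribute_id: attr, description: text}
#' reports:    {file: binning.csv, respondent_id: subj, member_id: photo,
#'              bin: bin, cluster: grp}
#' opinions:   {file: opinions.csv, respondent_id: subj, member_id: photo,
#'              attribute_id: attr, opinion: vote}
#' bin_values: {close: C1, recognized: C2, unknown: C3}   # optional recode
#' params:     {k: 40, B: 5}                              # optional
#' ```
#'
#' The `opinions` (and `attributes`) entries are optional; when omitted the
#' report set is loaded with an empty opinion table and a warning.
#'
#' @param zip_path path to the archive.
#' @param mapping_config path to the YAML mapping file.
#' @param mode validation mode, see [report_set()].
#' @return a validated [report_set()], identical to what [read_reports()]
#'   would produce from the equivalent canonical files.
#' @export
read_supplementary_archive <- function(zip_path, mapping_config,
                                       mode = c("strict", "lenient")) {
  if (!file.exists(zip_path)) stopf("unreadable archive: %s", zip_path)
  map <- yaml::read_yaml(mapping_config)
  exdir <- tempfile("tomonet_zip_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(zip_path, exdir = exdir)

  pull <- function(entry, fields, required) {
    entry_map <- map[[entry]]
    if (is.null(entry_map)) {
      if (required) stopf("mapping config lacks required entry '%s'", entry)
      return(NULL)
    }
    if (is.null(entry_map$file)) stopf("mapping entry '%s' lacks a 'file' key", entry)
    path <- file.path(exdir, entry_map$file)
    if (!file.exists(path)) {
      # archives may nest files in a single top-level directory
      hit <- list.files(exdir, pattern = paste0("^", entry_map$file, "$"),
                        recursive = TRUE, full.names = TRUE)
      if (length(hit) != 1L) stopf("archive member not found: %s", entry_map$file)
      path <- hit
    }
    raw <- utils::read.csv(path, colClasses = "character")
    out <- list()
    for (f in names(fields)) {
      src <- entry_map[[f]] %||% f
      if (!src %in% names(raw)) {
        if (fields[[f]]) stopf("mapping entry '%s': required field '%s' (source column '%s') absent",
                               entry, f, src)
        next
      }
      out[[f]] <- raw[[src]]
    }
    as.data.frame(out)
  }

  roster <- pull("roster", list(member_id = TRUE, label = FALSE), required = TRUE)
  attributes <- pull("attributes", list(attribute_id = TRUE, description = FALSE),
                     required = FALSE)
  reports <- pull("reports", list(respondent_id = TRUE, member_id = TRUE,
                                  bin = TRUE, cluster = FALSE), required = TRUE)
  opinions <- pull("opinions", list(respondent_id = TRUE, member_id = TRUE,
                                    attribute_id = TRUE, opinion = TRUE),
                   required = FALSE)
  if (is.null(opinions))
    warnf("mapping config declares no opinion table; loading with empty opinions")

  if (!is.null(map$bin_values)) {
    lut <- stats::setNames(names(map$bin_values), unlist(map$bin_values))
    reports$bin <- unname(lut[as.character(reports$bin)])
  }
  report_set(roster = roster, attributes = attributes, reports = reports,
             opinions = opinions,
             k = map$params$k, B = map$params$B, mode = match.arg(mode))
}
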