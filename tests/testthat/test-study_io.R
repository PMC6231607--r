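test_that("the canonical fixture loads with hand-counted recognition degrees", {
  dir <- write_tiny_fixture()
  rs <- read_reports(file.path(dir, "roster.csv"), file.path(dir, "attributes.csv"),
                     file.path(dir, "reports.csv"), file.path(dir, "opinions.csv"),
                     k = 4, B = 3)
  expect_s3_class(rs, "report_set")
  expect_equal(rs$params$m, 3L)
  expect_equal(rs$params$n, 5L)
  d <- recognition_degree(rs)
  expect_equal(d, c(p1 = 3L, p4 = 2L, p5 = 2L))
  # the three bins partition the shown set for every respondent
  counts <- table(rs$reports$respondent_id)
  expect_true(all(counts == 4L))
})

test_that("an empty reports file loads as m = 0 but is rejected downstream", {
  dir <- withr::local_tempdir()
  tt <- tiny_tables()
  write.csv(tt$roster, file.path(dir, "roster.csv"), row.names = FALSE)
  write.csv(tt$reports[0, ], file.path(dir, "reports.csv"), row.names = FALSE)
  rs <- read_reports(file.path(dir, "roster.csv"), NULL,
                     file.path(dir, "reports.csv"), NULL, k = 4, B = 3)
  expect_equal(rs$params$m, 0L)
  expect_error(estimate_gamma(rs), "undefined")
})

test_that("schema violations are reported with table and row", {
  tt <- tiny_tables()
  bad <- tt$reports
  bad$cluster[2] <- 6L   # B = 3
  expect_error(report_set(tt$roster, tt$attributes, bad, tt$opinions, k = 4, B = 3),
               "reports row 2: cluster outside 1..3", fixed = TRUE)

  bad <- rbind(tt$reports, tt$reports[1, ])
  expect_error(report_set(tt$roster, tt$attributes, bad, NULL, k = 4, B = 3),
               "duplicate \\(respondent, member\\) row")

  bad <- tt$reports
  bad$member_id[3] <- "p99"
  expect_error(report_set(tt$roster, tt$attributes, bad, NULL, k = 4, B = 3),
               "unknown member id")

  bad_op <- tt$opinions
  bad_op$member_id[1] <- "p5"  # p1 marked p5 unknown, not recognized
  expect_error(report_set(tt$roster, tt$attributes, tt$reports, bad_op, k = 4, B = 3),
               "did not place in the recognized bin")
})

test_that("a respondent's own photo is silently excluded", {
  tt <- tiny_tables()
  with_self <- rbind(tt$reports,
                     data.frame(respondent_id = "p1", member_id = "p1",
                                bin = "recognized", cluster = 1L))
  rs <- report_set(tt$roster, tt$attributes, with_self, tt$opinions, k = 5, B = 3)
  expect_equal(unname(recognition_degree(rs)["p1"]), 3L)
  expect_false(any(rs$reports$respondent_id == rs$reports$member_id))
})

test_that("strict mode demands clusters for recognized members; lenient does not", {
  tt <- tiny_tables()
  tt$reports$cluster[1] <- NA
  expect_error(report_set(tt$roster, tt$attributes, tt$reports, NULL, k = 4, B = 3),
               "lacks a cluster")
  rs <- report_set(tt$roster, tt$attributes, tt$reports, NULL, k = 4, B = 3,
                   mode = "lenient")
  # still counts as recognition, but is dropped from pair tallies
  expect_equal(unname(recognition_degree(rs)["p1"]), 3L)
  ev <- tally_pair_evidence(rs)
  expect_equal(ev[ev$u == "p2" & ev$v == "p3", ]$n_corecognized, 2L)
})

test_that("write/read round trip over canonical files is lossless", {
  rs <- tiny_report_set()
  dir <- withr::local_tempdir()
  write_reports(rs, dir)
  back <- read_reports(file.path(dir, "roster.csv"), file.path(dir, "attributes.csv"),
                       file.path(dir, "reports.csv"), file.path(dir, "opinions.csv"),
                       k = 4, B = 3)
  expect_equal(back$roster, rs$roster)
  expect_equal(back$reports, rs$reports)
  expect_equal(back$opinions, rs$opinions)
  expect_equal(back$params[c("n", "m", "k", "B", "M")],
               rs$params[c("n", "m", "k", "B", "M")])
})

test_that("archive ingestion reproduces read_reports under identity and renamed mappings", {
  dir <- write_tiny_fixture()
  rs <- tiny_report_set()

  zipfile <- file.path(withr::local_tempdir(), "study.zip")
  make_zip(zipfile, list.files(dir, full.names = TRUE), workdir = dir)

  cfg <- file.path(tempdir(), "map_identity.yaml")
  writeLines(c(
    "roster: {file: roster.csv}",
    "attributes: {file: attributes.csv}",
    "reports: {file: reports.csv}",
    "opinions: {file: opinions.csv}",
    "params: {k: 4, B: 3}"), cfg)
  back <- read_supplementary_archive(zipfile, cfg)
  expect_equal(back$reports, rs$reports)
  expect_equal(back$opinions, rs$opinions)

  # renamed columns + matching mapping give the same report set
  dir2 <- withr::local_tempdir()
  tt <- tiny_tables()
  names(tt$roster) <- c("id", "name")
  names(tt$reports) <- c("subj", "photo", "sorting", "grp")
  tt$reports$sorting <- c(close = "C1", recognized = "C2",
                          unknown = "C3")[tt$reports$sorting]
  names(tt$opinions) <- c("subj", "photo", "attr", "vote")
  for (nm in c("roster", "attributes", "reports", "opinions"))
    write.csv(tt[[nm]], file.path(dir2, paste0(nm, ".csv")), row.names = FALSE)
  zipfile2 <- file.path(withr::local_tempdir(), "study2.zip")
  make_zip(zipfile2, list.files(dir2, full.names = TRUE), workdir = dir2)
  cfg2 <- file.path(tempdir(), "map_renamed.yaml")
  writeLines(c(
    "roster: {file: roster.csv, member_id: id, label: name}",
    "attributes: {file: attributes.csv}",
    "reports: {file: reports.csv, respondent_id: subj, member_id: photo, bin: sorting, cluster: grp}",
    "opinions: {file: opinions.csv, respondent_id: subj, member_id: photo, attribute_id: attr, opinion: vote}",
    "bin_values: {close: C1, recognized: C2, unknown: C3}",
    "params: {k: 4, B: 3}"), cfg2)
  back2 <- read_supplementary_archive(zipfile2, cfg2)
  expect_equal(back2$reports, rs$reports)
  expect_equal(back2$opinions, rs$opinions)

  # omitting the opinion table loads with a warning and empty opinions
  cfg3 <- file.path(tempdir(), "map_noop.yaml")
  writeLines(c(
    "roster: {file: roster.csv}",
    "reports: {file: reports.csv}",
    "params: {k: 4, B: 3}"), cfg3)
  expect_warning(back3 <- read_supplementary_archive(zipfile, cfg3),
                 "no opinion table")
  expect_equal(nrow(back3$opinions), 0L)
})

test_that("signed-network exports round trip in every format", {
  net <- signed_net_from_edges(data.frame(u = c("a", "b"), v = c("b", "c"),
                                          sign = c(1L, -1L)),
                               nodes = c("a", "b", "c", "lonely"))
  dir <- withr::local_tempdir()

  p <- file.path(dir, "net.net")
  export_signed_network(net, "pajek_net", p)
  lines <- readLines(p)
  expect_true(any(grepl("^\\*Vertices 4", lines)))
  expect_true(any(grepl('"lonely"', lines)))          # isolate kept as vertex
  expect_equal(sum(grepl("^\\d+ \\d+ -?1$", lines)), 2L)
  back <- import_signed_network(p, "pajek_net")
  expect_setequal(back$nodes, net$nodes)
  expect_equal(back$edges[, c("u", "v", "sign")], net$edges[, c("u", "v", "sign")])

  # 50-node random network round trips through every format
  set.seed(11)
  big <- random_signed_network(50, p_edge = 0.1)
  for (fmt in c("pajek_net", "graphml", "edge_csv")) {
    p <- file.path(dir, paste0("big.", fmt))
    export_signed_network(big, fmt, p)
    back <- import_signed_network(p, fmt)
    key <- function(e) sort(paste(e$u, e$v, e$sign))
    expect_equal(key(back$edges), key(big$edges), info = fmt)
  }

  # partition CLU round trip
  clu <- file.path(dir, "part.clu")
  write_pajek_clu(stats::setNames(c(1L, 2L, 1L, 2L), net$nodes), clu)
  expect_equal(read_pajek_clu(clu), c(1L, 2L, 1L, 2L))
})
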