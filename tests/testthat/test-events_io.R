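test_that("rMATS SE tables parse with coordinates and replicate lists intact", {
  ev <- read_events(toy_table(), "SE")
  expect_s3_class(ev, "splicing_events")
  expect_equal(nrow(ev), 8)
  expect_equal(ev$event_id[1], "E1")
  # rMATS exonStart_0base / exonEnd map straight onto 0-based half-open
  expect_equal(ev$exon_start[1], 1000)
  expect_equal(ev$exon_end[1], 1100)
  expect_equal(ev$upstream_exon_end[1], 700)
  expect_equal(ev$downstream_exon_start[1], 1400)
  expect_equal(ev$inc_g1[[1]], c(6L, 5L))
  expect_equal(ev$skip_g2[[1]], c(3L, 3L))
  expect_equal(ev$psi_g1[[5]], c(0.55, 0.60))
  expect_equal(ev$delta_psi[5], -0.25)
})

test_that("delta-PSI consistency with replicate means is checked on read", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hdr <- readLines(toy_table())[1]
  row <- paste("X1", "G", "c", "+", 100, 200, 50, 300, "12,10", "3,5",
               "8,8", "8,8", "0.8,0.9", "0.5,0.5", 0.01, 0.02, 0.35,
               sep = "\t")
  writeLines(c(hdr, row), tmp)
  # mean(0.8, 0.9) - mean(0.5, 0.5) = 0.35: consistent, no warning
  expect_silent(ev <- read_events(tmp, "SE"))
  expect_equal(ev$delta_psi, 0.35)
  row_bad <- sub("0.35$", "0.2", row)
  writeLines(c(hdr, row_bad), tmp)
  expect_warning(read_events(tmp, "SE"), "differs from mean-PSI difference")
})

test_that("malformed tables fail with the offending row and column named", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  hdr <- readLines(toy_table())[1]
  row <- paste("X1", "G", "c", "+", 100, 200, 50, 300, "12,xx", "3,5",
               "8,8", "8,8", "0.8,0.9", "0.5,0.5", 0.01, 0.02, 0.35,
               sep = "\t")
  writeLines(c(hdr, row), tmp)
  expect_error(read_events(tmp, "SE"), "IJC_SAMPLE_1.*row 1")
  writeLines(c("ID\tGeneID", "a\tb"), tmp)
  expect_error(read_events(tmp, "SE"), "missing required columns")
  expect_error(read_events(toy_table(), "XE"), "unknown event_type")
})

test_that("total read support sums all counts of both groups", {
  ev <- make_events(n = 3,
                    inc_g1 = list(c(12L, 10L), c(0L, 0L), 5L),
                    skip_g1 = list(c(3L, 5L), c(0L, 0L), 2L),
                    inc_g2 = list(c(0L, 0L), c(0L, 0L), 4L),
                    skip_g2 = list(c(0L, 0L), c(0L, 0L), 4L))
  expect_identical(total_unique_reads(ev), c(30L, 0L, 15L))
})

test_that("significance filter applies the three thresholds with the stated strictness", {
  # at the boundaries: reads >= 15 (inclusive), |dPSI| > 0.10 and FDR < 0.05 (strict)
  keep <- make_events(inc_g1 = list(c(4L, 4L)), skip_g1 = list(c(2L, 2L)),
                      inc_g2 = list(c(2L, 1L)), skip_g2 = list(c(1L, 1L)),
                      delta_psi = 0.101, fdr = 0.049)
  expect_equal(nrow(filter_significant(keep)), 1)
  expect_equal(nrow(filter_significant(
    make_events(delta_psi = 0.10, fdr = 0.01))), 0)
  expect_equal(nrow(filter_significant(
    make_events(delta_psi = 0.2, fdr = 0.05))), 0)

  ev <- read_events(toy_table(), "SE")
  sig <- filter_significant(ev)
  expect_identical(sig$event_id, c("E1", "E5", "E8"))
  # idempotence
  expect_identical(filter_significant(sig)$event_id, sig$event_id)
})

test_that("background selection keeps unaffected, detectably spliced exons", {
  ev <- read_events(toy_table(), "SE")
  bg <- select_background(ev)
  expect_identical(bg$event_id, "E6")
  # individual rules
  expect_equal(nrow(select_background(make_events(
    fdr = 0.9, psi_g1 = list(c(0.4, 0.4)), psi_g2 = list(c(0.5, 0.5))))), 1)
  expect_equal(nrow(select_background(make_events(
    fdr = 0.9, psi_g1 = list(c(0.05, 0.05)), psi_g2 = list(c(0.05, 0.05))))), 0)
  expect_equal(nrow(select_background(make_events(
    fdr = 0.4, psi_g1 = list(c(0.4, 0.4)), psi_g2 = list(c(0.5, 0.5))))), 0)
  # events without PSI are skipped with a warning, not imputed
  nopsi <- make_events(fdr = 0.9, psi_g1 = list(c(NA_real_, NA_real_)),
                       psi_g2 = list(c(NA_real_, NA_real_)))
  expect_warning(out <- select_background(nopsi), "without PSI")
  expect_equal(nrow(out), 0)
})

test_that("significant and background sets are disjoint when FDR cuts do not overlap", {
  set.seed(71)
  n <- 60
  ev <- make_events(n = n,
                    psi_g1 = replicate(n, round(runif(2), 3), simplify = FALSE),
                    psi_g2 = replicate(n, round(runif(2), 3), simplify = FALSE),
                    fdr = round(runif(n), 3))
  sig <- filter_significant(ev)
  bg <- suppressWarnings(select_background(ev))
  expect_length(intersect(sig$event_id, bg$event_id), 0)
})

test_that("splicing direction follows the sign of control-minus-knockdown dPSI", {
  ev <- make_events(n = 3, delta_psi = c(0.2, -0.2, 0))
  expect_equal(as.character(classify_direction(ev)),
               c("spliced_in", "spliced_out", "unchanged"))
})

test_that("validation candidates need >50 reads within a single condition", {
  ev <- make_events(n = 3,
                    inc_g1 = list(c(26L, 25L), c(25L, 25L), c(0L, 0L)),
                    skip_g1 = list(c(0L, 0L), c(0L, 0L), c(0L, 0L)),
                    inc_g2 = list(c(5L, 5L), c(25L, 25L), c(0L, 0L)),
                    skip_g2 = list(c(0L, 0L), c(0L, 0L), c(0L, 0L)))
  # totals: g1 = 51/50/0, g2 = 10/50/0 -> only the first qualifies (strict >)
  expect_identical(select_validation_candidates(ev)$event_id, "T001")
  ev2 <- read_events(toy_table(), "SE")
  expect_identical(select_validation_candidates(ev2)$event_id, c("E5", "E6"))
})

test_that("read -> write round-trips the rMATS dialect byte for byte", {
  ev <- read_events(toy_table(), "SE")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, tmp)
  expect_identical(readLines(tmp), readLines(toy_table()))
  # and is a fixed point
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(read_events(tmp, "SE"), tmp2)
  expect_identical(readLines(tmp2), readLines(tmp))
})

test_that("the direction column is appended on request", {
  ev <- read_events(toy_table(), "SE")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, tmp, direction = TRUE)
  out <- read.delim(tmp)
  expect_equal(out$direction[out$ID == "E5"], "spliced_out")
})
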