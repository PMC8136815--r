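# rMATS-format event tables: parsing, significance / background / direction /
# validation-candidate rules.
#
# Events are held in an ordinary data.frame (class "splicing_events") with one
# row per event and list-columns for the per-replicate junction counts and PSI
# values. Coordinates are 0-based half-open internally; the rMATS dialect's
# 0-based start / 1-based end pair maps onto that convention unchanged
# (exonStart_0base = start, exonEnd = end).

# per-type column maps: target exon start/end plus the flanking-intron
# boundaries where the dialect provides them
.dialects <- list(
  SE   = list(start = "exonStart_0base", end = "exonEnd",
              up_end = "upstreamEE", down_start = "downstreamES"),
  MXE  = list(start = "X1stExonStart_0base", end = "X1stExonEnd",
              up_end = "upstreamEE", down_start = "downstreamES"),
  RI   = list(start = "riExonStart_0base", end = "riExonEnd",
              up_end = "upstreamEE", down_start = "downstreamES"),
  A3SS = list(start = "longExonStart_0base", end = "longExonEnd",
              up_end = NA, down_start = NA),
  A5SS = list(start = "longExonStart_0base", end = "longExonEnd",
              up_end = NA, down_start = NA)
)

.event_types <- names(.dialects)

.parse_int_list <- function(x, row, col) {
  out <- lapply(strsplit(as.character(x), ","), function(v) {
    v <- trimws(v)
    n <- suppressWarnings(as.integer(v))
    if (anyNA(n) || any(n < 0)) NULL else n
  })
  bad <- which(vapply(out, is.null, logical(1)))
  if (length(bad))
    stop(sprintf("malformed replicate counts in column '%s', row %d", col,
                 row[bad[1]]), call. = FALSE)
  out
}

.parse_psi_list <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) {
    v <- trimws(v)
    suppressWarnings(as.numeric(ifelse(v == "NA" | v == "", NA, v)))
  })
}

#' Criteria for calling an event significantly differentially spliced
#'
#' The three-threshold rule for differential splicing events: total junction
#' read support at least `min_unique_reads`, `|dPSI|` strictly above
#' `min_abs_delta_psi`, and FDR strictly below `max_fdr`.
#' `min_validation_reads` is the per-condition read support bound used by
#' [select_validation_candidates()].
#'
#' @param min_unique_reads minimum total inclusion+skipping reads over all
#'   replicates of both groups (default 15).
#' @param min_abs_delta_psi strict lower bound on `|dPSI|` (default 0.10).
#' @param max_fdr strict upper bound on the FDR (default 0.05).
#' @param min_validation_reads strict lower bound on within-condition read
#'   support for validation candidates (default 50).
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_unique_reads = 15L, min_abs_delta_psi = 0.10,
                            max_fdr = 0.05, min_validation_reads = 50L) {
  stopifnot(min_unique_reads >= 0, min_validation_reads >= 0,
            min_abs_delta_psi >= 0, min_abs_delta_psi <= 1,
            max_fdr >= 0, max_fdr <= 1)
  structure(list(min_unique_reads = as.integer(min_unique_reads),
                 min_abs_delta_psi = min_abs_delta_psi,
                 max_fdr = max_fdr,
                 min_validation_reads = as.integer(min_validation_reads)),
            class = "filter_criteria")
}

#' Criteria for selecting background (unaffected) exons
#'
#' Background exons are events with FDR > `min_fdr`, maximum replicate PSI
#' (over both groups) > `min_max_psi` and minimum replicate PSI <
#' `max_min_psi`; i.e. events that are detectably spliced in both directions
#' yet show no evidence of differential regulation.
#'
#' @param min_fdr strict lower bound on FDR (default 0.5).
#' @param min_max_psi strict lower bound on the maximum replicate PSI
#'   (default 0.15).
#' @param max_min_psi strict upper bound on the minimum replicate PSI
#'   (default 0.85).
#' @return an object of class `background_criteria`.
#' @export
background_criteria <- function(min_fdr = 0.5, min_max_psi = 0.15,
                                max_min_psi = 0.85) {
  stopifnot(min_fdr >= 0, min_fdr <= 1, min_max_psi >= 0, min_max_psi <= 1,
            max_min_psi >= 0, max_min_psi <= 1)
  structure(list(min_fdr = min_fdr, min_max_psi = min_max_psi,
                 max_min_psi = max_min_psi),
            class = "background_criteria")
}

.as_events <- function(df) {
  class(df) <- c("splicing_events", "data.frame")
  df
}

#' Read an rMATS-format differential splicing table
#'
#' Parses one tab-separated rMATS output table (one event type per table)
#' into a `splicing_events` data.frame. Required columns for the SE dialect:
#' `ID, GeneID, chr, strand, exonStart_0base, exonEnd, upstreamEE,
#' downstreamES, IJC_SAMPLE_1, SJC_SAMPLE_1, IJC_SAMPLE_2, SJC_SAMPLE_2,
#' IncLevel1, IncLevel2, PValue, FDR, IncLevelDifference`; comma-separated
#' replicate fields become integer / numeric list-columns. Missing PSI
#' replicates (`NA` entries) are kept as `NA`.
#'
#' @param table_path path to the TSV.
#' @param event_type one of `"SE"`, `"A3SS"`, `"A5SS"`, `"MXE"`, `"RI"`.
#' @return a `splicing_events` data.frame with columns `event_id, gene_id,
#'   event_type, chrom, strand, exon_start, exon_end, upstream_exon_end,
#'   downstream_exon_start`, list-columns `inc_g1, skip_g1, inc_g2, skip_g2,
#'   psi_g1, psi_g2`, and `pvalue, fdr, delta_psi`.
#' @export
read_events <- function(table_path, event_type = "SE") {
  if (!event_type %in% .event_types)
    stop("unknown event_type: ", event_type, call. = FALSE)
  if (!file.exists(table_path)) stop("no such file: ", table_path, call. = FALSE)
  d <- .dialects[[event_type]]
  tab <- read.delim(table_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = TRUE)
  req <- c("ID", "GeneID", "chr", "strand", d$start, d$end,
           "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
           "IncLevel1", "IncLevel2", "PValue", "FDR", "IncLevelDifference")
  req <- c(req, unlist(d[c("up_end", "down_start")], use.names = FALSE))
  req <- req[!is.na(req)]
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  n <- nrow(tab)
  rows <- seq_len(n)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !(tab[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("malformed numeric value in column '%s', row %d",
                   col, bad[1]), call. = FALSE)
    v
  }
  coord <- function(col) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v))
      stop(sprintf("malformed coordinate in column '%s', row %d", col,
                   which(is.na(v))[1]), call. = FALSE)
    v
  }
  ev <- data.frame(
    event_id = as.character(tab$ID),
    gene_id = as.character(tab$GeneID),
    event_type = rep(event_type, n),
    chrom = as.character(tab$chr),
    strand = as.character(tab$strand),
    exon_start = coord(d$start),
    exon_end = coord(d$end),
    stringsAsFactors = FALSE
  )
  if (any(!ev$strand %in% c("+", "-")))
    stop("strand column must be '+' or '-'", call. = FALSE)
  ev$upstream_exon_end <- if (is.na(d$up_end)) NA_integer_ else coord(d$up_end)
  ev$downstream_exon_start <-
    if (is.na(d$down_start)) NA_integer_ else coord(d$down_start)
  ev$inc_g1 <- I(.parse_int_list(tab$IJC_SAMPLE_1, rows, "IJC_SAMPLE_1"))
  ev$skip_g1 <- I(.parse_int_list(tab$SJC_SAMPLE_1, rows, "SJC_SAMPLE_1"))
  ev$inc_g2 <- I(.parse_int_list(tab$IJC_SAMPLE_2, rows, "IJC_SAMPLE_2"))
  ev$skip_g2 <- I(.parse_int_list(tab$SJC_SAMPLE_2, rows, "SJC_SAMPLE_2"))
  ev$psi_g1 <- I(.parse_psi_list(tab$IncLevel1))
  ev$psi_g2 <- I(.parse_psi_list(tab$IncLevel2))
  ev$pvalue <- num("PValue")
  ev$fdr <- num("FDR")
  ev$delta_psi <- num("IncLevelDifference")

  bad <- which(ev$exon_start >= ev$exon_end)
  if (length(bad))
    stop("exon_start >= exon_end at row ", bad[1], call. = FALSE)
  bad <- which(!is.na(ev$upstream_exon_end) &
                 ev$upstream_exon_end > ev$exon_start)
  if (length(bad))
    stop("upstream_exon_end > exon_start at row ", bad[1], call. = FALSE)
  bad <- which(!is.na(ev$downstream_exon_start) &
                 ev$downstream_exon_start < ev$exon_end)
  if (length(bad))
    stop("downstream_exon_start < exon_end at row ", bad[1], call. = FALSE)
  # dPSI must agree with the replicate PSI means when those are present
  for (r in rows) {
    m1 <- mean(ev$psi_g1[[r]], na.rm = TRUE)
    m2 <- mean(ev$psi_g2[[r]], na.rm = TRUE)
    if (is.finite(m1) && is.finite(m2) && is.finite(ev$delta_psi[r]) &&
        abs((m1 - m2) - ev$delta_psi[r]) > 1e-6 + 5e-4)
      warning(sprintf(
        "row %d: IncLevelDifference %.4f differs from mean-PSI difference %.4f",
        r, ev$delta_psi[r], m1 - m2), call. = FALSE)
  }
  .as_events(ev)
}

.fmt_list <- function(lst) {
  vapply(lst, function(v) paste(ifelse(is.na(v), "NA", as.character(v)),
                                collapse = ","), character(1))
}

#' Write a `splicing_events` table back to the rMATS TSV dialect
#'
#' Inverse of [read_events()]: emits the dialect columns of the events'
#' `event_type`. Reading a table written by `write_events()` and writing it
#' again reproduces the file byte for byte.
#'
#' @param events a `splicing_events` data.frame (single event type).
#' @param path output TSV path.
#' @param direction if `TRUE`, append a `direction` column from
#'   [classify_direction()].
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, direction = FALSE) {
  stopifnot(inherits(events, "data.frame"))
  et <- unique(events$event_type)
  if (length(et) != 1)
    stop("write_events expects a single event type", call. = FALSE)
  d <- .dialects[[et]]
  out <- data.frame(ID = events$event_id, GeneID = events$gene_id,
                    chr = events$chrom, strand = events$strand,
                    stringsAsFactors = FALSE)
  out[[sub("^X", "", d$start)]] <- events$exon_start
  out[[sub("^X", "", d$end)]] <- events$exon_end
  if (!is.na(d$up_end)) out[[d$up_end]] <- events$upstream_exon_end
  if (!is.na(d$down_start)) out[[d$down_start]] <- events$downstream_exon_start
  out$IJC_SAMPLE_1 <- .fmt_list(events$inc_g1)
  out$SJC_SAMPLE_1 <- .fmt_list(events$skip_g1)
  out$IJC_SAMPLE_2 <- .fmt_list(events$inc_g2)
  out$SJC_SAMPLE_2 <- .fmt_list(events$skip_g2)
  out$IncLevel1 <- .fmt_list(events$psi_g1)
  out$IncLevel2 <- .fmt_list(events$psi_g2)
  out$PValue <- as.character(events$pvalue)
  out$FDR <- as.character(events$fdr)
  out$IncLevelDifference <- as.character(events$delta_psi)
  if (direction) out$direction <- as.character(classify_direction(events))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Total junction read support of each event
#'
#' Sum of inclusion and skipping junction counts over all replicates of both
#' groups; the read-support measure behind the "at least 15 unique reads"
#' significance rule.
#'
#' @param events a `splicing_events` data.frame.
#' @return integer vector, one total per event.
#' @export
total_unique_reads <- function(events) {
  as.integer(vapply(seq_len(nrow(events)), function(r) {
    sum(events$inc_g1[[r]], events$skip_g1[[r]],
        events$inc_g2[[r]], events$skip_g2[[r]])
  }, numeric(1)))
}

#' Filter events to those called significantly differentially spliced
#'
#' Retains events with total read support `>= min_unique_reads`,
#' `|dPSI| > min_abs_delta_psi` (strict) and `FDR < max_fdr` (strict);
#' input order is preserved. Idempotent.
#'
#' @param events a `splicing_events` data.frame.
#' @param criteria a [filter_criteria()] object.
#' @return the retained subset, same class.
#' @export
filter_significant <- function(events, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- total_unique_reads(events) >= criteria$min_unique_reads &
    !is.na(events$delta_psi) &
    abs(events$delta_psi) > criteria$min_abs_delta_psi &
    !is.na(events$fdr) & events$fdr < criteria$max_fdr
  .as_events(events[keep, , drop = FALSE])
}

#' Select background (unaffected) exons
#'
#' Retains events with `FDR > min_fdr`, maximum replicate PSI over both
#' groups `> min_max_psi` and minimum replicate PSI `< max_min_psi`. Events
#' without any non-missing PSI value are skipped with a warning rather than
#' imputed.
#'
#' @param events a `splicing_events` data.frame.
#' @param criteria a [background_criteria()] object.
#' @return the retained subset, same class.
#' @export
select_background <- function(events, criteria = background_criteria()) {
  stopifnot(inherits(criteria, "background_criteria"))
  n <- nrow(events)
  keep <- logical(n)
  n_nopsi <- 0L
  for (r in seq_len(n)) {
    psi <- c(events$psi_g1[[r]], events$psi_g2[[r]])
    psi <- psi[!is.na(psi)]
    if (!length(psi)) { n_nopsi <- n_nopsi + 1L; next }
    keep[r] <- !is.na(events$fdr[r]) && events$fdr[r] > criteria$min_fdr &&
      max(psi) > criteria$min_max_psi && min(psi) < criteria$max_min_psi
  }
  if (n_nopsi > 0)
    warning(n_nopsi, " event(s) without PSI values skipped in background selection",
            call. = FALSE)
  .as_events(events[keep, , drop = FALSE])
}

#' Classify the splicing direction of each event
#'
#' With the convention dPSI = mean PSI(group 1 = control) - mean PSI(group 2 =
#' perturbed), `spliced_in` (dPSI > 0) means the exon is preferentially
#' included in control, i.e. skipped after the perturbation; `spliced_out`
#' (dPSI < 0) the converse; dPSI = 0 is `unchanged`.
#'
#' @param events a `splicing_events` data.frame.
#' @return factor with levels `spliced_in`, `spliced_out`, `unchanged`.
#' @export
classify_direction <- function(events) {
  d <- events$delta_psi
  out <- ifelse(is.na(d), NA_character_,
                ifelse(d > 0, "spliced_in",
                       ifelse(d < 0, "spliced_out", "unchanged")))
  factor(out, levels = c("spliced_in", "spliced_out", "unchanged"))
}

#' Select validation candidates by per-condition read support
#'
#' Retains events whose total inclusion+skipping counts within group 1 OR
#' within group 2 strictly exceed `min_validation_reads` — events with enough
#' coverage in at least one condition for RT-PCR follow-up.
#'
#' @param events a `splicing_events` data.frame.
#' @param criteria a [filter_criteria()] object.
#' @return the retained subset, same class.
#' @export
select_validation_candidates <- function(events, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  keep <- vapply(seq_len(nrow(events)), function(r) {
    g1 <- sum(events$inc_g1[[r]], events$skip_g1[[r]])
    g2 <- sum(events$inc_g2[[r]], events$skip_g2[[r]])
    g1 > criteria$min_validation_reads || g2 > criteria$min_validation_reads
  }, logical(1))
  .as_events(events[keep, , drop = FALSE])
}

#' @export
print.splicing_events <- function(x, ...) {
  cat(sprintf("splicing_events: %d %s event(s)\n", nrow(x),
              paste(unique(x$event_type), collapse = "/")))
  if (nrow(x)) {
    show <- x[, c("event_id", "gene_id", "chrom", "strand", "exon_start",
                  "exon_end", "fdr", "delta_psi")]
    print(utils::head(as.data.frame(show), 10), ...)
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  }
  invisible(x)
}
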