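# Cross-dataset event matching, hypergeometric overlap with expected
# overlap, delta-PSI direction concordance, and the 2x2 proportion test.

#' Coordinate keys identifying events across datasets
#'
#' @param events a `splicing_events` data.frame.
#' @return character vector of keys (chrom/strand/type/coordinates); two
#'   events from different tables share a key iff their coordinates agree
#'   exactly.
#' @export
event_key <- function(events) {
  paste(events$chrom, events$strand, events$event_type, events$exon_start,
        events$exon_end, events$upstream_exon_end,
        events$downstream_exon_start, sep = ":")
}

#' Match events between two datasets by coordinate key
#'
#' Duplicated keys within a list are collapsed to their first occurrence
#' with a warning.
#'
#' @param events_a,events_b `splicing_events` data.frames of the same event
#'   type.
#' @return data.frame of paired events: `key, event_id_a, event_id_b,
#'   delta_psi_a, delta_psi_b`.
#' @export
match_events <- function(events_a, events_b) {
  if (!identical(sort(unique(events_a$event_type)),
                 sort(unique(events_b$event_type))))
    stop("event types differ between datasets", call. = FALSE)
  ka <- event_key(events_a); kb <- event_key(events_b)
  if (anyDuplicated(ka)) {
    warning(sum(duplicated(ka)), " duplicate key(s) in first dataset collapsed",
            call. = FALSE)
    events_a <- events_a[!duplicated(ka), , drop = FALSE]; ka <- unique(ka)
  }
  if (anyDuplicated(kb)) {
    warning(sum(duplicated(kb)), " duplicate key(s) in second dataset collapsed",
            call. = FALSE)
    events_b <- events_b[!duplicated(kb), , drop = FALSE]; kb <- unique(kb)
  }
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  data.frame(key = common,
             event_id_a = events_a$event_id[ia],
             event_id_b = events_b$event_id[ib],
             delta_psi_a = events_a$delta_psi[ia],
             delta_psi_b = events_b$delta_psi[ib],
             stringsAsFactors = FALSE)
}

#' Hypergeometric overlap test for two event sets
#'
#' Two sets of sizes `nA` and `nB` drawn from a common universe of size `N`:
#' expected overlap `nA*nB/N`, p-value the upper hypergeometric tail
#' `P(K >= k_observed)`. The universe size must be supplied explicitly (e.g.
#' all events passing the read-support filter in both datasets).
#'
#' @param nA,nB set sizes.
#' @param N universe size.
#' @param k_observed observed overlap.
#' @return an object of class `overlap_result`: `nA, nB, N, k_observed,
#'   expected, p_value`.
#' @export
overlap_test <- function(nA, nB, N, k_observed) {
  if (nA > N || nB > N || nA < 0 || nB < 0 || N <= 0)
    stop("set sizes must satisfy 0 <= nA, nB <= N", call. = FALSE)
  if (k_observed > min(nA, nB) || k_observed < 0)
    stop("k_observed must be in [0, min(nA, nB)]", call. = FALSE)
  structure(list(nA = nA, nB = nB, N = N, k_observed = k_observed,
                 expected = nA * nB / N,
                 p_value = phyper(k_observed - 1, nA, N - nA, nB,
                                  lower.tail = FALSE)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of nA=%d, nB=%d (universe %d); expected %.2f; P(K >= k) = %.3g\n",
    x$k_observed, x$nA, x$nB, x$N, x$expected, x$p_value))
  invisible(x)
}

#' Direction concordance of paired delta-PSI values
#'
#' Pairs are `similar` when both dPSI values are nonzero with the same sign,
#' `opposite` when nonzero with opposite signs; pairs in which either dPSI
#' is zero (or missing) are excluded from both counts and reported
#' separately.
#'
#' @param paired_events output of [match_events()] (or any data.frame with
#'   `delta_psi_a`, `delta_psi_b`).
#' @return an object of class `concordance_result`: `n_common, n_similar,
#'   n_opposite, n_zero, proportion_similar`.
#' @export
direction_concordance <- function(paired_events) {
  sa <- sign(paired_events$delta_psi_a)
  sb <- sign(paired_events$delta_psi_b)
  nonzero <- !is.na(sa) & !is.na(sb) & sa != 0 & sb != 0
  n_similar <- sum(nonzero & sa == sb)
  n_opposite <- sum(nonzero & sa != sb)
  n_common <- n_similar + n_opposite
  structure(list(n_common = n_common, n_similar = n_similar,
                 n_opposite = n_opposite,
                 n_zero = nrow(paired_events) - n_common,
                 proportion_similar =
                   if (n_common > 0) n_similar / n_common else NA_real_),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "concordance: %d pairs, %d similar / %d opposite (%.1f%% similar), %d zero/missing excluded\n",
    x$n_common, x$n_similar, x$n_opposite, 100 * x$proportion_similar,
    x$n_zero))
  invisible(x)
}

#' Two-proportion chi-square test on a 2x2 table
#'
#' Pearson chi-square, 1 df, without continuity correction by default.
#'
#' @param counts 2x2 matrix of non-negative integer counts; both margins
#'   must be positive.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return list with `statistic` and `p_value`.
#' @export
two_proportion_chisq <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in 2x2 table", call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}
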