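# Per-window Wilcoxon rank-sum comparison of motif counts between regulated
# and background exons. Window counts are small, heavily tied integers, so
# the default test uses midranks with the tie-corrected normal approximation
# and a 0.5 continuity correction; tie-free small samples are handled by
# exact enumeration of rank assignments.

# cache of combn(N, nx) index matrices used by the exact path
.combn_cache <- new.env(parent = emptyenv())

.combn_idx <- function(N, nx) {
  key <- paste0(N, "_", nx)
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(N, nx)
  .combn_cache[[key]]
}

#' Map-analysis configuration
#'
#' @param window_width sliding-window width in nt (default 50).
#' @param step window step in nt (default 1).
#' @param region_length region length in nt (default 300; gives a family of
#'   250 windows).
#' @param alternative `"greater"` (default; tests enrichment in the regulated
#'   group) or `"two_sided"`.
#' @param exact_max_n largest total sample size at which tie-free samples are
#'   tested by exact enumeration (default 10).
#' @return an object of class `map_config`.
#' @export
map_config <- function(window_width = 50L, step = 1L, region_length = 300L,
                       alternative = c("greater", "two_sided"),
                       exact_max_n = 10L) {
  alternative <- match.arg(alternative)
  stopifnot(region_length > window_width, step >= 1)
  structure(list(window_width = as.integer(window_width),
                 step = as.integer(step),
                 region_length = as.integer(region_length),
                 alternative = alternative,
                 exact_max_n = as.integer(exact_max_n)),
            class = "map_config")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sample rank test with midranks for ties. When the pooled sample size
#' is at most `exact_max_n` and the data are tie-free, the p-value is exact
#' (enumeration of all rank assignments); otherwise a normal approximation
#' with tie-corrected variance and 0.5 continuity correction is used. A
#' degenerate pooled sample (zero rank variance) returns p = 0.5 one-sided /
#' 1 two-sided, the value of a statistic sitting at its null mean.
#'
#' @param x,y numeric samples; `alternative = "greater"` tests whether `x`
#'   (regulated) is stochastically larger than `y` (background).
#' @param alternative `"greater"`, `"two_sided"` or `"less"`.
#' @param exact_max_n exact-enumeration size threshold (default 10).
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("greater", "two_sided",
                                                    "less"),
                              exact_max_n = 10L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  mu <- nx * ny / 2

  if (!ties && N <= exact_max_n) {
    comb <- .combn_idx(N, nx)
    Uperm <- colSums(matrix(r[comb], nrow = nx)) - nx * (nx + 1) / 2
    p <- switch(alternative,
      greater = mean(Uperm >= U),
      less = mean(Uperm <= U),
      two_sided = mean(abs(Uperm - mu) >= abs(U - mu)))
    return(list(statistic = U, p_value = p, method = "exact"))
  }

  tt <- table(pooled)
  sigma2 <- nx * ny / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  if (sigma2 <= 0) {
    p <- if (alternative == "two_sided") 1 else 0.5
    return(list(statistic = U, p_value = p, method = "normal"))
  }
  s <- sqrt(sigma2)
  p <- switch(alternative,
    greater = pnorm((U - mu - 0.5) / s, lower.tail = FALSE),
    less = pnorm((U - mu + 0.5) / s),
    two_sided = {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / s
      min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    })
  list(statistic = U, p_value = p, method = "normal")
}

# fast column-wise rank-sum on small non-negative integer count matrices;
# midranks via counting sort, tie-corrected normal approximation (in C++)
.col_wilcoxon <- function(mreg, mbg, alternative = "greater") {
  storage.mode(mreg) <- "integer"
  storage.mode(mbg) <- "integer"
  col_wilcoxon_cpp(mreg, mbg, if (alternative == "two_sided") 2L else 1L)
}

#' Per-window enrichment p-values for one motif and region
#'
#' Runs one Wilcoxon rank-sum test per window column (regulated rows vs
#' background rows) and records the full p-value family together with its
#' minimum and argmin window (ties broken towards the smallest window
#' offset).
#'
#' @param counts_reg,counts_bg `window_count_matrix` objects for the same
#'   motif, region and window family.
#' @param config a [map_config()].
#' @param comparison free-text label of the comparison (e.g.
#'   `"spliced_out vs background"`).
#' @return an object of class `window_pvalue_series`: `list(motif, region,
#'   comparison, window_offsets, pvalues, min_p, min_p_window)` where
#'   `min_p_window` is the 0-based window offset of the minimum.
#' @export
enrichment_pvalues <- function(counts_reg, counts_bg, config = map_config(),
                               comparison = "regulated vs background") {
  stopifnot(inherits(counts_reg, "window_count_matrix"),
            inherits(counts_bg, "window_count_matrix"))
  if (counts_reg$motif != counts_bg$motif ||
      counts_reg$region != counts_bg$region ||
      !identical(counts_reg$window_offsets, counts_bg$window_offsets))
    stop("count matrices disagree in motif, region or window family",
         call. = FALSE)
  if (!nrow(counts_reg$counts) || !nrow(counts_bg$counts))
    stop("empty count matrix", call. = FALSE)
  N <- nrow(counts_reg$counts) + nrow(counts_bg$counts)
  alt <- config$alternative
  if (N <= config$exact_max_n) {
    pv <- vapply(seq_along(counts_reg$window_offsets), function(w) {
      wilcoxon_rank_sum(counts_reg$counts[, w], counts_bg$counts[, w],
                        alternative = alt,
                        exact_max_n = config$exact_max_n)$p_value
    }, numeric(1))
  } else {
    pv <- .col_wilcoxon(counts_reg$counts, counts_bg$counts, alternative = alt)
  }
  imin <- which.min(pv)  # which.min returns the first (smallest-offset) tie
  structure(list(motif = counts_reg$motif, region = counts_reg$region,
                 comparison = comparison,
                 window_offsets = counts_reg$window_offsets,
                 pvalues = pv, min_p = pv[imin],
                 min_p_window = counts_reg$window_offsets[imin]),
            class = "window_pvalue_series")
}

#' Rank motifs by minimum window p-value
#'
#' The classical RNA-map summary: each motif/region series is reduced to the
#' minimum of its (raw, highly correlated) window p-values and ranked
#' ascending; ties are broken by motif name. The minimum of 250 dependent
#' p-values is strongly biased towards small values, which is what the
#' post-hoc FDP screen ([posthoc_screen()]) corrects.
#'
#' @param series_collection list of `window_pvalue_series`.
#' @return data.frame with columns `motif, region, comparison, min_p,
#'   min_p_window`, sorted by `min_p`.
#' @export
summarize_min_p <- function(series_collection) {
  if (!length(series_collection))
    return(data.frame(motif = character(0), region = character(0),
                      comparison = character(0), min_p = numeric(0),
                      min_p_window = integer(0)))
  cmp <- unique(vapply(series_collection, `[[`, character(1), "comparison"))
  if (length(cmp) > 1)
    stop("series mix different comparisons: ", paste(cmp, collapse = "; "),
         call. = FALSE)
  out <- data.frame(
    motif = vapply(series_collection, `[[`, character(1), "motif"),
    region = vapply(series_collection, `[[`, character(1), "region"),
    comparison = cmp,
    min_p = vapply(series_collection, `[[`, numeric(1), "min_p"),
    min_p_window = vapply(series_collection, function(s)
      as.integer(s$min_p_window), integer(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$min_p, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-window p-value profile TSV
#'
#' @param series a `window_pvalue_series`.
#' @param path output TSV path (columns: window_offset, pvalue).
#' @return `path`, invisibly.
#' @export
write_pvalue_profile <- function(series, path) {
  write.table(data.frame(window_offset = series$window_offsets,
                         pvalue = series$pvalues),
              path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
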