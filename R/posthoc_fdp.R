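# Post-hoc false-discovery-proportion bounds over window intervals.
#
# For a family of m window p-values (one motif x one region), the
# Simes/linear-template post-hoc bound gives, simultaneously over every
# subset S and in particular every contiguous window interval,
#
#   V(S) = min_{k = 1..|S|} [ #{ p in S : p > alpha * k / m } + k - 1 ]
#
# an upper bound on the number of false positives in S that holds for all S
# at once with probability 1 - alpha (under Simes-type positive dependence,
# a reasonable assumption for overlapping-window p-values). The FDP bound of
# an interval is V(S)/|S|; because the bounds are simultaneous, the FDP
# threshold may be chosen after seeing the data.

#' Post-hoc inference configuration
#'
#' @param alpha confidence level of the simultaneous bound (default 0.05).
#' @param fdp_threshold intervals with FDP bound strictly below this value
#'   are called significant (default 0.25).
#' @param family_scope reference family; only `"per_motif_region"` (the m
#'   windows of one motif x one region) is currently implemented.
#' @return an object of class `posthoc_config`.
#' @export
posthoc_config <- function(alpha = 0.05, fdp_threshold = 0.25,
                           family_scope = "per_motif_region") {
  stopifnot(alpha > 0, alpha < 1, fdp_threshold > 0, fdp_threshold < 1)
  family_scope <- match.arg(family_scope, "per_motif_region")
  structure(list(alpha = alpha, fdp_threshold = fdp_threshold,
                 family_scope = family_scope),
            class = "posthoc_config")
}

#' Simes-template post-hoc bound on the false positives of a subset
#'
#' Evaluates `V(S) = min_k [ #{p in S : p > alpha*k/m} + k - 1 ]` over
#' `k = 1..|S|`, clipped to `[0, |S|]`, with strict `>` at each threshold.
#'
#' @param p_subset p-values of the selected subset S (any subset of the
#'   family, not necessarily contiguous).
#' @param m reference family size (must be `>= length(p_subset)`).
#' @param alpha confidence level.
#' @return integer upper bound on the number of false positives in S.
#' @export
simes_posthoc_bound <- function(p_subset, m, alpha = 0.05) {
  if (!length(p_subset)) stop("empty subset", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (m < length(p_subset)) stop("m must be >= |S|", call. = FALSE)
  s <- length(p_subset)
  k <- seq_len(s)
  counts <- vapply(alpha * k / m, function(t) sum(p_subset > t), integer(1))
  vbar <- min(counts + k - 1L)
  as.integer(min(max(vbar, 0L), s))
}

#' FDP bounds for all contiguous window intervals of a p-value series
#'
#' Computes `V(S)` and the FDP bound `V(S)/|S|` for every contiguous window
#' interval of the series, using the full window family size as the
#' reference `m` (per-k indicator prefix sums; the complete table for
#' m = 250 takes a few milliseconds).
#'
#' @param series a `window_pvalue_series` from [enrichment_pvalues()], or a
#'   bare numeric p-value vector.
#' @param config a [posthoc_config()].
#' @return data.frame with one row per interval: `motif, region, start, end`
#'   (0-based window offsets, inclusive), `size, vbar, fdp_bound`.
#' @export
interval_bounds <- function(series, config = posthoc_config()) {
  if (is.numeric(series))
    series <- list(motif = NA_character_, region = NA_character_,
                   window_offsets = seq_along(series) - 1L, pvalues = series)
  p <- series$pvalues
  m <- length(p)
  tab <- simes_interval_table_cpp(p, config$alpha, m)
  offs <- series$window_offsets
  out <- data.frame(motif = series$motif, region = series$region,
                    start = offs[tab$i + 1L], end = offs[tab$j + 1L],
                    size = tab$size, vbar = tab$vbar,
                    fdp_bound = tab$vbar / tab$size,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# drop intervals contained in another interval of the same group; rows must
# carry columns start, end
.maximal_intervals <- function(df) {
  if (nrow(df) < 2) return(df)
  o <- order(df$start, -df$end)
  df <- df[o, , drop = FALSE]
  keep <- logical(nrow(df))
  maxend <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > maxend) { keep[i] <- TRUE; maxend <- df$end[i] }
  }
  df[keep, , drop = FALSE]
}

#' Select significantly enriched intervals from an interval table
#'
#' Keeps intervals with FDP bound strictly below `fdp_threshold`, reduces
#' them to maximal intervals per motif/region (no selected interval contained
#' in another), and records `ph_fdp`, the minimum FDP bound over the whole
#' candidate table.
#'
#' @param interval_table output of [interval_bounds()] (possibly rbind-ed
#'   over regions of one motif).
#' @param config a [posthoc_config()].
#' @return list with `ph_fdp`, `selected` (maximal qualifying intervals) and
#'   `best` (the minimising interval row).
#' @export
select_intervals <- function(interval_table, config = posthoc_config()) {
  if (!nrow(interval_table))
    return(list(ph_fdp = NA_real_,
                selected = interval_table, best = interval_table))
  ibest <- which.min(interval_table$fdp_bound)
  sel <- interval_table[interval_table$fdp_bound < config$fdp_threshold, ,
                        drop = FALSE]
  if (nrow(sel)) {
    parts <- split(sel, paste(sel$motif, sel$region))
    sel <- do.call(rbind, lapply(parts, .maximal_intervals))
    sel <- sel[order(sel$motif, sel$region, sel$start), , drop = FALSE]
    rownames(sel) <- NULL
  }
  list(ph_fdp = interval_table$fdp_bound[ibest], selected = sel,
       best = interval_table[ibest, , drop = FALSE])
}

# fast per-series screen via the reduced C++ scan (no full table in memory);
# `alpha` is the (possibly multiplicity-shared) level for this family
.screen_series <- function(series, config, alpha = config$alpha) {
  p <- series$pvalues
  sc <- simes_interval_scan_cpp(p, alpha, length(p),
                                config$fdp_threshold)
  offs <- series$window_offsets
  nsel <- length(sc$sel_i)
  sel <- data.frame(motif = rep(series$motif, nsel),
                    region = rep(series$region, nsel),
                    start = offs[sc$sel_i + 1L], end = offs[sc$sel_j + 1L],
                    size = sc$sel_j - sc$sel_i + 1L, vbar = sc$sel_vbar,
                    stringsAsFactors = FALSE)
  sel$fdp_bound <- sel$vbar / sel$size
  list(min_fdp = sc$min_fdp,
       best = data.frame(motif = series$motif, region = series$region,
                         start = offs[sc$min_i + 1L],
                         end = offs[sc$min_j + 1L],
                         size = sc$min_j - sc$min_i + 1L,
                         vbar = sc$min_vbar, fdp_bound = sc$min_fdp,
                         stringsAsFactors = FALSE),
       selected = sel)
}

#' Post-hoc FDP screen over a collection of p-value series
#'
#' For every motif, computes the minimum FDP bound over all contiguous
#' intervals of all its regions (`ph_fdp`, the per-RBP summary value) and
#' the maximal intervals with FDP bound strictly below the threshold. Motifs
#' are ranked ascending by `ph_fdp`, ties broken by motif name.
#'
#' Each motif x region family carries its own Simes-template bound; so that
#' the FDP guarantee holds simultaneously over everything the screen looks
#' at (and hence over any selection made from its output), the confidence
#' level is shared across families by a union bound: every family is
#' evaluated at `alpha / n_series`. Single-family analyses
#' ([interval_bounds()], [select_intervals()]) use `alpha` undivided.
#'
#' @param all_series list of `window_pvalue_series` covering one shared
#'   comparison (several regions per motif allowed).
#' @param config a [posthoc_config()].
#' @return list with `summary` (data.frame `motif, ph_fdp, n_selected,
#'   best_region, best_start, best_end`) and `intervals` (selected maximal
#'   intervals across all motifs, with a `motif` column).
#' @export
posthoc_screen <- function(all_series, config = posthoc_config()) {
  empty_sum <- data.frame(motif = character(0), ph_fdp = numeric(0),
                          n_selected = integer(0), best_region = character(0),
                          best_start = integer(0), best_end = integer(0),
                          stringsAsFactors = FALSE)
  empty_int <- data.frame(motif = character(0), region = character(0),
                          start = integer(0), end = integer(0),
                          size = integer(0), vbar = integer(0),
                          fdp_bound = numeric(0), stringsAsFactors = FALSE)
  if (!length(all_series))
    return(list(summary = empty_sum, intervals = empty_int))
  cmp <- unique(vapply(all_series, `[[`, character(1), "comparison"))
  if (length(cmp) > 1)
    stop("series mix different comparisons", call. = FALSE)
  motifs <- vapply(all_series, `[[`, character(1), "motif")
  alpha_shared <- config$alpha / length(all_series)
  sums <- list(); ints <- list()
  for (mo in unique(motifs)) {
    scr <- lapply(all_series[motifs == mo], .screen_series, config = config,
                  alpha = alpha_shared)
    best_all <- do.call(rbind, lapply(scr, `[[`, "best"))
    sel_all <- do.call(rbind, lapply(scr, `[[`, "selected"))
    if (nrow(sel_all)) {
      parts <- split(sel_all, sel_all$region)
      sel_all <- do.call(rbind, lapply(parts, .maximal_intervals))
      sel_all <- sel_all[order(sel_all$region, sel_all$start), , drop = FALSE]
      rownames(sel_all) <- NULL
    }
    ib <- which.min(best_all$fdp_bound)
    sums[[mo]] <- data.frame(motif = mo, ph_fdp = best_all$fdp_bound[ib],
                             n_selected = nrow(sel_all),
                             best_region = best_all$region[ib],
                             best_start = best_all$start[ib],
                             best_end = best_all$end[ib],
                             stringsAsFactors = FALSE)
    ints[[mo]] <- sel_all
  }
  summary <- do.call(rbind, sums)
  summary <- summary[order(summary$ph_fdp, summary$motif), , drop = FALSE]
  rownames(summary) <- NULL
  intervals <- do.call(rbind, ints)
  if (is.null(intervals) || !nrow(intervals)) intervals <- empty_int
  rownames(intervals) <- NULL
  list(summary = summary, intervals = intervals, comparison = cmp,
       config = config)
}
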