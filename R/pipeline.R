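# End-to-end orchestration: filter -> background -> regions -> scan ->
# window Wilcoxon -> post-hoc FDP screen, with deterministic TSV/JSON
# outputs, plus the overlap/concordance runner.

#' Run the full motif RNA-map analysis
#'
#' Pipeline stages: (i) significance filtering of the event table and
#' background-exon selection; (ii) optional restriction of the regulated set
#' to one splicing direction; (iii) strand-aware region construction;
#' (iv) motif scanning and sliding-window counting; (v) per-window Wilcoxon
#' rank-sum enrichment p-values; (vi) post-hoc FDP interval screen and
#' per-motif ranking. All stages are deterministic, so a rerun on identical
#' inputs is bit-identical.
#'
#' @param events a `splicing_events` data.frame, or a path to an rMATS SE
#'   table.
#' @param genome a `DNAStringSet`, or a path to a genome FASTA.
#' @param motifs a list of [motif()] objects, or a path to a compendium TSV.
#' @param direction analyse `"all"` significant exons (default), only
#'   `"spliced_in"` or `"spliced_out"` exons, or `"both"` (two independent
#'   runs, one per direction).
#' @param filter a [filter_criteria()].
#' @param background a [background_criteria()].
#' @param spec a [region_spec()].
#' @param config a [map_config()].
#' @param posthoc a [posthoc_config()].
#' @param out_dir if non-`NULL`, write result TSVs and a run-metadata JSON.
#' @return a result bundle: `list(significant, background, series, min_p,
#'   ranking, intervals, direction, n_regions)`; for `direction = "both"` a
#'   named list of two such bundles.
#' @export
run_map <- function(events, genome, motifs,
                    direction = c("all", "spliced_in", "spliced_out", "both"),
                    filter = filter_criteria(),
                    background = background_criteria(),
                    spec = region_spec(), config = map_config(),
                    posthoc = posthoc_config(), out_dir = NULL) {
  direction <- match.arg(direction)
  if (is.character(events)) events <- read_events(events, "SE")
  if (is.character(genome)) genome <- load_genome(genome)
  if (is.character(motifs)) motifs <- load_compendium(motifs)
  if (!length(motifs)) stop("empty motif compendium", call. = FALSE)

  if (direction == "both") {
    out <- list(
      spliced_in = run_map(events, genome, motifs, "spliced_in", filter,
                           background, spec, config, posthoc,
                           if (is.null(out_dir)) NULL
                           else file.path(out_dir, "spliced_in")),
      spliced_out = run_map(events, genome, motifs, "spliced_out", filter,
                            background, spec, config, posthoc,
                            if (is.null(out_dir)) NULL
                            else file.path(out_dir, "spliced_out")))
    return(out)
  }

  sig <- filter_significant(events, filter)
  if (direction != "all")
    sig <- sig[as.character(classify_direction(sig)) == direction, ,
               drop = FALSE]
  bg <- select_background(events, background)
  if (!nrow(sig)) stop("no significant events after filtering (direction: ",
                       direction, ")", call. = FALSE)
  if (!nrow(bg)) stop("no background events selected", call. = FALSE)

  reg_sig <- build_regions(sig, genome, spec)
  reg_bg <- build_regions(bg, genome, spec)
  cmp <- paste(direction, "vs background")

  series <- list()
  for (lab in .region_labels) {
    rs <- reg_sig[reg_sig$region == lab & reg_sig$valid, , drop = FALSE]
    rb <- reg_bg[reg_bg$region == lab & reg_bg$valid, , drop = FALSE]
    if (!nrow(rs) || !nrow(rb)) next
    cms_sig <- build_count_matrices(rs, motifs, config$window_width,
                                    config$step)
    cms_bg <- build_count_matrices(rb, motifs, config$window_width,
                                   config$step)
    for (key in names(cms_sig))
      series[[key]] <- enrichment_pvalues(cms_sig[[key]], cms_bg[[key]],
                                          config, comparison = cmp)
  }
  if (!length(series)) stop("no valid regions to analyse", call. = FALSE)

  minp <- summarize_min_p(series)
  screen <- posthoc_screen(series, posthoc)

  bundle <- list(significant = sig, background = bg, series = series,
                 min_p = minp, ranking = screen$summary,
                 intervals = screen$intervals, direction = direction,
                 comparison = cmp,
                 n_windows = length(series[[1]]$window_offsets))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_events(sig, file.path(out_dir, "significant_events.tsv"),
                 direction = TRUE)
    write_events(bg, file.path(out_dir, "background_events.tsv"))
    prof <- do.call(rbind, lapply(series, function(s)
      data.frame(motif = s$motif, region = s$region,
                 window_offset = s$window_offsets, pvalue = s$pvalues,
                 stringsAsFactors = FALSE)))
    rownames(prof) <- NULL
    write.table(prof, file.path(out_dir, "window_pvalues.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, eol = "\n")
    write.table(minp, file.path(out_dir, "min_p_ranking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, eol = "\n")
    write.table(screen$summary, file.path(out_dir, "phfdp_ranking.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    ints <- screen$intervals
    ints$selected <- rep(TRUE, nrow(ints))
    write.table(ints, file.path(out_dir, "selected_intervals.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    meta <- list(package = "splicemaps",
                 version = as.character(utils::packageVersion("splicemaps")),
                 direction = direction,
                 n_significant = nrow(sig), n_background = nrow(bg),
                 window = list(width = config$window_width,
                               step = config$step,
                               region_length = config$region_length,
                               n_windows = bundle$n_windows,
                               convention = "region_length - window_width windows; match counted by start offset"),
                 filter = unclass(filter), background = unclass(background),
                 posthoc = unclass(posthoc))
    jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$out_dir <- out_dir
  }
  bundle
}

#' Overlap and direction-concordance comparison of two event tables
#'
#' Matches events by coordinate key, tests the overlap against the
#' hypergeometric null over a user-supplied universe, and classifies common
#' events as `similar` / `opposite` by dPSI sign. The universe size has no
#' default: it must be the number of events eligible for detection in both
#' datasets.
#'
#' @param events_a,events_b `splicing_events` data.frames (or table paths).
#' @param universe_size the universe size N for the hypergeometric test.
#' @param out_dir if non-`NULL`, write the paired events TSV and a summary
#'   JSON.
#' @return list with `pairs`, `overlap` ([overlap_test()] result) and
#'   `concordance` ([direction_concordance()] result).
#' @export
run_concordance <- function(events_a, events_b, universe_size,
                            out_dir = NULL) {
  if (missing(universe_size) || is.null(universe_size))
    stop("universe_size must be supplied (no default)", call. = FALSE)
  if (is.character(events_a)) events_a <- read_events(events_a, "SE")
  if (is.character(events_b)) events_b <- read_events(events_b, "SE")
  pairs <- match_events(events_a, events_b)
  ov <- overlap_test(nrow(events_a), nrow(events_b), universe_size,
                     nrow(pairs))
  cc <- direction_concordance(pairs)
  out <- list(pairs = pairs, overlap = ov, concordance = cc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(pairs, file.path(out_dir, "paired_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, eol = "\n")
    jsonlite::write_json(list(overlap = unclass(ov),
                              concordance = unclass(cc)),
                         file.path(out_dir, "concordance_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Plot a motif RNA map profile
#'
#' Positional profile of -log10 window p-values for one motif across the
#' four regions, with selected intervals (if any) marked along the axis.
#'
#' @param series_list list of `window_pvalue_series` of one motif (one per
#'   region).
#' @param intervals optional data.frame of selected intervals for the motif.
#' @param main plot title.
#' @return invisibly, `NULL`; draws on the current device.
#' @export
plot_rna_map <- function(series_list, intervals = NULL, main = NULL) {
  stopifnot(length(series_list) >= 1)
  labs <- vapply(series_list, `[[`, character(1), "region")
  nw <- length(series_list[[1]]$window_offsets)
  gap <- 20L
  xoff <- stats::setNames((match(labs, .region_labels) - 1L) * (nw + gap),
                          labs)
  ymax <- max(vapply(series_list, function(s) max(-log10(pmax(s$pvalues,
                                                              1e-300))),
                     numeric(1)))
  graphics::plot(NA, xlim = c(0, max(xoff) + nw), ylim = c(0, ymax * 1.05),
                 xlab = "window offset by region", ylab = "-log10 p",
                 main = main %||% series_list[[1]]$motif, xaxt = "n")
  graphics::axis(1, at = xoff + nw / 2, labels = labs)
  for (s in series_list)
    graphics::lines(xoff[s$region] + seq_len(nw) - 1,
                    -log10(pmax(s$pvalues, 1e-300)), col = "steelblue")
  if (!is.null(intervals) && nrow(intervals))
    for (r in seq_len(nrow(intervals)))
      graphics::segments(xoff[intervals$region[r]] + intervals$start[r], 0,
                         xoff[intervals$region[r]] + intervals$end[r], 0,
                         lwd = 4, col = "firebrick")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
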