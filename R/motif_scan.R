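# Degenerate IUPAC motifs, sequence scanning (sense strand only: binding
# sites live on the pre-mRNA) and aggregation of match offsets into sliding
# window counts. Matching is delegated to Biostrings with fixed = "subject",
# so pattern ambiguity codes act as wildcards while `N` in the scanned
# sequence matches nothing.

.iupac_codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")

#' Construct an RBP motif
#'
#' @param name RBP name.
#' @param patterns character vector of IUPAC-degenerate patterns (RNA `U`
#'   accepted and mapped to `T`); each pattern must be at least 4 nt and use
#'   only IUPAC codes.
#' @return an object of class `motif`.
#' @export
motif <- function(name, patterns) {
  patterns <- chartr("Uu", "Tt", toupper(patterns))
  for (p in patterns) {
    ch <- strsplit(p, "")[[1]]
    if (length(ch) < 4)
      stop(sprintf("motif '%s': pattern '%s' shorter than 4 nt", name, p),
           call. = FALSE)
    bad <- setdiff(ch, .iupac_codes)
    if (length(bad))
      stop(sprintf("motif '%s': invalid IUPAC code '%s' in pattern '%s'",
                   name, bad[1], p), call. = FALSE)
  }
  structure(list(name = name, patterns = unique(patterns)), class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif %s: %s\n", x$name, paste(x$patterns, collapse = ", ")))
  invisible(x)
}

#' Load a motif compendium TSV
#'
#' Two-column tab-separated file (name, IUPAC pattern), optionally with a
#' header line `name<TAB>pattern`; multiple rows per name are merged into one
#' multi-pattern motif.
#'
#' @param tsv_path path to the compendium.
#' @return named list of [motif()] objects, in first-appearance order.
#' @export
load_compendium <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("no such file: ", tsv_path, call. = FALSE)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^name\t", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad))
    stop("malformed compendium row ", bad[1], ": expected name<TAB>pattern",
         call. = FALSE)
  nm <- vapply(parts, `[[`, character(1), 1)
  pat <- vapply(parts, `[[`, character(1), 2)
  out <- list()
  for (i in seq_along(nm)) {
    m <- tryCatch(motif(nm[i], pat[i]),
                  error = function(e)
                    stop(sprintf("compendium row %d: %s", i, conditionMessage(e)),
                         call. = FALSE))
    if (is.null(out[[nm[i]]])) out[[nm[i]]] <- m
    else out[[nm[i]]]$patterns <- unique(c(out[[nm[i]]]$patterns, m$patterns))
  }
  out
}

#' Scan a sequence for motif matches
#'
#' Reports every 0-based start offset at which some pattern of the motif is
#' compatible with the sequence (overlapping matches included; union over
#' patterns, deduplicated). `N` in the sequence matches nothing.
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param m a [motif()].
#' @return sorted integer vector of 0-based match start offsets.
#' @export
scan_motif <- function(sequence, m) {
  stopifnot(inherits(m, "motif"), length(sequence) == 1)
  .scan_many(chartr("Uu", "Tt", toupper(sequence)), m)[[1]]
}

# batch scan: list of 0-based offset vectors, one per sequence; `seqs` may
# already be a DNAStringSet. An N in the subject is incompatible with every
# pattern position (Biostrings would let ambiguity codes match it), so
# matches whose window overlaps an N are dropped.
.scan_many <- function(seqs, m) {
  subj <- if (methods::is(seqs, "DNAStringSet")) seqs
          else Biostrings::DNAStringSet(seqs)
  acc <- vector("list", length(subj))
  has_n <- Biostrings::vcountPattern("N", subj, fixed = TRUE) > 0
  npos <- vector("list", length(subj))
  if (any(has_n))
    npos[has_n] <- lapply(Biostrings::startIndex(
      Biostrings::vmatchPattern("N", subj[has_n], fixed = TRUE)),
      function(v) v - 1L)
  wid <- Biostrings::width(subj)
  for (p in m$patterns) {
    L <- nchar(p)
    if (L > max(wid)) next
    ok <- L <= wid
    idx <- vector("list", length(subj))
    idx[ok] <- Biostrings::startIndex(
      Biostrings::vmatchPattern(p, subj[ok], fixed = "subject"))
    for (i in seq_along(acc)) {
      v <- idx[[i]]
      if (is.null(v)) next
      v <- v - 1L
      if (has_n[i] && length(v))
        v <- v[vapply(v, function(s)
          !any(npos[[i]] >= s & npos[[i]] < s + L), logical(1))]
      if (length(v)) acc[[i]] <- c(acc[[i]], v)
    }
  }
  lapply(acc, function(v) if (is.null(v)) integer(0) else sort(unique(v)))
}

#' Sliding-window counts of match offsets
#'
#' Windows are `[i, i + window_width)` for `i = 0, step, 2*step, ...` with
#' exactly `region_length - window_width` windows at step 1 (the package
#' convention; the final full window starting at `region_length -
#' window_width` is not part of the family). A match is counted in a window
#' when its start offset lies inside the window.
#'
#' @param match_offsets 0-based match start offsets.
#' @param region_length region length in nt.
#' @param window_width window width in nt (default 50).
#' @param step window step in nt (default 1).
#' @return integer vector of per-window counts, named by window offset.
#' @export
window_counts <- function(match_offsets, region_length, window_width = 50L,
                          step = 1L) {
  if (window_width >= region_length)
    stop("window_width must be smaller than region_length", call. = FALSE)
  if (length(match_offsets) &&
      (min(match_offsets) < 0 || max(match_offsets) >= region_length))
    stop("match offsets outside the region", call. = FALSE)
  starts <- window_offsets(region_length, window_width, step)
  cnt <- tabulate(match_offsets + 1L, nbins = region_length)
  cum <- c(0L, cumsum(cnt))
  out <- cum[pmin(starts + window_width, region_length) + 1L] - cum[starts + 1L]
  names(out) <- starts
  out
}

#' Window start offsets of the sliding-window family
#'
#' @inheritParams window_counts
#' @return integer vector of 0-based window start offsets
#'   (`0, step, ..., < region_length - window_width`).
#' @export
window_offsets <- function(region_length, window_width = 50L, step = 1L) {
  stopifnot(step >= 1, window_width < region_length)
  seq.int(0L, region_length - window_width - 1L, by = step)
}

#' Build per-motif, per-region window-count matrices
#'
#' For each motif and each region label, scans all valid region sequences and
#' assembles an events-by-windows count matrix. All valid sequences must have
#' equal length.
#'
#' @param regions output of [build_regions()] (invalid rows are dropped).
#' @param motifs list of [motif()] objects.
#' @param window_width,step sliding-window geometry.
#' @return named list (`motif|region`) of `window_count_matrix` objects:
#'   `list(motif, region, window_width, step, window_offsets, event_ids,
#'   counts)`.
#' @export
build_count_matrices <- function(regions, motifs, window_width = 50L,
                                 step = 1L) {
  reg <- regions[regions$valid, , drop = FALSE]
  if (!nrow(reg)) stop("no valid regions", call. = FALSE)
  lens <- unique(nchar(reg$seq))
  if (length(lens) != 1)
    stop("mixed region lengths: ", paste(lens, collapse = ", "), call. = FALSE)
  L <- lens
  offs <- window_offsets(L, window_width, step)
  out <- list()
  for (lab in unique(reg$region)) {
    rr <- reg[reg$region == lab, , drop = FALSE]
    subj <- Biostrings::DNAStringSet(rr$seq)
    for (m in motifs) {
      matches <- .scan_many(subj, m)
      counts <- matrix(0L, nrow = length(matches), ncol = length(offs))
      for (r in which(lengths(matches) > 0L))
        counts[r, ] <- window_counts(matches[[r]], L, window_width, step)
      rownames(counts) <- rr$event_id
      key <- paste0(m$name, "|", lab)
      out[[key]] <- structure(
        list(motif = m$name, region = lab, window_width = as.integer(window_width),
             step = as.integer(step), window_offsets = offs,
             event_ids = rr$event_id, counts = counts),
        class = "window_count_matrix")
    }
  }
  out
}
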