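# Strand-aware extraction of the four analysis regions flanking each cassette
# exon. All regions are reported in transcript orientation (pre-mRNA 5'->3');
# each one is `intronic_flank + exonic_flank` nt long (300 by default):
#
#   R1  upstream-exon 3' end (50 nt)   + upstream-intron 5' start (250 nt)
#   R2  upstream-intron 3' end (250)   + cassette-exon 5' start (50)
#   R3  cassette-exon 3' end (50)      + downstream-intron 5' start (250)
#   R4  downstream-intron 3' end (250) + downstream-exon 5' start (50)
#
# On the minus strand "upstream" follows the transcript, so the genomic roles
# of the two flanking introns swap and all sequences are reverse-complemented.

.region_labels <- c("R1", "R2", "R3", "R4")

#' Region geometry around a cassette exon
#'
#' @param exonic_flank nt taken from the exon side of each splice site
#'   (default 50).
#' @param intronic_flank nt taken from the intron side (default 250).
#' @return an object of class `region_spec`; region length is
#'   `exonic_flank + intronic_flank`.
#' @export
region_spec <- function(exonic_flank = 50L, intronic_flank = 250L) {
  stopifnot(exonic_flank > 0, intronic_flank > 0)
  structure(list(exonic_flank = as.integer(exonic_flank),
                 intronic_flank = as.integer(intronic_flank),
                 region_length = as.integer(exonic_flank + intronic_flank)),
            class = "region_spec")
}

#' Load a genome FASTA into a sequence store
#'
#' Reads a (multi-)FASTA into a `DNAStringSet`; sequences are upper-cased and
#' RNA `U` is mapped to `T`. Duplicate contig names are an error.
#'
#' @param fasta_path path to the FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by contig name.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path, call. = FALSE)
  raw <- Biostrings::readBStringSet(fasta_path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate contig names in FASTA: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  chr <- toupper(as.character(raw))
  chr <- chartr("U", "T", chr)
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(raw)
  out
}

#' Query a subsequence from a genome store
#'
#' 0-based half-open coordinates; minus-strand queries return the reverse
#' complement. Out-of-bounds queries are an error.
#'
#' @param genome a `DNAStringSet` from [load_genome()].
#' @param chrom contig name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return character scalar, the requested sequence 5'->3' on the requested
#'   strand.
#' @export
genome_subseq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom, call. = FALSE)
  len <- Biostrings::width(genome[chrom])
  if (start < 0 || end > len || start >= end)
    stop(sprintf("interval [%d, %d) outside contig %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# genomic (0-based half-open) intervals of the four regions of every event,
# plus the intron whose length gates validity; exon_ok records whether the
# exonic flank fits where that can be checked (the cassette exon for R2/R3).
# On the minus strand the transcript-upstream side is the genomic-right side.
.region_coords <- function(events, spec) {
  xf <- spec$exonic_flank; nf <- spec$intronic_flank
  es <- events$exon_start; ee <- events$exon_end
  ue <- events$upstream_exon_end; ds <- events$downstream_exon_start
  exon_ok <- (ee - es) >= xf
  up_intron <- es - ue          # genomic-left intron
  down_intron <- ds - ee        # genomic-right intron
  plus <- events$strand == "+"
  n <- nrow(events)
  blk <- function(sp, sm, ep, em, ip, im, eo) {
    data.frame(start = ifelse(plus, sp, sm), end = ifelse(plus, ep, em),
               intron_len = ifelse(plus, ip, im), exon_ok = eo,
               stringsAsFactors = FALSE)
  }
  co <- rbind(
    cbind(region = "R1", blk(ue - xf, ds - nf, ue + nf, ds + xf,
                             up_intron, down_intron, TRUE)),
    cbind(region = "R2", blk(es - nf, ee - xf, es + xf, ee + nf,
                             up_intron, down_intron, exon_ok)),
    cbind(region = "R3", blk(ee - xf, es - nf, ee + nf, es + xf,
                             down_intron, up_intron, exon_ok)),
    cbind(region = "R4", blk(ds - nf, ue - xf, ds + xf, ue + nf,
                             down_intron, up_intron, TRUE)))
  co$event_id <- rep(events$event_id, 4)
  co$chrom <- rep(events$chrom, 4)
  co$strand <- rep(events$strand, 4)
  co$ord <- rep(seq_len(n), 4)
  co <- co[order(co$ord, co$region), , drop = FALSE]
  co$ord <- NULL
  co
}

#' Build the four analysis regions for one cassette exon
#'
#' @param event one row of a `splicing_events` data.frame (SE type).
#' @param genome a `DNAStringSet` from [load_genome()].
#' @param spec a [region_spec()].
#' @return a data.frame with columns `event_id, region, seq, valid`; invalid
#'   regions (flanking intron shorter than `intronic_flank`, cassette exon
#'   shorter than `exonic_flank`, or interval outside the contig) carry
#'   `NA` sequence.
#' @export
build_event_regions <- function(event, genome, spec = region_spec()) {
  stopifnot(nrow(event) == 1)
  build_regions(event, genome, spec)
}

#' Build analysis regions for a set of cassette exon events
#'
#' Vectorized form of [build_event_regions()]: four rows per event.
#'
#' @param events a `splicing_events` data.frame, SE events only.
#' @param genome a `DNAStringSet` from [load_genome()].
#' @param spec a [region_spec()].
#' @return a data.frame with columns `event_id, region, seq, valid`.
#' @export
build_regions <- function(events, genome, spec = region_spec()) {
  if (any(events$event_type != "SE"))
    stop("regions are defined for SE (cassette exon) events only", call. = FALSE)
  if (any(is.na(events$upstream_exon_end)) ||
      any(is.na(events$downstream_exon_start)))
    stop("flanking intron boundaries required", call. = FALSE)
  if (!all(events$chrom %in% names(genome)))
    stop("event contig(s) absent from genome: ",
         paste(setdiff(unique(events$chrom), names(genome)), collapse = ", "),
         call. = FALSE)
  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  chr_str <- stats::setNames(as.character(genome), names(genome))

  co <- .region_coords(events, spec)
  co$valid <- co$exon_ok & co$intron_len >= spec$intronic_flank &
    co$start >= 0 & co$end <= clen[co$chrom]
  co$seq <- NA_character_
  v <- which(co$valid)
  if (length(v)) {
    co$seq[v] <- substr(chr_str[co$chrom[v]], co$start[v] + 1L, co$end[v])
    neg <- v[co$strand[v] == "-"]
    if (length(neg)) {
      rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(co$seq[neg]))
      co$seq[neg] <- as.character(rc)
    }
  }
  out <- co[, c("event_id", "region", "seq", "valid", "chrom", "strand",
                "start", "end")]
  rownames(out) <- NULL
  attr(out, "region_spec") <- spec
  out
}

#' Export region genomic intervals as BED6
#'
#' One line per valid region, 0-based half-open, name `eventid|region`,
#' score 0, strand column set.
#'
#' @param regions output of [build_regions()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  v <- regions[regions$valid, , drop = FALSE]
  bed <- data.frame(v$chrom, v$start, v$end,
                    paste0(v$event_id, "|", v$region), 0L, v$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
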