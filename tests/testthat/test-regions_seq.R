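rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_str <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

write_fasta <- function(named_seqs, path) {
  writeLines(unlist(lapply(names(named_seqs), function(n)
    c(paste0(">", n), named_seqs[[n]]))), path)
  path
}

test_that("genome loading maps U to T, upper-cases, and rejects duplicate contigs", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = "acgu", c2 = "ACGT"), tmp)
  g <- load_genome(tmp)
  expect_equal(as.character(g[["c1"]]), "ACGT")
  write_fasta(list(c1 = "ACGT", c1 = "ACGT"), tmp)
  expect_error(load_genome(tmp), "duplicate contig")
})

test_that("subsequence queries are 0-based half-open and strand-aware", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = "ACGT"), tmp)
  g <- load_genome(tmp)
  expect_equal(genome_subseq(g, "c1", 0, 4, "+"), "ACGT")
  expect_equal(genome_subseq(g, "c1", 0, 4, "-"), "ACGT")  # palindromic
  expect_equal(genome_subseq(g, "c1", 1, 3, "-"), "CG")    # revcomp of CG
  expect_error(genome_subseq(g, "c1", 0, 5, "+"), "outside contig")
  expect_error(genome_subseq(g, "c9", 0, 2, "+"), "unknown contig")
})

# shared layout: exon1[0,100) intron[100,400) cassette[400,500) intron[500,800)
# exon3[800,900)
layout_events <- function(strand) {
  make_events(strand = strand, exon_start = 400L, exon_end = 500L,
              upstream_exon_end = 100L, downstream_exon_start = 800L,
              chrom = "c1")
}

test_that("plus-strand regions tile the splice sites as intron/exon flanks", {
  gseq <- rand_seq(900, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = gseq), tmp)
  g <- load_genome(tmp)
  rr <- build_event_regions(layout_events("+"), g)
  expect_equal(nrow(rr), 4)
  expect_true(all(rr$valid))
  expect_equal(unique(nchar(rr$seq)), 300)
  # R2 = last 250 nt of upstream intron + first 50 nt of cassette exon
  expect_equal(rr$seq[rr$region == "R2"], substr(gseq, 151, 450))
  expect_equal(rr$seq[rr$region == "R1"], substr(gseq, 51, 350))
  expect_equal(rr$seq[rr$region == "R3"], substr(gseq, 451, 750))
  expect_equal(rr$seq[rr$region == "R4"], substr(gseq, 551, 850))
})

test_that("minus-strand regions follow transcript orientation with swapped introns", {
  gseq <- rand_seq(900, seed = 6)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = gseq), tmp)
  g <- load_genome(tmp)
  rr <- build_event_regions(layout_events("-"), g)
  expect_true(all(rr$valid))
  # transcript-upstream intron is the genomic-right one: R2 covers the exon
  # 3'-boundary-in-genome side, reverse-complemented
  expect_equal(rr$seq[rr$region == "R2"], revcomp_str(substr(gseq, 451, 750)))
  expect_equal(rr$seq[rr$region == "R1"], revcomp_str(substr(gseq, 551, 850)))
  expect_equal(rr$seq[rr$region == "R3"], revcomp_str(substr(gseq, 151, 450)))
  expect_equal(rr$seq[rr$region == "R4"], revcomp_str(substr(gseq, 51, 350)))
})

test_that("regions touching a too-short intron or contig edge are dropped, not padded", {
  gseq <- rand_seq(900, seed = 7)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = gseq), tmp)
  g <- load_genome(tmp)
  # 40-nt upstream intron: R1 and R2 invalid on the plus strand
  ev <- make_events(strand = "+", exon_start = 400L, exon_end = 500L,
                    upstream_exon_end = 360L, downstream_exon_start = 800L,
                    chrom = "c1")
  rr <- build_event_regions(ev, g)
  expect_identical(rr$valid, c(FALSE, FALSE, TRUE, TRUE))
  expect_true(all(is.na(rr$seq[!rr$valid])))
  expect_equal(unique(nchar(rr$seq[rr$valid])), 300)
  # narrow cassette exon: exonic flank does not fit in R2/R3
  ev2 <- make_events(strand = "+", exon_start = 400L, exon_end = 430L,
                     upstream_exon_end = 100L, downstream_exon_start = 800L,
                     chrom = "c1")
  rr2 <- build_event_regions(ev2, g)
  expect_identical(rr2$valid, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("non-SE events and unknown contigs are rejected", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = rand_seq(900, 8)), tmp)
  g <- load_genome(tmp)
  ev <- layout_events("+")
  ev$event_type <- "RI"
  expect_error(build_event_regions(ev, g), "SE")
  ev2 <- layout_events("+")
  ev2$chrom <- "c9"
  expect_error(build_event_regions(ev2, g), "absent from genome")
})

test_that("a motif planted in region coordinates is recovered after extraction, both strands", {
  # plant TGCATG at region-R2 offset 100 through the generator machinery and
  # re-find it through the independent region-extraction path
  cfg <- synthetic_config(n_regulated = 12, n_background = 0, seed = 33,
                          planting = list(list(pattern = "TGCATG",
                                               region = "R2",
                                               offset_range = c(100L, 100L),
                                               p_reg = 1, p_bg = 0)))
  d <- generate_dataset(cfg)
  rr <- build_regions(d$events, d$genome)
  r2 <- rr[rr$region == "R2", ]
  m <- motif("RBFOX", "TGCATG")
  hits <- lapply(r2$seq, scan_motif, m = m)
  expect_true(all(vapply(hits, function(h) 100L %in% h, logical(1))))
  expect_setequal(unique(d$events$strand), c("+", "-"))
  expect_equal(unique(nchar(rr$seq[rr$valid])), 300)
})

test_that("BED export writes valid regions as 0-based half-open intervals", {
  gseq <- rand_seq(900, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(c1 = gseq), tmp)
  rr <- build_event_regions(layout_events("+"), load_genome(tmp))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(rr, bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(nrow(b), 4)
  expect_equal(b$V2[b$V4 == "T001|R2"], 150)
  expect_equal(b$V3[b$V4 == "T001|R2"], 450)
  expect_equal(unique(b$V6), "+")
})
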