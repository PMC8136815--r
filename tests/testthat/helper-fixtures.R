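# shared fixtures, all built in code

toy_table <- function() {
  system.file("extdata", "toy_SE.tsv", package = "splicemaps")
}

example_compendium <- function() {
  load_compendium(system.file("extdata", "rbp_motifs.tsv",
                              package = "splicemaps"))
}

# minimal in-memory splicing_events table; per-argument lists give replicate
# vectors, scalars are recycled
make_events <- function(n = 1, inc_g1 = list(c(10L, 10L)),
                        skip_g1 = list(c(5L, 5L)),
                        inc_g2 = list(c(10L, 10L)),
                        skip_g2 = list(c(5L, 5L)),
                        psi_g1 = list(c(0.6, 0.6)),
                        psi_g2 = list(c(0.5, 0.5)),
                        fdr = 0.01, delta_psi = NULL, strand = "+",
                        exon_start = 750L, exon_end = 870L,
                        upstream_exon_end = 150L,
                        downstream_exon_start = 1470L,
                        chrom = NULL, event_id = NULL) {
  rep_list <- function(x) if (length(x) == n) x else rep(x, length.out = n)
  ev <- data.frame(
    event_id = event_id %||% sprintf("T%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    event_type = "SE",
    chrom = chrom %||% "chr1",
    strand = rep(strand, length.out = n),
    exon_start = rep(exon_start, length.out = n),
    exon_end = rep(exon_end, length.out = n),
    upstream_exon_end = rep(upstream_exon_end, length.out = n),
    downstream_exon_start = rep(downstream_exon_start, length.out = n),
    stringsAsFactors = FALSE)
  ev$inc_g1 <- I(rep_list(inc_g1)); ev$skip_g1 <- I(rep_list(skip_g1))
  ev$inc_g2 <- I(rep_list(inc_g2)); ev$skip_g2 <- I(rep_list(skip_g2))
  ev$psi_g1 <- I(rep_list(psi_g1)); ev$psi_g2 <- I(rep_list(psi_g2))
  ev$pvalue <- rep(fdr, length.out = n) / 2
  ev$fdr <- rep(fdr, length.out = n)
  ev$delta_psi <- if (is.null(delta_psi)) {
    vapply(seq_len(n), function(r)
      mean(ev$psi_g1[[r]]) - mean(ev$psi_g2[[r]]), numeric(1))
  } else rep(delta_psi, length.out = n)
  class(ev) <- c("splicing_events", "data.frame")
  ev
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fast generator configuration used by pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  synthetic_config(n_regulated = 40L, n_background = 120L, seed = seed, ...)
}

# independent naive evaluation of the Simes bound over all intervals
naive_interval_bounds <- function(p, alpha, m = length(p)) {
  n <- length(p)
  res <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      S <- p[i:j]
      k <- seq_along(S)
      counts <- vapply(alpha * k / m, function(t) sum(S > t), integer(1))
      vbar <- min(min(counts + k - 1L), length(S))
      res[[length(res) + 1L]] <- c(i = i - 1L, j = j - 1L, vbar = vbar)
    }
  }
  do.call(rbind, res)
}

# regex-based motif scan oracle (overlapping matches via lookahead)
regex_scan_oracle <- function(sequence, patterns) {
  iupac_re <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  hits <- integer(0)
  for (p in patterns) {
    re <- paste(iupac_re[strsplit(chartr("U", "T", toupper(p)), "")[[1]]],
                collapse = "")
    g <- gregexpr(paste0("(?=", re, ")"), sequence, perl = TRUE)[[1]]
    if (g[1] != -1) hits <- c(hits, as.integer(g) - 1L)
  }
  sort(unique(hits))
}
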