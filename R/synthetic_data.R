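# Seeded synthetic data: rMATS-style event tables plus a matching genome with
# motifs planted at known positions, and the full ground truth needed to
# validate every pipeline stage. One contig per event, laid out
# exon - intron - cassette - intron - exon; motif instances are substituted in
# place (sequence length never changes, so the window family stays uniform).

.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Synthetic dataset configuration
#'
#' Defaults describe the standard validation scenario: 300 regulated and
#' 1000 background cassette exons, the RBFOX element `TGCATG` planted in the
#' proximal upstream intron (region R2, offsets 0-200) in 60% of regulated
#' and 10% of background events, 6 replicates per group, replicate PSI drawn
#' from a Beta around the group mean (concentration 50), and per-replicate
#' read depth from a negative binomial (mean 80, dispersion 0.2) split into
#' inclusion/skipping reads by the replicate PSI.
#'
#' @param n_regulated,n_background event counts per class.
#' @param seed integer seed; the generator derives one substream per event
#'   from it, so identical seeds give bit-identical output.
#' @param base_composition probabilities of A, C, G, T in background
#'   sequence (default uniform).
#' @param flank_exon_len,intron_len,cassette_len contig geometry in nt.
#' @param planting list of planting rules, each a list with elements
#'   `pattern` (IUPAC string), `region` (`"R1"`..`"R4"`), `offset_range`
#'   (inclusive 0-based range of the planted start in region coordinates),
#'   `p_reg`, `p_bg` (per-event insertion probabilities in the regulated and
#'   background class). `NULL` disables planting (null data).
#' @param n_replicates replicates per group (default 6: enough for the exact
#'   rank test on replicate PSIs to reach Benjamini-Hochberg significance at
#'   FDR 0.05).
#' @param effect_floor minimum |dPSI| of regulated events (default 0.2;
#'   effects are drawn uniformly from `[effect_floor, effect_floor + 0.2]`).
#' @param bg_delta_sd sd of the (null) dPSI noise of background events
#'   (default 0.02).
#' @param psi_concentration Beta concentration of replicate PSI around the
#'   group mean (default 50).
#' @param depth_mean,depth_dispersion negative-binomial read depth per
#'   replicate (mean 80, dispersion 0.2).
#' @param spec the [region_spec()] the planted offsets refer to.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regulated = 300L, n_background = 1000L,
                             seed = 1L,
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             flank_exon_len = 150L, intron_len = 600L,
                             cassette_len = 120L,
                             planting = list(list(pattern = "TGCATG",
                                                  region = "R2",
                                                  offset_range = c(0L, 200L),
                                                  p_reg = 0.6, p_bg = 0.1)),
                             n_replicates = 6L,
                             effect_floor = 0.2, bg_delta_sd = 0.02,
                             psi_concentration = 50,
                             depth_mean = 80, depth_dispersion = 0.2,
                             spec = region_spec()) {
  stopifnot(n_regulated >= 0, n_background >= 0,
            abs(sum(base_composition) - 1) < 1e-8, all(base_composition >= 0),
            flank_exon_len > 0, intron_len > 0, cassette_len > 0,
            n_replicates >= 2, effect_floor > 0, effect_floor + 0.2 <= 0.9,
            psi_concentration > 0, depth_mean > 0, depth_dispersion > 0)
  if (intron_len < spec$intronic_flank)
    stop("intron_len must be >= the intronic flank of the region spec",
         call. = FALSE)
  if (cassette_len < spec$exonic_flank)
    stop("cassette_len must be >= the exonic flank of the region spec",
         call. = FALSE)
  if (!is.null(planting)) {
    for (pl in planting) {
      stopifnot(all(c("pattern", "region", "offset_range", "p_reg", "p_bg")
                    %in% names(pl)))
      if (!pl$region %in% .region_labels)
        stop("unknown region label: ", pl$region, call. = FALSE)
      L <- nchar(pl$pattern)
      if (pl$offset_range[1] < 0 ||
          pl$offset_range[2] + L > spec$region_length)
        stop(sprintf(
          "planting range [%d, %d] incompatible with region geometry (length %d, motif %d nt)",
          pl$offset_range[1], pl$offset_range[2], spec$region_length, L),
          call. = FALSE)
      stopifnot(pl$p_reg >= 0, pl$p_reg <= 1, pl$p_bg >= 0, pl$p_bg <= 1)
      motif(pl$region, pl$pattern)  # validates IUPAC codes
    }
  }
  structure(list(n_regulated = as.integer(n_regulated),
                 n_background = as.integer(n_background),
                 seed = as.integer(seed),
                 base_composition = base_composition,
                 flank_exon_len = as.integer(flank_exon_len),
                 intron_len = as.integer(intron_len),
                 cassette_len = as.integer(cassette_len),
                 planting = planting, n_replicates = as.integer(n_replicates),
                 effect_floor = effect_floor, bg_delta_sd = bg_delta_sd,
                 psi_concentration = psi_concentration,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 spec = spec),
            class = "synthetic_config")
}

# deterministic per-event substream seed
.event_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 59999L * 2654435L + i * 9973L) %% 2147483647L)
}

#' Plant a motif instance into a sequence by substitution
#'
#' Replaces `[offset, offset + nchar(pattern))` (0-based) with a concrete
#' instance of the (possibly degenerate) pattern; degenerate positions are
#' resolved uniformly at random among compatible bases using the current
#' RNG state. The sequence length is unchanged.
#'
#' @param sequence DNA string.
#' @param pattern IUPAC pattern (U mapped to T).
#' @param offset 0-based start of the substitution.
#' @return the modified sequence.
#' @export
plant_motif <- function(sequence, pattern, offset) {
  pattern <- chartr("Uu", "Tt", toupper(pattern))
  L <- nchar(pattern)
  if (offset < 0 || offset + L > nchar(sequence))
    stop("planting offset out of range", call. = FALSE)
  inst <- .resolve_iupac(pattern)
  paste0(substr(sequence, 1, offset), inst,
         substr(sequence, offset + L + 1, nchar(sequence)))
}

.resolve_iupac <- function(pattern) {
  ch <- strsplit(pattern, "")[[1]]
  paste(vapply(ch, function(cc) {
    set <- .iupac_sets[[cc]]
    if (is.null(set)) stop("invalid IUPAC code: ", cc, call. = FALSE)
    if (length(set) == 1) set else sample(set, 1)
  }, character(1)), collapse = "")
}

# genomic (start, end, use_revcomp) of region-coordinate interval
# [o, o + L) for the standard contig geometry; independent of build_regions
.plant_genomic <- function(region, strand, o, L, geom, spec) {
  xf <- spec$exonic_flank; nf <- spec$intronic_flank
  ue <- geom$ue; es <- geom$es; ee <- geom$ee; ds <- geom$ds
  if (strand == "+") {
    gs <- switch(region, R1 = ue - xf, R2 = es - nf, R3 = ee - xf,
                 R4 = ds - nf)
    list(start = gs + o, revcomp = FALSE)
  } else {
    ge <- switch(region, R1 = ds + xf, R2 = ee + nf, R3 = es + xf,
                 R4 = ue + nf)
    list(start = ge - o - L, revcomp = TRUE)
  }
}

.revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Generate a synthetic splicing dataset with planted motifs
#'
#' Produces an rMATS-style SE event table, a matching genome (one contig per
#' event) and a ground-truth record. Replicate PSI values are drawn from the
#' Beta PSI model, read counts from the negative-binomial depth model split
#' by PSI, reported PSI is the observed inclusion fraction (rounded to 3
#' decimals, as in rMATS output), the per-event p-value comes from a
#' two-sided rank test of the group-1 vs group-2 replicate PSIs, and FDR is
#' Benjamini-Hochberg across events. Identical seeds give bit-identical
#' output.
#'
#' @param config a [synthetic_config()].
#' @param out_dir if non-`NULL`, write `events_SE.tsv`, `genome.fa` and
#'   `truth.json` there.
#' @return list with `events` (a `splicing_events` data.frame), `genome`
#'   (a `DNAStringSet`), `truth` (regulated ids, planted offsets in region
#'   coordinates, group PSI means, seed) and, when written, `paths`.
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_regulated + config$n_background
  if (n == 0) stop("empty configuration", call. = FALSE)
  F_ <- config$flank_exon_len; I_ <- config$intron_len
  C_ <- config$cassette_len
  geom <- list(ue = F_, es = F_ + I_, ee = F_ + I_ + C_,
               ds = F_ + 2L * I_ + C_)
  contig_len <- 2L * F_ + 2L * I_ + C_
  nrep <- config$n_replicates
  bases <- c("A", "C", "G", "T")

  ids <- sprintf("EV%05d", seq_len(n))
  regulated <- seq_len(n) <= config$n_regulated

  seqs <- character(n)
  strand <- character(n)
  psi1 <- vector("list", n); psi2 <- vector("list", n)
  inc1 <- vector("list", n); skip1 <- vector("list", n)
  inc2 <- vector("list", n); skip2 <- vector("list", n)
  mu1v <- numeric(n); mu2v <- numeric(n)
  pval <- numeric(n)
  planted <- list()

  for (i in seq_len(n)) {
    set.seed(.event_seed(config$seed, i))
    strand[i] <- sample(c("+", "-"), 1)
    s <- paste(sample(bases, contig_len, replace = TRUE,
                      prob = config$base_composition), collapse = "")
    # motif planting (substitution in place)
    if (!is.null(config$planting)) {
      for (pl in config$planting) {
        pr <- if (regulated[i]) pl$p_reg else pl$p_bg
        if (pr > 0 && runif(1) < pr) {
          rng <- pl$offset_range
          o <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
          L <- nchar(pl$pattern)
          inst <- .resolve_iupac(chartr("Uu", "Tt", toupper(pl$pattern)))
          g <- .plant_genomic(pl$region, strand[i], o, L, geom, config$spec)
          piece <- if (g$revcomp) .revcomp_chr(inst) else inst
          s <- paste0(substr(s, 1, g$start), piece,
                      substr(s, g$start + L + 1, contig_len))
          planted[[length(planted) + 1L]] <-
            data.frame(event_id = ids[i], region = pl$region, offset = o,
                       pattern = pl$pattern, instance = inst,
                       stringsAsFactors = FALSE)
        }
      }
    }
    seqs[i] <- s

    # PSI model
    if (regulated[i]) {
      m <- runif(1, 0.25, 0.75)
      e <- runif(1, config$effect_floor, config$effect_floor + 0.2)
      sg <- sample(c(-1, 1), 1)
      mu1 <- m + sg * e / 2; mu2 <- m - sg * e / 2
    } else {
      m <- runif(1, 0.2, 0.8)
      d <- rnorm(1, 0, config$bg_delta_sd)
      mu1 <- min(max(m + d / 2, 0.01), 0.99)
      mu2 <- min(max(m - d / 2, 0.01), 0.99)
    }
    mu1v[i] <- mu1; mu2v[i] <- mu2
    cc <- config$psi_concentration
    true_psi1 <- rbeta(nrep, mu1 * cc, (1 - mu1) * cc)
    true_psi2 <- rbeta(nrep, mu2 * cc, (1 - mu2) * cc)

    # depth model: NB total reads, split inclusion/skipping by replicate PSI
    size <- 1 / config$depth_dispersion
    t1 <- as.integer(rnbinom(nrep, size = size, mu = config$depth_mean))
    t2 <- as.integer(rnbinom(nrep, size = size, mu = config$depth_mean))
    i1 <- as.integer(rbinom(nrep, t1, true_psi1))
    i2 <- as.integer(rbinom(nrep, t2, true_psi2))
    inc1[[i]] <- i1; skip1[[i]] <- t1 - i1
    inc2[[i]] <- i2; skip2[[i]] <- t2 - i2
    p1 <- ifelse(t1 > 0, round(i1 / t1, 3), NA_real_)
    p2 <- ifelse(t2 > 0, round(i2 / t2, 3), NA_real_)
    psi1[[i]] <- p1; psi2[[i]] <- p2

    x <- p1[!is.na(p1)]; y <- p2[!is.na(p2)]
    pval[i] <- if (length(x) && length(y))
      wilcoxon_rank_sum(x, y, alternative = "two_sided",
                        exact_max_n = 2L * nrep)$p_value else NA_real_
  }

  fdr <- p.adjust(pval, method = "BH")
  delta <- vapply(seq_len(n), function(i)
    mean(psi1[[i]], na.rm = TRUE) - mean(psi2[[i]], na.rm = TRUE), numeric(1))

  events <- data.frame(
    event_id = ids, gene_id = sprintf("GENE%05d", seq_len(n)),
    event_type = "SE", chrom = paste0("ctg_", ids), strand = strand,
    exon_start = geom$es, exon_end = geom$ee,
    upstream_exon_end = geom$ue, downstream_exon_start = geom$ds,
    stringsAsFactors = FALSE)
  events$inc_g1 <- I(inc1); events$skip_g1 <- I(skip1)
  events$inc_g2 <- I(inc2); events$skip_g2 <- I(skip2)
  events$psi_g1 <- I(psi1); events$psi_g2 <- I(psi2)
  events$pvalue <- pval; events$fdr <- fdr; events$delta_psi <- delta
  events <- .as_events(events)

  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- events$chrom

  planted_df <- if (length(planted)) do.call(rbind, planted) else
    data.frame(event_id = character(0), region = character(0),
               offset = integer(0), pattern = character(0),
               instance = character(0), stringsAsFactors = FALSE)
  truth <- list(seed = config$seed,
                regulated_ids = ids[regulated],
                planted = planted_df,
                group_psi_means = data.frame(event_id = ids, mu_g1 = mu1v,
                                             mu_g2 = mu2v,
                                             stringsAsFactors = FALSE))

  out <- list(events = events, genome = genome, truth = truth,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(events = file.path(out_dir, "events_SE.tsv"),
                  genome = file.path(out_dir, "genome.fa"),
                  truth = file.path(out_dir, "truth.json"))
    write_events(events, paths$events)
    Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
    jsonlite::write_json(list(seed = truth$seed,
                              regulated_ids = truth$regulated_ids,
                              planted = truth$planted,
                              group_psi_means = truth$group_psi_means),
                         paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
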