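## Synthetic study generator: genome, gene models, exclusion tracks, and
## multi-sample RNA/DNA alignments with planted ground truth.
##
## The generator emulates the statistical structure the caller assumes:
## spliced RNA reads from mature transcripts (junction reads carry N
## CIGARs) plus a per-tissue intron-retention fraction, planted A-to-I
## edits carried by overlapping RNA reads at designed per-tissue
## frequencies, germline het/hom SNPs carried by both RNA and DNA reads,
## independent base-call errors with degraded qualities, a small fraction
## of multi-mapping (NH=2) and low-quality reads to exercise the read
## filters, and uniform whole-genome DNA coverage. Same seed, same bytes.

#' Simulation configuration
#'
#' Defaults describe the package's standard toy study: a 1 Mb two-
#' chromosome genome carrying 40 genes, six RNA tissues at 15-40X
#' transcript coverage, two 30X whole-genome DNA samples (pooled 60X, so
#' the >20X subtraction depth holds with margin), 200 planted edits at
#' frequencies 0.1-1.0 and 100 germline SNPs, 75 bp single-end reads with
#' base-call errors at 0.001 (Q30-scale) and constant Q30 qualities with
#' errored bases at U{10..35}. Intron retention is elevated in "brain"
#' (0.30 vs 0.05) so intronic editing is preferentially detectable there.
#'
#' @param seed integer master seed; all randomness flows from it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes; error if they cannot be placed.
#' @param exons_per_gene integer range.
#' @param exon_size,intron_size bp ranges; the minimum exon size must be
#'   at least `read_length` (a read then spans at most one junction).
#' @param frac_noncoding fraction of genes without CDS.
#' @param tissues RNA sample names (one sample per tissue).
#' @param rna_depth named per-tissue target transcript coverage, or a
#'   2-vector range spread across tissues (highest first).
#' @param dna_depth,n_dna whole-genome samples and their coverage.
#' @param read_length read length in bp.
#' @param intron_retention named per-tissue pre-mRNA read fraction;
#'   unnamed tissues use `intron_retention_default`.
#' @param intron_retention_default see above.
#' @param n_edits,edit_freq_range,frac_intronic_edits,edit_tissue_rate
#'   planted editing design: count, frequency range, intronic fraction,
#'   and per-tissue activity probability (each edit is active in each
#'   tissue independently; at least one tissue always active).
#' @param n_snps,snp_het_frac germline SNPs and their het fraction.
#' @param base_error_rate per-base sequencing error probability.
#' @param base_qual,err_qual_range Phred for correct bases / errored bases.
#' @param low_qual_read_rate fraction of reads emitted with all-Q20
#'   qualities (fail the 70%-at-Q23 read filter).
#' @param multimap_read_rate fraction of reads emitted with NH=2.
#' @param frac_silent per-tissue probability that a gene is unexpressed.
#' @param n_homopolymers,homopolymer_len embedded homopolymer runs.
#' @param n_repeats,repeat_len embedded low-complexity repeats.
#' @param n_multimap,n_self_chain,artifact_len random artifact intervals.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 40L,
                       exons_per_gene = c(3L, 6L),
                       exon_size = c(150L, 400L),
                       intron_size = c(200L, 800L),
                       frac_noncoding = 0.1,
                       tissues = c("brain", "heart", "liver", "spleen",
                                   "kidney", "testis"),
                       rna_depth = c(40, 15),
                       dna_depth = 30, n_dna = 2L,
                       read_length = 75L,
                       intron_retention = c(brain = 0.30),
                       intron_retention_default = 0.05,
                       n_edits = 200L,
                       edit_freq_range = c(0.1, 1.0),
                       frac_intronic_edits = 0.3,
                       edit_tissue_rate = 0.8,
                       n_snps = 100L, snp_het_frac = 0.8,
                       base_error_rate = 0.001,
                       base_qual = 30L, err_qual_range = c(10L, 35L),
                       low_qual_read_rate = 0.02,
                       multimap_read_rate = 0.02,
                       frac_silent = 0.1,
                       n_homopolymers = 30L, homopolymer_len = 8L,
                       n_repeats = 20L, repeat_len = c(200L, 500L),
                       n_multimap = 10L, n_self_chain = 10L,
                       artifact_len = 300L) {
  cfg <- as.list(environment())
  if (cfg$exon_size[1] < cfg$read_length)
    stop("minimum exon size must be >= read_length")
  if (length(cfg$rna_depth) != length(cfg$tissues)) {
    cfg$rna_depth <- round(seq(cfg$rna_depth[1],
                               cfg$rna_depth[length(cfg$rna_depth)],
                               length.out = length(cfg$tissues)))
  }
  if (is.null(names(cfg$rna_depth)))
    names(cfg$rna_depth) <- cfg$tissues
  ret <- rep(cfg$intron_retention_default, length(cfg$tissues))
  names(ret) <- cfg$tissues
  ret[names(cfg$intron_retention)] <- cfg$intron_retention
  cfg$intron_retention <- ret
  structure(cfg, class = "sim_config")
}

rand_interval <- function(range) {
  if (length(range) == 1L || range[1] == range[2]) return(range[1])
  sample(range[1]:range[2], 1L)
}

## build one gene's structure starting at `at` (0-based); returns a
## gene_model or NULL if it would exceed `limit`
build_gene <- function(gid, chrom, at, limit, strand, coding, cfg) {
  n_ex <- rand_interval(cfg$exons_per_gene)
  ex_len <- vapply(seq_len(n_ex), function(i) rand_interval(cfg$exon_size),
                   integer(1))
  in_len <- if (n_ex > 1L)
    vapply(seq_len(n_ex - 1L), function(i) rand_interval(cfg$intron_size),
           integer(1)) else integer(0)
  span <- sum(ex_len) + sum(in_len)
  if (at + span > limit) return(NULL)
  starts <- at + cumsum(c(0L, head(ex_len, -1L) + in_len))
  exons <- cbind(starts, starts + ex_len)
  cds <- matrix(integer(), ncol = 2)
  if (coding) {
    tx_len <- sum(ex_len)
    u5 <- rand_interval(c(30L, min(100L, ex_len[1] - 30L)))
    u3 <- rand_interval(c(30L, min(100L, ex_len[n_ex] - 30L)))
    cds_len <- tx_len - u5 - u3
    u3 <- u3 + cds_len %% 3L  # pad 3' UTR so CDS is a codon multiple
    left <- if (strand == "+") u5 else u3
    right <- if (strand == "+") u3 else u5
    cds <- exons
    cds[1, 1] <- cds[1, 1] + left
    cds[n_ex, 2] <- cds[n_ex, 2] - right
  }
  gene_model(gid, paste0(gid, ".t1"), chrom, strand, exons, cds)
}

#' Simulate a genome with gene models, exclusion tracks and ground truth
#'
#' Generates a uniform-random genome, embeds homopolymer runs and
#' low-complexity repeats, places non-overlapping genes with valid CDS
#' structure, derives the four exclusion tracks (the homopolymer track is
#' the full scan of the finished sequence, so embedded runs are included
#' by construction), and plants the editing/SNP/expression design. Edit
#' positions fall on transcribed-sense adenosines inside genes, away from
#' exclusion tracks, splice-boundary buffers and transcript ends; SNP and
#' edit positions are disjoint.
#'
#' @param config a [sim_config()].
#' @return list: `genome`, `genes`, `tracks` ([exclusion_tracks()]),
#'   `truth` (list of data.tables: `edits` with per-tissue design
#'   frequencies, `snps`, `expression` design weights).
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- Biostrings::DNAStringSet(setNames(vapply(chroms, function(ch)
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = ""), character(1)), chroms))
  seqs <- as.character(genome)
  ## embed homopolymer runs and low-complexity repeats
  for (i in seq_len(cfg$n_homopolymers)) {
    ch <- sample(chroms, 1L)
    p <- sample.int(cfg$chrom_length - cfg$homopolymer_len - 10L, 1L)
    substr(seqs[ch], p + 1L, p + cfg$homopolymer_len) <-
      strrep(sample(c("A", "C", "G", "T"), 1L), cfg$homopolymer_len)
  }
  rep_iv <- list()
  for (i in seq_len(cfg$n_repeats)) {
    ch <- sample(chroms, 1L)
    len <- rand_interval(cfg$repeat_len)
    len <- len + len %% 2L
    p <- sample.int(cfg$chrom_length - len - 10L, 1L)
    substr(seqs[ch], p + 1L, p + len) <- strrep("AT", len %/% 2L)
    rep_iv[[i]] <- data.table(chrom = ch, start = p, end = p + len)
  }
  genome <- Biostrings::DNAStringSet(seqs)
  ## place genes round-robin across chromosomes
  genes <- list()
  margin <- 1000L
  cursor <- setNames(rep(margin, cfg$n_chroms), chroms)
  gi <- 0L
  while (length(genes) < cfg$n_genes) {
    placed <- FALSE
    for (ch in chroms) {
      if (length(genes) >= cfg$n_genes) break
      gi <- gi + 1L
      gid <- sprintf("g%03d", gi)
      at <- cursor[ch] + rand_interval(c(1500L, 4000L))
      g <- build_gene(gid, ch, at, cfg$chrom_length - margin,
                      sample(c("+", "-"), 1L),
                      runif(1) > cfg$frac_noncoding, cfg)
      if (is.null(g)) next
      genes[[length(genes) + 1L]] <- g
      cursor[ch] <- max(g$exons[, 2])
      placed <- TRUE
    }
    if (!placed)
      stop("config error: ", cfg$n_genes, " genes do not fit the genome (",
           length(genes), " placed)")
  }
  ## exclusion tracks
  rand_track <- function(n) {
    if (n == 0L) return(interval_set())
    ch <- sample(chroms, n, replace = TRUE)
    p <- vapply(seq_len(n), function(i)
      sample.int(cfg$chrom_length - cfg$artifact_len - 10L, 1L), integer(1))
    interval_set(ch, p, p + cfg$artifact_len)
  }
  rep_dt <- rbindlist(rep_iv)
  tracks <- exclusion_tracks(
    homopolymer = detect_homopolymers(genome, 5L),
    repeat_masker = if (nrow(rep_dt))
      interval_set(rep_dt$chrom, rep_dt$start, rep_dt$end) else
      interval_set(),
    multimap = rand_track(cfg$n_multimap),
    self_chain = rand_track(cfg$n_self_chain))
  excluded <- function(ch, p) {
    point_in_set(tracks$homopolymer, ch, p) |
      point_in_set(tracks$repeat_masker, ch, p) |
      point_in_set(tracks$multimap, ch, p) |
      point_in_set(tracks$self_chain, ch, p)
  }
  ## candidate edit positions: sense-A, clear of tracks/buffers/ends
  sense_base <- function(strand) if (strand == "+") "A" else "T"
  edge <- 12L  # keeps some supporting bases outside the 10 bp end windows
  exonic_pool <- list(); intronic_pool <- list()
  for (g in genes) {
    exmap <- exon_map(g)
    sseq <- strsplit(genome_slice(genome, rep(g$chrom, nrow(g$exons)),
                                  g$exons[, 1], g$exons[, 2]), NULL)
    tx <- unlist(sseq)
    sc <- which(tx == sense_base(g$strand)) - 1L
    sc <- sc[sc >= edge & sc < exmap$tx_len - edge]
    if (length(sc)) {
      gp <- tx_to_genome(exmap, sc)
      ok <- !excluded(rep(g$chrom, length(gp)), gp)
      if (any(ok))
        exonic_pool[[g$gene_id]] <- data.table(
          chrom = g$chrom, pos = gp[ok], strand = g$strand,
          gene_id = g$gene_id, intronic = FALSE)
    }
    if (nrow(g$introns)) {
      for (j in seq_len(nrow(g$introns))) {
        s <- g$introns[j, 1] + 9L; e <- g$introns[j, 2] - 9L
        if (e <= s) next
        piece <- strsplit(genome_slice(genome, g$chrom, s, e), NULL)[[1]]
        gp <- s + which(piece == sense_base(g$strand)) - 1L
        if (!length(gp)) next
        ok <- !excluded(rep(g$chrom, length(gp)), gp)
        if (any(ok))
          intronic_pool[[paste0(g$gene_id, ".", j)]] <- data.table(
            chrom = g$chrom, pos = gp[ok], strand = g$strand,
            gene_id = g$gene_id, intronic = TRUE)
      }
    }
  }
  exonic_pool <- rbindlist(exonic_pool)
  intronic_pool <- rbindlist(intronic_pool)
  n_int <- min(round(cfg$frac_intronic_edits * cfg$n_edits),
               nrow(intronic_pool))
  n_exo <- min(cfg$n_edits - n_int, nrow(exonic_pool))
  edits <- rbind(
    exonic_pool[sample.int(nrow(exonic_pool), n_exo)],
    if (n_int > 0L) intronic_pool[sample.int(nrow(intronic_pool), n_int)])
  if (nrow(edits) < cfg$n_edits)
    warning("only ", nrow(edits), " of ", cfg$n_edits,
            " edits could be placed")
  edits[, freq := runif(.N, cfg$edit_freq_range[1], cfg$edit_freq_range[2])]
  active <- matrix(runif(nrow(edits) * length(cfg$tissues)) <
                     cfg$edit_tissue_rate,
                   nrow(edits), length(cfg$tissues),
                   dimnames = list(NULL, cfg$tissues))
  none <- rowSums(active) == 0L
  if (any(none))
    active[cbind(which(none),
                 sample.int(length(cfg$tissues), sum(none),
                            replace = TRUE))] <- TRUE
  for (tt in cfg$tissues)
    edits[[paste0("freq_", tt)]] <- edits$freq * active[, tt]
  setkey(edits, chrom, pos)
  ## germline SNPs, disjoint from edits
  snps <- data.table()
  tries <- 0L
  while (nrow(snps) < cfg$n_snps && tries < 50L) {
    tries <- tries + 1L
    need <- cfg$n_snps - nrow(snps)
    ch <- sample(chroms, need, replace = TRUE)
    p <- vapply(seq_len(need), function(i)
      sample.int(cfg$chrom_length - 10L, 1L), integer(1))
    cand <- data.table(chrom = ch, pos = p)
    cand <- cand[!edits[, .(chrom, pos)], on = c("chrom", "pos")]
    if (nrow(snps)) cand <- cand[!snps[, .(chrom, pos)],
                                 on = c("chrom", "pos")]
    cand <- unique(cand)
    if (!nrow(cand)) next
    cand[, ref := genome_base(genome, chrom, pos)]
    cand <- cand[ref != "N"]
    cand[, alt := vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))]
    cand[, genotype := fifelse(runif(.N) < cfg$snp_het_frac, "het", "hom")]
    snps <- rbind(snps, cand)
  }
  setkey(snps, chrom, pos)
  ## expression design: per gene x tissue relative weight
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  expr <- CJ(gene_id = gene_ids, tissue = cfg$tissues, sorted = FALSE)
  expr[, weight := stats::rlnorm(.N, meanlog = 0, sdlog = 0.7) *
         (runif(.N) >= cfg$frac_silent)]
  list(genome = genome, genes = genes, tracks = tracks,
       truth = list(edits = edits, snps = snps, expression = expr))
}

## exon coordinate map for one transcript: genomic <-> spliced (genome-
## forward orientation, i.e. spliced coordinate 0 is the leftmost exonic
## base regardless of strand)
exon_map <- function(g) {
  lens <- g$exons[, 2] - g$exons[, 1]
  list(starts = g$exons[, 1], lens = lens,
       cum = cumsum(c(0L, lens)), tx_len = sum(lens),
       intron_lens = if (nrow(g$introns))
         g$introns[, 2] - g$introns[, 1] else integer(0))
}

tx_to_genome <- function(map, sc) {
  k <- findInterval(sc, map$cum, rightmost.closed = FALSE)
  map$starts[k] + (sc - map$cum[k])
}

genome_to_tx <- function(map, gp) {
  out <- rep(NA_integer_, length(gp))
  for (k in seq_along(map$starts)) {
    sel <- gp >= map$starts[k] & gp < map$starts[k] + map$lens[k]
    out[sel] <- map$cum[k] + (gp[sel] - map$starts[k])
  }
  out
}
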