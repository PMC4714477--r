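## The filter gauntlet: a hand-laid fixture with one candidate site per
## filter rule, each violating exactly that rule, plus clean sites that
## survive everything. Used by the cascade equivalence tests.

gauntlet_read_len <- 50L

## one cluster of reads covering position P: `n_ref` reference reads at
## staggered starts plus alt reads at given (start, base, qual) tweaks
gauntlet_cluster <- function(gseq, chrom, P, n_ref, alt_starts = integer(),
                             alt_base = "G", alt_qual = 30L,
                             prefix = "r") {
  rl <- gauntlet_read_len
  ref_starts <- P - 45L + (seq_len(n_ref) - 1L) %% 41L
  starts <- c(ref_starts, alt_starts)
  seqs <- substring(gseq, starts + 1L, starts + rl)
  quals <- rep(strrep(rawToChar(as.raw(30L + 33L)), rl), length(starts))
  if (length(alt_starts)) {
    ai <- n_ref + seq_along(alt_starts)
    off <- P - alt_starts + 1L
    s <- seqs[ai]; substr(s, off, off) <- alt_base; seqs[ai] <- s
    if (alt_qual != 30L) {
      q <- quals[ai]
      qc <- rawToChar(as.raw(alt_qual + 33L))
      substr(q, off, off) <- qc
      quals[ai] <- q
    }
  }
  data.table(start = starts, seq = seqs, qual = quals,
             id = paste0(prefix, "_", seq_along(starts)))
}

gauntlet_read_table <- function(clusters, chrom, sample_id) {
  dt <- rbindlist(clusters)
  out <- data.table(
    read_id = paste0(sample_id, "_", seq_len(nrow(dt)), "_", dt$id),
    sample_id = sample_id, flag = 0L, chrom = chrom, pos0 = dt$start,
    mapq = 60L, cigar = paste0(gauntlet_read_len, "M"), seq = dt$seq,
    qual = dt$qual, nh = 1L, unique_flag = TRUE, strand = "+")
  setattr(out, "class", c("read_table", class(out)))
  out
}

#' Build the filter-gauntlet fixture
#'
#' A single-chromosome toy study in which 13 candidate editing sites each
#' violate exactly one rule of the filter cascade — coverage < 10, < 2
#' unique supporting reads, base quality < 23, read-end-only support,
#' homopolymer / repeat / multi-mappability / self-chain overlap, intronic
#' splice-boundary proximity (distance 5), intergenic position,
#' opposite-strand gene ambiguity, DNA alternate support > 0, and DNA
#' coverage <= 20 — while 3 clean sites (two on a + gene, one genomic
#' T>C on a - gene) survive everything as A-to-I calls.
#'
#' @param seed seed for the random background sequence.
#' @return list: `genome`, `genes`, `tracks`, `rna` (one RNA
#'   `read_table`), `dna` (list of two DNA `read_table`s), and `sites`
#'   (data.table: `name`, `rule`, `chrom`, `pos`, `alt`,
#'   `expected_pass`).
#' @export
gauntlet_fixture <- function(seed = 42L) {
  set.seed(seed)
  chrom <- "chrT"
  glen <- 17000L
  gseq <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                collapse = "")
  sites <- data.table(
    name = c("low_cov", "few_unique", "low_qual", "end_only",
             "homopolymer", "repeat", "multimap", "self_chain",
             "splice_boundary", "intergenic", "strand_ambiguous",
             "dna_support", "dna_low_cov",
             "clean_plus_1", "clean_plus_2", "clean_minus"),
    rule = c("min_cov", "min_alt_reads", "min_base_qual", "end_exclusion",
             "homopolymer", "repeat", "multimap", "self_chain",
             "splice_boundary", "intergenic", "strand_ambiguous",
             "dna_support", "dna_low_cov", "none", "none", "none"),
    pos = c(1200L, 1500L, 1800L, 2600L, 2900L, 3200L, 3500L, 4100L,
            2204L, 15000L, 12800L, 4400L, 4700L, 1350L, 3050L, 8500L),
    expected_pass = c(rep(FALSE, 13L), rep(TRUE, 3L)))
  sites[, chrom := chrom]
  ## force the reference base at every site: A for sites analysed on "+",
  ## T (alt C) for the site inside the "-" gene
  sites[, ref := fifelse(name == "clean_minus", "T", "A")]
  sites[, alt := fifelse(name == "clean_minus", "C", "G")]
  for (i in seq_len(nrow(sites)))
    substr(gseq, sites$pos[i] + 1L, sites$pos[i] + 1L) <- sites$ref[i]
  genome <- Biostrings::DNAStringSet(setNames(gseq, chrom))
  ## gene models
  genes <- list(
    gene_model("gA", "gA.t1", chrom, "+",
               exons = rbind(c(1000L, 2200L), c(2500L, 3700L),
                             c(4000L, 5200L)),
               cds = rbind(c(1100L, 2200L), c(2500L, 3700L),
                           c(4000L, 5099L))),
    gene_model("gB", "gB.t1", chrom, "-",
               exons = rbind(c(8000L, 9200L)),
               cds = rbind(c(8100L, 9099L))),
    gene_model("gC", "gC.t1", chrom, "+", exons = rbind(c(12000L, 13200L))),
    gene_model("gD", "gD.t1", chrom, "-", exons = rbind(c(12500L, 13700L))))
  tracks <- exclusion_tracks(
    homopolymer = interval_set(chrom, 2895L, 2905L),
    repeat_masker = interval_set(chrom, 3195L, 3205L),
    multimap = interval_set(chrom, 3495L, 3505L),
    self_chain = interval_set(chrom, 4095L, 4105L))
  ## RNA clusters: default 30x coverage, 6 interior alt reads with
  ## distinct starts at Q30; per-rule tweaks below
  clean_alts <- function(P) P - 25L - seq_len(6L) + 1L
  cl <- list()
  add <- function(name, cluster) cl[[name]] <<- cluster
  for (i in seq_len(nrow(sites))) {
    nm <- sites$name[i]; P <- sites$pos[i]; ab <- sites$alt[i]
    cluster <- switch(
      nm,
      low_cov = gauntlet_cluster(gseq, chrom, P, n_ref = 4L,
                                 alt_starts = clean_alts(P)[1:5],
                                 alt_base = ab, prefix = nm),
      few_unique = gauntlet_cluster(gseq, chrom, P, n_ref = 28L,
                                    alt_starts = rep(P - 25L, 2L),
                                    alt_base = ab, prefix = nm),
      low_qual = gauntlet_cluster(gseq, chrom, P, n_ref = 27L,
                                  alt_starts = clean_alts(P)[1:3],
                                  alt_base = ab, alt_qual = 22L,
                                  prefix = nm),
      end_only = gauntlet_cluster(gseq, chrom, P, n_ref = 26L,
                                  alt_starts = c(P - 4L, P - 6L,
                                                 P - 44L, P - 42L),
                                  alt_base = ab, prefix = nm),
      gauntlet_cluster(gseq, chrom, P, n_ref = 24L,
                       alt_starts = clean_alts(P), alt_base = ab,
                       prefix = nm))
    add(nm, cluster)
  }
  rna <- gauntlet_read_table(cl, chrom, "rna_1")
  ## DNA clusters: 25 clean reads per site (split across two samples),
  ## except one alt-supporting read at dna_support and only 20 reads at
  ## dna_low_cov
  dna_cl <- list()
  for (i in seq_len(nrow(sites))) {
    nm <- sites$name[i]; P <- sites$pos[i]; ab <- sites$alt[i]
    n <- if (nm == "dna_low_cov") 20L else 25L
    alt_st <- if (nm == "dna_support") P - 25L else integer(0)
    dna_cl[[nm]] <- gauntlet_cluster(gseq, chrom, P, n_ref = n,
                                     alt_starts = alt_st, alt_base = ab,
                                     prefix = paste0("d_", nm))
  }
  dna_all <- rbindlist(dna_cl)
  odd <- seq_len(nrow(dna_all)) %% 2L == 1L
  dna1 <- gauntlet_read_table(list(dna_all[odd]), chrom, "dna_1")
  dna2 <- gauntlet_read_table(list(dna_all[!odd]), chrom, "dna_2")
  setcolorder(sites, c("name", "rule", "chrom", "pos", "ref", "alt",
                       "expected_pass"))
  list(genome = genome, genes = genes, tracks = tracks, rna = rna,
       dna = list(dna_1 = dna1, dna_2 = dna2), sites = sites)
}
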