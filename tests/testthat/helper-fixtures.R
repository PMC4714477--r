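# Fixtures built in code, plus the independent brute-force oracles used
# by the equivalence tests. Oracles deliberately use naive per-element
# loops and re-derivations so they share no code path with the package.

make_genome <- function(...) {
  v <- c(...)
  Biostrings::DNAStringSet(v)
}

## the worked two-exon transcript used across io/annotation tests:
## + strand, exons [0,100)+[200,300), CDS [50,100)+[200,250)
worked_gene <- function(strand = "+") {
  ## 100 bp CDS: deliberately not a codon multiple (frame warning
  ## expected); interval arithmetic is the point of this fixture
  suppressWarnings(
    gene_model("gX", "gX.t1", "chr1", strand,
               exons = rbind(c(0L, 100L), c(200L, 300L)),
               cds = rbind(c(50L, 100L), c(200L, 250L))))
}

## quick read_table builder; qual may be an integer (constant Phred) or a
## vector of quality strings
make_reads <- function(chrom, pos0, cigar, seq, qual = 30L,
                       sample_id = "s1", nh = 1L, flag = 0L) {
  n <- length(pos0)
  if (is.numeric(qual))
    qual <- vapply(nchar(seq), function(l)
      strrep(rawToChar(as.raw(qual + 33L)), l), character(1))
  out <- data.table::data.table(
    read_id = sprintf("%s_%03d", sample_id, seq_len(n)),
    sample_id = sample_id, flag = rep_len(flag, n), chrom = chrom,
    pos0 = as.integer(pos0), mapq = 60L, cigar = rep_len(cigar, n),
    seq = seq, qual = rep_len(qual, n), nh = rep_len(as.integer(nh), n),
    unique_flag = rep_len(as.integer(nh), n) == 1L,
    strand = ifelse(bitwAnd(rep_len(flag, n), 16L) != 0L, "-", "+"))
  data.table::setattr(out, "class", c("read_table", class(out)))
  out
}

## small simulation config for unit tests (~5 s end to end)
small_sim_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_chroms = 1L, chrom_length = 60000L,
               n_genes = 6L, tissues = c("brain", "liver"),
               rna_depth = c(25, 25), dna_depth = 25, n_dna = 1L,
               n_edits = 20L, n_snps = 10L, n_homopolymers = 5L,
               n_repeats = 3L, n_multimap = 2L, n_self_chain = 2L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

## ---- oracles -------------------------------------------------------------

## label one genomic base by scanning every transcript interval by hand
oracle_context <- function(genes, chrom, pos, strand = NULL) {
  labels <- character(0)
  for (g in genes) {
    if (g$chrom != chrom) next
    if (!is.null(strand) && g$strand != strand) next
    lab <- NA_character_
    inside <- function(m) {
      any(vapply(seq_len(nrow(m)), function(i)
        pos >= m[i, 1] && pos < m[i, 2], logical(1)))
    }
    if (nrow(g$cds) && inside(g$cds)) lab <- "cds"
    else if (nrow(g$utr5) && inside(g$utr5)) lab <- "utr5"
    else if (nrow(g$utr3) && inside(g$utr3)) lab <- "utr3"
    else if (inside(g$exons)) lab <- "noncoding_exon"
    else if (nrow(g$introns) && inside(g$introns)) lab <- "intron"
    if (!is.na(lab)) labels <- c(labels, lab)
  }
  if (!length(labels)) return(NA_character_)
  for (lab in c("cds", "utr5", "utr3", "noncoding_exon", "intron"))
    if (lab %in% labels) return(lab)
}

## consequence by re-translating the ENTIRE mutant CDS
oracle_consequence <- function(tx, genome, pos, sense_alt) {
  pieces <- lapply(seq_len(nrow(tx$cds)), function(i)
    substring(as.character(genome[[tx$chrom]]),
              tx$cds[i, 1] + 1L, tx$cds[i, 2]))
  cds <- paste(unlist(pieces), collapse = "")
  ## genomic offset within concatenated (genome-forward) CDS
  off <- NA_integer_
  cum <- 0L
  for (i in seq_len(nrow(tx$cds))) {
    if (pos >= tx$cds[i, 1] && pos < tx$cds[i, 2]) {
      off <- cum + (pos - tx$cds[i, 1])
      break
    }
    cum <- cum + (tx$cds[i, 2] - tx$cds[i, 1])
  }
  stopifnot(!is.na(off))
  mutant <- cds
  sub_base <- if (tx$strand == "-") {
    c(A = "T", C = "G", G = "C", T = "A")[[sense_alt]]
  } else sense_alt
  substr(mutant, off + 1L, off + 1L) <- sub_base
  tr <- function(s) {
    if (tx$strand == "-")
      s <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), NULL)[[1]]),
                 collapse = "")
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  }
  aa_ref <- tr(cds); aa_alt <- tr(mutant)
  if (aa_ref == aa_alt) return("synonymous")
  d <- which(strsplit(aa_ref, NULL)[[1]] != strsplit(aa_alt, NULL)[[1]])[1]
  r <- substr(aa_ref, d, d); a <- substr(aa_alt, d, d)
  if (a == "*") "stop_gain" else if (r == "*") "stop_loss" else
    "nonsynonymous"
}

## sharing fractions by explicit enumeration over sites
oracle_sharing <- function(called) {
  n_called <- apply(called, 1, sum)
  union_sites <- which(n_called >= 1)
  if (!length(union_sites)) return(c(NA_real_, NA_real_))
  any2 <- 0; alln <- 0
  for (i in union_sites) {
    if (n_called[i] >= 2) any2 <- any2 + 1
    if (n_called[i] == ncol(called)) alln <- alln + 1
  }
  c(any2 / length(union_sites), alln / length(union_sites))
}

## independent per-rule re-check of the filter cascade for one gauntlet
## site, from the raw reads (naive loops; no package pileup code)
oracle_gauntlet_rules <- function(fx, site_row, config = rdd_config()) {
  P <- site_row$pos; ab <- site_row$alt; ch <- site_row$chrom
  rl <- 50L
  cover <- list()
  for (i in seq_len(nrow(fx$rna))) {
    r <- fx$rna[i]
    if (r$chrom != ch) next
    if (P >= r$pos0 && P < r$pos0 + rl) {
      off <- P - r$pos0  # 0-based offset (all 50M reads)
      cover[[length(cover) + 1L]] <- list(
        base = substr(r$seq, off + 1L, off + 1L),
        qual = utf8ToInt(substr(r$qual, off + 1L, off + 1L)) - 33L,
        start = r$pos0,
        end_dist = min(off, rl - 1L - off))
    }
  }
  covn <- length(cover)
  alt_reads <- Filter(function(x) x$base == ab, cover)
  ev <- Filter(function(x) x$qual >= config$min_base_qual, alt_reads)
  dna_cov <- 0L; dna_alt <- 0L
  for (dtab in fx$dna) for (i in seq_len(nrow(dtab))) {
    r <- dtab[i]
    if (r$chrom == ch && P >= r$pos0 && P < r$pos0 + rl) {
      dna_cov <- dna_cov + 1L
      off <- P - r$pos0
      if (substr(r$seq, off + 1L, off + 1L) == ab)
        dna_alt <- dna_alt + 1L
    }
  }
  strands <- character(0)
  for (g in fx$genes) {
    lo <- min(g$exons[, 1]); hi <- max(g$exons[, 2])
    if (g$chrom == ch && P >= lo && P < hi)
      strands <- c(strands, g$strand)
  }
  intronic_near <- FALSE
  for (g in fx$genes) {
    if (g$chrom != ch || !nrow(g$introns)) next
    for (j in seq_len(nrow(g$introns))) {
      s <- g$introns[j, 1]; e <- g$introns[j, 2]
      if (P >= s && P < e &&
          min(P - s + 1L, e - P) <= config$splice_buffer_bp)
        intronic_near <- TRUE
    }
  }
  list(
    min_cov = covn >= config$min_cov,
    min_alt_reads = length(unique(vapply(ev, `[[`, 0L, "start"))) >=
      config$min_alt_reads,
    min_base_qual = length(ev) >= 1L,
    end_exclusion = any(vapply(ev, `[[`, 0L, "end_dist") >=
                          config$end_exclusion_bp),
    homopolymer = !point_in_set(fx$tracks$homopolymer, ch, P),
    "repeat" = !point_in_set(fx$tracks$repeat_masker, ch, P),
    multimap = !point_in_set(fx$tracks$multimap, ch, P),
    self_chain = !point_in_set(fx$tracks$self_chain, ch, P),
    splice_boundary = !intronic_near,
    intergenic = length(strands) >= 1L,
    strand_ambiguous = length(unique(strands)) <= 1L,
    dna_support = dna_alt == 0L,
    dna_low_cov = dna_cov > config$dna_min_cov)
}
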