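## Read-level simulation: spliced RNA reads with planted edits, germline
## SNPs, base errors and quality structure; uniform DNA reads.

## Vectorised in-place base substitution: one substr<- pass per "round"
## so that multiple substitutions in the same read do not collide.
apply_subs <- function(seqs, ridx, off, newbase) {
  if (!length(ridx)) return(seqs)
  dt <- data.table(ridx = ridx, off = off, nb = newbase)
  dt[, round := seq_len(.N), by = ridx]
  for (r in unique(dt$round)) {
    sub <- dt[round == r]
    s <- seqs[sub$ridx]
    substr(s, sub$off, sub$off) <- sub$nb
    seqs[sub$ridx] <- s
  }
  seqs
}

## Draw error positions for n reads of length rl; returns (ridx, off).
draw_errors <- function(n, rl, rate) {
  k <- stats::rbinom(n, rl, rate)
  if (sum(k) == 0L) return(data.table(ridx = integer(), off = integer()))
  ridx <- rep(seq_len(n), k)
  data.table(ridx = ridx, off = sample.int(rl, sum(k), replace = TRUE))
}

OTHER_BASES <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                    G = c("A", "C", "T"), T = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

random_other_base <- function(current) {
  idx <- sample.int(3L, length(current), replace = TRUE)
  mapply(function(b, i) OTHER_BASES[[b]][i], current, idx, USE.NAMES = FALSE)
}

## assemble a read_table from parallel vectors
make_read_table <- function(sample_id, prefix, chrom, pos0, cigar, seqs,
                            quals, nh) {
  n <- length(pos0)
  flag <- ifelse(runif(n) < 0.5, 0L, 16L)
  out <- data.table(
    read_id = sprintf("%s_r%07d", prefix, seq_len(n)),
    sample_id = sample_id, flag = flag, chrom = chrom, pos0 = pos0,
    mapq = fifelse(nh == 1L, 60L, 3L), cigar = cigar, seq = seqs,
    qual = quals, nh = nh, unique_flag = nh == 1L,
    strand = fifelse(flag == 16L, "-", "+"))
  setattr(out, "class", c("read_table", class(out)))
  out
}

## finishing pass shared by RNA and DNA reads: base errors, qualities,
## low-quality reads, multimap flags
finish_reads <- function(seqs, rl, cfg) {
  n <- length(seqs)
  err <- draw_errors(n, rl, cfg$base_error_rate)
  qual_base <- strrep(rawToChar(as.raw(cfg$base_qual + 33L)), rl)
  quals <- rep(qual_base, n)
  if (nrow(err)) {
    cur <- substring(seqs[err$ridx], err$off, err$off)
    seqs <- apply_subs(seqs, err$ridx, err$off, random_other_base(cur))
    eq <- sample(seq(cfg$err_qual_range[1], cfg$err_qual_range[2]),
                 nrow(err), replace = TRUE)
    quals <- apply_subs(quals, err$ridx, err$off,
                        rawToChar(as.raw(eq + 33L), multiple = TRUE))
  }
  lowq <- runif(n) < cfg$low_qual_read_rate
  quals[lowq] <- strrep(rawToChar(as.raw(20L + 33L)), rl)
  nh <- fifelse(runif(n) < cfg$multimap_read_rate, 2L, 1L)
  list(seqs = seqs, quals = quals, nh = nh)
}

#' Simulate aligned reads for every sample
#'
#' RNA reads are drawn from mature transcripts (junction-spanning reads
#' carry N CIGARs) with a per-tissue intron-retention fraction drawn from
#' pre-mRNA; per-gene read counts follow the expression design. At planted
#' edit sites each overlapping RNA read carries the edited base with the
#' tissue's design frequency; at het SNPs both RNA and DNA reads carry the
#' alternate allele with probability 0.5 (hom: always). DNA reads are
#' uniform over the genome. Read counts are inflated by the configured
#' multimap and low-quality rates so the post-filter depth approximates
#' the target.
#'
#' @param config a [sim_config()].
#' @param genome,genes,truth outputs of [simulate_genome()].
#' @return named list of `read_table`s: one per tissue plus
#'   `dna_1..n_dna`.
#' @export
simulate_reads <- function(config, genome, genes, truth) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  rl <- cfg$read_length
  inflate <- 1 / (1 - cfg$multimap_read_rate - cfg$low_qual_read_rate)
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  maps <- lapply(genes, exon_map)
  names(maps) <- gene_ids
  splice_seqs <- vapply(genes, function(g)
    paste(genome_slice(genome, rep(g$chrom, nrow(g$exons)),
                       g$exons[, 1], g$exons[, 2]), collapse = ""),
    character(1))
  names(splice_seqs) <- gene_ids
  spans <- lapply(genes, function(g)
    c(min(g$exons[, 1]), max(g$exons[, 2])))
  names(spans) <- gene_ids
  chrom_of <- setNames(vapply(genes, `[[`, "", "chrom"), gene_ids)
  ## per-gene variant lists (planted edits + SNPs inside the gene span)
  out <- list()
  for (tt in cfg$tissues) {
    expr <- truth$expression[tissue == tt]
    w <- setNames(expr$weight, expr$gene_id)[gene_ids]
    tx_lens <- vapply(maps, `[[`, integer(1), "tx_len")
    gene_w <- w * tx_lens
    expressed <- gene_w > 0
    if (!any(expressed)) {
      warning("tissue ", tt, " expresses no genes; empty sample")
      out[[tt]] <- empty_read_table(tt)
      next
    }
    n_total <- round(cfg$rna_depth[[tt]] * sum(tx_lens[expressed]) / rl *
                       inflate)
    n_per_gene <- as.integer(stats::rmultinom(
      1L, n_total, gene_w / sum(gene_w)))
    names(n_per_gene) <- gene_ids
    g_chrom <- character(); g_pos <- integer(); g_cigar <- character()
    g_seq <- character()
    for (gid in gene_ids[n_per_gene > 0L]) {
      g <- genes[[match(gid, gene_ids)]]
      map <- maps[[gid]]
      n_g <- n_per_gene[[gid]]
      retained <- runif(n_g) < cfg$intron_retention[[tt]]
      n_sp <- sum(!retained); n_re <- sum(retained)
      ## spliced reads
      if (n_sp > 0L && map$tx_len >= rl) {
        t0 <- sample.int(map$tx_len - rl + 1L, n_sp, replace = TRUE) - 1L
        sq <- substring(splice_seqs[[gid]], t0 + 1L, t0 + rl)
        ## at most one junction per read (min exon >= read length)
        k <- findInterval(t0, map$cum, rightmost.closed = FALSE)
        kend <- findInterval(t0 + rl - 1L, map$cum)
        pos <- map$starts[k] + (t0 - map$cum[k])
        cig <- rep(paste0(rl, "M"), n_sp)
        cross <- kend > k
        if (any(cross)) {
          m1 <- map$cum[k[cross] + 1L] - t0[cross]
          cig[cross] <- paste0(m1, "M", map$intron_lens[k[cross]], "N",
                               rl - m1, "M")
        }
        ## plant variants through spliced coordinates
        sq <- plant_variants_spliced(sq, t0, gid, g, map, truth, tt, rl)
        g_chrom <- c(g_chrom, rep(g$chrom, n_sp))
        g_pos <- c(g_pos, pos); g_cigar <- c(g_cigar, cig)
        g_seq <- c(g_seq, sq)
      }
      ## intron-retained (pre-mRNA) reads
      if (n_re > 0L) {
        span <- spans[[gid]]
        glen <- span[2] - span[1]
        if (glen >= rl) {
          p0 <- span[1] +
            sample.int(glen - rl + 1L, n_re, replace = TRUE) - 1L
          sq <- substring(chrom_seq(genome, g$chrom), p0 + 1L, p0 + rl)
          sq <- plant_variants_genomic(sq, p0, g$chrom, truth, tt, rl)
          g_chrom <- c(g_chrom, rep(g$chrom, n_re))
          g_pos <- c(g_pos, p0)
          g_cigar <- c(g_cigar, rep(paste0(rl, "M"), n_re))
          g_seq <- c(g_seq, sq)
        }
      }
    }
    fin <- finish_reads(g_seq, rl, cfg)
    out[[tt]] <- make_read_table(tt, tt, g_chrom, g_pos, g_cigar,
                                 fin$seqs, fin$quals, fin$nh)
  }
  ## DNA samples: uniform whole-genome coverage
  chroms <- names(genome)
  clens <- Biostrings::width(genome)
  for (d in seq_len(cfg$n_dna)) {
    sid <- paste0("dna_", d)
    n_total <- round(cfg$dna_depth * sum(clens) / rl * inflate)
    ch_idx <- sample.int(length(chroms), n_total, replace = TRUE,
                         prob = clens / sum(clens))
    p0 <- integer(n_total)
    for (ci in seq_along(chroms)) {
      sel <- ch_idx == ci
      p0[sel] <- sample.int(clens[ci] - rl + 1L, sum(sel),
                            replace = TRUE) - 1L
    }
    o <- order(ch_idx, p0)
    ch_idx <- ch_idx[o]; p0 <- p0[o]
    sq <- character(n_total)
    for (ci in seq_along(chroms)) {
      sel <- ch_idx == ci
      sq[sel] <- substring(chrom_seq(genome, chroms[ci]),
                           p0[sel] + 1L, p0[sel] + rl)
    }
    sq <- plant_snps_only(sq, p0, chroms[ch_idx], truth, rl)
    fin <- finish_reads(sq, rl, cfg)
    out[[sid]] <- make_read_table(sid, sid, chroms[ch_idx], p0,
                                  rep(paste0(rl, "M"), n_total),
                                  fin$seqs, fin$quals, fin$nh)
  }
  out
}

## plant edits and SNPs into spliced reads of one gene (t0: 0-based
## spliced start positions)
plant_variants_spliced <- function(sq, t0, gid, g, map, truth, tissue, rl) {
  vars <- gene_variants(g, map, truth, tissue)
  vars <- vars[!is.na(vars$sc)]
  if (!nrow(vars)) return(sq)
  for (v in seq_len(nrow(vars))) {
    sel <- which(t0 <= vars$sc[v] & vars$sc[v] < t0 + rl)
    if (!length(sel)) next
    hit <- sel[runif(length(sel)) < vars$p[v]]
    if (!length(hit)) next
    off <- vars$sc[v] - t0[hit] + 1L
    sq <- apply_subs(sq, hit, off, vars$alt_fwd[v])
  }
  sq
}

## plant edits and SNPs into contiguous genomic reads (retention reads)
plant_variants_genomic <- function(sq, p0, chrom, truth, tissue, rl) {
  lo <- min(p0); hi <- max(p0) + rl
  vars <- rbind(
    edit_vars(truth, tissue)[chrom, on = "chrom", nomatch = NULL][
      pos >= lo & pos < hi],
    snp_vars(truth)[chrom, on = "chrom", nomatch = NULL][
      pos >= lo & pos < hi], fill = TRUE)
  if (!nrow(vars)) return(sq)
  for (v in seq_len(nrow(vars))) {
    sel <- which(p0 <= vars$pos[v] & vars$pos[v] < p0 + rl)
    if (!length(sel)) next
    hit <- sel[runif(length(sel)) < vars$p[v]]
    if (!length(hit)) next
    off <- vars$pos[v] - p0[hit] + 1L
    sq <- apply_subs(sq, hit, off, vars$alt_fwd[v])
  }
  sq
}

## plant SNPs only (DNA reads); chrom is per-read here
plant_snps_only <- function(sq, p0, chrom, truth, rl) {
  vars <- snp_vars(truth)
  if (!nrow(vars)) return(sq)
  for (v in seq_len(nrow(vars))) {
    sel <- which(chrom == vars$chrom[v] & p0 <= vars$pos[v] &
                   vars$pos[v] < p0 + rl)
    if (!length(sel)) next
    hit <- sel[runif(length(sel)) < vars$p[v]]
    if (!length(hit)) next
    off <- vars$pos[v] - p0[hit] + 1L
    sq <- apply_subs(sq, hit, off, vars$alt_fwd[v])
  }
  sq
}

## edits as genome-forward substitutions with per-tissue probability
edit_vars <- function(truth, tissue) {
  e <- truth$edits
  fcol <- paste0("freq_", tissue)
  data.table(chrom = e$chrom, pos = e$pos,
             alt_fwd = fifelse(e$strand == "+", "G", "C"),
             p = e[[fcol]])
}

snp_vars <- function(truth) {
  s <- truth$snps
  if (!nrow(s)) return(data.table(chrom = character(), pos = integer(),
                                  alt_fwd = character(), p = numeric()))
  data.table(chrom = s$chrom, pos = s$pos, alt_fwd = s$alt,
             p = fifelse(s$genotype == "het", 0.5, 1.0))
}

## per-gene variant table in spliced coordinates (NA for intronic)
gene_variants <- function(g, map, truth, tissue) {
  span <- c(min(g$exons[, 1]), max(g$exons[, 2]))
  ev <- edit_vars(truth, tissue)[chrom == g$chrom &
                                   pos >= span[1] & pos < span[2]]
  sv <- snp_vars(truth)[chrom == g$chrom & pos >= span[1] & pos < span[2]]
  vars <- rbind(ev, sv)
  vars[, sc := genome_to_tx(map, pos)]
  vars[p > 0]
}

#' Write a complete synthetic study to disk
#'
#' Runs [simulate_genome()] and [simulate_reads()] and writes: the genome
#' FASTA, gene models GFF3, the four exclusion-track BEDs, one SAM per
#' sample, the ground-truth TSVs (`truth_edits.tsv`, `truth_snps.tsv`,
#' `truth_expression.tsv`, plus `truth_edits.bed`) and the serialized
#' configuration. Re-running with the same config yields byte-identical
#' files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list: `paths` (named file paths), plus the in-memory
#'   `genome`, `genes`, `tracks`, `truth`, `reads`.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(config)
  reads <- simulate_reads(config, sim$genome, sim$genes, sim$truth)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    homopolymer = file.path(dir, "homopolymer.bed"),
    repeat_masker = file.path(dir, "repeat_masker.bed"),
    multimap = file.path(dir, "multimap.bed"),
    self_chain = file.path(dir, "self_chain.bed"),
    truth_edits = file.path(dir, "truth_edits.tsv"),
    truth_edits_bed = file.path(dir, "truth_edits.bed"),
    truth_snps = file.path(dir, "truth_snps.tsv"),
    truth_expression = file.path(dir, "truth_expression.tsv"),
    config = file.path(dir, "sim_config.txt"))
  write_fasta(sim$genome, paths$genome)
  write_gff3(sim$genes, paths$genes)
  for (tn in c("homopolymer", "repeat_masker", "multimap", "self_chain"))
    write_bed(sim$tracks[[tn]], paths[[tn]])
  fwrite(sim$truth$edits, paths$truth_edits, sep = "\t")
  fwrite(sim$truth$edits[, .(chrom, pos, end = pos + 1L)],
         paths$truth_edits_bed, sep = "\t", col.names = FALSE)
  fwrite(sim$truth$snps, paths$truth_snps, sep = "\t")
  fwrite(sim$truth$expression, paths$truth_expression, sep = "\t")
  writeLines(serialize_config(config), paths$config)
  for (s in names(reads)) {
    paths[[paste0("sam_", s)]] <- file.path(dir, paste0(s, ".sam"))
    write_sam(reads[[s]], paths[[paste0("sam_", s)]], sim$genome)
  }
  invisible(c(list(paths = paths, reads = reads), sim))
}

## key = value serialization of a sim_config (single declarative file)
serialize_config <- function(cfg) {
  vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    val <- if (!is.null(names(v)) && length(names(v)))
      paste(paste0(names(v), ":", v), collapse = ",") else
      paste(v, collapse = ",")
    paste0(nm, " = ", val)
  }, character(1))
}
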