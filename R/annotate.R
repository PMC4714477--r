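## Genic context, coding consequence, sequence context, and category
## enrichment for edited genes.

CONTEXT_PRIORITY <- c(cds = 1L, utr5 = 2L, utr3 = 3L, noncoding_exon = 4L,
                      intron = 5L)

## context of a single 0-based position within one transcript, or NA when
## the position lies outside the transcript span
context_in_transcript <- function(tx, pos) {
  iniv <- function(m) nrow(m) > 0L && any(pos >= m[, 1] & pos < m[, 2])
  if (iniv(tx$cds)) return("cds")
  if (iniv(tx$utr5)) return("utr5")
  if (iniv(tx$utr3)) return("utr3")
  if (iniv(tx$exons)) return("noncoding_exon")
  if (iniv(tx$introns)) return("intron")
  NA_character_
}

#' Classify the genic context of sites
#'
#' Each site is labelled `cds`, `utr5`, `utr3`, `noncoding_exon` or
#' `intron` by interval membership in the transcripts overlapping it
#' (restricted to `strand` when given). Cross-transcript conflicts are
#' resolved by the priority cds > utr5 > utr3 > noncoding_exon > intron;
#' among transcripts giving `cds`, the one with the longest CDS is
#' recorded for downstream consequence prediction.
#'
#' @param chrom,pos site vectors (0-based positions).
#' @param genes list of [gene_model()]s.
#' @param strand optional per-site transcript strand restricting the
#'   transcripts considered (recycled if length 1).
#' @return data.table `chrom`, `pos`, `context` (`NA` if the site is
#'   outside every considered transcript), `transcript_id` (the transcript
#'   supplying the winning context).
#' @export
classify_context <- function(chrom, pos, genes, strand = NULL) {
  n <- length(pos)
  if (!is.null(strand)) strand <- rep_len(strand, n)
  hits <- genes_at_points(genes, chrom, pos)
  ctx <- rep(NA_character_, n)
  txid <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    idx <- hits[[i]]
    if (!length(idx)) next
    best_rank <- Inf; best_tx <- NA_character_; best_cdslen <- -1L
    for (j in idx) {
      tx <- genes[[j]]
      if (!is.null(strand) && tx$strand != strand[i]) next
      cc <- context_in_transcript(tx, pos[i])
      if (is.na(cc)) next
      r <- CONTEXT_PRIORITY[[cc]]
      cdslen <- if (nrow(tx$cds)) sum(tx$cds[, 2] - tx$cds[, 1]) else 0L
      better <- r < best_rank ||
        (r == best_rank && r == 1L && cdslen > best_cdslen)
      if (better) {
        best_rank <- r; best_tx <- tx$transcript_id
        best_cdslen <- cdslen
        ctx[i] <- cc; txid[i] <- best_tx
      }
    }
  }
  data.table(chrom = chrom, pos = pos, context = ctx,
             transcript_id = txid)
}

## spliced, strand-corrected CDS of a transcript as a character string
spliced_cds <- function(tx, genome) {
  if (!nrow(tx$cds)) stop("transcript ", tx$transcript_id, " has no CDS")
  pieces <- genome_slice(genome, rep(tx$chrom, nrow(tx$cds)),
                         tx$cds[, 1], tx$cds[, 2])
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

## 0-based offset of a genomic position within the spliced sense CDS
cds_offset <- function(tx, pos) {
  lens <- tx$cds[, 2] - tx$cds[, 1]
  hit <- which(pos >= tx$cds[, 1] & pos < tx$cds[, 2])
  if (!length(hit)) return(NA_integer_)
  off <- sum(lens[seq_len(hit - 1L)]) + (pos - tx$cds[hit, 1])
  if (tx$strand == "-") off <- sum(lens) - 1L - off
  off
}

#' Predict the coding consequence of a substitution
#'
#' The codon containing the site is extracted from the spliced,
#' strand-corrected CDS, the sense alternate base substituted, and the
#' standard genetic code applied (inosine is read as guanosine, so A-to-I
#' events enter as sense A>G). Changes creating a stop are `stop_gain`,
#' removing one `stop_loss`.
#'
#' @param chrom,pos site (0-based position, must fall in the CDS).
#' @param sense_alt alternate base on the transcript strand.
#' @param tx a coding [gene_model()].
#' @param genome genome container.
#' @return one-row data.table: `consequence` (`synonymous`,
#'   `nonsynonymous`, `stop_gain`, `stop_loss`), `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `transcript_id`.
#' @export
predict_consequence <- function(chrom, pos, sense_alt, tx, genome) {
  if (chrom != tx$chrom) stop("site not on transcript chromosome")
  off <- cds_offset(tx, pos)
  if (is.na(off)) stop("site maps to no CDS codon of ", tx$transcript_id)
  cds <- spliced_cds(tx, genome)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS of ", tx$transcript_id, " is not a codon multiple")
  ci <- off %/% 3L
  wi <- off %% 3L
  ref_codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  alt_codon <- ref_codon
  substr(alt_codon, wi + 1L, wi + 1L) <- sense_alt
  gc <- Biostrings::GENETIC_CODE
  ref_aa <- unname(gc[ref_codon]); alt_aa <- unname(gc[alt_codon])
  consequence <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "nonsynonymous"
  data.table(consequence = consequence, ref_codon = ref_codon,
             alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
             transcript_id = tx$transcript_id)
}

#' Annotate an RDD set with genic context and coding consequence
#'
#' Adds `context`, `consequence`, codon and amino-acid columns to the site
#' table. Consequence is computed only for `cds` sites, against the
#' longest-CDS transcript providing the cds context.
#'
#' @param rdds an [rdd_set()].
#' @param genes list of [gene_model()]s.
#' @param genome genome container.
#' @return the [rdd_set()] with annotated `sites`.
#' @export
annotate_rdds <- function(rdds, genes, genome) {
  sites <- copy(rdds$sites)
  if (!nrow(sites)) {
    sites[, `:=`(context = character(), transcript_id = character(),
                 consequence = character(), ref_codon = character(),
                 alt_codon = character(), ref_aa = character(),
                 alt_aa = character())]
    rdds$sites <- sites
    return(rdds)
  }
  ctx <- classify_context(sites$chrom, sites$pos, genes,
                          strand = sites$strand)
  sites[, `:=`(context = ctx$context, transcript_id = ctx$transcript_id)]
  sites[, `:=`(consequence = NA_character_, ref_codon = NA_character_,
               alt_codon = NA_character_, ref_aa = NA_character_,
               alt_aa = NA_character_)]
  tx_by_id <- setNames(genes, vapply(genes, `[[`, "", "transcript_id"))
  for (i in which(sites$context == "cds")) {
    cons <- predict_consequence(sites$chrom[i], sites$pos[i],
                                sites$sense_alt[i],
                                tx_by_id[[sites$transcript_id[i]]], genome)
    sites[i, `:=`(consequence = cons$consequence,
                  ref_codon = cons$ref_codon, alt_codon = cons$alt_codon,
                  ref_aa = cons$ref_aa, alt_aa = cons$alt_aa)]
  }
  rdds$sites <- sites
  rdds
}

#' Sequence context around edited sites
#'
#' Extracts strand-corrected windows of half-width `k` around each site
#' and tabulates the base frequency at every relative position -k..+k.
#' For canonical A-to-I site sets, position 0 is 100% `A` by construction.
#' Sites within `k` of a chromosome end are dropped (count reported in the
#' `n_dropped` attribute).
#'
#' @param chrom,pos,strand site vectors (0-based positions, transcript
#'   strands).
#' @param genome genome container.
#' @param k window half-width in bp.
#' @return 4 x (2k+1) numeric matrix (rows A,C,G,T; columns `-k`..`k`),
#'   each column summing to 1; attributes `n_sites`, `n_dropped`.
#' @export
context_matrix <- function(chrom, pos, strand, genome, k = 5L) {
  chrom <- rep_len(chrom, length(pos))
  strand <- rep_len(strand, length(pos))
  lens <- setNames(Biostrings::width(genome), names(genome))
  ok <- pos - k >= 0L & pos + k < lens[chrom]
  n_drop <- sum(!ok)
  chrom <- chrom[ok]; pos <- pos[ok]; strand <- strand[ok]
  mat <- matrix(0, 4L, 2L * k + 1L,
                dimnames = list(c("A", "C", "G", "T"),
                                as.character(seq(-k, k))))
  if (!length(pos)) {
    attr(mat, "n_sites") <- 0L; attr(mat, "n_dropped") <- n_drop
    return(mat)
  }
  win <- genome_slice(genome, chrom, pos - k, pos + k + 1L)
  win[strand == "-"] <- revcomp(win[strand == "-"])
  m <- do.call(rbind, strsplit(win, NULL))
  for (j in seq_len(ncol(m))) {
    tab <- table(factor(m[, j], levels = rownames(mat)))
    mat[, j] <- as.numeric(tab) / sum(tab)
  }
  attr(mat, "n_sites") <- length(pos)
  attr(mat, "n_dropped") <- n_drop
  mat
}

#' Category enrichment among edited genes
#'
#' For each category, a 2x2 table (edited vs not, in-category vs not) is
#' formed over the expressed-gene universe, tested with Fisher's exact
#' test (one-sided, enrichment), and summarised by an odds ratio
#' (Haldane-corrected by adding 0.5 to every cell when any cell is zero).
#' The reported `pass_filter` flag applies the screening used for
#' reporting: odds ratio > `or_filter` and at least `min_genes` edited
#' genes in the category. P-values are Benjamini-Hochberg adjusted across
#' all tested categories.
#'
#' @param edited_genes character vector of edited gene ids (must lie in
#'   the universe; others are dropped with a warning).
#' @param expressed_genes the universe: genes expressed in the sample
#'   (e.g. RPKM >= 10).
#' @param category_map data.frame with columns `gene_id`, `category`.
#' @param or_filter,min_genes reporting filters.
#' @return data.table per category: `category`, `n_edited`, `n_category`,
#'   `odds_ratio`, `p_value`, `p_adj`, `pass_filter`; sorted by `p_adj`.
#' @export
category_enrichment <- function(edited_genes, expressed_genes,
                                category_map, or_filter = 10,
                                min_genes = 2L) {
  expressed_genes <- unique(expressed_genes)
  if (!length(expressed_genes)) stop("empty expressed-gene universe")
  edited_genes <- unique(edited_genes)
  out_of_universe <- setdiff(edited_genes, expressed_genes)
  if (length(out_of_universe)) {
    warning(length(out_of_universe),
            " edited gene(s) outside the universe dropped")
    edited_genes <- intersect(edited_genes, expressed_genes)
  }
  cm <- as.data.table(category_map)
  cm <- cm[gene_id %in% expressed_genes]
  cats <- unique(cm$category)
  n_univ <- length(expressed_genes)
  n_edit <- length(edited_genes)
  res <- rbindlist(lapply(cats, function(cat) {
    in_cat <- unique(cm[category == cat, gene_id])
    a <- length(intersect(edited_genes, in_cat))        # edited, in cat
    b <- n_edit - a                                      # edited, not
    c_ <- length(in_cat) - a                             # not edited, in
    d <- n_univ - n_edit - c_
    tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    or <- if (any(tab == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    else (a * d) / (b * c_)
    data.table(category = cat, n_edited = a, n_category = length(in_cat),
               odds_ratio = or, p_value = p)
  }))
  if (!nrow(res))
    return(data.table(category = character(), n_edited = integer(),
                      n_category = integer(), odds_ratio = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      pass_filter = logical()))
  res[, p_adj := stats::p.adjust(p_value, method = "BH")]
  res[, pass_filter := odds_ratio > or_filter & n_edited >= min_genes]
  res[order(p_adj, -odds_ratio)]
}
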