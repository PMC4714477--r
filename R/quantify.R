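## Expression and editing quantification: RPKM over coding exons, splice
## junction usage, editing matrices with coverage masking, cross-sample
## sharing, and editing-frequency vs enzyme-expression correlation.

## unique (read, gene) overlap pairs between read blocks and per-gene CDS
## (or exon) unions; a read overlapping two genes counts toward both
reads_per_gene <- function(reads, genes, feature = c("cds", "exons")) {
  feature <- match.arg(feature)
  bl <- read_blocks(reads)
  counts <- setNames(integer(length(genes)),
                     vapply(genes, `[[`, "", "gene_id"))
  if (!nrow(bl)) return(counts)
  bl[, chrom := reads$chrom[ridx]]
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    iv <- g[[feature]]
    if (!nrow(iv)) next
    sub <- bl[chrom == g$chrom]
    if (!nrow(sub)) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(sub$gstart + 1L, sub$gstart + sub$len),
      IRanges::IRanges(iv[, 1] + 1L, iv[, 2]))
    counts[i] <- counts[i] + uniqueN(sub$ridx[hits])
  }
  counts
}

#' Gene expression as RPKM over coding exons
#'
#' A read counts toward a gene when any aligned block overlaps the union
#' of the gene's CDS exons; reads overlapping the CDS of several genes
#' count toward each. RPKM = count / (CDS length in kb x total mapped
#' reads in millions). Genes without CDS get `NA` (no defined feature
#' length); non-coding expression can be obtained with `feature =
#' "exons"`.
#'
#' @param reads a filtered `read_table` for one sample.
#' @param genes list of [gene_model()]s.
#' @param total_reads total uniquely mapped reads in the sample; defaults
#'   to `nrow(reads)`.
#' @param feature count over `"cds"` (default) or all `"exons"`.
#' @return data.table `gene_id`, `count`, `feature_kb`, `rpkm`.
#' @export
compute_rpkm <- function(reads, genes, total_reads = nrow(reads),
                         feature = "cds") {
  counts <- reads_per_gene(reads, genes, feature)
  by_gene <- tapply(
    vapply(genes, function(g) {
      iv <- g[[feature]]
      if (nrow(iv)) sum(iv[, 2] - iv[, 1]) else 0L
    }, numeric(1)),
    vapply(genes, `[[`, "", "gene_id"), max)
  kb <- as.numeric(by_gene[names(counts)]) / 1000
  rpkm <- ifelse(kb > 0, counts / (kb * (total_reads / 1e6)), NA_real_)
  data.table(gene_id = names(counts), count = as.integer(counts),
             feature_kb = kb, rpkm = rpkm)
}

#' Expression table across samples
#'
#' @param rna_samples named list of filtered `read_table`s.
#' @param genes list of [gene_model()]s.
#' @param total_reads optional named vector overriding per-sample totals.
#' @param feature see [compute_rpkm()].
#' @return list with `rpkm` (gene x sample matrix), `counts`, and
#'   `sample_info` (total reads, modal read length, analyzed_bases =
#'   reads x read length); class `expression_table`.
#' @export
expression_table <- function(rna_samples, genes, total_reads = NULL,
                             feature = "cds") {
  samples <- names(rna_samples)
  per <- lapply(samples, function(s) {
    tr <- if (!is.null(total_reads)) total_reads[[s]] else
      nrow(rna_samples[[s]])
    compute_rpkm(rna_samples[[s]], genes, tr, feature)
  })
  gene_ids <- per[[1]]$gene_id
  rpkm <- vapply(per, `[[`, numeric(length(gene_ids)), "rpkm")
  counts <- vapply(per, `[[`, integer(length(gene_ids)), "count")
  dimnames(rpkm) <- dimnames(counts) <- list(gene_ids, samples)
  info <- rbindlist(lapply(samples, function(s) {
    r <- rna_samples[[s]]
    tr <- if (!is.null(total_reads)) total_reads[[s]] else nrow(r)
    rl <- if (nrow(r)) as.integer(names(sort(table(nchar(r$seq)),
                                             decreasing = TRUE))[1]) else 0L
    data.table(sample_id = s, total_reads = tr, read_length = rl,
               analyzed_bases = as.numeric(tr) * rl)
  }))
  structure(list(rpkm = rpkm, counts = counts, sample_info = info),
            class = "expression_table")
}

#' Count reads supporting splice junctions
#'
#' A read supports junction (donor, acceptor) iff one of its CIGAR N gaps
#' is exactly that 0-based half-open intron interval; near-misses count
#' zero. The normalised value is log2(FPKM + 1) with the junction treated
#' as a fixed-length feature of one read length, so it is 0 exactly when
#' the raw count is 0.
#'
#' @param rna_samples named list of filtered `read_table`s.
#' @param catalog data.frame with columns `chrom`, `donor`, `acceptor`
#'   (0-based half-open intron), `label`, `strand`.
#' @param total_reads optional named per-sample totals (default:
#'   `nrow(reads)`).
#' @param read_length optional feature length in bp for the FPKM
#'   convention (default: modal read length per sample).
#' @return list with `counts` and `norm` (junction x sample matrices,
#'   rownames = labels) and `catalog`; class `junction_matrix`.
#' @export
quantify_junctions <- function(rna_samples, catalog, total_reads = NULL,
                               read_length = NULL) {
  catalog <- as.data.table(catalog)
  samples <- names(rna_samples)
  counts <- matrix(0L, nrow(catalog), length(samples),
                   dimnames = list(catalog$label, samples))
  norm <- matrix(0, nrow(catalog), length(samples),
                 dimnames = list(catalog$label, samples))
  for (i in seq_along(samples)) {
    r <- rna_samples[[i]]
    gaps <- read_junction_gaps(r)
    if (nrow(gaps)) {
      tab <- gaps[, .N, by = .(chrom, donor, acceptor)]
      j <- tab[catalog, on = c("chrom", "donor", "acceptor")]
      counts[, i] <- fifelse(is.na(j$N), 0L, j$N)
    }
    tr <- if (!is.null(total_reads)) total_reads[[samples[i]]] else nrow(r)
    rl <- if (!is.null(read_length)) read_length else if (nrow(r))
      as.integer(names(sort(table(nchar(r$seq)), decreasing = TRUE))[1])
    else 1L
    fpkm <- if (tr > 0) counts[, i] / ((rl / 1000) * (tr / 1e6)) else
      rep(0, nrow(catalog))
    norm[, i] <- log2(fpkm + 1)
  }
  structure(list(counts = counts, norm = norm, catalog = catalog),
            class = "junction_matrix")
}

#' Editing matrix with coverage masking
#'
#' Sites x samples grid of (frequency, coverage, called). Cells with
#' coverage below `min_cov` are masked (`NA` frequency) and excluded from
#' every downstream statistic — they correspond to measurements the
#' variant-calling depth rule would have rejected.
#'
#' @param rdds an [rdd_set()].
#' @param min_cov masking threshold.
#' @return list `sites`, `freq` (masked), `freq_raw`, `cov`, `called`,
#'   `samples`, `min_cov`; class `editing_matrix`.
#' @export
editing_matrix <- function(rdds, min_cov = 10L) {
  stopifnot(inherits(rdds, "rdd_set"))
  freq <- rdds$freq
  freq[rdds$cov < min_cov] <- NA_real_
  structure(list(sites = rdds$sites, freq = freq, freq_raw = rdds$freq,
                 cov = rdds$cov, called = rdds$called,
                 samples = rdds$samples, min_cov = min_cov),
            class = "editing_matrix")
}

#' Heatmap site selection
#'
#' Sites with at least `min_cov` coverage and an editing frequency
#' strictly greater than `min_freq` in at least one sample.
#'
#' @param em an [editing_matrix()].
#' @param min_cov,min_freq selection thresholds.
#' @return integer vector of site row indices.
#' @export
heatmap_sites <- function(em, min_cov = 10L, min_freq = 0.4) {
  sel <- em$cov >= min_cov & !is.na(em$freq_raw) & em$freq_raw > min_freq
  which(rowSums(sel) >= 1L)
}

#' Variably-edited site selection
#'
#' Sites sufficiently expressed across samples and edited somewhere: at
#' least `min_cov` coverage in at least `min_samples` samples, and called
#' as an RDD in at least one sample.
#'
#' @param em an [editing_matrix()].
#' @param min_cov,min_samples selection thresholds.
#' @return integer vector of site row indices.
#' @export
variable_sites <- function(em, min_cov = 10L, min_samples = 2L) {
  which(rowSums(em$cov >= min_cov) >= min_samples &
          rowSums(em$called) >= 1L)
}

#' Binary sharing statistics
#'
#' Over the union of called sites, the fraction called in more than one
#' sample and the fraction called in all samples, optionally per stratum
#' (e.g. all sites / coding / non-synonymous). Editing frequency is
#' ignored: a site is a binary edited-or-not variable per sample.
#'
#' @param called logical sites x samples matrix (or an [rdd_set()] /
#'   [editing_matrix()], whose `called` is used).
#' @param strata optional named list of logical/integer row selectors
#'   defining strata; default a single `all` stratum.
#' @return data.table `stratum`, `n_sites` (called in >= 1 sample),
#'   `shared_any` (fraction called in >= 2), `shared_all`.
#' @export
sharing_stats <- function(called, strata = NULL) {
  if (inherits(called, "rdd_set") || inherits(called, "editing_matrix"))
    called <- called$called
  if (ncol(called) < 2L)
    stop("sharing statistics need >= 2 samples")
  if (is.null(strata)) strata <- list(all = seq_len(nrow(called)))
  rbindlist(lapply(names(strata), function(nm) {
    sub <- called[strata[[nm]], , drop = FALSE]
    nc <- rowSums(sub)
    u <- nc >= 1L
    data.table(stratum = nm, n_sites = sum(u),
               shared_any = if (sum(u)) mean(nc[u] >= 2L) else NA_real_,
               shared_all = if (sum(u)) mean(nc[u] == ncol(sub)) else
                 NA_real_)
  }))
}

## does a site overlap an intron of any transcript?
overlaps_intron <- function(chrom, pos, genes) {
  iv <- rbindlist(lapply(genes, function(g) {
    if (!nrow(g$introns)) return(NULL)
    data.table(chrom = g$chrom, start = g$introns[, 1],
               end = g$introns[, 2])
  }))
  if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(pos)))
  point_in_set(interval_set(iv$chrom, iv$start, iv$end), chrom, pos)
}

#' Canonical RDD counts by analyzed bases
#'
#' Per sample: analyzed bases (uniquely mapped reads x read length) and
#' the number of called A-to-I sites, with and without sites overlapping
#' an intron of any transcript. The intron-excluded recount is what
#' de-inflates intron-retention-rich samples.
#'
#' @param rdds an [rdd_set()].
#' @param sample_info data.frame with `sample_id`, `total_reads`,
#'   `read_length` (e.g. from [expression_table()]).
#' @param genes list of [gene_model()]s.
#' @return data.table per sample: `sample_id`, `analyzed_bases`,
#'   `n_rdd`, `n_rdd_no_intron`.
#' @export
rdd_counts_by_depth <- function(rdds, sample_info, genes) {
  si <- as.data.table(sample_info)
  canon <- rdds$sites$canonical
  in_intron <- overlaps_intron(rdds$sites$chrom, rdds$sites$pos, genes)
  rbindlist(lapply(seq_along(rdds$samples), function(i) {
    s <- rdds$samples[i]
    called <- rdds$called[, i] & canon
    row <- si[sample_id == s]
    data.table(sample_id = s,
               analyzed_bases = row$total_reads * row$read_length,
               n_rdd = sum(called),
               n_rdd_no_intron = sum(called & !in_intron))
  }))
}

#' Correlate per-site editing frequency with enzyme expression
#'
#' For every site x enzyme pair, the editing frequencies across samples
#' with at least `min_cov` coverage at the site are correlated with the
#' enzyme's expression in those samples (Pearson by default), testing
#' one-sided for positive association. Pairs with fewer than `min_pairs`
#' usable samples, or with zero variance on either side, are recorded as
#' untested. P-values are Benjamini-Hochberg adjusted across all performed
#' tests.
#'
#' @param em an [editing_matrix()] (subset to the variable sites first,
#'   e.g. via [variable_sites()]).
#' @param expression enzymes x samples numeric matrix (rownames = enzyme
#'   or isoform names, colnames matching `em$samples`).
#' @param min_cov per-site coverage required for a sample to enter the
#'   test.
#' @param min_pairs minimum usable samples per test.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.table `site_id`, `enzyme`, `n_pairs`, `estimate`,
#'   `p_value`, `p_adj`, `tested`; tested rows sorted by `p_adj` first.
#' @export
correlate_editing_enzymes <- function(em, expression, min_cov = 10L,
                                      min_pairs = 3L,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "editing_matrix"))
  if (is.null(colnames(expression)) ||
      !all(em$samples %in% colnames(expression)))
    stop("expression matrix must have columns for every sample")
  expression <- expression[, em$samples, drop = FALSE]
  keys <- site_key(em$sites$chrom, em$sites$pos)
  res <- list()
  for (i in seq_len(nrow(em$freq))) {
    usable <- em$cov[i, ] >= min_cov & !is.na(em$freq_raw[i, ])
    for (e in rownames(expression)) {
      f <- em$freq_raw[i, usable]
      x <- expression[e, usable]
      n <- sum(usable)
      if (n < min_pairs || stats::sd(f) == 0 || stats::sd(x) == 0) {
        res[[length(res) + 1L]] <- data.table(
          site_id = keys[i], enzyme = e, n_pairs = n,
          estimate = NA_real_, p_value = NA_real_, tested = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(f, x, alternative = "greater", method = method,
                        exact = FALSE))
      res[[length(res) + 1L]] <- data.table(
        site_id = keys[i], enzyme = e, n_pairs = n,
        estimate = unname(ct$estimate), p_value = ct$p.value,
        tested = TRUE)
    }
  }
  out <- rbindlist(res)
  out[, p_adj := NA_real_]
  out[tested == TRUE, p_adj := stats::p.adjust(p_value, method = "BH")]
  out[order(!tested, p_adj)]
}
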