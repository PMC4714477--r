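## RNA-DNA difference calling: strand inference through gene annotations,
## genomic subtraction against pooled WGS evidence, edit classification,
## and the full per-sample composition.

#' Default thresholds for the RDD pipeline
#'
#' All evidence thresholds in one place: read-level quality fraction (70%
#' of cycles at Q23), pileup evidence rules (10X coverage, 2 unique
#' supporting reads at Q23+, 10 bp read-end windows), the 5 bp intronic
#' splice-boundary buffer, the homopolymer run length, and the DNA-side
#' subtraction depth (> 20X with zero supporting reads).
#'
#' @param min_cov,min_alt_reads,min_base_qual,end_exclusion_bp SNV evidence
#'   thresholds (see [call_snvs()]).
#' @param splice_buffer_bp intronic splice-boundary buffer.
#' @param dna_min_cov DNA coverage must be strictly greater than this.
#' @param read_min_frac,read_min_qual read-level filter (see
#'   [filter_reads()]).
#' @param homopolymer_run minimal homopolymer run length.
#' @param unique_rule evidence multiplicity rule (see [call_snvs()]).
#' @param canonical_only keep only A-to-I sites in the final set.
#' @return named list of thresholds.
#' @export
rdd_config <- function(min_cov = 10L, min_alt_reads = 2L,
                       min_base_qual = 23L, end_exclusion_bp = 10L,
                       splice_buffer_bp = 5L, dna_min_cov = 20L,
                       read_min_frac = 0.7, read_min_qual = 23L,
                       homopolymer_run = 5L,
                       unique_rule = "distinct_starts",
                       canonical_only = FALSE) {
  as.list(environment())
}

#' Infer transcript strand at genomic positions
#'
#' A site inherits the strand of the annotated gene(s) containing it. Sites
#' outside every gene are rejected as `intergenic`; sites inside genes on
#' both strands are rejected as `strand_ambiguous`. Multiple genes on the
#' same strand are permitted.
#'
#' @param chrom,pos vectors of chromosome and 0-based position.
#' @param genes list of [gene_model()]s.
#' @return data.table with `chrom`, `pos`, `strand` (`NA` when rejected),
#'   `status` (`ok`, `intergenic`, `strand_ambiguous`), `gene_ids`
#'   (semicolon-joined).
#' @export
infer_strand <- function(chrom, pos, genes) {
  hits <- genes_at_points(genes, chrom, pos)
  res <- lapply(hits, function(idx) {
    if (!length(idx)) return(list(NA_character_, "intergenic", ""))
    g <- genes[idx]
    strands <- unique(vapply(g, `[[`, "", "strand"))
    gids <- sort(unique(vapply(g, `[[`, "", "gene_id")))
    if (length(strands) > 1L)
      return(list(NA_character_, "strand_ambiguous",
                  paste(gids, collapse = ";")))
    list(strands, "ok", paste(gids, collapse = ";"))
  })
  data.table(chrom = chrom, pos = pos,
             strand = vapply(res, `[[`, "", 1L),
             status = vapply(res, `[[`, "", 2L),
             gene_ids = vapply(res, `[[`, "", 3L))
}

#' Genomic subtraction of candidate RNA variants
#'
#' A candidate passes iff the pooled DNA evidence at the site has total
#' coverage strictly greater than `min_dna_cov` and zero reads supporting
#' the edited base (any base quality). Sites absent from the DNA pileup
#' fail with reason `dna_low_cov`.
#'
#' @param chrom,pos,alt candidate site vectors (0-based positions; `alt` on
#'   the genome strand).
#' @param dna_counts pooled per-(position, base) DNA counts as returned by
#'   `pooled_base_counts()` (summed over all WGS samples).
#' @param min_dna_cov DNA depth bound (strict inequality).
#' @return data.table `chrom`, `pos`, `alt`, `dna_cov`, `dna_alt`, `pass`,
#'   `reason` (`""`, `dna_low_cov` or `dna_support`).
#' @export
genomic_subtraction <- function(chrom, pos, alt, dna_counts,
                                min_dna_cov = 20L) {
  q <- data.table(chrom = chrom, pos = pos, alt = alt)
  covs <- unique(dna_counts[, .(chrom, pos, coverage)])
  q <- covs[q, on = c("chrom", "pos")]
  q[is.na(coverage), coverage := 0L]
  altc <- dna_counts[, .(chrom, pos, base, count)]
  q <- altc[q, on = c("chrom", "pos", "base" = "alt")]
  setnames(q, "base", "alt")
  q[is.na(count), count := 0L]
  q[, `:=`(
    pass = coverage > min_dna_cov & count == 0L,
    reason = fifelse(coverage <= min_dna_cov, "dna_low_cov",
                     fifelse(count > 0L, "dna_support", "")))]
  q[, .(chrom, pos, alt, dna_cov = coverage, dna_alt = count, pass, reason)]
}

#' Classify an edit by strand-corrected base change
#'
#' Sense bases are the genomic bases reverse-complemented when the
#' transcript strand is `-`. The class label is `"<sense_ref>-to-<X>"`,
#' with the canonical adenosine-to-inosine event (sense A>G; genomic A>G on
#' `+`, T>C on `-`) labelled `A-to-I`.
#'
#' @param ref,alt genomic-strand reference and alternate bases.
#' @param strand transcript strand, `"+"` or `"-"`.
#' @return data.table `sense_ref`, `sense_alt`, `edit_class`, `canonical`.
#' @export
classify_edit <- function(ref, alt, strand) {
  sense_ref <- fifelse(strand == "-", comp_base(ref), ref)
  sense_alt <- fifelse(strand == "-", comp_base(alt), alt)
  canonical <- sense_ref == "A" & sense_alt == "G"
  edit_class <- fifelse(canonical, "A-to-I",
                        paste0(sense_ref, "-to-", sense_alt))
  data.table(sense_ref = sense_ref, sense_alt = sense_alt,
             edit_class = edit_class, canonical = canonical)
}

#' Call RNA-DNA differences across samples
#'
#' The full composition per RNA sample: read-level filtering, pileup,
#' candidate SNV calling, positional exclusion filters, transcript-strand
#' inference, genomic subtraction against the pooled DNA samples, and edit
#' classification. Sites surviving in at least one RNA sample are unified
#' into an [rdd_set()] with per-sample frequency, coverage and called
#' flags; frequency and coverage are reported for non-called samples
#' whenever depth is at least 1.
#'
#' @param rna_samples named list of RNA `read_table`s (one per sample;
#'   unfiltered — the read-level filter is applied here).
#' @param dna_samples named list of DNA `read_table`s (>= 1 required).
#' @param genome genome container.
#' @param genes list of [gene_model()]s.
#' @param tracks an [exclusion_tracks()] object.
#' @param config threshold list from [rdd_config()].
#' @return an [rdd_set()]; attribute `funnel` holds per-sample counts
#'   through every filter stage, attribute `subtraction` the per-candidate
#'   DNA audit table.
#' @export
call_rdds <- function(rna_samples, dna_samples, genome, genes, tracks,
                      config = rdd_config()) {
  if (!length(dna_samples))
    stop("no DNA samples provided: genomic subtraction is impossible")
  if (is.null(names(rna_samples)) || any(!nzchar(names(rna_samples))))
    stop("rna_samples must be a named list")
  samples <- names(rna_samples)
  funnel <- list()
  per_sample_calls <- list()
  per_sample_counts <- list()  # (chrom,pos,base,count,coverage)
  for (s in samples) {
    fr <- filter_reads(rna_samples[[s]], config$read_min_frac,
                       config$read_min_qual)
    fc <- attr(fr, "filter_counts")
    pu <- build_pileup(fr)
    calls <- call_snvs(pu, genome, config$min_cov, config$min_alt_reads,
                       config$min_base_qual, config$end_exclusion_bp,
                       config$unique_rule)
    calls <- apply_region_filters(calls, tracks, genes,
                                  config$splice_buffer_bp)
    pass <- passing_calls(calls)
    str_info <- infer_strand(pass$chrom, pass$pos, genes)
    pass <- cbind(pass, str_info[, .(strand, status, gene_ids)])
    stranded <- pass[status == "ok"]
    funnel[[s]] <- list(
      reads_in = fc$input, reads_low_quality = fc$low_quality,
      reads_not_unique = fc$not_unique, reads_kept = fc$kept,
      snv_candidates = nrow(calls),
      region_filtered = nrow(calls) - nrow(pass),
      intergenic = sum(str_info$status == "intergenic"),
      strand_ambiguous = sum(str_info$status == "strand_ambiguous"),
      stranded_candidates = nrow(stranded))
    per_sample_calls[[s]] <- stranded
    bc <- pu[, .(count = .N), by = .(chrom, pos, base)]
    bc[, coverage := sum(count), by = .(chrom, pos)]
    per_sample_counts[[s]] <- bc
  }
  cand <- rbindlist(per_sample_calls, idcol = NULL)
  if (nrow(cand)) {
    cand_sites <- unique(cand[, .(chrom, pos, ref, alt, strand, gene_ids)])
  } else {
    cand_sites <- data.table(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             strand = character(), gene_ids = character())
  }
  ## DNA side: pooled counts at candidate positions only
  dna_pileups <- lapply(dna_samples, function(r) {
    fr <- filter_reads(r, config$read_min_frac, config$read_min_qual)
    build_pileup(fr, positions = cand_sites[, .(chrom, pos)])
  })
  dna_counts <- pooled_base_counts(dna_pileups)
  sub <- genomic_subtraction(cand_sites$chrom, cand_sites$pos,
                             cand_sites$alt, dna_counts,
                             config$dna_min_cov)
  surv <- sub[pass == TRUE, .(chrom, pos, alt)]
  sites <- cand_sites[surv, on = c("chrom", "pos", "alt")]
  cls <- classify_edit(sites$ref, sites$alt, sites$strand)
  sites <- cbind(
    sites[, .(chrom, pos, genomic_ref = ref, genomic_alt = alt, strand,
              gene_ids)], cls)
  setcolorder(sites, c("chrom", "pos", "genomic_ref", "genomic_alt",
                       "strand", "sense_ref", "sense_alt", "edit_class",
                       "canonical", "gene_ids"))
  if (isTRUE(config$canonical_only)) sites <- sites[canonical == TRUE]
  setkey(sites, chrom, pos)
  ## per-sample matrices over surviving sites
  n <- nrow(sites); m <- length(samples)
  freq <- matrix(NA_real_, n, m, dimnames = list(NULL, samples))
  cov <- matrix(0L, n, m, dimnames = list(NULL, samples))
  called <- matrix(FALSE, n, m, dimnames = list(NULL, samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    bc <- per_sample_counts[[s]]
    covs <- unique(bc[, .(chrom, pos, coverage)])
    j <- covs[sites[, .(chrom, pos)], on = c("chrom", "pos")]
    cov[, i] <- fifelse(is.na(j$coverage), 0L, j$coverage)
    ac <- bc[sites[, .(chrom, pos, base = genomic_alt)],
             on = c("chrom", "pos", "base")]
    altn <- fifelse(is.na(ac$count), 0L, ac$count)
    freq[, i] <- ifelse(cov[, i] >= 1L, altn / cov[, i], NA_real_)
    pc <- per_sample_calls[[s]]
    if (nrow(pc) && n) {
      key <- paste(sites$chrom, sites$pos, sites$genomic_alt)
      called[, i] <- key %in% paste(pc$chrom, pc$pos, pc$alt)
    }
  }
  out <- rdd_set(sites, freq, cov, called, samples)
  attr(out, "funnel") <- funnel
  attr(out, "subtraction") <- sub
  out
}
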