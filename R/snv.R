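## Candidate SNV calling and positional exclusion filters.

#' Call candidate RNA SNVs from a pileup
#'
#' For every position/alternate-base pair, evidence reads are the
#' supporting reads with base quality `>= min_base_qual`. A call is emitted
#' iff total coverage `>= min_cov`, there are at least `min_alt_reads`
#' "unique" evidence reads (distinct alignment starts by default, see
#' `unique_rule`), and at least one evidence base lies more than
#' `end_exclusion_bp` from both read ends (variants supported solely within
#' the terminal windows are discarded). Coverage counts every filtered-read
#' base regardless of base quality; quality gates evidence only. Positions
#' whose reference base is `N` are skipped.
#'
#' @param pileup a `pileup` built from filtered reads.
#' @param genome genome container for reference-base lookup.
#' @param min_cov minimum total coverage.
#' @param min_alt_reads minimum number of unique supporting reads.
#' @param min_base_qual Phred threshold for a supporting base to count as
#'   evidence.
#' @param end_exclusion_bp width of the terminal read windows; a base with
#'   0-based distance `< end_exclusion_bp` from either effective read end
#'   is "within" the window.
#' @param unique_rule `"distinct_starts"` (default): unique evidence reads
#'   are those with distinct alignment start coordinates; `"count"`: any
#'   `min_alt_reads` evidence reads suffice.
#' @return `snv_calls` data.table: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `alt_count` (all supporting reads), `total_coverage`,
#'   `frequency` (= alt_count / total_coverage), `sample_id`,
#'   `filters_failed` (empty string; filled by [apply_region_filters()]).
#' @export
call_snvs <- function(pileup, genome, min_cov = 10L, min_alt_reads = 2L,
                      min_base_qual = 23L, end_exclusion_bp = 10L,
                      unique_rule = c("distinct_starts", "count")) {
  unique_rule <- match.arg(unique_rule)
  empty <- empty_snv_calls()
  if (!nrow(pileup)) return(empty)
  cov <- pileup[, .(total_coverage = .N,
                    sample_id = sample_id[1]), by = .(chrom, pos)]
  cov <- cov[total_coverage >= min_cov]
  if (!nrow(cov)) return(empty)
  cand <- pileup[cov[, .(chrom, pos)], on = c("chrom", "pos")]
  cand <- cand[base %in% c("A", "C", "G", "T")]
  cov[, ref := genome_base(genome, chrom, pos)]
  cand <- cov[, .(chrom, pos, ref, total_coverage)][cand,
               on = c("chrom", "pos")]
  cand <- cand[ref != "N" & base != ref]
  if (!nrow(cand)) return(empty)
  ev <- cand[, {
    evid <- qual >= min_base_qual
    n_uniq <- if (unique_rule == "distinct_starts")
      uniqueN(aln_start[evid]) else sum(evid)
    .(alt_count = .N,
      n_unique_alt = n_uniq,
      interior = any(evid & end_dist >= end_exclusion_bp),
      total_coverage = total_coverage[1],
      ref = ref[1],
      sample_id = sample_id[1])
  }, by = .(chrom, pos, base)]
  calls <- ev[n_unique_alt >= min_alt_reads & interior == TRUE]
  if (!nrow(calls)) return(empty)
  out <- calls[, .(chrom, pos, ref, alt = base, alt_count, total_coverage,
                   frequency = alt_count / total_coverage, sample_id,
                   filters_failed = "")]
  setkey(out, chrom, pos)
  setattr(out, "class", c("snv_calls", class(out)))
  out
}

empty_snv_calls <- function() {
  out <- data.table(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), alt_count = integer(),
                    total_coverage = integer(), frequency = numeric(),
                    sample_id = character(), filters_failed = character())
  setattr(out, "class", c("snv_calls", class(out)))
  out
}

#' Detect homopolymer tracts in a genome
#'
#' Maximal runs of a single nucleotide with length `>= min_run`, including
#' runs abutting chromosome ends. `N` runs are reported too (they are
#' equally hostile to alignment).
#'
#' @param genome genome container.
#' @param min_run minimal run length.
#' @return an [interval_set()] of 0-based half-open run intervals.
#' @export
detect_homopolymers <- function(genome, min_run = 5L) {
  ch <- character(); st <- integer(); en <- integer()
  for (nm in names(genome)) {
    r <- rle(strsplit(as.character(genome[[nm]]), NULL)[[1]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_run
    if (any(keep)) {
      ch <- c(ch, rep(nm, sum(keep)))
      st <- c(st, (ends - r$lengths)[keep])
      en <- c(en, ends[keep])
    }
  }
  interval_set(ch, st, en)
}

#' Apply positional exclusion filters to SNV calls
#'
#' Marks calls that overlap any exclusion track (homopolymer, repeat
#' masker, multi-mappability, self-chain) and intronic calls within
#' `splice_buffer_bp` of an exon-intron boundary (distance is 1-based from
#' the junction: the first intronic base is at distance 1; distance
#' `<= splice_buffer_bp` fails, inclusive). The rule is restricted to
#' intronic positions — an exonic call near a boundary is untouched.
#' Filters have set semantics: reapplication or reordering cannot change
#' the result.
#'
#' @param calls `snv_calls` table.
#' @param tracks an [exclusion_tracks()] object.
#' @param genes list of [gene_model()]s (for intron/boundary geometry).
#' @param splice_buffer_bp buffer width in bp.
#' @return the calls with `filters_failed` updated (semicolon-joined,
#'   sorted filter names among `homopolymer`, `repeat`, `multimap`,
#'   `self_chain`, `splice_boundary`).
#' @export
apply_region_filters <- function(calls, tracks, genes,
                                 splice_buffer_bp = 5L) {
  if (!nrow(calls)) return(calls)
  track_names <- c(homopolymer = "homopolymer", repeat_masker = "repeat",
                   multimap = "multimap", self_chain = "self_chain")
  fail <- lapply(strsplit(calls$filters_failed, ";", fixed = TRUE),
                 function(x) x[nzchar(x)])
  for (tn in names(track_names)) {
    hit <- point_in_set(tracks[[tn]], calls$chrom, calls$pos)
    fail[hit] <- lapply(fail[hit], function(x) union(x, track_names[[tn]]))
  }
  near <- near_splice_boundary(calls$chrom, calls$pos, genes,
                               splice_buffer_bp)
  fail[near] <- lapply(fail[near], function(x) union(x, "splice_boundary"))
  out <- copy(calls)
  out[, filters_failed := vapply(fail, function(x)
    paste(sort(x), collapse = ";"), character(1))]
  setattr(out, "class", class(calls))
  out
}

## TRUE where the position is intronic in >= 1 transcript AND within
## `buffer` bp (1-based, inclusive) of that intron's exon junctions.
near_splice_boundary <- function(chrom, pos, genes, buffer = 5L) {
  out <- rep(FALSE, length(pos))
  if (!length(genes)) return(out)
  introns <- rbindlist(lapply(genes, function(g) {
    if (!nrow(g$introns)) return(NULL)
    data.table(chrom = g$chrom, start = g$introns[, 1], end = g$introns[, 2])
  }))
  if (is.null(introns) || !nrow(introns)) return(out)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- introns[chrom == ch]
    if (!nrow(sub)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(pos[sel] + 1L, width = 1L),
      IRanges::IRanges(sub$start + 1L, sub$end))
    if (!length(ov)) next
    p <- pos[sel][S4Vectors::queryHits(ov)]
    s <- sub$start[S4Vectors::subjectHits(ov)]
    e <- sub$end[S4Vectors::subjectHits(ov)]
    dist <- pmin(p - s + 1L, e - p)  # 1-based distance from nearer junction
    hit <- S4Vectors::queryHits(ov)[dist <= buffer]
    out[sel[unique(hit)]] <- TRUE
  }
  out
}

#' Calls passing all filters
#'
#' @param calls `snv_calls` with `filters_failed` populated.
#' @return subset with empty `filters_failed`.
#' @export
passing_calls <- function(calls) {
  out <- calls[filters_failed == ""]
  setattr(out, "class", class(calls))
  out
}
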