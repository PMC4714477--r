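## Read-level filtering and per-base pileups.
##
## A pileup is a long data.table with one row per aligned read base:
## chrom, pos (0-based), base, qual (Phred), end_dist (0-based distance of
## the base from the nearer end of the effective read, soft clips removed),
## aln_start (genomic start of the supporting read, the "distinct starts"
## evidence key), read_uid and sample_id. Only bases from reads that passed
## the read-level filters should enter a pileup; positions under splice (N)
## gaps and deletions receive no evidence, and inserted bases are never
## represented.

BASE_LOOKUP <- local({
  v <- rep("N", 256L)  # indexed by byte value + 1
  for (b in c("A", "C", "G", "T")) {
    v[utf8ToInt(b) + 1L] <- b
    v[utf8ToInt(tolower(b)) + 1L] <- b
  }
  v
})

#' Read-level quality and uniqueness filter
#'
#' Keeps reads where at least `min_frac` of the cycles have Phred scores
#' `>= min_qual` (default: at least 70% of cycles at Q23 or better) and the
#' read is uniquely mapped. Rejection counts by reason are stored in the
#' `filter_counts` attribute.
#'
#' @param reads a `read_table` from [read_sam()].
#' @param min_frac minimum fraction of cycles passing the quality bar.
#' @param min_qual Phred threshold defining a passing cycle.
#' @return the filtered `read_table`.
#' @export
filter_reads <- function(reads, min_frac = 0.7, min_qual = 23L) {
  if (!nrow(reads)) {
    attr(reads, "filter_counts") <- list(input = 0L, low_quality = 0L,
                                         not_unique = 0L, kept = 0L)
    return(reads)
  }
  qlens <- nchar(reads$qual)
  q <- decode_quals(reads$qual)
  ridx <- rep(seq_len(nrow(reads)), qlens)
  n_pass <- tabulate(ridx[q >= min_qual], nbins = nrow(reads))
  qual_ok <- n_pass >= min_frac * qlens
  uniq_ok <- reads$unique_flag
  keep_row <- qual_ok & uniq_ok
  out <- reads[keep_row]
  setattr(out, "class", class(reads))
  attr(out, "filter_counts") <- list(
    input = nrow(reads),
    low_quality = sum(!qual_ok),
    not_unique = sum(qual_ok & !uniq_ok),
    kept = sum(keep_row))
  out
}

#' Build a per-base pileup
#'
#' Walks each read's CIGAR: every aligned (M) base contributes one pileup
#' row; splice gaps and deletions contribute nothing; inserted and
#' soft-clipped bases are skipped. When `positions` is given, only those
#' sites are materialised (used for the genomic-subtraction lookups where a
#' full whole-genome DNA pileup would be wasteful).
#'
#' @param reads a filtered `read_table`.
#' @param positions optional data.frame/data.table with columns `chrom`,
#'   `pos` (0-based) restricting the pileup.
#' @return a `pileup` data.table (see file header for columns).
#' @export
build_pileup <- function(reads, positions = NULL) {
  empty <- data.table(chrom = character(), pos = integer(),
                      base = character(), qual = integer(),
                      end_dist = integer(), aln_start = integer(),
                      read_uid = integer(), sample_id = character())
  setattr(empty, "class", c("pileup", class(empty)))
  if (!nrow(reads)) return(empty)
  bl <- read_blocks(reads)
  if (!is.null(positions)) {
    positions <- as.data.table(positions)[, .(chrom, pos)]
    ## keep only (block, position) intersections
    hits <- list()
    for (ch in unique(positions$chrom)) {
      psel <- positions[chrom == ch]
      bsel <- which(reads$chrom[bl$ridx] == ch)
      if (!length(bsel)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(psel$pos + 1L, width = 1L),
        IRanges::IRanges(bl$gstart[bsel] + 1L,
                         bl$gstart[bsel] + bl$len[bsel]))
      if (!length(ov)) next
      b <- bsel[S4Vectors::subjectHits(ov)]
      p <- psel$pos[S4Vectors::queryHits(ov)]
      hits[[ch]] <- data.table(
        ridx = bl$ridx[b], pos = p,
        qoff = bl$qstart[b] + (p - bl$gstart[b]),
        eoff = bl$estart[b] + (p - bl$gstart[b]),
        elen = bl$elen[b])
    }
    if (!length(hits)) return(empty)
    ex <- rbindlist(hits)
  } else {
    n <- bl$len
    ridx_exp <- rep(bl$ridx, n)
    within <- sequence(n) - 1L
    ex <- data.table(
      ridx = ridx_exp,
      pos = rep(bl$gstart, n) + within,
      qoff = rep(bl$qstart, n) + within,
      eoff = rep(bl$estart, n) + within,
      elen = rep(bl$elen, n))
  }
  ## pull bases and qualities through concatenated-string indexing
  seq_nc <- nchar(reads$seq)
  offset0 <- c(0L, cumsum(seq_nc))[ex$ridx]
  seqraw <- charToRaw(paste(reads$seq, collapse = ""))
  qualall <- decode_quals(reads$qual)
  gidx <- offset0 + ex$qoff + 1L
  out <- data.table(
    chrom = reads$chrom[ex$ridx],
    pos = ex$pos,
    base = BASE_LOOKUP[as.integer(seqraw[gidx]) + 1L],
    qual = qualall[gidx],
    end_dist = pmin(ex$eoff, ex$elen - 1L - ex$eoff),
    aln_start = reads$pos0[ex$ridx],
    read_uid = ex$ridx,
    sample_id = reads$sample_id[ex$ridx])
  setkey(out, chrom, pos)
  setattr(out, "class", c("pileup", class(out)))
  out
}

#' Per-position coverage of a pileup
#'
#' @param pileup a `pileup`.
#' @return data.table `chrom`, `pos`, `coverage`.
#' @export
pileup_coverage <- function(pileup) {
  if (!nrow(pileup)) return(data.table(chrom = character(),
                                       pos = integer(),
                                       coverage = integer()))
  pileup[, .(coverage = .N), by = .(chrom, pos)]
}

#' Nucleotide evidence at one site
#'
#' Returns the per-base counts and supporting-read metadata at a single
#' genomic position — the unit of evidence behind every coverage and
#' supporting-read rule.
#'
#' @param pileup a `pileup`.
#' @param chrom,pos chromosome and 0-based position.
#' @return list with `counts` (named integer vector over A,C,G,T),
#'   `total_coverage`, and `reads` (data.table of base, qual, end_dist,
#'   aln_start, read_uid).
#' @export
site_counts <- function(pileup, chrom, pos) {
  ch <- chrom; p <- pos
  sub <- pileup[list(ch, p), nomatch = NULL]
  counts <- setNames(integer(4), c("A", "C", "G", "T"))
  if (nrow(sub)) {
    tab <- sub[base %in% names(counts), .N, by = base]
    counts[tab$base] <- tab$N
  }
  list(counts = counts, total_coverage = nrow(sub),
       reads = sub[, .(base, qual, end_dist, aln_start, read_uid)])
}

## Pool per-(pos, base) counts across a list of pileups; used for the
## DNA side of genomic subtraction (multiple WGS samples summed).
pooled_base_counts <- function(pileups) {
  dt <- rbindlist(lapply(pileups, function(p)
    if (nrow(p)) p[, .(chrom, pos, base)] else NULL))
  if (is.null(dt) || !nrow(dt))
    return(data.table(chrom = character(), pos = integer(),
                      base = character(), count = integer(),
                      coverage = integer()))
  counts <- dt[, .(count = .N), by = .(chrom, pos, base)]
  counts[, coverage := sum(count), by = .(chrom, pos)]
  counts
}
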