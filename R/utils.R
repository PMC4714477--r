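## Small shared helpers: sequence complements, Phred decoding, interval sets.

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#'
#' Vectorised over `x`; only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement single bases
#'
#' @param b character vector of single bases in `A`,`C`,`G`,`T`,`N`.
#' @return complemented bases.
#' @export
comp_base <- function(b) {
  out <- unname(COMP[b])
  if (anyNA(out)) stop("non-ACGTN base in comp_base(): ",
                       paste(unique(b[is.na(out)]), collapse = ","))
  out
}

## Decode many Phred-33 quality strings at once. Returns an integer vector
## of length sum(nchar(q)); split back with rep(seq_along(q), nchar(q)).
decode_quals <- function(q) {
  if (length(q) == 0L) return(integer(0))
  as.integer(charToRaw(paste(q, collapse = ""))) - 33L
}

encode_quals <- function(q) {
  ## q: integer vector; returns single string
  rawToChar(as.raw(q + 33L))
}

## ---- interval sets -------------------------------------------------------
## 0-based half-open intervals per chromosome, stored as a data.table with
## columns chrom/start/end. Queries go through IRanges.

#' Construct an interval set
#'
#' Interval sets hold 0-based half-open genomic intervals and support
#' point-membership queries. Overlapping or book-ended intervals are merged;
#' membership is unchanged by merging.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return an `interval_set` object.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  dt <- data.table(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end))
  if (nrow(dt) && any(dt$start >= dt$end))
    stop("interval_set: start >= end")
  ## merge per chromosome
  if (nrow(dt)) {
    ir <- split(IRanges::IRanges(dt$start + 1L, dt$end), dt$chrom)
    ir <- lapply(ir, IRanges::reduce)
    dt <- rbindlist(lapply(names(ir), function(ch) {
      data.table(chrom = ch, start = IRanges::start(ir[[ch]]) - 1L,
                 end = IRanges::end(ir[[ch]]))
    }))
    setkey(dt, chrom, start)
  }
  structure(list(intervals = dt), class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> ", nrow(x$intervals), " merged intervals on ",
      length(unique(x$intervals$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Point membership in an interval set
#'
#' @param set an [interval_set()].
#' @param chrom,pos vectors of chromosome names and 0-based positions.
#' @return logical vector: `TRUE` where the point lies inside an interval.
#' @export
point_in_set <- function(set, chrom, pos) {
  stopifnot(inherits(set, "interval_set"))
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  if (n == 0L || nrow(set$intervals) == 0L) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  iv <- set$intervals
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    sub <- iv[chrom == ch]
    if (!nrow(sub)) next
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(pos[sel] + 1L, width = 1L),
      IRanges::IRanges(sub$start + 1L, sub$end))
    out[sel] <- hits
  }
  out
}

## number of intervals (post-merge)
n_intervals <- function(set) nrow(set$intervals)

## stable per-site identifier used across tables and matrices
site_key <- function(chrom, pos) paste0(chrom, ":", pos)
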