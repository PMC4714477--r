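## Text SAM input/output and CIGAR decomposition.
##
## Reads are held in a data.table ("read_table"): one row per aligned read
## with 0-based start, CIGAR, SEQ/QUAL strings and a uniqueness flag.
## Aligned blocks (pairs of genomic interval and read-offset interval) are
## derived from the CIGAR on demand; N gaps are splice junctions, insertions
## contribute no pileup evidence, deletions shift genomic offsets, soft
## clips shift read offsets and are excluded from the effective read used
## for end-distance accounting.

CIGAR_RE <- "\\d+[MIDNSH=X]"

## Parse a character vector of CIGARs into a per-op table
## (cig_idx into the *unique* cigar vector, op, len).
parse_cigar_ops <- function(cigars) {
  m <- regmatches(cigars, gregexpr(CIGAR_RE, cigars))
  n_ops <- lengths(m)
  flat <- unlist(m, use.names = FALSE)
  data.table(cig_idx = rep(seq_along(cigars), n_ops),
             op = substr(flat, nchar(flat), nchar(flat)),
             len = as.integer(substr(flat, 1L, nchar(flat) - 1L)))
}

## Per-unique-CIGAR summary used for both pileups and junction calls:
## for each M block, its genomic offset from POS and its offset within SEQ;
## plus leading/trailing soft-clip lengths and total reference span.
cigar_layout <- function(cigars) {
  ops <- parse_cigar_ops(cigars)
  blocks <- vector("list", length(cigars))
  juncs <- vector("list", length(cigars))
  lead <- integer(length(cigars)); trail <- integer(length(cigars))
  qlen <- integer(length(cigars)); rspan <- integer(length(cigars))
  for (i in seq_along(cigars)) {
    sub <- ops[ops$cig_idx == i, ]
    g <- 0L; q <- 0L
    b <- list(); j <- list()
    for (k in seq_len(nrow(sub))) {
      op <- sub$op[k]; len <- sub$len[k]
      if (op %in% c("M", "=", "X")) {
        b[[length(b) + 1L]] <- c(g, q, len)
        g <- g + len; q <- q + len
      } else if (op == "I") q <- q + len
      else if (op == "D") g <- g + len
      else if (op == "N") { j[[length(j) + 1L]] <- c(g, g + len); g <- g + len }
      else if (op == "S") {
        if (k == 1L || (k == 2L && sub$op[1] == "H")) lead[i] <- len
        else trail[i] <- trail[i] + len
        q <- q + len
      }
      ## H consumes nothing
    }
    blocks[[i]] <- if (length(b)) do.call(rbind, b) else
      matrix(integer(), ncol = 3)
    juncs[[i]] <- if (length(j)) do.call(rbind, j) else
      matrix(integer(), ncol = 2)
    qlen[i] <- q
    rspan[i] <- g
  }
  list(blocks = blocks, junctions = juncs, lead_clip = lead,
       trail_clip = trail, qlen = qlen, ref_span = rspan)
}

#' Read aligned reads from a text SAM file
#'
#' Unmapped reads (flag 0x4) are skipped. Reads whose CIGAR-implied query
#' length disagrees with `SEQ` are rejected, counted and reported in the
#' `n_rejected` attribute. Mapping uniqueness is taken from the `NH` tag
#' when present (`NH == 1`); otherwise `MAPQ >= mapq_unique` is used.
#'
#' @param path path to a SAM file (text, with header).
#' @param sample_id sample identifier attached to every read.
#' @param mapq_unique MAPQ fallback threshold for uniqueness when no `NH`
#'   tag is present.
#' @return a `read_table` data.table with columns `read_id`, `sample_id`,
#'   `flag`, `chrom`, `pos0` (0-based start), `mapq`, `cigar`, `seq`,
#'   `qual`, `nh`, `unique_flag`; attributes `n_rejected` (list of counts
#'   by reason).
#' @export
read_sam <- function(path, sample_id, mapq_unique = 20L) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  con <- file(path, "r")
  n_header <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "@")) break
    n_header <- n_header + 1L
  }
  close(con)
  dt <- tryCatch(
    fread(path, skip = n_header, header = FALSE, sep = "\t", fill = TRUE,
          quote = "", colClasses = list(character = 1), showProgress = FALSE),
    error = function(e) data.table())
  rejected <- list(unmapped = 0L, cigar_seq_mismatch = 0L)
  if (!nrow(dt)) {
    out <- empty_read_table(sample_id)
    attr(out, "n_rejected") <- rejected
    return(out)
  }
  if (ncol(dt) < 11L) stop("SAM body has fewer than 11 columns: ", path)
  ## optional tag columns -> NH
  nh <- rep(NA_integer_, nrow(dt))
  if (ncol(dt) > 11L) {
    for (j in seq(12L, ncol(dt))) {
      v <- as.character(dt[[j]])
      hit <- !is.na(v) & startsWith(v, "NH:i:")
      nh[hit] <- as.integer(substring(v[hit], 6L))
    }
  }
  out <- data.table(
    read_id = as.character(dt[[1]]), sample_id = sample_id,
    flag = as.integer(dt[[2]]), chrom = as.character(dt[[3]]),
    pos0 = as.integer(dt[[4]]) - 1L, mapq = as.integer(dt[[5]]),
    cigar = as.character(dt[[6]]), seq = as.character(dt[[10]]),
    qual = as.character(dt[[11]]), nh = nh)
  mapped <- bitwAnd(out$flag, 4L) == 0L
  rejected$unmapped <- sum(!mapped)
  out <- out[mapped]
  ## CIGAR/SEQ consistency: query-consuming ops must sum to nchar(seq)
  ucig <- unique(out$cigar)
  ops <- parse_cigar_ops(ucig)
  qlen <- ops[op %in% c("M", "I", "S", "=", "X"), sum(len), by = cig_idx]
  qmap <- integer(length(ucig)); qmap[qlen$cig_idx] <- qlen$V1
  ok <- out$seq == "*" | nchar(out$seq) == qmap[match(out$cigar, ucig)]
  rejected$cigar_seq_mismatch <- sum(!ok)
  out <- out[ok]
  out[, unique_flag := fifelse(!is.na(nh), nh == 1L, mapq >= mapq_unique)]
  out[, strand := fifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]
  setattr(out, "class", c("read_table", class(out)))
  attr(out, "n_rejected") <- rejected
  out
}

empty_read_table <- function(sample_id = character(0)) {
  out <- data.table(read_id = character(), sample_id = character(),
                    flag = integer(), chrom = character(), pos0 = integer(),
                    mapq = integer(), cigar = character(), seq = character(),
                    qual = character(), nh = integer(),
                    unique_flag = logical(), strand = character())
  setattr(out, "class", c("read_table", class(out)))
  out
}

#' Write a read table to text SAM
#'
#' @param reads a `read_table` (see [read_sam()]).
#' @param path output path.
#' @param genome genome container supplying `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, genome) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  Biostrings::width(genome)))
  con <- file(path, "w")
  writeLines(hdr, con)
  if (nrow(reads)) {
    reads <- reads[order(chrom, pos0)]
    body <- reads[, paste(read_id, flag, chrom, pos0 + 1L, mapq, cigar, "*",
                          0L, 0L, seq, qual,
                          paste0("NH:i:", fifelse(is.na(nh), 1L, nh)),
                          sep = "\t")]
    writeLines(body, con)
  }
  close(con)
  invisible(path)
}

## Aligned blocks of each read as a long table:
## read row index, genomic start, read (SEQ) offset start, length,
## effective-read offset start and effective read length (soft clips
## removed) for end-distance bookkeeping.
read_blocks <- function(reads) {
  if (!nrow(reads)) return(data.table(ridx = integer(), gstart = integer(),
    qstart = integer(), len = integer(), estart = integer(),
    elen = integer()))
  ucig <- unique(reads$cigar)
  lay <- cigar_layout(ucig)
  ci <- match(reads$cigar, ucig)
  nb <- vapply(lay$blocks, nrow, integer(1))[ci]
  bm <- do.call(rbind, lay$blocks[ci])
  data.table(ridx = rep(seq_len(nrow(reads)), nb),
             gstart = reads$pos0[rep(seq_len(nrow(reads)), nb)] + bm[, 1],
             qstart = bm[, 2], len = bm[, 3],
             estart = bm[, 2] - lay$lead_clip[ci][rep(seq_len(nrow(reads)),
                                                      nb)],
             elen = (lay$qlen - lay$lead_clip - lay$trail_clip)[ci][
               rep(seq_len(nrow(reads)), nb)])
}

## Splice junctions (N gaps) of each read: 0-based half-open intron
## intervals (donor = first intronic base, acceptor = first exonic base
## after the gap).
read_junction_gaps <- function(reads) {
  if (!nrow(reads)) return(data.table(ridx = integer(), chrom = character(),
    donor = integer(), acceptor = integer()))
  ucig <- unique(reads$cigar)
  lay <- cigar_layout(ucig)
  ci <- match(reads$cigar, ucig)
  nj <- vapply(lay$junctions, nrow, integer(1))[ci]
  if (sum(nj) == 0L) return(data.table(ridx = integer(),
    chrom = character(), donor = integer(), acceptor = integer()))
  jm <- do.call(rbind, lay$junctions[ci])
  ridx <- rep(seq_len(nrow(reads)), nj)
  data.table(ridx = ridx, chrom = reads$chrom[ridx],
             donor = reads$pos0[ridx] + jm[, 1],
             acceptor = reads$pos0[ridx] + jm[, 2])
}
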