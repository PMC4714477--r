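## Gene models: one record per transcript, 0-based half-open intervals.
## UTRs and introns are derived from exon/CDS structure on the correct
## strand; for a "-" transcript the 5'UTR is the exon sequence downstream
## (in genomic coordinates) of the CDS.

#' Construct a gene model
#'
#' A gene model is one transcript of one gene: sorted non-overlapping exons,
#' an optional CDS contained in the exons, and derived 5'UTR / 3'UTR /
#' intron interval lists. All intervals are 0-based half-open two-column
#' matrices (`start`, `end`).
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds integer matrices with columns start, end (0-based
#'   half-open); `cds` may have zero rows for a non-coding transcript.
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds = matrix(integer(), ncol = 2)) {
  exons <- normalize_ivmat(exons)
  cds <- normalize_ivmat(cds)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(exons) == 0L) stop("gene model needs >= 1 exon")
  if (any(exons[, 1] >= exons[, 2])) stop("degenerate exon interval")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  if (nrow(cds)) {
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    if (!ivmat_contains(exons, cds))
      stop("CDS outside exons in transcript ", transcript_id)
    if (sum(cds[, 2] - cds[, 1]) %% 3L != 0L)
      warning("CDS length not divisible by 3 in transcript ",
              transcript_id, "; consequence prediction will refuse it")
  }
  introns <- if (nrow(exons) > 1L)
    cbind(exons[-nrow(exons), 2], exons[-1L, 1]) else
    matrix(integer(), ncol = 2)
  utr <- derive_utrs(exons, cds, strand)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 utr5 = utr$utr5, utr3 = utr$utr3, introns = introns),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$transcript_id, " (", x$gene_id, ") ", x$chrom,
      x$strand, " ", nrow(x$exons), " exon(s), ",
      if (nrow(x$cds)) paste0("CDS ", sum(x$cds[, 2] - x$cds[, 1]), " bp")
      else "non-coding", "\n", sep = "")
  invisible(x)
}

normalize_ivmat <- function(m) {
  if (is.null(m) || length(m) == 0L) return(matrix(integer(), ncol = 2))
  m <- matrix(as.integer(m), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m
}

## is every interval of b contained in the union of a?
ivmat_contains <- function(a, b) {
  if (!nrow(b)) return(TRUE)
  ia <- IRanges::reduce(IRanges::IRanges(a[, 1] + 1L, a[, 2]))
  ib <- IRanges::IRanges(b[, 1] + 1L, b[, 2])
  all(IRanges::countOverlaps(ib, ia, type = "within") >= 1L)
}

## set difference union(exons) \ union(cds), as an interval matrix
ivmat_setdiff <- function(a, b) {
  ia <- IRanges::reduce(IRanges::IRanges(a[, 1] + 1L, a[, 2]))
  ib <- IRanges::reduce(IRanges::IRanges(b[, 1] + 1L, b[, 2]))
  d <- IRanges::setdiff(ia, ib)
  cbind(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

derive_utrs <- function(exons, cds, strand) {
  empty <- matrix(integer(), ncol = 2)
  if (!nrow(cds)) return(list(utr5 = empty, utr3 = empty))
  non_cds <- ivmat_setdiff(exons, cds)
  if (!nrow(non_cds)) return(list(utr5 = empty, utr3 = empty))
  cds_lo <- min(cds[, 1]); cds_hi <- max(cds[, 2])
  left <- non_cds[non_cds[, 2] <= cds_lo, , drop = FALSE]
  right <- non_cds[non_cds[, 1] >= cds_hi, , drop = FALSE]
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Read gene models from GFF3
#'
#' Expects gene / mRNA (or transcript) / exon / CDS features linked by
#' `Parent` attributes. GFF3 1-based closed coordinates are converted to the
#' package's 0-based half-open convention; UTRs and introns are derived.
#' Transcripts whose CDS falls outside their exons, or whose CDS length is
#' not a multiple of 3, are rejected with a warning naming the transcript;
#' orphan exons/CDS are skipped with a warning.
#'
#' @param path path to a GFF3 file.
#' @return list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path, format = "gff3")
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(g)),
    start = BiocGenerics::start(g) - 1L,  # to 0-based half-open
    end = BiocGenerics::end(g),
    strand = as.character(BiocGenerics::strand(g)),
    type = as.character(g$type),
    id = if (!is.null(g$ID)) as.character(g$ID) else NA_character_,
    parent = vapply(as.list(g$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1)))
  tx <- dt[type %in% c("mRNA", "transcript")]
  genes <- dt[type == "gene"]
  parts <- dt[type %in% c("exon", "CDS")]
  orphans <- parts[!parent %in% tx$id]
  if (nrow(orphans))
    warning(nrow(orphans), " exon/CDS feature(s) with unknown Parent skipped")
  parts <- parts[parent %in% tx$id]
  models <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$id[i]
    gid <- tx$parent[i]
    if (is.na(gid)) gid <- tid
    ex <- parts[parent == tid & type == "exon"]
    cd <- parts[parent == tid & type == "CDS"]
    if (!nrow(ex)) {
      warning("transcript ", tid, " has no exons; skipped")
      next
    }
    m <- tryCatch(
      gene_model(gid, tid, tx$chrom[i], tx$strand[i],
                 cbind(ex$start, ex$end), cbind(cd$start, cd$end)),
      error = function(e) {
        warning("transcript ", tid, " rejected: ", conditionMessage(e))
        NULL
      })
    if (!is.null(m)) models[[length(models) + 1L]] <- m
  }
  models
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()] for the features the package uses (gene, mRNA,
#' exon, CDS).
#'
#' @param genes list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  by_gene <- split(genes, vapply(genes, `[[`, "", "gene_id"))
  fmt <- function(chrom, type, s, e, strand, attrs)
    paste(chrom, "rnaedit", type, s + 1L, e, ".", strand, ".", attrs,
          sep = "\t")
  for (gid in names(by_gene)) {
    txs <- by_gene[[gid]]
    lo <- min(vapply(txs, function(t) min(t$exons[, 1]), integer(1)))
    hi <- max(vapply(txs, function(t) max(t$exons[, 2]), integer(1)))
    lines <- c(lines, fmt(txs[[1]]$chrom, "gene", lo, hi, txs[[1]]$strand,
                          paste0("ID=", gid)))
    for (t in txs) {
      lines <- c(lines, fmt(t$chrom, "mRNA", min(t$exons[, 1]),
                            max(t$exons[, 2]), t$strand,
                            paste0("ID=", t$transcript_id, ";Parent=", gid)))
      for (j in seq_len(nrow(t$exons)))
        lines <- c(lines, fmt(t$chrom, "exon", t$exons[j, 1], t$exons[j, 2],
                              t$strand, paste0("Parent=", t$transcript_id)))
      for (j in seq_len(nrow(t$cds)))
        lines <- c(lines, fmt(t$chrom, "CDS", t$cds[j, 1], t$cds[j, 2],
                              t$strand, paste0("Parent=", t$transcript_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- gene indexing -------------------------------------------------------

## Gene-level span table: one row per gene (all transcripts pooled).
gene_spans <- function(genes) {
  if (!length(genes)) return(data.table(gene_id = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character()))
  dt <- rbindlist(lapply(genes, function(g)
    data.table(gene_id = g$gene_id, chrom = g$chrom,
               start = min(g$exons[, 1]), end = max(g$exons[, 2]),
               strand = g$strand)))
  dt[, .(start = min(start), end = max(end), chrom = chrom[1],
         strand = strand[1]), by = gene_id]
}

## genes (list of gene_model) overlapping each query point; returns a list
## of integer index vectors into `genes`
genes_at_points <- function(genes, chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  spans <- rbindlist(lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    data.table(idx = i, chrom = g$chrom, start = min(g$exons[, 1]),
               end = max(g$exons[, 2]))
  }))
  out <- vector("list", length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- spans[chrom == ch]
    if (!nrow(sub)) { out[sel] <- list(integer(0)); next }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(pos[sel] + 1L, width = 1L),
      IRanges::IRanges(sub$start + 1L, sub$end))
    hl <- split(sub$idx[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(sel)))
    out[sel] <- lapply(hl, as.integer)
  }
  out
}
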