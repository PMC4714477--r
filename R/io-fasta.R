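#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masked lowercase input is accepted); the
#' original case is not retained. Chromosome names are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] (the package's genome
#'   container); zero-length with a warning for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(Biostrings::DNAStringSet())
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name(s) in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ","))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence record in ", path)
  ## uppercase; reject characters outside the IUPAC alphabet early
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = width)
  invisible(path)
}

## character sequence of one chromosome
chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  as.character(genome[[chrom]])
}

chrom_len <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  Biostrings::width(genome)[match(chrom, names(genome))]
}

## Vectorised single-base lookup at 0-based positions. Returns characters.
genome_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- genome[[ch]]
    p <- pos[sel]
    if (any(p < 0L) || any(p >= length(s)))
      stop("position out of range on ", ch)
    out[sel] <- as.character(Biostrings::extractAt(
      s, IRanges::IRanges(p + 1L, width = 1L)))
  }
  out
}

## Extract 0-based half-open windows [start, end) as character strings.
genome_slice <- function(genome, chrom, start, end) {
  out <- character(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- genome[[ch]]
    if (any(start[sel] < 0L) || any(end[sel] > length(s)))
      stop("slice out of range on ", ch)
    out[sel] <- as.character(Biostrings::extractAt(
      s, IRanges::IRanges(start[sel] + 1L, end[sel])))
  }
  out
}
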