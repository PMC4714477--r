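## The rdd_set container and its tabular serialization.

#' Construct an RDD site set
#'
#' The central result container: one row per RNA-DNA difference site with
#' strand-resolved edit class, plus per-sample frequency, coverage and
#' called-flag matrices aligned to `sites` rows.
#'
#' @param sites data.table with columns `chrom`, `pos` (0-based),
#'   `genomic_ref`, `genomic_alt`, `strand`, `sense_ref`, `sense_alt`,
#'   `edit_class`, `canonical`, `gene_ids`.
#' @param freq,cov numeric/integer matrices, sites x samples. `freq` is NA
#'   where coverage is 0.
#' @param called logical matrix, sites x samples: whether the site
#'   independently survived all RNA-side filters in that sample.
#' @param samples character vector of sample identifiers (column order).
#' @return an `rdd_set` object.
#' @export
rdd_set <- function(sites, freq, cov, called, samples) {
  sites <- as.data.table(sites)
  stopifnot(nrow(sites) == nrow(freq), nrow(sites) == nrow(cov),
            nrow(sites) == nrow(called), ncol(freq) == length(samples))
  o <- order(sites$chrom, sites$pos)
  colnames(freq) <- colnames(cov) <- colnames(called) <- samples
  structure(list(sites = sites[o],
                 freq = freq[o, , drop = FALSE],
                 cov = cov[o, , drop = FALSE],
                 called = called[o, , drop = FALSE],
                 samples = samples),
            class = "rdd_set")
}

#' @export
print.rdd_set <- function(x, ...) {
  cat("<rdd_set> ", nrow(x$sites), " site(s) x ", length(x$samples),
      " sample(s); ", sum(x$sites$canonical), " canonical A-to-I\n",
      sep = "")
  invisible(x)
}

#' Number of sites in an rdd_set
#' @param x an `rdd_set`.
#' @return integer.
#' @export
n_sites <- function(x) nrow(x$sites)

#' Write RDD sites to a TSV table
#'
#' Positions are written 1-based; `genomic_ref`/`genomic_alt` are on the
#' genome (+) strand and `sense_ref`/`sense_alt` on the transcript strand.
#' Per-sample columns are `freq_<sample>`, `cov_<sample>`,
#' `called_<sample>`. Rows are ordered by (chrom, position). A leading `#`
#' comment line documents the column semantics.
#'
#' @param rdds an [rdd_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdd_table <- function(rdds, path) {
  stopifnot(inherits(rdds, "rdd_set"))
  dt <- copy(rdds$sites)
  dt[, pos := pos + 1L]  # 1-based in output
  for (i in seq_along(rdds$samples)) {
    s <- rdds$samples[i]
    dt[[paste0("freq_", s)]] <- round(rdds$freq[, i], 6)
    dt[[paste0("cov_", s)]] <- rdds$cov[, i]
    dt[[paste0("called_", s)]] <- as.integer(rdds$called[, i])
  }
  con <- file(path, "w")
  writeLines(paste0(
    "# pos: 1-based; genomic_ref/alt: genome + strand; sense_ref/alt: ",
    "transcript strand; freq_*: edited-read fraction; cov_*: filtered-read ",
    "depth; called_*: 1 if site survives all RNA-side filters in sample"),
    con)
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE, na = "NA",
         quote = FALSE)
  invisible(path)
}

#' Read an RDD table written by [write_rdd_table()]
#'
#' @param path path to the TSV.
#' @return an [rdd_set()].
#' @export
read_rdd_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, skip = "chrom",
              showProgress = FALSE)
  samples <- sub("^freq_", "", grep("^freq_", names(dt), value = TRUE))
  site_cols <- c("chrom", "pos", "genomic_ref", "genomic_alt", "strand",
                 "sense_ref", "sense_alt", "edit_class", "canonical",
                 "gene_ids")
  sites <- dt[, ..site_cols]
  sites[, pos := pos - 1L]
  sites[, canonical := as.logical(canonical)]
  getm <- function(prefix, mode) {
    m <- as.matrix(dt[, paste0(prefix, samples), with = FALSE])
    colnames(m) <- samples
    storage.mode(m) <- mode
    m
  }
  called <- getm("called_", "integer") == 1L
  rdd_set(sites, getm("freq_", "double"), getm("cov_", "integer"),
          called, samples)
}
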