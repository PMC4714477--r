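#' Read a BED file into an interval set
#'
#' Accepts 3+ column BED (0-based half-open). Lines with `start >= end` are
#' rejected with a warning; overlapping intervals are merged (membership is
#' unchanged).
#'
#' @param path path to a BED file.
#' @return an [interval_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) return(interval_set())
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1), showProgress = FALSE)
  if (!nrow(dt)) return(interval_set())
  if (ncol(dt) < 3L) stop("BED file needs >= 3 columns: ", path)
  dt <- dt[, 1:3]
  setnames(dt, c("chrom", "start", "end"))
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  bad <- dt$start >= dt$end
  if (any(bad)) {
    warning(sum(bad), " BED line(s) with start >= end rejected in ", path)
    dt <- dt[!bad]
  }
  interval_set(dt$chrom, dt$start, dt$end)
}

#' Write an interval set as 3-column BED
#'
#' @param set an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  stopifnot(inherits(set, "interval_set"))
  iv <- set$intervals
  if (!nrow(iv)) {
    file.create(path)
    return(invisible(path))
  }
  fwrite(iv[order(chrom, start), .(chrom, start, end)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' Read exclusion tracks
#'
#' Loads the four positional exclusion tracks used by the variant filters:
#' homopolymer runs, repeat-masker elements (low complexity, simple repeats,
#' satellites), multi-mappability regions, and self-chain regions.
#'
#' @param homopolymer,repeat_masker,multimap,self_chain BED paths; `NULL`
#'   gives an empty track.
#' @return named list of [interval_set()]s with class `exclusion_tracks`.
#' @export
exclusion_tracks <- function(homopolymer = NULL, repeat_masker = NULL,
                             multimap = NULL, self_chain = NULL) {
  load1 <- function(x) {
    if (is.null(x)) return(interval_set())
    if (inherits(x, "interval_set")) return(x)
    read_bed(x)
  }
  structure(list(homopolymer = load1(homopolymer),
                 repeat_masker = load1(repeat_masker),
                 multimap = load1(multimap),
                 self_chain = load1(self_chain)),
            class = "exclusion_tracks")
}
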