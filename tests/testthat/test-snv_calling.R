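# Read filters, pileups, and the SNV evidence rules.

test_that("read filter enforces the 70%-of-cycles-at-Q23 rule exactly", {
  mkqual <- function(n_hi, n_lo)
    paste0(strrep(rawToChar(as.raw(23L + 33L)), n_hi),
           strrep(rawToChar(as.raw(10L + 33L)), n_lo))
  seqs <- strrep("A", 100L)
  rd <- make_reads("chr1", c(0L, 0L, 0L), "100M", rep(seqs, 3),
                   qual = c(mkqual(70L, 30L),   # exactly 70% -> kept
                            mkqual(69L, 31L),   # 69% -> rejected
                            mkqual(100L, 0L)))
  rd$unique_flag[3] <- FALSE                     # high-quality multimapper
  rd$nh[3] <- 2L
  out <- filter_reads(rd)
  expect_equal(out$read_id, rd$read_id[1])
  fc <- attr(out, "filter_counts")
  expect_equal(fc$low_quality, 1L)
  expect_equal(fc$not_unique, 1L)
})

test_that("pileups follow the CIGAR: M contributes, N and D do not", {
  g <- make_genome(chr1 = strrep("ACGT", 100))
  rd <- make_reads("chr1", c(10L, 10L, 10L), "4M", rep("GGGG", 3))
  pu <- build_pileup(rd)
  sc <- site_counts(pu, "chr1", 11L)
  expect_equal(unname(sc$counts["G"]), 3L)
  expect_equal(sc$total_coverage, 3L)

  spl <- make_reads("chr1", 9L, "3M100N3M", "ACGTAC")
  pu2 <- build_pileup(spl)
  expect_equal(sort(pu2$pos), c(9L, 10L, 11L, 112L, 113L, 114L))

  del <- make_reads("chr1", 9L, "3M2D3M", "ACGTAC")
  pu3 <- build_pileup(del)
  expect_equal(sort(pu3$pos), c(9L, 10L, 11L, 14L, 15L, 16L))

  ins <- make_reads("chr1", 9L, "3M2I3M", "ACGTACGT")
  pu4 <- build_pileup(make_reads("chr1", 9L, "3M2I3M", "ACGTACGT"))
  expect_equal(sort(pu4$pos), c(9L, 10L, 11L, 12L, 13L, 14L))
  expect_equal(nrow(build_pileup(rnaedit:::empty_read_table())), 0L)
})

test_that("soft clips shift read offsets and end distances", {
  rd <- make_reads("chr1", 20L, "5S10M", strrep("A", 15L))
  pu <- build_pileup(rd)
  expect_equal(range(pu$pos), c(20L, 29L))
  ## effective read is 10 bp: first aligned base has end_dist 0
  expect_equal(pu[pos == 20L]$end_dist, 0L)
  expect_equal(pu[pos == 29L]$end_dist, 0L)
  expect_equal(max(pu$end_dist), 4L)
})

test_that("position-restricted pileups match the full pileup", {
  g <- make_genome(chr1 = strrep("ACGT", 1000))
  set.seed(11)
  starts <- sample.int(3000L, 200L) - 1L
  rd <- make_reads("chr1", starts, "20M",
                   substring(as.character(g[[1]]), starts + 1L,
                             starts + 20L))
  full <- build_pileup(rd)
  want <- data.table::data.table(chrom = "chr1",
                                 pos = c(100L, 1000L, 2500L))
  sub <- build_pileup(rd, positions = want)
  for (p in want$pos) {
    a <- site_counts(full, "chr1", p)
    b <- site_counts(sub, "chr1", p)
    expect_equal(b$counts, a$counts)
    expect_equal(b$total_coverage, a$total_coverage)
  }
  expect_true(all(sub$pos %in% want$pos))
})

## one locus, configurable evidence: ref reads then alt reads at chosen
## offsets/quals; genome is all-A so ref=A, alt=G
snv_fixture <- function(n_ref, alt_offsets, alt_qual = 30L,
                        alt_same_start = FALSE) {
  P <- 50L; rl <- 30L
  g <- make_genome(chr1 = strrep("A", 200L))
  ref_starts <- P - 25L + (seq_len(n_ref) - 1L) %% 26L
  alt_starts <- if (alt_same_start) rep(P - alt_offsets[1],
                                        length(alt_offsets)) else
    P - alt_offsets
  seqs <- c(rep(strrep("A", rl), n_ref),
            vapply(P - alt_starts, function(off) {
              s <- strrep("A", rl); substr(s, off + 1L, off + 1L) <- "G"; s
            }, character(1)))
  quals <- c(rep(strrep(rawToChar(as.raw(63L)), rl), n_ref),
             vapply(P - alt_starts, function(off) {
               q <- strrep(rawToChar(as.raw(63L)), rl)
               substr(q, off + 1L, off + 1L) <-
                 rawToChar(as.raw(alt_qual + 33L))
               q
             }, character(1)))
  rd <- make_reads("chr1", c(ref_starts, alt_starts), paste0(rl, "M"),
                   seqs, qual = 30L)
  rd$qual <- quals
  list(genome = g, reads = rd, P = P)
}

test_that("SNV calls respect coverage, unique-evidence and end rules", {
  ## coverage 9 (7 ref + 2 alt): no call
  fx <- snv_fixture(7L, c(14L, 15L))
  expect_equal(nrow(call_snvs(build_pileup(fx$reads), fx$genome)), 0L)
  ## coverage 28, 2 interior alt reads with distinct starts: call
  fx <- snv_fixture(26L, c(14L, 15L))
  calls <- call_snvs(build_pileup(fx$reads), fx$genome)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, fx$P)
  expect_equal(calls$ref, "A"); expect_equal(calls$alt, "G")
  expect_equal(calls$alt_count, 2L)
  expect_equal(calls$total_coverage, 28L)
  expect_equal(calls$frequency, 2 / 28)
  ## same two alt reads sharing one start: not "unique" evidence
  fx <- snv_fixture(26L, c(14L, 15L), alt_same_start = TRUE)
  expect_equal(nrow(call_snvs(build_pileup(fx$reads), fx$genome)), 0L)
  ## ...unless the count rule is chosen instead
  expect_equal(nrow(call_snvs(build_pileup(fx$reads), fx$genome,
                              unique_rule = "count")), 1L)
  ## 4 alt reads all within 10 bp of an end: no call
  fx <- snv_fixture(26L, c(3L, 5L, 27L, 25L))
  expect_equal(nrow(call_snvs(build_pileup(fx$reads), fx$genome)), 0L)
  ## low-quality alt bases count toward coverage but not evidence
  fx <- snv_fixture(26L, c(14L, 15L, 16L), alt_qual = 22L)
  expect_equal(nrow(call_snvs(build_pileup(fx$reads), fx$genome)), 0L)
})

test_that("homopolymer detection finds maximal runs including at ends", {
  g <- make_genome(chr1 = "CAAAAAG", chr2 = "ACGT", chr3 = "TTTTTT")
  s <- detect_homopolymers(g, min_run = 5L)
  iv <- s$intervals
  expect_equal(iv[chrom == "chr1", .(start, end)],
               data.table::data.table(start = 1L, end = 6L))
  expect_equal(nrow(iv[chrom == "chr2"]), 0L)
  expect_equal(iv[chrom == "chr3", .(start, end)],
               data.table::data.table(start = 0L, end = 6L))
})

test_that("region filters are set-semantic, inclusive at 5 bp, and
           restricted to intronic positions", {
  genes <- list(worked_gene("+"))
  tracks <- exclusion_tracks(
    homopolymer = interval_set("chr1", 400L, 410L),
    repeat_masker = interval_set("chr1", 250L, 260L))
  mkcalls <- function(pos) {
    dt <- data.table::data.table(
      chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "G",
      alt_count = 5L, total_coverage = 20L, frequency = 0.25,
      sample_id = "s1", filters_failed = "")
    data.table::setattr(dt, "class", c("snv_calls", class(dt)))
    dt
  }
  ## intron is [100,200): distances 5 and 6 from the left junction
  calls <- mkcalls(c(104L, 105L, 99L, 255L, 405L, 60L))
  out <- apply_region_filters(calls, tracks, genes)
  expect_equal(out$filters_failed,
               c("splice_boundary",  # distance 5: inclusive removal
                 "",                 # distance 6: passes
                 "",                 # exonic base 1 bp from boundary
                 "repeat", "homopolymer", ""))
  ## distance 5 from the right junction (pos 195..199 fail)
  out2 <- apply_region_filters(mkcalls(c(195L, 194L)), tracks, genes)
  expect_equal(out2$filters_failed, c("splice_boundary", ""))
  ## idempotent and order-independent
  twice <- apply_region_filters(out, tracks, genes)
  expect_equal(twice$filters_failed, out$filters_failed)
})

test_that("filter application is permutation-invariant on random calls", {
  set.seed(3)
  genes <- list(worked_gene("+"))
  tracks <- exclusion_tracks(
    homopolymer = interval_set("chr1", c(10L, 300L), c(20L, 310L)),
    multimap = interval_set("chr1", 150L, 260L))
  pos <- sample.int(320L, 50L) - 1L
  calls <- data.table::data.table(
    chrom = "chr1", pos = pos, ref = "A", alt = "G", alt_count = 3L,
    total_coverage = 15L, frequency = 0.2, sample_id = "s1",
    filters_failed = "")
  data.table::setattr(calls, "class", c("snv_calls", class(calls)))
  a <- apply_region_filters(calls, tracks, genes)
  perm <- sample(nrow(calls))
  b <- apply_region_filters(calls[perm], tracks, genes)
  expect_equal(b[order(pos)]$filters_failed, a[order(pos)]$filters_failed)
})
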