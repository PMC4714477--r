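# RPKM, junction counting, editing matrices, sharing, correlation.

## gene with a 1 kb single-exon CDS at [100, 1100)
rpkm_gene <- function() {
  gene_model("gR", "gR.t1", "chr1", "+",
             exons = rbind(c(0L, 1200L)), cds = rbind(c(100L, 1099L)))
}

test_that("RPKM follows the closed form and its scale properties", {
  g <- rpkm_gene()
  g$cds <- rbind(c(100L, 1100L))  # exactly 1 kb (frame irrelevant here)
  reads <- make_reads("chr1", rep(500L, 1000L), "50M",
                      rep(strrep("A", 50L), 1000L))
  out <- compute_rpkm(reads, list(g), total_reads = 1e6)
  expect_equal(out$rpkm, 1000)            # 1000 / (1kb x 1M/1e6)
  ## doubling the library halves RPKM
  out2 <- compute_rpkm(reads, list(g), total_reads = 2e6)
  expect_equal(out2$rpkm, 500)
  ## zero reads -> 0; zero CDS -> NA
  none <- make_reads("chr1", 5000L, "10M", strrep("A", 10L))
  expect_equal(compute_rpkm(none, list(g), total_reads = 1e6)$rpkm, 0)
  nc <- gene_model("gN", "gN.t1", "chr1", "+",
                   exons = rbind(c(0L, 500L)))
  expect_true(is.na(compute_rpkm(reads, list(nc),
                                 total_reads = 1e6)$rpkm))
})

test_that("reads overlapping two genes' CDS count toward both", {
  g1 <- gene_model("g1", "g1.t1", "chr1", "+",
                   exons = rbind(c(0L, 300L)), cds = rbind(c(0L, 300L)))
  g2 <- gene_model("g2", "g2.t1", "chr1", "-",
                   exons = rbind(c(250L, 600L)), cds = rbind(c(250L, 550L)))
  reads <- make_reads("chr1", 260L, "20M", strrep("A", 20L))
  out <- compute_rpkm(reads, list(g1, g2), total_reads = 100L)
  expect_equal(out$count, c(1L, 1L))
})

test_that("junction counting is exact-match with log2(FPKM+1) = 0 iff 0", {
  catalog <- data.frame(chrom = "chr1", donor = 12L, acceptor = 112L,
                        label = "gA.J1", strand = "+")
  reads <- make_reads("chr1", c(9L, 9L, 30L), c("3M100N3M", "3M100N3M",
                                                "6M"),
                      c("ACGTAC", "ACGTAC", "ACGTAC"))
  jm <- quantify_junctions(list(s1 = reads), catalog)
  expect_equal(unname(jm$counts[1, 1]), 2L)
  expect_gt(jm$norm[1, 1], 0)
  ## near-miss gap (donor off by one) counts zero
  near <- make_reads("chr1", 10L, "3M100N3M", "ACGTAC")
  jm2 <- quantify_junctions(list(s1 = near), catalog)
  expect_equal(unname(jm2$counts[1, 1]), 0L)
  expect_equal(unname(jm2$norm[1, 1]), 0)
})

## build an rdd_set directly from matrices
matrix_rdd_set <- function(freq, cov, called) {
  n <- nrow(freq)
  sites <- data.table::data.table(
    chrom = "chr1", pos = seq_len(n) * 100L, genomic_ref = "A",
    genomic_alt = "G", strand = "+", sense_ref = "A", sense_alt = "G",
    edit_class = "A-to-I", canonical = TRUE, gene_ids = "g1")
  rdd_set(sites, freq, cov, called, paste0("s", seq_len(ncol(freq))))
}

test_that("heatmap and variable site selectors apply their predicates", {
  freq <- rbind(c(0.41, 0.1, NA), c(0.9, NA, NA), c(0.2, 0.3, 0.1),
                c(0.5, 0.0, NA))
  cov <- rbind(c(12L, 30L, 0L), c(9L, 5L, 0L), c(40L, 12L, 3L),
               c(15L, 9L, 1L))
  called <- rbind(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                  c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  em <- editing_matrix(matrix_rdd_set(freq, cov, called))
  ## site 1: freq 0.41 > 0.4 at 12X -> in heatmap set
  ## site 2: 0.9 but never >= 10X -> out; site 3: covered but freq <= 0.4
  ## site 4: 0.5 at 15X -> in
  expect_equal(heatmap_sites(em), c(1L, 4L))
  ## variable: >= 10X in >= 2 samples and called somewhere
  expect_equal(variable_sites(em), c(1L, 3L))
  ## masking: frequencies hidden where coverage < 10
  expect_true(is.na(em$freq[2, 1]))
  expect_equal(unname(em$freq[1, 1]), 0.41)
  ## brute-force re-check of both predicates
  for (i in 1:4) {
    hm <- FALSE; nv <- 0L
    for (j in 1:3) {
      if (cov[i, j] >= 10L && !is.na(freq[i, j]) && freq[i, j] > 0.4)
        hm <- TRUE
      if (cov[i, j] >= 10L) nv <- nv + 1L
    }
    expect_equal(i %in% heatmap_sites(em), hm)
    expect_equal(i %in% variable_sites(em), nv >= 2L && any(called[i, ]))
  }
})

test_that("sharing statistics match enumeration on the worked example and
           on random binary matrices", {
  called <- rbind(c(TRUE, FALSE, FALSE),
                  c(TRUE, TRUE, FALSE),
                  c(TRUE, TRUE, TRUE))
  out <- sharing_stats(called)
  expect_equal(out$shared_any, 2 / 3)
  expect_equal(out$shared_all, 1 / 3)
  ## degenerate patterns
  expect_equal(sharing_stats(diag(3) == 1)$shared_any, 0)
  one <- matrix(TRUE, 1, 4)
  expect_equal(sharing_stats(one)$shared_any, 1)
  expect_equal(sharing_stats(one)$shared_all, 1)
  expect_error(sharing_stats(matrix(TRUE, 3, 1)), ">= 2 samples")
  ## randomised equivalence with the enumeration oracle
  set.seed(31)
  for (k in 1:25) {
    m <- matrix(runif(12 * 5) < 0.4, 12, 5)
    got <- sharing_stats(m)
    want <- oracle_sharing(m)
    expect_equal(c(got$shared_any, got$shared_all), want)
  }
})

test_that("strata restrict sharing to the given site subsets", {
  called <- rbind(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE),
                  c(TRUE, TRUE))
  out <- sharing_stats(called, strata = list(all = 1:4, coding = c(1L, 2L)))
  expect_equal(out[stratum == "coding"]$shared_any, 1 / 2)
  expect_equal(out[stratum == "all"]$n_sites, 3L)
})

test_that("intron-excluded RDD recounts are monotone and exact", {
  genes <- list(worked_gene("+"))
  freq <- rbind(c(0.5, 0.6), c(0.7, 0.2))
  cov <- rbind(c(20L, 20L), c(20L, 20L))
  called <- rbind(c(TRUE, TRUE), c(TRUE, FALSE))
  rd <- matrix_rdd_set(freq, cov, called)
  ## site rows sit at pos 100 and 200 after ordering: pos 100 is intronic
  ## ([100,200) is the worked intron), pos 200 is exonic
  si <- data.frame(sample_id = c("s1", "s2"), total_reads = c(1000, 2000),
                   read_length = c(50L, 50L))
  out <- rdd_counts_by_depth(rd, si, genes)
  expect_equal(out$analyzed_bases, c(50000, 100000))
  expect_equal(out$n_rdd, c(2L, 1L))
  ## s2's only call is the intronic site, so its recount drops to 0
  expect_equal(out$n_rdd_no_intron, c(1L, 0L))
  expect_true(all(out$n_rdd_no_intron <= out$n_rdd))
})

test_that("enzyme correlation finds perfect dose-response and skips
           degenerate sites", {
  freq <- rbind(seq(0.1, 0.6, length.out = 6),   # proportional to enzyme
                rep(0.5, 6))                     # constant -> untested
  cov <- matrix(30L, 2, 6)
  called <- matrix(TRUE, 2, 6)
  em <- editing_matrix(matrix_rdd_set(freq, cov, called))
  expr <- matrix(seq(10, 60, length.out = 6), 1,
                 dimnames = list("Adar", paste0("s", 1:6)))
  res <- correlate_editing_enzymes(em, expr)
  r1 <- res[site_id == "chr1:100"]
  expect_equal(r1$estimate, 1)
  expect_lt(r1$p_value, 1e-6)
  r2 <- res[site_id == "chr1:200"]
  expect_false(r2$tested)
  ## too few usable pairs -> untested
  cov2 <- cov; cov2[1, 3:6] <- 5L
  em2 <- editing_matrix(matrix_rdd_set(freq, cov2, called))
  res2 <- correlate_editing_enzymes(em2, expr)
  expect_false(res2[site_id == "chr1:100"]$tested)
  expect_equal(res2[site_id == "chr1:100"]$n_pairs, 2L)
})

test_that("one-sided positive-correlation test holds its nominal size on
           null data", {
  set.seed(17)
  n_sites <- 60L; n_samp <- 8L; reps <- 5L
  hits <- 0L; total <- 0L
  for (r in seq_len(reps)) {
    freq <- matrix(runif(n_sites * n_samp, 0.1, 0.9), n_sites)
    cov <- matrix(30L, n_sites, n_samp)
    called <- matrix(TRUE, n_sites, n_samp)
    em <- editing_matrix(matrix_rdd_set(freq, cov, called))
    expr <- matrix(runif(n_samp, 5, 50), 1,
                   dimnames = list("Adar", paste0("s", seq_len(n_samp))))
    res <- correlate_editing_enzymes(em, expr)
    hits <- hits + sum(res$p_value < 0.05, na.rm = TRUE)
    total <- total + sum(res$tested)
  }
  ## binomial 3-sigma envelope around alpha = 0.05
  expect_lt(abs(hits / total - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})
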