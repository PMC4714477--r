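# Genic context, coding consequence, sequence context, enrichment.

test_that("context classification matches the worked gene's geometry", {
  genes <- list(worked_gene("+"))
  out <- classify_context("chr1", c(60L, 150L, 270L, 20L), genes,
                          strand = "+")
  expect_equal(out$context, c("cds", "intron", "utr3", "utr5"))
  ## noncoding transcript: exonic bases are noncoding_exon everywhere
  nc <- list(gene_model("gN", "gN.t1", "chr1", "+",
                        exons = rbind(c(0L, 100L), c(200L, 300L))))
  out <- classify_context("chr1", c(60L, 150L), nc)
  expect_equal(out$context, c("noncoding_exon", "intron"))
})

test_that("cross-transcript conflicts resolve by the cds-first priority", {
  genes <- list(
    worked_gene("+"),                        # cds at 60
    gene_model("gX", "gX.t2", "chr1", "+",   # intronic at 60
               exons = rbind(c(0L, 30L), c(90L, 300L))))
  out <- classify_context("chr1", 60L, genes)
  expect_equal(out$context, "cds")
  expect_equal(out$transcript_id, "gX.t1")
})

test_that("context classification agrees with the brute-force per-base
           oracle on random in-gene positions", {
  set.seed(9)
  cfg <- small_sim_config()
  sim <- simulate_genome(cfg)
  spans <- lapply(sim$genes, function(g)
    c(min(g$exons[, 1]), max(g$exons[, 2])))
  pos <- integer(0); chs <- character(0); str <- character(0)
  for (k in seq_len(300L)) {
    gi <- sample.int(length(sim$genes), 1L)
    g <- sim$genes[[gi]]
    p <- sample(spans[[gi]][1]:(spans[[gi]][2] - 1L), 1L)
    pos <- c(pos, p); chs <- c(chs, g$chrom); str <- c(str, g$strand)
  }
  got <- classify_context(chs, pos, sim$genes, strand = str)
  want <- vapply(seq_along(pos), function(i)
    oracle_context(sim$genes, chs[i], pos[i], str[i]), character(1))
  expect_equal(got$context, want)
})

## 30-codon single-exon toy gene with a fixed sequence
toy_coding_gene <- function(strand = "+") {
  set.seed(123)
  utr <- 20L
  cds_seq <- paste(sample(c("A", "C", "G", "T"), 90L, replace = TRUE),
                   collapse = "")
  seq <- paste0(strrep("C", utr), cds_seq, strrep("G", utr))
  g <- make_genome(chr1 = seq)
  tx <- gene_model("gT", "gT.t1", "chr1", strand,
                   exons = rbind(c(0L, nchar(seq))),
                   cds = rbind(c(utr, utr + 90L)))
  list(genome = g, tx = tx, utr = utr)
}

test_that("consequence prediction handles the canonical examples", {
  ## CAA -> CGA: Gln to Arg, nonsynonymous (sense A>G at codon pos 2)
  g <- make_genome(chr1 = "CCCCAATTTGGG")
  tx <- gene_model("gQ", "gQ.t1", "chr1", "+",
                   exons = rbind(c(0L, 12L)), cds = rbind(c(3L, 12L)))
  out <- predict_consequence("chr1", 4L, "G", tx, g)
  expect_equal(out$consequence, "nonsynonymous")
  expect_equal(out$ref_codon, "CAA"); expect_equal(out$alt_codon, "CGA")
  expect_equal(out$ref_aa, "Q"); expect_equal(out$alt_aa, "R")
  ## GGA -> GGG: wobble, synonymous
  g2 <- make_genome(chr1 = "GGATTTTAA")
  tx2 <- gene_model("gW", "gW.t1", "chr1", "+",
                    exons = rbind(c(0L, 9L)), cds = rbind(c(0L, 9L)))
  out2 <- predict_consequence("chr1", 2L, "G", tx2, g2)
  expect_equal(out2$consequence, "synonymous")
  ## TAA -> CAA on ref stop: stop_loss; TGG -> TGA: stop_gain
  out3 <- predict_consequence("chr1", 6L, "C", tx2, g2)
  expect_equal(out3$consequence, "stop_loss")
})

test_that("consequence prediction agrees with full-CDS re-translation for
           every substitution of the toy gene, both strands", {
  for (strand in c("+", "-")) {
    fx <- toy_coding_gene(strand)
    for (p in fx$utr:(fx$utr + 89L)) {
      ref <- substring(as.character(fx$genome[[1]]), p + 1L, p + 1L)
      sense_ref <- if (strand == "-") comp_base(ref) else ref
      for (alt in setdiff(c("A", "C", "G", "T"), sense_ref)) {
        got <- predict_consequence("chr1", p, alt, fx$tx, fx$genome)
        want <- oracle_consequence(fx$tx, fx$genome, p, alt)
        expect_equal(got$consequence, want,
                     label = paste(strand, p, alt))
      }
    }
  }
})

test_that("context matrices are strand-corrected with unit columns", {
  g <- make_genome(chr1 = "AAAACGTTTTT")
  m <- context_matrix("chr1", 3L, "+", g, k = 2L)   # window AAACG
  expect_equal(unname(m["A", "0"]), 1)       # site base
  expect_equal(unname(m["A", "-1"]), 1)
  expect_equal(unname(m["C", "1"]), 1)
  expect_equal(unname(m["G", "2"]), 1)
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  ## minus strand: window is the reverse complement, CGTTT
  m2 <- context_matrix("chr1", 3L, "-", g, k = 2L)
  expect_equal(unname(m2["T", "0"]), 1)
  expect_equal(unname(m2["G", "-1"]), 1)
  ## near-end sites are dropped and counted
  m3 <- context_matrix("chr1", c(0L, 4L), c("+", "+"), g, k = 2L)
  expect_equal(attr(m3, "n_dropped"), 1L)
  expect_equal(attr(m3, "n_sites"), 1L)
})

test_that("off-center context columns approximate genome composition on
           uniformly placed sites", {
  set.seed(21)
  g <- make_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 50000L,
                                       replace = TRUE), collapse = ""))
  pos <- sample(100:49900, 1000L)
  m <- context_matrix("chr1", pos, "+", g, k = 3L)
  for (j in c("-3", "-1", "2")) {
    chi <- suppressWarnings(
      stats::chisq.test(round(m[, j] * 1000), p = rep(0.25, 4)))
    expect_gt(chi$p.value, 0.001)
  }
})

test_that("category enrichment matches a Fisher oracle and applies the
           odds-ratio and minimum-gene filters", {
  universe <- paste0("g", 1:100)
  edited <- paste0("g", 1:10)
  cmap <- data.frame(
    gene_id = c(paste0("g", 1:2), paste0("g", 11:18),   # catA: 2 edited
                paste0("g", 5), paste0("g", 30:33),     # catB: 1 edited
                universe),                              # catU: everything
    category = c(rep("catA", 10), rep("catB", 5), rep("catU", 100)))
  res <- category_enrichment(edited, universe, cmap)
  a <- res[category == "catA"]
  ## oracle 2x2: edited-in 2, edited-out 8, rest-in 8, rest-out 82
  or_expect <- (2 * 82) / (8 * 8)
  p_expect <- stats::fisher.test(matrix(c(2, 8, 8, 82), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
  expect_equal(a$odds_ratio, or_expect)
  expect_equal(a$p_value, p_expect)
  expect_equal(a$n_edited, 2L)
  expect_false(a$pass_filter)           # OR ~ 2.6 <= 10
  b <- res[category == "catB"]
  expect_false(b$pass_filter)           # single edited gene excluded
  u <- res[category == "catU"]
  expect_false(u$pass_filter)           # OR with a zero cell, corrected
  expect_true(all(res$p_adj >= res$p_value))
  ## Haldane correction on a zero cell: (2,0,8,90)
  cmap2 <- data.frame(gene_id = c("g1", "g2", paste0("x", 1:0)),
                      category = "catZ")
  univ2 <- c(paste0("g", 1:10), paste0("h", 1:90))
  res2 <- category_enrichment(c("g1", "g2"), univ2, cmap2)
  expect_equal(res2$odds_ratio,
               (2.5 * 98.5) / (0.5 * 0.5))
  expect_true(res2$pass_filter)
  expect_error(category_enrichment("g1", character(0), cmap), "universe")
})
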