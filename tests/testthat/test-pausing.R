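# One plus-strand and one minus-strand gene with hand-placed reads.
ei_fixture <- function() {
  genes <- make_genes(
    gene_id = c("fwd", "rev"),
    chrom = "chr1", strand = c("+", "-"),
    start = c(10000, 100000), end = c(30000, 120000)
  )
  list(genes = genes)
}

test_that("EI is the ratio of body to promoter density", {
  genes <- ei_fixture()$genes
  # uniform 1 read/bp over promoter and body of the + gene -> EI = 1
  reads <- tibble::tibble(chrom = "chr1",
                          start = 9750:11999, end = 9751:12000)
  ei <- compute_ei(reads, genes[1, ])
  expect_equal(ei$ei, 1.0)

  # promoter 4x denser than body -> EI = 0.5... construct: dp=4/bp, db=2/bp
  prom <- tibble::tibble(chrom = "chr1",
                         start = rep(9750:10099, 4), end = rep(9751:10100, 4))
  body <- tibble::tibble(chrom = "chr1",
                         start = rep(10100:11999, 2), end = rep(10101:12000, 2))
  ei2 <- compute_ei(dplyr::bind_rows(prom, body), genes[1, ])
  expect_equal(ei2$ei, 0.5)

  # scale invariance: triplicating every read leaves EI unchanged
  all_reads <- dplyr::bind_rows(prom, body)
  tripled <- dplyr::bind_rows(all_reads, all_reads, all_reads)
  expect_equal(compute_ei(tripled, genes[1, ])$ei, ei2$ei)
})

test_that("EI matches the per-base coverage oracle on synthetic reads", {
  g <- simulate_genome(30, seed = 41)
  genes <- filter_clear_signal(filter_min_length(g$genes))
  sim <- simulate_chip_reads(genes, seed = 43)
  ei <- suppressMessages(compute_ei(sim$control, genes))
  lib <- nrow(sim$control)
  for (i in sample(nrow(ei), 5)) {
    gi <- genes[genes$gene_id == ei$gene_id[i], ]
    pw <- if (gi$strand == "+") c(gi$tss - 250, gi$tss + 100)
          else c(gi$tss - 100, gi$tss + 250)
    bw <- if (gi$strand == "+") c(gi$tss + 100, gi$tss + 2000)
          else c(gi$tss - 2000, gi$tss - 100)
    dp <- oracle_base_density(sim$control, gi$chrom, pw[1], pw[2], lib)
    db <- oracle_base_density(sim$control, gi$chrom, bw[1], bw[2], lib)
    expect_equal(ei$ei[i], db / dp, tolerance = 1e-12)
  }
})

test_that("delta-EI uses a strict increase rule and self-comparison is null", {
  ei <- tibble::tibble(gene_id = c("a", "b"), dp = 1, db = c(2, 3),
                       ei = c(2, 3))
  self <- compute_delta_ei(ei, ei)
  expect_equal(self$delta_ei, c(1, 1))
  expect_false(any(self$increased))
  expect_equal(percent_increased(self), 0)

  doubled <- dplyr::mutate(ei, ei = ei * 2)
  d <- compute_delta_ei(ei, doubled)
  expect_equal(d$delta_ei, c(2, 2))
  expect_true(all(d$increased))
  expect_equal(percent_increased(d), 100)

  expect_error(compute_delta_ei(ei, dplyr::mutate(ei, gene_id = c("x", "y"))),
               "no shared genes")
})

test_that("planted EI values are recovered with high rank correlation", {
  g <- simulate_genome(300, seed = 51)
  genes <- filter_clear_signal(filter_min_length(g$genes))
  # >= 200 reads per gene: promoter 60 + body ~ EI * 326
  sim <- simulate_chip_reads(genes, seed = 53)
  ei <- suppressMessages(compute_ei(sim$control, genes))
  truth <- sim$truth$ei_true[match(ei$gene_id, sim$truth$gene_id)]
  expect_gt(stats::cor(ei$ei, truth, method = "spearman"), 0.95)
})

test_that("activity classification follows the peak-overlap truth table", {
  genes <- make_genes(gene_id = c("act", "none"), chrom = "chr1",
                      strand = "+", start = c(10000, 50000),
                      end = c(20000, 60000))
  ser2p <- tibble::tibble(chrom = "chr1", start = 10100, end = 10300)
  k27ac <- tibble::tibble(chrom = "chr1", start = 11000, end = 11200)
  k27me3 <- tibble::tibble(chrom = "chr2", start = 1, end = 100)
  lab <- classify_activity(genes, ser2p, k27ac, k27me3)
  expect_equal(as.character(lab$label), c("active", "inactive"))
})

test_that("activity labels equal the exhaustive oracle and partition the genes", {
  genes <- random_genes(1000, seed = 61, span = 2e7, min_len = 2000)
  ser2p <- random_intervals(400, seed = 62, span = 2e7)
  k27ac <- random_intervals(400, seed = 63, span = 2e7)
  k27me3 <- random_intervals(400, seed = 64, span = 2e7)
  lab <- classify_activity(genes, ser2p, k27ac, k27me3)
  expect_equal(as.character(lab$label),
               oracle_activity(genes, ser2p, k27ac, k27me3))
  counts <- table(lab$label)
  expect_equal(sum(counts), nrow(genes))

  lab2 <- classify_activity(genes, k27me3, k27ac, ser2p)
  expect_setequal(common_active_set(lab, lab),
                  lab$gene_id[lab$label == "active"])
  expect_equal(common_active_set(lab, lab2),
               intersect(lab$gene_id[lab$label == "active"],
                         lab2$gene_id[lab2$label == "active"]))
})
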