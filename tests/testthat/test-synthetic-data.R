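test_that("generators are deterministic given a seed", {
  g1 <- simulate_genome(50, seed = 201)
  g2 <- simulate_genome(50, seed = 201)
  expect_identical(g1, g2)
  expect_false(identical(g1$genes$start,
                         simulate_genome(50, seed = 202)$genes$start))

  c1 <- simulate_chip_reads(g1$genes, seed = 203)
  c2 <- simulate_chip_reads(g1$genes, seed = 203)
  expect_identical(c1, c2)
  expect_identical(simulate_wave(seed = 205, n_genes = 20,
                                 region_len = 20000),
                   simulate_wave(seed = 205, n_genes = 20,
                                 region_len = 20000))
  expect_identical(simulate_pulse_chase(seed = 207, n_genes = 50),
                   simulate_pulse_chase(seed = 207, n_genes = 50))
  expect_identical(simulate_atac(g1$genes[1:20, ], seed = 209),
                   simulate_atac(g1$genes[1:20, ], seed = 209))
})

test_that("single-gene genome is a valid annotation", {
  g <- simulate_genome(1, seed = 211)
  expect_equal(nrow(g$genes), 1L)
  expect_true(g$genes$start < g$genes$end)
  expect_true(g$chrom_sizes$size > g$genes$end)
})

test_that("planted close TSS pairs are removed by the clear-signal filter", {
  g <- simulate_genome(100, seed = 213, planted_close_pairs = 10,
                       pair_distance = 1000)
  survivors <- filter_clear_signal(g$genes)
  planted <- grep("_pair$", g$genes$gene_id, value = TRUE)
  partners <- sub("_pair$", "", planted)
  expect_true(all(!c(planted, partners) %in% survivors$gene_id))
  # all other genes are >= 5 kb apart and must survive
  others <- setdiff(g$genes$gene_id, c(planted, partners))
  expect_setequal(survivors$gene_id, others)
})

test_that("null ChIP simulation gives a ~50% increase rate, full response near 100%", {
  g <- simulate_genome(1000, seed = 215)
  genes <- filter_clear_signal(filter_min_length(g$genes))
  null <- simulate_chip_reads(genes, seed = 217, responder_fraction = 0)
  ei_c <- suppressMessages(compute_ei(null$control, genes))
  ei_t <- suppressMessages(compute_ei(null$treated, genes))
  pct_null <- percent_increased(suppressMessages(compute_delta_ei(ei_c, ei_t)))
  expect_lt(abs(pct_null - 50), 5)

  full <- simulate_chip_reads(genes[1:300, ], seed = 219,
                              responder_fraction = 1)
  ei_c2 <- suppressMessages(compute_ei(full$control, genes[1:300, ]))
  ei_t2 <- suppressMessages(compute_ei(full$treated, genes[1:300, ]))
  expect_gt(percent_increased(suppressMessages(
    compute_delta_ei(ei_c2, ei_t2))), 95)
})

test_that("wave generator plants fronts at speed * time", {
  sim <- simulate_wave(seed = 221, n_genes = 200, speed = 2,
                       timepoints = c(10, 20), region_len = 60000)
  tr <- sim$truth
  expect_equal(stats::median(tr$front_bp[tr$timepoint == 10]), 20000,
               tolerance = 0.05)
  expect_equal(stats::median(tr$front_bp[tr$timepoint == 20]), 40000,
               tolerance = 0.05)
  # median front is non-decreasing in time for a fixed speed
  expect_true(stats::median(tr$front_bp[tr$timepoint == 20]) >=
                stats::median(tr$front_bp[tr$timepoint == 10]))
})

test_that("noise-free wave counts reproduce fronts through the last-nonzero rule", {
  sim <- simulate_wave(seed = 223, n_genes = 100, speed = 2, timepoints = 10,
                       lambda_on = 25, lambda_off = 0, region_len = 50000)
  fit <- fit_wave_hmm(sim$counts$t10, bin_size = 100)
  called <- call_fronts(sim$counts$t10, fit)
  truth <- sim$truth[sim$truth$timepoint == 10, ]
  err <- abs(called$front_bp - truth$front_bp[match(called$gene_id,
                                                    truth$gene_id)])
  # quantised to bins and thinned by Poisson zeros near the front edge
  expect_gte(mean(err <= 200), 0.95)
})

test_that("speed ordering of two simulated cell lines is recovered", {
  speeds <- vapply(c(fast = 2.0, slow = 1.2), function(sp) {
    sim <- simulate_wave(seed = 225, n_genes = 100, speed = sp,
                         timepoints = c(10, 20, 40), region_len = 100000)
    fronts <- dplyr::bind_rows(lapply(names(sim$counts), function(tp) {
      fit <- fit_wave_hmm(sim$counts[[tp]], bin_size = 100)
      dplyr::mutate(call_fronts(sim$counts[[tp]], fit),
                    timepoint = as.numeric(sub("^t", "", tp)))
    }))
    estimate_speed(wave_summary(fronts))$speed
  }, numeric(1))
  expect_gt(speeds[["fast"]], speeds[["slow"]])
  expect_equal(speeds[["fast"]], 2.0, tolerance = 0.15)
  expect_equal(speeds[["slow"]], 1.2, tolerance = 0.15)
})

test_that("zero decay keeps retention at one; equal seeds give equal tables", {
  sim <- simulate_pulse_chase(seed = 227, n_genes = 500,
                              decay = c(A = 0, B = 0), timepoints = 6.5)
  keep <- median_activity_filter(list(sim$A$nascent_t0, sim$B$nascent_t0))
  r <- suppressMessages(compute_retention(sim$A$pulse_chase$t6.5,
                                          sim$A$nascent_t0, keep))
  expect_equal(stats::median(r$retention), 1, tolerance = 0.1)
})

test_that("ATAC generator respects the size mixture and plants dyads", {
  g <- simulate_genome(50, seed = 229)
  sim <- simulate_atac(g$genes, seed = 231,
                       size_mixture = c(sub = 0, mono = 1, di = 0))
  expect_true(all(sim$fragments$size >= 100 & sim$fragments$size <= 250))
  expect_equal(nrow(sim$truth), 100L)  # two dyads per gene
  expect_equal(unique(sim$truth$offset_from_tss[sim$truth$rank == 1]), 120)
  expect_equal(unique(sim$truth$offset_from_tss[sim$truth$rank == 2]), 310)

  no_mono <- simulate_atac(g$genes, seed = 233,
                           size_mixture = c(sub = 0.7, mono = 0, di = 0.3))
  expect_equal(sum(no_mono$fragments$size >= 127 &
                     no_mono$fragments$size <= 167), 0L)
})
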