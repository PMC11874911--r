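count_tab <- function(gene, exonic, lib = 1e6, cond = "c") {
  tab <- tibble::tibble(gene_id = sprintf("g%03d", seq_along(gene)),
                        gene_count = gene, exonic_count = exonic)
  attr(tab, "library_size") <- lib
  attr(tab, "condition") <- cond
  tab
}

test_that("intronic counts are gene minus exonic, floored at zero", {
  tab <- count_tab(c(100, 50, 30), c(60, 50, 45))
  expect_message(out <- derive_intronic(tab), "floored")
  expect_equal(out$intronic_count, c(40, 0, 0))
  rnd <- withr::with_seed(5, count_tab(rpois(200, 50), rpois(200, 30)))
  expect_equal(suppressMessages(derive_intronic(rnd))$intronic_count,
               pmax(rnd$gene_count - rnd$exonic_count, 0))
})

test_that("median filter keeps genes strictly above the median in every condition", {
  t1 <- count_tab(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(median_activity_filter(list(t1)), c("g004", "g005"))
  # above the median in one condition, below in another -> excluded
  t2 <- count_tab(c(5, 4, 3, 2, 1), rep(0, 5))
  expect_equal(median_activity_filter(list(t1, t2)), character(0))
  tabs <- withr::with_seed(7, lapply(1:3, function(i)
    count_tab(rpois(100, 40), rpois(100, 10))))
  manual <- Reduce(intersect, lapply(tabs, function(tt)
    tt$gene_id[tt$gene_count > median(tt$gene_count)]))
  expect_equal(median_activity_filter(tabs), manual)
})

test_that("retention is the CPM ratio of intronic(t1) to nascent(t0)", {
  pc <- derive_intronic(count_tab(c(80, 40), c(30, 40), lib = 2e6))
  nas <- count_tab(c(100, 100), c(0, 0), lib = 4e6)
  r <- compute_retention(pc, nas)
  # gene 1: (50/2e6) / (100/4e6) = 1.0; gene 2: intronic 0 -> 0
  expect_equal(r$retention, c(1, 0))

  # scaling either library by a constant rescales retention accordingly;
  # equal scaling of counts and library leaves it unchanged
  pc2 <- derive_intronic(count_tab(c(160, 80), c(60, 80), lib = 4e6))
  expect_equal(compute_retention(pc2, nas)$retention, r$retention)

  nas0 <- count_tab(c(0, 100), c(0, 0), lib = 1e6)
  expect_equal(nrow(compute_retention(pc, nas0)), 1L)  # zero baseline dropped
  expect_error(compute_retention(pc, nas, library_size_pc = 0), "positive")
})

test_that("simulated exponential decay is recovered by the retention median", {
  sim <- simulate_pulse_chase(seed = 91, n_genes = 800,
                              decay = c(A = 0.4, B = 0.1),
                              timepoints = c(1.5, 6.5))
  tabs <- c(list(sim$A$nascent_t0), sim$A$pulse_chase,
            list(sim$B$nascent_t0), sim$B$pulse_chase)
  keep <- median_activity_filter(tabs)
  for (cl in c("A", "B")) {
    lam <- c(A = 0.4, B = 0.1)[[cl]]
    for (tp in c(1.5, 6.5)) {
      r <- suppressMessages(compute_retention(
        sim[[cl]]$pulse_chase[[paste0("t", tp)]], sim[[cl]]$nascent_t0, keep))
      expect_equal(stats::median(r$retention), exp(-lam * tp),
                   tolerance = 0.1)
    }
  }
})

test_that("IQR permutation test is exchange-symmetric, seeded, and powered", {
  withr::with_seed(93, {
    a <- exp(stats::rnorm(500, log(0.2), 0.15))
    b <- exp(stats::rnorm(500, log(0.6), 0.15))
  })
  res <- permutation_t_test_iqr(a, b, seed = 11)
  expect_lte(res$p_value, 0.001)
  # label exchange: same p, opposite statistic sign
  res_swap <- permutation_t_test_iqr(b, a, seed = 11)
  expect_equal(res_swap$p_value, res$p_value)
  expect_equal(sign(res_swap$statistic), -sign(res$statistic))
  # determinism
  expect_equal(permutation_t_test_iqr(a, b, seed = 11)$p_value, res$p_value)
  expect_error(permutation_t_test_iqr(a[1:4], b), "underpowered")
})

test_that("identical groups are far from significance", {
  withr::with_seed(95, x <- exp(stats::rnorm(200, -1, 0.5)))
  res <- permutation_t_test_iqr(x, x, n_perm = 400, n_sampling = 40, seed = 3)
  expect_gte(res$p_value, 0.2)
})

test_that("cell line with halted decay shows higher late retention", {
  # line B stops losing introns: planted direction must be recovered
  sim <- simulate_pulse_chase(seed = 97, n_genes = 600,
                              decay = c(A = 0.4, B = 0.05),
                              timepoints = 6.5)
  keep <- median_activity_filter(c(
    list(sim$A$nascent_t0), sim$A$pulse_chase,
    list(sim$B$nascent_t0), sim$B$pulse_chase))
  rA <- suppressMessages(compute_retention(sim$A$pulse_chase$t6.5,
                                           sim$A$nascent_t0, keep))
  rB <- suppressMessages(compute_retention(sim$B$pulse_chase$t6.5,
                                           sim$B$nascent_t0, keep))
  expect_gt(stats::median(rB$retention), stats::median(rA$retention))
  res <- permutation_t_test_iqr(rA$retention, rB$retention,
                                n_perm = 500, n_sampling = 50, seed = 13)
  expect_lte(res$p_value, 0.01)
})
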