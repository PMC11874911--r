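test_that("Vplot accumulation places fragments at the right size and offset", {
  anchors <- tibble::tibble(chrom = "chr1", pos = c(1000, 5000), strand = "+")
  # size-147 fragments with midpoints exactly on each anchor
  frags <- tibble::tibble(chrom = "chr1",
                          start = c(1000, 5000) - 73, end = c(1000, 5000) + 74)
  vp <- build_vplot(frags, anchors)
  expect_equal(sum(vp$matrix), 2)
  expect_equal(vp$matrix["147", "0"], 2)

  # minus-strand anchor: a fragment 30 bp 3' of the dyad maps to offset +30
  minus <- tibble::tibble(chrom = "chr1", pos = 1000, strand = "-")
  frag <- tibble::tibble(chrom = "chr1", start = 970 - 50, end = 970 + 50)
  vm <- build_vplot(frag, minus)
  expect_equal(vm$matrix["100", "30"], 1)
})

test_that("Vplot equals the brute-force double loop and conserves mass", {
  withr::with_seed(101, {
    anchors <- tibble::tibble(chrom = "chr1",
                              pos = sort(sample.int(2e4, 20)),
                              strand = sample(c("+", "-"), 20, replace = TRUE))
  })
  frags <- random_intervals(10000, seed = 103, chroms = "chr1", span = 2e4,
                            min_len = 30, max_len = 280)
  vp <- build_vplot(frags, anchors)
  expect_equal(vp$matrix, oracle_vplot(frags, anchors))
  expect_equal(sum(vp$matrix), vp$n_pairs)
  dens <- build_vplot(frags, anchors, normalization = "density")
  expect_equal(sum(dens$matrix), 1)
})

test_that("Vplot subtraction floors at zero and is bounded by the minuend", {
  frags <- random_intervals(3000, seed = 107, chroms = "chr1", span = 1e4,
                            min_len = 50, max_len = 250)
  frags2 <- random_intervals(3000, seed = 109, chroms = "chr1", span = 1e4,
                             min_len = 50, max_len = 250)
  anchors <- tibble::tibble(chrom = "chr1", pos = c(2000, 7000), strand = "+")
  a <- build_vplot(frags, anchors, normalization = "density")
  b <- build_vplot(frags2, anchors, normalization = "density")
  d <- subtract_vplots(a, b)
  expect_true(all(d$matrix >= 0))
  expect_true(all(d$matrix <= a$matrix + 1e-15))
  expect_equal(d$matrix, pmax(a$matrix - b$matrix, 0))
  zero <- subtract_vplots(a, a)
  expect_true(all(zero$matrix == 0))
  expect_error(subtract_vplots(a, build_vplot(frags2, anchors, flank = 100,
                                              normalization = "density")),
               "dimensions")
})

test_that("flatten and band tests detect identity and planted direction", {
  frags <- random_intervals(3000, seed = 113, chroms = "chr1", span = 1e4,
                            min_len = 50, max_len = 250)
  anchors <- tibble::tibble(chrom = "chr1", pos = c(2000, 7000), strand = "+")
  a <- build_vplot(frags, anchors)
  same_flat <- vplot_flatten_test(a, a)
  expect_equal(same_flat$statistic, 0)
  expect_equal(same_flat$p_value, 1)
  same_band <- mononucleosome_band_test(a, a)
  expect_equal(same_band$p_value, 1)
  expect_true(same_band$degenerate)
  expect_error(mononucleosome_band_test(a, a, band = c(300, 400)), "band")

  # planted mononucleosome excess in b (midpoints jittered around the
  # anchors so the excess spreads across offsets): the band test must see it
  withr::with_seed(131, {
    mids <- rep(c(2000, 7000), each = 300) + round(stats::rnorm(600, 0, 40))
  })
  mono <- tibble::tibble(chrom = "chr1", start = mids - 73, end = mids + 74)
  b <- build_vplot(dplyr::bind_rows(frags, mono), anchors)
  band <- mononucleosome_band_test(a, b)
  expect_lt(band$p_value, 0.05)
})

test_that("mononucleosome band mass grows with the planted mono fraction", {
  g <- simulate_genome(80, seed = 115)
  band_mass <- vapply(c(0.1, 0.4, 0.7), function(p) {
    sim <- simulate_atac(g$genes, seed = 117,
                         size_mixture = c(sub = (1 - p) * 0.7, mono = p,
                                          di = (1 - p) * 0.3))
    tr <- sim$truth[sim$truth$rank == 1, ]
    anchors <- tibble::tibble(
      chrom = g$genes$chrom[match(tr$gene_id, g$genes$gene_id)],
      pos = tr$dyad_pos,
      strand = g$genes$strand[match(tr$gene_id, g$genes$gene_id)])
    vp <- build_vplot(sim$fragments, anchors, normalization = "density")
    rows <- vp$sizes >= 127 & vp$sizes <= 167
    sum(vp$matrix[rows, ])
  }, numeric(1))
  expect_true(all(diff(band_mass) > 0))
})

test_that("dyad calling recovers planted positions and spread", {
  g <- make_genes(gene_id = "g", chrom = "chr1", strand = "+",
                  start = 10000, end = 30000)
  # all midpoints at one coordinate -> dyad there with zero fuzziness
  mid <- 10120
  frags <- tibble::tibble(chrom = "chr1", start = mid - 73, end = mid + 74)
  frags <- frags[rep(1, 20), ]
  d <- call_dyads(frags, g)
  expect_equal(nrow(d), 1L)
  expect_equal(d$position, mid)
  expect_equal(d$fuzziness, 0)
  expect_equal(d$offset_from_tss, 120)

  # Normal(mu, 25) midpoints: dyad within +/-5 bp, fuzziness near 25
  withr::with_seed(119, {
    mids <- round(stats::rnorm(500, 10120, 25))
  })
  nf <- tibble::tibble(chrom = "chr1", start = mids - 73, end = mids + 74)
  dn <- call_dyads(nf, g)
  expect_equal(nrow(dn), 1L)
  expect_lte(abs(dn$position - 10120), 5)
  expect_lte(abs(dn$fuzziness - 25), 5)

  # two planted nucleosomes in the 1-kb window -> two calls within 10 bp
  withr::with_seed(121, {
    m1 <- round(stats::rnorm(300, 10120, 10))
    m2 <- round(stats::rnorm(300, 10310, 10))
  })
  two <- tibble::tibble(chrom = "chr1",
                        start = c(m1, m2) - 73, end = c(m1, m2) + 74)
  d2 <- call_dyads(two, g, region_width = 1000)
  expect_equal(nrow(d2), 2L)
  expect_lte(max(abs(sort(d2$position) - c(10120, 10310))), 10)

  # fewer than 5 supporting fragments -> no call
  sparse <- tibble::tibble(chrom = "chr1", start = 10120 - 73, end = 10120 + 74)
  expect_equal(nrow(call_dyads(sparse[rep(1, 3), ], g)), 0L)
})

test_that("spacing mode recovers planted distances and excludes > 1 kb", {
  genes <- make_genes(gene_id = c("a", "b", "c"), chrom = "chr1",
                      strand = "+", start = c(1e4, 5e4, 9e4),
                      end = c(3e4, 7e4, 11e4))
  dyads <- tibble::tibble(
    chrom = "chr1",
    position = c(1e4 + 120, 1e4 + 310,   # gene a: +1 at 120, +2 at 310
                 5e4 + 120, 5e4 + 310,   # gene b
                 9e4 + 1500))            # gene c: only a distant dyad
  sp <- spacing_mode(dyads, genes)
  expect_equal(sp$mode_distance[sp$rank == "+1"], 120)
  expect_equal(sp$mode_distance[sp$rank == "+2"], 310)
  expect_equal(sp$mode_distance[sp$rank == "spacing"], 190)
  expect_equal(sum(sp$n[sp$rank == "+1"]), 2)  # gene c excluded entirely
})

test_that("firmer nucleosomes yield lower fuzziness and extreme-EI groups compare", {
  g <- simulate_genome(120, seed = 123)
  tight <- simulate_atac(g$genes, seed = 125, positional_sd = 10)
  loose <- simulate_atac(g$genes, seed = 125, positional_sd = 30)
  dt <- call_dyads(tight$fragments, g$genes)
  dl <- call_dyads(loose$fragments, g$genes)
  j <- dplyr::inner_join(dt[dt$rank == 1, c("gene_id", "fuzziness")],
                         dl[dl$rank == 1, c("gene_id", "fuzziness")],
                         by = "gene_id", suffix = c("_t", "_l"))
  expect_gt(mean(j$fuzziness_t < j$fuzziness_l), 0.95)

  # planted fuzziness/delta-EI association shows up in the extremes test
  withr::with_seed(127, {
    n <- 400
    delta <- sort(stats::rlnorm(n, 0, 0.5))
    fz <- 10 + seq(0, 10, length.out = n) + stats::rnorm(n, 0, 1)
  })
  calls <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), fuzziness = fz,
                          rank = 1L)
  deltas <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), delta_ei = delta)
  expect_warning(res <- fuzziness_by_delta_ei(calls, deltas, n = 1000),
                 "shrinking")
  med <- tapply(res$groups$fuzziness, res$groups$group, median)
  expect_gt(med[["high_delta_ei"]], med[["low_delta_ei"]])
  expect_lt(res$test$p_value, 0.01)
})
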