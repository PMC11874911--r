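#' Simulate a non-pathological gene layout
#'
#' Places `n_genes` genes on a small set of chromosomes with at least
#' `min_gap` bp between consecutive genes, random strands, and lengths drawn
#' uniformly from `gene_length_range`. Optionally plants pairs of extra
#' genes whose TSSs sit `pair_distance` bp downstream of an existing TSS, to
#' exercise the clear-signal filter with known truth.
#'
#' @param n_genes Number of genes (> 0).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param gene_length_range Min/max gene length in bp.
#' @param min_gap Minimum intergenic gap in bp (default 5000).
#' @param genes_per_chrom Genes per simulated chromosome (default 500).
#' @param planted_close_pairs Number of extra close-TSS genes to plant
#'   (default 0).
#' @param pair_distance TSS-to-TSS distance of planted pairs in bp
#'   (default 1000).
#' @return A list with `genes` (a gene table; planted partners are named
#'   `<id>_pair`), and `chrom_sizes` (tibble `chrom`, `size`).
#' @export
simulate_genome <- function(n_genes = 1000, seed = 1,
                            gene_length_range = c(4000, 20000),
                            min_gap = 5000, genes_per_chrom = 500,
                            planted_close_pairs = 0, pair_distance = 1000) {
  stopifnot(n_genes > 0)
  with_seed_maybe(seed, {
    lens <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                   replace = TRUE)
    gaps <- min_gap + sample.int(15000L, n_genes, replace = TRUE)
    chrom_idx <- (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L
    genes <- tibble(
      gene_id = sprintf("G%05d", seq_len(n_genes)),
      chrom = paste0("chr", chrom_idx),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    start <- unlist(lapply(split(seq_len(n_genes), chrom_idx), function(idx) {
      cumsum(gaps[idx] + lens[idx]) - lens[idx]
    }), use.names = FALSE)
    genes$start <- as.integer(start)
    genes$end <- as.integer(start + lens)
    if (planted_close_pairs > 0) {
      pick <- seq_len(min(planted_close_pairs, n_genes))
      base <- genes[pick, ]
      partner <- dplyr::mutate(
        base,
        gene_id = paste0(.data$gene_id, "_pair"),
        start = ifelse(.data$strand == "+", .data$start + pair_distance,
                       .data$start),
        end = ifelse(.data$strand == "+", .data$end + pair_distance,
                     .data$end - pair_distance)
      )
      partner$end <- pmax(partner$end, partner$start + 1000L)
      genes <- dplyr::bind_rows(genes, partner)
    }
    genes <- gene_table(genes)
    chrom_sizes <- genes |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(size = max(.data$end) + 10000L, .groups = "drop")
    list(genes = genes, chrom_sizes = chrom_sizes)
  })
}

# Per-gene RNG substreams: gene i's reads depend only on (seed, i) and that
# gene's own parameters, so changing one gene's condition (e.g. its
# responder flag) leaves every other gene's draws untouched. This makes
# paired simulations with common random numbers possible.
gene_substream_seeds <- function(seed, n) {
  with_seed_maybe(seed, sample.int(2147483646L, n))
}

place_reads <- function(chrom, win_start, win_end, count, read_length,
                        noiseless = FALSE) {
  if (count <= 0) return(NULL)
  lo <- win_start
  hi <- win_end - read_length
  starts <- if (noiseless) {
    as.integer(round(seq(lo, hi, length.out = count)))
  } else {
    lo + sample.int(hi - lo + 1L, count, replace = TRUE) - 1L
  }
  tibble(chrom = chrom, start = starts, end = starts + as.integer(read_length))
}

#' Simulate paused-vs-elongating ChIP reads with known escape indices
#'
#' Per gene, a true escape index `EI` is drawn log-normally and reads are
#' placed uniformly (fully contained) in the promoter-proximal window
#' `[-250, +100)` and the body window `[+100, +2000)`, with expected counts
#' chosen so that the analytic density ratio equals the drawn EI. In the
#' treated (UV) condition, a planted fraction of responder genes has its
#' body intensity multiplied by `body_boost`, mimicking release of paused
#' polymerase into the gene body. With `noise = "poisson"` counts are
#' Poisson; with `noise = "none"` expected counts are rounded to integers
#' and the emitted ground-truth EI is recomputed from the realised counts,
#' so the measured EI equals the truth exactly.
#'
#' @param genes A gene table (>= 2 kb genes).
#' @param seed Integer seed.
#' @param ei_meanlog,ei_sdlog Log-normal parameters of the true EI
#'   (defaults 0 and 0.5).
#' @param responder_fraction Fraction of genes whose pause release responds
#'   to treatment (default 0.3).
#' @param body_boost Body-intensity multiplier for responders (default 2).
#' @param promoter_reads Expected promoter read count per gene (default 60).
#' @param read_length Read length in bp (default 50).
#' @param noise `"poisson"` (default) or `"none"`.
#' @return A list with `control` and `treated` read tibbles and `truth`
#'   (tibble: `gene_id`, `ei_true`, `ei_true_treated`, `responder`).
#' @export
simulate_chip_reads <- function(genes, seed, ei_meanlog = 0, ei_sdlog = 0.5,
                                responder_fraction = 0.3, body_boost = 2,
                                promoter_reads = 60, read_length = 50,
                                noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  genes <- gene_table(genes)
  n <- nrow(genes)
  prom <- oriented_window(genes$tss, genes$strand, 250L, 100L)
  body <- oriented_window(genes$tss, genes$strand, -100L, 2000L)
  prom_len <- 350
  body_len <- 1900
  sub_seeds <- gene_substream_seeds(seed, n)
  shared <- with_seed_maybe(derive_seed(seed, 1L), {
    list(
      ei = stats::rlnorm(n, ei_meanlog, ei_sdlog),
      responder = stats::runif(n) < responder_fraction
    )
  })
  noiseless <- noise == "none"
  res <- purrr::map(seq_len(n), function(i) {
    withr::with_seed(sub_seeds[i], {
      mu_p <- promoter_reads
      mu_b <- shared$ei[i] * mu_p * body_len / prom_len
      boost <- if (shared$responder[i]) body_boost else 1
      if (noiseless) {
        np0 <- max(round(mu_p), 1); nb0 <- round(mu_b)
        np1 <- np0; nb1 <- round(mu_b * boost)
      } else {
        np0 <- stats::rpois(1, mu_p); nb0 <- stats::rpois(1, mu_b)
        np1 <- stats::rpois(1, mu_p); nb1 <- stats::rpois(1, mu_b * boost)
      }
      list(
        control = dplyr::bind_rows(
          place_reads(genes$chrom[i], prom$start[i], prom$end[i], np0,
                      read_length, noiseless),
          place_reads(genes$chrom[i], body$start[i], body$end[i], nb0,
                      read_length, noiseless)),
        treated = dplyr::bind_rows(
          place_reads(genes$chrom[i], prom$start[i], prom$end[i], np1,
                      read_length, noiseless),
          place_reads(genes$chrom[i], body$start[i], body$end[i], nb1,
                      read_length, noiseless)),
        counts = c(np0, nb0, np1, nb1)
      )
    })
  })
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  truth <- tibble(
    gene_id = genes$gene_id,
    responder = shared$responder,
    ei_true = if (noiseless) {
      (counts[, 2] / body_len) / (counts[, 1] / prom_len)
    } else shared$ei,
    ei_true_treated = if (noiseless) {
      (counts[, 4] / body_len) / (counts[, 3] / prom_len)
    } else shared$ei * ifelse(shared$responder, body_boost, 1)
  )
  list(
    control = dplyr::bind_rows(lapply(res, `[[`, "control")),
    treated = dplyr::bind_rows(lapply(res, `[[`, "treated")),
    truth = truth
  )
}

#' Simulate elongation-wave binned counts with known fronts
#'
#' Each gene's true wave front at chase time `t` is
#' `speed * 1000 * t + Normal(0, front_jitter_sd)`, clipped to the region.
#' Bin counts are Poisson with mean `lambda_on` before the front and
#' `lambda_off` after it (the bin straddling the front gets the
#' length-weighted mixture).
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 300).
#' @param speed True elongation speed in kb/min (default 2).
#' @param timepoints Chase times in minutes (default `c(10, 20, 60)`).
#' @param lambda_on,lambda_off Poisson means per bin (defaults 15 and 0.3).
#' @param bin_size Bin width in bp (default 100).
#' @param region_len Profiled region length in bp (default 150000, long
#'   enough that a 2 kb/min front is uncensored at 60 min).
#' @param front_jitter_sd Per-gene front jitter in bp (default 2000).
#' @return A list with `counts` (named list of gene-by-bin matrices, one per
#'   timepoint), `truth` (tibble `gene_id`, `timepoint`, `front_bp`),
#'   `bin_size`, `region_len`.
#' @export
simulate_wave <- function(seed, n_genes = 300, speed = 2,
                          timepoints = c(10, 20, 60),
                          lambda_on = 15, lambda_off = 0.3,
                          bin_size = 100, region_len = 150000,
                          front_jitter_sd = 2000) {
  n_bins <- region_len %/% bin_size
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  with_seed_maybe(seed, {
    out <- lapply(timepoints, function(t) {
      front <- pmin(pmax(speed * 1000 * t +
                           stats::rnorm(n_genes, 0, front_jitter_sd), 0),
                    region_len)
      bin_start <- (seq_len(n_bins) - 1L) * bin_size
      frac_on <- vapply(front, function(f) {
        pmin(pmax((f - bin_start) / bin_size, 0), 1)
      }, numeric(n_bins))                      # n_bins x n_genes
      lam <- lambda_off + (lambda_on - lambda_off) * t(frac_on)
      counts <- matrix(stats::rpois(length(lam), lam), nrow = n_genes,
                       dimnames = list(gene_id, NULL))
      list(counts = counts, front = front)
    })
    names(out) <- paste0("t", timepoints)
    truth <- dplyr::bind_rows(lapply(seq_along(timepoints), function(j) {
      tibble(gene_id = gene_id, timepoint = timepoints[j],
             front_bp = out[[j]]$front)
    }))
    list(counts = lapply(out, `[[`, "counts"), truth = truth,
         bin_size = as.integer(bin_size), region_len = as.integer(region_len))
  })
}

#' Simulate pulse-chase count tables with exponential retention decay
#'
#' Per gene, a baseline nascent intensity `N0` is drawn log-normally and
#' shared between cell lines. The nascent baseline table has
#' `gene_count ~ Poisson(N0)` with a binomial exonic split. At chase time
#' `t`, the labelled intronic pool decays exponentially at the cell line's
#' rate: `intronic(t) ~ Poisson(N0 * exp(-lambda * t))`; exonic counts decay
#' at a common processing rate and `gene = intronic + exonic` by
#' construction. All tables carry the same nominal library size
#' (depth-matched libraries), so the CPM-normalised retention of a gene has
#' expectation `exp(-lambda * t)`.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (default 2000).
#' @param decay Named per-hour decay rates, one per cell line
#'   (default `c(A = 0.4, B = 0.1)`).
#' @param timepoints Chase times in hours (default `c(1.5, 6.5, 8)`).
#' @param n0_meanlog,n0_sdlog Log-normal parameters of `N0`.
#' @param exon_frac Expected exonic fraction of the nascent baseline
#'   (default 0.6).
#' @param exon_decay Per-hour decay of exonic label (default 0.2).
#' @param library_size Nominal library size stamped on all tables
#'   (default 1e6).
#' @return A list per cell line, each with `nascent_t0` and `pulse_chase`
#'   (named list by timepoint) count tables, plus `truth` (tibble
#'   `cell_line`, `timepoint`, `retention_true`).
#' @export
simulate_pulse_chase <- function(seed, n_genes = 2000,
                                 decay = c(A = 0.4, B = 0.1),
                                 timepoints = c(1.5, 6.5, 8),
                                 n0_meanlog = log(200), n0_sdlog = 0.6,
                                 exon_frac = 0.6, exon_decay = 0.2,
                                 library_size = 1e6) {
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  with_seed_maybe(seed, {
    n0 <- stats::rlnorm(n_genes, n0_meanlog, n0_sdlog)
    make_table <- function(gene, exonic, condition) {
      tab <- tibble(gene_id = gene_id, gene_count = gene,
                    exonic_count = exonic)
      attr(tab, "condition") <- condition
      attr(tab, "library_size") <- library_size
      tab
    }
    lines <- lapply(names(decay), function(cl) {
      lam <- decay[[cl]]
      g0 <- stats::rpois(n_genes, n0)
      e0 <- stats::rbinom(n_genes, g0, exon_frac)
      nascent <- make_table(g0, e0, paste0(cl, "_nascent_t0"))
      pulse <- lapply(timepoints, function(t) {
        intr <- stats::rpois(n_genes, n0 * exp(-lam * t))
        exo <- stats::rpois(n_genes, exon_frac * n0 * exp(-exon_decay * t))
        make_table(intr + exo, exo, paste0(cl, "_pulse_t", t))
      })
      names(pulse) <- paste0("t", timepoints)
      list(nascent_t0 = nascent, pulse_chase = pulse)
    })
    names(lines) <- names(decay)
    truth <- tidyr::expand_grid(cell_line = names(decay),
                                timepoint = timepoints) |>
      dplyr::mutate(retention_true = exp(-unname(decay[.data$cell_line]) *
                                           .data$timepoint))
    c(lines, list(truth = truth))
  })
}

#' Simulate ATAC fragments around planted +1/+2 nucleosomes
#'
#' Per gene, fragments are drawn from a three-component size mixture:
#' sub-nucleosomal fragments from the nucleosome-free region around the TSS,
#' mononucleosome-protecting fragments (sizes ~ Normal(147, 10), clipped)
#' with midpoints jittered Normal(dyad, `positional_sd`) around the planted
#' +1 and +2 dyads, and di-nucleosome fragments (sizes ~ Normal(300, 20))
#' spanning both. The planted dyads sit at `plus1_offset` and
#' `plus1_offset + spacing` bp downstream of the TSS; `positional_sd` is the
#' planted positioning firmness knob.
#'
#' @param genes A gene table.
#' @param seed Integer seed.
#' @param plus1_offset +1 dyad offset downstream of the TSS in bp
#'   (default 120).
#' @param spacing +1 to +2 dyad distance in bp (default 190).
#' @param positional_sd Midpoint jitter SD in bp (default 10).
#' @param size_mixture Proportions `c(sub, mono, di)`; must sum to 1.
#' @param frags_per_gene Expected fragments per gene (default 300).
#' @param nfr_sd Midpoint SD of sub-nucleosomal fragments around the TSS
#'   (default 30).
#' @return A list with `fragments` (tibble `chrom`, `start`, `end`, `size`,
#'   `midpoint`) and `truth` (tibble `gene_id`, `rank`, `dyad_pos`,
#'   `offset_from_tss`, `positional_sd`).
#' @export
simulate_atac <- function(genes, seed, plus1_offset = 120, spacing = 190,
                          positional_sd = 10,
                          size_mixture = c(sub = 0.35, mono = 0.5, di = 0.15),
                          frags_per_gene = 300, nfr_sd = 30) {
  stopifnot(abs(sum(size_mixture) - 1) < 1e-8)
  genes <- gene_table(genes)
  n <- nrow(genes)
  down <- function(tss, strand, off) {
    as.integer(ifelse(strand == "+", tss + off, tss - 1L - off))
  }
  dyad1 <- down(genes$tss, genes$strand, plus1_offset)
  dyad2 <- down(genes$tss, genes$strand, plus1_offset + spacing)
  sub_seeds <- gene_substream_seeds(seed, n)
  frags <- purrr::map_dfr(seq_len(n), function(i) {
    withr::with_seed(sub_seeds[i], {
      n_tot <- stats::rpois(1, frags_per_gene)
      comp <- sample(c("sub", "mono", "di"), n_tot, replace = TRUE,
                     prob = size_mixture)
      n_sub <- sum(comp == "sub"); n_mono <- sum(comp == "mono")
      n_di <- sum(comp == "di")
      mono_dyad <- sample(c(dyad1[i], dyad2[i]), n_mono, replace = TRUE)
      mid <- c(
        round(stats::rnorm(n_sub, down(genes$tss[i], genes$strand[i], 0L),
                           nfr_sd)),
        round(stats::rnorm(n_mono, mono_dyad, positional_sd)),
        round(stats::rnorm(n_di, (dyad1[i] + dyad2[i]) / 2, positional_sd))
      )
      size <- c(
        pmin(pmax(round(stats::rnorm(n_sub, 60, 15)), 20L), 100L),
        pmin(pmax(round(stats::rnorm(n_mono, 147, 10)), 100L), 250L),
        pmax(round(stats::rnorm(n_di, 300, 20)), 250L)
      )
      if (length(mid) == 0L) return(NULL)
      tibble(chrom = genes$chrom[i],
             start = as.integer(mid - size %/% 2L),
             end = as.integer(mid - size %/% 2L + size),
             size = as.integer(size), midpoint = as.integer(mid))
    })
  })
  truth <- tibble(
    gene_id = rep(genes$gene_id, 2L),
    rank = rep(1:2, each = n),
    dyad_pos = c(dyad1, dyad2),
    offset_from_tss = rep(c(plus1_offset, plus1_offset + spacing), each = n),
    positional_sd = positional_sd
  )
  list(fragments = frags, truth = dplyr::arrange(truth, .data$gene_id,
                                                 .data$rank))
}
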