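#' Run the synthetic end-to-end analysis pipeline from a manifest
#'
#' Orchestrates the package's stages in dependency order on seeded synthetic
#' data: genome simulation and filtering, then any of `ei` (escape index and
#' responder summary), `activity` (peak-overlap classification), `wave`
#' (elongation-wave fronts and speed), `retention` (pulse-chase retention
#' and group test), and `nucleosome` (Vplots, dyads, spacing). Each stage
#' writes tab-delimited tables and a JSON summary; a run-level `index.tsv`
#' records every output file with its MD5 checksum, so re-running with the
#' same manifest and seed reproduces the run byte-for-byte.
#'
#' @param manifest A list, or path to a YAML file, with elements `seed`
#'   (integer), `outdir`, `stages` (character subset of `c("ei",
#'   "activity", "wave", "retention", "nucleosome")`), and optional `params`
#'   (a named list of per-stage argument overrides for the corresponding
#'   `simulate_*` generators).
#' @param outdir,seed Optional overrides of the manifest fields.
#' @return The output directory, invisibly; side effect: files under
#'   `outdir`.
#' @export
run_pipeline <- function(manifest, outdir = NULL, seed = NULL) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  seed <- as.integer(seed %||% manifest$seed %||%
                       abort("manifest must provide a seed"))
  outdir <- outdir %||% manifest$outdir %||% abort("manifest must provide outdir")
  stages <- manifest$stages %||% c("ei", "activity", "wave", "retention",
                                   "nucleosome")
  params <- manifest$params %||% list()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_line <- function(...) cat(paste0(..., "\n"), file = log_path,
                                append = TRUE)
  cat(sprintf("run_pipeline seed=%d stages=%s\n", seed,
              paste(stages, collapse = ",")), file = log_path)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(outdir, name)
    readr::write_tsv(x, path)
    written <<- c(written, path)
    path
  }
  emit_json <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <<- c(written, path)
    path
  }

  genome_args <- c(list(seed = derive_seed(seed, 10L)), params$genome)
  genome <- do.call(simulate_genome, genome_args)
  genes <- genome$genes |>
    filter_min_length() |>
    filter_clear_signal()
  emit(genome$genes, "genes_all.tsv")
  emit(genes, "genes_filtered.tsv")
  log_line(sprintf("genome: %d genes simulated, %d after filters",
                   nrow(genome$genes), nrow(genes)))

  if ("ei" %in% stages) {
    args <- c(list(genes = genes, seed = derive_seed(seed, 20L)), params$ei)
    sim <- do.call(simulate_chip_reads, args)
    ei_c <- suppressMessages(compute_ei(sim$control, genes))
    ei_t <- suppressMessages(compute_ei(sim$treated, genes))
    deltas <- suppressMessages(compute_delta_ei(ei_c, ei_t))
    emit(ei_c, "ei_control.tsv"); emit(ei_t, "ei_treated.tsv")
    emit(deltas, "delta_ei.tsv"); emit(sim$truth, "ei_truth.tsv")
    emit_json(list(stage = "ei", seed = seed, n_genes = nrow(deltas),
                   percent_increased = percent_increased(deltas)),
              "ei_summary.json")
    log_line(sprintf("ei: %.1f%% of %d genes increased",
                     percent_increased(deltas), nrow(deltas)))
  }
  if ("activity" %in% stages) {
    with_seed_maybe(derive_seed(seed, 30L), {
      mk_peaks <- function(p) {
        pick <- which(stats::runif(nrow(genes)) < p)
        win <- oriented_window(genes$tss[pick], genes$strand[pick], 100L, 300L)
        tibble(chrom = genes$chrom[pick], start = win$start, end = win$end)
      }
      ser2p <- mk_peaks(0.55); k27ac <- mk_peaks(0.6); k27me3 <- mk_peaks(0.2)
      labels <- classify_activity(genes, ser2p, k27ac, k27me3)
      emit(labels, "activity_labels.tsv")
      emit_json(c(list(stage = "activity", seed = seed),
                  as.list(table(labels$label))), "activity_summary.json")
      log_line(sprintf("activity: %d active of %d genes",
                       sum(labels$label == "active"), nrow(labels)))
    })
  }
  if ("wave" %in% stages) {
    args <- c(list(seed = derive_seed(seed, 40L)), params$wave)
    sim <- do.call(simulate_wave, args)
    fronts <- dplyr::bind_rows(lapply(names(sim$counts), function(tp) {
      fit <- fit_wave_hmm(sim$counts[[tp]], bin_size = sim$bin_size)
      dplyr::mutate(call_fronts(sim$counts[[tp]], fit),
                    timepoint = as.numeric(sub("^t", "", tp)))
    }))
    summaries <- wave_summary(fronts)
    speed <- estimate_speed(summaries)
    emit(fronts, "wave_fronts.tsv"); emit(summaries, "wave_summary.tsv")
    emit(sim$truth, "wave_truth.tsv")
    emit_json(list(stage = "wave", seed = seed, speed_kb_min = speed$speed,
                   intercept_kb = speed$intercept,
                   n_censored = sum(fronts$censored)), "wave_summary.json")
    log_line(sprintf("wave: estimated speed %.2f kb/min", speed$speed))
  }
  if ("retention" %in% stages) {
    args <- c(list(seed = derive_seed(seed, 50L)), params$retention)
    sim <- do.call(simulate_pulse_chase, args)
    lines <- setdiff(names(sim), "truth")
    tabs <- unlist(lapply(lines, function(cl) {
      c(list(sim[[cl]]$nascent_t0), sim[[cl]]$pulse_chase)
    }), recursive = FALSE)
    keep_genes <- median_activity_filter(tabs)
    ret <- dplyr::bind_rows(lapply(lines, function(cl) {
      dplyr::bind_rows(lapply(names(sim[[cl]]$pulse_chase), function(tp) {
        r <- suppressMessages(compute_retention(
          sim[[cl]]$pulse_chase[[tp]], sim[[cl]]$nascent_t0, keep_genes))
        dplyr::mutate(r, cell_line = cl,
                      timepoint = as.numeric(sub("^t", "", tp)))
      }))
    }))
    tests <- lapply(unique(ret$timepoint), function(tp) {
      a <- ret$retention[ret$cell_line == lines[1] & ret$timepoint == tp]
      b <- ret$retention[ret$cell_line == lines[2] & ret$timepoint == tp]
      res <- permutation_t_test_iqr(a, b, seed = derive_seed(seed, 51L))
      list(timepoint = tp, statistic = res$statistic, p_value = res$p_value)
    })
    emit(ret, "retention.tsv"); emit(sim$truth, "retention_truth.tsv")
    emit_json(list(stage = "retention", seed = seed,
                   n_genes = length(keep_genes), tests = tests),
              "retention_summary.json")
    log_line(sprintf("retention: %d genes pass the median filter",
                     length(keep_genes)))
  }
  if ("nucleosome" %in% stages) {
    args <- c(list(genes = genes, seed = derive_seed(seed, 60L)),
              params$nucleosome)
    sim <- do.call(simulate_atac, args)
    dyads <- call_dyads(sim$fragments, genes, region_width = 1000)
    anchors <- dyads |>
      dplyr::filter(.data$rank == 1L) |>
      dplyr::inner_join(dplyr::select(genes, "gene_id", "strand"),
                        by = "gene_id") |>
      dplyr::transmute(chrom = .data$chrom, pos = .data$position,
                       strand = .data$strand)
    vp <- build_vplot(sim$fragments, anchors, normalization = "density")
    spacing <- spacing_mode(dyads, genes)
    emit(dyads, "dyads.tsv"); emit(spacing, "spacing.tsv")
    emit(sim$truth, "nucleosome_truth.tsv")
    write_vplot(vp, file.path(outdir, "vplot_density.tsv"))
    written <- c(written, file.path(outdir, "vplot_density.tsv"))
    emit_json(list(stage = "nucleosome", seed = seed,
                   n_dyads = nrow(dyads),
                   median_fuzziness = stats::median(dyads$fuzziness),
                   spacing = stats::setNames(as.list(spacing$mode_distance),
                                             spacing$rank)),
              "nucleosome_summary.json")
    log_line(sprintf("nucleosome: %d dyads called", nrow(dyads)))
  }
  index <- tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  readr::write_tsv(index, file.path(outdir, "index.tsv"))
  invisible(outdir)
}
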