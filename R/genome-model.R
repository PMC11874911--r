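#' Build a validated gene table
#'
#' Normalises a transcript/gene annotation into the tibble all windowed
#' metrics in this package are anchored on. Coordinates follow the BED
#' convention (0-based, half-open); the transcription start site (TSS) of a
#' minus-strand gene is its BED `end` coordinate and its termination site
#' (TTS) its BED `start`.
#'
#' @param x A data frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`), `start` and `end`.
#' @return A tibble with the input columns plus `tss`, `tts` and `length`.
#' @examples
#' gene_table(data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
#'                       start = 1000, end = 6000))
#' @export
gene_table <- function(x) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("gene table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  out <- as_tibble(x)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (any(out$start < 0L)) abort("gene start coordinates must be >= 0")
  if (any(out$start >= out$end)) abort("gene start must be < end")
  if (!all(out$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out$tts <- ifelse(out$strand == "+", out$end, out$start)
  out$length <- out$end - out$start
  out
}

#' Collapse transcripts that share a TSS neighbourhood
#'
#' Transcripts on the same chromosome and strand whose TSSs fall within
#' `radius` bp of each other (single linkage, so chains of nearby TSSs merge)
#' are clustered, and the longest transcript of each cluster is kept. Ties on
#' length are broken toward the lexicographically smallest `gene_id`.
#'
#' @param transcripts A gene table (see [gene_table()]).
#' @param radius Clustering radius in bp around each TSS (default 50).
#' @return A gene table with one representative transcript per TSS cluster.
#' @export
cluster_tss <- function(transcripts, radius = 50) {
  stopifnot(radius >= 0)
  transcripts <- gene_table(transcripts)
  if (nrow(transcripts) == 0L) return(transcripts)
  transcripts |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::arrange(.data$tss, .by_group = TRUE) |>
    dplyr::mutate(
      # a gap > radius between consecutive sorted TSSs starts a new
      # single-linkage cluster
      .cluster = cumsum(c(0L, diff(.data$tss) > radius))
    ) |>
    dplyr::group_by(.data$.cluster, .add = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$gene_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select(-".cluster") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Keep genes at or above a minimum length
#'
#' @param genes A gene table.
#' @param min_len Minimum gene length in bp, inclusive (default 2000).
#' @return The gene table restricted to genes with `length >= min_len`.
#' @export
filter_min_length <- function(genes, min_len = 2000) {
  stopifnot(min_len > 0)
  genes <- gene_table(genes)
  dplyr::filter(genes, .data$length >= min_len)
}

#' Drop genes with a neighbouring TSS in their promoter window
#'
#' A gene is removed when any other gene's TSS (on the same chromosome,
#' either strand) falls within its strand-oriented window
#' `[tss - window_up, tss + window_down]` — i.e. within 250 bp upstream to
#' 2 kb downstream by default. Both members of an offending pair are removed,
#' leaving only genes with an uncontaminated promoter-proximal signal.
#'
#' @param genes A gene table.
#' @param window_up Upstream extent of the exclusion window in bp (default 250).
#' @param window_down Downstream extent in bp (default 2000).
#' @return The gene table restricted to genes with no neighbouring TSS in
#'   the window.
#' @export
filter_clear_signal <- function(genes, window_up = 250, window_down = 2000) {
  stopifnot(window_up >= 0, window_down >= 0)
  genes <- gene_table(genes)
  n <- nrow(genes)
  if (n <= 1L) return(genes)
  win <- oriented_window(genes$tss, genes$strand, window_up, window_down)
  # inclusive window: an offending TSS may sit exactly at either bound
  windows <- tibble(chrom = genes$chrom, start = win$start, end = win$end + 1L)
  points <- tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L)
  pairs <- interval_overlap_pairs(windows, points)
  pairs <- pairs[pairs$query != pairs$subject, , drop = FALSE]
  bad <- unique(c(pairs$query, pairs$subject))
  if (length(bad)) genes[-bad, , drop = FALSE] else genes
}

#' Assign peaks to TSS/TTS/intragenic/intergenic categories
#'
#' Each peak receives exactly one label from the gene-anchored category
#' footprints: TSS = `[tss - 500, tss + 500)`, TTS = `[tts - 500, tts + 500)`,
#' intragenic = the strand-oriented gene body between them, intergenic =
#' everything else. A peak overlapping several footprints is labelled by the
#' priority TSS > TTS > Intragenic > Intergenic; set `multiple = TRUE` to also
#' report every overlapping category.
#'
#' @param peaks A data frame of intervals (`chrom`, `start`, `end`).
#' @param genes A gene table, already length-filtered (genes shorter than the
#'   analysis minimum should be excluded upstream).
#' @param flank Half-width of the TSS and TTS footprints in bp (default 500).
#' @param multiple Also return logical columns `overlaps_tss`,
#'   `overlaps_tts`, `overlaps_intragenic` (default `FALSE`).
#' @return The peak tibble with a `category` factor column (levels TSS,
#'   Intragenic, TTS, Intergenic).
#' @export
assign_region_category <- function(peaks, genes, flank = 500, multiple = FALSE) {
  peaks <- as_tibble(peaks)
  genes <- gene_table(genes)
  tss_fp <- tibble(chrom = genes$chrom,
                   start = genes$tss - flank, end = genes$tss + flank)
  tts_fp <- tibble(chrom = genes$chrom,
                   start = genes$tts - flank, end = genes$tts + flank)
  body <- oriented_window(genes$tss, genes$strand,
                          up = -flank, down = genes$length - flank)
  body_fp <- tibble(chrom = genes$chrom, start = body$start, end = body$end)
  body_fp <- body_fp[body_fp$end > body_fp$start, , drop = FALSE]

  in_tss <- overlaps_any(peaks, tss_fp)
  in_tts <- overlaps_any(peaks, tts_fp)
  in_body <- overlaps_any(peaks, body_fp)

  category <- dplyr::case_when(
    in_tss ~ "TSS",
    in_tts ~ "TTS",
    in_body ~ "Intragenic",
    TRUE ~ "Intergenic"
  )
  out <- dplyr::mutate(
    peaks,
    category = factor(category, levels = c("TSS", "Intragenic", "TTS", "Intergenic"))
  )
  if (multiple) {
    out$overlaps_tss <- in_tss
    out$overlaps_tts <- in_tts
    out$overlaps_intragenic <- in_body
  }
  out
}
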