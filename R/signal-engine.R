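#' Count reads in a set of windows
#'
#' Counts either every read that intersects a window by at least 1 bp
#' (`mode = "overlap"`, the `coverageBed -counts` convention used for
#' escape-index windows) or every read whose midpoint falls inside the window
#' (`mode = "midpoint"`, which assigns each read to exactly one window and so
#' conserves mass across a tiling).
#'
#' @param reads A data frame of read intervals (`chrom`, `start`, `end`;
#'   BED half-open).
#' @param windows A data frame of windows (`chrom`, `start`, `end`).
#' @param mode Counting mode, `"overlap"` or `"midpoint"`.
#' @return `windows` as a tibble with an integer `count` column.
#' @export
count_in_windows <- function(reads, windows, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  reads <- as_tibble(reads)
  windows <- as_tibble(windows)
  if (any(windows$end <= windows$start)) abort("windows must have end > start")
  if (mode == "midpoint") {
    mid <- (reads$start + reads$end) %/% 2L
    reads <- tibble(chrom = reads$chrom, start = mid, end = mid + 1L)
  }
  pairs <- interval_overlap_pairs(windows, reads)
  counts <- tabulate(pairs$query, nbins = nrow(windows))
  dplyr::mutate(windows, count = as.integer(counts))
}

#' Count reads in one window
#'
#' Scalar convenience wrapper around [count_in_windows()].
#'
#' @inheritParams count_in_windows
#' @param chrom,start,end The window (BED half-open).
#' @return An integer count.
#' @export
count_in_window <- function(reads, chrom, start, end,
                            mode = c("overlap", "midpoint")) {
  win <- tibble(chrom = chrom, start = as.integer(start), end = as.integer(end))
  count_in_windows(reads, win, mode = mode)$count[[1L]]
}

#' Bin read signal over the 5' region of genes
#'
#' Assigns each read (by midpoint, so every read lands in exactly one bin) to
#' fixed-width bins over the first `region_len` bp of each gene, ordered
#' 5'-to-3' from the TSS regardless of strand. This is the substrate of the
#' elongation-wave analysis: nascent-transcription signal binned at 100 bp
#' over the first 100-250 kb of long genes.
#'
#' @param reads A data frame of read intervals.
#' @param genes A gene table; every gene must be at least `region_len` long.
#' @param region_len Length of the profiled region in bp.
#' @param bin_size Bin width in bp; must divide `region_len`.
#' @return A long tibble with columns `gene_id`, `bin` (0-based), and
#'   `count`, carrying attributes `bin_size`, `region_len`, and
#'   `normalization` (`"raw_counts"`).
#' @export
bin_gene_signal <- function(reads, genes, region_len, bin_size = 100) {
  genes <- gene_table(genes)
  if (region_len %% bin_size != 0L) abort("region_len must be divisible by bin_size")
  if (any(genes$length < region_len)) abort("gene below length threshold")
  n_bins <- region_len %/% bin_size
  reads <- as_tibble(reads)
  mid <- (reads$start + reads$end) %/% 2L
  mids <- tibble(chrom = reads$chrom, start = mid, end = mid + 1L)
  win <- oriented_window(genes$tss, genes$strand, up = 0L, down = region_len)
  regions <- tibble(chrom = genes$chrom, start = win$start, end = win$end)
  pairs <- interval_overlap_pairs(regions, mids)
  if (nrow(pairs)) {
    off <- oriented_offset(mid[pairs$subject],
                           genes$tss[pairs$query],
                           genes$strand[pairs$query])
    bin <- off %/% bin_size
    idx <- (pairs$query - 1L) * n_bins + bin + 1L
    counts <- tabulate(idx, nbins = nrow(genes) * n_bins)
  } else {
    counts <- integer(nrow(genes) * n_bins)
  }
  out <- tibble(
    gene_id = rep(genes$gene_id, each = n_bins),
    bin = rep.int(seq_len(n_bins) - 1L, nrow(genes)),
    count = as.numeric(counts)
  )
  attr(out, "bin_size") <- as.integer(bin_size)
  attr(out, "region_len") <- as.integer(region_len)
  attr(out, "normalization") <- "raw_counts"
  out
}

#' Convert a long binned-signal tibble to a gene-by-bin matrix
#'
#' @param binned Output of [bin_gene_signal()] (or any tibble with
#'   `gene_id`, `bin`, and a value column).
#' @param value Name of the value column (default `"count"`).
#' @return A numeric matrix, one row per gene (rownames = gene ids), bins in
#'   order as columns.
#' @export
bins_to_matrix <- function(binned, value = "count") {
  wide <- tidyr::pivot_wider(
    binned[, c("gene_id", "bin", value)],
    names_from = "bin", values_from = dplyr::all_of(value), values_fill = 0
  )
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$gene_id
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' RPKM-normalise a binned signal
#'
#' Each bin value `v` over `bin_size` bp becomes
#' `v / (bin_size/1000) / (library_size/1e6)` — reads per kilobase per
#' million mapped reads.
#'
#' @param binned Output of [bin_gene_signal()].
#' @param library_size Total mapped reads in the library; must be positive.
#' @return The tibble with `count` replaced by RPKM values and the
#'   `normalization` attribute set to `"RPKM"`.
#' @export
normalize_rpkm <- function(binned, library_size) {
  if (length(library_size) != 1L || library_size <= 0) {
    abort("library_size must be a single positive number")
  }
  bin_size <- attr(binned, "bin_size") %||%
    abort("binned signal is missing its bin_size attribute")
  out <- dplyr::mutate(
    binned,
    count = .data$count / (bin_size / 1000) / (library_size / 1e6)
  )
  attr(out, "bin_size") <- bin_size
  attr(out, "region_len") <- attr(binned, "region_len")
  attr(out, "normalization") <- "RPKM"
  out
}

#' Per-window read density in reads-per-million per bp
#'
#' Density = overlap count / window length * 1e6 / library size — the "rpm"
#' average coverage used for promoter and gene-body densities.
#'
#' @inheritParams count_in_windows
#' @param library_size Total mapped reads; positive.
#' @return `windows` as a tibble with `count` and `density` columns.
#' @export
window_density_rpm <- function(reads, windows, library_size,
                               mode = c("overlap", "midpoint")) {
  if (library_size <= 0) abort("library_size must be positive")
  windows <- as_tibble(windows)
  if (any(windows$end <= windows$start)) abort("zero-length window")
  counted <- count_in_windows(reads, windows, mode = mode)
  dplyr::mutate(
    counted,
    density = .data$count / (.data$end - .data$start) * 1e6 / library_size
  )
}
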