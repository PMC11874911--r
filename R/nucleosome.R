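#' Build a Vplot (fragment size x midpoint offset density) around dyads
#'
#' Accumulates ATAC fragments into a 2-D histogram: rows are fragment sizes
#' (1 bp resolution over `size_range`), columns are strand-oriented offsets
#' of the fragment midpoint from each anchor (typically a +1 nucleosome
#' dyad), over `[-flank, +flank]`. Mononucleosome-protecting fragments show
#' up as a band near 147 bp centred on the dyad; sub-nucleosomal fragments
#' from the nucleosome-free region sit below it.
#'
#' @param fragments A data frame with `chrom`, `start`, `end` (half-open);
#'   fragment size is `end - start` and the midpoint `floor((start+end)/2)`.
#' @param anchors A data frame of dyads with `chrom`, `pos` (genomic bp) and
#'   `strand`.
#' @param size_range Inclusive fragment-size range in bp (default `c(1, 250)`).
#' @param flank Offset half-width in bp (default 250).
#' @param normalization `"counts"` (default) or `"density"` (matrix sums
#'   to 1).
#' @return An object of class `vplot`: a list with `matrix` (sizes x
#'   offsets), `sizes`, `offsets`, `n_anchors`, `n_pairs`, `normalization`.
#' @export
build_vplot <- function(fragments, anchors, size_range = c(1, 250),
                        flank = 250, normalization = c("counts", "density")) {
  normalization <- match.arg(normalization)
  anchors <- as_tibble(anchors)
  if (nrow(anchors) == 0L) abort("at least one anchor is required")
  fragments <- as_tibble(fragments)
  sizes <- size_range[1]:size_range[2]
  offsets <- (-flank):flank
  mat <- matrix(0, nrow = length(sizes), ncol = length(offsets),
                dimnames = list(size = sizes, offset = offsets))
  size <- fragments$end - fragments$start
  mid <- (fragments$start + fragments$end) %/% 2L
  keep <- size >= size_range[1] & size <= size_range[2]
  n_pairs <- 0L
  if (any(keep)) {
    mids <- tibble(chrom = fragments$chrom[keep], start = mid[keep],
                   end = mid[keep] + 1L)
    wins <- tibble(chrom = anchors$chrom, start = anchors$pos - flank,
                   end = anchors$pos + flank + 1L)
    pairs <- interval_overlap_pairs(wins, mids)
    if (nrow(pairs)) {
      off <- ifelse(anchors$strand[pairs$query] == "+",
                    mids$start[pairs$subject] - anchors$pos[pairs$query],
                    anchors$pos[pairs$query] - mids$start[pairs$subject])
      s <- size[keep][pairs$subject]
      idx <- (s - size_range[1]) + length(sizes) * (off + flank) + 1L
      acc <- tabulate(idx, nbins = length(sizes) * length(offsets))
      mat[] <- acc
      n_pairs <- nrow(pairs)
    }
  }
  if (n_pairs == 0L) warn("no fragments in range; Vplot is all zero")
  if (normalization == "density" && n_pairs > 0L) mat <- mat / sum(mat)
  structure(
    list(matrix = mat, sizes = sizes, offsets = offsets,
         n_anchors = nrow(anchors), n_pairs = n_pairs,
         normalization = normalization),
    class = "vplot"
  )
}

#' @export
print.vplot <- function(x, ...) {
  cat(sprintf("Vplot: %d sizes x %d offsets, %d anchors, %d fragment-anchor pairs (%s)\n",
              length(x$sizes), length(x$offsets), x$n_anchors, x$n_pairs,
              x$normalization))
  invisible(x)
}

#' Subtract one density Vplot from another, flooring at zero
#'
#' `max(a - b, 0)` elementwise: the surviving signal is where `a` has excess
#' density over `b`; negative differences are assigned zero.
#'
#' @param a,b Density-normalised `vplot` objects of identical dimensions.
#' @return A `vplot` holding the floored difference.
#' @export
subtract_vplots <- function(a, b) {
  if (!identical(dim(a$matrix), dim(b$matrix)) ||
      !identical(a$sizes, b$sizes) || !identical(a$offsets, b$offsets)) {
    abort("Vplot dimensions do not match")
  }
  if (a$normalization != "density" || b$normalization != "density") {
    abort("subtraction requires density-normalised Vplots")
  }
  out <- a
  out$matrix <- pmax(a$matrix - b$matrix, 0)
  out$n_anchors <- NA_integer_
  out$n_pairs <- NA_integer_
  out
}

#' Paired t-test on flattened Vplots
#'
#' Flattens each matrix by column sums (total signal per offset) and applies
#' a two-sided paired t-test across the offset-matched vectors.
#'
#' @param a,b `vplot` objects of identical dimensions.
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
vplot_flatten_test <- function(a, b) {
  if (!identical(dim(a$matrix), dim(b$matrix))) abort("Vplot dimensions do not match")
  paired_t(colSums(a$matrix), colSums(b$matrix))
}

#' Wilcoxon signed-rank test on the mononucleosome band of two Vplots
#'
#' Restricts both matrices to fragment sizes within the mononucleosome band
#' (147 +/- 20 bp by default), takes per-offset column sums, and compares
#' the paired vectors with a two-sided Wilcoxon signed-rank test. Identical
#' inputs (all-zero differences) return `p = 1` with the degenerate flag.
#'
#' @param a,b `vplot` objects of identical dimensions.
#' @param band Inclusive size band in bp (default `c(127, 167)`).
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
mononucleosome_band_test <- function(a, b, band = c(127, 167)) {
  if (!identical(dim(a$matrix), dim(b$matrix))) abort("Vplot dimensions do not match")
  rows <- which(a$sizes >= band[1] & a$sizes <= band[2])
  if (length(rows) == 0L) abort("empty mononucleosome band")
  wilcoxon_rank(colSums(a$matrix[rows, , drop = FALSE]),
                colSums(b$matrix[rows, , drop = FALSE]), paired = TRUE)
}

#' Call nucleosome dyads downstream of TSSs from fragment midpoints
#'
#' A simplified dyad caller: within each gene's strand-oriented search
#' region (TSS to `region_width` bp downstream), the midpoints of
#' mononucleosome-sized fragments are smoothed with a Gaussian kernel
#' (`kernel_bw` bp) on a 1-bp grid; local maxima of the density at least
#' `min_separation` bp apart are reported as dyads. For each dyad, occupancy
#' is the density at the peak and fuzziness the (population) standard
#' deviation of the supporting midpoints within +/- 75 bp — positionally
#' firm nucleosomes give low fuzziness. Regions or peaks supported by fewer
#' than `min_fragments` fragments yield no call.
#'
#' @param fragments A fragment data frame (`chrom`, `start`, `end`).
#' @param genes A gene table.
#' @param region_width Downstream search extent in bp: 250 targets the +1
#'   nucleosome only (default), 1000 targets +1 and +2.
#' @param mono_size Inclusive mononucleosome fragment-size range
#'   (default `c(130, 180)`).
#' @param kernel_bw Gaussian kernel bandwidth in bp (default 20).
#' @param min_fragments Minimum supporting fragments per call (default 5).
#' @param min_separation Minimum distance between reported dyads in bp
#'   (default 120).
#' @return A tibble with `gene_id`, `chrom`, `position` (genomic bp),
#'   `offset_from_tss` (strand-oriented bp), `occupancy`, `fuzziness`, and
#'   `rank` (1 = closest to the TSS).
#' @export
call_dyads <- function(fragments, genes, region_width = 250,
                       mono_size = c(130, 180), kernel_bw = 20,
                       min_fragments = 5, min_separation = 120) {
  genes <- gene_table(genes)
  fragments <- as_tibble(fragments)
  size <- fragments$end - fragments$start
  keep <- size >= mono_size[1] & size <= mono_size[2]
  mid <- (fragments$start + fragments$end) %/% 2L
  mids <- tibble(chrom = fragments$chrom[keep], start = mid[keep],
                 end = mid[keep] + 1L)
  win <- oriented_window(genes$tss, genes$strand, up = 0L, down = region_width)
  regions <- tibble(chrom = genes$chrom, start = win$start, end = win$end)
  pairs <- interval_overlap_pairs(regions, mids)
  if (nrow(pairs) == 0L) {
    return(tibble(gene_id = character(), chrom = character(),
                  position = integer(), offset_from_tss = integer(),
                  occupancy = numeric(), fuzziness = numeric(),
                  rank = integer()))
  }
  by_gene <- split(mids$start[pairs$subject], pairs$query)
  out <- purrr::map_dfr(names(by_gene), function(gi) {
    g <- as.integer(gi)
    x <- by_gene[[gi]]
    if (length(x) < min_fragments) return(NULL)
    grid_from <- regions$start[g]
    grid_to <- regions$end[g] - 1L
    npts <- grid_to - grid_from + 1L
    d <- stats::density(x, bw = kernel_bw, from = grid_from, to = grid_to,
                        n = npts)
    y <- d$y
    is_peak <- c(FALSE, y[-c(1L, npts)] > y[-c(npts - 1L, npts)] &
                   y[-c(1L, npts)] >= y[-c(1L, 2L)], FALSE)
    cand <- which(is_peak)
    if (length(cand) == 0L) cand <- which.max(y)
    cand <- cand[order(y[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (ci in cand) {
      if (all(abs(ci - kept) >= min_separation)) kept <- c(kept, ci)
    }
    calls <- purrr::map_dfr(kept, function(ci) {
      pos <- grid_from + ci - 1L
      support <- x[abs(x - pos) <= 75]
      if (length(support) < min_fragments) return(NULL)
      tibble(
        gene_id = genes$gene_id[g],
        chrom = genes$chrom[g],
        position = as.integer(pos),
        offset_from_tss = as.integer(
          ifelse(genes$strand[g] == "+", pos - genes$tss[g],
                 genes$tss[g] - pos)),
        occupancy = y[ci],
        fuzziness = sqrt(mean((support - mean(support))^2))
      )
    })
    if (nrow(calls) == 0L) return(NULL)
    calls <- dplyr::arrange(calls, .data$offset_from_tss)
    dplyr::mutate(calls, rank = dplyr::row_number())
  })
  out
}

#' Modal +1/+2 nucleosome distances from active TSSs
#'
#' For each gene, the `k` nearest downstream dyad centres (strand-oriented
#' distance from the TSS) are collected; distances above `max_dist` are
#' excluded. The mode of the integer-distance histogram — the density point
#' with the most occurrences — is reported per neighbour rank, with ties
#' broken toward the smaller distance, plus the modal +1-to-+2 spacing
#' (per-gene difference of the two distances).
#'
#' @param dyads A dyad table with `gene_id`-independent genomic positions:
#'   columns `chrom`, `position` (e.g. from [call_dyads()]).
#' @param genes A gene table.
#' @param k Number of downstream neighbours per TSS (default 2).
#' @param max_dist Maximum retained distance in bp (default 1000).
#' @return A tibble with `rank` (`"+1"`, `"+2"`, ..., `"spacing"`),
#'   `mode_distance`, and `n` (distances contributing).
#' @export
spacing_mode <- function(dyads, genes, k = 2, max_dist = 1000) {
  genes <- gene_table(genes)
  dyads <- as_tibble(dyads)
  dists <- purrr::map_dfr(seq_len(nrow(genes)), function(g) {
    on_chrom <- dyads$position[dyads$chrom == genes$chrom[g]]
    d <- if (genes$strand[g] == "+") on_chrom - genes$tss[g]
         else genes$tss[g] - on_chrom
    d <- sort(d[d >= 0])
    d <- d[seq_len(min(k, length(d)))]
    d <- d[d <= max_dist]
    if (length(d) == 0L) return(NULL)
    tibble(gene_id = genes$gene_id[g], rank = seq_along(d), distance = d)
  })
  if (nrow(dists) == 0L) {
    return(tibble(rank = character(), mode_distance = integer(), n = integer()))
  }
  hist_mode <- function(x) {
    tab <- table(x)
    vals <- as.integer(names(tab))
    vals[tab == max(tab)][1L]  # names are sorted ascending: tie -> smaller
  }
  per_rank <- dists |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(mode_distance = hist_mode(.data$distance),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rank = paste0("+", .data$rank))
  spacing <- dists |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(spacing = .data$distance[2L] - .data$distance[1L],
                     .groups = "drop")
  if (nrow(spacing) > 0) {
    per_rank <- dplyr::bind_rows(
      per_rank,
      tibble(rank = "spacing", mode_distance = hist_mode(spacing$spacing),
             n = nrow(spacing))
    )
  }
  per_rank
}

#' Compare +1 nucleosome fuzziness between EI-response extremes
#'
#' Sorts genes by their EI change (`delta_ei`), takes the `n` lowest and `n`
#' highest, and compares the +1 dyad fuzziness of the two groups with a
#' two-sided Wilcoxon rank-sum test. If fewer than `2n` genes carry both a
#' dyad call and a delta-EI record, `n` is shrunk with a warning.
#'
#' @param dyad_calls Output of [call_dyads()]; the rank-1 call per gene is
#'   used.
#' @param delta_ei Output of [compute_delta_ei()].
#' @param n Group size (default 1000).
#' @return A list with `groups` (tibble: `gene_id`, `delta_ei`, `fuzziness`,
#'   `group`) and `test` (a test-result tibble).
#' @export
fuzziness_by_delta_ei <- function(dyad_calls, delta_ei, n = 1000) {
  plus1 <- dyad_calls |>
    dplyr::filter(.data$rank == 1L) |>
    dplyr::select("gene_id", "fuzziness")
  joined <- dplyr::inner_join(plus1,
                              dplyr::select(delta_ei, "gene_id", "delta_ei"),
                              by = "gene_id") |>
    dplyr::arrange(.data$delta_ei)
  if (nrow(joined) < 2L * n) {
    n <- nrow(joined) %/% 2L
    warn(paste0("fewer than 2n eligible genes; shrinking group size to ", n))
  }
  if (n < 1L) abort("no eligible genes")
  groups <- dplyr::bind_rows(
    dplyr::mutate(dplyr::slice_head(joined, n = n), group = "low_delta_ei"),
    dplyr::mutate(dplyr::slice_tail(joined, n = n), group = "high_delta_ei")
  )
  test <- wilcoxon_rank(groups$fuzziness[groups$group == "low_delta_ei"],
                        groups$fuzziness[groups$group == "high_delta_ei"],
                        paired = FALSE)
  list(groups = groups, test = test)
}
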