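#' Compute the promoter escape index (EI) per gene
#'
#' The escape index of a gene is the average read density over its gene body
#' window divided by the average density over its promoter-proximal window,
#' both strand-oriented around the TSS: promoter `[-250, +100)` and body
#' `[+100, +2000)` by default. High EI means efficient release of paused
#' RNA polymerase II into productive elongation. Densities are reported in
#' rpm/bp; the ratio itself is library-size invariant. Genes with zero
#' promoter signal are dropped (no pseudocounts) and their number reported
#' via a message.
#'
#' @param reads A data frame of read intervals for one condition.
#' @param genes A gene table (length-filtered and TSS-overlap-filtered
#'   upstream; see [filter_min_length()], [filter_clear_signal()]).
#' @param library_size Total mapped reads; defaults to `nrow(reads)`.
#' @param promoter_up,promoter_down Promoter window extent in bp upstream /
#'   downstream of the TSS (defaults 250 and 100).
#' @param body_start,body_end Body window offsets in bp downstream of the TSS
#'   (defaults 100 and 2000).
#' @param mode Window counting mode passed to [count_in_windows()]
#'   (default `"overlap"`, the `coverageBed -counts` convention).
#' @return A tibble with columns `gene_id`, `dp` (promoter density, rpm/bp),
#'   `db` (body density), and `ei = db / dp`, one row per gene with `dp > 0`.
#' @export
compute_ei <- function(reads, genes, library_size = NULL,
                       promoter_up = 250, promoter_down = 100,
                       body_start = 100, body_end = 2000,
                       mode = "overlap") {
  genes <- gene_table(genes)
  library_size <- library_size %||% nrow(reads)
  prom <- oriented_window(genes$tss, genes$strand, promoter_up, promoter_down)
  body <- oriented_window(genes$tss, genes$strand, -body_start, body_end)
  prom_d <- window_density_rpm(
    reads, tibble(chrom = genes$chrom, start = prom$start, end = prom$end),
    library_size, mode = mode)
  body_d <- window_density_rpm(
    reads, tibble(chrom = genes$chrom, start = body$start, end = body$end),
    library_size, mode = mode)
  out <- tibble(
    gene_id = genes$gene_id,
    dp = prom_d$density,
    db = body_d$density
  )
  n_zero <- sum(out$dp == 0)
  if (n_zero > 0) {
    inform(paste0(n_zero, " gene(s) dropped: zero promoter-proximal signal"))
  }
  out <- dplyr::filter(out, .data$dp > 0)
  dplyr::mutate(out, ei = .data$db / .data$dp)
}

#' EI change between two conditions
#'
#' Joins per-gene EI records of a control and a treated condition and
#' computes `delta_ei = ei_treated / ei_control` together with a strict
#' increase flag (`delta_ei > 1`; exact ties are not increases). Genes absent
#' from either condition (e.g. dropped for zero promoter signal) or with zero
#' control EI are excluded.
#'
#' @param control,treated EI tibbles from [compute_ei()].
#' @return A tibble with `gene_id`, `ei_control`, `ei_treated`, `delta_ei`,
#'   and logical `increased`.
#' @export
compute_delta_ei <- function(control, treated) {
  joined <- dplyr::inner_join(
    dplyr::select(control, "gene_id", ei_control = "ei"),
    dplyr::select(treated, "gene_id", ei_treated = "ei"),
    by = "gene_id"
  )
  if (nrow(joined) == 0L) abort("no shared genes")
  n_zero <- sum(joined$ei_control == 0)
  if (n_zero > 0) {
    inform(paste0(n_zero, " gene(s) dropped: zero control EI"))
    joined <- dplyr::filter(joined, .data$ei_control > 0)
  }
  dplyr::mutate(
    joined,
    delta_ei = .data$ei_treated / .data$ei_control,
    increased = .data$delta_ei > 1
  )
}

#' Percentage of genes with increased EI
#'
#' @param deltas Output of [compute_delta_ei()].
#' @return `100 * #increased / #records`, a single number.
#' @export
percent_increased <- function(deltas) {
  if (nrow(deltas) == 0L) abort("no delta-EI records")
  100 * mean(deltas$increased)
}

#' Classify gene activity from peak overlaps
#'
#' Each gene's TSS is extended to the strand-oriented region
#' `[-upstream, +downstream)` (default -250 bp to +2 kb) and intersected with
#' three peak sets: elongating polymerase (RNAPII Ser2P), the active
#' enhancer/promoter mark H3K27ac, and the repressive mark H3K27me3. Labels,
#' in order of precedence:
#' * `ambiguous` — overlaps both H3K27ac and H3K27me3 (excluded downstream);
#' * `active` — overlaps Ser2P and H3K27ac;
#' * `repressed` — overlaps H3K27me3 but neither Ser2P nor H3K27ac;
#' * `inactive` — overlaps none of the three sets.
#' Genes matching none of these rules (e.g. Ser2P only) are `inactive`.
#'
#' @param genes A gene table.
#' @param ser2p,k27ac,k27me3 Peak interval data frames (`chrom`, `start`,
#'   `end`).
#' @param upstream,downstream Extent of the tested region in bp (defaults
#'   250 and 2000).
#' @return A tibble with `gene_id`, `label` (factor: active, repressed,
#'   inactive, ambiguous) and the three overlap indicator columns.
#' @export
classify_activity <- function(genes, ser2p, k27ac, k27me3,
                              upstream = 250, downstream = 2000) {
  genes <- gene_table(genes)
  win <- oriented_window(genes$tss, genes$strand, upstream, downstream)
  region <- tibble(chrom = genes$chrom, start = win$start, end = win$end)
  has_ser2p <- overlaps_any(region, as_tibble(ser2p))
  has_k27ac <- overlaps_any(region, as_tibble(k27ac))
  has_k27me3 <- overlaps_any(region, as_tibble(k27me3))
  label <- dplyr::case_when(
    has_k27ac & has_k27me3 ~ "ambiguous",
    has_ser2p & has_k27ac ~ "active",
    has_k27me3 & !has_ser2p & !has_k27ac ~ "repressed",
    !has_ser2p & !has_k27ac & !has_k27me3 ~ "inactive",
    TRUE ~ "inactive"
  )
  tibble(
    gene_id = genes$gene_id,
    label = factor(label, levels = c("active", "repressed", "inactive", "ambiguous")),
    overlaps_ser2p = has_ser2p,
    overlaps_k27ac = has_k27ac,
    overlaps_k27me3 = has_k27me3
  )
}

#' Genes active in both of two labelled sets
#'
#' @param labels_a,labels_b Outputs of [classify_activity()] over the same
#'   annotation.
#' @return A character vector of gene ids labelled `active` in both.
#' @export
common_active_set <- function(labels_a, labels_b) {
  intersect(
    labels_a$gene_id[labels_a$label == "active"],
    labels_b$gene_id[labels_b$label == "active"]
  )
}
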