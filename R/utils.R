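#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom S4Vectors queryHits subjectHits
#' @keywords internal
"_PACKAGE"

# Strand-oriented genomic window around an anchor (BED half-open coordinates).
# Offsets o in [-up, down) map to genomic positions anchor+o on '+' and
# anchor-o-1 on '-' (offset 0 is the first transcribed base), so the genomic
# footprint is [anchor-up, anchor+down) on '+' and [anchor-down, anchor+up)
# on '-'.
oriented_window <- function(anchor, strand, up, down) {
  plus <- strand == "+"
  tibble(
    start = ifelse(plus, anchor - up, anchor - down),
    end   = ifelse(plus, anchor + down, anchor + up)
  )
}

# Strand-oriented offset of genomic position `pos` from `anchor`.
oriented_offset <- function(pos, anchor, strand) {
  ifelse(strand == "+", pos - anchor, anchor - 1L - pos)
}

# Overlap pairs between two interval tables (chrom/start/end, half-open).
# Returns a tibble with columns `query` and `subject` (row indices).
interval_overlap_pairs <- function(query, subject) {
  stopifnot(all(c("chrom", "start", "end") %in% names(query)),
            all(c("chrom", "start", "end") %in% names(subject)))
  shared <- intersect(unique(query$chrom), unique(subject$chrom))
  if (length(shared) == 0L) {
    return(tibble(query = integer(), subject = integer()))
  }
  out <- lapply(shared, function(ch) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    q <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    s <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(q, s)
    tibble(query = qi[S4Vectors::queryHits(hits)],
           subject = si[S4Vectors::subjectHits(hits)])
  })
  dplyr::bind_rows(out)
}

# Which rows of `query` overlap any row of `subject` by >= 1 bp.
overlaps_any <- function(query, subject) {
  hit <- rep(FALSE, nrow(query))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(hit)
  pairs <- interval_overlap_pairs(query, subject)
  hit[unique(pairs$query)] <- TRUE
  hit
}

# Run `code` under a temporary RNG seed when `seed` is not NULL; otherwise
# use the ambient RNG state.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a bounded child seed from a parent seed (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647) + 1L
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
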