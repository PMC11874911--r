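#' Read a gene annotation table
#'
#' Accepts 6+-column BED (chrom, start, end, name, score, strand; no header)
#' or a tab-delimited file with a header naming at least `gene_id`, `chrom`,
#' `strand`, `start`, `end`. BED12 files are consumed by their first six
#' columns.
#'
#' @param path Path to the annotation file.
#' @return A gene table (see [gene_table()]).
#' @export
read_gene_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  if (has_header) {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
  } else {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
    if (ncol(raw) < 6) abort("BED annotation needs >= 6 columns (strand)")
    tab <- tibble(chrom = raw[[1]], start = raw[[2]], end = raw[[3]],
                  gene_id = as.character(raw[[4]]), strand = raw[[6]])
  }
  gene_table(tab)
}

#' Read a BED3+ interval file
#'
#' @param path Path to a headerless BED file (>= 3 columns).
#' @return A tibble with `chrom`, `start`, `end` (plus `name`/`strand` when
#'   present).
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 3) abort("BED file needs >= 3 columns")
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]), end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 6) out$strand <- as.character(raw[[6]])
  out
}

#' Read a count table (gene_id, gene_count, exonic_count)
#'
#' @param path Path to a tab-delimited file with a header.
#' @param library_size Optional explicit library size stored as an
#'   attribute.
#' @param condition Optional condition label stored as an attribute.
#' @return A count tibble suitable for [derive_intronic()] /
#'   [compute_retention()].
#' @export
read_count_table <- function(path, library_size = NULL, condition = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "gene_count") %in% names(tab))) {
    abort("count table needs gene_id and gene_count columns")
  }
  attr(tab, "library_size") <- library_size
  attr(tab, "condition") <- condition
  tab
}

#' Write a Vplot matrix as tab-delimited text
#'
#' Offsets form the header row; fragment sizes the first column.
#'
#' @param vplot A `vplot` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vplot <- function(vplot, path) {
  df <- as.data.frame(vplot$matrix)
  names(df) <- vplot$offsets
  df <- cbind(size = vplot$sizes, df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Read a Vplot written by [write_vplot()]
#'
#' @param path Path to the matrix file.
#' @param normalization Normalisation state of the stored matrix.
#' @return A `vplot` object.
#' @export
read_vplot <- function(path, normalization = "counts") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  sizes <- as.integer(tab$size)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  offsets <- as.integer(colnames(m))
  dimnames(m) <- list(size = sizes, offset = offsets)
  structure(list(matrix = m, sizes = sizes, offsets = offsets,
                 n_anchors = NA_integer_, n_pairs = NA_integer_,
                 normalization = normalization),
            class = "vplot")
}
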