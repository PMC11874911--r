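# Independent brute-force oracles used to freeze expected values.
# Every oracle is a direct, unoptimised restatement of the definition and
# shares no code with the implementation under test.

make_genes <- function(...) gene_table(tibble::tibble(...))

random_genes <- function(n, seed, chroms = c("chr1", "chr2"),
                         span = 5e6, min_len = 1000, max_len = 30000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n)
    len <- sample(min_len:max_len, n, replace = TRUE)
    make_genes(
      gene_id = sprintf("R%04d", seq_len(n)),
      chrom = sample(chroms, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      start = start, end = start + len
    )
  })
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             span = 5e6, min_len = 50, max_len = 2000) {
  withr::with_seed(seed, {
    start <- sample.int(span, n, replace = TRUE)
    len <- min_len + sample.int(max_len - min_len + 1L, n, replace = TRUE) - 1L
    tibble::tibble(
      chrom = sample(chroms, n, replace = TRUE),
      start = start, end = start + len
    )
  })
}

# single-linkage TSS clustering by exhaustive pairwise distances
oracle_cluster_tss <- function(genes, radius) {
  genes <- gene_table(genes)
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && genes$chrom[i] == genes$chrom[j] &&
        genes$strand[i] == genes$strand[j] &&
        abs(genes$tss[i] - genes$tss[j]) <= radius) {
      parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(unique(root), function(r) {
    members <- which(root == r)
    members[order(-genes$length[members], genes$gene_id[members])][1L]
  }, integer(1))
  sort(genes$gene_id[keep])
}

# all-pairs scan for the clear-signal filter
oracle_clear_signal <- function(genes, up, down) {
  genes <- gene_table(genes)
  n <- nrow(genes)
  removed <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || genes$chrom[i] != genes$chrom[j]) next
    off <- if (genes$strand[i] == "+") genes$tss[j] - genes$tss[i]
           else genes$tss[i] - genes$tss[j]
    if (off >= -up && off <= down) { removed[i] <- TRUE; removed[j] <- TRUE }
  }
  sort(genes$gene_id[!removed])
}

# per-peak exhaustive footprint check with TSS > TTS > Intragenic priority
oracle_region_category <- function(peaks, genes, flank = 500) {
  genes <- gene_table(genes)
  overlap1 <- function(ps, pe, ws, we) ps < we && pe > ws
  vapply(seq_len(nrow(peaks)), function(p) {
    hit <- c(tss = FALSE, tts = FALSE, body = FALSE)
    for (g in seq_len(nrow(genes))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      if (overlap1(peaks$start[p], peaks$end[p],
                   genes$tss[g] - flank, genes$tss[g] + flank)) hit["tss"] <- TRUE
      if (overlap1(peaks$start[p], peaks$end[p],
                   genes$tts[g] - flank, genes$tts[g] + flank)) hit["tts"] <- TRUE
      bs <- min(genes$tss[g], genes$tts[g]) + flank
      be <- max(genes$tss[g], genes$tts[g]) - flank
      if (be > bs && overlap1(peaks$start[p], peaks$end[p], bs, be)) {
        hit["body"] <- TRUE
      }
    }
    if (hit["tss"]) "TSS" else if (hit["tts"]) "TTS"
    else if (hit["body"]) "Intragenic" else "Intergenic"
  }, character(1))
}

# per-read window counting
oracle_count <- function(reads, chrom, start, end, mode) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    if (mode == "overlap") {
      if (reads$start[i] < end && reads$end[i] > start) n <- n + 1L
    } else {
      m <- (reads$start[i] + reads$end[i]) %/% 2L
      if (m >= start && m < end) n <- n + 1L
    }
  }
  n
}

# per-base read depth averaged over a window (reads fully or partly inside
# contribute their covered bases), in rpm/bp
oracle_base_density <- function(reads, chrom, start, end, library_size) {
  depth <- numeric(end - start)
  touching <- which(reads$chrom == chrom & reads$start < end &
                      reads$end > start)
  for (i in touching) {
    lo <- max(reads$start[i], start)
    hi <- min(reads$end[i], end)
    idx <- (lo - start + 1L):(hi - start)
    depth[idx] <- depth[idx] + 1
  }
  mean(depth) * 1e6 / library_size
}

# truth-table activity labels from exhaustive overlap checks
oracle_activity <- function(genes, ser2p, k27ac, k27me3,
                            up = 250, down = 2000) {
  genes <- gene_table(genes)
  hits <- function(peaks, g) {
    ws <- if (genes$strand[g] == "+") genes$tss[g] - up else genes$tss[g] - down
    we <- if (genes$strand[g] == "+") genes$tss[g] + down else genes$tss[g] + up
    any(peaks$chrom == genes$chrom[g] & peaks$start < we & peaks$end > ws)
  }
  vapply(seq_len(nrow(genes)), function(g) {
    s <- hits(ser2p, g); a <- hits(k27ac, g); m <- hits(k27me3, g)
    if (a && m) "ambiguous"
    else if (s && a) "active"
    else if (m && !s && !a) "repressed"
    else "inactive"
  }, character(1))
}

# double-loop Vplot accumulation
oracle_vplot <- function(fragments, anchors, size_range = c(1, 250),
                         flank = 250) {
  sizes <- size_range[1]:size_range[2]
  offsets <- (-flank):flank
  mat <- matrix(0, length(sizes), length(offsets),
                dimnames = list(size = sizes, offset = offsets))
  for (f in seq_len(nrow(fragments))) {
    sz <- fragments$end[f] - fragments$start[f]
    if (sz < size_range[1] || sz > size_range[2]) next
    mid <- (fragments$start[f] + fragments$end[f]) %/% 2L
    for (a in seq_len(nrow(anchors))) {
      if (fragments$chrom[f] != anchors$chrom[a]) next
      off <- if (anchors$strand[a] == "+") mid - anchors$pos[a]
             else anchors$pos[a] - mid
      if (abs(off) <= flank) {
        mat[sz - size_range[1] + 1L, off + flank + 1L] <-
          mat[sz - size_range[1] + 1L, off + flank + 1L] + 1
      }
    }
  }
  mat
}
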