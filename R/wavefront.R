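#' Fit the two-state elongation-wave HMM by EM
#'
#' Models per-gene binned nascent-transcription signal after release of
#' paused polymerase as a left-to-right chain: the gene starts in the
#' transcribed (ON) state at its TSS-proximal bin, stays ON with probability
#' `p_stay_on` before each bin, and once OFF never returns (the wave has a
#' single advancing front). Emissions are Poisson with mean `lambda_on` in
#' ON bins and `lambda_off` in OFF bins. Because every hidden path is
#' determined by its front index k (number of ON bins), the E-step is
#' computed exactly by enumerating k with cumulative sums, and the M-step
#' updates the two Poisson means and `p_stay_on` from the posterior over k,
#' pooled across genes. Initialisation is deterministic, from data
#' quantiles: `lambda_on` = mean of the top-decile bins, `lambda_off` = mean
#' of the bottom half.
#'
#' @param counts A gene-by-bin matrix of raw counts (genes as rows), or a
#'   long binned tibble from [bin_gene_signal()].
#' @param bin_size Bin width in bp; taken from the tibble attribute when
#'   `counts` is a binned tibble.
#' @param init Optional list with `lambda_on`, `lambda_off`, `p_stay_on`
#'   overriding the quantile initialisation.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or a
#'   log-likelihood gain below `tol` (defaults 200 and 1e-6).
#' @return An object of class `wave_hmm`: `lambda_on`, `lambda_off`,
#'   `p_stay_on`, `loglik` (per-iteration trace), `n_iter`, `converged`,
#'   `bin_size`, `n_bins`, `n_genes`.
#' @export
fit_wave_hmm <- function(counts, bin_size = NULL, init = NULL,
                         max_iter = 200, tol = 1e-6) {
  if (is.data.frame(counts)) {
    bin_size <- bin_size %||% attr(counts, "bin_size")
    counts <- bins_to_matrix(counts)
  }
  if (is.null(bin_size)) abort("bin_size must be supplied for matrix input")
  if (all(counts == 0)) abort("degenerate input: all-zero signal set")
  n <- ncol(counts)
  v <- as.vector(counts)
  lambda_on <- init$lambda_on %||%
    mean(v[v >= stats::quantile(v, 0.9, names = FALSE)])
  lambda_off <- init$lambda_off %||%
    mean(v[v <= stats::quantile(v, 0.5, names = FALSE)])
  p_stay <- init$p_stay_on %||% 0.995
  lambda_on <- max(lambda_on, 1e-6)
  lambda_off <- max(lambda_off, 1e-8)
  if (lambda_on <= lambda_off) lambda_on <- lambda_off * 10 + 1e-3

  prefix <- cbind(0, t(apply(counts, 1L, cumsum)))  # genes x (n+1)
  total <- prefix[, n + 1L]
  k_vec <- 0:n
  const <- -sum(lgamma(counts + 1))
  loglik_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    prior <- k_vec * log(p_stay) +
      c(rep(log1p(-p_stay), n), 0)                  # k = n has no OFF entry
    ll <- sweep(prefix * log(lambda_on) +
                  (total - prefix) * log(lambda_off), 2L,
                k_vec * lambda_on + (n - k_vec) * lambda_off - prior, "-")
    lse <- log_sum_exp_rows(ll)
    w <- exp(ll - lse)                              # posterior over k per gene
    loglik <- sum(lse) + const
    loglik_trace <- c(loglik_trace, loglik)
    e_on_counts <- sum(w * prefix)
    e_on_bins <- sum(w %*% k_vec)
    e_off_counts <- sum(w * (total - prefix))
    e_off_bins <- sum(w %*% (n - k_vec))
    e_interior <- sum(w[, seq_len(n), drop = FALSE]) # P(k < n) summed over genes
    lambda_on_new <- if (e_on_bins > 0) e_on_counts / e_on_bins else lambda_on
    lambda_off_new <- if (e_off_bins > 0) e_off_counts / e_off_bins else lambda_off
    p_new <- e_on_bins / (e_on_bins + e_interior)
    lambda_on <- max(lambda_on_new, 1e-6)
    lambda_off <- max(lambda_off_new, 1e-8)
    p_stay <- min(max(p_new, 1e-6), 1 - 1e-9)
    if (iter > 1 &&
        abs(loglik_trace[iter] - loglik_trace[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(lambda_on = lambda_on, lambda_off = lambda_off, p_stay_on = p_stay,
         loglik = loglik_trace, n_iter = length(loglik_trace),
         converged = converged, bin_size = as.integer(bin_size),
         n_bins = n, n_genes = nrow(counts)),
    class = "wave_hmm"
  )
}

#' @export
print.wave_hmm <- function(x, ...) {
  cat("Two-state left-to-right Poisson wave HMM\n")
  cat(sprintf("  lambda_on = %.4g, lambda_off = %.4g, p_stay_on = %.6g\n",
              x$lambda_on, x$lambda_off, x$p_stay_on))
  cat(sprintf("  %d genes x %d bins (%d bp); %d EM iterations, converged: %s\n",
              x$n_genes, x$n_bins, x$bin_size, x$n_iter, x$converged))
  invisible(x)
}

# Most probable front index per gene (Viterbi decode of the left-to-right
# chain, equivalent to an argmax over the front index k). lambda_off = 0 is
# handled exactly: any positive count after the front is impossible, so the
# decode reduces to the last-nonzero-bin rule.
front_index <- function(counts, params) {
  n <- ncol(counts)
  k_vec <- 0:n
  log_off <- if (params$lambda_off > 0) log(params$lambda_off) else -1e12
  prefix <- cbind(0, t(apply(counts, 1L, cumsum)))
  total <- prefix[, n + 1L]
  prior <- k_vec * log(params$p_stay_on) +
    c(rep(log1p(-params$p_stay_on), n), 0)
  ll <- sweep(prefix * log(params$lambda_on) + (total - prefix) * log_off, 2L,
              k_vec * params$lambda_on + (n - k_vec) * params$lambda_off - prior,
              "-")
  max.col(ll, ties.method = "first") - 1L
}

#' Call the elongation-wave front of each gene
#'
#' Viterbi-decodes each gene's binned signal under fitted wave-HMM
#' parameters. The front is the genomic extent of the ON segment:
#' `front_bp = bin_size * (number of ON bins)`. An all-OFF decode gives a
#' front of 0; an all-ON decode is censored at the region boundary.
#'
#' @param counts A gene-by-bin count matrix or binned tibble, with the same
#'   `bin_size` as the fit.
#' @param params A fitted `wave_hmm` object (see [fit_wave_hmm()]).
#' @return A tibble with `gene_id`, `front_bp`, and logical `censored`.
#' @export
call_fronts <- function(counts, params) {
  if (is.data.frame(counts)) {
    bs <- attr(counts, "bin_size")
    if (!is.null(bs) && bs != params$bin_size) {
      abort("bin_size of signal does not match fitted parameters")
    }
    counts <- bins_to_matrix(counts)
  }
  if (ncol(counts) != params$n_bins) {
    abort("bin count of signal does not match fitted parameters")
  }
  k <- front_index(counts, params)
  tibble(
    gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
    front_bp = k * params$bin_size,
    censored = k == params$n_bins
  )
}

#' Summarise called fronts per timepoint
#'
#' @param fronts A tibble of front calls with a `timepoint` column (minutes)
#'   and `front_bp`.
#' @return A tibble per timepoint with `n`, `n_censored`, `median_bp`,
#'   `q1_bp`, `q3_bp`, and `median_kb`.
#' @export
wave_summary <- function(fronts) {
  fronts |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_censored = sum(.data$censored),
      median_bp = stats::median(.data$front_bp),
      q1_bp = stats::quantile(.data$front_bp, 0.25, names = FALSE),
      q3_bp = stats::quantile(.data$front_bp, 0.75, names = FALSE),
      median_kb = .data$median_bp / 1000,
      .groups = "drop"
    )
}

#' Estimate elongation speed from per-timepoint front medians
#'
#' Ordinary least-squares line of median front position (kb) against time
#' (min), intercept free; the slope is the elongation speed in kb/min.
#'
#' @param summaries Output of [wave_summary()] with >= 2 timepoints.
#' @param cell_line,condition Optional labels carried into the result.
#' @return An object of class `wave_speed`: `speed` (kb/min), `intercept`
#'   (kb), `n_timepoints`, labels, and the underlying `lm` fit.
#' @export
estimate_speed <- function(summaries, cell_line = NA_character_,
                           condition = NA_character_) {
  if (nrow(summaries) < 2) abort("speed estimation needs >= 2 timepoints")
  fit <- stats::lm(median_kb ~ timepoint, data = summaries)
  structure(
    list(speed = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         n_timepoints = nrow(summaries),
         cell_line = cell_line, condition = condition, fit = fit),
    class = "wave_speed"
  )
}

#' @export
print.wave_speed <- function(x, ...) {
  cat(sprintf("Elongation wave speed: %.3f kb/min (intercept %.2f kb, %d timepoints)\n",
              x$speed, x$intercept, x$n_timepoints))
  invisible(x)
}

#' Compare front positions between two conditions on shared genes
#'
#' Joins per-gene front calls and applies either a two-sided paired t-test
#' on the per-gene front differences (default) or a seeded permutation test
#' with the Pearson (point-biserial) statistic — both readings of the
#' published significance annotations are available.
#'
#' @param fronts_a,fronts_b Front tibbles (from [call_fronts()]) sharing
#'   >= 10 genes.
#' @param method `"paired_t"` or `"pearson_perm"`.
#' @param n_perm,seed Permutation settings for `"pearson_perm"`.
#' @return A one-row test-result tibble (see [welch_t()]).
#' @export
compare_fronts <- function(fronts_a, fronts_b,
                           method = c("paired_t", "pearson_perm"),
                           n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  joined <- dplyr::inner_join(
    dplyr::select(fronts_a, "gene_id", a = "front_bp"),
    dplyr::select(fronts_b, "gene_id", b = "front_bp"),
    by = "gene_id"
  )
  if (nrow(joined) == 0L) abort("no shared genes")
  if (nrow(joined) < 10L) abort("fewer than 10 shared genes")
  if (method == "paired_t") {
    paired_t(joined$a, joined$b)
  } else {
    permutation_engine(joined$a, joined$b, statistic = "pearson",
                       n_perm = n_perm, seed = seed)
  }
}
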