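#' Blind CpG-density calibration of nrpm to beta-values
#'
#' MBD capture enriches a window in proportion to both its methylation level
#' and its CpG density, so a raw nrpm value is not comparable across
#' windows. Blind calibration estimates, within strata of CpG count `d`,
#' the background nrpm level `bg(d)` expected at beta = 0 and the
#' fully-methylated level `full(d)` expected at beta = 1, using only the
#' density structure of a pooled reference sample: within each stratum the
#' lowest-decile windows anchor the background, and the upper-decile
#' windows are assumed to average a methylation level `beta0` (default
#' 0.9), which fixes the scale. The default anchor was validated by
#' parameter recovery against the package's forward simulator: ranking by
#' observed nrpm selects both the upper tail of the methylated mode and
#' upward counting noise, which under a typical bimodal methylome places
#' the top-decile mean near 0.9 of the fully-methylated level.
#' `full(d)` is made non-decreasing in `d` by
#' isotonic adjustment. Beta-values are then read off linearly:
#' `beta = (nrpm - bg(d)) / (full(d) - bg(d))`, clamped to \[0, 1\].
#'
#' @param cm reference-pool [count_matrix()] (one or more samples; nrpm are
#'   averaged across its columns).
#' @param windows a [genome_windows] table matching `cm` rows.
#' @param beta0 assumed mean beta of upper-decile windows per stratum.
#' @param strata integer breakpoints of CpG-count strata; windows with
#'   `d >= max(strata)` form the top stratum.
#' @param min_support minimum windows per stratum; under-supported strata
#'   are interpolated from neighbors with a warning.
#' @return a `calibration_table` data.frame with columns `d_lo`, `d_hi`
#'   (inclusive), `bg`, `full`, `n`.
#' @export
fit_calibration <- function(cm, windows, beta0 = 0.9,
                            strata = c(0:9, 12, 16, 20, 25),
                            min_support = 50) {
  stopifnot(nrow(cm$counts) == nrow(windows))
  if (ncol(cm$counts) < 1) stop("reference pool must contain at least one sample")
  v <- rowMeans(nrpm(cm))
  # the known always-methylated QC list would contaminate the background
  # (lowest-decile) estimate of its density strata, so it sits out
  use <- !windows$excluded & !windows$qc_always_methylated
  d <- windows$cpg_count
  lo <- strata
  hi <- c(strata[-1] - 1L, Inf)
  tab <- data.frame(d_lo = lo, d_hi = hi, bg = NA_real_, full = NA_real_,
                    n = 0L)
  for (i in seq_len(nrow(tab))) {
    sel <- use & d >= tab$d_lo[i] & d <= tab$d_hi[i]
    n <- sum(sel)
    tab$n[i] <- n
    if (n >= min_support) {
      x <- v[sel]
      q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
      bg <- mean(x[x <= q[1]])
      up <- mean(x[x >= q[2]])
      tab$bg[i] <- bg
      tab$full[i] <- bg + max(up - bg, 0) / beta0
    }
  }
  bad <- is.na(tab$bg)
  if (all(bad)) stop("no calibration stratum has sufficient support")
  if (any(bad)) {
    warning(sum(bad), " calibration strata under-supported; interpolated from neighbors")
    mid <- ifelse(is.finite(tab$d_hi), (tab$d_lo + tab$d_hi) / 2, tab$d_lo + 2)
    tab$bg[bad] <- stats::approx(mid[!bad], tab$bg[!bad], mid[bad], rule = 2)$y
    tab$full[bad] <- stats::approx(mid[!bad], tab$full[!bad], mid[bad], rule = 2)$y
  }
  # enforce full(d) non-decreasing in d, weighted by stratum support
  iso <- weighted_isotonic(tab$full, pmax(tab$n, 1L))
  tab$full <- pmax(iso, tab$bg)
  structure(tab, class = c("calibration_table", "data.frame"), beta0 = beta0)
}

# pool-adjacent-violators with weights (isoreg is unweighted)
weighted_isotonic <- function(y, w) {
  n <- length(y)
  val <- y; wt <- as.numeric(w); len <- rep(1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tw <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (val[k - 1L] * wt[k - 1L] + val[k] * wt[k]) / tw
      wt[k - 1L] <- tw
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], len[seq_len(k)])
}

# map window CpG counts to calibration rows
calibration_lookup <- function(calibration, d) {
  idx <- findInterval(d, calibration$d_lo)
  idx[idx < 1L] <- 1L
  idx
}

#' Per-window bg/full nrpm levels implied by a calibration table
#' @param calibration a calibration table from [fit_calibration()].
#' @param windows a [genome_windows] table.
#' @return data.frame with per-window `bg` and `full` nrpm levels.
#' @export
calibration_levels <- function(calibration, windows) {
  idx <- calibration_lookup(calibration, windows$cpg_count)
  data.frame(window_id = windows$window_id,
             bg = calibration$bg[idx], full = calibration$full[idx])
}

#' Estimate beta-values from counts via a calibration table
#'
#' @param cm a [count_matrix()] (TMM-normalized).
#' @param calibration table from [fit_calibration()].
#' @param windows matching [genome_windows].
#' @param min_expected windows whose calibrated dynamic range
#'   `full(d) - bg(d)` falls below this nrpm value cannot resolve a beta and
#'   are returned as `NA`, as are excluded windows. The default (20 nrpm)
#'   corresponds to a dynamic range of a few fragments at typical depth;
#'   below that the denominator is dominated by counting noise.
#' @return numeric window-by-sample matrix of beta-values in \[0, 1\] or `NA`.
#' @export
estimate_beta <- function(cm, calibration, windows, min_expected = 20) {
  lv <- calibration_levels(calibration, windows)
  rng <- lv$full - lv$bg
  b <- (nrpm(cm) - lv$bg) / rng
  b[b < 0] <- 0; b[b > 1] <- 1
  b[rng < min_expected | windows$excluded, ] <- NA_real_
  b
}

#' Relative CpG enrichment score of a sample
#'
#' Ratio of the mean CpG density of captured fragments (count-weighted mean
#' window density) to the genome-wide mean window density, over non-excluded
#' windows. Samples below 2.5 are flagged low-quality.
#'
#' @param counts named integer vector or one-column matrix over windows.
#' @param windows [genome_windows].
#' @param threshold pass threshold on the ratio.
#' @return list with `relative_enrichment` and `pass_enrichment`.
#' @export
relative_enrichment <- function(counts, windows, threshold = 2.5) {
  counts <- as.numeric(counts)
  use <- !windows$excluded
  c_j <- counts[use]; d_j <- windows$cpg_count[use]
  tot <- sum(c_j)
  if (tot == 0) return(list(relative_enrichment = NA_real_, pass_enrichment = FALSE))
  ratio <- (sum(c_j * d_j) / tot) / mean(d_j)
  list(relative_enrichment = ratio, pass_enrichment = ratio >= threshold)
}

#' Always-methylated window QC
#'
#' Fraction of the designated always-methylated QC windows whose estimated
#' beta is at least `beta_min` (missing values count as below); a sample
#' passes when the fraction reaches `min_frac`.
#'
#' @param beta numeric vector of beta-values over windows (one sample).
#' @param windows [genome_windows] with `qc_always_methylated` flags.
#' @param beta_min,min_frac QC thresholds.
#' @return list with `frac_qc_windows_high` and `pass_always_methylated`.
#' @export
qc_always_methylated <- function(beta, windows, beta_min = 0.8, min_frac = 0.40) {
  sel <- windows$qc_always_methylated
  if (!any(sel)) stop("no QC always-methylated windows flagged")
  b <- beta[sel]
  frac <- mean(!is.na(b) & b >= beta_min)
  list(frac_qc_windows_high = frac, pass_always_methylated = frac >= min_frac)
}

#' Full sample QC report
#' @param counts count vector for the sample.
#' @param beta beta vector for the sample.
#' @param windows [genome_windows].
#' @return list combining [relative_enrichment()] and
#'   [qc_always_methylated()] fields.
#' @export
qc_report <- function(counts, beta, windows) {
  c(relative_enrichment(counts, windows),
    qc_always_methylated(beta, windows))
}

#' PCA on the most variable windows with batch centering
#'
#' Removes per-window batch means (limma-style location adjustment), centers
#' each window, ranks windows by standard deviation across samples, and
#' runs principal components on the top `k_windows`. Windows with any
#' missing beta are dropped first.
#'
#' @param beta window-by-sample beta matrix.
#' @param batch optional per-sample batch labels; a single batch makes the
#'   step an identity.
#' @param k_windows number of most-variable windows to keep.
#' @param n_pcs number of components returned.
#' @return list with `scores` (samples x PCs), `sdev`, `windows_used`, and
#'   `degenerate` (TRUE when total variance is zero).
#' @export
pca_variable_windows <- function(beta, batch = NULL, k_windows = 50000,
                                 n_pcs = 10) {
  if (ncol(beta) < 3) stop("PCA requires at least 3 samples")
  keep <- stats::complete.cases(beta)
  x <- beta[keep, , drop = FALSE]
  if (!is.null(batch) && length(unique(batch)) > 1) {
    batch <- as.factor(batch)
    for (b in levels(batch)) {
      cols <- which(batch == b)
      x[, cols] <- x[, cols] - rowMeans(x[, cols, drop = FALSE])
    }
  }
  x <- x - rowMeans(x)
  sds <- apply(x, 1, stats::sd)
  if (all(sds == 0)) {
    return(list(scores = matrix(0, ncol(beta), 0,
                                dimnames = list(colnames(beta), NULL)),
                sdev = numeric(0), windows_used = character(0),
                degenerate = TRUE))
  }
  ord <- order(sds, decreasing = TRUE)
  top <- ord[seq_len(min(k_windows, length(ord)))]
  p <- stats::prcomp(t(x[top, , drop = FALSE]), center = FALSE)
  k <- min(n_pcs, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE], sdev = p$sdev,
       windows_used = rownames(beta)[keep][top], degenerate = FALSE)
}
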