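#' Differential methylation between two sample groups
#'
#' Per-window negative-binomial GLM on fragment counts with a two-group
#' design. CpG density enters through the offset,
#' `log(library_size * norm_factor * full(d) / 1e6)`, where `full(d)` is
#' the calibrated fully-methylated nrpm level of the window's density
#' stratum, so the group coefficient reads as a methylation change rather
#' than a density effect. Dispersions are estimated per window and shrunk
#' toward the fitted mean-dispersion trend (edgeR empirical Bayes);
#' significance is a likelihood-ratio test with BH correction across the
#' tested windows. Windows are prefiltered to nrpm > 1 in at least one
#' sample. The effect size Delta-beta is the difference of group mean
#' beta-values.
#'
#' @param cm a TMM-normalized [count_matrix()].
#' @param calibration table from [fit_calibration()].
#' @param windows matching [genome_windows].
#' @param group_a,group_b character vectors of sample ids (>= 2 each);
#'   Delta-beta and the log-fold-change are A minus B.
#' @param min_nrpm prefilter: keep windows with nrpm above this in at least
#'   one sample of either group.
#' @param beta optional precomputed beta matrix (from [estimate_beta()]).
#' @return a `dmr_table` data.frame: `window_id`, `lfc`, `p`, `q`,
#'   `delta_beta`, `direction` (+1 hyper in A, -1 hypo), `context` (`NA`
#'   until [annotate_cgi_context()]), `converged`.
#' @export
call_dmrs <- function(cm, calibration, windows, group_a, group_b,
                      min_nrpm = 1, beta = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 samples")
  ids <- c(group_a, group_b)
  if (!all(ids %in% colnames(cm$counts))) stop("unknown sample ids in groups")
  sub <- cm$counts[, ids, drop = FALSE]
  v <- sweep(sub, 2, cm$library_size[ids] * cm$norm_factor[ids], "/") * 1e6
  keep <- apply(v, 1, max) > min_nrpm & !windows$excluded
  if (!any(keep)) stop("no windows pass the nrpm prefilter")

  lv <- calibration_levels(calibration, windows)
  wgt <- pmax(lv$full, 1e-6)
  off <- outer(log(wgt[keep]),
               log(cm$library_size[ids] * cm$norm_factor[ids] / 1e6), "+")
  grp <- factor(rep(c("A", "B"), c(length(group_a), length(group_b))),
                levels = c("B", "A"))
  design <- stats::model.matrix(~grp)

  y <- edgeR::DGEList(counts = sub[keep, , drop = FALSE])
  y <- edgeR::scaleOffset(y, off)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  res <- lrt$table

  if (is.null(beta)) beta <- estimate_beta(cm, calibration, windows)
  ba <- rowMeans(beta[, group_a, drop = FALSE], na.rm = TRUE)
  bb <- rowMeans(beta[, group_b, drop = FALSE], na.rm = TRUE)
  delta <- (ba - bb)[keep]
  delta[is.nan(delta)] <- 0

  p <- res$PValue
  conv <- is.finite(p)
  p[!conv] <- 1
  # windows with no count variation at all carry no evidence
  flat <- apply(sub[keep, , drop = FALSE], 1, function(x) all(x == x[1]))
  p[flat & abs(delta) < 1e-12] <- 1

  out <- data.frame(window_id = windows$window_id[keep],
                    lfc = res$logFC,
                    p = p,
                    q = stats::p.adjust(p, "BH"),
                    delta_beta = delta,
                    direction = ifelse(delta >= 0, 1L, -1L),
                    context = NA_character_,
                    converged = conv,
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Filter a DMR table on FDR and effect size
#'
#' The most significant DMRs are those at `q <= fdr` with
#' `|delta_beta| >= min_abs_delta_beta` (0.5 for tissue contrasts, 0.3 for
#' cfDNA contrasts).
#'
#' @param dmrs a `dmr_table`.
#' @param fdr BH FDR threshold.
#' @param min_abs_delta_beta minimum absolute group beta difference.
#' @return the filtered `dmr_table`.
#' @export
filter_significant <- function(dmrs, fdr = 0.001, min_abs_delta_beta = 0.5) {
  dmrs[dmrs$q <= fdr & abs(dmrs$delta_beta) >= min_abs_delta_beta, ,
       drop = FALSE]
}

#' Annotate DMRs with CpG-island context
#'
#' Labels each DMR window `CGI` if it overlaps a CpG island, `shore` if
#' within 2 kb of one, `shelf` if within 4 kb, else `open_sea`
#' (precedence CGI > shore > shelf).
#'
#' @param dmrs a `dmr_table` (window ids encode coordinates as
#'   `contig:start-end`).
#' @param cgi CGI intervals: a BED path or a data.frame with `contig`,
#'   `start`, `end` (0-based half-open).
#' @return `dmrs` with the `context` column filled.
#' @export
annotate_cgi_context <- function(dmrs, cgi) {
  if (is.character(cgi)) cgi <- read_bed(cgi)
  coords <- parse_window_ids(dmrs$window_id)
  ctx <- rep("open_sea", nrow(dmrs))
  if (nrow(cgi) > 0) {
    win_gr <- GenomicRanges::GRanges(
      coords$contig, IRanges::IRanges(coords$start + 1L, coords$end))
    cgi_gr <- GenomicRanges::GRanges(
      cgi$contig, IRanges::IRanges(cgi$start + 1L, cgi$end))
    dist <- rep(Inf, nrow(dmrs))
    hit <- GenomicRanges::distanceToNearest(win_gr, cgi_gr)
    dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    ctx[dist <= 4000] <- "shelf"
    ctx[dist <= 2000] <- "shore"
    ctx[dist == 0] <- "CGI"
  }
  dmrs$context <- ctx
  dmrs
}

parse_window_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("window ids must look like 'contig:start-end'")
  data.frame(contig = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Venn partition of DMR sets
#'
#' Exact multi-set intersection counts by window id: one row per region of
#' the Venn partition (membership pattern over the input sets).
#'
#' @param ... two or more DMR sets: `dmr_table`s or character vectors of
#'   window ids. Unnamed sets are called `set1`, `set2`, ...
#' @return data.frame with one logical membership column per set plus `n`.
#' @export
intersect_dmr_sets <- function(...) {
  sets <- list(...)
  if (length(sets) < 2) stop("need at least two sets")
  ids <- lapply(sets, function(s) {
    if (is.data.frame(s)) unique(s$window_id) else unique(as.character(s))
  })
  if (is.null(names(ids)) || any(!nzchar(names(ids))))
    names(ids) <- paste0("set", seq_along(ids))
  universe <- unique(unlist(ids))
  member <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(ids)))
  pat <- expand.grid(rep(list(c(FALSE, TRUE)), length(ids)))
  names(pat) <- names(ids)
  pat <- pat[rowSums(pat) > 0, , drop = FALSE]
  pat$n <- apply(pat, 1, function(p)
    sum(apply(member, 1, function(row) all(row == as.logical(p)))))
  rownames(pat) <- NULL
  pat
}
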