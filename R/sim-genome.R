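#' Simulate a synthetic tiled genome
#'
#' Lays out `n_windows` contiguous 300-bp windows on one synthetic contig
#' (`sim1`). A fraction `cgi_fraction` of windows is organised into
#' CpG-island-like blocks (1-3 consecutive windows) whose CpG counts are
#' drawn at the CGI Poisson rate; all remaining windows draw from the
#' background rate. A designated always-methylated QC subset is flagged
#' among the densest background windows (always-methylated CpG sites carry
#' CpGs by definition, so an informative QC window needs measurable
#' density).
#'
#' @param config a [sim_config()].
#' @return a [genome_windows] table with an extra logical `cgi` column.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  n <- config$n_windows
  if (n < 100) stop("sim_config: 'n_windows' must be at least 100")
  with_seed(child_seed(config$seed, "genome"), {
    cgi <- logical(n)
    n_cgi_target <- round(n * config$cgi_fraction)
    if (n_cgi_target > 0) {
      mean_block <- 2
      n_blocks <- max(1L, round(n_cgi_target / mean_block))
      # one block per genome segment keeps blocks separated so shores and
      # shelves exist around them
      seg <- floor(n / n_blocks)
      placed <- 0L
      for (b in seq_len(n_blocks)) {
        len <- sample(1:3, 1L)
        len <- min(len, n_cgi_target - placed)
        if (len <= 0) break
        lo <- (b - 1L) * seg + 1L
        hi <- max(lo, b * seg - len - 14L)  # keep >= 14 windows to next block
        start <- if (hi > lo) sample(lo:hi, 1L) else lo
        cgi[start:(start + len - 1L)] <- TRUE
        placed <- placed + len
      }
    }
    d <- integer(n)
    d[cgi] <- stats::rpois(sum(cgi), config$cpg_rate_cgi)
    d[!cgi] <- stats::rpois(sum(!cgi), config$cpg_rate_bg)
    start <- WINDOW_WIDTH * (seq_len(n) - 1L)
    df <- data.frame(contig = "sim1", start = start,
                     end = start + WINDOW_WIDTH,
                     cpg_count = d, excluded = FALSE,
                     qc_always_methylated = FALSE,
                     cgi = cgi, stringsAsFactors = FALSE)
    # QC subset: densest background (non-CGI) windows
    bg_idx <- which(!cgi)
    dense <- bg_idx[d[bg_idx] >= 5]
    if (length(dense) < config$n_qc_windows)
      dense <- bg_idx[order(d[bg_idx], decreasing = TRUE)][
        seq_len(min(config$n_qc_windows, length(bg_idx)))]
    qc <- if (length(dense) > config$n_qc_windows)
      sort(sample(dense, config$n_qc_windows)) else sort(dense)
    df$qc_always_methylated[qc] <- TRUE
    new_genome_windows(df)
  })
}

#' CGI intervals implied by simulated windows
#'
#' Merges consecutive CGI-flagged windows into 0-based half-open intervals
#' (a synthetic CGI BED track).
#' @param windows output of [simulate_genome()].
#' @return data.frame with `contig`, `start`, `end`.
#' @export
cgi_intervals <- function(windows) {
  stopifnot("cgi" %in% names(windows))
  r <- rle(windows$cgi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(contig = windows$contig[starts[sel]],
             start = windows$start[starts[sel]],
             end = windows$end[ends[sel]],
             stringsAsFactors = FALSE)
}

# window context relative to CGI blocks: CGI > shore (<=2kb) > shelf (<=4kb)
window_context <- function(windows, cgi = cgi_intervals(windows)) {
  ctx <- rep("open_sea", nrow(windows))
  if (nrow(cgi) == 0) return(ctx)
  win_gr <- windows_granges(windows)
  cgi_gr <- GenomicRanges::GRanges(cgi$contig,
                                   IRanges::IRanges(cgi$start + 1L, cgi$end))
  dist <- rep(Inf, nrow(windows))
  hit <- GenomicRanges::distanceToNearest(win_gr, cgi_gr)
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  ctx[dist <= 4000] <- "shelf"
  ctx[dist <= 2000] <- "shore"
  ctx[dist == 0] <- "CGI"
  ctx
}

#' Simulate ground-truth methylomes
#'
#' Builds a normal methylome plus three tumor methylomes (`tumor_ASCL1`,
#' `tumor_NEUROD1`, `tumor_DN`) sharing pan-tumor DMRs and carrying
#' subtype-specific marker blocks. Methylation within each density class is
#' bimodal (most CGI windows unmethylated with a methylated minority;
#' background windows mostly methylated), which both reflects real genomes
#' and makes blind calibration identifiable. Hypermethylated pan-tumor DMRs
#' (`frac_hyper` of `n_dmrs`) are placed on unmethylated CGI windows;
#' hypomethylated DMRs fill shore/shelf windows until the configured
#' CGI-context fraction is met, then open sea. QC windows carry beta 1 in
#' every class.
#'
#' @param windows output of [simulate_genome()].
#' @param config the same [sim_config()].
#' @return object of class `methylome_set`: list with `beta` (window x
#'   class matrix over `normal`, `tumor_ASCL1`, `tumor_NEUROD1`,
#'   `tumor_DN`), `dmr` (pan-tumor DMR table with `window_id`, `direction`
#'   +1 hyper / -1 hypo in tumor, `delta_beta_true`), and `subtype_markers`
#'   (named list of window ids per subtype).
#' @export
simulate_methylomes <- function(windows, config) {
  n <- nrow(windows)
  classes <- c("normal", "tumor_ASCL1", "tumor_NEUROD1", "tumor_DN")
  with_seed(child_seed(config$seed, "methylomes"), {
    lowb <- function(k) stats::rbeta(k, 2, 23)   # mean ~0.08
    highb <- function(k) stats::rbeta(k, 16, 4)  # mean ~0.80
    normal <- numeric(n)
    is_cgi <- windows$cgi
    nc <- sum(is_cgi)
    hi_cgi <- stats::runif(nc) < 0.25
    normal[is_cgi][hi_cgi] <- highb(sum(hi_cgi))
    normal[is_cgi][!hi_cgi] <- lowb(sum(!hi_cgi))
    nb <- sum(!is_cgi)
    lo_bg <- stats::runif(nb) < 0.10
    normal[!is_cgi][lo_bg] <- lowb(sum(lo_bg))
    normal[!is_cgi][!lo_bg] <- highb(sum(!lo_bg))
    normal[windows$qc_always_methylated] <- 1

    beta <- matrix(normal, n, 4, dimnames = list(windows$window_id, classes))
    ctx <- window_context(windows)
    usable <- !windows$excluded & !windows$qc_always_methylated

    n_hyper <- round(config$n_dmrs * config$frac_hyper)
    n_hypo <- config$n_dmrs - n_hyper
    # hyper DMRs: unmethylated CGI windows gain methylation in all tumors
    cand_hyper <- which(usable & is_cgi & normal <= 0.9 - config$dmr_delta)
    if (length(cand_hyper) < n_hyper)
      stop("DMR demand exceeds available CGI windows (", length(cand_hyper),
           " candidates for ", n_hyper, " hypermethylated DMRs)")
    hyper <- sort(sample(cand_hyper, n_hyper))
    beta[hyper, 2:4] <- matrix(stats::runif(n_hyper, 0.88, 0.97), n_hyper, 3)

    # hypo DMRs: methylated windows lose methylation in tumor; fill
    # shore/shelf first to hit the configured CGI-context fraction
    n_ctx_target <- round(config$n_dmrs * config$frac_dmr_cgi_context)
    n_hypo_ctx <- max(0L, min(n_hypo, n_ctx_target - n_hyper))
    taken <- rep(FALSE, n); taken[hyper] <- TRUE
    cand_ss <- which(usable & !taken & ctx %in% c("shore", "shelf") &
                       normal >= config$dmr_delta + 0.03)
    if (length(cand_ss) < n_hypo_ctx) n_hypo_ctx <- length(cand_ss)
    hypo1 <- if (n_hypo_ctx > 0) sort(sample(cand_ss, n_hypo_ctx)) else integer(0)
    taken[hypo1] <- TRUE
    cand_os <- which(usable & !taken & ctx == "open_sea" &
                       normal >= config$dmr_delta + 0.03)
    n_hypo_os <- n_hypo - n_hypo_ctx
    if (length(cand_os) < n_hypo_os)
      stop("DMR demand exceeds available windows for hypomethylated DMRs")
    hypo2 <- if (n_hypo_os > 0) sort(sample(cand_os, n_hypo_os)) else integer(0)
    hypo <- sort(c(hypo1, hypo2))
    taken[hypo] <- TRUE
    beta[hypo, 2:4] <- matrix(stats::runif(length(hypo), 0.01, 0.05),
                              length(hypo), 3)

    # subtype marker blocks: per subtype, unmethylated CGI windows gain
    # methylation only in that subtype
    markers <- list(ASCL1 = integer(0), NEUROD1 = integer(0), DN = integer(0))
    for (s in names(markers)) {
      k <- config$n_subtype_dmrs_per_contrast
      cand <- which(usable & !taken & is_cgi & normal <= 0.9 - config$dmr_delta)
      if (length(cand) < k)
        stop("subtype DMR demand exceeds available CGI windows for ", s)
      sel <- sort(sample(cand, k))
      taken[sel] <- TRUE
      beta[sel, paste0("tumor_", s)] <- stats::runif(k, 0.88, 0.97)
      markers[[s]] <- windows$window_id[sel]
    }

    dmr <- data.frame(
      window_id = windows$window_id[c(hyper, hypo)],
      direction = c(rep(1L, length(hyper)), rep(-1L, length(hypo))),
      delta_beta_true = c(beta[hyper, 2] - beta[hyper, 1],
                          beta[hypo, 2] - beta[hypo, 1]),
      stringsAsFactors = FALSE)
    structure(list(beta = beta, dmr = dmr, subtype_markers = markers,
                   classes = classes),
              class = "methylome_set")
  })
}
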