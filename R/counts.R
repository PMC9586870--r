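#' Per-window fragment count matrices
#'
#' A `count_matrix` holds an integer window-by-sample matrix of MBD-capture
#' fragment counts together with per-sample library sizes and TMM
#' normalization factors. Normalized reads per million (nrpm) are derived as
#' `count / (library_size * norm_factor) * 1e6`.
#'
#' @param counts integer matrix, rows = window ids, columns = sample ids.
#' @param library_size named per-sample totals; defaults to column sums.
#' @param norm_factor named per-sample TMM factors; defaults to 1.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_size = NULL, norm_factor = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have window ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  if (is.null(library_size)) library_size <- colSums(counts)
  library_size <- library_size[colnames(counts)]
  if (is.null(norm_factor))
    norm_factor <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  norm_factor <- norm_factor[colnames(counts)]
  if (any(norm_factor <= 0)) stop("norm_factor must be positive")
  structure(list(counts = counts,
                 library_size = library_size,
                 norm_factor = norm_factor),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "windows x", ncol(x$counts), "samples\n")
  cat("library sizes:", paste(utils::head(round(x$library_size), 4), collapse = ", "),
      if (ncol(x$counts) > 4) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Combine count columns into a matrix
#' @param columns named list of integer count vectors over the same windows.
#' @param ... passed to [count_matrix()].
#' @export
bind_count_columns <- function(columns, ...) {
  m <- do.call(cbind, columns)
  colnames(m) <- names(columns)
  count_matrix(m, ...)
}

#' Normalized reads per million
#' @param cm a [count_matrix()].
#' @return numeric matrix of nrpm values.
#' @export
nrpm <- function(cm) {
  sweep(cm$counts, 2, cm$library_size * cm$norm_factor, "/") * 1e6
}

#' Assign fragments to windows by midpoint
#'
#' Applies the read filters (MAPQ >= 10, fragment length in \[50, 1000\] bp)
#' and assigns each surviving fragment to exactly one window by its midpoint
#' `floor((start + end) / 2)`; midpoints on a boundary fall in the
#' right-hand (half-open) window. Fragments on unknown contigs or landing in
#' excluded windows are tallied, not counted.
#'
#' @param fragments data.frame with `contig`, `start`, `end` (0-based
#'   half-open) and `mapq`.
#' @param windows a [genome_windows] table.
#' @param min_mapq,min_len,max_len filter thresholds.
#' @return list with `counts` (named integer vector over window ids),
#'   `library_size` (surviving fragments counted), `n_rejected_contig`,
#'   `n_rejected_excluded`, `n_filtered`.
#' @export
assign_fragments <- function(fragments, windows, min_mapq = 10,
                             min_len = 50, max_len = 1000) {
  stopifnot(all(c("contig", "start", "end", "mapq") %in% names(fragments)))
  if (any(fragments$end <= fragments$start))
    stop("fragment records must satisfy start < end")
  len <- fragments$end - fragments$start
  pass <- fragments$mapq >= min_mapq & len >= min_len & len <= max_len
  n_filtered <- sum(!pass)
  frg <- fragments[pass, , drop = FALSE]
  counts <- stats::setNames(integer(nrow(windows)), windows$window_id)
  n_rej_contig <- 0L; n_rej_excl <- 0L
  if (nrow(frg) > 0) {
    mid <- floor((frg$start + frg$end) / 2)
    known <- frg$contig %in% unique(windows$contig)
    n_rej_contig <- sum(!known)
    frg <- frg[known, , drop = FALSE]; mid <- mid[known]
    # windows tile from 0 contiguously per contig, so index = floor(mid/300)
    idx_in_contig <- floor(mid / WINDOW_WIDTH)
    key <- paste0(frg$contig, ":", idx_in_contig * WINDOW_WIDTH)
    wkey <- paste0(windows$contig, ":", windows$start)
    pos <- match(key, wkey)
    off <- is.na(pos)
    n_rej_contig <- n_rej_contig + sum(off)  # beyond tiled span
    pos <- pos[!off]
    excl <- windows$excluded[pos]
    n_rej_excl <- sum(excl)
    pos <- pos[!excl]
    tab <- tabulate(pos, nbins = nrow(windows))
    counts[] <- tab
  }
  list(counts = counts,
       library_size = sum(counts),
       n_rejected_contig = n_rej_contig,
       n_rejected_excluded = n_rej_excl,
       n_filtered = n_filtered)
}

#' TMM normalization factors against a pooled reference
#'
#' Computes, per sample, the weighted trimmed mean of log2 ratios (M-values)
#' against a reference column, trimming 30% of windows at each M extreme and
#' 5% at each A (average log intensity) extreme, excluding doubly-trimmed
#' windows, with inverse-variance (delta-method binomial) weights. The
#' exponentiated mean is the sample's normalization factor; the reference
#' has factor 1 against itself by construction.
#'
#' @param cm a [count_matrix()].
#' @param reference either a sample id present in `cm`, or a numeric count
#'   vector over the same windows (e.g. a pooled reference), or `NULL` to
#'   pool all columns of `cm`.
#' @param trim_m,trim_a trim fractions for M and A (each side).
#' @return `cm` with `norm_factor` replaced.
#' @export
tmm_normalize <- function(cm, reference = NULL, trim_m = 0.3, trim_a = 0.05) {
  ref <- if (is.null(reference)) {
    rowSums(cm$counts)
  } else if (is.character(reference) && length(reference) == 1L) {
    cm$counts[, reference]
  } else {
    as.numeric(reference)
  }
  if (length(ref) != nrow(cm$counts)) stop("reference length mismatch")
  nf <- vapply(colnames(cm$counts), function(s) {
    tmm_factor(cm$counts[, s], ref, trim_m, trim_a)
  }, numeric(1))
  # no geometric-mean re-centering: factors are anchored to the pooled
  # reference, whose own factor is exactly 1
  cm$norm_factor <- stats::setNames(nf, colnames(cm$counts))
  cm
}

# single-sample TMM factor vs a reference count vector
tmm_factor <- function(obs, ref, trim_m = 0.3, trim_a = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  n_o <- sum(obs); n_r <- sum(ref)
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("sample shares no nonzero windows with the reference; factor set to 1")
    return(1)
  }
  o <- obs[keep] / n_o; r <- ref[keep] / n_r
  m <- log2(o / r)
  a <- 0.5 * log2(o * r)
  if (max(m) - min(m) < 1e-10) return(1)  # identical profiles
  w <- 1 / ((n_o - obs[keep]) / (n_o * obs[keep]) +
              (n_r - ref[keep]) / (n_r * ref[keep]))
  lo_m <- stats::quantile(m, trim_m); hi_m <- stats::quantile(m, 1 - trim_m)
  lo_a <- stats::quantile(a, trim_a); hi_a <- stats::quantile(a, 1 - trim_a)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' Write / read a count matrix as TSV
#' @param cm a [count_matrix()].
#' @param path TSV path (windows x samples; extra columns for library size
#'   and normalization factors are stored as header-comment lines).
#' @export
write_counts_tsv <- function(cm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#library_size\t",
                    paste(colnames(cm$counts), round(cm$library_size, 6),
                          sep = "=", collapse = "\t")), con)
  writeLines(paste0("#norm_factor\t",
                    paste(colnames(cm$counts),
                          format(cm$norm_factor, digits = 15),
                          sep = "=", collapse = "\t")), con)
  df <- data.frame(window_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path, n = 2)
  parse_kv <- function(line) {
    kv <- strsplit(strsplit(line, "\t")[[1]][-1], "=")
    stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                    vapply(kv, `[`, "", 1))
  }
  lib <- parse_kv(lines[1]); nf <- parse_kv(lines[2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$window_id
  count_matrix(m, library_size = lib, norm_factor = nf)
}
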