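#' Genomic window tables
#'
#' A `genome_windows` object is a data.frame of contiguous, non-overlapping
#' 300-bp half-open windows (0-based `start`, exclusive `end`) with a
#' per-window CpG count `cpg_count`, an `excluded` flag (windows that must
#' never receive fragment counts downstream) and a `qc_always_methylated`
#' flag marking the always-methylated quality-control subset.
#'
#' @name genome_windows
NULL

WINDOW_WIDTH <- 300L

new_genome_windows <- function(df) {
  stopifnot(all(c("contig", "start", "end", "cpg_count", "excluded",
                  "qc_always_methylated") %in% names(df)))
  df$window_id <- paste0(df$contig, ":", df$start, "-", df$end)
  rownames(df) <- NULL
  class(df) <- c("genome_windows", "data.frame")
  df
}

#' Tile contigs into 300-bp windows
#'
#' Tiles each contig into non-overlapping 300-bp half-open windows starting
#' at 0; a trailing partial window is dropped. Windows overlapping any
#' exclusion interval are flagged `excluded`.
#'
#' @param contig_lengths named numeric vector of contig lengths (bp).
#' @param exclusion either `NULL`, a path to a BED file, or a data.frame
#'   with columns `contig`, `start`, `end` (0-based half-open).
#' @param cpg_count optional per-window CpG counts (recycled error if the
#'   length does not match); defaults to 0 (annotate later).
#' @return a [genome_windows] data.frame.
#' @export
tile_genome <- function(contig_lengths, exclusion = NULL, cpg_count = NULL) {
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be named")
  if (any(contig_lengths <= 0)) stop("contig lengths must be positive")
  pieces <- lapply(names(contig_lengths), function(ctg) {
    n <- floor(contig_lengths[[ctg]] / WINDOW_WIDTH)
    if (n < 1) return(NULL)
    start <- WINDOW_WIDTH * (seq_len(n) - 1L)
    data.frame(contig = ctg, start = as.integer(start),
               end = as.integer(start + WINDOW_WIDTH),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) stop("no contig long enough to hold a window")
  if (is.null(cpg_count)) cpg_count <- 0L
  if (length(cpg_count) != 1L && length(cpg_count) != nrow(df))
    stop("cpg_count length must be 1 or the number of windows")
  df$cpg_count <- as.integer(cpg_count)
  df$excluded <- FALSE
  df$qc_always_methylated <- FALSE
  if (!is.null(exclusion)) {
    excl <- if (is.character(exclusion)) read_bed(exclusion) else exclusion
    if (nrow(excl) > 0) {
      win_gr <- GenomicRanges::GRanges(
        df$contig, IRanges::IRanges(df$start + 1L, df$end))
      excl_gr <- GenomicRanges::GRanges(
        excl$contig, IRanges::IRanges(excl$start + 1L, excl$end))
      hit <- GenomicRanges::countOverlaps(win_gr, excl_gr) > 0
      df$excluded <- hit
    }
  }
  new_genome_windows(df)
}

#' Read a BED file (3+ columns, 0-based half-open)
#'
#' Minimal strict reader used for exclusion lists and CGI tracks; reports
#' the offending line number on malformed input.
#'
#' @param path BED file path.
#' @return data.frame with `contig`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(data.frame(contig = character(), start = integer(), end = integer()))
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[[i]], "\t| +")[[1]]
    if (length(f) < 3)
      stop("malformed BED at line ", i, ": fewer than 3 fields", call. = FALSE)
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s)
      stop("malformed BED at line ", i, ": bad interval [", f[2], ", ", f[3], ")",
           call. = FALSE)
    list(contig = f[1], start = s, end = e,
         name = if (length(f) >= 4) f[4] else NA_character_)
  })
  data.frame(contig = vapply(rows, `[[`, "", "contig"),
             start = vapply(rows, `[[`, 0L, "start"),
             end = vapply(rows, `[[`, 0L, "end"),
             name = vapply(rows, `[[`, "", "name"),
             stringsAsFactors = FALSE)
}

#' Write windows as BED (4th column = CpG count)
#' @param windows a [genome_windows] table.
#' @param path output path.
#' @export
write_windows_bed <- function(windows, path) {
  utils::write.table(
    data.frame(windows$contig, windows$start, windows$end, windows$cpg_count),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRanges view of windows (1-based closed, as GRanges requires)
windows_granges <- function(windows) {
  GenomicRanges::GRanges(windows$contig,
                         IRanges::IRanges(windows$start + 1L, windows$end))
}
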