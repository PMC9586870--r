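#' Multinomial downsampling of a count column
#'
#' Draws `m` fragments without modelling duplicates: a multinomial
#' subsample with window probabilities proportional to the observed counts.
#'
#' @param column named integer count vector over windows.
#' @param m target total fragment count (`<= sum(column)`).
#' @param seed integer seed.
#' @return named integer vector summing exactly to `m`.
#' @export
downsample_counts <- function(column, m, seed) {
  tot <- sum(column)
  if (m > tot) stop("cannot downsample to ", m, " fragments from ", tot)
  if (m == tot) return(column)
  if (m == 0) return(stats::setNames(integer(length(column)), names(column)))
  with_seed(seed, {
    out <- stats::rmultinom(1, m, prob = column / tot)[, 1]
    stats::setNames(as.integer(out), names(column))
  })
}

#' Mix fragment counts from a tumor source into a background
#'
#' Builds one in-silico spike-in column: `round(p * M)` fragments
#' downsampled from the tumor source plus `M - round(p * M)` from the
#' background. With no tumor source, two backgrounds are mixed the same way
#' (a negative control mixture).
#'
#' @param counts a [count_matrix()] holding the source columns.
#' @param tumor_source tumor sample id, or `NA`/`NULL` for a
#'   background-only mixture.
#' @param background_source background sample id (the second background for
#'   negative mixtures goes in `tumor_source`'s place via
#'   `background_source2`).
#' @param background_source2 second background id for negative mixtures.
#' @param p tumor (or second-background) proportion in `[0, 1]`.
#' @param m total fragments M of the mixture.
#' @param seed integer seed.
#' @return list with `counts` (named integer vector, total `m`) and `truth`
#'   (`tumor_fraction` = `p` for tumor mixtures, 0 otherwise; `label` 1/0).
#' @export
mix_counts <- function(counts, tumor_source, background_source, p, m, seed,
                       background_source2 = NULL) {
  if (p < 0 || p > 1) stop("proportion p must be in [0, 1]")
  if (m <= 0) stop("total fragments M must be positive")
  m_top <- round(p * m)
  m_bg <- m - m_top
  is_tumor <- !(is.null(tumor_source) || is.na(tumor_source))
  top_id <- if (is_tumor) tumor_source else background_source2
  if (is.null(top_id) || is.na(top_id))
    stop("background-only mixtures need 'background_source2'")
  get_col <- function(id) {
    if (!id %in% colnames(counts$counts)) stop("unknown source '", id, "'")
    counts$counts[, id]
  }
  top <- get_col(top_id); bg <- get_col(background_source)
  if (m_top > sum(top))
    stop("insufficient depth in source '", top_id, "' for ", m_top, " fragments")
  if (m_bg > sum(bg))
    stop("insufficient depth in source '", background_source, "' for ",
         m_bg, " fragments")
  col <- downsample_counts(top, m_top, child_seed(seed, "top")) +
    downsample_counts(bg, m_bg, child_seed(seed, "bg"))
  list(counts = stats::setNames(as.integer(col), rownames(counts$counts)),
       truth = list(tumor_fraction = if (is_tumor) p else 0,
                    label = as.integer(is_tumor)))
}

#' Generate a balanced in-silico mixture collection
#'
#' Reproducibly builds `n_positive` tumor-in-background mixtures (tumor
#' proportion uniform over `p_range`) and `n_negative` background-only
#' mixtures (two distinct backgrounds), each at a total fragment count
#' drawn log-uniformly over `m_range`. Tumor sources are cycled so every
#' source is represented. The manifest records every spec, enabling
#' source-aware train/test splits.
#'
#' @param counts a [count_matrix()] holding all source columns.
#' @param tumor_pool,background_pool character vectors of source ids.
#' @param p_range length-2 tumor-proportion range.
#' @param m_range length-2 range of total fragments.
#' @param n_positive,n_negative collection sizes.
#' @param seed integer seed.
#' @return list with `counts` (a [count_matrix()] of mixture columns) and
#'   `manifest` (data.frame: `mixture_id`, `label`, `tumor_source`,
#'   `background_source`, `background_source2`, `p`, `m`).
#' @export
generate_mixture_collection <- function(counts, tumor_pool, background_pool,
                                        p_range = c(0.005, 0.05),
                                        m_range = c(5e4, 2e5),
                                        n_positive = 100, n_negative = 100,
                                        seed = 1) {
  if (n_positive > 0 && length(tumor_pool) == 0) stop("empty tumor pool")
  if (length(background_pool) < 2 && n_negative > 0)
    stop("need at least two background sources for negative mixtures")
  if (length(background_pool) == 0) stop("empty background pool")
  n <- n_positive + n_negative
  if (n == 0)
    return(list(counts = NULL,
                manifest = data.frame(mixture_id = character(),
                                      label = integer(),
                                      tumor_source = character(),
                                      background_source = character(),
                                      background_source2 = character(),
                                      p = numeric(), m = numeric())))
  with_seed(seed, {
    pos_tumor <- if (n_positive > 0)
      rep_len(sample(tumor_pool), n_positive) else character(0)
    pos_bg <- if (n_positive > 0)
      sample(background_pool, n_positive, replace = TRUE) else character(0)
    neg_bg <- if (n_negative > 0)
      sample(background_pool, n_negative, replace = TRUE) else character(0)
    neg_bg2 <- vapply(neg_bg, function(b)
      sample(setdiff(background_pool, b), 1L), "")
    p <- stats::runif(n, p_range[1], p_range[2])
    m <- round(exp(stats::runif(n, log(m_range[1]), log(m_range[2]))))
    manifest <- data.frame(
      mixture_id = sprintf("mix_%04d", seq_len(n)),
      label = rep(c(1L, 0L), c(n_positive, n_negative)),
      tumor_source = c(pos_tumor, rep(NA_character_, n_negative)),
      background_source = c(pos_bg, neg_bg),
      background_source2 = c(rep(NA_character_, n_positive), neg_bg2),
      p = p, m = m, stringsAsFactors = FALSE)
    mix_seeds <- sample.int(.Machine$integer.max - 1L, n)
  })
  cols <- lapply(seq_len(n), function(i) {
    r <- manifest[i, ]
    mx <- mix_counts(counts, r$tumor_source, r$background_source, r$p, r$m,
                     mix_seeds[i], background_source2 = r$background_source2)
    mx$counts
  })
  names(cols) <- manifest$mixture_id
  list(counts = bind_count_columns(cols), manifest = manifest)
}

#' Count-level dilution ladder
#'
#' One mixture per proportion at a fixed total fragment count; feeds
#' limit-of-detection curves.
#'
#' @param counts a [count_matrix()] with the two source columns.
#' @param tumor_source,background_source sample ids.
#' @param proportions increasing tumor proportions.
#' @param m total fragments per rung.
#' @param seed integer seed.
#' @return list with `counts` ([count_matrix()], one column per proportion,
#'   named `dil_<p>`) and `proportions`.
#' @export
dilution_series <- function(counts, tumor_source, background_source,
                            proportions, m, seed = 1) {
  if (is.unsorted(proportions)) stop("proportions must be sorted increasing")
  cols <- lapply(seq_along(proportions), function(i) {
    mix_counts(counts,
               tumor_source = if (proportions[i] > 0) tumor_source else NA,
               background_source = background_source,
               background_source2 = tumor_source,  # unused when p = 0
               p = proportions[i], m = m,
               seed = child_seed(seed, paste0("dil", i)))$counts
  })
  names(cols) <- sprintf("dil_%g", proportions)
  cm <- bind_count_columns(cols)
  list(counts = cm, proportions = proportions)
}
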