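#' Assign an SCLC subtype from marker-gene expression
#'
#' Uses normalized expression of ASCL1, NEUROD1, POU2F3 and YAP1. In
#' `cell_line` context a gene counts as expressed above the threshold
#' (default 9): samples expressing both ASCL1 and NEUROD1 are `excluded`;
#' POU2F3- or YAP1-only samples are `double_negative`; samples expressing
#' none are `unclassified`. In `model` context the label is the argmax
#' among ASCL1/NEUROD1/POU2F3, with ASCL1/NEUROD1 co-expression resolved
#' to NEUROD1.
#'
#' @param expression named numeric vector (or 1-row data.frame/matrix) with
#'   entries `ASCL1`, `NEUROD1`, `POU2F3`, `YAP1`.
#' @param context `"cell_line"` or `"model"`.
#' @param threshold expression threshold for `cell_line` context.
#' @return one of `"ASCL1"`, `"NEUROD1"`, `"double_negative"`,
#'   `"excluded"`, `"unclassified"`.
#' @export
assign_subtype_from_expression <- function(expression,
                                           context = c("cell_line", "model"),
                                           threshold = 9) {
  context <- match.arg(context)
  e <- unlist(expression)[c("ASCL1", "NEUROD1", "POU2F3", "YAP1")]
  if (any(is.na(e))) stop("expression values for all four genes are required")
  if (context == "cell_line") {
    hi <- e >= threshold
    if (hi[["ASCL1"]] && hi[["NEUROD1"]]) return("excluded")
    if (hi[["ASCL1"]]) return("ASCL1")
    if (hi[["NEUROD1"]]) return("NEUROD1")
    if (hi[["POU2F3"]] || hi[["YAP1"]]) return("double_negative")
    return("unclassified")
  }
  # model context: highest of ASCL1/NEUROD1/POU2F3; co-expression -> NEUROD1
  if (e[["NEUROD1"]] >= threshold && e[["ASCL1"]] >= threshold) return("NEUROD1")
  top <- names(which.max(e[c("ASCL1", "NEUROD1", "POU2F3")]))
  if (top == "POU2F3") "double_negative" else top
}

#' Convert an array beta profile to expected capture counts
#'
#' Inverts the calibration lookup: per window, the beta-value is the
#' maximum over its probes; expected nrpm is
#' `bg(d) + beta * (full(d) - bg(d))`, converted to integer counts at the
#' target library size. Windows without probes carry zero counts and are
#' reported in the `covered` mask (they are masked, not imputed,
#' downstream). Probes mapping to excluded windows are dropped and
#' tallied.
#'
#' @param profile data.frame with `probe_id`, `window_id`, `beta`.
#' @param calibration table from [fit_calibration()].
#' @param windows [genome_windows].
#' @param target_library_size library size of the pseudo-sample.
#' @return list: `counts` (named integer vector), `covered` (logical mask
#'   over windows), `beta_window` (max-probe beta, `NA` where uncovered),
#'   `n_dropped_excluded`.
#' @export
array_to_counts <- function(profile, calibration, windows,
                            target_library_size = 2e6) {
  stopifnot(all(c("window_id", "beta") %in% names(profile)))
  excl_ids <- windows$window_id[windows$excluded]
  drop <- profile$window_id %in% excl_ids
  n_drop <- sum(drop)
  pr <- profile[!drop, , drop = FALSE]
  bmax <- tapply(pr$beta, pr$window_id, max)
  beta_w <- stats::setNames(rep(NA_real_, nrow(windows)), windows$window_id)
  beta_w[names(bmax)] <- bmax
  lv <- calibration_levels(calibration, windows)
  nr <- lv$bg + beta_w * (lv$full - lv$bg)
  cnt <- round(nr * target_library_size / 1e6)
  cnt[is.na(cnt)] <- 0
  list(counts = stats::setNames(as.integer(cnt), windows$window_id),
       covered = !is.na(beta_w),
       beta_window = beta_w,
       n_dropped_excluded = n_drop)
}

#' Select subtype classifier windows (50 + 50 per contrast)
#'
#' For one target subtype, takes the significant DMR tables of the target
#' against each other group, ranks each by Delta-beta and keeps the 50 most
#' hypermethylated and 50 most hypomethylated windows per contrast
#' (3 contrasts x 100 = 300 windows), then deduplicates. Contrasts with
#' fewer than 50 significant windows in a direction contribute all they
#' have, with a warning.
#'
#' @param contrast_dmrs named list of significance-filtered `dmr_table`s,
#'   one per opposing group (Delta-beta oriented target minus other).
#' @param n_each windows per direction per contrast.
#' @return character vector of distinct window ids.
#' @export
select_subtype_dmrs <- function(contrast_dmrs, n_each = 50) {
  picked <- character(0)
  for (nm in names(contrast_dmrs)) {
    d <- contrast_dmrs[[nm]]
    hyper <- d$window_id[order(d$delta_beta, decreasing = TRUE)]
    hyper <- hyper[seq_len(min(n_each, sum(d$delta_beta > 0)))]
    hypo <- d$window_id[order(d$delta_beta)]
    hypo <- hypo[seq_len(min(n_each, sum(d$delta_beta < 0)))]
    if (length(hyper) < n_each || length(hypo) < n_each)
      warning("contrast '", nm, "' has fewer than ", n_each,
              " significant windows in a direction; taking all available")
    picked <- c(picked, hyper, hypo)
  }
  unique(picked)
}

#' Train the ASCL1 and NEUROD1 subtype ensembles
#'
#' Two ensembles over the union of the per-target window lists: the
#' NEUROD1 ensemble labels NEUROD1-source mixtures positive against
#' ASCL1 + double-negative mixtures; the ASCL1 ensemble analogously. Each
#' member draws 80% of the NEUROD1 and double-negative sources, an
#' undersampled ASCL1 subset of similar size (class balance, within one
#' source), and 80% of the background sources.
#'
#' @param features mixtures x windows matrix over the union window list.
#' @param manifest mixture manifest with a `subtype` column giving each
#'   tumor source's subtype (`ASCL1`, `NEUROD1`, `DN`); background-only
#'   mixtures have `NA` subtype and are not used here (the negatives of a
#'   subtype ensemble are mixtures of the other subtypes).
#' @param source_subtype named character vector mapping tumor source id to
#'   subtype.
#' @param windows_neurod1,windows_ascl1 per-target window lists (recorded
#'   in the bundle).
#' @param n_members,subsample,seed,nrounds,eta,params as
#'   [train_ensemble()].
#' @return object of class `subtype_model_bundle`: `neurod1_model`,
#'   `ascl1_model`, `subtype_windows` (union), per-target lists, cutoffs
#'   `NA` until [derive_sequential_cutoffs()].
#' @export
train_subtype_ensembles <- function(features, manifest, source_subtype,
                                    windows_neurod1 = NULL,
                                    windows_ascl1 = NULL,
                                    n_members = 100, subsample = 0.8,
                                    seed = 1, nrounds = 500, eta = 0.02,
                                    params = list()) {
  stopifnot(nrow(features) == nrow(manifest))
  manifest$subtype <- unname(source_subtype[manifest$tumor_source])
  tumor_mix <- !is.na(manifest$subtype)
  if (!all(c("ASCL1", "NEUROD1", "DN") %in% manifest$subtype[tumor_mix]))
    stop("mixtures must cover all three subtypes (ASCL1, NEUROD1, DN)")
  bg_src <- unique(stats::na.omit(c(manifest$background_source,
                                    manifest$background_source2)))
  src_by_sub <- split(names(source_subtype), source_subtype)

  train_one <- function(target, seed_label) {
    pos_sub <- target
    members <- list(); member_sources <- list(); member_train_ids <- list()
    with_seed(child_seed(seed, seed_label), {
      for (k in seq_len(n_members)) {
        for (try in 1:10) {
          take <- function(v, f) sample(v, max(1L, round(f * length(v))))
          n1 <- take(src_by_sub$NEUROD1, subsample)
          dn <- take(src_by_sub$DN, subsample)
          basis <- length(n1) + length(dn)
          n_a <- min(length(src_by_sub$ASCL1),
                     max(1L, basis + sample(-1:1, 1L)))
          a1 <- sample(src_by_sub$ASCL1, n_a)
          bs <- take(bg_src, subsample)
          ts <- c(n1, dn, a1)
          idx <- mixture_in_subsets(manifest, ts, bs)
          idx <- idx[!is.na(manifest$subtype[idx])]  # tumor mixtures only
          y <- as.integer(manifest$subtype[idx] == pos_sub)
          if (length(unique(y)) == 2) break
          if (try == 10) stop("could not draw a two-class member subset")
        }
        members[[k]] <- fit_member(features[idx, , drop = FALSE], y,
                                   nrounds, eta, params)
        member_sources[[k]] <- list(tumor = ts, background = bs,
                                    ascl1_undersampled = a1)
        member_train_ids[[k]] <- manifest$mixture_id[idx]
      }
    })
    structure(list(feature_windows = colnames(features),
                   members = members, member_sources = member_sources,
                   member_train_ids = member_train_ids,
                   cutoff = NA_real_,
                   meta = list(target = target, n_members = n_members,
                               subsample = subsample, nrounds = nrounds,
                               eta = eta, seed = seed)),
              class = "ensemble_model")
  }

  structure(list(neurod1_model = train_one("NEUROD1", "neurod1"),
                 ascl1_model = train_one("ASCL1", "ascl1"),
                 subtype_windows = colnames(features),
                 windows_neurod1 = windows_neurod1,
                 windows_ascl1 = windows_ascl1,
                 cutoffs = c(neurod1 = NA_real_, ascl1 = NA_real_)),
            class = "subtype_model_bundle")
}

#' Jointly derive sequential NEUROD1/ASCL1 cutoffs
#'
#' Exhaustive 2-D grid search: at each pair `(c_N, c_A)`, NEUROD1 balanced
#' accuracy is computed on all held-out mixtures at `c_N`, and ASCL1
#' balanced accuracy at `c_A` only on mixtures the NEUROD1 classifier left
#' unclaimed (`score_N < c_N`); the objective is the mean of the two.
#' Cells whose ASCL1-eligible set lacks a class are skipped. Ties break to
#' the lexicographically smallest pair.
#'
#' @param scores_n,scores_a held-out median scores of the two ensembles.
#' @param truth subtype truth per mixture (`ASCL1`, `NEUROD1`, `DN`).
#' @param grid_step grid increment.
#' @return list: `cutoff_neurod1`, `cutoff_ascl1`, `objective`,
#'   `ba_neurod1`, `ba_ascl1` at the optimum.
#' @export
derive_sequential_cutoffs <- function(scores_n, scores_a, truth,
                                      grid_step = 0.01) {
  keep <- !is.na(scores_n) & !is.na(scores_a)
  scores_n <- scores_n[keep]; scores_a <- scores_a[keep]
  truth <- truth[keep]
  y_n <- truth == "NEUROD1"
  y_a <- truth == "ASCL1"
  grid <- seq(0, 1, by = grid_step)
  ba_n <- vapply(grid, function(ct)
    balanced_accuracy(scores_n, as.integer(y_n), ct), numeric(1))
  best <- list(obj = -Inf, cn = NA, ca = NA, ban = NA, baa = NA)
  for (i in seq_along(grid)) {
    elig <- scores_n < grid[i]
    if (!any(y_a[elig]) || !any(!y_a[elig])) next
    sa <- scores_a[elig]; ya <- as.integer(y_a[elig])
    for (j in seq_along(grid)) {
      ba_a <- balanced_accuracy(sa, ya, grid[j])
      obj <- (ba_n[i] + ba_a) / 2
      if (obj > best$obj + 1e-12) {
        best <- list(obj = obj, cn = grid[i], ca = grid[j],
                     ban = ba_n[i], baa = ba_a)
      }
    }
  }
  if (!is.finite(best$obj))
    stop("no cutoff pair admits an ASCL1-eligible two-class set")
  list(cutoff_neurod1 = best$cn, cutoff_ascl1 = best$ca,
       objective = best$obj, ba_neurod1 = best$ban, ba_ascl1 = best$baa)
}

#' Set jointly derived cutoffs on a subtype bundle
#' @param bundle a `subtype_model_bundle`.
#' @param cutoff_neurod1,cutoff_ascl1 thresholds in `[0, 1]`.
#' @export
set_subtype_cutoffs <- function(bundle, cutoff_neurod1, cutoff_ascl1) {
  bundle$cutoffs <- c(neurod1 = cutoff_neurod1, ascl1 = cutoff_ascl1)
  bundle$neurod1_model$cutoff <- cutoff_neurod1
  bundle$ascl1_model$cutoff <- cutoff_ascl1
  bundle
}

#' Sequential subtype call with tumor-fraction gating
#'
#' Samples below the tumor-fraction gate (default 4%) are
#' `not_evaluable`. Otherwise the NEUROD1 classifier decides first
#' (`score_N >= c_N`), then ASCL1 (`score_A >= c_A`), else
#' `double_negative`; the NEUROD1 call never consults the ASCL1 score.
#'
#' @param neurod1_score,ascl1_score median ensemble scores (vectors).
#' @param tumor_fraction per-sample tumor fraction (mandatory).
#' @param cutoffs named vector `c(neurod1 = ..., ascl1 = ...)` or a bundle
#'   with derived cutoffs.
#' @param gate minimum tumor fraction for an evaluable call.
#' @return data.frame: `neurod1_score`, `ascl1_score`, `tumor_fraction`,
#'   `call`.
#' @export
call_subtype <- function(neurod1_score, ascl1_score, tumor_fraction,
                         cutoffs, gate = 0.04) {
  if (inherits(cutoffs, "subtype_model_bundle")) cutoffs <- cutoffs$cutoffs
  if (any(is.na(tumor_fraction)))
    stop("tumor_fraction is required for every sample (gating is mandatory)")
  if (any(is.na(cutoffs))) stop("cutoffs have not been derived")
  call <- ifelse(tumor_fraction < gate, "not_evaluable",
                 ifelse(neurod1_score >= cutoffs[["neurod1"]], "NEUROD1",
                        ifelse(ascl1_score >= cutoffs[["ascl1"]], "ASCL1",
                               "double_negative")))
  data.frame(neurod1_score = neurod1_score, ascl1_score = ascl1_score,
             tumor_fraction = tumor_fraction, call = call,
             stringsAsFactors = FALSE)
}
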