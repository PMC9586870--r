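#' Select tumor-detection windows from two DMR contrasts
#'
#' Intersects the tumor-vs-healthy-tissue and tumor-vs-training-NCC DMR
#' tables (both already filtered at FDR and Delta-beta thresholds), keeping
#' windows whose direction agrees in the two contrasts.
#'
#' @param dmrs_vs_tissue,dmrs_vs_ncc filtered `dmr_table`s.
#' @return character vector of feature window ids.
#' @export
select_detection_windows <- function(dmrs_vs_tissue, dmrs_vs_ncc) {
  common <- intersect(dmrs_vs_tissue$window_id, dmrs_vs_ncc$window_id)
  d1 <- dmrs_vs_tissue$direction[match(common, dmrs_vs_tissue$window_id)]
  d2 <- dmrs_vs_ncc$direction[match(common, dmrs_vs_ncc$window_id)]
  sel <- common[d1 == d2]
  if (length(sel) == 0)
    stop("no direction-consistent windows shared by the two contrasts; ",
         "detector is untrainable")
  sel
}

#' Build a classifier feature matrix from beta-values
#'
#' One row per sample, one column per feature window; missing beta-values
#' are encoded as 0 (a depth-invariant, bounded representation).
#'
#' @param beta window x sample beta matrix.
#' @param feature_windows ordered window ids; all must exist in `beta`.
#' @return samples x windows numeric matrix.
#' @export
build_feature_matrix <- function(beta, feature_windows) {
  missing_w <- setdiff(feature_windows, rownames(beta))
  if (length(missing_w) > 0)
    stop("feature windows absent from beta matrix: ",
         paste(utils::head(missing_w, 3), collapse = ", "),
         if (length(missing_w) > 3) ", ..." else "")
  x <- t(beta[feature_windows, , drop = FALSE])
  x[is.na(x)] <- 0
  x
}

# train one xgboost member; single-threaded and deterministic given data
fit_member <- function(x, y, nrounds, eta, params = list()) {
  dm <- xgboost::xgb.DMatrix(x, label = y)
  pars <- utils::modifyList(
    list(objective = "binary:logistic", eta = eta, nthread = 1),
    params)
  xgboost::xgb.train(params = pars, data = dm, nrounds = nrounds, verbose = 0)
}

#' Train the tumor/healthy ensemble
#'
#' Trains `n_members` gradient-boosted classifiers (500 rounds, learning
#' rate 0.02, other hyperparameters at library defaults). Each member
#' draws 80% of the tumor sources and 80% of the background sources and is
#' trained only on mixtures whose every source lies inside those subsets;
#' a member whose draw yields single-class data is re-drawn (bounded
#' retries).
#'
#' @param features mixtures x windows matrix from [build_feature_matrix()].
#' @param manifest mixture manifest from [generate_mixture_collection()]
#'   (rows aligned with `features`).
#' @param n_members ensemble size.
#' @param subsample fraction of sources per member.
#' @param seed integer seed.
#' @param nrounds,eta boosting rounds and learning rate.
#' @param params named list of extra xgboost parameters.
#' @return object of class `ensemble_model`: `feature_windows`, `members`,
#'   `member_sources` (per member, `tumor` and `background` subsets),
#'   `member_train_ids` (mixture ids seen), `cutoff` (NA until
#'   [derive_cutoff()]), `meta`.
#' @export
train_ensemble <- function(features, manifest, n_members = 100,
                           subsample = 0.8, seed = 1, nrounds = 500,
                           eta = 0.02, params = list()) {
  stopifnot(nrow(features) == nrow(manifest))
  tumor_src <- unique(stats::na.omit(manifest$tumor_source))
  bg_src <- unique(stats::na.omit(c(manifest$background_source,
                                    manifest$background_source2)))
  if (length(tumor_src) < 2 || length(bg_src) < 2)
    stop("need at least 2 sources per class to form 80% subsets")
  members <- vector("list", n_members)
  member_sources <- vector("list", n_members)
  member_train_ids <- vector("list", n_members)
  with_seed(child_seed(seed, "ensemble"), {
    for (k in seq_len(n_members)) {
      for (try in 1:10) {
        ts <- sample(tumor_src, max(1L, round(subsample * length(tumor_src))))
        bs <- sample(bg_src, max(1L, round(subsample * length(bg_src))))
        idx <- mixture_in_subsets(manifest, ts, bs)
        y <- manifest$label[idx]
        if (length(unique(y)) == 2) break
        if (try == 10) stop("could not draw a two-class member subset")
      }
      members[[k]] <- fit_member(features[idx, , drop = FALSE], y,
                                 nrounds, eta, params)
      member_sources[[k]] <- list(tumor = ts, background = bs)
      member_train_ids[[k]] <- manifest$mixture_id[idx]
    }
  })
  structure(list(feature_windows = colnames(features),
                 members = members,
                 member_sources = member_sources,
                 member_train_ids = member_train_ids,
                 cutoff = NA_real_,
                 meta = list(n_members = n_members, subsample = subsample,
                             nrounds = nrounds, eta = eta, seed = seed)),
            class = "ensemble_model")
}

# strict rule: every source of a mixture must lie in the member's subsets
mixture_in_subsets <- function(manifest, tumor_subset, background_subset) {
  ok_t <- is.na(manifest$tumor_source) | manifest$tumor_source %in% tumor_subset
  ok_b <- manifest$background_source %in% background_subset
  ok_b2 <- is.na(manifest$background_source2) |
    manifest$background_source2 %in% background_subset
  which(ok_t & ok_b & ok_b2)
}

member_scores <- function(model, features) {
  if (!identical(colnames(features), model$feature_windows))
    stop("feature columns do not match the model's windows")
  dm <- xgboost::xgb.DMatrix(features)
  vapply(model$members, function(m) stats::predict(m, dm),
         numeric(nrow(features)))
}

#' Median ensemble prediction score
#'
#' Scores samples with every eligible member and reports the median. With
#' `exclude_sources`, members whose training subsets touch any excluded
#' source are left out (leakage-free prediction for samples related to a
#' training source).
#'
#' @param model an [train_ensemble()] model.
#' @param features samples x windows matrix (columns must match the model).
#' @param exclude_sources optional character vector of source ids.
#' @return data.frame: `sample_id`, `median_score`, `hard_call` (when the
#'   model has a cutoff), `n_members_used`.
#' @export
predict_median_score <- function(model, features, exclude_sources = NULL) {
  eligible <- seq_along(model$members)
  if (!is.null(exclude_sources) && length(exclude_sources) > 0) {
    eligible <- which(vapply(model$member_sources, function(s)
      !any(c(s$tumor, s$background) %in% exclude_sources), logical(1)))
    if (length(eligible) == 0)
      stop("no ensemble member avoids all excluded sources")
  }
  sc <- member_scores(model, features)
  sc <- sc[, eligible, drop = FALSE]
  if (nrow(features) == 1) sc <- matrix(sc, nrow = 1)
  med <- apply(sc, 1, stats::median)
  data.frame(sample_id = rownames(features) %||% seq_len(nrow(features)),
             median_score = med,
             hard_call = if (is.na(model$cutoff)) NA else med >= model$cutoff,
             n_members_used = length(eligible),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Out-of-bag median scores over a mixture collection
#'
#' For every mixture, the median prediction over the members that did not
#' see that mixture during training — the held-out scores used to derive
#' the ensemble cutoff.
#'
#' @param model an [train_ensemble()] model.
#' @param features mixtures x windows matrix.
#' @param manifest matching manifest.
#' @return data.frame: `mixture_id`, `label`, `median_score`, `n_members_used`.
#' @export
predict_oob_scores <- function(model, features, manifest) {
  sc <- member_scores(model, features)
  seen <- vapply(model$member_train_ids, function(ids)
    manifest$mixture_id %in% ids, logical(nrow(manifest)))
  if (nrow(manifest) == 1) seen <- matrix(seen, nrow = 1)
  med <- vapply(seq_len(nrow(manifest)), function(i) {
    use <- !seen[i, ]
    if (!any(use)) return(NA_real_)
    stats::median(sc[i, use])
  }, numeric(1))
  data.frame(mixture_id = manifest$mixture_id, label = manifest$label,
             median_score = med,
             n_members_used = rowSums(!seen),
             stringsAsFactors = FALSE)
}

balanced_accuracy <- function(scores, labels, cutoff) {
  call <- scores >= cutoff
  sens <- mean(call[labels == 1])
  spec <- mean(!call[labels == 0])
  (sens + spec) / 2
}

#' Balanced-accuracy-optimal score cutoff
#'
#' Evaluates balanced accuracy (mean of sensitivity and specificity) of
#' `score >= cutoff` over a grid of cutoffs and returns the smallest grid
#' value attaining the maximum.
#'
#' @param scores held-out median scores.
#' @param labels 0/1 truth.
#' @param grid_step grid increment over `[0, 1]`.
#' @return list: `cutoff`, `balanced_accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
derive_cutoff <- function(scores, labels, grid_step = 0.01) {
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2)
    stop("cutoff derivation needs both classes in the held-out set")
  grid <- seq(0, 1, by = grid_step)
  ba <- vapply(grid, function(ct) balanced_accuracy(scores, labels, ct),
               numeric(1))
  i <- which(ba >= max(ba) - 1e-12)[1]  # smallest optimal grid value
  ct <- grid[i]
  call <- scores >= ct
  list(cutoff = ct, balanced_accuracy = ba[i],
       sensitivity = mean(call[labels == 1]),
       specificity = mean(!call[labels == 0]))
}

#' Set the decision cutoff on an ensemble model
#' @param model an `ensemble_model`.
#' @param cutoff score threshold in `[0, 1]`.
#' @export
set_cutoff <- function(model, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  model$cutoff <- cutoff
  model
}

#' Ensemble feature importance
#'
#' Per-window gain importance averaged over the members; windows unused by
#' a member contribute 0 for that member.
#'
#' @param model an `ensemble_model`.
#' @return named numeric vector over `feature_windows`.
#' @export
feature_importance <- function(model) {
  fw <- model$feature_windows
  acc <- stats::setNames(numeric(length(fw)), fw)
  for (m in model$members) {
    imp <- tryCatch(xgboost::xgb.importance(model = m), error = function(e) NULL)
    if (!is.null(imp) && nrow(imp) > 0)
      acc[imp$Feature] <- acc[imp$Feature] + imp$Gain
  }
  acc / length(model$members)
}
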