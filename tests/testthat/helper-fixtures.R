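# Shared fixtures, built once per test run and cached.
#
# The "small" cohort (8,000 windows) feeds the pipeline-level tests:
# calibration, detection ensemble and subtype ensembles are expensive to
# refit, and every test that needs them reads the same frozen objects.

.fixture_env <- new.env(parent = emptyenv())

fixture_config <- function(seed = 5) {
  sim_config(n_windows = 8000, n_dmrs = 150,
             n_subtype_dmrs_per_contrast = 30, n_qc_windows = 100,
             seed = seed)
}

# cohort + normalization + calibration + beta
fixture_cohort <- function() {
  if (!is.null(.fixture_env$coh)) return(as.list(.fixture_env))
  cfg <- fixture_config()
  coh <- simulate_cohort(cfg)
  w <- coh$windows
  ref_counts <- coh$reference_pool$counts
  ref <- count_matrix(matrix(ref_counts, ncol = 1,
                             dimnames = list(rownames(coh$counts$counts), "ref")))
  cm <- tmm_normalize(coh$counts, ref_counts)
  cal <- suppressWarnings(fit_calibration(ref, w))
  beta <- estimate_beta(cm, cal, w)
  samples <- coh$samples
  ncc <- samples$sample_id[samples$type == "ncc"]
  for (nm in c("cfg", "coh", "w", "ref_counts", "cm", "cal", "beta", "samples"))
    assign(nm, get(nm), envir = .fixture_env)
  .fixture_env$tumor_ids <- samples$sample_id[samples$type == "tissue_tumor"]
  .fixture_env$lung_ids <- samples$sample_id[samples$type == "healthy_tissue"]
  .fixture_env$train_ncc <- ncc[1:10]
  .fixture_env$valid_ncc <- ncc[11:20]
  as.list(.fixture_env)
}

# detection pipeline on top of the cohort: DMRs, feature windows, mixture
# collection, 20-member ensemble, OOB cutoff
fixture_detector <- function() {
  fx <- fixture_cohort()
  if (!is.null(.fixture_env$det)) return(.fixture_env$det)
  d1 <- filter_significant(
    call_dmrs(fx$cm, fx$cal, fx$w, fx$tumor_ids, fx$lung_ids, beta = fx$beta),
    fdr = 0.001, min_abs_delta_beta = 0.5)
  d2 <- filter_significant(
    call_dmrs(fx$cm, fx$cal, fx$w, fx$tumor_ids, fx$train_ncc, beta = fx$beta),
    fdr = 0.001, min_abs_delta_beta = 0.5)
  fw <- select_detection_windows(d1, d2)
  mx <- generate_mixture_collection(fx$coh$counts, fx$tumor_ids, fx$train_ncc,
                                    p_range = c(0.005, 0.05),
                                    m_range = c(5e4, 1.5e5),
                                    n_positive = 120, n_negative = 120,
                                    seed = 21)
  mcm <- tmm_normalize(mx$counts, fx$ref_counts)
  X <- build_feature_matrix(estimate_beta(mcm, fx$cal, fx$w), fw)
  mod <- train_ensemble(X, mx$manifest, n_members = 20, seed = 31)
  oob <- predict_oob_scores(mod, X, mx$manifest)
  co <- derive_cutoff(oob$median_score, oob$label)
  mod <- set_cutoff(mod, co$cutoff)
  det <- list(dmr_tissue = d1, dmr_ncc = d2, feature_windows = fw,
              mixtures = mx, X = X, model = mod, oob = oob, cutoff = co)
  .fixture_env$det <- det
  det
}

# subtype pipeline: array pseudo-counts, per-target windows, two 20-member
# ensembles, sequential cutoffs
fixture_subtyper <- function() {
  fx <- fixture_cohort()
  if (!is.null(.fixture_env$sub)) return(.fixture_env$sub)
  prof <- split(fx$coh$arrays$profiles, fx$coh$arrays$profiles$sample_id)
  acols <- lapply(prof, function(p) array_to_counts(p, fx$cal, fx$w)$counts)
  grp <- fx$coh$arrays$groups[names(acols)]
  acm <- tmm_normalize(bind_count_columns(acols), fx$ref_counts)
  by_grp <- split(names(grp), grp)
  sel_target <- function(target) {
    others <- setdiff(names(by_grp), target)
    tabs <- lapply(others, function(o)
      filter_significant(call_dmrs(acm, fx$cal, fx$w, by_grp[[target]],
                                   by_grp[[o]]),
                         fdr = 0.001, min_abs_delta_beta = 0))
    names(tabs) <- others
    suppressWarnings(select_subtype_dmrs(tabs, n_each = 50))
  }
  wins_n <- sel_target("NEUROD1")
  wins_a <- sel_target("ASCL1")
  sw <- union(wins_n, wins_a)
  pool <- bind_count_columns(c(
    acols, stats::setNames(lapply(fx$train_ncc, function(s)
      fx$coh$counts$counts[, s]), fx$train_ncc)))
  mx <- generate_mixture_collection(pool, names(acols), fx$train_ncc,
                                    p_range = c(0.05, 0.40),
                                    m_range = c(5e4, 1.5e5),
                                    n_positive = 150, n_negative = 0,
                                    seed = 55)
  mcm <- tmm_normalize(mx$counts, fx$ref_counts)
  X <- build_feature_matrix(estimate_beta(mcm, fx$cal, fx$w), sw)
  src_sub <- stats::setNames(
    ifelse(grp %in% c("POU2F3", "YAP1"), "DN", grp), names(grp))
  bun <- train_subtype_ensembles(X, mx$manifest, src_sub,
                                 windows_neurod1 = wins_n,
                                 windows_ascl1 = wins_a,
                                 n_members = 20, seed = 66)
  oob_n <- predict_oob_scores(bun$neurod1_model, X, mx$manifest)
  oob_a <- predict_oob_scores(bun$ascl1_model, X, mx$manifest)
  truth_mix <- src_sub[mx$manifest$tumor_source]
  sc <- derive_sequential_cutoffs(oob_n$median_score, oob_a$median_score,
                                  truth_mix)
  bun <- set_subtype_cutoffs(bun, sc$cutoff_neurod1, sc$cutoff_ascl1)
  sub <- list(windows_n = wins_n, windows_a = wins_a, subtype_windows = sw,
              mixtures = mx, X = X, bundle = bun, cutoffs = sc,
              source_subtype = src_sub, array_counts = acols)
  .fixture_env$sub <- sub
  sub
}

# features over given windows for arbitrary count columns
fixture_features <- function(cols, windows_list) {
  fx <- fixture_cohort()
  cmx <- tmm_normalize(bind_count_columns(cols), fx$ref_counts)
  build_feature_matrix(estimate_beta(cmx, fx$cal, fx$w), windows_list)
}

# adjusted Rand index (used for PCA subtype-recovery checks)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
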