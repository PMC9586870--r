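#' Simulate MBD-capture fragment counts for one methylome
#'
#' Forward model of the enrichment assay: window `j` with true methylation
#' `beta_j` and CpG count `d_j` has capture weight
#' `w_j = background_capture + beta_j * g(d_j)` with the saturating density
#' response `g`; counts are negative binomial with mean
#' `library_size * w_j / sum(w)` and dispersion `phi`. Excluded windows
#' receive no counts.
#'
#' @param beta numeric vector of true beta-values over windows.
#' @param windows a [genome_windows] table.
#' @param config a [sim_config()].
#' @param seed integer seed for this draw.
#' @return named integer count vector over window ids.
#' @export
simulate_counts <- function(beta, windows, config, seed) {
  stopifnot(length(beta) == nrow(windows))
  mu <- expected_counts(beta, windows, config)
  with_seed(seed, {
    cnt <- stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    stats::setNames(as.integer(cnt), windows$window_id)
  })
}

#' Expected counts under the capture forward model
#' @inheritParams simulate_counts
#' @return named numeric vector of per-window expected counts (summing to
#'   `library_size`).
#' @export
expected_counts <- function(beta, windows, config) {
  w <- capture_weight(beta, windows$cpg_count, config)
  w[windows$excluded] <- 0
  stats::setNames(config$library_size * w / sum(w), windows$window_id)
}

#' Simulate a cfDNA sample as a tumor/normal mixture
#'
#' Counts are generated from the mixed methylome
#' `beta_mix = tf * beta_tumor + (1 - tf) * beta_normal`.
#'
#' @param tumor_beta,normal_beta true beta vectors.
#' @param tf tumor fraction in `[0, 1]`.
#' @inheritParams simulate_counts
#' @return list with `counts` (named integer vector) and `truth`
#'   (`tumor_fraction`, `beta_mix`).
#' @export
simulate_cfdna_sample <- function(tumor_beta, normal_beta, tf, windows,
                                  config, seed) {
  if (!is.numeric(tf) || length(tf) != 1L || is.na(tf) || tf < 0 || tf > 1)
    stop("tumor fraction 'tf' must be in [0, 1]")
  beta_mix <- tf * tumor_beta + (1 - tf) * normal_beta
  list(counts = simulate_counts(beta_mix, windows, config, seed),
       truth = list(tumor_fraction = tf, beta_mix = beta_mix))
}

#' Design a synthetic methylation array
#'
#' Chooses the covered window subset (`array_coverage` of non-excluded
#' windows) and the per-window probe count from the configured
#' distribution; shared by every array profile of a cohort.
#'
#' @param windows a [genome_windows] table.
#' @param config a [sim_config()].
#' @return data.frame with `probe_id` and `window_id`.
#' @export
design_array <- function(windows, config) {
  with_seed(child_seed(config$seed, "array_design"), {
    cand <- which(!windows$excluded)
    k <- round(length(cand) * config$array_coverage)
    covered <- sort(sample(cand, k))
    npr <- as.integer(names(config$probes_per_window))
    counts <- sample(npr, length(covered), replace = TRUE,
                     prob = config$probes_per_window)
    wid <- rep(windows$window_id[covered], counts)
    data.frame(probe_id = paste0("probe_", seq_along(wid)),
               window_id = wid, stringsAsFactors = FALSE)
  })
}

#' Simulate an array beta profile of a methylome
#'
#' Probe beta = window true beta plus Gaussian noise truncated to `[0, 1]`.
#'
#' @param beta true beta vector over windows (named by window id, or in
#'   window order).
#' @param windows a [genome_windows] table.
#' @param config a [sim_config()].
#' @param seed seed for the noise draw.
#' @param design optional probe design from [design_array()]; derived from
#'   the config when omitted.
#' @return data.frame with `probe_id`, `window_id`, `beta`.
#' @export
simulate_array <- function(beta, windows, config, seed,
                           design = design_array(windows, config)) {
  names(beta) <- windows$window_id
  b0 <- beta[design$window_id]
  with_seed(seed, {
    b <- b0 + stats::rnorm(length(b0), 0, config$array_noise_sd)
    data.frame(probe_id = design$probe_id, window_id = design$window_id,
               beta = pmin(1, pmax(0, b)), stringsAsFactors = FALSE)
  })
}

#' Simulate subtype marker gene expression
#'
#' Normalized expression of ASCL1/NEUROD1/POU2F3/YAP1 per sample: the
#' sample's driver gene is high (around 12), the rest low (around 3), on
#' the scale where 9 is the subtype-call threshold.
#'
#' @param groups character vector of expression groups per sample, from
#'   `ASCL1`, `NEUROD1`, `POU2F3`, `YAP1`.
#' @param seed seed.
#' @return samples x 4 numeric matrix.
#' @export
simulate_expression <- function(groups, seed) {
  genes <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1")
  with_seed(seed, {
    m <- matrix(stats::rnorm(length(groups) * 4, 3, 0.8),
                length(groups), 4, dimnames = list(names(groups), genes))
    for (i in seq_along(groups))
      m[i, groups[[i]]] <- stats::rnorm(1, 12, 0.8)
    m
  })
}

#' Simulate overall survival outcomes
#'
#' Exponential event times with log hazard linear in the burden covariate
#' (the cohort-standardized tumor fraction) with coefficient
#' `surv_log_hr`; independent exponential censoring tuned to the configured
#' censoring probability; age, sex and stage covariates attached.
#'
#' @param samples data.frame with a `tumor_fraction` column.
#' @param config a [sim_config()].
#' @param seed seed.
#' @param base_median_os baseline median OS (months) at average burden.
#' @return `samples` with `burden`, `os_months`, `event`, `age`, `sex`,
#'   `stage` columns added.
#' @export
simulate_survival <- function(samples, config, seed, base_median_os = 12) {
  tf <- samples$tumor_fraction
  if (any(is.na(tf))) stop("all samples need a tumor fraction for survival simulation")
  s <- stats::sd(tf)
  burden <- if (is.na(s) || s == 0) rep(0, length(tf)) else (tf - mean(tf)) / s
  lambda0 <- log(2) / base_median_os
  with_seed(seed, {
    rate <- lambda0 * exp(config$surv_log_hr * burden)
    t_ev <- stats::rexp(length(rate), rate)
    if (config$censor_rate > 0) {
      rate_c <- lambda0 * config$censor_rate / (1 - config$censor_rate)
      t_cn <- stats::rexp(length(rate), rate_c)
    } else {
      t_cn <- rep(Inf, length(rate))
    }
    samples$burden <- burden
    samples$os_months <- pmin(t_ev, t_cn)
    samples$event <- as.integer(t_ev <= t_cn)
    samples$age <- round(stats::rnorm(length(rate), 67, 8))
    samples$sex <- sample(c("F", "M"), length(rate), replace = TRUE)
    samples$stage <- sample(c("LS", "ES"), length(rate), replace = TRUE,
                            prob = c(0.37, 0.63))
    samples
  })
}

#' Simulate a complete synthetic cohort
#'
#' Bundles everything downstream stages consume: tiled windows with CpG
#' structure, ground-truth methylomes, tissue-like tumor samples (purity
#' 1), healthy tissue, NCC cfDNA, SCLC cfDNA mixtures at known tumor
#' fractions with subtype labels and survival outcomes, cell-line array
#' profiles with matching expression, and a pooled NCC reference for
#' calibration. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_cohort`; see Details.
#' @details The returned list holds `windows`, `methylomes`, `counts` (a
#'   [count_matrix()]), `samples` (metadata table), `arrays` (probe design
#'   plus per-cell-line profiles), `expression` (samples x genes),
#'   `reference_pool` (pooled NCC count vector and the ids pooled) and the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  windows <- simulate_genome(config)
  meth <- simulate_methylomes(windows, config)
  B <- meth$beta

  samp <- list(); cols <- list()
  add_sample <- function(id, type, class_label, subtype, tf, batch, beta_vec) {
    cols[[id]] <<- simulate_counts(beta_vec, windows, config,
                                   child_seed(config$seed, paste0("counts_", id)))
    samp[[id]] <<- data.frame(sample_id = id, type = type,
                              class_label = class_label,
                              subtype_truth = subtype,
                              tumor_fraction = tf, batch = batch,
                              stringsAsFactors = FALSE)
  }

  nts <- config$n_tissue_per_subtype
  for (s in names(nts)) for (i in seq_len(nts[[s]]))
    add_sample(sprintf("CDX_%s_%d", s, i), "tissue_tumor",
               paste0("tumor_", s), s, 1,
               batch = c("b1", "b2")[1 + i %% 2], B[, paste0("tumor_", s)])
  for (i in seq_len(config$n_healthy_tissue))
    add_sample(sprintf("LUNG_%d", i), "healthy_tissue", "normal", NA, 0,
               "b1", B[, "normal"])
  for (i in seq_len(config$n_ncc))
    add_sample(sprintf("NCC_%d", i), "ncc", "normal", NA, 0,
               c("b1", "b2")[1 + i %% 2], B[, "normal"])

  sub_pool <- c("ASCL1", "NEUROD1", "DN")
  sub_prob <- c(0.60, 0.25, 0.15)
  with_seed(child_seed(config$seed, "sclc_design"), {
    subs <- sample(sub_pool, config$n_sclc_cfdna, replace = TRUE, prob = sub_prob)
    tfs <- stats::runif(config$n_sclc_cfdna, config$sclc_tf_range[1],
                        config$sclc_tf_range[2])
  })
  for (i in seq_len(config$n_sclc_cfdna)) {
    bmix <- tfs[i] * B[, paste0("tumor_", subs[i])] + (1 - tfs[i]) * B[, "normal"]
    add_sample(sprintf("SCLC_%d", i), "sclc_cfdna",
               paste0("tumor_", subs[i]), subs[i], tfs[i],
               c("b1", "b2")[1 + i %% 2], bmix)
  }

  counts <- bind_count_columns(cols)
  samples <- do.call(rbind, samp)
  rownames(samples) <- NULL

  is_sclc <- samples$type == "sclc_cfdna"
  if (any(is_sclc)) {
    surv <- simulate_survival(samples[is_sclc, , drop = FALSE], config,
                              child_seed(config$seed, "survival"))
    for (cl in setdiff(names(surv), names(samples))) {
      samples[[cl]] <- NA
      samples[[cl]][is_sclc] <- surv[[cl]]
    }
  }

  # cell-line array profiles; POU2F3/YAP1 groups share the DN methylome
  design <- design_array(windows, config)
  ncl <- config$n_cell_lines
  cl_groups <- unlist(lapply(names(ncl), function(g) {
    stats::setNames(rep(g, ncl[[g]]), sprintf("CL_%s_%d", g, seq_len(ncl[[g]])))
  }))
  meth_of_group <- c(ASCL1 = "tumor_ASCL1", NEUROD1 = "tumor_NEUROD1",
                     POU2F3 = "tumor_DN", YAP1 = "tumor_DN")
  profiles <- lapply(names(cl_groups), function(id) {
    pr <- simulate_array(B[, meth_of_group[[cl_groups[[id]]]]], windows, config,
                         child_seed(config$seed, paste0("array_", id)), design)
    pr$sample_id <- id
    pr
  })
  arrays <- list(design = design, profiles = do.call(rbind, profiles),
                 groups = cl_groups)

  expression <- simulate_expression(cl_groups,
                                    child_seed(config$seed, "expression"))

  ref_ids <- samples$sample_id[samples$type == "ncc"]
  ref_ids <- ref_ids[seq_len(min(8L, length(ref_ids)))]
  reference_pool <- list(sample_ids = ref_ids,
                         counts = rowSums(counts$counts[, ref_ids, drop = FALSE]))

  structure(list(windows = windows, methylomes = meth, counts = counts,
                 samples = samples, arrays = arrays, expression = expression,
                 reference_pool = reference_pool, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$windows), "windows,", nrow(x$samples),
      "sequenced samples,", length(x$arrays$groups), "array cell lines\n")
  print(table(x$samples$type))
  invisible(x)
}

#' Write / read a cohort as plain-text files
#'
#' Writes windows (BED, 4th column CpG count), counts, sample metadata,
#' array profiles, expression and truth tables (TSV) into a directory.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_windows_bed(cohort$windows, p("windows.bed"))
  utils::write.table(as.data.frame(cohort$windows), p("windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_tsv(cohort$counts, p("counts.tsv"))
  utils::write.table(cohort$samples, p("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$arrays$profiles, p("arrays.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cohort$expression),
                                cohort$expression),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- data.frame(window_id = rownames(cohort$methylomes$beta),
                      cohort$methylomes$beta, check.names = FALSE)
  utils::write.table(truth, p("truth_beta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$methylomes$dmr, p("truth_dmr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir directory written by [write_cohort()].
#' @return for `read_cohort`, a list with `windows`, `counts`, `samples`,
#'   `arrays`, `expression`, `truth_beta`, `truth_dmr`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  windows <- utils::read.table(p("windows.tsv"), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  class(windows) <- c("genome_windows", "data.frame")
  expr <- utils::read.table(p("expression.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  em <- as.matrix(expr[, -1]); rownames(em) <- expr$sample_id
  tb <- utils::read.table(p("truth_beta.tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  bm <- as.matrix(tb[, -1]); rownames(bm) <- tb$window_id
  list(windows = windows,
       counts = read_counts_tsv(p("counts.tsv")),
       samples = utils::read.table(p("samples.tsv"), sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE),
       arrays = utils::read.table(p("arrays.tsv"), sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE),
       expression = em,
       truth_beta = bm,
       truth_dmr = utils::read.table(p("truth_dmr.tsv"), sep = "\t",
                                     header = TRUE, stringsAsFactors = FALSE))
}
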