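#' Simulation configuration for synthetic MBD-capture cohorts
#'
#' Collects every knob of the synthetic-cohort generator: genome layout
#' (number of 300-bp windows, CpG-island fraction and CpG rates), the
#' differential-methylation structure (number of pan-tumor DMRs, fraction
#' hypermethylated in tumor, subtype marker blocks), the capture forward
#' model (library size, negative-binomial dispersion, saturating
#' CpG-density response), methylation-array noise, and survival-model
#' parameters.
#'
#' The capture forward model gives window `j` an unnormalized capture
#' weight `w_j = background_capture + beta_j * g(d_j)` with
#' `g(d) = d^a / (k^a + d^a)` (monotone and saturating in the window CpG
#' count `d`); fragment counts are negative binomial with mean
#' `library_size * w_j / sum(w)` and dispersion `phi`
#' (`Var = mu + phi * mu^2`).
#'
#' @param n_windows number of 300-bp windows on the synthetic contig.
#' @param cgi_fraction proportion of windows belonging to CpG-island-like
#'   blocks.
#' @param cpg_rate_cgi,cpg_rate_bg Poisson means of CpG counts per window for
#'   the CGI-like and background components.
#' @param n_dmrs number of pan-tumor DMR windows shared by all tumor
#'   subtypes.
#' @param frac_hyper fraction of pan-tumor DMRs hypermethylated in tumor.
#' @param frac_dmr_cgi_context target fraction of pan-tumor DMRs lying in
#'   CGI/shore/shelf context.
#' @param n_subtype_dmrs_per_contrast windows per subtype-specific marker
#'   block (one block per tumor subtype).
#' @param dmr_delta minimum absolute true beta difference spiked at DMR and
#'   subtype-marker windows.
#' @param library_size expected total fragment count per sample.
#' @param dispersion negative-binomial dispersion `phi` (> 0).
#' @param capture_saturation length-2 numeric `c(a, k)` of the density
#'   response `g(d) = d^a/(k^a + d^a)`.
#' @param background_capture nonnegative methylation-independent capture
#'   level.
#' @param array_noise_sd standard deviation of truncated Gaussian noise on
#'   array probe beta-values.
#' @param probes_per_window named numeric vector of probabilities over probe
#'   counts per covered window (names "1","2",... must sum to 1).
#' @param array_coverage fraction of windows carrying at least one probe.
#' @param n_qc_windows number of always-methylated QC windows (beta 1 in all
#'   classes), drawn from dense background windows.
#' @param surv_log_hr log hazard ratio per unit of scaled tumor fraction.
#' @param censor_rate independent censoring probability in `[0, 1]`.
#' @param n_tissue_per_subtype named integer vector, tissue-like tumor
#'   samples per subtype (`ASCL1`, `NEUROD1`, `DN`).
#' @param n_healthy_tissue number of healthy-tissue samples.
#' @param n_ncc number of non-cancer control cfDNA samples.
#' @param n_sclc_cfdna number of SCLC cfDNA samples.
#' @param sclc_tf_range tumor-fraction range for SCLC cfDNA samples.
#' @param n_cell_lines named integer vector of array cell lines per
#'   expression group (`ASCL1`, `NEUROD1`, `POU2F3`, `YAP1`).
#' @param seed integer seed; the same config and seed give a bit-identical
#'   cohort.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_windows = 20000L,
                       cgi_fraction = 0.15,
                       cpg_rate_cgi = 18,
                       cpg_rate_bg = 1.0,
                       n_dmrs = 300L,
                       frac_hyper = 0.69,
                       frac_dmr_cgi_context = 0.75,
                       n_subtype_dmrs_per_contrast = 60L,
                       dmr_delta = 0.6,
                       library_size = 2e5,
                       dispersion = 0.005,
                       capture_saturation = c(a = 2, k = 7),
                       background_capture = 0.02,
                       array_noise_sd = 0.03,
                       probes_per_window = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                       array_coverage = 0.6,
                       n_qc_windows = 200L,
                       surv_log_hr = log(3.6),
                       censor_rate = 0.3,
                       n_tissue_per_subtype = c(ASCL1 = 6L, NEUROD1 = 4L, DN = 2L),
                       n_healthy_tissue = 4L,
                       n_ncc = 20L,
                       n_sclc_cfdna = 16L,
                       sclc_tf_range = c(0.01, 0.40),
                       n_cell_lines = c(ASCL1 = 12L, NEUROD1 = 6L, POU2F3 = 3L, YAP1 = 4L),
                       seed = 1L) {
  cfg <- list(
    n_windows = as.integer(n_windows), cgi_fraction = cgi_fraction,
    cpg_rate_cgi = cpg_rate_cgi, cpg_rate_bg = cpg_rate_bg,
    n_dmrs = as.integer(n_dmrs), frac_hyper = frac_hyper,
    frac_dmr_cgi_context = frac_dmr_cgi_context,
    n_subtype_dmrs_per_contrast = as.integer(n_subtype_dmrs_per_contrast),
    dmr_delta = dmr_delta,
    library_size = library_size, dispersion = dispersion,
    capture_saturation = capture_saturation,
    background_capture = background_capture,
    array_noise_sd = array_noise_sd,
    probes_per_window = probes_per_window,
    array_coverage = array_coverage,
    n_qc_windows = as.integer(n_qc_windows),
    surv_log_hr = surv_log_hr, censor_rate = censor_rate,
    n_tissue_per_subtype = n_tissue_per_subtype,
    n_healthy_tissue = as.integer(n_healthy_tissue),
    n_ncc = as.integer(n_ncc), n_sclc_cfdna = as.integer(n_sclc_cfdna),
    sclc_tf_range = sclc_tf_range,
    n_cell_lines = n_cell_lines,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("sim_config: '", nm, "' must be a proportion in [0, 1]", call. = FALSE)
  }
  chk_pos <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || (strict && x <= 0) ||
        (!strict && x < 0))
      stop("sim_config: '", nm, "' must be ", if (strict) "positive" else "nonnegative",
           call. = FALSE)
  }
  chk_prop(cfg$cgi_fraction, "cgi_fraction")
  chk_prop(cfg$frac_hyper, "frac_hyper")
  chk_prop(cfg$frac_dmr_cgi_context, "frac_dmr_cgi_context")
  chk_prop(cfg$censor_rate, "censor_rate")
  chk_prop(cfg$array_coverage, "array_coverage")
  chk_pos(cfg$n_windows, "n_windows")
  chk_pos(cfg$cpg_rate_cgi, "cpg_rate_cgi", strict = FALSE)
  chk_pos(cfg$cpg_rate_bg, "cpg_rate_bg", strict = FALSE)
  chk_pos(cfg$library_size, "library_size")
  chk_pos(cfg$dispersion, "dispersion")
  chk_pos(cfg$background_capture, "background_capture", strict = FALSE)
  chk_pos(cfg$array_noise_sd, "array_noise_sd", strict = FALSE)
  if (cfg$n_dmrs < 0) stop("sim_config: 'n_dmrs' must be nonnegative", call. = FALSE)
  if (length(cfg$capture_saturation) != 2L || any(cfg$capture_saturation <= 0))
    stop("sim_config: 'capture_saturation' must be two positive numbers (a, k)",
         call. = FALSE)
  if (abs(sum(cfg$probes_per_window) - 1) > 1e-8 || any(cfg$probes_per_window < 0))
    stop("sim_config: 'probes_per_window' must be nonnegative probabilities summing to 1",
         call. = FALSE)
  if (length(cfg$sclc_tf_range) != 2L || any(cfg$sclc_tf_range < 0) ||
      any(cfg$sclc_tf_range > 1) || cfg$sclc_tf_range[1] > cfg$sclc_tf_range[2])
    stop("sim_config: 'sclc_tf_range' must be an increasing range inside [0, 1]",
         call. = FALSE)
  if (!is.numeric(cfg$surv_log_hr) || length(cfg$surv_log_hr) != 1L)
    stop("sim_config: 'surv_log_hr' must be a single number", call. = FALSE)
  invisible(cfg)
}

# saturating CpG-density capture response g(d) = d^a / (k^a + d^a)
density_response <- function(d, saturation) {
  a <- saturation[[1]]; k <- saturation[[2]]
  da <- d^a
  ifelse(d <= 0, 0, da / (k^a + da))
}

# unnormalized capture weight of a window given true beta
capture_weight <- function(beta, d, config) {
  config$background_capture + beta * density_response(d, config$capture_saturation)
}

# Deterministic child seed derived from a base seed and a label; keeps every
# simulation step independently reproducible. Stays below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
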