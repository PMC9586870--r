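test_that("config validation names the offending field", {
  expect_error(sim_config(cgi_fraction = 1.4), "cgi_fraction")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(frac_hyper = -0.1), "frac_hyper")
  expect_error(sim_config(capture_saturation = c(1, -2)), "capture_saturation")
  expect_error(sim_config(probes_per_window = c("1" = 0.5)), "probes_per_window")
  expect_error(simulate_genome(sim_config(n_windows = 50)), "n_windows")
})

test_that("simulated genome is deterministic and respects the CGI mixture", {
  cfg <- sim_config(n_windows = 2000, n_qc_windows = 40, seed = 9)
  w1 <- simulate_genome(cfg)
  w2 <- simulate_genome(cfg)
  expect_identical(w1, w2)
  expect_true(all(w1$end - w1$start == 300L))
  expect_true(all(diff(w1$start) == 300L))
  # degenerate mixture: no CGI component at all
  w0 <- simulate_genome(sim_config(n_windows = 500, cgi_fraction = 0,
                                   n_qc_windows = 10, seed = 2))
  expect_true(all(!w0$cgi))
  expect_lt(mean(w0$cpg_count), 3)  # background Poisson rate only
})

test_that("CpG-count tail fraction matches the exact mixture tail", {
  cfg <- sim_config(n_windows = 10000, cgi_fraction = 0.1, cpg_rate_cgi = 18,
                    cpg_rate_bg = 1, n_qc_windows = 20, seed = 4)
  w <- simulate_genome(cfg)
  # exact two-component tail P(d >= 10), computed independently
  p_tail <- 0.1 * sum(dpois(10:200, 18)) + 0.9 * sum(dpois(10:200, 1))
  obs <- mean(w$cpg_count >= 10)
  se <- sqrt(p_tail * (1 - p_tail) / 10000)
  expect_lt(abs(obs - p_tail), 4 * se + 0.01)
})

test_that("pan-tumor DMR split honours the hypermethylated fraction", {
  cfg <- sim_config(n_windows = 4000, n_dmrs = 100, frac_hyper = 0.69,
                    n_subtype_dmrs_per_contrast = 10, n_qc_windows = 40,
                    seed = 8)
  w <- simulate_genome(cfg)
  meth <- simulate_methylomes(w, cfg)
  expect_equal(sum(meth$dmr$direction == 1), 69)
  expect_equal(sum(meth$dmr$direction == -1), 31)
  # direction matches the actual beta change
  expect_true(all(sign(meth$dmr$delta_beta_true) == meth$dmr$direction))
})

test_that("without pan-tumor DMRs tumor and normal differ only at subtype blocks", {
  cfg <- sim_config(n_windows = 2000, n_dmrs = 0,
                    n_subtype_dmrs_per_contrast = 15, n_qc_windows = 30,
                    seed = 3)
  w <- simulate_genome(cfg)
  meth <- simulate_methylomes(w, cfg)
  diff_w <- w$window_id[meth$beta[, "tumor_ASCL1"] != meth$beta[, "normal"]]
  expect_setequal(diff_w, meth$subtype_markers$ASCL1)
})

test_that("subtype marker effects meet the configured size and placement is exact", {
  cfg <- fixture_config()
  fx <- fixture_cohort()
  meth <- fx$coh$methylomes
  for (s in c("ASCL1", "NEUROD1", "DN")) {
    idx <- match(meth$subtype_markers[[s]], rownames(meth$beta))
    own <- meth$beta[idx, paste0("tumor_", s)]
    other <- setdiff(c("tumor_ASCL1", "tumor_NEUROD1", "tumor_DN"),
                     paste0("tumor_", s))
    for (o in other)
      expect_true(all(own - meth$beta[idx, o] >= cfg$dmr_delta))
  }
  # effect placement: classes differ exactly on dmr mask + subtype blocks
  spiked <- sort(unique(c(meth$dmr$window_id, unlist(meth$subtype_markers))))
  changed <- rownames(meth$beta)[apply(meth$beta, 1, function(r) any(r != r[1]))]
  expect_setequal(changed, spiked)
})

test_that("capture forward model has the closed-form mean structure", {
  cfg <- sim_config(n_windows = 300, n_dmrs = 0,
                    n_subtype_dmrs_per_contrast = 2, n_qc_windows = 5,
                    seed = 6)
  w <- simulate_genome(cfg)
  # all-zero methylome: expectation proportional to background capture only
  mu0 <- expected_counts(rep(0, nrow(w)), w, cfg)
  expect_equal(unname(mu0), rep(cfg$library_size / nrow(w), nrow(w)))
  expect_equal(sum(mu0), cfg$library_size)
  # two windows with equal density, beta 1 vs 0: ratio (bg + g(d)) / bg
  d <- w$cpg_count
  dup_d <- as.integer(names(which(table(d[d > 0]) >= 2))[1])
  same_d <- which(d == dup_d)[1:2]
  beta <- rep(0, nrow(w)); beta[same_d[1]] <- 1
  mu <- expected_counts(beta, w, cfg)
  g <- dup_d^2 / (7^2 + dup_d^2)
  expect_equal(unname(mu[same_d[1]] / mu[same_d[2]]),
               (cfg$background_capture + g) / cfg$background_capture,
               tolerance = 1e-10)
})

test_that("Monte-Carlo count means match the model mean within 3 s.e.", {
  cfg <- sim_config(n_windows = 200, n_dmrs = 10,
                    n_subtype_dmrs_per_contrast = 2, n_qc_windows = 5,
                    library_size = 2e4, seed = 12)
  w <- simulate_genome(cfg)
  meth <- simulate_methylomes(w, cfg)
  b <- meth$beta[, "tumor_ASCL1"]
  mu <- expected_counts(b, w, cfg)
  reps <- vapply(1:200, function(r) simulate_counts(b, w, cfg, 400 + r),
                 numeric(nrow(w)))
  emp <- rowMeans(reps)
  sd_mean <- sqrt((mu + cfg$dispersion * mu^2) / 200)
  expect_gt(mean(abs(emp - mu) <= 3 * sd_mean), 0.98)
  # conservation: realized totals within 4 s.d. of the NB sum
  tot_sd <- sqrt(sum(mu + cfg$dispersion * mu^2))
  expect_true(all(abs(colSums(reps) - cfg$library_size) < 4 * tot_sd + 1))
})

test_that("cfDNA mixtures are exact convex combinations and validate tf", {
  fx <- fixture_cohort()
  B <- fx$coh$methylomes$beta
  s <- simulate_cfdna_sample(B[, "tumor_DN"], B[, "normal"], 0.5, fx$w,
                             fx$cfg, 77)
  expect_equal(s$truth$beta_mix,
               0.5 * B[, "tumor_DN"] + 0.5 * B[, "normal"])
  hyper <- fx$coh$methylomes$dmr$window_id[fx$coh$methylomes$dmr$direction == 1][1]
  expect_equal(unname(s$truth$beta_mix[hyper]),
               unname(0.5 * B[hyper, "tumor_DN"] + 0.5 * B[hyper, "normal"]))
  expect_error(simulate_cfdna_sample(B[, "tumor_DN"], B[, "normal"], 1.2,
                                     fx$w, fx$cfg, 1), "\\[0, 1\\]")
  # boundary fractions reduce to the pure classes (same seed, same draw)
  s0 <- simulate_cfdna_sample(B[, "tumor_DN"], B[, "normal"], 0, fx$w, fx$cfg, 5)
  expect_identical(s0$counts, simulate_counts(B[, "normal"], fx$w, fx$cfg, 5))
  s1 <- simulate_cfdna_sample(B[, "tumor_DN"], B[, "normal"], 1, fx$w, fx$cfg, 5)
  expect_identical(s1$counts, simulate_counts(B[, "tumor_DN"], fx$w, fx$cfg, 5))
})

test_that("array profiles carry per-probe noise with the expected magnitude", {
  cfg <- sim_config(n_windows = 2000, n_qc_windows = 20, array_noise_sd = 0,
                    seed = 10)
  w <- simulate_genome(cfg)
  beta <- rep(0.5, nrow(w))
  pr <- simulate_array(beta, w, cfg, 3)
  expect_true(all(pr$beta == 0.5))  # zero noise: probe beta equals truth
  # windows drawn with 3 probes get 3 rows
  tab <- table(pr$window_id)
  expect_true(any(tab == 3))
  expect_equal(sum(tab == 3) / length(tab),
               unname(cfg$probes_per_window["3"]), tolerance = 0.15)
  # folded-normal mean |error| at interior beta
  cfg2 <- sim_config(n_windows = 2000, n_qc_windows = 20,
                     array_noise_sd = 0.03, seed = 10)
  pr2 <- simulate_array(beta, w, cfg2, 3)
  expect_equal(mean(abs(pr2$beta - 0.5)), 0.03 * sqrt(2 / pi),
               tolerance = 0.05)
})

test_that("survival generator honours censoring and hazard settings", {
  st <- data.frame(sample_id = sprintf("s%d", 1:300),
                   tumor_fraction = runif(300, 0.01, 0.4))
  cfg0 <- sim_config(censor_rate = 0, surv_log_hr = 0, seed = 1)
  s0 <- simulate_survival(st, cfg0, 11)
  expect_true(all(s0$event == 1))  # no censoring: every event observed
  # zero log-HR: event times independent of tumor fraction
  expect_gt(cor.test(s0$tumor_fraction, s0$os_months)$p.value, 0.01)
  cfg1 <- sim_config(censor_rate = 0.4, seed = 1)
  s1 <- simulate_survival(st, cfg1, 11)
  expect_lt(abs(mean(s1$event == 0) - 0.4), 0.12)
})

test_that("Cox regression recovers the simulated log hazard ratio", {
  # parameter-recovery oracle: survival package fit on the generator's own
  # burden covariate, CI coverage near nominal
  cfg <- sim_config(surv_log_hr = log(3.6), censor_rate = 0.3, seed = 1)
  cover <- vapply(1:50, function(r) {
    st <- data.frame(sample_id = sprintf("s%d", 1:300),
                     tumor_fraction = runif(300, 0.01, 0.4))
    sv <- simulate_survival(st, cfg, 3000 + r)
    fit <- survival::coxph(survival::Surv(os_months, event) ~ burden, sv)
    ci <- confint(fit)
    ci[1] <= log(3.6) && log(3.6) <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("cohorts are seed-deterministic and survive a disk round trip", {
  cfg <- sim_config(n_windows = 600, n_dmrs = 20,
                    n_subtype_dmrs_per_contrast = 5, n_qc_windows = 10,
                    n_ncc = 6, n_sclc_cfdna = 4,
                    n_tissue_per_subtype = c(ASCL1 = 2L, NEUROD1 = 2L, DN = 2L),
                    n_cell_lines = c(ASCL1 = 3L, NEUROD1 = 2L, POU2F3 = 2L,
                                     YAP1 = 2L),
                    seed = 19)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_true(all(c1$samples$tumor_fraction >= 0 &
                    c1$samples$tumor_fraction <= 1))
  expect_setequal(colnames(c1$counts$counts), c1$samples$sample_id)
  dir <- withr::local_tempdir()
  write_cohort(c1, dir)
  rt <- read_cohort(dir)
  expect_equal(rt$counts$counts, c1$counts$counts)
  expect_equal(rt$counts$library_size, c1$counts$library_size)
  expect_equal(rt$truth_beta, c1$methylomes$beta)
  expect_equal(rt$expression, c1$expression)
  expect_equal(rt$samples$sample_id, c1$samples$sample_id)
  expect_equal(rt$windows$cpg_count, c1$windows$cpg_count)
})
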