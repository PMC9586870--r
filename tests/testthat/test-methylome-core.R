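test_that("genome tiling drops partial windows and flags exclusions", {
  w <- tile_genome(c(chrA = 900))
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(0L, 300L, 600L))
  expect_equal(w$end, c(300L, 600L, 900L))
  # trailing 100 bp dropped
  expect_equal(nrow(tile_genome(c(chrA = 1000))), 3)
  # exclusion interval anywhere inside a window flags it
  excl <- data.frame(contig = "chrA", start = 250L, end = 260L)
  w2 <- tile_genome(c(chrA = 900), exclusion = excl)
  expect_equal(w2$excluded, c(TRUE, FALSE, FALSE))
  # brute-force interval-overlap oracle on random exclusions
  set.seed(42)
  for (r in 1:20) {
    s <- sample(0:2900, 1); e <- s + sample(1:400, 1)
    w3 <- tile_genome(c(chrA = 3000),
                      exclusion = data.frame(contig = "chrA", start = s, end = e))
    manual <- vapply(seq_len(nrow(w3)), function(i)
      max(w3$start[i], s) < min(w3$end[i], e), logical(1))
    expect_identical(w3$excluded, manual)
  }
})

test_that("BED parser reports malformed lines by number", {
  f <- withr::local_tempfile(lines = c("chr1\t0\t300", "chr1\tx\t600",
                                       "chr1\t600\t900"))
  expect_error(read_bed(f), "line 2")
  f2 <- withr::local_tempfile(lines = c("chr1\t100\t50"))
  expect_error(read_bed(f2), "line 1")
  f3 <- withr::local_tempfile(lines = c("track name=x", "chr1\t0\t300\tcgi1"))
  b <- read_bed(f3)
  expect_equal(b$start, 0L)
  expect_equal(b$name, "cgi1")
})

test_that("fragments are filtered and assigned by midpoint to one window", {
  w <- tile_genome(c(chrA = 1200))
  fr <- data.frame(
    contig = c("chrA", "chrA", "chrA", "chrA", "chrA", "chrZ", "chrA"),
    start  = c(100L,   0L,     500L,   100L,   100L,   10L,    100L),
    end    = c(400L,   600L,   560L,   1300L,  400L,   300L,   160L),
    mapq   = c(30L,    30L,    30L,    30L,    5L,     30L,    30L))
  res <- assign_fragments(fr, w)
  # row 1: midpoint 250 -> [0,300); row 2: midpoint 300 -> [300,600) (half-open);
  # row 3: midpoint 530 -> [300,600); row 4: length 1200 filtered;
  # row 5: mapq 5 filtered; row 6: unknown contig; row 7: length 60 -> [0,300)
  expect_equal(unname(res$counts), c(2L, 2L, 0L, 0L))
  expect_equal(res$library_size, sum(res$counts))
  expect_equal(res$n_filtered, 2L)
  expect_equal(res$n_rejected_contig, 1L)
  # excluded windows receive nothing
  w2 <- tile_genome(c(chrA = 1200),
                    exclusion = data.frame(contig = "chrA", start = 0L, end = 10L))
  res2 <- assign_fragments(fr, w2)
  expect_equal(unname(res2$counts[1]), 0L)
  expect_equal(res2$n_rejected_excluded, 2L)
})

test_that("TMM factors are scale-invariant and match a brute-force oracle", {
  set.seed(7)
  ref <- rpois(1000, 50)
  ids <- sprintf("w%04d", 1:1000)
  cm <- count_matrix(matrix(c(ref, ref * 2L), ncol = 2,
                            dimnames = list(ids, c("a", "b"))))
  cm <- tmm_normalize(cm, ref)
  # identical profile (any scale): factor 1, nrpm equal to reference
  expect_equal(unname(cm$norm_factor), c(1, 1), tolerance = 1e-8)
  v <- nrpm(cm)
  expect_equal(v[, "a"], v[, "b"])
  # 5% DE windows: factor within 2% of an independently coded trimmed mean
  de <- sample(1000, 50)
  obs <- ref; obs[de] <- obs[de] * 6L
  cm2 <- tmm_normalize(count_matrix(matrix(obs, ncol = 1,
                                           dimnames = list(ids, "s"))), ref)
  oracle <- local({
    o <- obs / sum(obs); r <- ref / sum(ref)
    keep <- obs > 0 & ref > 0
    m <- log2(o / r)[keep]; a <- (0.5 * log2(o * r))[keep]
    w <- 1 / ((sum(obs) - obs) / (sum(obs) * obs) +
                (sum(ref) - ref) / (sum(ref) * ref))[keep]
    k <- m >= quantile(m, 0.3) & m <= quantile(m, 0.7) &
      a >= quantile(a, 0.05) & a <= quantile(a, 0.95)
    2^(sum((w * m)[k]) / sum(w[k]))
  })
  expect_equal(unname(cm2$norm_factor), oracle, tolerance = 0.02)
  # cross-check against edgeR's TMM (independent implementation)
  edger_nf <- edgeR::calcNormFactors(cbind(ref = ref, s = obs), refColumn = 1,
                                     method = "TMM")
  expect_equal(unname(cm2$norm_factor["s"] / 1),
               unname(edger_nf["s"] / edger_nf["ref"]), tolerance = 0.02)
})

test_that("zero-overlap samples fall back to factor 1 with a warning", {
  ids <- sprintf("w%d", 1:10)
  cm <- count_matrix(matrix(c(rep(0L, 5), rep(10L, 5)), ncol = 1,
                            dimnames = list(ids, "s")))
  expect_warning(tmm_normalize(cm, c(rep(10, 5), rep(0, 5))), "factor set to 1")
})

test_that("calibration inverts the forward model", {
  fx <- fixture_cohort()
  cfg <- fx$cfg; w <- fx$w
  # noiseless self-consistency: a calibration table built from the true
  # model levels recovers beta exactly from the model-mean counts
  g <- w$cpg_count^2 / (7^2 + w$cpg_count^2)
  B <- fx$coh$methylomes$beta[, "normal"]
  mu <- expected_counts(B, w, cfg)
  scale_nrpm <- 1e6 / cfg$library_size
  wsum <- sum(mbdflow:::capture_weight(B, w$cpg_count, cfg))
  true_tab <- data.frame(
    d_lo = 0:max(w$cpg_count), d_hi = c(1:max(w$cpg_count), Inf),
    bg = cfg$background_capture * cfg$library_size / wsum * scale_nrpm,
    full = (cfg$background_capture + (0:max(w$cpg_count))^2 /
              (49 + (0:max(w$cpg_count))^2)) *
      cfg$library_size / wsum * scale_nrpm,
    n = 1L)
  class(true_tab) <- c("calibration_table", "data.frame")
  big <- 1e9  # scale counts up so integer rounding is negligible
  cmx <- count_matrix(matrix(as.integer(round(mu / cfg$library_size * big)),
                             ncol = 1, dimnames = list(w$window_id, "x")),
                      library_size = c(x = big))
  bhat <- estimate_beta(cmx, true_tab, w, min_expected = 1)
  ok <- !is.na(bhat[, 1])
  expect_gt(mean(ok), 0.2)
  expect_lt(max(abs(bhat[ok, 1] - B[ok])), 0.002)
  # blind-calibrated dynamic range tracks the density response g(d)
  rng <- fx$cal$full - fx$cal$bg
  mid <- ifelse(is.finite(fx$cal$d_hi), (fx$cal$d_lo + fx$cal$d_hi) / 2,
                fx$cal$d_lo + 2)
  g_mid <- mid^2 / (49 + mid^2)
  expect_gte(cor(rng, g_mid, method = "spearman"), 0.95)
  # d = 0 stratum: no CpGs, no enrichment signal
  expect_lt(rng[1], 0.25 * max(rng))
  # full(d) is non-decreasing and never below bg
  expect_true(all(diff(fx$cal$full) >= -1e-9))
  expect_true(all(fx$cal$full >= fx$cal$bg))
})

test_that("beta estimates hit the calibration anchors and clamp", {
  fx <- fixture_cohort()
  lv <- calibration_levels(fx$cal, fx$w)
  i <- which(fx$w$cpg_count >= 16)[1]
  mk <- function(nr) {
    cmx <- count_matrix(matrix(0L, nrow(fx$w), 1,
                               dimnames = list(fx$w$window_id, "x")),
                        library_size = c(x = 1e6))
    cmx$counts[i, 1] <- as.integer(round(nr))
    cmx
  }
  b_bg <- estimate_beta(mk(lv$bg[i]), fx$cal, fx$w)
  expect_equal(unname(b_bg[i, 1]), 0, tolerance = 0.01)
  b_full <- estimate_beta(mk(lv$full[i]), fx$cal, fx$w)
  expect_equal(unname(b_full[i, 1]), 1, tolerance = 0.01)
  b_over <- estimate_beta(mk(2 * lv$full[i]), fx$cal, fx$w)
  expect_equal(unname(b_over[i, 1]), 1)  # clamped
  expect_true(all(is.na(b_bg[fx$w$excluded, ])))
})

test_that("relative enrichment has its closed forms and is monotone in density", {
  w <- fixture_cohort()$w
  J <- nrow(w)
  uni <- rep(5L, J)
  expect_equal(relative_enrichment(uni, w)$relative_enrichment, 1)
  # all mass in the densest window
  one <- integer(J); imax <- which.max(w$cpg_count); one[imax] <- 100L
  expect_equal(relative_enrichment(one, w)$relative_enrichment,
               w$cpg_count[imax] / mean(w$cpg_count))
  # counts proportional to density: ratio = sum(d^2) / (sum(d) * mean(d))
  set.seed(3)
  prop <- rpois(J, lambda = w$cpg_count * 2 + 0.01)
  r <- relative_enrichment(prop, w)$relative_enrichment
  d <- w$cpg_count
  expect_equal(r, sum(d^2) / (sum(d) * mean(d)), tolerance = 0.03)
  # moving a fragment from a low-d to a high-d window strictly increases it
  lo <- which.min(d)
  shifted <- uni; shifted[lo] <- shifted[lo] - 1L; shifted[imax] <- shifted[imax] + 1L
  expect_gt(relative_enrichment(shifted, w)$relative_enrichment, 1)
  # zero counts: undefined, failed
  z <- relative_enrichment(integer(J), w)
  expect_true(is.na(z$relative_enrichment) && !z$pass_enrichment)
})

test_that("always-methylated QC separates good from scrambled samples", {
  fx <- fixture_cohort()
  w <- fx$w
  b1 <- rep(NA_real_, nrow(w)); b1[w$qc_always_methylated] <- 1
  expect_equal(qc_always_methylated(b1, w)$frac_qc_windows_high, 1)
  expect_true(qc_always_methylated(b1, w)$pass_always_methylated)
  bna <- rep(NA_real_, nrow(w))
  expect_equal(qc_always_methylated(bna, w)$frac_qc_windows_high, 0)
  w_noqc <- w; w_noqc$qc_always_methylated <- FALSE
  expect_error(qc_always_methylated(b1, w_noqc), "no QC")
  # generator contrast: real NCC passes, scrambled beta fails
  for (s in fx$samples$sample_id[fx$samples$type == "ncc"][1:5]) {
    good <- qc_always_methylated(fx$beta[, s], w)
    expect_true(good$pass_always_methylated)
    set.seed(match(s, colnames(fx$beta)))
    bad <- qc_always_methylated(sample(fx$beta[, s]), w)
    expect_false(bad$pass_always_methylated)
  }
  # enrichment QC passes for simulated capture samples
  re <- relative_enrichment(fx$coh$counts$counts[, "NCC_1"], w)
  expect_true(re$pass_enrichment)
})

test_that("PCA removes batch offsets and separates subtypes", {
  fx <- fixture_cohort()
  # constant per-batch offsets are removed exactly
  set.seed(5)
  base <- matrix(runif(200 * 6), 200, 6,
                 dimnames = list(sprintf("w%d", 1:200), sprintf("s%d", 1:6)))
  batch <- rep(c("x", "y"), each = 3)
  shifted <- base
  shifted[, batch == "y"] <- shifted[, batch == "y"] + 0.3
  p1 <- pca_variable_windows(base, batch, k_windows = 200)
  p2 <- pca_variable_windows(shifted, batch, k_windows = 200)
  expect_equal(abs(p1$scores), abs(p2$scores), tolerance = 1e-8)
  # identical samples: degenerate, flagged
  flat <- matrix(0.4, 50, 4, dimnames = list(sprintf("w%d", 1:50), letters[1:4]))
  expect_true(pca_variable_windows(flat, k_windows = 50)$degenerate)
  # three-subtype tissue cohort recovers labels on 2 PCs
  B <- fx$coh$methylomes$beta
  cols <- list()
  for (s in c("ASCL1", "NEUROD1", "DN")) for (i in 1:6) {
    id <- sprintf("P_%s_%d", s, i)
    cols[[id]] <- simulate_counts(B[, paste0("tumor_", s)], fx$w, fx$cfg,
                                  50000 + length(cols))
  }
  cmx <- tmm_normalize(bind_count_columns(cols), fx$ref_counts)
  bx <- estimate_beta(cmx, fx$cal, fx$w)
  pc <- pca_variable_windows(bx, batch = NULL, k_windows = 2000, n_pcs = 2)
  set.seed(1)
  km <- kmeans(pc$scores, centers = 3, nstart = 20)
  truth <- rep(c("ASCL1", "NEUROD1", "DN"), each = 6)
  expect_gte(adjusted_rand_index(km$cluster, truth), 0.9)
})

test_that("count matrices survive a TSV round trip", {
  fx <- fixture_cohort()
  cm <- fx$cm
  sub <- count_matrix(cm$counts[1:50, 1:3],
                      library_size = cm$library_size[1:3],
                      norm_factor = cm$norm_factor[1:3])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(sub, f)
  rt <- read_counts_tsv(f)
  expect_equal(rt$counts, sub$counts)
  expect_equal(rt$library_size, sub$library_size)
  expect_equal(rt$norm_factor, sub$norm_factor, tolerance = 1e-12)
})
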