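test_that("the canonical HRF peaks at the configured time and is linear", {
  dt <- 0.1
  h <- canonical_hrf(dt, peak = 5)
  expect_lte(abs((which.max(h) - 1) * dt - 5), dt)
  expect_equal(max(h), 1)
  h2 <- canonical_hrf(dt, peak = 7)
  expect_lte(abs((which.max(h2) - 1) * dt - 7), dt)

  # convolution linearity through the regressor builder
  ev <- event_table("m1", 0, 30, 5, 5)
  base <- window_sums(data.frame(onset = c(2, 9, 17), value = 1), ev)
  mk <- function(vals) {
    s <- base; s$value <- vals
    parametric_regressor(s, TR = 1, n_volumes = 60, center = FALSE)$samples
  }
  a <- c(1, 0, 2); b <- c(0, 3, 1)
  expect_equal(mk(a + b), mk(a) + mk(b), tolerance = 1e-10)
  expect_equal(mk(c(0, 0, 0)), rep(0, 60))
})

test_that("parametric regressors are centered impulse-HRF superpositions", {
  # two retained windows at 3 s and 12 s (only start and value are used)
  ws <- data.frame(start = c(3, 12), end = c(8, 17), value = c(2, 2),
                   n_words = c(3, 3), empty = FALSE)
  # constant modulator vanishes after centering
  expect_lt(max(abs(parametric_regressor(ws, TR = 1, n_volumes = 70)$samples)),
            1e-12)

  # two-window series equals a hand-built superposition of shifted kernels
  ws$value <- c(2, 5)
  got <- parametric_regressor(ws, TR = 1, n_volumes = 70)$samples
  dt <- 0.1
  hrf <- canonical_hrf(dt)
  n_fine <- ceiling(69 / dt) + 1
  manual <- numeric(n_fine)
  cvals <- ws$value - mean(ws$value)
  starts_idx <- round(ws$start / dt) + 1
  for (i in 1:2) {
    idx <- starts_idx[i] + seq_along(hrf) - 1
    keep <- idx <= n_fine
    manual[idx[keep]] <- manual[idx[keep]] + cvals[i] * hrf[keep]
  }
  manual_tr <- manual[round((0:69) / dt) + 1] * dt
  expect_equal(got, manual_tr, tolerance = 1e-8)

  far <- ws; far$start <- far$start + 1000
  expect_error(parametric_regressor(far, TR = 1, n_volumes = 70), "beyond")
})

test_that("duration-modulated regressors follow the three-part model", {
  tab <- event_table("m1", c(0, 20, 45), c(15, 20, 10), c(4, 4, 4),
                     c(2, 6, 7))
  regs <- duration_modulated_regressor(tab, "semantic", TR = 1,
                                       n_volumes = 80)
  expect_named(regs, c("baseline", "modulated", "nuisance"))
  # all ratings equal -> modulated regressor identically zero
  expect_lt(max(abs(regs$modulated$samples)), 1e-12)
  expect_gt(max(abs(regs$baseline$samples)), 0)

  # independent time-domain integration oracle at the same grid
  dt <- 0.1
  hrf <- canonical_hrf(dt)
  n_fine <- ceiling(79 / dt) + 1
  amp <- tab$social - mean(tab$social)
  stim <- numeric(n_fine)
  for (i in 1:3) {
    a <- round(tab$onset[i] / dt) + 1
    b <- min(round((tab$onset[i] + tab$duration[i]) / dt), n_fine)
    stim[a:b] <- stim[a:b] + amp[i]
  }
  conv <- numeric(n_fine)
  for (t in seq_len(n_fine)) {
    kmax <- min(t, length(hrf))
    conv[t] <- sum(stim[t - seq_len(kmax) + 1] * hrf[seq_len(kmax)]) * dt
  }
  oracle <- conv[round((0:79) / dt) + 1]
  expect_equal(regs$nuisance$samples, oracle, tolerance = 1e-6)

  # ratings one unit off the mean reduce to signed unit boxcars per event
  tab1 <- event_table("m1", c(0, 30), c(10, 10), c(4, 6), c(5, 5))
  r1 <- duration_modulated_regressor(tab1, "semantic", TR = 1, n_volumes = 60)
  box <- function(on) duration_modulated_regressor(
    event_table("m1", on, 10, 5, 5), "semantic", TR = 1,
    n_volumes = 60)$baseline$samples
  expect_equal(r1$modulated$samples, box(30) - box(0), tolerance = 1e-10)
})

test_that("modulated and baseline regressors decorrelate under random ratings", {
  set.seed(20)
  rs <- replicate(20, {
    tab <- random_event_table(25, seed = sample.int(1e6, 1))
    nv <- ceiling(sum(tab$duration)) + 10
    regs <- duration_modulated_regressor(tab, "semantic", TR = 1,
                                         n_volumes = nv)
    cor(regs$modulated$samples, regs$baseline$samples)
  })
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("the voxelwise GLM is exact on noiseless data and flags collinearity", {
  ev <- gen_events(30, seed = 3)
  merged <- merge_short_events(ev$table)
  nv <- ceiling(max(merged$onset + merged$duration)) + 8
  regs <- duration_modulated_regressor(merged, "semantic", TR = 1,
                                       n_volumes = nv)
  gb <- gen_bold(regs, betas = c(semantic_modulated = 0.8), dims = c(8, 8, 8),
                 noise_sd = 0, seed = 4)
  fit <- fit_first_level(gb$bold, regs)
  expect_lt(max(abs(fit$betas$semantic_modulated$data -
                      gb$truth$beta_maps$semantic_modulated)), 1e-8)

  dup <- regs
  dup$copy <- dup$modulated
  dup$copy$name <- "copy"
  expect_error(fit_first_level(gb$bold, dup), "collinear")

  # determinism and t/beta sign agreement
  gb2 <- gen_bold(regs, betas = c(semantic_modulated = 0.5), dims = c(8, 8, 8),
                  noise_sd = 1, seed = 5)
  f1 <- fit_first_level(gb2$bold, regs)
  f2 <- fit_first_level(gb2$bold, regs)
  expect_identical(f1$tmaps$semantic_modulated$data,
                   f2$tmaps$semantic_modulated$data)
  expect_true(all(sign(f1$tmaps$semantic_modulated$data) ==
                    sign(f1$betas$semantic_modulated$data)))
})

test_that("censored volumes are excluded from the fit", {
  ev <- gen_events(20, seed = 6)
  merged <- merge_short_events(ev$table)
  nv <- ceiling(max(merged$onset + merged$duration)) + 8
  regs <- duration_modulated_regressor(merged, "semantic", TR = 1,
                                       n_volumes = nv)
  gb <- gen_bold(regs, betas = c(semantic_modulated = 0.6), dims = c(8, 8, 8),
                 noise_sd = 0, seed = 7)
  # corrupt some volumes, then censor them out: recovery stays exact
  bold <- gb$bold
  spikes <- c(5, 50, 100)
  bold$data[, , , spikes] <- 99
  censor <- rep(1, nv); censor[spikes] <- 0
  fit <- fit_first_level(bold, regs, censor = censor)
  expect_lt(max(abs(fit$betas$semantic_modulated$data -
                      gb$truth$beta_maps$semantic_modulated)), 1e-8)
  expect_identical(fit$df, as.integer(nv - 3 - 4))
})

test_that("first-level t tests hold their size under iid noise", {
  ev <- gen_events(40, seed = 3)
  merged <- merge_short_events(ev$table)
  nv <- ceiling(max(merged$onset + merged$duration)) + 8
  regs <- duration_modulated_regressor(merged, "semantic", TR = 1,
                                       n_volumes = nv)
  gb0 <- gen_bold(regs, betas = c(semantic_modulated = 0), dims = c(10, 10, 10),
                  noise_sd = 1, ar1 = 0, fwhm = 0, seed = 1)
  fit0 <- fit_first_level(gb0$bold, regs)
  tv <- as.vector(fit0$tmaps$semantic_modulated$data)[1:500]
  rate <- mean(abs(tv) > qt(0.975, fit0$df))
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("smoothness estimates recover known kernels and compose with voxel size", {
  set.seed(5)
  dims <- c(16, 16, 16); n_t <- 40
  mask <- array(TRUE, dims)
  white <- array(rnorm(prod(dims) * n_t), c(dims, n_t))
  fw <- as.numeric(estimate_smoothness(white, mask, 2))
  expect_true(all(abs(fw - 2) / 2 < 0.2))

  smooth_at <- function(fwhm_mm) {
    sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / 2
    arr <- array(0, c(dims, n_t))
    for (t in seq_len(n_t)) {
      arr[, , , t] <- natsemsoc:::.smooth3d(array(rnorm(prod(dims)), dims),
                                            rep(sig, 3))
    }
    arr
  }
  f6 <- as.numeric(estimate_smoothness(smooth_at(6), mask, 2))
  truth <- sqrt(6^2 + 2^2)
  expect_true(all(abs(f6 - truth) / truth < 0.15))

  f4 <- as.numeric(estimate_smoothness(smooth_at(4), mask, 2))
  f8 <- as.numeric(estimate_smoothness(smooth_at(8), mask, 2))
  expect_true(all(fw < f4 & f4 < f8))

  expect_error(estimate_smoothness(white[, , , 1:5, drop = FALSE], mask, 2),
               "10 time points")
  tiny <- array(FALSE, dims); tiny[1:3, 1:3, 1:3] <- TRUE
  expect_error(estimate_smoothness(white, tiny, 2), "mask too small")
})
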