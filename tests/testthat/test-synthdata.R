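test_that("every generator is a pure function of parameters and seed", {
  expect_identical(gen_lexicon(150, 0.1, seed = 3), gen_lexicon(150, 0.1, seed = 3))
  lex <- gen_lexicon(150, 0, seed = 3)
  expect_identical(gen_embeddings(lex, seed = 4)$vectors,
                   gen_embeddings(lex, seed = 4)$vectors)
  expect_identical(gen_events(50, seed = 5)$table, gen_events(50, seed = 5)$table)
  ev <- gen_events(50, seed = 5)
  expect_identical(gen_transcript(ev, lex, seed = 6), gen_transcript(ev, lex, seed = 6))
})

test_that("lexicon respects bounds, missingness and argument validation", {
  expect_error(gen_lexicon(50), "at least 100")
  expect_error(gen_lexicon(200, missing_rate = 0.6), "below 0.5")
  lex0 <- gen_lexicon(200, missing_rate = 0, seed = 1)
  expect_false(anyNA(lex0$table[, natsemsoc:::WORD_PROPERTIES]))
  lex <- gen_lexicon(500, missing_rate = 0.2, seed = 2)
  rate <- mean(is.na(as.matrix(lex$table[, natsemsoc:::WORD_PROPERTIES])))
  expect_lt(abs(rate - 0.2), 0.03)
  s <- lex$truth$complete$socialness
  expect_true(all(s >= 1 & s <= 5))
  counts <- lex$truth$complete$n_letters
  expect_true(all(counts >= 0))
})

test_that("event tables honour the duration and rating calibration", {
  meds <- shorts <- c()
  for (sd in 1:20) {
    ev <- gen_events(350, seed = sd)
    expect_identical(nrow(validate_events(ev$table)), 0L)
    expect_false(any(ev$table$semantic >= 9 & ev$table$social >= 9))
    shorts <- c(shorts, mean(ev$table$duration < 3))
    merged <- merge_short_events(ev$table)
    meds <- c(meds, median(merged$duration))
  }
  expect_true(all(meds >= 13 & meds <= 19))
  expect_gte(mean(shorts), 0.02)
  expect_lte(mean(shorts), 0.06)
  # post-merge durations live in the observed range
  merged <- merge_short_events(gen_events(350, seed = 3)$table)
  expect_gte(min(merged$duration), 3)
  expect_lte(max(merged$duration), 135)
})

test_that("transcripts reproduce the rating/word-count correlation structure", {
  rd <- rs <- rc <- c()
  for (sd in 1:5) {
    ev <- gen_events(350, seed = sd)
    tr <- gen_transcript(ev, seed = sd + 500)
    expect_true(all(tr$onset >= 0))
    # each word lies inside its event
    m <- match(tr$event_index, ev$table$index)
    expect_true(all(tr$onset >= ev$table$onset[m] &
                      tr$onset < ev$table$onset[m] + ev$table$duration[m]))
    nw <- vapply(ev$table$index,
                 function(i) sum(tr$event_index == i), numeric(1))
    rd <- c(rd, cor(ev$table$duration, nw))
    rs <- c(rs, cor(ev$table$semantic, nw))
    rc <- c(rc, cor(ev$table$social, nw))
  }
  expect_true(all(rd >= 0.55 & rd <= 0.86))
  expect_true(all(rs >= 0.40 & rs <= 0.76))
  expect_true(all(rc >= 0.32 & rc <= 0.56))
})

test_that("embedding neighbourhoods carry socialness", {
  lex <- gen_lexicon(600, missing_rate = 0, seed = 7)
  emb <- gen_embeddings(lex, seed = 8)
  expect_true(all(rowSums(emb$vectors^2) > 0))
  expect_error(gen_embeddings(lex, dim = 4), "at least 8")

  s <- lex$truth$complete$socialness
  V <- emb$vectors
  set.seed(9)
  ii <- sample(600, 300); jj <- sample(600, 300)
  sims <- rowSums(V[ii, ] * V[jj, ]) /
    (sqrt(rowSums(V[ii, ]^2)) * sqrt(rowSums(V[jj, ]^2)))
  close_s <- abs(s[ii] - s[jj]) < 0.5
  expect_gt(mean(sims[close_s]), median(sims))

  # hold-out extrapolation recovers ratings well inside a rating point
  normed <- 1:300; held <- 301:360
  social <- data.frame(word = lex$table$word[normed],
                       mean_rating = pmin(pmax(s[normed], 1), 5))
  errs <- vapply(held, function(i) {
    abs(extrapolate_social(lex$table$word[i], emb, social) - s[i])
  }, numeric(1))
  expect_lt(mean(errs), 0.8)
})

test_that("the BOLD forward model is exact and reproducible", {
  ev <- gen_events(20, seed = 10)
  merged <- merge_short_events(ev$table)
  nv <- ceiling(max(merged$onset + merged$duration)) + 8
  regs <- duration_modulated_regressor(merged, "semantic", TR = 1,
                                       n_volumes = nv)
  # zero betas, zero noise: constant (zero) image
  g0 <- gen_bold(regs, betas = c(semantic_modulated = 0), dims = c(8, 8, 8),
                 noise_sd = 0, seed = 11)
  expect_true(all(g0$bold$data == 0))
  # noiseless effect is recovered exactly by the GLM
  g1 <- gen_bold(regs, betas = c(semantic_modulated = 0.7), dims = c(8, 8, 8),
                 noise_sd = 0, seed = 11)
  fit <- fit_first_level(g1$bold, regs)
  expect_lt(max(abs(fit$betas$semantic_modulated$data -
                      g1$truth$beta_maps$semantic_modulated)), 1e-6)
  # bit-identical on repeated calls
  g2 <- gen_bold(regs, betas = c(semantic_modulated = 0.7), dims = c(8, 8, 8),
                 noise_sd = 1, seed = 12)
  g3 <- gen_bold(regs, betas = c(semantic_modulated = 0.7), dims = c(8, 8, 8),
                 noise_sd = 1, seed = 12)
  expect_identical(g2$bold$data, g3$bold$data)
  expect_error(gen_bold(regs, betas = c(semantic_modulated = 0),
                        dims = c(4, 4, 4)), "at least 8")
})

test_that("subject beta maps correlate with the planted truth at default SNR", {
  ev <- gen_events(40, seed = 13)
  merged <- merge_short_events(ev$table)
  nv <- ceiling(max(merged$onset + merged$duration)) + 8
  regs <- duration_modulated_regressor(merged, "semantic", TR = 1,
                                       n_volumes = nv)
  act <- sphere_mask(c(10, 10, 10), radius = 3)
  g <- gen_bold(regs, betas = c(semantic_modulated = 0.8),
                dims = c(10, 10, 10),
                active = list(semantic_modulated = act), seed = 14)
  fit <- fit_first_level(g$bold, regs)
  r <- cor(as.vector(fit$betas$semantic_modulated$data),
           as.vector(g$truth$beta_maps$semantic_modulated))
  expect_gte(r, 0.7)
  # recovered beta signs match truth inside the active region
  sgn_ok <- mean(sign(fit$betas$semantic_modulated$data[act]) ==
                   sign(g$truth$beta_maps$semantic_modulated[act]))
  expect_gte(sgn_ok, 0.95)
})
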