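props <- natsemsoc:::WORD_PROPERTIES

make_norms <- function(words, seed = 1) {
  set.seed(seed)
  norms <- data.frame(word = words, pos = "open", stringsAsFactors = FALSE)
  for (p in props) norms[[p]] <- round(runif(length(words), 1, 5), 2)
  norms
}

test_that("word table assembly applies the exclusion rules", {
  norms <- make_norms(c("apple", "lonely", "sparse"))
  norms$frequency <- 3                             # equal: nothing high-frequency
  norms[norms$word == "sparse", props[-12]] <- NA  # 11 of 12 missing
  norms <- rbind(norms,
                 cbind(data.frame(word = "the", pos = "closed"),
                       as.data.frame(as.list(setNames(rep(3, 12), props)))))
  tab <- assemble_word_table(c("apple", "the", "lonely", "sparse"), norms)
  expect_true(all(c("apple", "lonely") %in% tab$word))   # complete rows kept
  expect_false("the" %in% tab$word)                      # closed class out
  expect_false("sparse" %in% tab$word)                   # > 10 missing out
  expect_false(anyNA(tab[tab$word == "apple", props]))
})

test_that("high-frequency exclusion uses the frequency quantile cutoff", {
  norms <- make_norms(sprintf("w%02d", 1:40))
  norms$frequency <- seq_len(40)
  tab <- assemble_word_table(norms$word, norms, freq_quantile = 0.9)
  expect_false(any(c("w39", "w40") %in% tab$word))
  expect_true("w01" %in% tab$word)
})

test_that("assembly rejects empty transcripts and duplicate norms", {
  norms <- make_norms(c("a", "b"))
  expect_error(assemble_word_table(character(), norms), "empty")
  expect_error(assemble_word_table("a", rbind(norms, norms)), "duplicate")
})

test_that("imputation is a no-op on complete data and never alters observed cells", {
  lex <- gen_lexicon(200, missing_rate = 0, seed = 4)
  out <- impute_chained(lex$table, m = 3, seed = 1)
  expect_length(out, 3)
  for (d in out) expect_identical(d, lex$table)

  lex2 <- gen_lexicon(300, missing_rate = 0.15, seed = 5)
  out2 <- impute_chained(lex2$table, m = 2, seed = 2)
  for (d in out2) {
    expect_false(anyNA(d[, props]))
    for (p in props) {
      obs <- !is.na(lex2$table[[p]])
      expect_identical(d[[p]][obs], lex2$table[[p]][obs])
    }
  }
})

test_that("predictive mean matching imputes observed donor values deterministically", {
  lex <- gen_lexicon(150, missing_rate = 0, seed = 6)
  tab <- lex$table
  tab$concreteness[5] <- NA
  out <- impute_chained(tab, m = 1, seed = 3)[[1]]
  expect_true(out$concreteness[5] %in% tab$concreteness[-5])  # PMM donor
  out2 <- impute_chained(tab, m = 1, seed = 3)[[1]]
  expect_identical(out, out2)
  expect_error(impute_chained(transform(tab, valence = NA_real_)),
               "fewer than 2 observed")
})

test_that("imputation under MCAR missingness preserves property means", {
  lex <- gen_lexicon(600, missing_rate = 0.2, seed = 8)
  imp <- impute_chained(lex$table, m = 5, seed = 3)
  comp <- lex$truth$complete
  for (p in props) {
    for (d in imp) {
      expect_lt(abs(mean(d[[p]]) - mean(comp[[p]])) / sd(comp[[p]]), 0.1)
    }
  }
})

test_that("varimax rotation is orthogonal and preserves retained variance", {
  lex <- gen_lexicon(800, missing_rate = 0, seed = 9)
  fm <- fit_pca_varimax(lex$table)
  expect_lt(max(abs(crossprod(fm$rotation) - diag(4))), 1e-8)
  # rotation preserves the total sum of squared loadings
  Z <- scale(as.matrix(lex$table[, props]))
  pc <- prcomp(Z, center = FALSE)
  unrotated_ssq <- sum(pc$sdev[1:4]^2)
  expect_lt(abs(sum(fm$loadings^2) - unrotated_ssq), 1e-8)
  expect_true(all(fm$variance_explained > 0 & fm$variance_explained < 1))
  expect_lte(sum(fm$variance_explained), 1)
  expect_error(fit_pca_varimax(lex$table, k = 13), "exceeds")
})

test_that("planted loading structure is recovered with high congruence", {
  lex <- gen_lexicon(3000, missing_rate = 0, seed = 10)
  fm <- fit_pca_varimax(lex$table)
  L <- lex$truth$loadings
  for (j in 1:4) {
    cong <- max(abs(crossprod(L[, j], fm$loadings)) /
                  (sqrt(sum(L[, j]^2)) * sqrt(colSums(fm$loadings^2))))
    expect_gte(cong, 0.95)
  }
  # variance ordering matches the generator's planted split
  expect_identical(fm$factor_names, natsemsoc:::CANONICAL_FACTORS)
})

test_that("factor scores average over imputations and take |EmotionalStrength|", {
  lex <- gen_lexicon(400, missing_rate = 0, seed = 11)
  fm <- fit_pca_varimax(lex$table)
  one <- score_factors(fm, lex$table)
  avg <- score_factors(fm, list(lex$table, lex$table, lex$table))
  expect_equal(one, avg, tolerance = 1e-12, ignore_attr = TRUE)
  expect_gte(min(one$EmotionalStrength), 0)
  expect_true(attr(one, "emotional_strength_abs_applied"))
  raw <- score_factors(fm, lex$table, abs_emotional = FALSE)
  for (f in c("WordLength", "SemanticFlexibility", "SocialImpact")) {
    expect_lt(abs(mean(raw[[f]])), 1e-6)
  }
  bad <- lex$table[, c("word", props[1:6])]
  expect_error(score_factors(fm, bad), "match")
})

test_that("scores track the generating latent factors on clean 4-factor data", {
  # strong simple structure (three markers per factor, loading 0.85)
  set.seed(12)
  n <- 3000
  Lc <- matrix(0, 12, 4)
  for (j in 1:4) Lc[(j - 1) * 3 + 1:3, j] <- 0.85
  FF <- matrix(rnorm(n * 4), n, 4)
  X <- FF %*% t(Lc) + matrix(rnorm(n * 12, sd = sqrt(1 - 0.85^2)), n, 12)
  tab <- data.frame(word = sprintf("w%04d", 1:n), X)
  names(tab)[-1] <- props
  fm <- fit_pca_varimax(tab)
  sc <- score_factors(fm, tab, abs_emotional = FALSE)
  # each recovered factor correlates >= 0.9 with one true latent
  for (j in 1:4) {
    r <- max(abs(cor(FF[, j], as.matrix(sc[, -1]))))
    expect_gte(r, 0.9)
  }
  expect_gte(max(abs(cor(FF, sc$SemanticFlexibility))), 0.9)
})

test_that("social extrapolation follows the similarity-weighted mean", {
  # 2D embeddings with exact cosine similarities to the target
  ang <- acos(c(0.9, 0.8, 0.7, 0.1, 0.05))
  emb <- list(words = c("target", "n1", "n2", "n3", "far1", "far2"),
              vectors = rbind(c(1, 0), cbind(cos(ang), sin(ang))))
  norms <- data.frame(word = c("n1", "n2", "n3", "far1", "far2"),
                      mean_rating = c(5, 3, 1, 2, 2))
  got <- extrapolate_social("target", emb, norms, k = 3)
  expect_equal(got, (0.9 * 5 + 0.8 * 3 + 0.7 * 1) / (0.9 + 0.8 + 0.7),
               tolerance = 1e-12)
  # constant neighbours give the constant regardless of weights
  norms3 <- transform(norms, mean_rating = 3)
  expect_equal(extrapolate_social("target", emb, norms3, k = 3), 3)
  expect_error(extrapolate_social("missing", emb, norms), "no embedding")
  expect_error(extrapolate_social("target", emb, norms, k = 99), "exceeds")
})

test_that("a word identical to a normed word dominates its own neighbourhood", {
  lex <- gen_lexicon(300, missing_rate = 0, seed = 13)
  emb <- gen_embeddings(lex, seed = 14)
  norms <- data.frame(word = lex$table$word[1:100],
                      mean_rating = pmin(pmax(lex$table$socialness[1:100], 1), 5))
  # target is itself normed: self-similarity 1 puts it in the neighbour set
  w <- norms$word[7]
  got <- extrapolate_social(w, emb, norms, k = 10)
  expect_true(got >= 1 && got <= 5)
  wi <- match(w, emb$words)
  sims <- drop(emb$vectors %*% emb$vectors[wi, ]) /
    (sqrt(rowSums(emb$vectors^2)) * sqrt(sum(emb$vectors[wi, ]^2)))
  normed_sims <- sims[match(norms$word, emb$words)]
  expect_equal(max(normed_sims), normed_sims[7], tolerance = 1e-12)
})

test_that("extrapolated ratings stay within the neighbour rating range", {
  lex <- gen_lexicon(200, missing_rate = 0, seed = 15)
  emb <- gen_embeddings(lex, seed = 16)
  norms <- data.frame(word = lex$table$word[1:80],
                      mean_rating = pmin(pmax(lex$table$socialness[1:80], 1), 5))
  for (w in lex$table$word[101:140]) {
    got <- extrapolate_social(w, emb, norms, k = 5)
    wi <- match(w, emb$words)
    sims <- drop(emb$vectors %*% emb$vectors[wi, ])
    ni <- match(norms$word, emb$words)
    top <- order(-(sims[ni] / sqrt(rowSums(emb$vectors[ni, ]^2))))[1:5]
    expect_gte(got, min(norms$mean_rating[top]) - 1e-12)
    expect_lte(got, max(norms$mean_rating[top]) + 1e-12)
  }
})
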