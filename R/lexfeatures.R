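# The 12 critical psycholinguistic properties carried for every word.
# Order matters: it is the column order of loading matrices throughout.
WORD_PROPERTIES <- c(
  "n_letters", "n_phonemes", "n_phon_neighbors", "n_orth_neighbors",
  "frequency", "concreteness", "sem_neighborhood_density",
  "semantic_diversity", "valence", "arousal", "dominance", "socialness"
)

CANONICAL_FACTORS <- c("WordLength", "SemanticFlexibility",
                       "EmotionalStrength", "SocialImpact")

# Which properties are expected to dominate each factor; used only to attach
# interpretable names to rotated components.
FACTOR_PROPERTY_MAP <- list(
  WordLength          = c("n_letters", "n_phonemes", "n_phon_neighbors",
                          "n_orth_neighbors"),
  SemanticFlexibility = c("frequency", "concreteness",
                          "sem_neighborhood_density", "semantic_diversity"),
  EmotionalStrength   = c("valence", "dominance"),
  SocialImpact        = c("socialness", "arousal")
)

#' Assemble the per-word property table
#'
#' Combines the unique tokens of one or more movie transcripts with
#' psycholinguistic norms and word-level social ratings into a single table,
#' applying the exclusion rules used throughout the pipeline: closed-class
#' words and high-frequency words are dropped, as is any word missing more
#' than `max_missing` of the 12 critical properties. Socialness is taken from
#' the social norms where available and otherwise extrapolated from word
#' embeddings via [extrapolate_social()]; words with neither stay missing and
#' are left for imputation.
#'
#' @param transcript_words character vector of (lowercase) tokens, or a
#'   data frame with columns `word` and `pos` (`"open"`/`"closed"`).
#' @param norms data frame of norms keyed by `word`, with any subset of the
#'   12 property columns (see `natsemsoc:::WORD_PROPERTIES`) and optionally
#'   `pos`.
#' @param social optional social norms, a data frame with columns `word`,
#'   `mean_rating` (1-5) and `n_raters`.
#' @param embeddings optional embedding table from [read_embeddings()] or
#'   [gen_embeddings()], used to extrapolate socialness for un-normed words.
#' @param freq_quantile frequency quantile above which words are excluded as
#'   high frequency (default 0.95). The exclusion is computed on the
#'   `frequency` column of the merged table.
#' @param max_missing maximum number of missing critical properties tolerated
#'   per word (default 10: words missing more than 10 of 12 are dropped).
#' @param k_neighbors neighbours used for socialness extrapolation.
#' @return data frame with columns `word`, `pos`, and the 12 properties.
#' @export
assemble_word_table <- function(transcript_words, norms, social = NULL,
                                embeddings = NULL, freq_quantile = 0.95,
                                max_missing = 10, k_neighbors = 10) {
  if (is.data.frame(transcript_words)) {
    tokens <- tolower(as.character(transcript_words$word))
    pos_in <- transcript_words$pos
  } else {
    tokens <- tolower(as.character(transcript_words))
    pos_in <- NULL
  }
  if (length(tokens) == 0) stop("empty transcript: no words to assemble")
  if (anyDuplicated(norms$word)) stop("norms table has duplicate words")

  uw <- unique(tokens)
  tab <- data.frame(word = uw, stringsAsFactors = FALSE)
  # part of speech: transcript tags take precedence over norms tags
  pos <- rep(NA_character_, length(uw))
  if (!is.null(pos_in)) {
    first <- !duplicated(tokens)
    pos[match(tokens[first], uw)] <- as.character(pos_in[first])
  }
  if (!is.null(norms$pos)) {
    mi <- match(uw, norms$word)
    use <- is.na(pos) & !is.na(mi)
    pos[use] <- as.character(norms$pos[mi[use]])
  }
  tab$pos <- pos

  mi <- match(tab$word, norms$word)
  for (p in WORD_PROPERTIES) {
    tab[[p]] <- if (p %in% names(norms)) as.numeric(norms[[p]][mi]) else NA_real_
  }

  # socialness: norms first, then embedding-based extrapolation
  if (!is.null(social)) {
    if (anyDuplicated(social$word)) stop("social norms table has duplicate words")
    si <- match(tab$word, social$word)
    have <- !is.na(si)
    tab$socialness[have] <- as.numeric(social$mean_rating[si[have]])
    if (!is.null(embeddings)) {
      need <- which(is.na(tab$socialness))
      for (i in need) {
        r <- tryCatch(
          extrapolate_social(tab$word[i], embeddings, social, k = k_neighbors),
          error = function(e) NA_real_
        )
        tab$socialness[i] <- r
      }
    }
  }

  # exclusions: closed class, high frequency, too-missing rows
  keep <- is.na(tab$pos) | tab$pos != "closed"
  tab <- tab[keep, , drop = FALSE]
  if (any(!is.na(tab$frequency))) {
    cutoff <- stats::quantile(tab$frequency, freq_quantile, na.rm = TRUE)
    tab <- tab[is.na(tab$frequency) | tab$frequency <= cutoff, , drop = FALSE]
  }
  n_miss <- rowSums(is.na(tab[, WORD_PROPERTIES, drop = FALSE]))
  tab <- tab[n_miss <= max_missing, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing cells of a word property table by iterated per-property
#' regression with predictive mean matching (PMM): each missing cell receives
#' an observed donor value whose regression prediction is closest to the
#' prediction for the missing cell, so imputations always lie in the observed
#' range. Produces `m` completed tables; observed cells are never altered.
#'
#' @param table word property table from [assemble_word_table()].
#' @param m number of completed datasets (default 5).
#' @param iters chained-equation cycles per dataset (default 10).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param donors PMM donor pool size (default 5).
#' @return list of `m` complete data frames.
#' @export
impute_chained <- function(table, m = 5, iters = 10, seed = 1, donors = 5) {
  props <- intersect(WORD_PROPERTIES, names(table))
  X <- as.matrix(table[, props, drop = FALSE])
  miss <- is.na(X)
  if (any(colSums(!miss) < 2)) {
    bad <- props[colSums(!miss) < 2]
    stop("property cannot be imputed (fewer than 2 observed values): ",
         paste(bad, collapse = ", "))
  }
  if (!any(miss)) {
    out <- replicate(m, table, simplify = FALSE)
    return(out)
  }

  impute_one <- function(sub_seed) {
    set.seed(sub_seed)
    Z <- X
    # initial fill: random draws from each property's observed values
    for (j in seq_along(props)) {
      mj <- miss[, j]
      if (any(mj)) Z[mj, j] <- sample(X[!mj, j], sum(mj), replace = TRUE)
    }
    vars_with_missing <- which(colSums(miss) > 0)
    for (it in seq_len(iters)) {
      for (j in vars_with_missing) {
        obs <- !miss[, j]
        pred <- Z[, -j, drop = FALSE]
        fit <- stats::lm.fit(cbind(1, pred[obs, , drop = FALSE]), X[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        yhat_obs <- drop(cbind(1, pred[obs, , drop = FALSE]) %*% beta)
        yhat_mis <- drop(cbind(1, pred[!obs, , drop = FALSE]) %*% beta)
        yobs <- X[obs, j]
        # PMM: for each missing cell pick one of `donors` nearest predictions
        for (ii in seq_along(yhat_mis)) {
          d <- abs(yhat_obs - yhat_mis[ii])
          pool <- order(d)[seq_len(min(donors, length(d)))]
          Z[which(!obs)[ii], j] <- yobs[sample(pool, 1)]
        }
      }
    }
    out <- table
    out[, props] <- as.data.frame(Z)
    out
  }

  sub_seeds <- seed + seq_len(m) * 1009L
  lapply(sub_seeds, impute_one)
}

#' Principal component analysis with varimax rotation across imputations
#'
#' Runs PCA on the standardized 12 word properties of each imputed table,
#' varimax-rotates the first `k` components, and aggregates the per-imputation
#' loading matrices by element-wise mean after aligning factor order and sign
#' to the first imputation (by maximal absolute congruence). Factors are
#' ordered by rotated variance and signed so each factor's largest-magnitude
#' loading is positive.
#'
#' @param tables list of complete word property tables (e.g. from
#'   [impute_chained()]); a single data frame is accepted.
#' @param k number of retained components (default 4).
#' @return object of class `factor_model` with elements `loadings` (p x k),
#'   `rotation` (k x k orthogonal), `variance_explained`, `standardization`
#'   (per-property mean/sd averaged over imputations), and `factor_names`.
#' @export
fit_pca_varimax <- function(tables, k = 4) {
  if (is.data.frame(tables)) tables <- list(tables)
  props <- intersect(WORD_PROPERTIES, names(tables[[1]]))
  if (k > length(props)) stop("k exceeds the number of properties")

  fit_one <- function(tab) {
    X <- as.matrix(tab[, props, drop = FALSE])
    if (anyNA(X)) stop("fit_pca_varimax requires complete tables")
    sds <- apply(X, 2, stats::sd)
    if (sum(sds > 0) < k) stop("need at least k properties with non-zero variance")
    Z <- scale(X)
    pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
    L <- pc$rotation[, seq_len(k), drop = FALSE] %*% diag(pc$sdev[seq_len(k)], k)
    vr <- stats::varimax(L, normalize = TRUE)
    Lr <- unclass(vr$loadings)
    rot <- vr$rotmat
    # order by rotated variance, sign so largest |loading| is positive
    ssq <- colSums(Lr^2)
    ord <- order(ssq, decreasing = TRUE)
    Lr <- Lr[, ord, drop = FALSE]
    rot <- rot[, ord, drop = FALSE]
    sgn <- apply(Lr, 2, function(v) sign(v[which.max(abs(v))]))
    sgn[sgn == 0] <- 1
    Lr <- sweep(Lr, 2, sgn, `*`)
    rot <- sweep(rot, 2, sgn, `*`)
    list(L = Lr, rot = rot,
         mean = colMeans(X), sd = sds)
  }

  fits <- lapply(tables, fit_one)
  ref <- fits[[1]]$L

  align_to_ref <- function(f) {
    L <- f$L; rot <- f$rot
    kk <- ncol(L)
    cong <- abs(crossprod(ref, L)) /
      outer(sqrt(colSums(ref^2)), sqrt(colSums(L^2)))
    perm <- integer(kk); taken <- rep(FALSE, kk)
    for (i in seq_len(kk)) {          # greedy match by congruence
      j <- which.max(ifelse(taken, -Inf, cong[i, ]))
      perm[i] <- j; taken[j] <- TRUE
    }
    L <- L[, perm, drop = FALSE]; rot <- rot[, perm, drop = FALSE]
    sgn <- sign(colSums(ref * L)); sgn[sgn == 0] <- 1
    f$L <- sweep(L, 2, sgn, `*`)
    f$rot <- sweep(rot, 2, sgn, `*`)
    f
  }
  fits <- c(fits[1], lapply(fits[-1], align_to_ref))

  L_bar <- Reduce(`+`, lapply(fits, `[[`, "L")) / length(fits)
  rot_bar <- Reduce(`+`, lapply(fits, `[[`, "rot")) / length(fits)
  # re-orthogonalize the averaged rotation (nearest orthogonal matrix)
  sv <- svd(rot_bar)
  rot_bar <- sv$u %*% t(sv$v)

  var_exp <- colSums(L_bar^2) / length(props)
  names(var_exp) <- NULL

  factor_names <- .name_factors(L_bar, props)
  colnames(L_bar) <- factor_names
  rownames(L_bar) <- props

  structure(list(
    loadings = L_bar,
    rotation = rot_bar,
    variance_explained = var_exp,
    standardization = list(
      mean = Reduce(`+`, lapply(fits, `[[`, "mean")) / length(fits),
      sd = Reduce(`+`, lapply(fits, `[[`, "sd")) / length(fits)
    ),
    factor_names = factor_names,
    properties = props
  ), class = "factor_model")
}

# Attach interpretable names: each factor is named after the canonical factor
# whose marker properties carry most of its squared loading mass.
.name_factors <- function(L, props) {
  k <- ncol(L)
  nm <- character(k)
  avail <- CANONICAL_FACTORS
  for (j in seq_len(k)) {
    mass <- vapply(avail, function(f) {
      idx <- match(intersect(FACTOR_PROPERTY_MAP[[f]], props), props)
      if (length(idx) == 0) return(0)
      sum(L[idx, j]^2) / sum(L[, j]^2)
    }, numeric(1))
    if (length(mass) == 0 || max(mass) <= 0) {
      nm[j] <- paste0("Factor", j)
    } else {
      nm[j] <- avail[which.max(mass)]
      avail <- setdiff(avail, nm[j])
    }
  }
  nm
}

#' Score words on the rotated factors
#'
#' Regression-method component scores on standardized properties, computed per
#' imputed table and averaged per word. The EmotionalStrength column (when
#' present) is replaced by its absolute value, so it indexes emotional versus
#' neutral content rather than valence direction.
#'
#' @param model a `factor_model` from [fit_pca_varimax()].
#' @param tables list of complete tables matching the model's properties.
#' @param abs_emotional apply the absolute-value transform (default TRUE).
#' @return data frame: `word` plus one column per factor; attribute
#'   `emotional_strength_abs_applied` records the transform flag.
#' @export
score_factors <- function(model, tables, abs_emotional = TRUE) {
  if (is.data.frame(tables)) tables <- list(tables)
  props <- model$properties
  if (!all(props %in% names(tables[[1]]))) {
    stop("table columns do not match the factor model's properties")
  }
  L <- model$loadings
  W <- L %*% solve(crossprod(L))   # regression weights for component scores

  score_one <- function(tab) {
    X <- as.matrix(tab[, props, drop = FALSE])
    if (anyNA(X)) stop("score_factors requires complete tables")
    Z <- scale(X)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
    Z %*% W
  }
  S <- Reduce(`+`, lapply(tables, score_one)) / length(tables)
  colnames(S) <- model$factor_names
  out <- data.frame(word = tables[[1]]$word, S, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (abs_emotional && "EmotionalStrength" %in% names(out)) {
    out$EmotionalStrength <- abs(out$EmotionalStrength)
  }
  attr(out, "emotional_strength_abs_applied") <-
    abs_emotional && "EmotionalStrength" %in% model$factor_names
  out
}

#' Extrapolate a word's socialness from embedding neighbours
#'
#' Finds the `k` normed words most cosine-similar to the target word's
#' embedding and returns the similarity-weighted mean of their social ratings.
#' Negative similarities are clipped to zero before weights are normalized;
#' if every neighbour similarity is non-positive, the unweighted mean of the
#' `k` neighbours is returned with a warning. The result is guaranteed to lie
#' within the range of the neighbour ratings (hence within [1, 5]).
#'
#' @param word token to rate.
#' @param embeddings embedding table (list with `words` and `vectors` matrix,
#'   as returned by [read_embeddings()] / [gen_embeddings()]).
#' @param norms social norms data frame (`word`, `mean_rating`).
#' @param k number of neighbours (default 10); ties in similarity are broken
#'   lexicographically by word.
#' @return rating in [1, 5].
#' @export
extrapolate_social <- function(word, embeddings, norms, k = 10) {
  wi <- match(word, embeddings$words)
  if (is.na(wi)) stop("no embedding for word '", word, "'")
  normed <- intersect(norms$word, embeddings$words)
  if (length(normed) == 0) stop("social norms table is empty or shares no words with embeddings")
  if (k > length(normed)) stop("k exceeds the number of normed words with embeddings")

  v <- embeddings$vectors[wi, ]
  M <- embeddings$vectors[match(normed, embeddings$words), , drop = FALSE]
  sims <- drop(M %*% v) / (sqrt(rowSums(M^2)) * sqrt(sum(v^2)))
  ord <- order(-sims, normed)           # ties broken lexicographically
  top <- ord[seq_len(k)]
  ratings <- norms$mean_rating[match(normed[top], norms$word)]
  w <- pmax(sims[top], 0)
  if (sum(w) <= 0) {
    warning("all neighbour similarities non-positive; using unweighted mean")
    return(mean(ratings))
  }
  sum(w * ratings) / sum(w)
}
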