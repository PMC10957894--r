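# Calibrated true loading pattern for the synthetic lexicon. Rows follow
# WORD_PROPERTIES order; columns are the four latent factors
# (WordLength, SemanticFlexibility, EmotionalStrength, SocialImpact).
# Magnitudes are calibrated so a varimax-rotated PCA on large samples
# reproduces a rotated variance split of about 29/17/16/11%.
.LEXICON_LOADINGS <- function() {
  L <- matrix(0, 12, 4,
              dimnames = list(WORD_PROPERTIES, CANONICAL_FACTORS))
  L["n_letters", 1] <- 0.93
  L["n_phonemes", 1] <- 0.93
  L["n_phon_neighbors", 1] <- -0.88
  L["n_orth_neighbors", 1] <- -0.88
  L["frequency", 2] <- -0.60
  L["concreteness", 2] <- -0.52
  L["sem_neighborhood_density", 2] <- 0.63
  L["semantic_diversity", 2] <- 0.67
  L["valence", 3] <- 0.88
  L["dominance", 3] <- 0.86
  L["arousal", 4] <- 0.62
  L["socialness", 4] <- 0.66
  L
}

#' Generate a synthetic lexicon with planted 4-factor structure
#'
#' Word properties are generated as `loadings %*% latents + noise` from four
#' orthogonal latent factors (word length, semantic flexibility, emotional
#' strength, social impact), then mapped onto realistic scales (counts
#' rounded and non-negative, socialness bounded into [1, 5]). The loading
#' magnitudes are calibrated so that a varimax-rotated PCA recovers a
#' variance split of approximately 29/17/16/11%. Cells are then masked
#' missing completely at random at `missing_rate`.
#'
#' @param n_words number of words (>= 100).
#' @param missing_rate MCAR missingness fraction (< 0.5).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return list: `table` (word property data frame with missingness),
#'   `truth` (complete table, latent scores, true loadings, variance split
#'   target, seed).
#' @export
gen_lexicon <- function(n_words = 2000, missing_rate = 0.1, seed = 1) {
  if (n_words < 100) stop("n_words must be at least 100")
  if (missing_rate >= 0.5) stop("missing_rate must be below 0.5")
  set.seed(seed)
  L <- .LEXICON_LOADINGS()
  FF <- matrix(stats::rnorm(n_words * 4), n_words, 4)
  uniq <- pmax(0.15, 1 - rowSums(L^2))      # residual variance per property
  E <- matrix(stats::rnorm(n_words * 12), n_words, 12) %*% diag(sqrt(uniq))
  X <- FF %*% t(L) + E
  colnames(X) <- WORD_PROPERTIES

  # map standardized columns onto realistic scales
  out <- data.frame(
    word = sprintf("w%05d", seq_len(n_words)),
    pos = "open",
    stringsAsFactors = FALSE
  )
  scales <- list(
    n_letters = c(6, 2), n_phonemes = c(5, 1.8),
    n_phon_neighbors = c(8, 5), n_orth_neighbors = c(6, 4),
    frequency = c(8, 2), concreteness = c(3, 0.9),
    sem_neighborhood_density = c(0.5, 0.15), semantic_diversity = c(1.7, 0.4),
    valence = c(5, 1.3), arousal = c(4, 1.1), dominance = c(5, 1.2),
    socialness = c(3, 0.8)
  )
  for (p in WORD_PROPERTIES) {
    v <- scales[[p]][1] + scales[[p]][2] * X[, p]
    if (p %in% c("n_letters", "n_phonemes", "n_phon_neighbors",
                 "n_orth_neighbors")) {
      v <- pmax(round(v), 1)
    }
    if (p == "socialness") v <- pmin(pmax(v, 1), 5)
    out[[p]] <- v
  }

  complete <- out
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_words * 12) < missing_rate, n_words, 12)
    for (j in seq_along(WORD_PROPERTIES)) {
      out[[WORD_PROPERTIES[j]]][mask[, j]] <- NA_real_
    }
  }
  list(
    table = out,
    truth = list(
      complete = complete, latents = FF, loadings = L,
      variance_split_target = c(0.29, 0.17, 0.16, 0.11),
      missing_rate = missing_rate, seed = seed
    )
  )
}

#' Generate word embeddings whose neighbourhoods carry socialness
#'
#' Embeds each lexicon word near a point on a one-dimensional manifold
#' parameterized by the word's (true) socialness, plus isotropic noise, so
#' cosine neighbourhoods are enriched for words of similar socialness. This
#' supports socialness extrapolation for un-normed words.
#'
#' @param lexicon result of [gen_lexicon()] (or a data frame with `word` and
#'   complete `socialness`).
#' @param dim embedding dimension (>= 8, default 50).
#' @param noise relative noise level (default 0.35).
#' @param seed integer seed.
#' @return embedding table: list with `words` and row-matched `vectors`
#'   matrix.
#' @export
gen_embeddings <- function(lexicon, dim = 50, noise = 0.35, seed = 1) {
  if (dim < 8) stop("dim must be at least 8")
  tab <- if (is.data.frame(lexicon)) lexicon else lexicon$truth$complete
  set.seed(seed)
  n <- nrow(tab)
  s <- tab$socialness
  theta <- (s - 1) / 4 * (pi / 2)          # socialness 1..5 -> angle 0..pi/2
  basis <- qr.Q(qr(matrix(stats::rnorm(dim * 2), dim, 2)))
  V <- cos(theta) %o% basis[, 1] + sin(theta) %o% basis[, 2]
  V <- V + matrix(stats::rnorm(n * dim, sd = noise / sqrt(dim)), n, dim)
  nz <- sqrt(rowSums(V^2))
  nz[nz == 0] <- 1
  V <- V / nz
  list(words = tab$word, vectors = V, dim = dim)
}

#' Generate a synthetic movie event table
#'
#' Event durations are log-normal with median about 16 s, clipped to
#' [4, 131] s, with about 4% of pre-merge events shorter than 3 s. Integer
#' semantic and social ratings (1-10) arise from latent Gaussian signals
#' correlated with log duration (so that rating/word-count correlations later
#' fall in the observed ranges), and the dual-maximum rule (no event rated
#' >= 9 on both scales) is enforced. Events are contiguous from `start`.
#'
#' @param n_events number of events (a plausible movie has roughly 240-430).
#' @param movie_id movie identifier.
#' @param seed integer seed.
#' @param start onset of the first event in seconds.
#' @return list: `table` (`event_table`, pre-merge), `truth` (latent rating
#'   signals, duration parameters, seed).
#' @export
gen_events <- function(n_events = 300, movie_id = "movie1", seed = 1,
                       start = 0) {
  set.seed(seed)
  short <- stats::runif(n_events) < 0.04
  dur <- stats::rlnorm(n_events, meanlog = log(16), sdlog = 0.72)
  dur <- pmin(pmax(dur, 4), 131)
  dur[short] <- stats::runif(sum(short), 1, 2.9)

  d <- as.vector(scale(log(dur)))
  e1 <- stats::rnorm(n_events); e2 <- stats::rnorm(n_events)
  z_sem <- 0.45 * d + sqrt(1 - 0.45^2) * e1
  z_soc <- 0.32 * d + 0.25 * e1 + sqrt(1 - 0.32^2 - 0.25^2) * e2
  to_rating <- function(z) pmin(pmax(round(5.5 + 2.2 * z), 1), 10)
  sem <- to_rating(z_sem); soc <- to_rating(z_soc)
  both_high <- sem >= 9 & soc >= 9
  demote <- ifelse(z_sem[both_high] >= z_soc[both_high], "soc", "sem")
  soc[both_high][demote == "soc"] <- 8
  sem[both_high][demote == "sem"] <- 8

  onset <- start + c(0, cumsum(dur[-n_events]))
  tab <- event_table(movie_id, onset, dur, sem, soc)
  list(table = tab,
       truth = list(z_sem = z_sem, z_soc = z_soc, log_dur = d,
                    short_frac = mean(short), seed = seed))
}

# Common closed-class filler tokens for synthetic transcripts.
.CLOSED_WORDS <- c("the", "a", "an", "and", "of", "to", "in", "it", "is",
                   "was", "he", "she", "that", "you", "with", "on", "for",
                   "at", "by", "this")

#' Generate a synthetic transcript for an event table
#'
#' Draws per-event word counts whose correlations with event duration and
#' with the semantic and social ratings fall inside the observed ranges
#' (duration: 0.55-0.86; semantic: 0.40-0.76; social: 0.32-0.56) in
#' expectation, places word onsets uniformly within events, and samples
#' tokens from the synthetic lexicon (open class) mixed with closed-class
#' fillers.
#'
#' @param events result of [gen_events()] (or an `event_table`; latent
#'   rating signals are then reconstructed from the integer ratings).
#' @param lexicon result of [gen_lexicon()] (token source); optional.
#' @param words_per_sec baseline speech rate (default 1.4 words/s).
#' @param open_frac fraction of open-class (content) tokens (default 0.55).
#' @param seed integer seed.
#' @return data frame: `word`, `onset`, `duration`, `pos`, `event_index`.
#' @export
gen_transcript <- function(events, lexicon = NULL, words_per_sec = 1.4,
                           open_frac = 0.55, seed = 1) {
  set.seed(seed)
  tab <- if (is.data.frame(events)) events else events$table
  z_sem <- if (is.data.frame(events)) as.vector(scale(tab$semantic))
           else events$truth$z_sem
  z_soc <- if (is.data.frame(events)) as.vector(scale(tab$social))
           else events$truth$z_soc
  n_ev <- nrow(tab)
  # sub-linear duration scaling plus rating-driven modulation, calibrated so
  # the duration/semantic/social vs word-count correlations land in the
  # 0.55-0.86 / 0.40-0.76 / 0.32-0.56 ranges
  rate <- words_per_sec * 16^0.25 * tab$duration^0.75 *
    pmax(1 + 0.40 * z_sem + 0.26 * z_soc + stats::rnorm(n_ev, sd = 0.30),
         0.05)
  n_words <- stats::rpois(n_ev, rate)

  open_pool <- if (is.null(lexicon)) sprintf("w%05d", 1:500) else {
    t0 <- if (is.data.frame(lexicon)) lexicon else lexicon$truth$complete
    t0$word[t0$pos == "open"]
  }
  rows <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    k <- n_words[i]
    if (k == 0) next
    onsets <- sort(stats::runif(k, tab$onset[i], tab$onset[i] + tab$duration[i]))
    open <- stats::runif(k) < open_frac
    w <- character(k)
    w[open] <- sample(open_pool, sum(open), replace = TRUE)
    w[!open] <- sample(.CLOSED_WORDS, sum(!open), replace = TRUE)
    rows[[i]] <- data.frame(
      word = w, onset = onsets, duration = stats::runif(k, 0.15, 0.6),
      pos = ifelse(open, "open", "closed"),
      event_index = tab$index[i], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a BOLD image container
#' @param data 4D array (x, y, z, t).
#' @param TR repetition time in seconds.
#' @param mask logical 3D array (defaults to all TRUE).
#' @param voxel_size voxel edge length(s) in mm.
#' @return list of class `bold_image`.
#' @export
bold_image <- function(data, TR = 1, mask = NULL, voxel_size = 2) {
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(TR > 0, identical(dim(mask), dim(data)[1:3]))
  structure(list(data = data, TR = TR, mask = mask,
                 voxel_size = rep_len(voxel_size, 3)),
            class = "bold_image")
}

#' A centered spherical region of activation
#' @param dims 3D grid dimensions.
#' @param radius sphere radius in voxels.
#' @param center voxel coordinates of the centre (defaults to the grid
#'   centre).
#' @return logical 3D array.
#' @export
sphere_mask <- function(dims, radius = 3, center = NULL) {
  if (is.null(center)) center <- (dims + 1) / 2
  co <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  array(d2 <= radius^2, dims)
}

#' Generate synthetic 4D BOLD from the pipeline's own forward model
#'
#' `y(v, t) = sum_r beta_r(v) x_r(t) + noise(v, t)`, where each regressor's
#' beta map is its amplitude inside an active region (and 0 outside), and
#' the noise is temporally AR(1) with spatially smoothed innovations.
#'
#' @param regressors list of `regressor` objects (defines `x_r` and the
#'   number of volumes).
#' @param betas named numeric vector of effect amplitudes, one per regressor
#'   name present in `regressors` (others treated as 0).
#' @param dims 3D grid dimensions (each >= 8).
#' @param active named list of logical 3D arrays (active region per named
#'   beta); defaults to a centred sphere of radius 3 for every named beta.
#' @param ar1 AR(1) coefficient of the noise (default 0.3).
#' @param noise_sd innovation standard deviation (default 1).
#' @param fwhm spatial smoothness (mm FWHM) of the noise (default 4).
#' @param TR repetition time (default 1 s).
#' @param voxel_size voxel edge length in mm (default 2).
#' @param seed integer seed.
#' @return list: `bold` (`bold_image`), `truth` (beta arrays, active masks,
#'   noise parameters, seed).
#' @export
gen_bold <- function(regressors, betas, dims = c(16, 16, 16), active = NULL,
                     ar1 = 0.3, noise_sd = 1, fwhm = 4, TR = 1,
                     voxel_size = 2, seed = 1) {
  if (any(dims < 8)) stop("grid must be at least 8 voxels per axis")
  set.seed(seed)
  n_t <- length(regressors[[1]]$samples)
  nv <- prod(dims)
  if (is.null(active)) {
    active <- stats::setNames(
      replicate(length(betas), sphere_mask(dims), simplify = FALSE),
      names(betas))
  }
  beta_maps <- list()
  signal <- matrix(0, nv, n_t)
  for (r in regressors) {
    b <- if (r$name %in% names(betas)) betas[[r$name]] else 0
    bm <- array(0, dims)
    if (b != 0) bm[active[[r$name]]] <- b
    beta_maps[[r$name]] <- bm
    if (b != 0) signal <- signal + as.vector(bm) %o% r$samples
  }
  noise <- matrix(0, nv, n_t)
  if (noise_sd > 0) {
    sigma_vox <- rep(fwhm / (2 * sqrt(2 * log(2))) / voxel_size, 3)
    innov_sd <- noise_sd * sqrt(1 - ar1^2)
    # smooth all frames at once (time as trailing columns), then run the
    # AR(1) recursion over time per voxel
    innov <- array(stats::rnorm(nv * n_t), c(dims, n_t))
    innov <- .smooth_frames(innov, sigma_vox)
    innov <- innov / stats::sd(innov) * innov_sd
    if (ar1 != 0) {
      noise <- t(stats::filter(t(matrix(innov, nv, n_t)), ar1,
                               method = "recursive"))
    } else {
      noise <- matrix(innov, nv, n_t)
    }
  }
  arr <- array(signal + noise, c(dims, n_t))
  list(bold = bold_image(arr, TR = TR, voxel_size = voxel_size),
       truth = list(beta_maps = beta_maps, active = active, ar1 = ar1,
                    noise_sd = noise_sd, fwhm = fwhm, seed = seed))
}

# Gaussian-smooth every frame of a 4D array spatially (axes 1-3 only).
.smooth_frames <- function(arr4, sigma_vox) {
  dims <- dim(arr4)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- dims[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr4, perm)
    sh <- dim(a)
    a <- K %*% matrix(a, sh[1])
    dim(a) <- sh
    arr4 <- aperm(a, order(perm))
  }
  arr4
}
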