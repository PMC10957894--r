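#' Sensitivity power analysis for the omnibus regression F test
#'
#' Solves for the Cohen's f-squared effect size at which an omnibus multiple
#' regression F test with `u` predictors and `n` observations attains the
#' target power, using the exact noncentral F distribution with numerator df
#' `u`, denominator df `v = n - u - 1`, and noncentrality
#' `lambda = f2 * (u + v + 1)`.
#'
#' @param u number of predictors (numerator df).
#' @param n sample size.
#' @param alpha significance level.
#' @param power target power.
#' @return list of class `sensitivity_spec`: `u`, `n`, `v`, `alpha`, `power`,
#'   `f2`.
#' @export
sensitivity_f2 <- function(u, n, alpha = 0.05, power = 0.95) {
  stopifnot(u >= 1, n > u + 1, alpha > 0, alpha < 1, power > 0, power < 1)
  v <- n - u - 1
  crit <- stats::qf(1 - alpha, u, v)
  pow <- function(f2) {
    stats::pf(crit, u, v, ncp = f2 * (u + v + 1), lower.tail = FALSE)
  }
  if (pow(100) < power) stop("target power unattainable")
  f2 <- stats::uniroot(function(x) pow(x) - power, c(1e-10, 100),
                       tol = 1e-9)$root
  structure(list(u = u, n = n, v = v, alpha = alpha, power = power, f2 = f2),
            class = "sensitivity_spec")
}

#' Simulate a complete synthetic study
#'
#' Generates every input of the pipeline with known ground truth: a lexicon
#' with planted factor structure, embeddings, social norms, per-movie event
#' tables and transcripts, and per-subject 4D BOLD produced by the pipeline's
#' own forward model with the requested effect amplitudes on the event-level
#' regressors.
#'
#' @param n_movies number of movies (>= 2 for movie variance estimation).
#' @param subjects_per_movie subjects watching each movie.
#' @param n_events events per movie (pre-merge).
#' @param dims BOLD grid dimensions.
#' @param effects named numeric vector of forward-model amplitudes; names
#'   among `"semantic_modulated"`, `"social_modulated"`, `"event_baseline"`.
#'   An empty vector gives null data.
#' @param active optional named list of logical active-region masks (defaults
#'   to a centred sphere, shared across effects).
#' @param TR repetition time (default 1 s).
#' @param noise_sd,ar1,fwhm noise parameters passed to [gen_bold()].
#' @param lexicon_n,missing_rate lexicon size and missingness.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `synthetic_study`: `lexicon`, `embeddings`,
#'   `social_norms`, `movies` (per movie: `events_raw`, `events` (merged),
#'   `transcript`, `n_volumes`), `subjects` (per subject: `id`, `movie`,
#'   `bold`, `truth`), `design` (`group_design`), `seed`.
#' @export
simulate_study <- function(n_movies = 2, subjects_per_movie = 3,
                           n_events = 60, dims = c(16, 16, 16),
                           effects = c(semantic_modulated = 0),
                           active = NULL, TR = 1, noise_sd = 1, ar1 = 0.3,
                           fwhm = 4, lexicon_n = 400, missing_rate = 0.1,
                           seed = 1) {
  lex <- gen_lexicon(lexicon_n, missing_rate = missing_rate, seed = seed)
  emb <- gen_embeddings(lex, seed = seed + 11)
  # social norms: a normed subset of the lexicon (true socialness as ratings)
  set.seed(seed + 13)
  normed <- sample(nrow(lex$truth$complete), min(200, lexicon_n %/% 2))
  social <- data.frame(word = lex$truth$complete$word[normed],
                       mean_rating = pmin(pmax(
                         lex$truth$complete$socialness[normed], 1), 5),
                       n_raters = 34)

  movies <- list()
  for (m in seq_len(n_movies)) {
    ev <- gen_events(n_events, movie_id = paste0("movie", m),
                     seed = seed + 100 * m)
    merged <- merge_short_events(ev$table)
    tr <- gen_transcript(ev, lex, seed = seed + 100 * m + 1)
    total <- max(merged$onset + merged$duration)
    movies[[paste0("movie", m)]] <- list(
      events_raw = ev$table, events = merged, transcript = tr,
      truth = ev$truth, n_volumes = ceiling(total / TR) + 8
    )
  }

  if (is.null(active) && length(effects) > 0) {
    active <- stats::setNames(
      replicate(length(effects), sphere_mask(dims), simplify = FALSE),
      names(effects))
  }

  subjects <- list()
  sid <- 0
  for (m in seq_len(n_movies)) {
    mv <- paste0("movie", m)
    regs <- duration_modulated_regressor(
      movies[[mv]]$events, which = "semantic", TR = TR,
      n_volumes = movies[[mv]]$n_volumes)
    # rename so both semantic and social modulations can carry effects
    regs$nuisance$name <- "social_modulated"
    regs$modulated$name <- "semantic_modulated"
    for (s in seq_len(subjects_per_movie)) {
      sid <- sid + 1
      gb <- gen_bold(regs, betas = effects, dims = dims, active = active,
                     ar1 = ar1, noise_sd = noise_sd, fwhm = fwhm, TR = TR,
                     seed = seed + 1000 * sid)
      subjects[[sprintf("sub-%02d", sid)]] <- list(
        id = sprintf("sub-%02d", sid), movie = mv, bold = gb$bold,
        truth = gb$truth)
    }
  }
  design <- group_design(names(subjects),
                         vapply(subjects, `[[`, character(1), "movie"))
  structure(list(lexicon = lex, embeddings = emb, social_norms = social,
                 movies = movies, subjects = subjects, design = design,
                 effects = effects, seed = seed),
            class = "synthetic_study")
}

# Memoized Monte-Carlo cluster threshold: synthetic subjects typically share
# (near-)identical residual smoothness, so thresholds are cached on rounded
# smoothness, mask size, rule and simulation count.
.cluster_cache <- new.env(parent = emptyenv())

cluster_size_threshold_cached <- function(smoothness, mask, rule, n_sim,
                                          seed, voxel_size = 2) {
  key <- paste(paste(round(as.numeric(smoothness) * 4) / 4, collapse = ","),
               sum(mask), rule$cluster_forming_p, rule$fwe_p, rule$sided,
               n_sim, sep = "|")
  if (!is.null(.cluster_cache[[key]])) return(.cluster_cache[[key]])
  k <- cluster_size_threshold(smoothness, mask, rule, n_sim = n_sim,
                              seed = seed, voxel_size = voxel_size)
  .cluster_cache[[key]] <- k
  k
}

#' Build the word-level predictor series for one movie
#'
#' Runs the full word-level feature pipeline (assembly, imputation, PCA with
#' varimax, factor scoring) once across all movie transcripts, then returns
#' the per-movie smoothed series: residualized factor time courses for
#' Semantic Flexibility and Social Impact (empty windows dropped) and the
#' content-word count series (zeros kept).
#'
#' @param study `synthetic_study` (or a compatible list of inputs).
#' @param m imputations (default 5).
#' @param seed seed for imputation.
#' @return list per movie: `semantic_flexibility`, `social_impact`
#'   (residualized `window_series`), `content_words` (`window_series`),
#'   plus the shared `scores` and `model`.
#' @export
build_word_predictors <- function(study, m = 5, seed = 1) {
  all_words <- do.call(rbind, lapply(study$movies, function(mv)
    mv$transcript[, c("word", "pos")]))
  tab <- assemble_word_table(all_words, study$lexicon$table,
                             social = study$social_norms,
                             embeddings = study$embeddings)
  imp <- impute_chained(tab, m = m, seed = seed)
  model <- fit_pca_varimax(imp)
  scores <- score_factors(model, imp)

  out <- list()
  for (mv in names(study$movies)) {
    tr <- study$movies[[mv]]$transcript
    ev <- study$movies[[mv]]$events
    si <- match(tolower(tr$word), scores$word)
    series <- list()
    # total words per window (all transcript words), shared grid
    totals <- window_sums(data.frame(onset = tr$onset,
                                     value = rep(1, nrow(tr))), ev)
    for (f in c("SemanticFlexibility", "SocialImpact")) {
      has <- !is.na(si) & !is.na(scores[[f]][si])
      wv <- data.frame(onset = tr$onset[has], value = scores[[f]][si[has]])
      ws <- window_sums(wv, ev)
      # windows with no scored words are removed before residualization so
      # the residuals are orthogonal to counts on the analysed windows
      keep <- !ws$empty
      if (!any(keep)) stop("all windows empty for ", f, " in ", mv)
      series[[f]] <- residualize(ws[keep, , drop = FALSE],
                                 totals[keep, , drop = FALSE])
    }
    cw <- content_word_counts(tr, ev)
    out[[mv]] <- list(semantic_flexibility = series$SemanticFlexibility,
                      social_impact = series$SocialImpact,
                      content_words = cw)
  }
  list(movies = out, scores = scores, model = model)
}

#' Run the word-level analysis end to end
#'
#' For the selected word content type, builds the smoothed predictor series,
#' constructs the HRF-convolved parametric modulator per movie, fits the
#' subject-level GLMs, the group mixed-effects map, and applies Monte-Carlo
#' cluster-extent FWE correction.
#'
#' @param study `synthetic_study`.
#' @param content `"content_words"`, `"semantic_flexibility"`, or
#'   `"social_impact"`.
#' @param predictors optional precomputed result of
#'   [build_word_predictors()] (rebuilt otherwise).
#' @param rule `cluster_rule`.
#' @param n_sim Monte-Carlo simulations for the cluster threshold.
#' @param seed integer seed.
#' @param out_dir optional directory: maps and cluster tables are written
#'   there (NIfTI/TSV) with a provenance JSON.
#' @return list of class `analysis_result`: `content`, `subject_tmaps`,
#'   `subject_smoothness`, `group_map`, `thresholded`, `clusters`, `k_min`.
#' @export
run_words_analysis <- function(study, content = c("content_words",
                                                  "semantic_flexibility",
                                                  "social_impact"),
                               predictors = NULL, rule = cluster_rule(),
                               n_sim = 1000, seed = 1, out_dir = NULL) {
  content <- match.arg(content)
  if (is.null(predictors)) predictors <- build_word_predictors(study, seed = seed)

  subject_tmaps <- list()
  smooth_list <- list()
  for (sn in names(study$subjects)) {
    sub <- study$subjects[[sn]]
    series <- predictors$movies[[sub$movie]][[content]]
    n_vol <- dim(sub$bold$data)[4]
    reg <- parametric_regressor(series, TR = sub$bold$TR, n_volumes = n_vol,
                                name = content)
    fit <- fit_first_level(sub$bold, list(reg))
    subject_tmaps[[sn]] <- fit$tmaps[[content]]
    smooth_list[[sn]] <- estimate_smoothness(fit$residuals, sub$bold$mask,
                                             sub$bold$voxel_size)
  }
  .finish_group_analysis(study, content, subject_tmaps, smooth_list, rule,
                         n_sim, seed, out_dir)
}

#' Run the event-level (duration-modulated) analysis end to end
#'
#' Builds the duration-modulated regressor set per movie (baseline boxcar,
#' rating-modulated regressor, other-rating nuisance), fits subject GLMs with
#' the modulated regressor as the statistic of interest, then the group map
#' and cluster correction. `which = "scrambled"` scrambles both rating
#' columns first (null comparison condition).
#'
#' @param study `synthetic_study`.
#' @param which `"semantic"`, `"social"`, or `"scrambled"`.
#' @param scramble_seed seed for the scrambled condition.
#' @inheritParams run_words_analysis
#' @return `analysis_result` (see [run_words_analysis()]); for the
#'   primary and strict FWE variants see `thresholded` and
#'   `thresholded_strict`.
#' @export
run_events_analysis <- function(study, which = c("semantic", "social",
                                                 "scrambled"),
                                rule = cluster_rule(), n_sim = 1000,
                                seed = 1, scramble_seed = 1, out_dir = NULL) {
  which <- match.arg(which)
  content <- paste0(if (which == "scrambled") "scrambled" else which,
                    "_events")
  subject_tmaps <- list()
  smooth_list <- list()
  reg_cache <- list()
  for (sn in names(study$subjects)) {
    sub <- study$subjects[[sn]]
    mv <- sub$movie
    if (is.null(reg_cache[[mv]])) {
      ev <- study$movies[[mv]]$events
      rating <- which
      if (which == "scrambled") {
        ev <- scramble_ratings(ev, "both", seed = scramble_seed)
        rating <- "semantic"
      }
      n_vol <- study$movies[[mv]]$n_volumes
      reg_cache[[mv]] <- duration_modulated_regressor(
        ev, which = rating, TR = sub$bold$TR, n_volumes = n_vol)
    }
    regs <- reg_cache[[mv]]
    fit <- fit_first_level(sub$bold, regs)
    subject_tmaps[[sn]] <- fit$tmaps[[regs$modulated$name]]
    smooth_list[[sn]] <- estimate_smoothness(fit$residuals, sub$bold$mask,
                                             sub$bold$voxel_size)
  }
  res <- .finish_group_analysis(study, content, subject_tmaps, smooth_list,
                                rule, n_sim, seed, out_dir)
  # strict FWE variant (same forming threshold, FWE p = 0.01)
  strict_rule <- cluster_rule(rule$cluster_forming_p, 0.01, rule$sided)
  med <- apply(do.call(rbind, lapply(smooth_list, as.numeric)), 2,
               stats::median)
  k_strict <- cluster_size_threshold_cached(
    structure(med, class = "smoothness_estimate"),
    study$subjects[[1]]$bold$mask, strict_rule, n_sim, seed + 7,
    voxel_size = study$subjects[[1]]$bold$voxel_size[1])
  st <- apply_cluster_threshold(res$group_map, strict_rule,
                                k_min = as.integer(k_strict))
  res$thresholded_strict <- st$map
  res$clusters_strict <- st$clusters
  res$k_min_strict <- as.integer(k_strict)
  res
}

.finish_group_analysis <- function(study, content, subject_tmaps, smooth_list,
                                   rule, n_sim, seed, out_dir) {
  design <- study$design
  design$content <- content
  group_map <- fit_group_map(subject_tmaps, design)
  med <- apply(do.call(rbind, lapply(smooth_list, as.numeric)), 2,
               stats::median)
  mask <- study$subjects[[1]]$bold$mask
  vs <- study$subjects[[1]]$bold$voxel_size[1]
  k_min <- cluster_size_threshold_cached(
    structure(med, class = "smoothness_estimate"), mask, rule, n_sim,
    seed + 3, voxel_size = vs)
  th <- apply_cluster_threshold(group_map, rule, k_min = as.integer(k_min))
  res <- structure(list(content = content, subject_tmaps = subject_tmaps,
                        subject_smoothness = smooth_list,
                        group_map = group_map, thresholded = th$map,
                        clusters = th$clusters, k_min = as.integer(k_min),
                        rule = rule),
                   class = "analysis_result")
  if (!is.null(out_dir)) .write_analysis(res, study, seed, out_dir)
  res
}

.write_analysis <- function(res, study, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_nifti_map(res$group_map,
                  file.path(out_dir, paste0(res$content, "_group_z.nii.gz")))
  write_nifti_map(res$thresholded,
                  file.path(out_dir, paste0(res$content, "_thresholded.nii.gz")))
  utils::write.table(res$clusters,
                     file.path(out_dir, paste0(res$content, "_clusters.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  prov <- list(content = res$content, seed = seed, study_seed = study$seed,
               k_min = res$k_min,
               rule = res$rule[c("cluster_forming_p", "fwe_p", "sided")],
               n_subjects = length(study$subjects),
               timestamp_free = TRUE)
  jsonlite::write_json(prov, file.path(out_dir,
                                       paste0(res$content, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Subject-level thresholding and cross-system overlap analysis
#'
#' Thresholds each subject's statistical maps for two content types with
#' subject-specific Monte-Carlo cluster-size thresholds derived from that
#' subject's residual smoothness, quantifies per-subject overlap (voxel
#' count, Dice, functional-zero rule), builds normalized statistical overlap
#' maps (thresholded map / max t, multiplied across conditions), and fits the
#' group random-effects model to the overlap maps.
#'
#' @param res_a,res_b `analysis_result` objects for the two content types
#'   (e.g. semantic events and social events), from the same study.
#' @param study the `synthetic_study` both results came from.
#' @param rule `cluster_rule` for subject-level thresholding.
#' @param n_sim Monte-Carlo simulations per distinct smoothness.
#' @param seed integer seed.
#' @return list of class `overlap_analysis`: `per_subject` (data frame:
#'   subject, n_overlap_voxels, dice, functional_zero), `overlap_maps`,
#'   `group_overlap` (z map with anti-conservative note),
#'   `thresholded_group_overlap`, `k_min_group`.
#' @export
run_overlap_analysis <- function(res_a, res_b, study, rule = cluster_rule(),
                                 n_sim = 500, seed = 1) {
  subjects <- names(res_a$subject_tmaps)
  stopifnot(identical(subjects, names(res_b$subject_tmaps)))
  mask <- study$subjects[[1]]$bold$mask
  vs <- study$subjects[[1]]$bold$voxel_size[1]

  per_subject <- list()
  overlap_maps <- list()
  for (sn in subjects) {
    th <- list()
    for (side in c("a", "b")) {
      res <- if (side == "a") res_a else res_b
      k <- cluster_size_threshold_cached(res$subject_smoothness[[sn]], mask,
                                         rule, n_sim, seed + 17,
                                         voxel_size = vs)
      t_th <- apply_cluster_threshold(res$subject_tmaps[[sn]], rule,
                                      k_min = as.integer(k))$map
      # overlap analysis follows the positive-cluster convention
      t_th$data[t_th$data < 0] <- 0
      th[[side]] <- t_th
    }
    ov <- overlap_voxels(th$a$data != 0, th$b$data != 0)
    per_subject[[sn]] <- data.frame(
      subject = sn, n_overlap_voxels = ov$n_overlap_voxels, dice = ov$dice,
      functional_zero = ov$functional_zero, stringsAsFactors = FALSE)
    na <- suppressWarnings(normalize_stat_map(th$a))
    nb <- suppressWarnings(normalize_stat_map(th$b))
    overlap_maps[[sn]] <- statistical_overlap_map(na, nb)
  }
  group_overlap <- group_overlap_rfx(overlap_maps, study$design)
  med <- apply(do.call(rbind, lapply(res_a$subject_smoothness, as.numeric)),
               2, stats::median)
  k_g <- cluster_size_threshold_cached(
    structure(med, class = "smoothness_estimate"), mask,
    cluster_rule(rule$cluster_forming_p, rule$fwe_p, "one.sided"),
    n_sim, seed + 19, voxel_size = vs)
  th_g <- apply_cluster_threshold(
    group_overlap, cluster_rule(rule$cluster_forming_p, rule$fwe_p,
                                "one.sided"),
    k_min = as.integer(k_g))
  structure(list(per_subject = do.call(rbind, per_subject),
                 overlap_maps = overlap_maps,
                 group_overlap = group_overlap,
                 thresholded_group_overlap = th_g$map,
                 group_overlap_clusters = th_g$clusters,
                 k_min_group = as.integer(k_g)),
            class = "overlap_analysis")
}
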