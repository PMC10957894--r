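#' Canonical double-gamma hemodynamic response function
#'
#' Double-gamma kernel (positive response plus undershoot) sampled at `dt`,
#' truncated at `duration` seconds and scaled to unit peak. The positive lobe
#' peaks at `peak` seconds and the undershoot at `undershoot` seconds.
#'
#' @param dt sampling interval in seconds.
#' @param peak time-to-peak of the positive lobe (default 5 s).
#' @param undershoot time-to-peak of the undershoot (default 15 s).
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#' @param duration kernel length in seconds (default 32).
#' @return numeric kernel vector.
#' @export
canonical_hrf <- function(dt, peak = 5, undershoot = 15, ratio = 6,
                          duration = 32) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  a1 <- 6; a2 <- 16
  b1 <- (a1 - 1) / peak           # gamma mode = (shape-1)/rate
  b2 <- (a2 - 1) / undershoot
  h <- stats::dgamma(t, shape = a1, rate = b1) -
    stats::dgamma(t, shape = a2, rate = b2) / ratio
  h / max(h)
}

# Convolve a fine-grid (dt) stimulus vector with the HRF and sample at the
# TR grid (volume acquisition times 0, TR, 2TR, ...).
.convolve_sample <- function(stim_fine, dt, TR, n_volumes, hrf = NULL, ...) {
  if (is.null(hrf)) hrf <- canonical_hrf(dt, ...)
  conv <- stats::convolve(stim_fine, rev(hrf), type = "open")[seq_along(stim_fine)] * dt
  idx <- round((seq_len(n_volumes) - 1) * TR / dt) + 1
  if (max(idx) > length(conv)) stop("scan grid extends beyond the stimulus grid")
  conv[idx]
}

#' Build a parametric-modulation regressor from a window series
#'
#' Window values are mean-centered over the retained windows, placed as
#' impulses at the window start times on a fine (`dt`) grid, convolved with
#' the canonical HRF and sampled at the TR grid. Centering decorrelates the
#' "how much content" modulation from the mere presence of windows.
#'
#' @param series `window_series` (empty windows should already be dropped for
#'   factor predictors).
#' @param TR repetition time in seconds.
#' @param n_volumes number of BOLD volumes.
#' @param dt oversampled convolution grid (default 0.1 s).
#' @param center mean-center the modulator (default TRUE).
#' @param name regressor name.
#' @param hrf optional pre-computed kernel sampled at `dt`.
#' @return list of class `regressor`: `name`, `samples` (length `n_volumes`),
#'   `kind`.
#' @export
parametric_regressor <- function(series, TR, n_volumes, dt = 0.1,
                                 center = TRUE, name = "modulator",
                                 hrf = NULL) {
  t_max <- (n_volumes - 1) * TR
  if (any(series$start > t_max + 1e-9)) {
    stop("window start times extend beyond the scan")
  }
  vals <- series$value
  if (center) vals <- vals - mean(vals)
  n_fine <- ceiling(t_max / dt) + 1
  stim <- numeric(n_fine)
  idx <- round(series$start / dt) + 1
  for (i in seq_along(idx)) stim[idx[i]] <- stim[idx[i]] + vals[i]
  samples <- .convolve_sample(stim, dt, TR, n_volumes, hrf = hrf)
  structure(list(name = name, samples = samples, kind = "amplitude"),
            class = "regressor")
}

#' Duration-modulated event regressors
#'
#' Builds the three regressors of the duration-modulated event model: an
#' unmodulated baseline (boxcars spanning each event's onset and duration),
#' a rating-modulated regressor (boxcars scaled by the mean-centered chosen
#' rating), and a nuisance regressor (boxcars scaled by the mean-centered
#' other rating). All three are HRF-convolved and sampled at the TR grid.
#'
#' @param table merged `event_table` for one movie.
#' @param which `"semantic"` or `"social"`: the rating of interest; the other
#'   becomes the nuisance regressor.
#' @param TR,n_volumes,dt as in [parametric_regressor()].
#' @return named list of three `regressor` objects: `baseline`, `modulated`,
#'   `nuisance`.
#' @export
duration_modulated_regressor <- function(table, which = c("semantic", "social"),
                                         TR, n_volumes, dt = 0.1) {
  which <- match.arg(which)
  other <- if (which == "semantic") "social" else "semantic"
  t_max <- (n_volumes - 1) * TR
  n_fine <- ceiling(t_max / dt) + 1
  hrf <- canonical_hrf(dt)

  boxcar <- function(amp) {
    stim <- numeric(n_fine)
    for (i in seq_len(nrow(table))) {
      a <- round(table$onset[i] / dt) + 1
      b <- min(round((table$onset[i] + table$duration[i]) / dt), n_fine)
      if (a <= b) stim[a:b] <- stim[a:b] + amp[i]
    }
    stim
  }
  mk <- function(amp, name, kind) {
    structure(list(name = name,
                   samples = .convolve_sample(boxcar(amp), dt, TR, n_volumes,
                                              hrf = hrf),
                   kind = kind), class = "regressor")
  }
  list(
    baseline = mk(rep(1, nrow(table)), "event_baseline", "baseline"),
    modulated = mk(table[[which]] - mean(table[[which]]),
                   paste0(which, "_modulated"), "duration"),
    nuisance = mk(table[[other]] - mean(table[[other]]),
                  paste0(other, "_nuisance"), "nuisance")
  )
}

#' Voxelwise first-level GLM
#'
#' Ordinary least squares of every in-mask voxel time series on the supplied
#' regressors plus polynomial drift columns (order 0 = intercept only; the
#' input data are assumed detrended upstream). Censored volumes, if any, are
#' dropped from the fit. Returns beta and t maps for each regressor of
#' interest, plus the residual 4D array for smoothness estimation.
#'
#' @param bold `bold_image` (list with 4D `data`, `TR`, logical 3D `mask`,
#'   `voxel_size` in mm), e.g. from [gen_bold()] or [read_bold()].
#' @param regressors list of `regressor` objects.
#' @param drift_order polynomial drift order (default 0).
#' @param censor optional logical/0-1 vector, TRUE/1 = keep volume.
#' @return list: `betas` and `tmaps` (named lists of `stat_map`), `df`,
#'   `residuals` (4D array, censored volumes set to 0), `design` (matrix).
#' @export
fit_first_level <- function(bold, regressors, drift_order = 0, censor = NULL) {
  dims <- dim(bold$data)
  n_t <- dims[4]
  mask <- bold$mask
  X <- cbind(Intercept = rep(1, n_t))
  if (drift_order > 0) {
    tt <- seq_len(n_t) / n_t
    for (d in seq_len(drift_order)) X <- cbind(X, stats::poly(tt, d)[, d])
    colnames(X) <- c("Intercept", paste0("drift", seq_len(drift_order)))
  }
  for (r in regressors) {
    if (length(r$samples) != n_t) stop("regressor '", r$name, "' length mismatch")
    X <- cbind(X, r$samples)
    colnames(X)[ncol(X)] <- r$name
  }
  keep <- if (is.null(censor)) rep(TRUE, n_t) else as.logical(censor)
  Xk <- X[keep, , drop = FALSE]
  qrX <- qr(Xk)
  if (qrX$rank < ncol(Xk)) {
    dropped <- colnames(Xk)[qrX$pivot[(qrX$rank + 1):ncol(Xk)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  Y <- matrix(bold$data, prod(dims[1:3]), n_t)
  vox <- which(as.vector(mask))
  Yk <- t(Y[vox, keep, drop = FALSE])
  beta <- qr.coef(qrX, Yk)
  resid <- Yk - Xk %*% beta
  df <- sum(keep) - ncol(Xk)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- solve(crossprod(Xk))
  se <- sqrt(outer(diag(XtXinv), sigma2))
  tval <- beta / se

  interest <- vapply(regressors, function(r) r$name, character(1))
  mk_map <- function(vals, kind) {
    arr <- array(0, dims[1:3])
    arr[vox] <- vals
    stat_map(arr, kind = kind, df = df, mask = mask,
             voxel_size = bold$voxel_size)
  }
  betas <- tmaps <- list()
  for (nm in interest) {
    betas[[nm]] <- mk_map(beta[nm, ], "beta")
    tmaps[[nm]] <- mk_map(tval[nm, ], "t")
  }
  res4d <- array(0, dims)
  Rfull <- matrix(0, prod(dims[1:3]), n_t)
  Rfull[vox, keep] <- t(resid)
  res4d[] <- Rfull
  list(betas = betas, tmaps = tmaps, df = df, residuals = res4d, design = X)
}

#' Construct a statistical map
#'
#' @param data 3D array of statistic values (zero outside the mask).
#' @param kind `"t"`, `"z"`, or `"beta"`.
#' @param df degrees of freedom (NA for z/beta).
#' @param mask logical 3D array.
#' @param voxel_size voxel edge length(s) in mm.
#' @return list of class `stat_map`.
#' @export
stat_map <- function(data, kind = "t", df = NA_real_, mask = NULL,
                     voxel_size = 2) {
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  data[!mask] <- 0
  structure(list(data = data, kind = kind, df = df, mask = mask,
                 voxel_size = rep_len(voxel_size, 3)),
            class = "stat_map")
}

#' Estimate residual spatial smoothness (Gaussian-equivalent FWHM)
#'
#' Per-axis smoothness of the first-level residuals, estimated from the
#' lag-one spatial autocorrelation of standardized residuals (variance of
#' first differences between in-mask neighbours, pooled over time) under a
#' Gaussian autocorrelation model. The reported FWHM composes the implied
#' smoothing kernel with the voxel width in quadrature, so unsmoothed white
#' noise reports approximately one voxel.
#'
#' @param residuals 4D residual array (or `bold_image` whose `data` holds
#'   residuals).
#' @param mask logical 3D array.
#' @param voxel_size voxel edge length(s) in mm.
#' @return numeric length-3 vector of FWHM (mm) per axis, class
#'   `smoothness_estimate`.
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size = 2) {
  arr <- if (is.list(residuals)) residuals$data else residuals
  dims <- dim(arr)
  if (dims[4] < 10) stop("need at least 10 time points")
  if (sum(mask) < 100) stop("mask too small (< 100 voxels)")
  voxel_size <- rep_len(voxel_size, 3)

  # standardize each voxel's residual series to unit variance
  V <- matrix(arr, prod(dims[1:3]), dims[4])
  vox <- which(as.vector(mask))
  sds <- sqrt(rowMeans(V[vox, ]^2))
  sds[sds == 0] <- 1
  V[vox, ] <- V[vox, ] / sds

  fwhm <- numeric(3)
  for (ax in 1:3) {
    # index pairs of face neighbours along this axis, both inside the mask
    idx <- arrayInd(vox, dims[1:3])
    nb <- idx
    nb[, ax] <- nb[, ax] + 1
    ok <- nb[, ax] <= dims[ax]
    lin_a <- vox[ok]
    lin_b <- (nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
                (nb[ok, 3] - 1) * dims[1] * dims[2])
    ok2 <- as.vector(mask)[lin_b]
    a <- V[lin_a[ok2], , drop = FALSE]
    b <- V[lin_b[ok2], , drop = FALSE]
    if (nrow(a) == 0) { fwhm[ax] <- voxel_size[ax]; next }
    vdiff <- mean((a - b)^2)
    vavg <- (mean(a^2) + mean(b^2)) / 2
    rho <- 1 - vdiff / (2 * vavg)
    d <- voxel_size[ax]
    if (rho <= 0) {
      fwhm[ax] <- d
    } else {
      sigma_k <- sqrt(-d^2 / (4 * log(rho)))   # Gaussian ACF model
      fwhm_k <- 2 * sqrt(2 * log(2)) * sigma_k
      fwhm[ax] <- sqrt(fwhm_k^2 + d^2)
    }
  }
  structure(fwhm, class = "smoothness_estimate")
}
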