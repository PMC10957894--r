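#' Group design
#'
#' Subject-to-movie assignment for the second-level analysis. Each subject
#' watched exactly one movie; at least two movies are needed to estimate the
#' movie variance component.
#'
#' @param subjects character vector of subject ids.
#' @param movies character vector, same length: the movie each subject saw.
#' @param content label of the content type being analysed.
#' @return list of class `group_design`.
#' @export
group_design <- function(subjects, movies, content = "content") {
  if (length(subjects) != length(movies)) stop("subjects and movies differ in length")
  if (anyDuplicated(subjects)) stop("duplicate subject ids")
  structure(list(subjects = as.character(subjects),
                 movies = as.character(movies),
                 content = content),
            class = "group_design")
}

# Profiled REML for the voxelwise one-way random-intercept model
# y_sj = mu + b_j + e_sj, b_j ~ N(0, tau * sigma2), e ~ N(0, sigma2).
# Returns mu_hat, its SE, the REML tau, and the residual df used for the
# t -> z conversion.
.reml_intercept <- function(y, g, nj, groups) {
  n <- length(y)
  J <- length(groups)
  sums <- vapply(groups, function(gr) sum(y[g == gr]), numeric(1))

  neg_reml <- function(ltau) {
    tau <- exp(ltau)
    w <- 1 / (1 + nj * tau)               # group shrinkage weights
    # GLS mean under V = sigma2 * (I + tau Z Z')
    sw <- sum(nj * w)
    mu <- sum(w * sums) / sw
    # quadratic form y' V^{-1} y with V scaled by sigma2
    rss <- sum(y^2) - sum((1 - w) * sums^2 / nj) -
      2 * mu * sum(w * sums) + mu^2 * sw
    sigma2 <- rss / (n - 1)
    # REML log-likelihood (up to constants): -0.5*[ (n-1) log sigma2
    #   + sum log(1 + nj tau) + log sum(nj w) + rss/sigma2 ]
    0.5 * ((n - 1) * log(sigma2) + sum(log(1 + nj * tau)) + log(sw))
  }

  opt <- stats::optimize(neg_reml, c(log(1e-8), log(1e4)))
  tau <- exp(opt$minimum)
  if (neg_reml(log(1e-10)) <= opt$objective + 1e-10) tau <- 0  # boundary
  w <- 1 / (1 + nj * tau)
  sw <- sum(nj * w)
  mu <- sum(w * sums) / sw
  rss <- sum(y^2) - sum((1 - w) * sums^2 / nj) -
    2 * mu * sum(w * sums) + mu^2 * sw
  sigma2 <- rss / (n - 1)
  se <- sqrt(sigma2 / sw)
  df <- if (tau <= 1e-7) n - 1 else J - 1
  list(mu = mu, se = se, tau = tau, sigma2 = sigma2, df = df)
}

.t_to_z <- function(t, df) {
  z <- sign(t) * stats::qnorm(stats::pt(abs(t), df, lower.tail = FALSE),
                              lower.tail = FALSE)
  pmin(pmax(z, -40), 40)
}

#' Voxelwise group mixed-effects map
#'
#' Fits, at every in-mask voxel, an intercept-only linear mixed model to the
#' subject-level statistic values with a random intercept of movie (REML).
#' Because each subject contributes exactly one observation per voxel, a
#' separate subject intercept is not identifiable and is absorbed by the
#' residual. The fixed-effect estimate is converted to a z statistic via the
#' t distribution (df = movies - 1 when the movie variance is positive,
#' df = n - 1 when it collapses to zero, in which case the statistic equals
#' the one-sample t). Degenerate voxels (zero variance) are capped at |z| = 40
#' with a warning.
#'
#' @param maps list of subject `stat_map`s on a common grid (one per subject,
#'   in `design$subjects` order).
#' @param design `group_design`.
#' @return `stat_map` of kind `"z"`.
#' @export
fit_group_map <- function(maps, design) {
  if (length(maps) < 3) stop("need at least 3 subjects")
  if (length(maps) != length(design$subjects)) {
    stop("one map per subject required")
  }
  dims <- dim(maps[[1]]$data)
  for (m in maps) if (!identical(dim(m$data), dims)) stop("map grid mismatch")
  mask <- maps[[1]]$mask
  vox <- which(as.vector(mask))
  Y <- vapply(maps, function(m) as.vector(m$data)[vox], numeric(length(vox)))
  # Y: voxels x subjects
  g <- design$movies
  groups <- unique(g)
  nj <- as.numeric(table(factor(g, levels = groups)))

  n <- ncol(Y)
  z <- numeric(length(vox))
  capped <- FALSE
  if (length(groups) < 2) {
    # degenerate grouping: one-sample t test per voxel
    mu <- rowMeans(Y)
    se <- sqrt(apply(Y, 1, stats::var) / n)
    tt <- mu / se
    zerovar <- se == 0
    tt[zerovar & mu == 0] <- 0
    if (any(zerovar & mu != 0)) {
      tt[zerovar & mu != 0] <- sign(mu[zerovar & mu != 0]) * Inf
      capped <- TRUE
    }
    z <- .t_to_z(tt, n - 1)
  } else {
    for (i in seq_along(vox)) {
      y <- Y[i, ]
      if (stats::var(y) == 0) {
        z[i] <- if (mean(y) == 0) 0 else sign(mean(y)) * 40
        if (mean(y) != 0) capped <- TRUE
        next
      }
      f <- .reml_intercept(y, g, nj, groups)
      z[i] <- .t_to_z(f$mu / f$se, f$df)
    }
  }
  if (capped) warning("degenerate voxels with zero variance: z capped at +/-40")
  arr <- array(0, dims)
  arr[vox] <- z
  stat_map(arr, kind = "z", df = NA_real_, mask = mask,
           voxel_size = maps[[1]]$voxel_size)
}

#' Cluster rule
#'
#' Parameters of cluster-extent familywise-error correction: voxelwise
#' cluster-forming p threshold, FWE level, faces-only (NN = 1) connectivity,
#' and sidedness of the forming threshold ("bisided": positive and negative
#' supra-threshold voxels form separate clusters).
#'
#' @param cluster_forming_p voxelwise threshold (default 0.01).
#' @param fwe_p familywise error level (default 0.05; strict variant 0.01).
#' @param sided `"bisided"` (default) or `"one.sided"` (positive tail only).
#' @return list of class `cluster_rule`.
#' @export
cluster_rule <- function(cluster_forming_p = 0.01, fwe_p = 0.05,
                         sided = c("bisided", "one.sided")) {
  stopifnot(cluster_forming_p > 0, cluster_forming_p < 1,
            fwe_p > 0, fwe_p < 1)
  structure(list(cluster_forming_p = cluster_forming_p, fwe_p = fwe_p,
                 connectivity = 1L, sided = match.arg(sided)),
            class = "cluster_rule")
}

# Label connected components of a logical 3D array under faces-only (NN=1)
# adjacency. Returns an integer array (0 = background).
label_clusters <- function(x) {
  dims <- dim(x)
  lab <- array(0L, dims)
  idx <- which(x)
  if (length(idx) == 0) return(lab)
  coords <- arrayInd(idx, dims)
  inset <- array(FALSE, dims); inset[idx] <- TRUE
  nxt <- 0L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, dims)
      nb <- integer(0)
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        ok <- co[, ax] + dlt >= 1L & co[, ax] + dlt <= dims[ax]
        if (!any(ok)) next
        cand <- frontier[ok] + dlt * strides[ax]
        nb <- c(nb, cand)
      }
      nb <- unique(nb)
      nb <- nb[inset[nb] & lab[nb] == 0L]
      lab[nb] <- nxt
      frontier <- nb
    }
  }
  lab
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
.smooth3d <- function(arr, sigma_vox) {
  dims <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    n <- dims[ax]
    # dense convolution matrix along this axis (small n, cheap)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    sh <- dim(a)
    a <- K %*% matrix(a, sh[1])
    dim(a) <- sh
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Monte-Carlo minimum cluster size for FWE correction
#'
#' Simulates Gaussian null fields at the given smoothness inside the mask,
#' applies the cluster-forming threshold, records the maximum cluster size of
#' each simulated field, and returns the smallest cluster size k such that the
#' proportion of null fields with any cluster of at least k voxels does not
#' exceed the FWE level.
#'
#' @param smoothness `smoothness_estimate` (FWHM per axis, mm, voxel-composed
#'   as produced by [estimate_smoothness()]).
#' @param mask logical 3D array.
#' @param rule `cluster_rule`.
#' @param n_sim number of simulated fields (>= 1000 for production use).
#' @param seed integer seed.
#' @param voxel_size voxel edge length(s) in mm.
#' @return integer minimum cluster size; attribute `max_sizes` carries the
#'   simulated max-cluster-size distribution.
#' @export
cluster_size_threshold <- function(smoothness, mask, rule = cluster_rule(),
                                   n_sim = 1000, seed = 1, voxel_size = 2) {
  voxel_size <- rep_len(voxel_size, 3)
  fwhm <- as.numeric(smoothness)
  if (any(fwhm < voxel_size / 2)) {
    warning("smoothness below half a voxel; treating as unsmoothed")
  }
  # de-compose the voxel width to recover the smoothing kernel itself
  fwhm_k <- sqrt(pmax(fwhm^2 - voxel_size^2, 0))
  sigma_vox <- fwhm_k / (2 * sqrt(2 * log(2))) / voxel_size

  dims <- dim(mask)
  pad <- ceiling(3 * max(sigma_vox))
  dims_p <- dims + 2 * pad
  zthr <- if (rule$sided == "bisided") {
    stats::qnorm(1 - rule$cluster_forming_p / 2)
  } else {
    stats::qnorm(1 - rule$cluster_forming_p)
  }

  set.seed(seed)
  max_sizes <- integer(n_sim)
  mvec <- as.vector(mask)
  for (s in seq_len(n_sim)) {
    noise <- array(stats::rnorm(prod(dims_p)), dims_p)
    sm <- .smooth3d(noise, sigma_vox)
    sm <- sm[(pad + 1):(pad + dims[1]), (pad + 1):(pad + dims[2]),
             (pad + 1):(pad + dims[3]), drop = FALSE]
    sm <- sm / stats::sd(sm[mvec])
    max_sizes[s] <- .max_cluster_size(sm, mvec, dims, zthr, rule$sided)
  }
  # smallest k with P(max >= k) <= fwe_p
  k <- 1L
  cand <- sort(unique(c(0L, max_sizes)))
  for (kk in c(cand + 1L)) {
    if (mean(max_sizes >= kk) <= rule$fwe_p) { k <- kk; break }
  }
  structure(k, max_sizes = max_sizes)
}

.max_cluster_size <- function(field, mvec, dims, zthr, sided) {
  supra_pos <- array(as.vector(field) > zthr & mvec, dims)
  mx <- 0L
  lab <- label_clusters(supra_pos)
  if (any(lab > 0)) mx <- max(tabulate(lab))
  if (sided == "bisided") {
    supra_neg <- array(as.vector(field) < -zthr & mvec, dims)
    lab <- label_clusters(supra_neg)
    if (any(lab > 0)) mx <- max(mx, max(tabulate(lab)))
  }
  as.integer(mx)
}

#' Apply cluster-forming and cluster-extent thresholds to a map
#'
#' Voxels failing the cluster-forming threshold are zeroed; the survivors are
#' grouped into faces-only connected components (positive and negative
#' components separately under the bisided rule); components smaller than
#' `k_min` are zeroed. Returns the thresholded map and a cluster table with
#' sizes, peak values and peak voxel coordinates.
#'
#' @param map `stat_map` of kind `"z"` or `"t"`.
#' @param rule `cluster_rule`.
#' @param k_min minimum cluster size in voxels (from
#'   [cluster_size_threshold()]).
#' @return list: `map` (thresholded `stat_map`), `clusters` (data frame:
#'   `cluster`, `size`, `sign`, `peak_value`, `peak_x`, `peak_y`, `peak_z`).
#' @export
apply_cluster_threshold <- function(map, rule = cluster_rule(), k_min = 1) {
  stopifnot(k_min >= 1)
  vals <- map$data
  thr <- if (map$kind == "t" && is.finite(map$df)) {
    if (rule$sided == "bisided") stats::qt(1 - rule$cluster_forming_p / 2, map$df)
    else stats::qt(1 - rule$cluster_forming_p, map$df)
  } else {
    if (rule$sided == "bisided") stats::qnorm(1 - rule$cluster_forming_p / 2)
    else stats::qnorm(1 - rule$cluster_forming_p)
  }
  out <- array(0, dim(vals))
  rows <- list()
  signs <- if (rule$sided == "bisided") c(1, -1) else 1
  cl_id <- 0L
  for (sgn in signs) {
    supra <- (sgn * vals > thr) & map$mask
    lab <- label_clusters(supra)
    if (!any(lab > 0)) next
    sizes <- tabulate(lab)
    for (cc in which(sizes >= k_min)) {
      sel <- which(lab == cc)
      out[sel] <- vals[sel]
      cl_id <- cl_id + 1L
      pk <- sel[which.max(sgn * vals[sel])]
      co <- arrayInd(pk, dim(vals))
      rows[[cl_id]] <- data.frame(cluster = cl_id, size = sizes[cc],
                                  sign = sgn, peak_value = vals[pk],
                                  peak_x = co[1], peak_y = co[2],
                                  peak_z = co[3])
    }
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster = integer(), size = integer(), sign = numeric(),
               peak_value = numeric(), peak_x = integer(),
               peak_y = integer(), peak_z = integer())
  list(map = stat_map(out, kind = map$kind, df = map$df, mask = map$mask,
                      voxel_size = map$voxel_size),
       clusters = clusters)
}
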