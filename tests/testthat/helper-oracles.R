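# Independent oracles used across tests. These deliberately re-derive the
# quantities with naive algorithms so they share no code with the package
# implementations they check.

# Naive double-loop sliding-window oracle: for every event, enumerate window
# starts, and for every window scan every word.
naive_window_oracle <- function(word_values, events, window = 5, step = 1) {
  events <- events[order(events$onset), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]
    en <- on + events$duration[i]
    k <- 0
    repeat {
      s <- on + k * step
      if (s >= en - 1e-12) break
      e <- min(s + window, en)
      val <- 0; cnt <- 0
      for (j in seq_len(nrow(word_values))) {
        wo <- word_values$onset[j]
        if (wo >= on && wo < en && wo >= s && wo < e) {
          val <- val + word_values$value[j]
          cnt <- cnt + 1
        }
      }
      out[[length(out) + 1]] <- data.frame(event_index = events$index[i],
                                           start = s, end = e, value = val,
                                           n_words = cnt)
      k <- k + 1
    }
    if (k == 0) {
      # zero-length guard: never reached for valid events (duration > 0)
      stop("event with no windows in oracle")
    }
  }
  do.call(rbind, out)
}

# Pair-enumeration Krippendorff alpha (interval metric), straight from the
# definition: observed disagreement from within-unit pairs, expected
# disagreement from all cross-unit pairs of pooled pairable values.
alpha_pair_oracle <- function(M) {
  units <- lapply(seq_len(ncol(M)), function(u) M[!is.na(M[, u]), u])
  units <- units[vapply(units, length, 1L) >= 2]
  Do_num <- 0
  pooled <- c()
  for (x in units) {
    m <- length(x)
    for (a in 1:m) for (b in 1:m) if (a != b) {
      Do_num <- Do_num + (x[a] - x[b])^2 / (m - 1)
    }
    pooled <- c(pooled, x)
  }
  n <- length(pooled)
  Do <- Do_num / n
  De <- 0
  for (a in 1:n) for (b in 1:n) if (a != b) De <- De + (pooled[a] - pooled[b])^2
  De <- De / (n * (n - 1))
  unname(1 - Do / De)
}

# Recursive flood fill over faces-touching neighbours, one voxel at a time.
flood_label_oracle <- function(x) {
  dims <- dim(x)
  lab <- array(0L, dims)
  nxt <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      if (!x[i, j, k] || lab[i, j, k] != 0L) next
      nxt <- nxt + 1L
      stack <- list(c(i, j, k))
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > dims[1] || p[2] < 1 || p[2] > dims[2] ||
            p[3] < 1 || p[3] > dims[3]) next
        if (!x[p[1], p[2], p[3]] || lab[p[1], p[2], p[3]] != 0L) next
        lab[p[1], p[2], p[3]] <- nxt
        for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
          stack[[length(stack) + 1]] <- p + d
        }
      }
    }
  }
  lab
}

# Power of the omnibus F test by numerical quadrature over the noncentral F
# density (independent of stats::pf's lower-tail path used by the solver).
power_quadrature_oracle <- function(f2, u, v, alpha) {
  crit <- qf(1 - alpha, u, v)
  ncp <- f2 * (u + v + 1)
  integrand <- function(x) df(x, u, v, ncp = ncp)
  stats::integrate(integrand, crit, Inf, rel.tol = 1e-10)$value
}

# Iterative brute-force short-event merger: repeatedly locate the first
# too-short event and merge it pairwise (forward; backward at the end).
merge_oracle <- function(e, min_duration = 3) {
  e <- e[order(e$onset), , drop = FALSE]
  repeat {
    short <- which(e$duration < min_duration)
    if (length(short) == 0 || nrow(e) == 1) break
    i <- short[1]
    j <- if (i < nrow(e)) i + 1 else i - 1
    a <- min(i, j); b <- max(i, j)
    e$duration[a] <- e$duration[a] + e$duration[b]
    e$onset[a] <- min(e$onset[a], e$onset[b])
    e$semantic[a] <- (e$semantic[a] + e$semantic[b]) / 2
    e$social[a] <- (e$social[a] + e$social[b]) / 2
    e <- e[-b, , drop = FALSE]
  }
  e
}

# Small random event table (contiguous, valid ratings).
random_event_table <- function(n, seed, movie = "m1", min_dur = 0.5,
                               max_dur = 12) {
  set.seed(seed)
  dur <- runif(n, min_dur, max_dur)
  onset <- c(0, cumsum(dur[-n]))
  sem <- sample(1:8, n, replace = TRUE)
  soc <- sample(1:8, n, replace = TRUE)
  event_table(movie, onset, dur, sem, soc)
}
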