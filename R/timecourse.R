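#' Event-bounded sliding-window sums
#'
#' Builds the 1 Hz smoothed predictor series: within each event, windows of
#' length `window` start at the event onset and slide every `step` seconds;
#' a window never crosses the event boundary, so it is clipped at the event
#' end (events shorter than the window, and sub-second final portions, yield
#' correspondingly shorter windows). The window value is the sum of word
#' values whose onsets fall in the half-open window span; windows containing
#' no qualifying words carry value 0 and an `empty` flag.
#'
#' @param word_values data frame with columns `onset` (seconds) and `value`.
#' @param table merged, validated `event_table` for one movie.
#' @param window window length in seconds (default 5).
#' @param step slide step in seconds (default 1).
#' @return data frame of class `window_series` with columns `movie_id`,
#'   `event_index`, `start`, `end`, `value`, `n_words`, `empty`.
#' @export
window_sums <- function(word_values, table, window = 5, step = 1) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  e <- table[order(table$onset), , drop = FALSE]
  onsets <- word_values$onset
  vals <- word_values$value
  out <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    ev_on <- e$onset[i]; ev_end <- ev_on + e$duration[i]
    starts <- seq(ev_on, ev_end, by = step)
    starts <- starts[starts < ev_end - 1e-12]
    if (length(starts) == 0) starts <- ev_on
    ends <- pmin(starts + window, ev_end)
    n <- length(starts)
    v <- numeric(n); cnt <- integer(n)
    in_event <- which(onsets >= ev_on & onsets < ev_end)
    for (j in seq_len(n)) {
      sel <- in_event[onsets[in_event] >= starts[j] & onsets[in_event] < ends[j]]
      cnt[j] <- length(sel)
      v[j] <- if (cnt[j] > 0) sum(vals[sel]) else 0
    }
    out[[i]] <- data.frame(
      movie_id = e$movie_id[i], event_index = e$index[i],
      start = starts, end = ends, value = v, n_words = cnt,
      empty = cnt == 0, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_series", "data.frame")
  res
}

#' Content-word counts per sliding window
#'
#' Applies [window_sums()] with value 1 for each open-class (content) word.
#' Words absent from the norm databases can still be counted by listing them
#' in `overrides` with a manually tagged part of speech (character names,
#' dates, movie-specific words). Words with no part of speech and no override
#' are excluded with a warning.
#'
#' @param transcript data frame with columns `word`, `onset`, and `pos`
#'   (`"open"`/`"closed"`, possibly `NA`).
#' @param table merged `event_table`.
#' @param overrides optional data frame (`word`, `pos`) of manual tags.
#' @param window,step as in [window_sums()].
#' @return `window_series` of content-word counts.
#' @export
content_word_counts <- function(transcript, table, overrides = NULL,
                                window = 5, step = 1) {
  pos <- as.character(transcript$pos)
  if (!is.null(overrides)) {
    oi <- match(tolower(transcript$word), tolower(overrides$word))
    pos[!is.na(oi)] <- as.character(overrides$pos[oi[!is.na(oi)]])
  }
  if (any(is.na(pos))) {
    warning(sum(is.na(pos)), " word(s) with no part of speech and no override; excluded")
  }
  open <- !is.na(pos) & pos == "open"
  wv <- data.frame(onset = transcript$onset[open],
                   value = rep(1, sum(open)))
  window_sums(wv, table, window = window, step = step)
}

#' Residualize a factor series on window word counts
#'
#' Fits, per movie, an ordinary least squares model predicting the smoothed
#' factor values from the total number of words per window, and replaces the
#' values by the residuals. This removes the (strong) association between
#' factor sums and sheer word quantity, so the residual series indexes the
#' content of the words rather than how many there are. If the counts are
#' constant within a movie the residuals are the mean-centered values (with a
#' warning).
#'
#' @param series `window_series` of factor sums.
#' @param counts `window_series` of total word counts on the identical grid.
#' @return `window_series` with residual values.
#' @export
residualize <- function(series, counts) {
  if (nrow(series) != nrow(counts) ||
      any(abs(series$start - counts$start) > 1e-9) ||
      any(series$movie_id != counts$movie_id)) {
    stop("series and counts must share an identical window grid")
  }
  out <- series
  for (mv in unique(series$movie_id)) {
    sel <- series$movie_id == mv
    y <- series$value[sel]
    x <- counts$value[sel]
    if (stats::sd(x) == 0) {
      warning("constant word counts in movie ", mv, "; residuals are centered values")
      out$value[sel] <- y - mean(y)
    } else {
      fit <- stats::lm.fit(cbind(1, x), y)
      out$value[sel] <- fit$residuals
    }
  }
  out
}

#' Drop empty windows from a series
#'
#' Windows containing no words (or no words with ratings) are removed rather
#' than zero-scored: after mean-centering, a value of 0 would denote words of
#' average score, not the absence of words. (Content-word count series keep
#' their zeros; a zero count is meaningful.)
#'
#' @param series `window_series`.
#' @return `window_series` without empty-flagged samples, order preserved.
#' @export
drop_empty <- function(series) {
  out <- series[!series$empty, , drop = FALSE]
  if (nrow(out) == 0) stop("all windows are empty")
  rownames(out) <- NULL
  class(out) <- c("window_series", "data.frame")
  out
}

#' Serialize / read a window series as TSV
#' @param series `window_series`.
#' @param path file path.
#' @export
write_window_series <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_series
#' @export
read_window_series <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("window_series", "data.frame")
  out
}
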