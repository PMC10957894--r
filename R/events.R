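#' Construct an event table
#'
#' Minor movie events with onsets, durations and semantic/social content
#' ratings on a 1-10 scale. Events within a movie must be ordered and
#' non-overlapping; an event may not carry a 9 or 10 on both the semantic and
#' the social scale (the rating rubric reserves the top ratings for a single
#' primary purpose).
#'
#' @param movie_id movie identifier (recycled if scalar).
#' @param onset event onsets in seconds.
#' @param duration event durations in seconds (> 0).
#' @param semantic,social ratings in [1, 10].
#' @param index optional ordinal index (defaults to order within movie).
#' @param is_major optional logical flag; defaults to FALSE (minor events).
#' @param notes optional free-text description.
#' @return data frame of class `event_table`.
#' @export
event_table <- function(movie_id, onset, duration, semantic, social,
                        index = NULL, is_major = FALSE, notes = "") {
  n <- length(onset)
  tab <- data.frame(
    movie_id = rep_len(as.character(movie_id), n),
    index = if (is.null(index)) stats::ave(onset, rep_len(as.character(movie_id), n),
                                           FUN = function(x) rank(x, ties.method = "first"))
            else index,
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    semantic = as.numeric(semantic),
    social = as.numeric(social),
    is_major = rep_len(as.logical(is_major), n),
    notes = rep_len(as.character(notes), n),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("event_table", "data.frame")
  tab
}

#' Validate an event table against the rating rubric's machine-checkable rules
#'
#' Report-only check of: per-movie ordering, event overlap, rating range
#' (1-10), positive durations, and the dual-maximum rule (no event may have
#' both ratings >= 9).
#'
#' @param table an `event_table`.
#' @return data frame of violations (`movie_id`, `index`, `rule`, `detail`);
#'   zero rows iff the table is valid.
#' @export
validate_events <- function(table) {
  v <- list()
  note <- function(movie, idx, rule, detail) {
    v[[length(v) + 1]] <<- data.frame(movie_id = movie, index = idx,
                                      rule = rule, detail = detail,
                                      stringsAsFactors = FALSE)
  }
  bad_dur <- which(!(table$duration > 0))
  for (i in bad_dur) note(table$movie_id[i], table$index[i], "duration",
                          "duration must be > 0")
  for (col in c("semantic", "social")) {
    bad <- which(table[[col]] < 1 | table[[col]] > 10 | is.na(table[[col]]))
    for (i in bad) note(table$movie_id[i], table$index[i], "rating_range",
                        paste0(col, " rating outside [1,10]"))
  }
  dual <- which(table$semantic >= 9 & table$social >= 9)
  for (i in dual) note(table$movie_id[i], table$index[i], "dual_maximum",
                       "event rated >= 9 on both semantic and social scales")
  for (mv in unique(table$movie_id)) {
    e <- table[table$movie_id == mv, , drop = FALSE]
    if (is.unsorted(e$onset)) {
      note(mv, NA, "ordering", "event onsets not sorted within movie")
      e <- e[order(e$onset), , drop = FALSE]
    }
    if (nrow(e) > 1) {
      ends <- e$onset + e$duration
      ov <- which(e$onset[-1] < ends[-nrow(e)] - 1e-9)
      for (i in ov) note(mv, e$index[i + 1], "overlap",
                         "event starts before the previous event ends")
    }
  }
  if (length(v) == 0) {
    return(data.frame(movie_id = character(), index = numeric(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Merge excessively short events into their neighbours
#'
#' Events shorter than `min_duration` are merged with the subsequent event:
#' the merged event starts at the earlier onset, spans the summed duration,
#' and carries the arithmetic mean of the two events' semantic and social
#' ratings. A short event at the end of a movie merges backward into its
#' predecessor. Merging repeats until no event is short (or a movie is down
#' to a single event), so runs of consecutive short events resolve by
#' chaining. Total rated time is conserved.
#'
#' @param table validated `event_table`.
#' @param min_duration merge threshold in seconds (default 3).
#' @return merged `event_table` with re-numbered indices.
#' @export
merge_short_events <- function(table, min_duration = 3.0) {
  if (nrow(table) == 0) stop("empty event table")
  merge_movie <- function(e) {
    e <- e[order(e$onset), , drop = FALSE]
    repeat {
      short <- which(e$duration < min_duration)
      if (length(short) == 0 || nrow(e) == 1) break
      i <- short[1]
      j <- if (i < nrow(e)) i + 1L else i - 1L   # trailing short merges backward
      a <- min(i, j); b <- max(i, j)
      e$onset[a] <- min(e$onset[a], e$onset[b])
      e$duration[a] <- e$duration[a] + e$duration[b]
      e$semantic[a] <- mean(c(e$semantic[a], e$semantic[b]))
      e$social[a] <- mean(c(e$social[a], e$social[b]))
      e$notes[a] <- paste(e$notes[a], e$notes[b], sep = " | ")
      e <- e[-b, , drop = FALSE]
    }
    e$index <- seq_len(nrow(e))
    e
  }
  out <- do.call(rbind, lapply(split(table, table$movie_id), merge_movie))
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Krippendorff's alpha inter-rater reliability
#'
#' Coincidence-matrix formulation of Krippendorff's alpha for a raters-by-items
#' matrix with possible missing ratings, at the interval (default) or ordinal
#' level. Items with fewer than two ratings contribute nothing. The result is
#' flagged for revision when alpha falls below the revision threshold (0.75):
#' in the annotation workflow, low-agreement events are rewatched and given a
#' consensus rating.
#'
#' @param ratings numeric matrix, raters in rows, items in columns, `NA` for
#'   missing.
#' @param level `"interval"` or `"ordinal"`.
#' @param threshold revision threshold (default 0.75).
#' @return list of class `reliability_result`: `alpha`, `threshold`,
#'   `needs_revision`.
#' @export
krippendorff_alpha <- function(ratings, level = c("interval", "ordinal"),
                               threshold = 0.75) {
  level <- match.arg(level)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) < 2) stop("need at least 2 raters")
  m_u <- colSums(!is.na(ratings))
  usable <- m_u >= 2
  if (sum(usable) < 2) stop("need at least 2 items with at least 2 ratings")

  vals <- sort(unique(stats::na.omit(as.vector(ratings[, usable]))))
  nv <- length(vals)
  O <- matrix(0, nv, nv)   # coincidence matrix
  for (u in which(usable)) {
    x <- ratings[, u]
    x <- x[!is.na(x)]
    m <- length(x)
    idx <- match(x, vals)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a != b) O[idx[a], idx[b]] <- O[idx[a], idx[b]] + 1 / (m - 1)
    }
  }
  n_c <- rowSums(O)
  n_tot <- sum(n_c)

  if (level == "interval") {
    delta2 <- outer(vals, vals, function(a, b) (a - b)^2)
  } else {
    # ordinal metric: squared difference of cumulative-frequency midpoints
    cum <- cumsum(n_c)
    mid <- cum - n_c / 2
    delta2 <- outer(mid, mid, function(a, b) (a - b)^2)
  }

  D_o <- sum(O * delta2) / n_tot
  D_e <- sum(outer(n_c, n_c) * delta2) / (n_tot * (n_tot - 1))
  if (D_e <= 0) stop("expected disagreement is zero (all ratings identical); alpha undefined")
  alpha <- 1 - D_o / D_e
  structure(list(alpha = alpha, threshold = threshold,
                 needs_revision = alpha < threshold),
            class = "reliability_result")
}

#' Scramble event ratings to build a null comparison condition
#'
#' Randomly permutes the selected rating column(s) across each movie's events,
#' leaving onsets and durations untouched. Used to generate the null
#' ("scrambled") condition against which the semantic and social event
#' analyses are compared.
#'
#' @param table `event_table`.
#' @param which `"semantic"`, `"social"`, or `"both"`.
#' @param seed integer seed; deterministic given it.
#' @return `event_table` with permuted ratings.
#' @export
scramble_ratings <- function(table, which = c("both", "semantic", "social"),
                             seed = 1) {
  which <- match.arg(which)
  cols <- if (which == "both") c("semantic", "social") else which
  set.seed(seed)
  out <- table
  for (mv in unique(out$movie_id)) {
    sel <- out$movie_id == mv
    for (cl in cols) {
      out[[cl]][sel] <- sample(out[[cl]][sel])
    }
  }
  out
}

#' Assign transcript words to events by onset
#'
#' Each word is assigned to the unique event whose half-open interval
#' `[onset, onset + duration)` contains the word's onset; words falling in
#' gaps between events are unassigned (`NA`). A word at exactly an event's
#' end time belongs to the next event.
#'
#' @param transcript data frame with columns `word` and `onset` (seconds),
#'   sorted by onset.
#' @param table `event_table` for the same movie.
#' @return integer vector: for each word the row index into `table`, or `NA`.
#' @export
assign_words_to_events <- function(transcript, table) {
  if (is.unsorted(transcript$onset)) stop("transcript is not ordered by onset")
  e <- table[order(table$onset), , drop = FALSE]
  pos <- findInterval(transcript$onset, e$onset)
  idx <- ifelse(pos >= 1 &
                  transcript$onset < e$onset[pmax(pos, 1)] + e$duration[pmax(pos, 1)],
                pos, NA_integer_)
  # map back to the original row order of `table`
  ord <- order(table$onset)
  out <- rep(NA_integer_, length(idx))
  out[!is.na(idx)] <- ord[idx[!is.na(idx)]]
  out
}
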