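#' Read and write pipeline file formats
#'
#' Plain-text readers/writers for every input the pipeline consumes: word
#' norm tables (CSV with the 12 property columns), social norms (CSV:
#' `word, mean_rating, n_raters`), embeddings (word2vec text format), event
#' annotations (CSV), transcripts (TSV: `word, onset, duration, pos`), and
#' NIfTI images via RNifti.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
read_norms <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param norms data frame to write.
#' @export
write_norms <- function(norms, path) {
  utils::write.csv(norms, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname io
#' @export
read_social_norms <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("word", "mean_rating") %in% names(out))) {
    stop("social norms file must have columns word, mean_rating")
  }
  if (any(out$mean_rating < 1 | out$mean_rating > 5)) {
    stop("social ratings must lie in [1, 5]")
  }
  out
}

#' @rdname io
#' @param embeddings embedding table (list with `words`, `vectors`).
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(embeddings$words), ncol(embeddings$vectors)), con)
  for (i in seq_along(embeddings$words)) {
    writeLines(paste(embeddings$words[i],
                     paste(formatC(embeddings$vectors[i, ], format = "g",
                                   digits = 8), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname io
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  n <- hdr[1]; d <- hdr[2]
  words <- character(n)
  V <- matrix(0, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1], "\\s+")[[1]]
    words[i] <- parts[1]
    V[i, ] <- as.numeric(parts[-1])
  }
  if (any(rowSums(V^2) == 0)) stop("embedding table contains zero vectors")
  list(words = words, vectors = V, dim = d)
}

#' @rdname io
#' @param table `event_table` to write.
#' @export
write_events <- function(table, path) {
  out <- data.frame(movie_id = table$movie_id, index = table$index,
                    onset_s = table$onset, duration_s = table$duration,
                    semantic = table$semantic, social = table$social,
                    is_major = table$is_major, notes = table$notes)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_events <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(raw$movie_id, raw$onset_s, raw$duration_s, raw$semantic,
              raw$social, index = raw$index,
              is_major = if (is.null(raw$is_major)) FALSE else raw$is_major,
              notes = if (is.null(raw$notes)) "" else raw$notes)
}

#' @rdname io
#' @param transcript transcript data frame to write.
#' @export
write_transcript <- function(transcript, path) {
  utils::write.table(transcript, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_transcript <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param map `stat_map` or `bold_image` to write.
#' @export
write_nifti_map <- function(map, path) {
  arr <- if (inherits(map, "stat_map") || inherits(map, "bold_image")) {
    map$data
  } else {
    map
  }
  vs <- if (is.list(map) && !is.null(map$voxel_size)) map$voxel_size else c(2, 2, 2)
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- c(vs, if (length(dim(arr)) == 4) 1 else NULL)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname io
#' @param TR repetition time for 4D reads.
#' @export
read_bold <- function(path, TR = 1) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  bold_image(arr, TR = TR, voxel_size = vs)
}

#' @rdname io
#' @param kind statistic kind for map reads.
#' @export
read_stat_map <- function(path, kind = "z") {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  stat_map(arr, kind = kind, voxel_size = RNifti::pixdim(img)[1:3])
}
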