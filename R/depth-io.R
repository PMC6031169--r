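#' @include AllClasses.R
NULL

# --- PGM (P5/P2) -----------------------------------------------------------
# Hand-rolled because no installed package reads plain/raw PGM; the format is
# a header plus raw bytes. Only maxval <= 255 (8-bit) is accepted.

.readPgmHeader <- function(con) {
  tokens <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header")
    if (ch == "#") { # comment to end of line
      repeat {
        c2 <- readChar(con, 1L, useBytes = TRUE)
        if (length(c2) == 0L || c2 == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) next
    tok <- ch
    repeat {
      c2 <- readChar(con, 1L, useBytes = TRUE)
      if (length(c2) == 0L || grepl("[[:space:]]", c2)) break
      tok <- paste0(tok, c2)
    }
    tokens <- c(tokens, tok)
  }
  tokens
}

.readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .readPgmHeader(con)
  magic <- hdr[1]
  if (!magic %in% c("P5", "P2"))
    stop("not a PGM file (magic '", magic, "'): ", path)
  w <- as.integer(hdr[2]); h <- as.integer(hdr[3]); maxval <- as.integer(hdr[4])
  if (is.na(w) || is.na(h) || w < 1L || h < 1L)
    stop("invalid PGM dimensions in ", path)
  if (is.na(maxval) || maxval > 255L)
    stop("only 8-bit depth images are supported (maxval ", maxval, " in ",
         path, "); refusing to down-convert")
  n <- w * h
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n))
  } else {
    scan(con, integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

.writePGM <- function(m, path) {
  storage.mode(m) <- "integer"
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(m), nrow(m)), con, eos = NULL)
  writeBin(as.raw(as.vector(t(m))), con)
  invisible(path)
}

# --- PNG -------------------------------------------------------------------
# The IHDR chunk carries bit depth (byte 25) and color type (byte 26); any
# dialect other than 8-bit grayscale is rejected rather than rescaled.

.readDepthPNG <- function(path) {
  hdr <- readBin(path, "raw", 26L)
  if (length(hdr) < 26L || !identical(as.integer(hdr[1:4]), c(137L, 80L, 78L, 71L)))
    stop("not a PNG file: ", path)
  bitDepth <- as.integer(hdr[25])
  colorType <- as.integer(hdr[26])
  if (bitDepth != 8L)
    stop("only 8-bit depth images are supported (", bitDepth, "-bit PNG in ",
         path, "); refusing to down-convert")
  if (colorType != 0L)
    stop("only single-channel grayscale PNG is supported (color type ",
         colorType, " in ", path, ")")
  img <- png::readPNG(path)
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

.writeDepthPNG <- function(m, path) {
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read one depth frame from disk
#'
#' Reads a PGM (P5 or P2) or 8-bit grayscale PNG depth image. Any other
#' dialect (16-bit, multi-channel) is a format error; values are never
#' rescaled.
#'
#' @param path path to a `.pgm` or `.png` file.
#' @param frameIndex,viewId metadata attached to the frame.
#' @return A [DepthFrame-class].
#' @seealso [readDepthSequence()], [writeDepthFrame()]
#' @export
readDepthFrame <- function(path, frameIndex = 1L, viewId = "view1") {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    pgm = .readPGM(path),
    png = .readDepthPNG(path),
    stop("unsupported depth image format: .", ext))
  DepthFrame(m, frameIndex = frameIndex, viewId = viewId)
}

#' Write one depth frame to disk
#'
#' @param frame a [DepthFrame-class].
#' @param path output path; format chosen by extension (`.pgm` writes binary
#'   P5, `.png` writes 8-bit grayscale).
#' @return The path, invisibly.
#' @export
writeDepthFrame <- function(frame, path) {
  stopifnot(is(frame, "DepthFrame"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = .writePGM(frame@pixels, path),
    png = .writeDepthPNG(frame@pixels, path),
    stop("unsupported depth image format: .", ext))
  invisible(path)
}

#' Read an ordered depth-frame sequence as a ViewStream
#'
#' Frames are read in lexicographic filename order. All frames must share
#' dimensions and be 8-bit single-channel; violations are format errors.
#'
#' @param src a directory containing `.pgm`/`.png` frames, or a character
#'   vector of file paths (used in the given order).
#' @param viewId camera identifier for the stream.
#' @param backgroundCount number of leading background-only frames.
#' @param viewAngle camera azimuth in degrees (metadata).
#' @return A [ViewStream-class].
#' @examples
#' d <- tempfile(); dir.create(d)
#' for (i in 1:3) writeDepthFrame(DepthFrame(matrix(i, 4, 4)),
#'                                file.path(d, sprintf("%06d.pgm", i)))
#' nframes(readDepthSequence(d))
#' @export
readDepthSequence <- function(src, viewId = "view1", backgroundCount = 0L,
                              viewAngle = NA_real_) {
  paths <- if (length(src) == 1L && dir.exists(src)) {
    sort(list.files(src, pattern = "\\.(pgm|png)$", full.names = TRUE,
                    ignore.case = TRUE))
  } else {
    as.character(src)
  }
  if (length(paths) == 0L) stop("no frames found in ", paste(src, collapse = ", "))
  fr <- lapply(seq_along(paths), function(i)
    readDepthFrame(paths[i], frameIndex = i, viewId = viewId))
  dims <- vapply(fr, function(f) dim(f@pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("mixed frame dimensions in sequence: ",
         paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = " vs "))
  ViewStream(fr, viewId = viewId, viewAngle = viewAngle,
             backgroundCount = backgroundCount)
}

#' Write a ViewStream as numbered frame files
#'
#' @param stream a [ViewStream-class].
#' @param dir output directory (created if missing).
#' @param format `"pgm"` or `"png"`.
#' @return The directory, invisibly.
#' @export
writeDepthSequence <- function(stream, dir, format = c("pgm", "png")) {
  stopifnot(is(stream, "ViewStream"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(stream@frames)) {
    writeDepthFrame(stream@frames[[i]],
                    file.path(dir, sprintf("%06d.%s", i, format)))
  }
  invisible(dir)
}

#' Pair synchronized frames across views
#'
#' Streams are assumed pre-synchronized, so pairing is by ordinal index:
#' sample `t` holds frame `t` of every stream (background frames excluded
#' via each stream's `backgroundCount`). The output length is the shortest
#' stream's action-frame count; trailing extras are dropped with a warning.
#'
#' @param streams list of [ViewStream-class] objects (>= 1).
#' @param labels optional character vector of per-time-step action labels.
#' @return List of [MultiViewSample-class] objects.
#' @export
synchronizeViews <- function(streams, labels = NULL) {
  if (length(streams) == 0L) stop("need at least one stream to synchronize")
  stopifnot(all(vapply(streams, is, logical(1), "ViewStream")))
  actionCounts <- vapply(streams, function(s)
    length(s@frames) - s@backgroundCount, integer(1))
  n <- min(actionCounts)
  if (any(actionCounts != n))
    warning("streams have unequal lengths (", paste(actionCounts, collapse = ", "),
            "); truncating to ", n, " synchronized samples")
  if (n <= 0L) stop("no action frames to synchronize")
  lapply(seq_len(n), function(t) {
    fr <- lapply(streams, function(s) s@frames[[s@backgroundCount + t]])
    lab <- if (!is.null(labels) && t <= length(labels)) labels[t] else NA_character_
    new("MultiViewSample", frames = fr, timeIndex = as.integer(t),
        label = as.character(lab))
  })
}
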