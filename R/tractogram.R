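#' Streamline tractogram
#'
#' A `safconn_tractogram` holds a list of streamlines — each an n x 3 matrix
#' of ordered points in world millimetres — and one positive weight per
#' streamline (1.0 for plain streamline counting; SIFT-style weights when
#' supplied).
#'
#' @param streamlines list of numeric matrices with 3 columns (>= 1 row).
#' @param weights numeric vector, one positive value per streamline
#'   (default all 1).
#' @return An object of class `safconn_tractogram`.
#' @export
tractogram <- function(streamlines = list(), weights = NULL) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L || nrow(s) < 1L) stop("each streamline must be an n x 3 matrix, n >= 1")
    if (!all(is.finite(s))) stop("streamline coordinates must be finite")
    storage.mode(s) <- "double"
    dimnames(s) <- NULL
    s
  })
  if (is.null(weights)) weights <- rep(1.0, length(streamlines))
  weights <- as.numeric(weights)
  if (length(weights) != length(streamlines)) {
    stop("weights length (", length(weights), ") must equal streamline count (",
         length(streamlines), ")")
  }
  if (length(weights) && any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive and finite")
  }
  structure(list(streamlines = streamlines, weights = weights),
            class = "safconn_tractogram")
}

#' @export
print.safconn_tractogram <- function(x, ...) {
  cat("<safconn_tractogram> ", length(x$streamlines), " streamlines, total weight ",
      format(sum(x$weights)), "\n", sep = "")
  invisible(x)
}

#' Streamline arc length
#'
#' Sum of Euclidean segment lengths of the polyline, in mm. A single point
#' has length 0.
#'
#' @param s an n x 3 matrix of points in mm, or a streamline from a
#'   [tractogram()].
#' @return length in mm.
#' @export
streamline_length <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2L) return(0)
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Lengths of all streamlines in a tractogram
#' @param tg a [tractogram()].
#' @return numeric vector of lengths in mm.
#' @export
tractogram_lengths <- function(tg) {
  vapply(tg$streamlines, streamline_length, numeric(1))
}

# ---- TCK (MRtrix track file) I/O -------------------------------------------
# Text header terminated by "END\n" with a "file: . <offset>" pointer, then
# little-endian Float32 point triplets; (NaN,NaN,NaN) separates streamlines
# and (Inf,Inf,Inf) terminates the stream.

#' Read and write MRtrix TCK track files
#'
#' Coordinates are stored as little-endian 32-bit floats, so a write/read
#' round trip preserves them to float32 precision. Per-streamline weights
#' (tcksift2 style) live in a separate plain-text file, one value per line,
#' whose length must match the streamline count.
#'
#' @param tg a [tractogram()].
#' @param path TCK file path.
#' @param weights_path optional path for per-streamline weights.
#' @return `read_tractogram_tck` returns a [tractogram()];
#'   `write_tractogram_tck` returns `path` invisibly.
#' @export
write_tractogram_tck <- function(tg, path, weights_path = NULL) {
  stopifnot(inherits(tg, "safconn_tractogram"))
  hdr_fixed <- c("mrtrix tracks",
                 "datatype: Float32LE",
                 paste0("count: ", length(tg$streamlines)))
  # compute the data offset; widen if the offset's digit count changes it
  offset <- 0L
  for (i in 1:3) {
    lines <- c(hdr_fixed, paste0("file: . ", offset), "END")
    new_offset <- sum(nchar(lines, type = "bytes")) + length(lines)
    if (new_offset == offset) break
    offset <- new_offset
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr_fixed, paste0("file: . ", offset), "END"), con, sep = "\n")
  for (s in tg$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  if (!is.null(weights_path)) {
    writeLines(format(tg$weights, digits = 17, scientific = FALSE, trim = TRUE),
               weights_path)
  }
  invisible(path)
}

#' @rdname write_tractogram_tck
#' @export
read_tractogram_tck <- function(path, weights_path = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  nl <- which(raw == charToRaw("\n"))
  if (!length(nl)) stop("not a TCK file (no header): ", path)
  first <- rawToChar(raw[seq_len(nl[1] - 1L)])
  if (first != "mrtrix tracks") stop("not a TCK file (bad magic): ", path)
  # scan header lines up to END
  offset <- NA_integer_
  datatype <- "Float32LE"
  start <- nl[1] + 1L
  for (k in nl[-1]) {
    line <- rawToChar(raw[start:(k - 1L)])
    start <- k + 1L
    if (line == "END") break
    if (grepl("^file:", line)) {
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", line))
    } else if (grepl("^datatype:", line)) {
      datatype <- trimws(sub("^datatype:", "", line))
    }
    if (k == nl[length(nl)]) stop("TCK header not terminated by END: ", path)
  }
  if (is.na(offset)) stop("TCK header lacks a 'file: . <offset>' line: ", path)
  if (datatype != "Float32LE") stop("unsupported TCK datatype: ", datatype)
  body <- raw[(offset + 1L):length(raw)]
  vals <- readBin(body, "numeric", n = length(body) %/% 4L, size = 4L,
                  endian = "little")
  if (length(vals) %% 3L != 0L) stop("TCK data is not a whole number of triplets")
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  term <- which(is.infinite(pts[, 1]))
  if (length(term)) pts <- pts[seq_len(term[1] - 1L), , drop = FALSE]
  sep <- is.nan(pts[, 1])
  id <- cumsum(c(TRUE, sep[-length(sep)])) # streamline index per row
  keep <- !sep
  streamlines <- if (any(keep)) {
    unname(split.data.frame(pts[keep, , drop = FALSE], id[keep]))
  } else list()
  weights <- NULL
  if (!is.null(weights_path)) {
    weights <- as.numeric(readLines(weights_path))
    if (length(weights) != length(streamlines)) {
      stop("weights file has ", length(weights), " values for ",
           length(streamlines), " streamlines")
    }
  }
  tractogram(streamlines, weights)
}
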