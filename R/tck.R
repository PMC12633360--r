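#' Tractogram container
#'
#' Ordered streamline polylines in world millimetres, with optional
#' per-streamline weights (e.g. SIFT2) and the key/value header carried by the
#' TCK file they came from.
#'
#' @param streamlines List of numeric matrices, each n_i x 3 with n_i >= 2,
#'   vertices in world mm.
#' @param weights Optional numeric vector, one non-negative finite weight per
#'   streamline.
#' @param header Named character vector/list of TCK header fields.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, weights = NULL, header = list()) {
  if (!is.list(streamlines)) stop("streamlines must be a list of matrices")
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be an n x 3 matrix with n >= 2")
    if (!all(is.finite(s))) stop("streamline vertices must be finite")
  }
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    if (length(weights) != length(streamlines))
      stop("weights length must equal streamline count")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be non-negative and finite")
  }
  structure(list(streamlines = streamlines, weights = weights,
                 header = as.list(header)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("tractogram:", length(x$streamlines), "streamlines",
      if (!is.null(x$weights)) "(weighted)" else "", "\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

tck_datatypes <- list(
  Float32LE = list(size = 4L, endian = "little"),
  Float32BE = list(size = 4L, endian = "big"),
  Float64LE = list(size = 8L, endian = "little"),
  Float64BE = list(size = 8L, endian = "big")
)

#' Read a TCK tractogram
#'
#' Parses the MRtrix TCK dialect: an ASCII header opened by the magic line
#' `mrtrix tracks` and closed by `END`, a `file: . <offset>` pointer to the
#' binary body, then float vertex triplets with an all-NaN triplet between
#' streamlines and an all-Inf triplet terminating the stream. Little/big
#' endian 32- and 64-bit float bodies are supported per the declared
#' `datatype`.
#'
#' @param path Path to a `.tck` file.
#' @return A [tractogram()]; the header `count` field, when present, is
#'   verified against the parsed streamline count.
#' @export
read_tck <- function(path) {
  n_bytes <- file.size(path)
  if (is.na(n_bytes)) stop("cannot read '", path, "'")
  raw <- readBin(path, "raw", n = n_bytes)
  hdr <- parse_tck_header(raw)
  dt <- tck_datatypes[[hdr$datatype]]
  if (is.null(dt)) stop("TCK format error: unsupported datatype ", hdr$datatype)
  body <- raw[(hdr$offset + 1L):n_bytes]
  if (length(body) %% (3L * dt$size) != 0L)
    stop("TCK integrity error: truncated body")
  vals <- readBin(body, "double", n = length(body) %/% dt$size,
                  size = dt$size, endian = dt$endian)
  m <- matrix(vals, nrow = 3L)
  is_nan <- colSums(matrix(is.nan(vals), nrow = 3L)) == 3L
  is_inf <- colSums(matrix(is.infinite(vals), nrow = 3L)) == 3L
  term <- which(is_inf)[1]
  if (is.na(term)) stop("TCK integrity error: truncated body (no terminator)")
  sep <- is_nan[seq_len(term - 1L)]
  streamlines <- list()
  if (term > 1L) {
    keep <- !sep
    idx <- seq_len(term - 1L)[keep]
    grp <- (cumsum(sep) + 1L)[keep]
    if (length(idx)) {
      streamlines <- lapply(split(idx, grp), function(cols) t(m[, cols, drop = FALSE]))
      names(streamlines) <- NULL
    }
  }
  if (!is.null(hdr$fields$count)) {
    declared <- suppressWarnings(as.integer(hdr$fields$count))
    if (!is.na(declared) && declared != length(streamlines))
      stop("TCK integrity error: header count ", declared,
           " but body holds ", length(streamlines), " streamlines")
  }
  fields <- hdr$fields
  fields$count <- as.character(length(streamlines))
  tractogram(streamlines, header = fields)
}

parse_tck_header <- function(raw) {
  # header is ASCII; locate the END line at byte level (body may contain nuls)
  end_at <- grepRaw("\nEND\n", raw, fixed = TRUE)
  if (length(end_at) == 0L) stop("TCK format error: header END not found")
  header_txt <- rawToChar(raw[seq_len(end_at[1] + 4L)])
  lines <- strsplit(header_txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 2L || trimws(lines[1]) != "mrtrix tracks")
    stop("TCK format error: missing 'mrtrix tracks' magic line")
  fields <- list()
  offset <- NA_integer_
  for (ln in lines[-1]) {
    if (ln == "END") break
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) next
    key <- trimws(substr(ln, 1L, colon - 1L))
    val <- trimws(substr(ln, colon + 1L, nchar(ln)))
    if (key == "file") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) != 2L || parts[1] != ".")
        stop("TCK format error: unsupported 'file' field '", val, "'")
      offset <- as.integer(parts[2])
    } else {
      fields[[key]] <- val
    }
  }
  if (is.na(offset)) stop("TCK format error: missing 'file' offset")
  datatype <- if (is.null(fields$datatype)) "Float32LE" else fields$datatype
  list(fields = fields, offset = offset, datatype = datatype)
}

#' Write a TCK tractogram
#'
#' Emits the standard Float32LE body; [read_tck()] on the result reproduces
#' the vertices bit-exactly at float32 precision and preserves streamline
#' order.
#'
#' @param t A [tractogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(t, path) {
  stopifnot(inherits(t, "tractogram"))
  fields <- t$header
  fields$count <- as.character(length(t$streamlines))
  fields$datatype <- "Float32LE"
  keyvals <- vapply(names(fields), function(k)
    paste0(k, ": ", fields[[k]]), character(1))
  base <- paste0("mrtrix tracks\n",
                 paste0(keyvals, collapse = "\n"),
                 if (length(keyvals)) "\n" else "")
  # 'file: . <offset>' must state the total header length; iterate to fixpoint
  offset <- nchar(base, type = "bytes") + nchar("file: . \nEND\n") + 1L
  repeat {
    hdr <- paste0(base, "file: . ", offset, "\nEND\n")
    len <- nchar(hdr, type = "bytes")
    if (len == offset) break
    offset <- len
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read per-streamline weights
#'
#' Weight files (e.g. SIFT2 output) are headerless whitespace/newline
#' separated decimal floats; because they carry no length information,
#' validation against the tractogram's streamline count is mandatory.
#'
#' @param path Path to the text file.
#' @param n Expected number of weights (the streamline count).
#' @return Numeric vector of `n` non-negative finite weights, in file order.
#' @export
read_weights <- function(path, n) {
  w <- scan(path, what = numeric(), quiet = TRUE)
  if (length(w) != n)
    stop("weights integrity error: expected ", n, " values, found ", length(w))
  if (any(!is.finite(w)))
    stop("weights value error: non-finite entry")
  if (any(w < 0))
    stop("weights value error: negative entry")
  w
}

#' Combine two tractograms
#'
#' Concatenates streamlines (and weights, when both inputs carry them) in
#' order; the combined count is the sum of the input counts.
#'
#' @param a,b [tractogram()] objects.
#' @return A [tractogram()] with `length(a) + length(b)` streamlines.
#' @export
combine_tractograms <- function(a, b) {
  stopifnot(inherits(a, "tractogram"), inherits(b, "tractogram"))
  has_wa <- !is.null(a$weights); has_wb <- !is.null(b$weights)
  if (has_wa != has_wb)
    stop("cannot combine a weighted with an unweighted tractogram")
  w <- if (has_wa) c(a$weights, b$weights) else NULL
  tractogram(c(a$streamlines, b$streamlines), weights = w, header = a$header)
}
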