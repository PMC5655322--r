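#' Read a furrow-pattern image
#'
#' Reads a grayscale height-map image as a [furrow_pattern()]. PGM (both
#' ASCII `P2` and binary `P5`) and PNG are supported; PNG is converted to
#' grayscale by channel averaging when needed, and tones are rescaled to
#' the 8-bit range [0, 255].
#'
#' @param path image file (`.pgm` or `.png`).
#' @inheritParams furrow_pattern
#' @return a [furrow_pattern()].
#' @export
read_pattern <- function(path, height_scale = 1, pixel_pitch = 1) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("no such file: ", path)
  g <- switch(ext,
              pgm = read_pgm(path),
              png = {
                img <- png::readPNG(path)
                if (length(dim(img)) == 3L) {
                  img <- apply(img[, , 1:min(3L, dim(img)[3L]), drop = FALSE],
                               c(1, 2), mean)
                }
                img * 255
              },
              stop("unsupported image format: ", ext))
  furrow_pattern(g, height_scale = height_scale, pixel_pitch = pixel_pitch)
}

#' Write a furrow pattern as ASCII PGM
#'
#' Tones are rounded to the nearest integer in [0, 255].
#'
#' @param pattern a [furrow_pattern()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  if (!inherits(pattern, "furrow_pattern")) stop("not a furrow_pattern")
  g <- round(pattern$grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2",
               paste0("# written by hornfold ",
                      utils::packageVersion("hornfold")),
               paste(ncol(g), nrow(g)), "255"), con)
  writeLines(apply(g, 1L, paste, collapse = " "), con)
  invisible(path)
}

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # header tokens (width, height, maxval), skipping whitespace and comments
  tokens <- integer(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  w <- tokens[1L]; h <- tokens[2L]; maxval <- tokens[3L]
  if (w < 1L || h < 1L || maxval < 1L) stop("bad PGM header: ", path)
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
    if (length(vals) < w * h) stop("truncated PGM body: ", path)
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- sub("#.*$", "", txt)
    vals <- suppressWarnings(as.integer(unlist(strsplit(
      paste(txt, collapse = " "), "[[:space:]]+"))))
    vals <- vals[!is.na(vals)]
    if (length(vals) < w * h) stop("truncated PGM body: ", path)
  }
  matrix(vals[seq_len(w * h)] / maxval * 255, h, w, byrow = TRUE)
}
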