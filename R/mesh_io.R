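#' Read a triangle mesh from file
#'
#' Supports ASCII OFF, Wavefront OBJ and ASCII PLY. The format is inferred
#' from the file extension unless given explicitly. OBJ files use 1-based
#' vertex indices, OFF and PLY 0-based; all are converted to the package's
#' internal 1-based convention.
#'
#' @param path file path.
#' @param format one of `"off"`, `"obj"`, `"ply"`, or `NULL` to infer from
#'   the extension.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("off", "obj", "ply"))
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  switch(format,
         off = parse_off(lines, path),
         obj = parse_obj(lines, path),
         ply = parse_ply(lines, path))
}

#' Write a triangle mesh to file
#'
#' Writers emit a comment header with the package version (OBJ/PLY/OFF all
#' allow comments) and coordinates with 15 significant digits, so a
#' write-read round trip preserves vertices to at least 12 significant
#' digits and facet lists exactly.
#'
#' @param mesh a [triangle_mesh()].
#' @inheritParams read_mesh
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot_mesh(mesh)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("off", "obj", "ply"))
  v <- mesh$vertices; f <- mesh$facets
  ver <- as.character(utils::packageVersion("hornfold"))
  vtxt <- sprintf("%.15g %.15g %.15g", v[, 1L], v[, 2L], v[, 3L])
  out <- switch(format,
    off = c("OFF",
            paste0("# written by hornfold ", ver),
            sprintf("%d %d 0", nrow(v), nrow(f)),
            vtxt,
            sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)),
    obj = c(paste0("# written by hornfold ", ver),
            paste("v", vtxt),
            sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L])),
    ply = c("ply",
            "format ascii 1.0",
            paste0("comment written by hornfold ", ver),
            sprintf("element vertex %d", nrow(v)),
            "property double x", "property double y", "property double z",
            sprintf("element face %d", nrow(f)),
            "property list uchar int vertex_indices",
            "end_header",
            vtxt,
            sprintf("3 %d %d %d", f[, 1L] - 1L, f[, 2L] - 1L, f[, 3L] - 1L)))
  writeLines(out, path)
  invisible(path)
}

parse_fail <- function(path, lineno, why) {
  stop(sprintf("parse error in %s at line %d: %s", path, lineno, why),
       call. = FALSE)
}

split_fields <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1L]]
}

# lines with content, skipping blanks/comments; returns indices into `lines`
content_lines <- function(lines, comment = "#") {
  t <- trimws(lines)
  which(nzchar(t) & substr(t, 1L, 1L) != comment)
}

parse_off <- function(lines, path) {
  idx <- content_lines(lines)
  if (length(idx) < 2L) parse_fail(path, length(lines), "truncated OFF file")
  if (trimws(lines[idx[1L]]) != "OFF") {
    parse_fail(path, idx[1L], "missing OFF magic")
  }
  counts <- suppressWarnings(as.integer(split_fields(lines[idx[2L]])))
  if (length(counts) < 2L || anyNA(counts[1:2])) {
    parse_fail(path, idx[2L], "bad count line")
  }
  nv <- counts[1L]; nf <- counts[2L]
  if (length(idx) < 2L + nv + nf) {
    parse_fail(path, length(lines), sprintf(
      "expected %d vertex and %d face lines, found %d",
      nv, nf, length(idx) - 2L))
  }
  vidx <- idx[3:(2L + nv)]
  fidx <- idx[(3L + nv):(2L + nv + nf)]
  v <- parse_vertex_lines(lines, vidx, path)
  f <- matrix(0L, nf, 3L)
  for (r in seq_len(nf)) {
    fl <- suppressWarnings(as.integer(split_fields(lines[fidx[r]])))
    if (anyNA(fl) || length(fl) < 4L || fl[1L] != 3L) {
      parse_fail(path, fidx[r], "expected triangle face line '3 i j k'")
    }
    f[r, ] <- fl[2:4] + 1L
  }
  triangle_mesh(v, f)
}

parse_obj <- function(lines, path) {
  vs <- list(); fs <- list()
  for (i in seq_along(lines)) {
    t <- trimws(lines[i])
    if (!nzchar(t) || startsWith(t, "#")) next
    fields <- split_fields(t)
    if (fields[1L] == "v") {
      xyz <- suppressWarnings(as.numeric(fields[2:4]))
      if (length(fields) < 4L || anyNA(xyz)) {
        parse_fail(path, i, "bad vertex line")
      }
      vs[[length(vs) + 1L]] <- xyz
    } else if (fields[1L] == "f") {
      if (length(fields) != 4L) {
        parse_fail(path, i, "only triangular faces are supported")
      }
      # tolerate v/vt/vn references; keep the vertex index
      iv <- suppressWarnings(as.integer(sub("/.*$", "", fields[2:4])))
      if (anyNA(iv)) parse_fail(path, i, "bad face line")
      fs[[length(fs) + 1L]] <- iv
    }
    # other directives (vn, vt, o, g, s, usemtl, ...) are ignored
  }
  if (length(vs) == 0L) parse_fail(path, length(lines), "no vertices")
  v <- do.call(rbind, vs)
  f <- do.call(rbind, fs)
  # OBJ allows negative (relative) indices; resolve against vertex count
  f[f < 0L] <- nrow(v) + 1L + f[f < 0L]
  triangle_mesh(v, f)
}

parse_ply <- function(lines, path) {
  if (length(lines) == 0L || trimws(lines[1L]) != "ply") {
    parse_fail(path, 1L, "missing ply magic")
  }
  nv <- NA_integer_; nf <- NA_integer_; header_end <- NA_integer_
  for (i in seq_along(lines)) {
    fields <- split_fields(lines[i])
    if (length(fields) == 0L) next
    if (fields[1L] == "format" &&
          !identical(fields[2L], "ascii")) {
      parse_fail(path, i, "only ascii PLY is supported")
    }
    if (fields[1L] == "element" && length(fields) >= 3L) {
      if (fields[2L] == "vertex") nv <- as.integer(fields[3L])
      if (fields[2L] == "face") nf <- as.integer(fields[3L])
    }
    if (fields[1L] == "end_header") { header_end <- i; break }
  }
  if (is.na(header_end)) parse_fail(path, length(lines), "no end_header")
  if (is.na(nv) || is.na(nf)) {
    parse_fail(path, header_end, "missing vertex/face element counts")
  }
  idx <- content_lines(lines[-seq_len(header_end)])
  idx <- idx + header_end
  if (length(idx) < nv + nf) {
    parse_fail(path, length(lines), "truncated PLY body")
  }
  v <- parse_vertex_lines(lines, idx[seq_len(nv)], path)
  f <- matrix(0L, nf, 3L)
  for (r in seq_len(nf)) {
    li <- idx[nv + r]
    fl <- suppressWarnings(as.integer(split_fields(lines[li])))
    if (anyNA(fl[1:4]) || fl[1L] != 3L) {
      parse_fail(path, li, "expected triangle face line '3 i j k'")
    }
    f[r, ] <- fl[2:4] + 1L
  }
  triangle_mesh(v, f)
}

parse_vertex_lines <- function(lines, vidx, path) {
  v <- matrix(NA_real_, length(vidx), 3L)
  for (r in seq_along(vidx)) {
    xyz <- suppressWarnings(as.numeric(split_fields(lines[vidx[r]])))
    if (length(xyz) < 3L || anyNA(xyz[1:3])) {
      parse_fail(path, vidx[r], "bad vertex line")
    }
    v[r, ] <- xyz[1:3]
  }
  v
}
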