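# Plain-text readers/writers: ASCII PGM (P2) rasters and Sunnybrook-dialect
# contour files. Contour files carry "x y" pairs, one per line, 0-based, with
# x = column and y = row (the distribution convention); the in-memory API is
# 1-based (row, col), converted here at the boundary.

#' Write a raster as ASCII PGM (P2)
#'
#' Values are scaled from \[0, 1\] (or taken as-is when already in
#' \[0, maxval\]) and rounded to integers.
#'
#' @param img numeric matrix.
#' @param path output file.
#' @param maxval maximum gray level.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  v <- img
  if (max(v) <= 1 + 1e-12) v <- v * maxval
  v <- round(pmin(pmax(v, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # one image row per line, row-major like the raster
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PGM (P2) raster
#'
#' @param path input file.
#' @param normalize divide by maxval so values lie in \[0, 1\].
#' @return numeric matrix (H x W).
#' @export
read_pgm <- function(path, normalize = TRUE) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*#", txt)]
  if (!length(txt) || trimws(txt[1]) != "P2") stop("not an ASCII PGM (P2) file: ", path)
  toks <- scan(text = paste(txt[-1], collapse = "\n"), what = numeric(),
               quiet = TRUE)
  W <- toks[1]; H <- toks[2]; maxval <- toks[3]
  vals <- toks[-(1:3)]
  if (length(vals) != W * H) stop("PGM pixel count mismatch in ", path)
  m <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
  if (normalize) m / maxval else m
}

#' Read a contour text file
#'
#' One whitespace-separated "x y" pair per line (floating point accepted,
#' 0-based, x = column, y = row); blank lines are ignored.
#'
#' @param path input file.
#' @param closed mark the loaded contour closed.
#' @return a [contour()] with 1-based (row, col) points.
#' @export
load_contour_file <- function(path, closed = TRUE) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  pts <- matrix(0, length(keep), 2)
  for (i in seq_along(keep)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[keep[i]]), "\\s+")[[1]]))
    if (length(f) != 2 || anyNA(f)) {
      stop(sprintf("malformed contour line %d in %s: '%s'", keep[i], path,
                   lines[keep[i]]))
    }
    pts[i, ] <- c(f[2] + 1, f[1] + 1)   # y -> row, x -> col, 0- to 1-based
  }
  if (nrow(pts) == 0) stop("empty contour file: ", path)
  contour(pts, closed = closed)
}

#' Write a contour text file
#'
#' @param c a [contour()] (1-based row/col points).
#' @param path output file.
#' @export
write_contour_file <- function(c, path) {
  c <- as_contour(c)
  writeLines(sprintf("%g %g", c$points[, 2] - 1, c$points[, 1] - 1), path)
  invisible(path)
}
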