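# Standard-format I/O: MRC2014 maps/images and STAR metadata tables.

#' Write an image or map in MRC2014 format
#'
#' Mode 2 (32-bit float), little-endian, pixel size recorded in the cell
#' header. Matrix dim 1 is written as the MRC fast (column) axis.
#'
#' @param x a matrix, 3D array, [micrograph()] or [density_map()].
#' @param path output path.
#' @param pixel_size pixel size (A); taken from the object if available.
#' @export
write_mrc <- function(x, path, pixel_size = NULL) {
  if (inherits(x, "micrograph")) {
    pixel_size <- pixel_size %||% x$pixel_size
    x <- x$data
  } else if (inherits(x, "density_map")) {
    pixel_size <- pixel_size %||% x$pixel_size
    x <- x$data
  }
  if (is.null(pixel_size)) stop("pixel_size required")
  d <- dim(x)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                              # nx ny nz
  wi(2)                              # mode 2 = float32
  wi(c(0, 0, 0))                     # nxstart
  wi(d)                              # mx my mz
  wf(d * pixel_size)                 # cella
  wf(c(90, 90, 90))                  # cellb
  wi(c(1, 2, 3))                     # mapc mapr maps
  wf(c(min(x), max(x), mean(x)))     # dmin dmax dmean
  wi(if (d[3] > 1) 1 else 0)         # ispg
  wi(0)                              # nsymbt
  writeBin(raw(100), con)            # extra (words 26-50)
  wf(c(0, 0, 0))                     # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(x))                   # rms
  wi(0)                              # nlabl
  writeBin(raw(800), con)            # labels
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 file
#'
#' Supports modes 0 (int8), 1 (int16) and 2 (float32). Returns a
#' [density_map()] for volumes (nz > 1) and a [micrograph()] for single
#' images.
#'
#' @param path input path.
#' @return [density_map()] or [micrograph()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3)               # nxstart
  mgrid <- ri(3)      # mx my mz
  cella <- rf(3)
  if (any(d <= 0) || any(!is.finite(d)))
    stop("corrupt MRC header in ", path)
  px <- if (mgrid[1] > 0 && cella[1] > 0) cella[1] / mgrid[1] else 1
  seek(con, 92)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  nvox <- prod(d)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode))
  if (length(data) < nvox)
    stop("truncated MRC file: expected ", nvox, " voxels, got ",
         length(data))
  if (d[3] > 1) {
    density_map(array(data, d), px)
  } else {
    micrograph(matrix(data, d[1], d[2]), px)
  }
}

#' Write a particle stack as an MRCS image stack
#'
#' @param stack a [particle_stack()].
#' @param path output path (conventionally .mrcs).
#' @export
write_mrcs <- function(stack, path) {
  write_mrc(stack$images, path, pixel_size = stack$pixel_size)
}

#' Write a STAR table
#'
#' Single-block `loop_` table; numeric cells are written with at least 6
#' significant digits.
#'
#' @param table a data frame.
#' @param path output path.
#' @param block block name (default "data_").
#' @export
write_star <- function(table, path, block = "data_") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(block, "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(table), seq_along(table)), con)
  if (nrow(table) > 0) {
    cells <- vapply(table, function(col) {
      if (is.numeric(col)) format(col, digits = 8, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, character(nrow(table)))
    cells <- matrix(cells, nrow = nrow(table))
    writeLines(apply(cells, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a STAR table
#'
#' Reads the first `loop_` block of a STAR file into a data frame,
#' preserving column names (leading underscore stripped) and row order;
#' unknown columns pass through untouched.
#'
#' @param path input path.
#' @param required character vector of column names that must be present.
#' @return data frame.
#' @export
read_star <- function(path, required = NULL) {
  lines <- readLines(path)
  li <- which(trimws(lines) == "loop_")
  if (length(li) == 0) stop("no loop_ block in ", path)
  i <- li[1] + 1
  cols <- character(0)
  while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
    cols <- c(cols, sub("^_", "", strsplit(trimws(lines[i]), "[ \t#]+")[[1]][1]))
    i <- i + 1
  }
  rows <- character(0)
  while (i <= length(lines) && nzchar(trimws(lines[i])) &&
         !startsWith(trimws(lines[i]), "data_")) {
    rows <- c(rows, trimws(lines[i]))
    i <- i + 1
  }
  out <- if (length(rows) == 0) {
    as.data.frame(matrix(nrow = 0, ncol = length(cols),
                         dimnames = list(NULL, cols)))
  } else {
    sp <- strsplit(rows, "[ \t]+")
    df <- as.data.frame(do.call(rbind, sp), stringsAsFactors = FALSE)
    names(df) <- cols
    utils::type.convert(df, as.is = TRUE)
  }
  if (!is.null(required)) {
    miss <- setdiff(required, names(out))
    if (length(miss) > 0)
      stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  out
}
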