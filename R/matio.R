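# Minimal MAT v5 container support, enough to ingest numeric arrays from a
# PLIF dye-intensity dataset.  Uncompressed numeric matrices are fully
# supported; zlib-compressed elements are attempted via memDecompress and
# reported clearly when not decodable.  Cell/struct/char variables are
# skipped with a message (the reader is deliberately schema-tolerant: the
# dataset's internal layout is described only in external metadata).

.mi_types <- c(miINT8 = 1, miUINT8 = 2, miINT16 = 3, miUINT16 = 4,
               miINT32 = 5, miUINT32 = 6, miSINGLE = 7, miDOUBLE = 9,
               miINT64 = 12, miUINT64 = 13, miMATRIX = 14,
               miCOMPRESSED = 15, miUTF8 = 16)

.read_mi_numeric <- function(raw, type, n) {
  sz <- switch(as.character(type),
               "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
               "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L,
               stop("unsupported MAT numeric subtype ", type))
  what <- if (type %in% c(7, 9)) "double" else "integer"
  signed <- !(type %in% c(2, 4, 6, 13))
  out <- readBin(raw, what = what, n = n, size = sz, signed = signed,
                 endian = "little")
  as.numeric(out)
}

# parse one data element at offset (1-based) in raw vector; returns
# list(type, data_raw, next_offset)
.read_mat_tag <- function(raw, off) {
  t32 <- readBin(raw[off + 0:3], "integer", size = 4, endian = "little")
  small_n <- bitwAnd(bitwShiftR(t32, 16), 0xFFFFL)
  if (small_n != 0L) {  # small data element: 2-byte type, 2-byte length
    type <- bitwAnd(t32, 0xFFFFL)
    nbytes <- small_n
    list(type = type, data = raw[off + 4:(3 + nbytes)], nxt = off + 8L)
  } else {
    type <- t32
    nbytes <- readBin(raw[off + 4:7], "integer", size = 4, endian = "little")
    data <- if (nbytes > 0) raw[off + 8:(7 + nbytes)] else raw(0)
    pad <- (8 - nbytes %% 8) %% 8
    if (type == .mi_types[["miCOMPRESSED"]]) pad <- 0  # no padding after compressed
    list(type = type, data = data, nxt = off + 8L + nbytes + pad)
  }
}

.parse_mat_matrix <- function(raw) {
  off <- 1L
  flags <- .read_mat_tag(raw, off); off <- flags$nxt
  cls <- as.integer(flags$data[1])
  dims_el <- .read_mat_tag(raw, off); off <- dims_el$nxt
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4,
                  size = 4, endian = "little")
  name_el <- .read_mat_tag(raw, off); off <- name_el$nxt
  name <- rawToChar(name_el$data)
  if (!cls %in% 6:13) return(list(name = name, value = NULL, class = cls))
  data_el <- .read_mat_tag(raw, off)
  vals <- .read_mi_numeric(data_el$data, data_el$type, prod(dims))
  if (length(dims) > 1) dim(vals) <- dims
  list(name = name, value = vals, class = cls)
}

# read all numeric variables from a MAT v5 file; named list of arrays
.read_mat_v5 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128) stop("not a MAT v5 file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (!endian %in% c("IM", "MI"))
    stop("not a MAT v5 file (bad endian indicator): ", path)
  if (endian == "MI")
    stop("big-endian MAT files are not supported: ", path)
  vars <- list()
  off <- 129L
  while (off + 7L <= length(raw)) {
    el <- .read_mat_tag(raw, off)
    payload <- el$data
    type <- el$type
    if (type == .mi_types[["miCOMPRESSED"]]) {
      payload <- tryCatch(
        memDecompress(payload, type = "gzip"),
        error = function(e) NULL)
      if (is.null(payload)) {
        message("skipping compressed MAT element (not decodable here)")
        off <- el$nxt; next
      }
      inner <- .read_mat_tag(payload, 1L)
      type <- inner$type
      payload <- inner$data
    }
    if (type == .mi_types[["miMATRIX"]] && length(payload) > 0) {
      v <- .parse_mat_matrix(payload)
      if (is.null(v$value)) {
        message("skipping non-numeric MAT variable '", v$name, "'")
      } else {
        vars[[v$name]] <- v$value
      }
    }
    off <- el$nxt
  }
  vars
}

# write named numeric arrays as an uncompressed little-endian MAT v5 file
# (fixture/export helper; canonical full-tag layout only)
.write_mat_v5 <- function(vars, path) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by plumetime"))
  header <- c(header, raw(116 - length(header)))
  writeBin(header, con)
  writeBin(raw(8), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeBin(charToRaw("IM"), con)
  pad8 <- function(n) (8 - n %% 8) %% 8
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- if (is.null(dim(v))) c(length(v), 1L) else dim(v)
    name_raw <- charToRaw(nm)
    n_name <- length(name_raw)
    n_dims <- 4L * length(dims)
    n_data <- 8L * length(v)
    body <- 16L +                                  # array flags
            8L + n_dims + pad8(n_dims) +           # dimensions
            8L + n_name + pad8(n_name) +           # name
            8L + n_data + pad8(n_data)             # real data (miDOUBLE)
    writeBin(as.integer(c(.mi_types[["miMATRIX"]], body)), con, size = 4, endian = "little")
    writeBin(as.integer(c(.mi_types[["miUINT32"]], 8L)), con, size = 4, endian = "little")
    writeBin(c(6L, 0L), con, size = 4, endian = "little")  # mxDOUBLE_CLASS
    writeBin(as.integer(c(.mi_types[["miINT32"]], n_dims)), con, size = 4, endian = "little")
    writeBin(as.integer(dims), con, size = 4, endian = "little")
    writeBin(raw(pad8(n_dims)), con)
    writeBin(as.integer(c(.mi_types[["miINT8"]], n_name)), con, size = 4, endian = "little")
    writeBin(name_raw, con)
    writeBin(raw(pad8(n_name)), con)
    writeBin(as.integer(c(.mi_types[["miDOUBLE"]], n_data)), con, size = 4, endian = "little")
    writeBin(as.numeric(v), con, size = 8, endian = "little")
    writeBin(raw(pad8(n_data)), con)
  }
  invisible(path)
}

# best-effort "x150_y10"-style coordinate extraction from a variable name
.coords_from_name <- function(nm) {
  mx <- regmatches(nm, regexec("x[_ ]?(-?[0-9.]+)", nm, ignore.case = TRUE))[[1]]
  my <- regmatches(nm, regexec("y[_ ]?(-?[0-9.]+)", nm, ignore.case = TRUE))[[1]]
  c(x = if (length(mx) == 2) as.numeric(mx[2]) else NA_real_,
    y = if (length(my) == 2) as.numeric(my[2]) else NA_real_)
}

#' Read a PLIF dye-intensity dataset (MAT v5)
#'
#' Best-effort reader for MAT v5 containers holding per-site dye
#' concentration time series (values in % of source concentration, 60
#' frames/s).  Every numeric vector becomes one series; every numeric matrix
#' contributes one series per column (rows are assumed to be frames when the
#' matrix is taller than wide, otherwise it is transposed first).  Site
#' coordinates are parsed from variable names of the form `...x<cm>...y<cm>...`
#' when present.  Non-numeric and higher-dimensional variables are skipped
#' with a message; 3-D frame stacks can be reduced with
#' [extract_annulus_series()] after reading them separately.
#'
#' The reader is optional plumbing: the rest of the package is fully
#' functional on synthetic series from [generate_site_series()].
#'
#' @param path Path to a MAT v5 file.
#' @param dt Sampling interval of the recordings (s), default 1/60.
#' @return A list of [site_series()] objects, named by variable (and column).
#' @export
read_plif_dataset <- function(path, dt = 1 / 60) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read PLIF dataset, no such file: ", path)
  vars <- .read_mat_v5(path)
  if (length(vars) == 0)
    stop("no numeric variables found in MAT file (unknown layout): ", path)
  out <- list()
  for (nm in names(vars)) {
    v <- vars[[nm]]
    xy <- .coords_from_name(nm)
    if (is.null(dim(v)) || length(dim(v)) == 1L || min(dim(v)) == 1L) {
      out[[nm]] <- site_series(x = xy["x"], y = xy["y"], values = as.numeric(v),
                               dt = dt, label = nm)
    } else if (length(dim(v)) == 2L) {
      if (nrow(v) < ncol(v)) v <- t(v)
      for (j in seq_len(ncol(v))) {
        lab <- sprintf("%s[,%d]", nm, j)
        out[[lab]] <- site_series(x = xy["x"], y = xy["y"], values = v[, j],
                                  dt = dt, label = lab)
      }
    } else {
      message("skipping ", length(dim(v)), "-D variable '", nm,
              "' (use extract_annulus_series on frame stacks)")
    }
  }
  if (length(out) == 0)
    stop("MAT file contained no usable series (unknown layout): ", path)
  out
}

#' Average a 3x3 pixel annulus window through a frame stack
#'
#' Reduces a `rows x cols x frames` intensity array to a single time series
#' by averaging the 9 pixel intensities of the 3x3 window centered at
#' `center` in every frame — the footprint of a single antennule annulus on
#' the imaging plane.
#'
#' @param frames Numeric 3-D array, `rows x cols x frames`.
#' @param center Integer pair `(row, col)`; the 3x3 window must lie inside
#'   the frame bounds.
#' @param dt Sampling interval (s), default 1/60.
#' @return A [site_series()] (site coordinates unknown, `NA`).
#' @export
extract_annulus_series <- function(frames, center, dt = 1 / 60) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L, length(center) == 2L)
  r <- as.integer(center[1]); cc <- as.integer(center[2])
  dd <- dim(frames)
  if (r < 2L || cc < 2L || r > dd[1] - 1L || cc > dd[2] - 1L)
    stop("3x3 window around center (", r, ", ", cc, ") falls outside the frame")
  win <- frames[(r - 1L):(r + 1L), (cc - 1L):(cc + 1L), , drop = FALSE]
  vals <- apply(win, 3, mean)
  site_series(values = vals, dt = dt, label = sprintf("annulus(%d,%d)", r, cc))
}
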