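# Minimal MAT v5 (Level 5 MAT-file) reader/writer.
#
# Covers what ground-truthed extracellular benchmark files need: numeric
# arrays of any integer/float storage class, character arrays, cell arrays,
# and zlib-compressed elements on read. Structs, sparse and complex arrays
# are out of scope and raise errors. The writer emits uncompressed double
# arrays only, which MATLAB/Octave/scipy all read.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L

mat_type_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
         "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L, "16" = 1L,
         abort(sprintf("unsupported MAT data type %d", type), class = "spikecnn_format_error"))
}

mat_read_numeric <- function(raw, type) {
  n <- length(raw) %/% mat_type_size(type)
  switch(as.character(type),
         "1" = as.double(readBin(raw, "integer", n, size = 1L, signed = TRUE)),
         "2" = as.double(readBin(raw, "integer", n, size = 1L, signed = FALSE)),
         "3" = as.double(readBin(raw, "integer", n, size = 2L, signed = TRUE,
                                 endian = "little")),
         "4" = as.double(readBin(raw, "integer", n, size = 2L, signed = FALSE,
                                 endian = "little")),
         "5" = as.double(readBin(raw, "integer", n, size = 4L, endian = "little")),
         "6" = as.double(readBin(raw, "integer", n, size = 4L, endian = "little")),
         "7" = as.double(readBin(raw, "double", n, size = 4L, endian = "little")),
         "9" = readBin(raw, "double", n, size = 8L, endian = "little"),
         "12" = mat_read_int64(raw, signed = TRUE),
         "13" = mat_read_int64(raw, signed = FALSE),
         abort(sprintf("unsupported numeric MAT type %d", type),
               class = "spikecnn_format_error"))
}

# 64-bit integers come back as doubles (exact below 2^53, ample for indices)
mat_read_int64 <- function(raw, signed) {
  n <- length(raw) %/% 8L
  u <- readBin(raw, "integer", 2L * n, size = 4L, endian = "little")
  lo <- u[seq(1L, 2L * n, 2L)]
  hi <- u[seq(2L, 2L * n, 2L)]
  lo <- ifelse(lo < 0, lo + 2^32, lo)
  if (!signed) hi <- ifelse(hi < 0, hi + 2^32, hi)
  hi * 2^32 + lo
}

# one tagged data element starting at `pos` (1-based); returns value + new pos
mat_read_element <- function(buf, pos) {
  if (pos + 7L > length(buf) + 1L) {
    abort("truncated MAT file", class = "spikecnn_format_error")
  }
  w1 <- readBin(buf[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  small_n <- bitwAnd(bitwShiftR(w1, 16L), 0xFFFFL)
  type <- bitwAnd(w1, 0xFFFFL)
  if (small_n > 0L) {
    data <- if (small_n > 0) buf[(pos + 4L):(pos + 3L + small_n)] else raw()
    return(list(type = type, data = data, pos = pos + 8L))
  }
  nbytes <- readBin(buf[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L,
                    endian = "little")
  data <- if (nbytes > 0L) buf[(pos + 8L):(pos + 7L + nbytes)] else raw()
  adv <- 8L + nbytes
  if (type != MI_COMPRESSED) adv <- adv + (-nbytes) %% 8L
  list(type = type, data = data, pos = pos + adv)
}

mat_parse_matrix <- function(data) {
  # array flags
  el <- mat_read_element(data, 1L)
  cls <- as.integer(el$data[1L])
  flags <- as.integer(el$data[2L])
  if (bitwAnd(flags, 0x08L) != 0L) {
    abort("complex MAT arrays are not supported", class = "spikecnn_format_error")
  }
  # dimensions
  el2 <- mat_read_element(data, el$pos)
  dims <- readBin(el2$data, "integer", length(el2$data) %/% 4L, size = 4L,
                  endian = "little")
  # name
  el3 <- mat_read_element(data, el2$pos)
  name <- rawToChar(el3$data)
  pos <- el3$pos

  if (cls == MX_CELL) {
    n <- prod(dims)
    value <- vector("list", n)
    for (i in seq_len(n)) {
      el4 <- mat_read_element(data, pos)
      if (el4$type != MI_MATRIX) {
        abort("malformed cell array in MAT file", class = "spikecnn_format_error")
      }
      value[[i]] <- if (length(el4$data) == 0L) numeric(0) else
        mat_parse_matrix(el4$data)$value
      pos <- el4$pos
    }
    return(list(name = name, value = value))
  }
  if (cls == MX_STRUCT) {
    abort("MAT struct arrays are not supported", class = "spikecnn_format_error")
  }
  el4 <- mat_read_element(data, pos)
  if (cls == MX_CHAR) {
    value <- if (el4$type %in% c(MI_UTF8, MI_INT8, MI_UINT8)) {
      rawToChar(el4$data)
    } else {
      intToUtf8(mat_read_numeric(el4$data, el4$type))
    }
    return(list(name = name, value = value))
  }
  value <- mat_read_numeric(el4$data, el4$type)
  if (length(dims) == 2L && 1L %in% dims) {
    # return plain vectors for row/column vectors
    value <- as.vector(value)
  } else {
    dim(value) <- dims
  }
  list(name = name, value = value)
}

#' Read a MAT v5 file
#'
#' Reads the named variables of a Level 5 MAT-file into a list. Numeric
#' arrays (all storage classes, returned as doubles), character arrays and
#' cell arrays are supported, including zlib-compressed elements; structs,
#' sparse and complex arrays are not.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of variables.
#' @seealso [read_waveclus_mat()] for the spike-benchmark layout on top of
#'   this, [write_mat_v5()] for the writer.
#' @export
read_mat_v5 <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) abort("not a MAT v5 file (too short)",
                                class = "spikecnn_format_error")
  endian <- rawToChar(buf[127:128])
  if (endian == "MI") {
    abort("big-endian MAT files are not supported", class = "spikecnn_format_error")
  }
  if (endian != "IM") {
    abort("not a MAT v5 file (bad endian indicator)", class = "spikecnn_format_error")
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf) + 1L) {
    el <- mat_read_element(buf, pos)
    pos <- el$pos
    if (el$type == MI_COMPRESSED) {
      inner <- memDecompress(el$data, type = "gzip")
      el <- mat_read_element(inner, 1L)
    }
    if (el$type != MI_MATRIX) next
    v <- mat_parse_matrix(el$data)
    out[[v$name]] <- v$value
  }
  out
}

mat_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4L, endian = "little"))
}

mat_pad8 <- function(r) c(r, raw((-length(r)) %% 8L))

mat_encode_matrix <- function(name, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  flags <- mat_tag(MI_UINT32, 8L)
  flags <- c(flags, as.raw(c(MX_DOUBLE, 0L, 0L, 0L)), raw(4L))
  dims <- c(mat_tag(MI_INT32, 8L),
            writeBin(as.integer(dim(x)), raw(), size = 4L, endian = "little"))
  nm <- charToRaw(name)
  nme <- mat_pad8(c(mat_tag(MI_INT8, length(nm)), nm))
  dat <- mat_pad8(c(mat_tag(MI_DOUBLE, 8L * length(x)),
                    writeBin(as.vector(x), raw(), size = 8L, endian = "little")))
  body <- c(flags, dims, nme, dat)
  c(mat_tag(MI_MATRIX, length(body)), body)
}

#' Write numeric variables to a MAT v5 file
#'
#' Writes a named list of numeric vectors/matrices as uncompressed double
#' arrays in Level 5 MAT-file format (vectors are stored as 1-by-n arrays).
#'
#' @param vars Named list of numeric vectors or matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat_v5 <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    abort("all variables must be named")
  }
  desc <- sprintf("MATLAB 5.0 MAT-file, created by spikecnn on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  hdr <- c(hdr, charToRaw(strrep(" ", 116L - length(hdr))))
  hdr <- c(hdr, raw(8L),
           writeBin(as.integer(0x0100), raw(), size = 2L, endian = "little"),
           charToRaw("IM"))
  body <- lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    if (!is.numeric(v)) abort(sprintf("variable '%s' is not numeric", nm))
    mat_encode_matrix(nm, if (is.matrix(v)) v else matrix(v, nrow = 1L))
  })
  writeBin(c(hdr, unlist(body)), path)
  invisible(path)
}
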