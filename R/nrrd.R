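# Minimal NRRD0004 reader/writer.
#
# Covers the subset of the format the volume contract needs: 3-D double or
# integer payloads, attached header, raw or gzip encoding, little endian,
# `spacings`/`space directions` and `space origin` metadata. The writer emits
# sizes in the package's (z, y, x) axis order with z fastest, which is how
# the reader interprets them.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic)) {
    abort_cleftmorph(sprintf("not an NRRD file: %s", path), "cleftmorph_format_error")
  }
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) {
      abort_cleftmorph("NRRD header ended before blank line", "cleftmorph_format_error")
    }
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- tolower(trimws(kv[1]))
    fields[[key]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  need <- function(key) {
    if (is.null(fields[[key]])) {
      abort_cleftmorph(sprintf("NRRD header missing '%s'", key), "cleftmorph_metadata_error")
    }
    fields[[key]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L) abort_cleftmorph("only 3-D NRRD supported", "cleftmorph_format_error")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  encoding <- tolower(need("encoding"))
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(seq_along(vecs), function(i) {
      v <- as.numeric(strsplit(gsub("[()]", "", vecs[i]), ",")[[1]])
      sqrt(sum(v^2))
    }, numeric(1))
  }
  if (is.null(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    abort_cleftmorph("NRRD spacing metadata missing or non-positive",
                     "cleftmorph_metadata_error")
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    # NRRD stores the origin in world (x, y, z) order; the volume contract
    # carries (z, y, x)
    origin <- rev(as.numeric(strsplit(gsub("[()]", "",
                                           fields[["space origin"]]), ",")[[1]]))
  }
  rtype <- switch(type,
    "double" = list(what = "double", size = 8L),
    "float" = list(what = "double", size = 4L),
    "short" = , "int16" = list(what = "integer", size = 2L),
    "int" = , "int32" = list(what = "integer", size = 4L),
    "uchar" = , "uint8" = list(what = "integer", size = 1L),
    abort_cleftmorph(sprintf("unsupported NRRD type '%s'", type),
                     "cleftmorph_format_error")
  )
  n <- prod(sizes)
  payload_con <- con
  if (encoding == "gzip") {
    raw_rest <- readBin(con, "raw", n = file.info(path)$size)
    payload <- memDecompress(raw_rest, type = "gzip")
    vals <- readBin(payload, rtype$what, n = n, size = rtype$size,
                    endian = if (endian == "big") "big" else "little",
                    signed = !(type %in% c("uchar", "uint8")))
  } else if (encoding == "raw") {
    vals <- readBin(payload_con, rtype$what, n = n, size = rtype$size,
                    endian = if (endian == "big") "big" else "little",
                    signed = !(type %in% c("uchar", "uint8")))
  } else {
    abort_cleftmorph(sprintf("unsupported NRRD encoding '%s'", encoding),
                     "cleftmorph_format_error")
  }
  if (length(vals) != n) {
    abort_cleftmorph("NRRD payload shorter than sizes imply", "cleftmorph_format_error")
  }
  data <- array(as.numeric(vals), dim = sizes)
  list(data = data, spacing = spacing, origin = origin)
}

write_nrrd <- function(data, path, spacing, origin = c(0, 0, 0),
                       encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  sizes <- dim(data)
  # axes are written fastest-first in the package's (z, y, x) order; the
  # per-axis space vectors and the origin are world (x, y, z)
  dirs <- c(sprintf("(0,0,%s)", format(spacing[1], digits = 17)),
            sprintf("(0,%s,0)", format(spacing[2], digits = 17)),
            sprintf("(%s,0,0)", format(spacing[3], digits = 17)))
  header <- c(
    "NRRD0004",
    "# written by cleftmorph",
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    sprintf("sizes: %s", paste(sizes, collapse = " ")),
    sprintf("space directions: %s", paste(dirs, collapse = " ")),
    sprintf("space origin: (%s)",
            paste(format(rev(origin), digits = 17), collapse = ",")),
    "endian: little",
    sprintf("encoding: %s", encoding),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con, sep = "\n")
  payload <- writeBin(as.numeric(data), raw(), size = 8L, endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  writeBin(payload, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
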