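# Minimal NRRD (.nrrd, detached headers unsupported) reader/writer covering
# the scalar 3-D case this package needs: raw or gzip encoding, common
# numeric types, spacing via `spacings:` or `space directions:`.

.nrrd_types <- list(
  "double" = list(what = "double", size = 8),
  "float" = list(what = "double", size = 4),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE)
)

#' @keywords internal
read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line
  nl <- which(raw_all == as.raw(10))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p - prev <= 2L) { hdr_end <- p; break }  # "\n\n" or "\n\r\n"
    prev <- p
  }
  if (is.na(hdr_end)) stop("malformed NRRD: no end-of-header blank line",
                           call. = FALSE)
  hdr <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1]))
    stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("NRRD header missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (as.integer(fields$dimension) != 3L)
    stop("only 3-D NRRD volumes are supported", call. = FALSE)
  sizes <- as.integer(strsplit(trimws(fields$sizes), " +")[[1]])
  type <- .nrrd_types[[fields$type]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields$type,
                          call. = FALSE)
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  spacing <- NULL
  origin <- c(0, 0, 0)
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), " +")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(s) {
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
    }, numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  if (is.null(spacing))
    stop("NRRD header has no spacings or space directions", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid NRRD spacing (must be strictly positive): ",
         paste(spacing, collapse = " "), call. = FALSE)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  payload <- raw_all[(hdr_end + 1L):length(raw_all)]
  if (fields$encoding == "gzip") {
    payload <- memDecompress(payload, type = "gzip")
  } else if (fields$encoding != "raw") {
    stop("unsupported NRRD encoding: ", fields$encoding, call. = FALSE)
  }
  n <- prod(sizes)
  vals <- readBin(payload, what = type$what, n = n, size = type$size,
                  endian = endian,
                  signed = if (type$what == "integer")
                    isTRUE(type$signed) else TRUE)
  if (length(vals) != n)
    stop("NRRD payload shorter than `sizes` imply", call. = FALSE)
  new_volume(array(as.numeric(vals), dim = sizes), spacing = spacing,
             origin = origin)
}

#' @keywords internal
write_nrrd <- function(vol, path, encoding = c("raw", "gzip")) {
  encoding <- match.arg(encoding)
  d <- dim(vol$values)
  hdr <- c(
    "NRRD0004",
    "# generated by calvarisk",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(d, collapse = " ")),
    paste0("space directions: (", vol$spacing[1], ",0,0) (0,",
           vol$spacing[2], ",0) (0,0,", vol$spacing[3], ")"),
    "endian: little",
    paste("encoding:", encoding),
    paste0("space origin: (", paste(vol$origin, collapse = ","), ")"),
    ""
  )
  payload <- writeBin(as.numeric(vol$values), raw(), size = 8,
                      endian = "little")
  if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}
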