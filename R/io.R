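#' Read a point cloud from PLY or ASCII XYZ
#'
#' Supported formats: PLY (ASCII or binary little-endian, `vertex` element
#' with float `x`,`y`,`z` and optional integer `label` / `instance`
#' properties) and whitespace-separated ASCII `x y z [label] [instance]`
#' with `#` comments, the dialect exported by common point-cloud editors.
#'
#' @param path file to read.
#' @param format `"auto"` (sniff from the first bytes / extension),
#'   `"ply"`, or `"xyz"`.
#' @return a [labeled_cloud()]; row order of the file is preserved.
#' @export
read_cloud <- function(path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    head <- readBin(path, "raw", n = 4L)
    format <- if (identical(rawToChar(head), "ply\n") ||
                  identical(rawToChar(head[1:3]), "ply")) "ply" else "xyz"
  }
  if (format == "ply") read_ply(path) else read_xyz(path)
}

#' Write a point cloud to PLY or ASCII XYZ
#'
#' @param cloud a [labeled_cloud()].
#' @param path output file.
#' @param format `"ply"` or `"xyz"`.
#' @param binary for PLY: write `binary_little_endian` (default, bit-exact
#'   float32 round-trip) or ASCII.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = c("ply", "xyz"),
                        binary = TRUE) {
  format <- match.arg(format)
  if (format == "ply") write_ply(cloud, path, binary) else write_xyz(cloud, path)
  invisible(path)
}

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("parse error in ", path, ": no data rows")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("parse error in %s: row %d has %d columns, expected %d",
                 path, bad, ncols[bad], ncols[1]))
  }
  nc <- ncols[1]
  if (nc < 3L) stop("parse error in ", path, ": need at least 3 columns")
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = nc,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("parse error in %s: non-numeric field on data row %d",
                 path, bad))
  }
  labeled_cloud(m[, 1:3, drop = FALSE],
                semantic = if (nc >= 4L) as.integer(m[, 4]),
                instance = if (nc >= 5L) as.integer(m[, 5]))
}

write_xyz <- function(cloud, path) {
  m <- cloud$coords
  cols <- list(format(m[, 1], digits = 17, trim = TRUE, scientific = FALSE),
               format(m[, 2], digits = 17, trim = TRUE, scientific = FALSE),
               format(m[, 3], digits = 17, trim = TRUE, scientific = FALSE))
  if (!is.null(cloud$semantic)) cols <- c(cols, list(cloud$semantic))
  if (!is.null(cloud$instance)) {
    if (is.null(cloud$semantic)) stop("instance ids require semantic labels in XYZ output")
    cols <- c(cols, list(cloud$instance))
  }
  writeLines(do.call(paste, cols), path)
}

ply_header <- function(cloud, binary) {
  fmt <- if (binary) "binary_little_endian" else "ascii"
  h <- c("ply", paste("format", fmt, "1.0"),
         "comment written by phenocloud",
         paste("element vertex", n_points(cloud)),
         "property float x", "property float y", "property float z")
  if (!is.null(cloud$semantic)) h <- c(h, "property int label")
  if (!is.null(cloud$instance)) h <- c(h, "property int instance")
  c(h, "end_header")
}

write_ply <- function(cloud, path, binary = TRUE) {
  n <- n_points(cloud)
  header <- ply_header(cloud, binary)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  if (binary) {
    # interleave per-vertex bytes: 12 coord bytes (+4 per int property)
    parts <- list(matrix(writeBin(as.vector(t(cloud$coords)), raw(),
                                  size = 4L, endian = "little"), nrow = 12L))
    if (!is.null(cloud$semantic))
      parts <- c(parts, list(matrix(writeBin(cloud$semantic, raw(),
                                             size = 4L, endian = "little"),
                                    nrow = 4L)))
    if (!is.null(cloud$instance))
      parts <- c(parts, list(matrix(writeBin(cloud$instance, raw(),
                                             size = 4L, endian = "little"),
                                    nrow = 4L)))
    writeBin(as.vector(do.call(rbind, parts)), con)
  } else {
    m <- float32_round(cloud$coords)
    cols <- list(format(m[, 1], digits = 9, trim = TRUE),
                 format(m[, 2], digits = 9, trim = TRUE),
                 format(m[, 3], digits = 9, trim = TRUE))
    if (!is.null(cloud$semantic)) cols <- c(cols, list(cloud$semantic))
    if (!is.null(cloud$instance)) cols <- c(cols, list(cloud$instance))
    txt <- paste0(paste(do.call(paste, cols), collapse = "\n"), "\n")
    writeBin(charToRaw(txt), con)
  }
}

# Position of the first occurrence of raw pattern `pat` in `x` (NA if absent).
find_raw <- function(x, pat) {
  hits <- which(x == pat[1])
  for (h in hits) {
    if (h + length(pat) - 1L > length(x)) next
    if (all(x[h:(h + length(pat) - 1L)] == pat)) return(h)
  }
  NA_integer_
}

# Round a double matrix through float32 representation.
float32_round <- function(m) {
  v <- readBin(writeBin(as.vector(m), raw(), size = 4L), "numeric",
               n = length(m), size = 4L)
  matrix(v, nrow = nrow(m), dimnames = dimnames(m))
}

read_ply <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # locate "end_header\n" in the raw stream
  marker <- charToRaw("end_header\n")
  idx <- find_raw(bytes, marker)
  if (is.na(idx)) stop("parse error in ", path, ": no end_header")
  header <- strsplit(rawToChar(bytes[1:(idx - 1L)]), "\r?\n")[[1]]
  body <- bytes[(idx + length(marker)):length(bytes)]
  if (!identical(trimws(header[1]), "ply"))
    stop("parse error in ", path, ": missing 'ply' magic")
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("parse error in ", path, ": missing format line")
  fmt <- strsplit(trimws(fmt_line), "[[:space:]]+")[[1]][2]
  el <- grep("^element ", header)
  vi <- grep("^element vertex ", header)
  if (length(vi) != 1L) stop("parse error in ", path, ": need one vertex element")
  n <- as.integer(strsplit(trimws(header[vi]), "[[:space:]]+")[[1]][3])
  # properties of the vertex element only
  after <- el[el > vi]
  stop_at <- if (length(after)) min(after) - 1L else length(header)
  props <- header[(vi + 1):stop_at]
  props <- props[grepl("^property ", props)]
  ptoks <- strsplit(trimws(props), "[[:space:]]+")
  if (any(vapply(ptoks, function(t) t[2] == "list", logical(1))))
    stop("parse error in ", path, ": list properties are not supported")
  ptype <- vapply(ptoks, `[`, "", 2)
  pname <- vapply(ptoks, `[`, "", 3)
  need <- c("x", "y", "z")
  if (!all(need %in% pname))
    stop("parse error in ", path, ": vertex element lacks x/y/z properties")
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
             short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
             int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
             float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (!all(ptype %in% names(sizes)))
    stop("parse error in ", path, ": unknown property type")
  if (fmt == "ascii") {
    rows <- strsplit(rawToChar(body), "\r?\n")[[1]]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows) < n) stop("parse error in ", path, ": truncated vertex data")
    m <- matrix(as.numeric(unlist(strsplit(trimws(rows[seq_len(n)]),
                                           "[[:space:]]+"))),
                ncol = length(pname), byrow = TRUE)
    colnames(m) <- pname
  } else if (fmt == "binary_little_endian") {
    psz <- sizes[ptype]
    stride <- sum(psz)
    if (length(body) < n * stride)
      stop("parse error in ", path, ": truncated vertex data")
    bm <- matrix(body[seq_len(n * stride)], nrow = stride)
    off <- cumsum(c(0L, psz[-length(psz)]))
    m <- matrix(0, n, length(pname), dimnames = list(NULL, pname))
    for (j in seq_along(pname)) {
      raw_j <- as.vector(bm[(off[j] + 1L):(off[j] + psz[j]), , drop = FALSE])
      tp <- ptype[j]
      m[, j] <- if (tp %in% c("float", "float32", "double", "float64")) {
        readBin(raw_j, "numeric", n = n, size = sizes[tp], endian = "little")
      } else {
        readBin(raw_j, "integer", n = n, size = sizes[tp], endian = "little",
                signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
      }
    }
  } else {
    stop("parse error in ", path, ": unsupported PLY format '", fmt, "'")
  }
  labeled_cloud(m[, need, drop = FALSE],
                semantic = if ("label" %in% pname) as.integer(m[, "label"]),
                instance = if ("instance" %in% pname) as.integer(m[, "instance"]))
}
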