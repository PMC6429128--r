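#' Read a triangle mesh from OFF or PLY (ASCII)
#'
#' The format is chosen from the file extension (`.off` / `.ply`) unless
#' given explicitly.  Only ASCII variants are supported; faces must be
#' triangles.
#'
#' @param path file to read.
#' @param unit length unit to tag the mesh with (`"A"` or `"nm"`).
#' @param format `"off"`, `"ply"` or `NULL` to infer from the extension.
#' @return A [hc_mesh()].
#' @export
read_mesh <- function(path, unit = c("A", "nm"), format = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         off = read_off(path, unit),
         ply = read_ply(path, unit),
         stop("unsupported mesh format: ", format))
}

#' Write a triangle mesh to OFF or PLY (ASCII)
#'
#' @param mesh a [hc_mesh()].
#' @param path output file.
#' @param format `"off"`, `"ply"` or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  v <- mesh$vertices
  f <- mesh$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("comment unit %s", mesh$unit),
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stop("unsupported mesh format: ", format)
  invisible(path)
}

read_off <- function(path, unit) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (toupper(trimws(lines[[1]])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[[2]], quiet = TRUE)
  nv <- counts[[1]]; nf <- counts[[2]]
  nums <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  v <- matrix(nums[seq_len(3 * nv)], ncol = 3, byrow = TRUE)
  rest <- nums[-seq_len(3 * nv)]
  f <- matrix(0L, nf, 3)
  pos <- 1
  for (i in seq_len(nf)) {
    k <- rest[[pos]]
    if (k != 3) stop("non-triangular face in OFF file")
    f[i, ] <- as.integer(rest[pos + 1:3]) + 1L
    pos <- pos + k + 1
  }
  hc_mesh(v, f, unit = unit)
}

read_ply <- function(path, unit) {
  lines <- readLines(path)
  if (trimws(lines[[1]]) != "ply") stop("not a PLY file: ", path)
  hdr_end <- which(trimws(lines) == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[-(seq_len(hdr_end))]
  vdat <- scan(text = paste(body[seq_len(nv)], collapse = "\n"), quiet = TRUE)
  nprop <- length(scan(text = body[[1]], quiet = TRUE))
  v <- matrix(vdat, ncol = nprop, byrow = TRUE)[, 1:3, drop = FALSE]
  f <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    row <- scan(text = body[[nv + i]], quiet = TRUE)
    if (row[[1]] != 3) stop("non-triangular face in PLY file")
    f[i, ] <- as.integer(row[2:4]) + 1L
  }
  hc_mesh(v, f, unit = unit)
}
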