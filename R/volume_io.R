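# Voxel volume container and 3D medical-image readers/writers.
#
# Geometry convention: axis-aligned volumes only (identity direction matrix),
# 0-based voxel indices, world coordinates refer to voxel centers, world
# position of voxel (i,j,k) = origin + index * spacing. When synthesizing
# CBCT volumes the volume center is placed at world (0,0,0), the isocenter.

#' Voxel volume
#'
#' @param data 3D numeric array (attenuation, arbitrary units); the first
#'   array dimension is X (fastest-varying on disk), then Y, then Z.
#' @param spacing length-3 voxel size (mm), strictly positive.
#' @param origin length-3 world position (mm) of the center of voxel (0,0,0).
#' @param frame frame label, `"c"` for CBCT volumes.
#' @export
voxel_volume <- function(data, spacing, origin, frame = "c") {
  if (length(dim(data)) != 3L)
    .helixreg_error("helixreg_invalid_volume", "data must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    .helixreg_error("helixreg_invalid_volume", "spacing must be 3 positive values")
  if (length(origin) != 3L)
    .helixreg_error("helixreg_invalid_volume", "origin must have length 3")
  structure(list(data = data, spacing = spacing, origin = origin, frame = frame),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Voxel volume %d x %d x %d, spacing [%s] mm, origin [%s] mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' World coordinates of voxel indices
#' @param v a `voxel_volume`.
#' @param index length-3 0-based voxel index, or n x 3 matrix of indices.
#' @return world position(s) in mm.
#' @export
voxel_to_world <- function(v, index) {
  single <- is.null(dim(index))
  im <- if (single) matrix(as.numeric(index), nrow = 1L) else base::as.matrix(index)
  d <- dim(v$data)
  if (any(im < 0) || any(im > matrix(d - 1L, nrow(im), 3, byrow = TRUE)))
    .helixreg_error("helixreg_out_of_bounds", "voxel index out of bounds")
  out <- im * matrix(v$spacing, nrow(im), 3, byrow = TRUE) +
    matrix(v$origin, nrow(im), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' Voxel indices of world coordinates (nearest voxel, 0-based)
#' @param v a `voxel_volume`.
#' @param point length-3 world point or n x 3 matrix (mm).
#' @export
world_to_voxel <- function(v, point) {
  single <- is.null(dim(point))
  pm <- if (single) matrix(as.numeric(point), nrow = 1L) else base::as.matrix(point)
  out <- round((pm - matrix(v$origin, nrow(pm), 3, byrow = TRUE)) /
                 matrix(v$spacing, nrow(pm), 3, byrow = TRUE))
  storage.mode(out) <- "integer"
  if (single) drop(out) else out
}

.guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) "nrrd"
  else if (grepl("\\.mha$", lp)) "mha"
  else if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else .helixreg_error("helixreg_format_error",
                       paste("cannot guess volume format from", path))
}

#' Write a volume to NRRD, MetaImage or NIfTI
#'
#' NRRD and MetaImage are written with attached little-endian float32 raw
#' payloads and an identity direction matrix; NIfTI goes through RNifti with
#' the geometry carried in the sform.
#'
#' @param v a `voxel_volume`.
#' @param path output file (`.nrrd`, `.mha`, `.nii` or `.nii.gz`).
#' @param format override the format guessed from the extension.
#' @export
write_volume <- function(v, path, format = .guess_format(path)) {
  stopifnot(inherits(v, "voxel_volume"))
  d <- dim(v$data)
  switch(format,
    nrrd = {
      hdr <- c("NRRD0004",
               "# Complete NRRD file format specification at:",
               "# http://teem.sourceforge.net/nrrd/format.html",
               "type: float",
               "dimension: 3",
               "space dimension: 3",
               sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
               sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                       v$spacing[1], v$spacing[2], v$spacing[3]),
               "kinds: domain domain domain",
               "endian: little",
               "encoding: raw",
               sprintf("space origin: (%.17g,%.17g,%.17g)",
                       v$origin[1], v$origin[2], v$origin[3]),
               "")
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      writeBin(as.numeric(v$data), con, size = 4L, endian = "little")
    },
    mha = {
      hdr <- c("ObjectType = Image",
               "NDims = 3",
               "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               "CompressedData = False",
               "TransformMatrix = 1 0 0 0 1 0 0 0 1",
               sprintf("Offset = %.17g %.17g %.17g",
                       v$origin[1], v$origin[2], v$origin[3]),
               "CenterOfRotation = 0 0 0",
               sprintf("ElementSpacing = %.17g %.17g %.17g",
                       v$spacing[1], v$spacing[2], v$spacing[3]),
               sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
               "ElementType = MET_FLOAT",
               "ElementDataFile = LOCAL")
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(hdr, con, sep = "\n")
      writeBin(as.numeric(v$data), con, size = 4L, endian = "little")
    },
    nifti = {
      img <- RNifti::asNifti(v$data)
      RNifti::pixdim(img) <- v$spacing
      m <- diag(c(v$spacing, 1))
      m[1:3, 4] <- v$origin
      img <- RNifti::`sform<-`(img, structure(m, code = 2L))
      img <- RNifti::`qform<-`(img, structure(m, code = 2L))
      RNifti::writeNifti(img, path)
    },
    .helixreg_error("helixreg_format_error", paste("unsupported format:", format)))
  invisible(path)
}

.read_text_header <- function(con, terminator_blank = TRUE, max_lines = 200L) {
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L)
      .helixreg_error("helixreg_format_error", "truncated header")
    if (terminator_blank && !nzchar(ln)) break
    lines <- c(lines, ln)
    if (!terminator_blank && grepl("^ElementDataFile", ln)) break
    if (length(lines) > max_lines)
      .helixreg_error("helixreg_format_error", "header too long or unterminated")
  }
  lines
}

.parse_vectors <- function(s) {
  # "(a,b,c) (d,e,f)" -> list of numeric vectors
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(x) as.numeric(strsplit(gsub("[()]", "", x), ",")[[1]]))
}

.check_axis_aligned <- function(dirs, tol = 1e-9) {
  # dirs: 3x3 matrix, rows = per-axis direction vectors scaled by spacing
  spacing <- sqrt(rowSums(dirs^2))
  if (max(abs(dirs - diag(spacing))) > tol * max(spacing))
    .helixreg_error("helixreg_unsupported_geometry",
                    "only identity direction matrices are supported")
  spacing
}

.read_raw_payload <- function(con, n, size, what = "numeric") {
  data <- readBin(con, what = what, n = n, size = size, endian = "little")
  if (length(data) != n)
    .helixreg_error("helixreg_format_error", "truncated volume payload")
  data
}

#' Read a volume from NRRD, MetaImage or NIfTI
#'
#' Populates spacing and origin from the header. Files with non-identity
#' direction matrices are rejected; NRRD support covers attached raw
#' little-endian payloads (float/double/short).
#'
#' @param path input file.
#' @param format override the format guessed from the extension.
#' @return a `voxel_volume`.
#' @export
read_volume <- function(path, format = .guess_format(path)) {
  if (!file.exists(path))
    .helixreg_error("helixreg_io_error", paste("no such file:", path))
  switch(format,
    nrrd = {
      con <- file(path, "rb")
      on.exit(close(con))
      hdr <- .read_text_header(con)
      if (!grepl("^NRRD", hdr[1]))
        .helixreg_error("helixreg_format_error", "not an NRRD file")
      fields <- hdr[grepl(":", hdr) & !grepl("^#", hdr)]
      keys <- tolower(trimws(sub(":.*$", "", fields)))
      vals <- trimws(sub("^[^:]*:=?", "", fields))
      get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
      if (!identical(tolower(get("encoding")), "raw"))
        .helixreg_error("helixreg_format_error", "only raw NRRD encoding is supported")
      endian <- get("endian")
      if (!is.null(endian) && tolower(endian) != "little")
        .helixreg_error("helixreg_format_error", "only little-endian NRRD is supported")
      sizes <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
      if (length(sizes) != 3L)
        .helixreg_error("helixreg_unsupported_geometry", "only 3D NRRD is supported")
      dirs <- .parse_vectors(get("space directions"))
      spacing <- .check_axis_aligned(do.call(rbind, dirs))
      origin <- .parse_vectors(get("space origin"))[[1]]
      type <- tolower(get("type"))
      sz <- switch(type, float = 4L, double = 8L, short = 2L, int16 = 2L,
                   .helixreg_error("helixreg_format_error",
                                   paste("unsupported NRRD type:", type)))
      what <- if (sz == 2L) "integer" else "numeric"
      data <- .read_raw_payload(con, prod(sizes), sz, what)
      voxel_volume(array(data, sizes), spacing, origin)
    },
    mha = {
      con <- file(path, "rb")
      on.exit(close(con))
      hdr <- .read_text_header(con, terminator_blank = FALSE)
      kv <- strsplit(hdr, "\\s*=\\s*")
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
      get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
      if (!identical(get("ElementDataFile"), "LOCAL"))
        .helixreg_error("helixreg_format_error", "only attached (LOCAL) MetaImage data is supported")
      if (identical(tolower(get("BinaryDataByteOrderMSB")), "true"))
        .helixreg_error("helixreg_format_error", "only little-endian MetaImage is supported")
      tm <- as.numeric(strsplit(get("TransformMatrix"), "\\s+")[[1]])
      if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-9)
        .helixreg_error("helixreg_unsupported_geometry",
                        "only identity direction matrices are supported")
      sizes <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
      spacing <- as.numeric(strsplit(get("ElementSpacing"), "\\s+")[[1]])
      origin <- as.numeric(strsplit(get("Offset"), "\\s+")[[1]])
      et <- get("ElementType")
      sz <- switch(et, MET_FLOAT = 4L, MET_DOUBLE = 8L, MET_SHORT = 2L,
                   .helixreg_error("helixreg_format_error",
                                   paste("unsupported MetaImage type:", et)))
      what <- if (sz == 2L) "integer" else "numeric"
      data <- .read_raw_payload(con, prod(sizes), sz, what)
      voxel_volume(array(data, sizes), spacing, origin)
    },
    nifti = {
      img <- RNifti::readNifti(path)
      if (length(dim(img)) != 3L)
        .helixreg_error("helixreg_unsupported_geometry", "only 3D NIfTI is supported")
      xf <- RNifti::xform(img)
      spacing <- .check_axis_aligned(t(xf[1:3, 1:3]))
      voxel_volume(array(as.numeric(img), dim(img)), spacing, xf[1:3, 4])
    },
    .helixreg_error("helixreg_format_error", paste("unsupported format:", format)))
}

#' Origin placing the volume center at world (0, 0, 0)
#'
#' Convenience for the CBCT convention used throughout: the isocenter (the
#' FOV center) is the world origin.
#'
#' @param dims length-3 voxel counts.
#' @param spacing length-3 voxel size (mm).
#' @export
centered_origin <- function(dims, spacing) {
  -(dims - 1) / 2 * spacing
}
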