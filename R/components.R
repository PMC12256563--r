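# 3D binary-mask utilities: connected components (run-length union-find),
# majority (median) filtering, closing and hole filling. Written against
# logical 3D arrays; label_components is the workhorse behind fiducial
# extraction and treatment-zone post-processing.

#' Label connected components of a 3D mask
#'
#' Run-length encodes the mask along the first axis and merges runs between
#' neighboring columns with a union-find, so cost scales with the number of
#' foreground runs rather than the volume size.
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (face) or 26 (face/edge/corner) neighborhood.
#' @return integer array of component labels (0 = background), with an
#'   attribute `n` giving the number of components.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # run-length encode each x-column
  runs_start <- integer(0); runs_end <- integer(0); runs_col <- integer(0)
  col_runs <- vector("list", ny * nz)  # run ids per column
  rid <- 0L
  for (k in seq_len(nz)) {
    for (j in seq_len(ny)) {
      cm <- mask[, j, k]
      if (!any(cm)) next
      r <- rle(cm)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values
      s <- starts[keep]; e <- ends[keep]
      ids <- rid + seq_along(s)
      rid <- rid + length(s)
      runs_start <- c(runs_start, s); runs_end <- c(runs_end, e)
      runs_col <- c(runs_col, rep.int((k - 1L) * ny + j, length(s)))
      col_runs[[(k - 1L) * ny + j]] <- ids
    }
  }
  labels <- array(0L, d)
  if (rid == 0L) { attr(labels, "n") <- 0L; return(labels) }
  parent <- seq_len(rid)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  # neighbor column offsets (forward half-space to visit each pair once)
  offs <- if (connectivity == 6) list(c(1L, 0L), c(0L, 1L)) else
    list(c(1L, 0L), c(0L, 1L), c(-1L, 1L), c(1L, 1L))
  slack <- if (connectivity == 26) 1L else 0L
  for (k in seq_len(nz)) {
    for (j in seq_len(ny)) {
      a_ids <- col_runs[[(k - 1L) * ny + j]]
      if (is.null(a_ids)) next
      for (o in offs) {
        j2 <- j + o[1]; k2 <- k + o[2]
        if (j2 < 1L || j2 > ny || k2 > nz) next
        b_ids <- col_runs[[(k2 - 1L) * ny + j2]]
        if (is.null(b_ids)) next
        for (a in a_ids) {
          for (b in b_ids) {
            if (runs_start[a] <= runs_end[b] + slack &&
                runs_start[b] <= runs_end[a] + slack) {
              ra <- find(a); rb <- find(b)
              if (ra != rb) parent[ra] <- rb
            }
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(rid), find, 0L)
  lab_of_root <- integer(rid)
  uroots <- unique(roots)
  lab_of_root[uroots] <- seq_along(uroots)
  run_labels <- lab_of_root[roots]
  for (i in seq_len(rid)) {
    col <- runs_col[i]
    k <- (col - 1L) %/% ny + 1L
    j <- col - (k - 1L) * ny
    labels[runs_start[i]:runs_end[i], j, k] <- run_labels[i]
  }
  attr(labels, "n") <- length(uroots)
  labels
}

#' Keep only the largest connected component
#' @param mask 3D logical array.
#' @param connectivity neighborhood passed to [label_components()].
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (attr(lab, "n") == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L], nbins = attr(lab, "n"))
  lab == which.max(counts)
}

# sum of mask over a centered box neighborhood of half-widths r (voxels),
# zero-padded; vectorized via shifted-array accumulation
.box_count <- function(mask, r) {
  d <- dim(mask)
  acc <- array(0L, d)
  m <- array(as.integer(mask), d)
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    xs <- max(1L, 1L + dx):min(d[1], d[1] + dx)
    ys <- max(1L, 1L + dy):min(d[2], d[2] + dy)
    zs <- max(1L, 1L + dz):min(d[3], d[3] + dz)
    acc[xs - dx, ys - dy, zs - dz] <- acc[xs - dx, ys - dy, zs - dz] + m[xs, ys, zs]
  }
  acc
}

.kernel_radius_vox <- function(kernel_mm, spacing) {
  pmax(1L, as.integer(round(kernel_mm / spacing)))
}

#' Median (majority) filter for a binary mask
#' @param mask 3D logical array.
#' @param radius_vox length-3 integer half-widths of the box kernel (voxels).
#' @export
median_filter_mask <- function(mask, radius_vox = c(1L, 1L, 1L)) {
  radius_vox <- rep_len(as.integer(radius_vox), 3L)
  k <- prod(2L * radius_vox + 1L)
  .box_count(mask, radius_vox) * 2L > k
}

#' Morphological closing of a binary mask
#' @param mask 3D logical array.
#' @param radius_vox length-3 integer half-widths of the box structuring
#'   element (voxels).
#' @export
close_mask <- function(mask, radius_vox = c(1L, 1L, 1L)) {
  radius_vox <- rep_len(as.integer(radius_vox), 3L)
  k <- prod(2L * radius_vox + 1L)
  dil <- .box_count(mask, radius_vox) > 0L
  .box_count(dil, radius_vox) == k
}

#' Fill enclosed cavities in a binary mask
#'
#' Background components (6-connectivity) not reaching the volume border are
#' interior cavities and are filled.
#'
#' @param mask 3D logical array.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 6)
  n <- attr(lab, "n")
  if (n == 0L) return(mask)
  d <- dim(mask)
  border <- unique(c(lab[c(1L, d[1]), , ], lab[, c(1L, d[2]), ], lab[, , c(1L, d[3])]))
  border <- border[border > 0L]
  interior <- setdiff(seq_len(n), border)
  if (length(interior)) mask[lab %in% interior] <- TRUE
  mask
}
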