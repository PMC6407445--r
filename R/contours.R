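# Contour-stack to volume conversion.
#
# Hand-drawn per-slice regions of interest are represented as closed planar
# polygons; the stack is turned into a voxel solid by computing a signed
# distance field (SDF, negative inside) for each slice and linearly
# interpolating the SDFs between slice centres. Each slice represents a
# slab of thickness slice_thickness centred on the slice position, so a
# stack of n identical slices yields a solid n * thickness deep.

#' Construct a contour stack
#'
#' @param polygons list with one element per slice; each element is a list
#'   of closed polygons (n x 2 matrices of in-plane mm coordinates, first
#'   vertex repeated as the last). A slice may be an empty list.
#' @param slice_thickness_mm slice thickness / spacing (mm).
#' @param slice_axis axis perpendicular to the slices, 1, 2 or 3 (world x,
#'   y or z); in-plane polygon coordinates refer to the remaining two axes
#'   in ascending order.
#' @param slice0_mm world position of the first slice centre along
#'   `slice_axis`.
#' @return An object of class `sns_contours`.
#' @export
contour_stack <- function(polygons, slice_thickness_mm,
                          slice_axis = 3L, slice0_mm = slice_thickness_mm / 2) {
  stopifnot(is.list(polygons), slice_thickness_mm > 0,
            slice_axis %in% 1:3)
  if (length(polygons) == 0) {
    stop("contour stack has zero slices", call. = FALSE)
  }
  n_poly <- 0L
  for (s in seq_along(polygons)) {
    for (p in polygons[[s]]) {
      stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 4)
      if (!isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE))) {
        stop("polygon on slice ", s, " is not closed (first vertex must ",
             "equal the last)", call. = FALSE)
      }
      n_poly <- n_poly + 1L
    }
  }
  if (n_poly == 0L) {
    stop("contour stack has no non-empty slice", call. = FALSE)
  }
  structure(list(polygons = polygons,
                 slice_thickness_mm = slice_thickness_mm,
                 slice_axis = as.integer(slice_axis),
                 slice0_mm = slice0_mm),
            class = "sns_contours")
}

# signed distance (negative inside) from grid points (xg, yg vectors) to the
# union of polygons; +Inf when the slice is empty
slice_sdf <- function(polys, xg, yg) {
  nx <- length(xg)
  ny <- length(yg)
  if (length(polys) == 0) {
    return(matrix(Inf, nx, ny))
  }
  px <- rep(xg, times = ny)
  py <- rep(yg, each = nx)
  dmin <- rep(Inf, nx * ny)
  inside <- rep(FALSE, nx * ny)
  for (p in polys) {
    v <- p[-nrow(p), , drop = FALSE]   # unique vertices
    w <- p[-1, , drop = FALSE]         # next vertex
    for (e in seq_len(nrow(v))) {
      ax <- v[e, 1]; ay <- v[e, 2]
      bx <- w[e, 1]; by <- w[e, 2]
      ex <- bx - ax; ey <- by - ay
      len2 <- ex * ex + ey * ey
      t <- if (len2 > 0) pmin(1, pmax(0, ((px - ax) * ex + (py - ay) * ey) /
                                        len2)) else 0
      dx <- px - (ax + t * ex)
      dy <- py - (ay + t * ey)
      dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
    }
    inside <- inside | as.logical(pracma::inpolygon(px, py, v[, 1], v[, 2],
                                                    boundary = TRUE))
  }
  matrix(ifelse(inside, -dmin, dmin), nx, ny)
}

#' Voxelise a contour stack
#'
#' Converts the stack into a binary voxel mask on a regular grid by linear
#' interpolation of per-slice signed distance fields between slice centres
#' (a reproducible stand-in for proprietary surface lofting). Within half a
#' slice thickness beyond the end slices the end SDF is used unchanged, so
#' the solid depth equals slices x thickness for a constant cross-section.
#'
#' @param stack an `sns_contours` from [contour_stack()].
#' @param voxel_mm isotropic voxel size of the output grid (mm).
#' @param extent_mm optional length-3 extent of the output grid (mm);
#'   defaults to the stack bounding box padded by one voxel.
#' @param origin_mm world low corner of the output grid.
#' @return List with `mask` (logical 3-D array), `voxel_mm`, `origin_mm`.
#' @export
contours_to_volume <- function(stack, voxel_mm, extent_mm = NULL,
                               origin_mm = NULL) {
  stopifnot(inherits(stack, "sns_contours"), voxel_mm > 0)
  sa <- stack$slice_axis
  ip <- setdiff(1:3, sa)  # in-plane axes, ascending
  ns <- length(stack$polygons)
  zpos <- stack$slice0_mm + (seq_len(ns) - 1) * stack$slice_thickness_mm

  allv <- do.call(rbind, unlist(stack$polygons, recursive = FALSE))
  if (is.null(extent_mm) || is.null(origin_mm)) {
    lo <- numeric(3); hi <- numeric(3)
    lo[ip] <- apply(allv, 2, min) - 2 * voxel_mm
    hi[ip] <- apply(allv, 2, max) + 2 * voxel_mm
    lo[sa] <- zpos[1] - stack$slice_thickness_mm / 2 - voxel_mm
    hi[sa] <- zpos[ns] + stack$slice_thickness_mm / 2 + voxel_mm
    if (is.null(origin_mm)) origin_mm <- lo
    if (is.null(extent_mm)) extent_mm <- hi - origin_mm
  }
  d <- pmax(1L, as.integer(round(extent_mm / voxel_mm)))
  axes <- lapply(1:3, function(a) origin_mm[a] + (seq_len(d[a]) - 0.5) *
                   voxel_mm)
  # bounding-box coverage check
  if (min(axes[[ip[1]]]) > min(allv[, 1]) ||
      max(axes[[ip[1]]]) < max(allv[, 1]) ||
      min(axes[[ip[2]]]) > min(allv[, 2]) ||
      max(axes[[ip[2]]]) < max(allv[, 2])) {
    stop("output grid does not cover the contour bounding box", call. = FALSE)
  }

  sdfs <- lapply(stack$polygons, slice_sdf, xg = axes[[ip[1]]],
                 yg = axes[[ip[2]]])
  half <- stack$slice_thickness_mm / 2
  zq <- axes[[sa]]
  mask_planes <- vector("list", d[sa])
  for (k in seq_len(d[sa])) {
    z <- zq[k]
    if (z < zpos[1] - half || z > zpos[ns] + half) {
      mask_planes[[k]] <- matrix(FALSE, d[ip[1]], d[ip[2]])
    } else if (z <= zpos[1]) {
      mask_planes[[k]] <- sdfs[[1]] < 0
    } else if (z >= zpos[ns]) {
      mask_planes[[k]] <- sdfs[[ns]] < 0
    } else {
      s1 <- findInterval(z, zpos)
      w <- (z - zpos[s1]) / (zpos[s1 + 1] - zpos[s1])
      f1 <- sdfs[[s1]]; f2 <- sdfs[[s1 + 1]]
      # Inf (empty slice) blended with a finite SDF: cap at a large finite
      # distance so the solid tapers out within the gap
      big <- 10 * max(stack$slice_thickness_mm, voxel_mm)
      f1 <- pmin(f1, big); f2 <- pmin(f2, big)
      mask_planes[[k]] <- ((1 - w) * f1 + w * f2) < 0
    }
  }
  mask <- array(FALSE, dim = d)
  idx <- vector("list", 3)
  for (k in seq_len(d[sa])) {
    idx[[sa]] <- k
    idx[[ip[1]]] <- seq_len(d[ip[1]])
    idx[[ip[2]]] <- seq_len(d[ip[2]])
    mask[idx[[1]], idx[[2]], idx[[3]]] <- mask_planes[[k]]
  }
  list(mask = mask, voxel_mm = rep(voxel_mm, 3), origin_mm = origin_mm)
}

#' Read / write contour stacks as CSV
#'
#' CSV columns: `slice_index` (1-based), `polygon_id`, `x`, `y` (in-plane
#' mm). Polygons are closed on read if the last vertex does not repeat the
#' first.
#'
#' @param stack an `sns_contours`.
#' @param path file path.
#' @param slice_thickness_mm,slice_axis,slice0_mm stack metadata for
#'   [read_contours_csv()] (not stored in the CSV).
#' @return [read_contours_csv()] returns an `sns_contours`;
#'   [write_contours_csv()] returns `path` invisibly.
#' @export
write_contours_csv <- function(stack, path) {
  rows <- list()
  for (s in seq_along(stack$polygons)) {
    for (q in seq_along(stack$polygons[[s]])) {
      p <- stack$polygons[[s]][[q]]
      rows[[length(rows) + 1]] <- data.frame(
        slice_index = s, polygon_id = q, x = p[, 1], y = p[, 2])
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path, slice_thickness_mm, slice_axis = 3L,
                              slice0_mm = slice_thickness_mm / 2) {
  df <- read.csv(path)
  stopifnot(all(c("slice_index", "polygon_id", "x", "y") %in% names(df)))
  ns <- max(df$slice_index)
  polys <- vector("list", ns)
  for (s in seq_len(ns)) polys[[s]] <- list()
  for (key in unique(paste(df$slice_index, df$polygon_id))) {
    sub <- df[paste(df$slice_index, df$polygon_id) == key, ]
    p <- as.matrix(sub[, c("x", "y")])
    if (!isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE))) {
      p <- rbind(p, p[1, ])
    }
    s <- sub$slice_index[1]
    polys[[s]][[length(polys[[s]]) + 1]] <- unname(p)
  }
  contour_stack(polys, slice_thickness_mm, slice_axis, slice0_mm)
}
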