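# Operations on solved potential fields: interpolation, isopotential
# volume, field-line tracing and the activating function.

#' Sample a potential field at world points
#'
#' Trilinear interpolation on the voxel-centre grid; exact at voxel
#' centres. Points must lie within the convex hull of the voxel centres.
#'
#' @param field an `sns_field`.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of potentials (V), one per point.
#' @export
sample_potential <- function(field, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  d <- dim(field$values)
  h <- field$voxel_mm
  # continuous index coordinate: voxel centre i is at index i
  ci <- sweep(sweep(points, 2, field$origin_mm), 2, h, "/") + 0.5
  bad <- which(apply(ci, 1, function(r) any(r < 1 - 1e-9) ||
                       any(r > d + 1e-9)))
  if (length(bad) > 0) {
    stop("point(s) outside the field grid: index ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  ci <- pmin(pmax(ci, 1), matrix(d, nrow(ci), 3, byrow = TRUE))
  i0 <- pmin(pmax(floor(ci), 1), matrix(d - 1L, nrow(ci), 3, byrow = TRUE))
  fr <- ci - i0
  v <- field$values
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  out <-
    idx(0, 0, 0) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    idx(1, 0, 0) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    idx(0, 1, 0) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    idx(1, 1, 0) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    idx(0, 0, 1) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    idx(1, 0, 1) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    idx(0, 1, 1) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    idx(1, 1, 1) * fr[, 1] * fr[, 2] * fr[, 3]
  as.numeric(out)
}

#' Isopotential volume
#'
#' Voxel-counted volume of the region at or below a (cathodic, negative)
#' potential level, e.g. the -0.2 V isopotential volume around the active
#' contact.
#'
#' @param field an `sns_field`.
#' @param level_V potential level (V), between the field minimum and 0.
#' @return Volume in cubic millimetres.
#' @export
isopotential_volume <- function(field, level_V) {
  stopifnot(length(level_V) == 1, level_V <= 0)
  vox <- prod(field$voxel_mm)
  sum(field$values <= level_V, na.rm = TRUE) * vox
}

#' Trace electric field lines
#'
#' Streamlines of the electric field E = -grad(V), integrated with fixed
#' Euler steps from seed points (conventionally on the cathode surface,
#' where lines run from the anode towards the cathode; tracing ascends the
#' potential from cathode to anode). Lines terminate near the anode
#' potential, at the grid boundary, at a vanishing gradient, or at the step
#' cap.
#'
#' @param field an `sns_field`.
#' @param seeds n x 3 matrix of world seed points (mm).
#' @param step_mm integration step (mm).
#' @param max_steps step cap per line.
#' @return List of polylines (matrices of world points), one per seed.
#' @export
trace_field_lines <- function(field, seeds, step_mm = NULL, max_steps = 2000L) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3)
  if (is.null(step_mm)) step_mm <- 0.5 * min(field$voxel_mm)
  h <- field$voxel_mm
  d <- dim(field$values)
  lo <- field$origin_mm + h
  hi <- field$origin_mm + d * h - h
  grad_at <- function(p) {
    g <- numeric(3)
    for (a in 1:3) {
      e <- c(0, 0, 0); e[a] <- 0.5 * h[a]
      g[a] <- (sample_potential(field, matrix(p + e, 1)) -
                 sample_potential(field, matrix(p - e, 1))) / h[a]
    }
    g
  }
  lapply(seq_len(nrow(seeds)), function(q) {
    p <- seeds[q, ]
    pts <- matrix(p, 1)
    for (s in seq_len(max_steps)) {
      if (any(p < lo) || any(p > hi)) break
      g <- grad_at(p)
      gn <- sqrt(sum(g^2))
      if (gn < 1e-12) break
      # ascend V: from the cathode (minimum) towards the anode (0 V)
      p <- p + step_mm * g / gn
      if (any(p < lo) || any(p > hi)) break
      pts <- rbind(pts, p)
      vcur <- sample_potential(field, matrix(p, 1))
      if (vcur > -1e-3 * field$amplitude_V) break
    }
    unname(pts)
  })
}

#' Activating function along a fibre path
#'
#' Second spatial difference of the extracellular potential along an
#' ordered, evenly spaced set of sample points:
#' `D2V[i] = V[i-1] - 2 V[i] + V[i+1]` (endpoints excluded). Large positive
#' values predict sites of extracellular cathodic activation.
#'
#' @param field an `sns_field`, or a numeric vector of potentials already
#'   sampled along the path.
#' @param path n x 3 matrix of evenly spaced points (mm), n >= 3; ignored
#'   when `field` is a numeric vector.
#' @return Numeric vector of length n - 2 (volts).
#' @export
activating_function <- function(field, path = NULL) {
  if (is.numeric(field) && is.null(dim(field))) {
    v <- field
  } else {
    if (is.null(dim(path))) path <- matrix(path, ncol = 3)
    if (nrow(path) < 3) {
      stop("activating function needs at least 3 sample points", call. = FALSE)
    }
    v <- sample_potential(field, path)
  }
  if (length(v) < 3) {
    stop("activating function needs at least 3 sample points", call. = FALSE)
  }
  n <- length(v)
  v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]
}
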