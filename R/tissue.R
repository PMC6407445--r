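# Labelled voxel tissue volumes.
#
# A tissue model is a 3-D integer label array on a regular grid plus a
# label -> conductivity table (S/m). World coordinates: the voxel (i,j,k)
# has its centre at origin + (c(i,j,k) - 0.5) * voxel_mm. Hardware labels
# (shaft insulation, the four contacts, the IPG) are reserved and carry
# zero conductivity in the table; during a solve the active contacts are
# treated as ideal conductors held at the driving potential.

#' Tissue label codes
#'
#' Integer codes used in tissue label grids. Codes 1-9 are tissues,
#' 10-19 lead hardware, 20 the IPG.
#' @return Named integer vector of label codes.
#' @export
tissue_labels <- function() {
  c(fat = 1L, bone = 2L, colon = 3L,
    shaft = 10L, contact0 = 11L, contact1 = 12L, contact2 = 13L,
    contact3 = 14L, ipg = 20L)
}

#' Default tissue conductivities
#'
#' Conductivities at stimulation frequency: bone 0.02 S/m, colon 0.01 S/m,
#' fat (used for the whole pelvic background) 0.01 S/m. Hardware labels are
#' insulating (0 S/m) unless a contact is driven.
#' @return Named numeric vector, S/m.
#' @export
default_conductivities <- function() {
  c(fat = 0.01, bone = 0.02, colon = 0.01,
    shaft = 0, contact0 = 0, contact1 = 0, contact2 = 0, contact3 = 0,
    ipg = 0)
}

#' Construct a tissue model
#'
#' @param label_grid 3-D integer array of label codes (see [tissue_labels()]).
#' @param voxel_mm voxel edge lengths, length-3 numeric (mm); a scalar is
#'   recycled (isotropic voxels).
#' @param origin_mm world coordinates of the low corner of the volume (mm).
#' @param conductivity named numeric vector, label name -> sigma (S/m); every
#'   label present in `label_grid` must be covered.
#' @return An object of class `sns_tissue`.
#' @export
tissue_model <- function(label_grid, voxel_mm,
                         origin_mm = c(0, 0, 0),
                         conductivity = default_conductivities()) {
  stopifnot(is.array(label_grid), length(dim(label_grid)) == 3)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(length(voxel_mm) == 3, all(voxel_mm > 0))
  storage.mode(label_grid) <- "integer"
  codes <- tissue_labels()
  present <- sort(unique(as.integer(label_grid)))
  covered <- codes[intersect(names(codes), names(conductivity))]
  missing_codes <- setdiff(present, covered)
  if (length(missing_codes) > 0) {
    stop("label codes without a conductivity entry: ",
         paste(missing_codes, collapse = ", "), call. = FALSE)
  }
  structure(list(
    labels = label_grid,
    voxel_mm = as.numeric(voxel_mm),
    origin_mm = as.numeric(origin_mm),
    conductivity = conductivity
  ), class = "sns_tissue")
}

#' @export
print.sns_tissue <- function(x, ...) {
  d <- dim(x$labels)
  ext <- d * x$voxel_mm
  cat(sprintf("sns_tissue: %d x %d x %d voxels at %.3g x %.3g x %.3g mm (%.0f x %.0f x %.0f mm)\n",
              d[1], d[2], d[3], x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3],
              ext[1], ext[2], ext[3]))
  codes <- tissue_labels()
  tab <- table(x$labels)
  for (nm in names(tab)) {
    lbl <- names(codes)[match(as.integer(nm), codes)]
    if (is.na(lbl)) lbl <- paste0("code ", nm)
    cat(sprintf("  %-9s %9d voxels (sigma = %g S/m)\n", lbl, tab[[nm]],
                if (!is.na(lbl) && lbl %in% names(x$conductivity))
                  x$conductivity[[lbl]] else NA))
  }
  invisible(x)
}

# voxel-centre coordinate vectors along each axis
grid_axes <- function(tissue) {
  d <- dim(tissue$labels)
  lapply(1:3, function(a) {
    tissue$origin_mm[a] + (seq_len(d[a]) - 0.5) * tissue$voxel_mm[a]
  })
}

grid_extent <- function(tissue) {
  dim(tissue$labels) * tissue$voxel_mm
}

# conductivity array (S/m) from labels; hardware sigma comes from the table
sigma_array <- function(tissue) {
  codes <- tissue_labels()
  sig <- tissue$conductivity[match(as.integer(tissue$labels), codes)]
  sig <- array(as.numeric(sig), dim = dim(tissue$labels))
  sig
}

#' Homogeneous tissue block
#'
#' A single-label volume at the fat conductivity (0.01 S/m), used as the
#' no-anatomy reference medium.
#'
#' @param extent_mm overall size, mm (default `c(150, 150, 120)`).
#' @param voxel_mm isotropic voxel size, mm (default 1.15, echoing the
#'   in-plane MRI resolution the pipeline emulates).
#' @return An `sns_tissue` whose every voxel is fat.
#' @export
make_homogeneous <- function(extent_mm = c(150, 150, 120), voxel_mm = 1.15) {
  extent_mm <- as.numeric(extent_mm)
  stopifnot(length(extent_mm) == 3, all(extent_mm > 0), voxel_mm > 0)
  d <- pmax(1L, as.integer(round(extent_mm / voxel_mm)))
  tissue_model(array(tissue_labels()[["fat"]], dim = d), voxel_mm)
}

#' Parametric synthetic pelvis
#'
#' Generates a labelled volume with the gross structure of a segmented
#' pelvic scan: a fat background, one sacral bone slab transverse to the
#' lead axis pierced by cylindrical foramen channels (channel interior kept
#' at fat), and one colon-labelled tube. The geometry is parametric, not
#' anatomically registered; `seed` jitters the foramen centres and the tube
#' path slightly so that repeated studies sample mildly different anatomy
#' while `identical(seed, params)` runs are bit-identical.
#'
#' @param extent_mm overall size, mm.
#' @param voxel_mm isotropic voxel size, mm.
#' @param slab_x_mm axial range `(x0, x1)` of the bone slab, mm.
#' @param slab_y_mm,slab_z_mm transverse ranges of the slab, mm.
#' @param foramen_z_mm axial (z) positions of the foramen channel centres.
#' @param foramen_y_mm y position of the channels.
#' @param foramen_diameter_mm channel diameter, mm; must not exceed the slab
#'   transverse extent.
#' @param rectum_centre_mm `(x, y)` of the colon tube axis (tube runs in z).
#' @param rectum_radius_mm tube radius, mm.
#' @param jitter_mm amplitude of seeded geometric jitter, mm.
#' @param seed integer seed for the jitter.
#' @return An `sns_tissue` with labels fat/bone/colon.
#' @export
make_synthetic_pelvis <- function(extent_mm = c(150, 150, 120),
                                  voxel_mm = 1.15,
                                  slab_x_mm = c(40, 70),
                                  slab_y_mm = c(45, 105),
                                  slab_z_mm = c(15, 105),
                                  foramen_z_mm = c(35, 55, 75, 95),
                                  foramen_y_mm = 75,
                                  foramen_diameter_mm = 6,
                                  rectum_centre_mm = c(95, 78),
                                  rectum_radius_mm = 11,
                                  jitter_mm = 0.5,
                                  seed = 1L) {
  stopifnot(length(foramen_z_mm) >= 1, foramen_diameter_mm > 0)
  slab_w <- min(diff(slab_y_mm), diff(slab_z_mm))
  if (foramen_diameter_mm >= slab_w) {
    stop("foramen diameter (", foramen_diameter_mm,
         " mm) must be smaller than the bone slab cross-section", call. = FALSE)
  }
  tis <- make_homogeneous(extent_mm, voxel_mm)
  codes <- tissue_labels()
  ax <- grid_axes(tis)
  d <- dim(tis$labels)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fz <- foramen_z_mm + runif(length(foramen_z_mm), -jitter_mm, jitter_mm)
  fy <- foramen_y_mm + runif(length(foramen_z_mm), -jitter_mm, jitter_mm)
  rphase <- runif(1, 0, 2 * pi)
  ramp <- runif(1, 0, jitter_mm)

  lab <- tis$labels
  # bone slab
  inx <- ax[[1]] >= slab_x_mm[1] & ax[[1]] <= slab_x_mm[2]
  iny <- ax[[2]] >= slab_y_mm[1] & ax[[2]] <= slab_y_mm[2]
  inz <- ax[[3]] >= slab_z_mm[1] & ax[[3]] <= slab_z_mm[2]
  slab_mask <- outer(outer(inx, iny, "&"), inz, "&")
  lab[slab_mask] <- codes[["bone"]]
  # foramen channels along x through the slab (interior back to fat)
  r2 <- (foramen_diameter_mm / 2)^2
  for (q in seq_along(fz)) {
    dy2 <- (ax[[2]] - fy[q])^2
    dz2 <- (ax[[3]] - fz[q])^2
    chan_yz <- outer(dy2, dz2, "+") <= r2
    chan <- outer(inx, chan_yz, "&")
    lab[chan & slab_mask] <- codes[["fat"]]
  }
  # colon tube along z with a gentle seeded bend
  zmid <- mean(range(ax[[3]]))
  for (k in seq_len(d[3])) {
    cx <- rectum_centre_mm[1] + ramp * sin(2 * pi * (ax[[3]][k] - zmid) /
                                             diff(range(ax[[3]])) + rphase)
    cy <- rectum_centre_mm[2]
    dmask <- outer((ax[[1]] - cx)^2, (ax[[2]] - cy)^2, "+") <=
      rectum_radius_mm^2
    sl <- lab[, , k]
    sl[dmask & sl == codes[["fat"]]] <- codes[["colon"]]
    lab[, , k] <- sl
  }
  tis$labels <- lab
  tis$params <- list(extent_mm = extent_mm, voxel_mm = voxel_mm,
                     slab_x_mm = slab_x_mm, slab_y_mm = slab_y_mm,
                     slab_z_mm = slab_z_mm, foramen_z_mm = foramen_z_mm,
                     foramen_y_mm = foramen_y_mm,
                     foramen_diameter_mm = foramen_diameter_mm,
                     rectum_centre_mm = rectum_centre_mm,
                     rectum_radius_mm = rectum_radius_mm,
                     jitter_mm = jitter_mm, seed = as.integer(seed))
  tis
}
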