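# Rasterisation of implanted hardware into the tissue label grid.

#' Rasterise lead and IPG into a tissue model
#'
#' Labels every voxel whose centre falls inside the lead shaft cylinder as
#' insulating shaft, overwrites the contact bands with per-contact labels
#' (contact0..contact3), and labels the IPG cuboid. Tissue labels elsewhere
#' are unchanged. Membership is a voxel-centre-inside test with no
#' partial-volume weighting, so band edges are accurate to one voxel.
#'
#' @param tissue an `sns_tissue`.
#' @param electrode an `sns_electrode` from [make_electrode()].
#' @param placement an `sns_placement` (lead tip + unit axis).
#' @param ipg an `sns_ipg`, or `NULL` to omit the pulse generator.
#' @return The tissue model with hardware labels added; the hardware specs
#'   are recorded in `$hardware`.
#' @export
rasterize_hardware <- function(tissue, electrode, placement, ipg = NULL) {
  stopifnot(inherits(tissue, "sns_tissue"),
            inherits(electrode, "sns_electrode"),
            inherits(placement, "sns_placement"))
  codes <- tissue_labels()
  lo <- tissue$origin_mm
  hi <- tissue$origin_mm + grid_extent(tissue)
  rad <- electrode$diameter_mm / 2

  # containment checks on the analytic solids
  p0 <- placement$tip_mm
  p1 <- placement$tip_mm + placement$axis * electrode$shaft_length_mm
  for (pt in list(p0, p1)) {
    if (any(pt - rad < lo) || any(pt + rad > hi)) {
      stop("lead extends outside the tissue volume", call. = FALSE)
    }
  }
  if (!is.null(ipg)) {
    stopifnot(inherits(ipg, "sns_ipg"))
    clo <- ipg$centre_mm - ipg$dims_mm / 2
    chi <- ipg$centre_mm + ipg$dims_mm / 2
    if (any(clo < lo) || any(chi > hi)) {
      stop("IPG extends outside the tissue volume", call. = FALSE)
    }
  }

  ax <- grid_axes(tissue)
  d <- dim(tissue$labels)
  lab <- tissue$labels

  # lead cylinder: axial coordinate s and radial distance r of voxel centres.
  # Work on a bounding sub-box for speed.
  bb_lo <- pmin(p0, p1) - rad - max(tissue$voxel_mm)
  bb_hi <- pmax(p0, p1) + rad + max(tissue$voxel_mm)
  ix <- which(ax[[1]] >= bb_lo[1] & ax[[1]] <= bb_hi[1])
  iy <- which(ax[[2]] >= bb_lo[2] & ax[[2]] <= bb_hi[2])
  iz <- which(ax[[3]] >= bb_lo[3] & ax[[3]] <= bb_hi[3])
  if (length(ix) && length(iy) && length(iz)) {
    gx <- ax[[1]][ix]; gy <- ax[[2]][iy]; gz <- ax[[3]][iz]
    nxs <- length(ix); nys <- length(iy); nzs <- length(iz)
    px <- array(rep(gx, times = nys * nzs), dim = c(nxs, nys, nzs))
    py <- array(rep(rep(gy, each = nxs), times = nzs), dim = c(nxs, nys, nzs))
    pz <- array(rep(gz, each = nxs * nys), dim = c(nxs, nys, nzs))
    rx <- px - p0[1]; ry <- py - p0[2]; rz <- pz - p0[3]
    s <- rx * placement$axis[1] + ry * placement$axis[2] +
      rz * placement$axis[3]
    r2 <- (rx - s * placement$axis[1])^2 + (ry - s * placement$axis[2])^2 +
      (rz - s * placement$axis[3])^2
    in_shaft <- s >= 0 & s <= electrode$shaft_length_mm & r2 <= rad^2
    sub <- lab[ix, iy, iz]
    sub[in_shaft] <- codes[["shaft"]]
    ext <- contact_extents(electrode)
    for (k in 0:3) {
      on_band <- in_shaft & s >= ext[k + 1, "start"] & s <= ext[k + 1, "end"]
      sub[on_band] <- codes[[paste0("contact", k)]]
    }
    lab[ix, iy, iz] <- sub
  }

  if (!is.null(ipg)) {
    inx <- ax[[1]] >= clo[1] & ax[[1]] <= chi[1]
    iny <- ax[[2]] >= clo[2] & ax[[2]] <= chi[2]
    inz <- ax[[3]] >= clo[3] & ax[[3]] <= chi[3]
    lab[outer(outer(inx, iny, "&"), inz, "&")] <- codes[["ipg"]]
  }

  tissue$labels <- lab
  tissue$hardware <- list(electrode = electrode, placement = placement,
                          ipg = ipg)
  tissue
}
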