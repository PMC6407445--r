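# Quasi-static field solve: del . (sigma del V) = 0 on the voxel grid.
#
# Discretisation: 7-point finite volume with harmonic-mean face
# conductances G = A / (h_a / (2 sigma_a) + h_b / (2 sigma_b)). Active
# electrode voxels are treated as ideal conductors (very large sigma) held
# at the drive potential (Dirichlet); all other hardware is insulating
# (zero sigma, natural zero-flux faces), as is the outer boundary. The
# symmetric positive-definite system is solved by Jacobi-preconditioned
# conjugate gradient with a zero initial guess.

SIGMA_METAL <- 1e6  # S/m, effective conductivity of driven contacts

#' Solve the quasi-static potential
#'
#' Solves the Laplace problem for one stimulation configuration on a tissue
#' model containing rasterised hardware. The cathode voxels are held at
#' `-amplitude_V`, the anode voxels (IPG in monopolar mode, the named
#' contact in bipolar mode) at 0 V. A discrete maximum principle check
#' (values within the Dirichlet range up to solver tolerance) is asserted on
#' the result.
#'
#' @param tissue an `sns_tissue` with hardware labels (see
#'   [rasterize_hardware()]).
#' @param stim an `sns_stim`.
#' @param amplitude_V optional override of the drive amplitude (V).
#' @param tol relative residual tolerance of the conjugate-gradient solve.
#' @param maxit iteration cap.
#' @return An object of class `sns_field`: `values` (3-D array, volts; `NA`
#'   inside insulating hardware unless filled), grid metadata, and solver
#'   diagnostics in `$solve`.
#' @export
solve_potential <- function(tissue, stim, amplitude_V = stim$amplitude_V,
                            tol = 1e-8, maxit = 20000L) {
  stopifnot(inherits(tissue, "sns_tissue"), inherits(stim, "sns_stim"),
            amplitude_V > 0)
  codes <- tissue_labels()
  lab <- tissue$labels
  cath_code <- codes[[paste0("contact", stim$cathode)]]
  an_code <- if (identical(stim$anode, "ipg")) codes[["ipg"]] else
    codes[[paste0("contact", stim$anode)]]
  n_cath <- sum(lab == cath_code)
  n_an <- sum(lab == an_code)
  if (n_cath == 0) {
    stop("cathode contact ", stim$cathode,
         " has no rasterised voxels in the tissue model", call. = FALSE)
  }
  if (n_an == 0) {
    stop("anode (", if (identical(stim$anode, "ipg")) "IPG" else
      paste("contact", stim$anode),
      ") has no rasterised voxels in the tissue model", call. = FALSE)
  }

  sig <- sigma_array(tissue)
  sig[lab == cath_code] <- SIGMA_METAL
  sig[lab == an_code] <- SIGMA_METAL

  d <- dim(lab)
  h <- tissue$voxel_mm  # mm; conductance units cancel in the linear solve
  # harmonic-mean face conductances; zero when either side is insulating
  harm <- function(sa, sb, axis) {
    area <- prod(h[-axis])
    g <- 2 * sa * sb / (sa + sb) * area / h[axis]
    g[!is.finite(g)] <- 0
    g
  }
  gx <- harm(sig[-d[1], , , drop = FALSE], sig[-1, , , drop = FALSE], 1)
  gy <- harm(sig[, -d[2], , drop = FALSE], sig[, -1, , drop = FALSE], 2)
  gz <- harm(sig[, , -d[3], drop = FALSE], sig[, , -1, drop = FALSE], 3)

  # embedded-boundary correction: faces between a driven-hardware voxel and
  # tissue use the distance from the tissue voxel centre to the analytic
  # hardware surface (the electrode is thinner than a voxel at the default
  # grid, so the half-voxel default misplaces its surface)
  gg <- cutcell_faces(tissue, lab, sig, gx, gy, gz,
                      c(cath_code, an_code))
  gx <- gg$gx; gy <- gg$gy; gz <- gg$gz

  mask <- array(0L, dim = d)
  mask[sig == 0] <- 2L
  mask[lab == cath_code] <- 1L
  mask[lab == an_code] <- 1L
  dirval <- array(0, dim = d)
  dirval[lab == cath_code] <- -amplitude_V

  res <- .cg_laplace(as.integer(d), as.numeric(gx), as.numeric(gy),
                     as.numeric(gz), as.integer(mask), as.numeric(dirval),
                     tol, as.integer(maxit))
  if (res$relres > tol && res$iterations >= maxit) {
    warning("conjugate gradient reached the iteration cap (relres = ",
            signif(res$relres, 3), ")")
  }
  vals <- array(res$values, dim = d)
  excl <- array(res$excluded_mask, dim = d) == 2L

  # discrete maximum principle on solved + Dirichlet voxels
  vr <- range(vals[!excl])
  slack <- 10 * tol * amplitude_V + 1e-12
  if (vr[1] < -amplitude_V - slack || vr[2] > slack) {
    stop("discrete maximum principle violated: solved potentials outside [",
         -amplitude_V, ", 0]", call. = FALSE)
  }

  # fill insulating interiors by neighbour averaging so that trilinear
  # sampling next to hardware stays well-defined (values remain in range)
  vals <- fill_excluded(vals, excl)

  structure(list(values = vals,
                 voxel_mm = tissue$voxel_mm,
                 origin_mm = tissue$origin_mm,
                 excluded = excl,
                 stim = stim,
                 amplitude_V = amplitude_V,
                 solve = list(iterations = res$iterations,
                              relres = res$relres,
                              tol = tol,
                              n_cathode_vox = n_cath,
                              n_anode_vox = n_an)),
            class = "sns_field")
}

# Cut-cell face conductances next to driven hardware.
#
# For each face between a Dirichlet hardware voxel and a tissue voxel, the
# conductance becomes sigma_tissue * area / d, where d is the distance from
# the tissue voxel centre to the analytic hardware surface along the
# face-centre segment (found by bisection on the inside test), clamped to
# [0.05, 1] voxel. Without this, the Dirichlet surface sits at the hardware
# voxel centre, which understates the potential around a lead thinner than
# one voxel. Requires the hardware record written by rasterize_hardware();
# tissue models with hand-labelled electrodes (no $hardware) are left with
# the plain harmonic-mean faces.
cutcell_faces <- function(tissue, lab, sig, gx, gy, gz, active_codes) {
  hw <- tissue$hardware
  if (is.null(hw)) return(list(gx = gx, gy = gy, gz = gz))
  codes <- tissue_labels()
  d <- dim(lab)
  h <- tissue$voxel_mm
  ax <- grid_axes(tissue)
  ext <- contact_extents(hw$electrode)
  rad <- hw$electrode$diameter_mm / 2
  p0 <- hw$placement$tip_mm
  u <- hw$placement$axis

  inside_solid <- function(p, code) {
    if (code == codes[["ipg"]]) {
      lo <- hw$ipg$centre_mm - hw$ipg$dims_mm / 2
      hi <- hw$ipg$centre_mm + hw$ipg$dims_mm / 2
      all(p >= lo) && all(p <= hi)
    } else {
      k <- code - codes[["contact0"]]
      s <- sum((p - p0) * u)
      r2 <- sum((p - p0 - s * u)^2)
      r2 <= rad^2 && s >= ext[k + 1, "start"] && s <= ext[k + 1, "end"]
    }
  }

  for (code in active_codes) {
    if (code == codes[["ipg"]] && is.null(hw$ipg)) next
    idx <- which(lab == code, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    for (q in seq_len(nrow(idx))) {
      a <- idx[q, ]
      ca <- c(ax[[1]][a[1]], ax[[2]][a[2]], ax[[3]][a[3]])
      for (axis in 1:3) for (dir in c(-1L, 1L)) {
        b <- a
        b[axis] <- b[axis] + dir
        if (b[axis] < 1 || b[axis] > d[axis]) next
        if (sig[b[1], b[2], b[3]] <= 0 || sig[b[1], b[2], b[3]] >= SIGMA_METAL)
          next
        cb <- ca
        cb[axis] <- ax[[axis]][b[axis]]
        # bisection for the surface crossing on the segment cb -> ca
        tlo <- 0; thi <- 1
        if (!inside_solid(ca, code)) next  # jagged corner; keep default face
        for (it in 1:20) {
          tm <- (tlo + thi) / 2
          if (inside_solid(cb + tm * (ca - cb), code)) thi <- tm else tlo <- tm
        }
        dist_surf <- max(0.05 * h[axis], min(h[axis], thi * h[axis]))
        sigma_t <- sig[b[1], b[2], b[3]]
        area <- prod(h[-axis])
        gval <- sigma_t * area / dist_surf
        f <- pmin(a, b)
        if (axis == 1) gx[f[1], f[2], f[3]] <- gval
        else if (axis == 2) gy[f[1], f[2], f[3]] <- gval
        else gz[f[1], f[2], f[3]] <- gval
      }
    }
  }
  list(gx = gx, gy = gy, gz = gz)
}

# iterative neighbour-mean fill of NA voxels (hardware interiors)
fill_excluded <- function(vals, excl, max_pass = 50L) {
  if (!any(excl)) return(vals)
  d <- dim(vals)
  todo <- excl
  for (pass in seq_len(max_pass)) {
    if (!any(todo)) break
    acc <- array(0, d)
    cnt <- array(0, d)
    shift <- function(a, axis, by) {
      idx <- vector("list", 3)
      for (q in 1:3) idx[[q]] <- seq_len(d[q])
      src <- idx; dst <- idx
      if (by == 1) { src[[axis]] <- 1:(d[axis] - 1); dst[[axis]] <- 2:d[axis] }
      else { src[[axis]] <- 2:d[axis]; dst[[axis]] <- 1:(d[axis] - 1) }
      out <- array(NA_real_, d)
      out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (axis in 1:3) for (by in c(1, -1)) {
      nb <- shift(vals, axis, by)
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt[ok] <- cnt[ok] + 1
    }
    fill_now <- todo & cnt > 0
    vals[fill_now] <- acc[fill_now] / cnt[fill_now]
    todo <- todo & !fill_now
  }
  vals
}

#' @export
print.sns_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("sns_field: %d x %d x %d grid, drive %.3g V (%s, cathode %d)\n",
              d[1], d[2], d[3], x$amplitude_V, x$stim$mode, x$stim$cathode))
  cat(sprintf("  CG: %d iterations, relative residual %.3g\n",
              x$solve$iterations, x$solve$relres))
  cat(sprintf("  potential range: [%.4g, %.4g] V\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}
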