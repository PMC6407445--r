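# Shared fixtures, built in code at test time.

# concentric-spheres Dirichlet problem in a homogeneous block:
# cathode = voxels within ra of the centre (-1 V), anode = voxels beyond rb
# (0 V). Effective electrode radii are the volume-equivalent radii of the
# voxelised Dirichlet sets, computed from geometry alone.
spheres_fixture <- function(extent = 50, h = 1.0, ra = 3, rb = 22) {
  tis <- make_homogeneous(rep(extent, 3), h)
  codes <- tissue_labels()
  ax <- grid_axes(tis)
  ctr <- rep(extent / 2, 3)
  R <- sqrt(outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                  (ax[[3]] - ctr[3])^2, "+"))
  lab <- tis$labels
  lab[R <= ra] <- codes[["contact0"]]
  lab[R >= rb] <- codes[["ipg"]]
  tis$labels <- lab
  ra_eff <- (3 * sum(R <= ra) * h^3 / (4 * pi))^(1 / 3)
  rb_eff <- (3 * sum(R < rb) * h^3 / (4 * pi))^(1 / 3)
  v_analytic <- function(r, amp = 1) {
    -amp * (1 / r - 1 / rb_eff) / (1 / ra_eff - 1 / rb_eff)
  }
  list(tissue = tis, centre = ctr, ra = ra, rb = rb,
       ra_eff = ra_eff, rb_eff = rb_eff, v_analytic = v_analytic, h = h)
}

# small homogeneous block with a lead along +x and a reduced-size return
# block, for fast activation runs
small_lead_fixture <- function(model = "3889", extent = c(110, 44, 44),
                               voxel = 1.0, tip = c(30, 22.5, 22.5)) {
  tis <- make_homogeneous(extent, voxel)
  el <- make_electrode(model)
  plc <- placement(tip, c(1, 0, 0))
  ipg <- ipg_spec(centre_mm = c(extent[1] - 12, 10, 22),
                  dims_mm = c(16, 12, 8))
  list(tissue = tis, electrode = el, placement = plc, ipg = ipg)
}

# analytic extracellular profile of a point current source at transverse
# distance d_mm from the fibre, scaled to peak_V at the closest compartment
point_source_ve <- function(morph, d_mm, peak_V = -1,
                            x0 = mean(range(morph$comp$centre_mm))) {
  r <- sqrt((morph$comp$centre_mm - x0)^2 + d_mm^2)
  peak_V * d_mm / r
}

# short fibre reused across axon tests (built once per test run)
test_axon_30 <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_axon(5.7, 30)
    m
  }
})

three_pulse_train <- function(amplitude_V = 1) {
  stim_config("monopolar", 0, amplitude_V = amplitude_V,
              duration_ms = 3 * 1000 / 14)
}
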