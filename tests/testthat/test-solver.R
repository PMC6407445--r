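# Finite-volume Laplace solver and field operations.

test_that("the solve matches the concentric-spheres analytic solution", {
  fx <- spheres_fixture()
  stim <- stim_config("monopolar", 0, duration_ms = 100)
  f <- solve_potential(fx$tissue, stim)
  # sample along three axes and a diagonal, >= 3 voxels from both boundaries
  rs <- seq(fx$ra + 3 * fx$h, fx$rb - 3 * fx$h, by = 1)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  for (q in seq_len(nrow(dirs))) {
    pts <- sweep(outer(rs, dirs[q, ]), 2, fx$centre, "+")
    err <- abs(sample_potential(f, pts) - fx$v_analytic(rs))
    expect_lt(max(err), 0.05)  # 5% of the 1 V drive
  }
})

test_that("the solve is linear in the drive amplitude", {
  fx <- spheres_fixture(extent = 30, rb = 12)
  stim <- stim_config("monopolar", 0, duration_ms = 100)
  f1 <- solve_potential(fx$tissue, stim, amplitude_V = 1)
  f2 <- solve_potential(fx$tissue, stim, amplitude_V = 2)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-7)
})

test_that("a pure-Dirichlet zero problem returns the zero field", {
  # all Dirichlet voxels at 0 V, nothing driven: V identically 0, no iterations
  d <- c(8L, 8L, 8L)
  mask <- array(0L, d)
  mask[1, , ] <- 1L
  g <- function(dd) array(1, dd)
  res <- .cg_laplace(d, g(c(7, 8, 8)), g(c(8, 7, 8)), g(c(8, 8, 7)),
                     as.integer(mask), array(0, d), 1e-10, 100L)
  expect_equal(res$iterations, 0)
  expect_true(all(res$values == 0))
})

test_that("solves without rasterised cathode or anode are rejected", {
  tis <- make_homogeneous(c(20, 20, 20), 1)
  stim <- stim_config("monopolar", 0, duration_ms = 100)
  expect_error(solve_potential(tis, stim), "cathode")
  codes <- tissue_labels()
  tis$labels[10, 10, 10] <- codes[["contact0"]]
  expect_error(solve_potential(tis, stim), "anode")
})

test_that("the discrete maximum principle holds on an inhomogeneous solve", {
  fx <- small_lead_fixture()
  tis <- fx$tissue
  # add a bone block near the lead to exercise conductivity contrast
  codes <- tissue_labels()
  tis$labels[40:70, 30:40, ] <- codes[["bone"]]
  tis <- rasterize_hardware(tis, fx$electrode, fx$placement, fx$ipg)
  f <- solve_potential(tis, stim_config("monopolar", 1, duration_ms = 100))
  expect_gte(min(f$values, na.rm = TRUE), -1 - 1e-6)
  expect_lte(max(f$values, na.rm = TRUE), 1e-6)
})

test_that("swapped-Dirichlet solves superpose to the constant drive", {
  # with all-Neumann outer boundaries, u(a=-1,b=0) + u(a=0,b=-1) = -1
  fx <- small_lead_fixture()
  tis <- rasterize_hardware(fx$tissue, fx$electrode, fx$placement, fx$ipg)
  s01 <- stim_config("bipolar", 0, anode = 1, duration_ms = 100)
  s10 <- stim_config("bipolar", 1, anode = 0, duration_ms = 100)
  u1 <- solve_potential(tis, s01, tol = 1e-10)
  u2 <- solve_potential(tis, s10, tol = 1e-10)
  resid <- u1$values + u2$values + 1
  expect_lt(max(abs(resid[!u1$excluded])), 1e-4)
})

test_that("sampling is exact at voxel centres and linear between them", {
  fx <- spheres_fixture(extent = 20, ra = 2, rb = 9)
  f <- solve_potential(fx$tissue, stim_config("monopolar", 0,
                                              duration_ms = 100))
  ax <- grid_axes(fx$tissue)
  p1 <- c(ax[[1]][4], ax[[2]][10], ax[[3]][10])
  p2 <- c(ax[[1]][5], ax[[2]][10], ax[[3]][10])
  expect_equal(sample_potential(f, rbind(p1)), f$values[4, 10, 10])
  expect_equal(sample_potential(f, rbind((p1 + p2) / 2)),
               (f$values[4, 10, 10] + f$values[5, 10, 10]) / 2)
  expect_error(sample_potential(f, rbind(c(-5, 10, 10))), "outside")
})

test_that("isopotential volumes match the analytic sphere and shrink with level", {
  fx <- spheres_fixture()
  f <- solve_potential(fx$tissue, stim_config("monopolar", 0,
                                              duration_ms = 100))
  level <- -0.2
  # analytic radius where V = level
  riso <- 1 / (-level * (1 / fx$ra_eff - 1 / fx$rb_eff) + 1 / fx$rb_eff)
  v_ana <- 4 / 3 * pi * riso^3
  v_num <- isopotential_volume(f, level)
  expect_lt(abs(v_num - v_ana) / v_ana, 0.1)
  expect_lte(isopotential_volume(f, -0.4), v_num)  # monotone
  expect_equal(isopotential_volume(f, min(f$values, na.rm = TRUE) - 0.1), 0)
})

test_that("the isopotential volume converges under grid refinement", {
  vols <- vapply(c(2.0, 1.0, 0.5), function(h) {
    fx <- spheres_fixture(extent = 40, h = h, ra = 3, rb = 17)
    f <- solve_potential(fx$tissue, stim_config("monopolar", 0,
                                                duration_ms = 100))
    isopotential_volume(f, -0.2)
  }, 0)
  inc <- abs(diff(vols)) / vols[-1]
  expect_lt(inc[2], inc[1])  # strictly decreasing relative increment
})

test_that("field lines from the cathode are radial in the spheres problem", {
  fx <- spheres_fixture()
  f <- solve_potential(fx$tissue, stim_config("monopolar", 0,
                                              duration_ms = 100))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0),
                c(1, 1, 0) / sqrt(2))
  seeds <- sweep(dirs * (fx$ra + 1.5), 2, fx$centre, "+")
  lines <- trace_field_lines(f, seeds, step_mm = 0.5)
  expect_length(lines, nrow(seeds))
  for (q in seq_along(lines)) {
    pl <- lines[[q]]
    expect_gt(nrow(pl), 5)
    steps <- diff(pl)
    radial <- sweep(pl[-nrow(pl), , drop = FALSE], 2, fx$centre)
    cosang <- rowSums(steps * radial) /
      (sqrt(rowSums(steps^2)) * sqrt(rowSums(radial^2)))
    # ignore the last couple of steps near the outer Dirichlet staircase
    keep <- seq_len(max(1, nrow(steps) - 2))
    expect_gt(min(cosang[keep]), cos(5 * pi / 180))
  }
  # seed in the flat interior of the cathode: zero gradient, zero-length line
  inner <- trace_field_lines(f, rbind(fx$centre), step_mm = 0.5)
  expect_equal(nrow(inner[[1]]), 1)
})

test_that("the activating function reproduces exact finite differences", {
  # linear potential: all zeros; quadratic: constant 2 h^2
  x <- seq(0, 10, by = 0.5)
  expect_equal(activating_function(3 * x + 1), rep(0, length(x) - 2))
  expect_equal(activating_function(x^2), rep(2 * 0.5^2, length(x) - 2))
  expect_error(activating_function(c(1, 2)), "3 sample points")

  # point source: maximum at the node closest to the source
  xs <- seq(-20, 20, by = 0.5)
  src <- 3.2
  v <- -1 / sqrt((xs - src)^2 + 2^2)
  af <- activating_function(v)
  expect_equal(which.max(af), which.min(abs(xs[-c(1, length(xs))] - src)))
})
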