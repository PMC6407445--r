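# Axon grid placement, percent activation and activation runs.

test_that("the axon grid is 4 x 10 parallel fibres at 0.5 mm spacing", {
  spec <- axon_grid_spec()
  el <- make_electrode(3093)
  plc <- placement(c(10, 50, 50), c(1, 0, 0))
  axons <- place_axon_grid(spec, plc, el, centre_axial_mm = 12)
  expect_length(axons, 40)
  groups <- vapply(axons, `[[`, "", "group")
  expect_equal(as.integer(table(groups)[spec$groups]), rep(10L, 4))
  # every path direction equals the lead axis
  for (a in axons) expect_equal(a$direction, plc$axis)
  # adjacent axons in a group are 0.5 mm apart
  for (g in spec$groups) {
    offs <- t(vapply(axons[groups == g], `[[`, c(0, 0), "offset_mm"))
    d <- sqrt(rowSums(offs^2))
    expect_equal(diff(sort(d)), rep(0.5, 9))
    # first row: lead radius + clearance from the axis
    expect_equal(min(d), el$diameter_mm / 2 + spec$clearance_mm)
  }
  expect_error(axon_grid_spec(clearance_mm = 0), "clearance")
  expect_error(axon_grid_spec(clearance_mm = -1), "clearance")
})

test_that("percent activation is the percentage of 1:1 fibres", {
  expect_equal(percent_activated(rep(TRUE, 40)), 100)
  expect_equal(percent_activated(rep(c(TRUE, FALSE), 20)), 50)
  expect_equal(percent_activated(c(rep(TRUE, 14), rep(FALSE, 26))), 35)
  expect_error(percent_activated(rep(TRUE, 39)), "40")
  # invariant to enumeration order
  out <- c(rep(TRUE, 11), rep(FALSE, 29))
  set.seed(42)
  expect_equal(percent_activated(sample(out)), percent_activated(out))
})

test_that("zero amplitude activates nothing", {
  fx <- small_lead_fixture()
  stim <- stim_config("monopolar", 0, duration_ms = 2 * 1000 / 14)
  stim$amplitude_V <- 0  # silent drive (constructor enforces > 0 for runs)
  grid <- axon_grid_spec(length_mm = 40)
  morph <- build_axon(5.7, 40)
  res <- run_configuration(fx$tissue, fx$electrode, fx$placement, stim,
                           grid, ipg = fx$ipg, morph = morph)
  expect_equal(res$percent_activated, 0)
  expect_false(any(res$outcomes$activated))
})

test_that("identical 3 mm contacts activate identical fractions in a homogeneous block", {
  fx <- small_lead_fixture(model = "3889")
  tis <- rasterize_hardware(fx$tissue, fx$electrode, fx$placement, fx$ipg)
  grid <- axon_grid_spec(length_mm = 40)
  morph <- build_axon(5.7, 40)
  pct <- vapply(0:2, function(k) {
    stim <- stim_config("monopolar", k, duration_ms = 2 * 1000 / 14)
    run_configuration(tis, fx$electrode, fx$placement, stim, grid,
                      ipg = fx$ipg, morph = morph)$percent_activated
  }, 0)
  expect_lte(max(pct) - min(pct), 2.5)  # within one axon step
})

test_that("the VTA map is monotone in amplitude and mirror-symmetric", {
  fx <- small_lead_fixture(model = "3889")
  offs <- seq(-2.5, 2.5, by = 1)  # excludes the lead axis cell
  morph <- build_axon(5.7, 40)
  stim1 <- stim_config("monopolar", 1, amplitude_V = 1,
                       duration_ms = 2 * 1000 / 14)
  v1 <- compute_vta_map(fx$tissue, fx$electrode, fx$placement, stim1,
                        ipg = fx$ipg, offsets_u_mm = offs,
                        offsets_w_mm = offs, morph = morph)
  stim2 <- stim_config("monopolar", 1, amplitude_V = 2,
                       duration_ms = 2 * 1000 / 14)
  v2 <- compute_vta_map(fx$tissue, fx$electrode, fx$placement, stim2,
                        ipg = fx$ipg, offsets_u_mm = offs,
                        offsets_w_mm = offs, morph = morph)
  ok <- !is.na(v1$map)
  expect_true(all(v2$map[ok] | !v1$map[ok]))      # superset at higher drive
  expect_gt(sum(v2$map, na.rm = TRUE), sum(v1$map, na.rm = TRUE))
  # mirror symmetry across the lead in the homogeneous medium
  expect_equal(v1$map, v1$map[rev(seq_along(offs)), ])
  expect_equal(v1$map, v1$map[, rev(seq_along(offs))])

  # zero amplitude: all-false map, lead interior masked
  stim0 <- stim_config("monopolar", 1, duration_ms = 2 * 1000 / 14)
  stim0$amplitude_V <- 0
  offs0 <- seq(-1, 1, by = 0.5)
  v0 <- compute_vta_map(fx$tissue, fx$electrode, fx$placement, stim0,
                        ipg = fx$ipg, offsets_u_mm = offs0,
                        offsets_w_mm = offs0, morph = morph)
  expect_true(all(is.na(v0$map[abs(outer(offs0^2, offs0^2, "+")) <=
                                 (fx$electrode$diameter_mm / 2)^2])))
  expect_false(any(v0$map, na.rm = TRUE))
})

test_that("VTA maps export to PNG plus a numeric grid", {
  vta <- structure(list(map = matrix(c(TRUE, FALSE, NA, TRUE), 2),
                        offsets_u_mm = c(0, 1), offsets_w_mm = c(0, 1),
                        model_id = "3889",
                        stim = stim_config("monopolar", 0, duration_ms = 100),
                        centre_axial_mm = 5), class = "sns_vtamap")
  path <- tempfile(fileext = ".png")
  write_vta_png(vta, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".tsv")))
  img <- png::readPNG(path)
  expect_equal(dim(img), c(2, 2))
})
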