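# Double-cable axon model: morphology, rest, excitation, thresholds.

test_that("morphology follows the published internodal pattern", {
  m <- build_axon(5.7, 100)
  expect_equal(m$n_nodes, 201)  # floor(100 mm / 0.5 mm) + 1
  expect_equal(m$comp$type[1], "node")
  expect_equal(m$comp$type[m$n_comp], "node")
  # repeating pattern between consecutive nodes
  nodes <- which(m$comp$type == "node")
  between <- m$comp$type[(nodes[1] + 1):(nodes[2] - 1)]
  expect_equal(between,
               c("MYSA", "FLUT", rep("STIN", 6), "FLUT", "MYSA"))
  # compartment lengths per internode sum to the internodal spacing
  internode <- sum(m$comp$length_um[nodes[1]:(nodes[2] - 1)])
  expect_equal(internode, m$internode_um)
  expect_true(all(m$geom$ga > 0))
  expect_true(all(m$geom$gp > 0))
})

test_that("unsupported diameters and lengths are rejected", {
  expect_error(build_axon(6.5), "5.7")
  expect_error(build_axon(5.7, 0), "internode")
  m <- test_axon_30()
  tr <- three_pulse_train()
  expect_error(simulate_axon(m, rep(0, m$n_comp), tr, dt = 0.05), "0.025")
  expect_error(simulate_axon(m, rep(0, m$n_comp), tr, dt = -1), "0.025")
  expect_error(simulate_axon(m, rep(0, 5), tr), "per compartment")
})

test_that("the unstimulated fibre rests stably near -80 mV", {
  m <- test_axon_30()
  rest_vm <- m$rest$vi - m$rest$vp
  expect_true(all(rest_vm > -85 & rest_vm < -75))
  tr <- stim_config("monopolar", 0, duration_ms = 50)
  sp <- simulate_axon(m, rep(0, m$n_comp), tr, amplitude_scale = 0,
                      onsets_ms = numeric(0), fast_forward = FALSE,
                      return_vm = TRUE)
  expect_length(sp, 0)
  vm <- attr(sp, "vm")[, 1]
  expect_lt(max(abs(vm - vm[1])), 0.1)  # < 0.1 mV drift over 50 ms
})

test_that("at rest the net membrane current is a tiny fraction of spike currents", {
  m <- test_axon_30()
  tr <- three_pulse_train()
  # resting |C dVm/dt| from an unstimulated run
  sp0 <- simulate_axon(m, rep(0, m$n_comp), tr, amplitude_scale = 0,
                       onsets_ms = numeric(0), fast_forward = FALSE,
                       return_vm = TRUE, dt_quiet = 0.005)
  vm0 <- attr(sp0, "vm")[, 1]
  t0 <- attr(sp0, "vm_times")
  rest_didt <- max(abs(diff(vm0) / diff(t0)))
  # spike |C dVm/dt| at the same node during a suprathreshold response
  ve <- point_source_ve(m, 2)
  sp1 <- simulate_axon(m, ve, tr, amplitude_scale = 1, return_vm = TRUE,
                       record_nodes = m$n_nodes - 10L, dt_quiet = 0.005)
  vm1 <- attr(sp1, "vm")[, 1]
  t1 <- attr(sp1, "vm_times")
  spike_didt <- max(abs(diff(vm1) / diff(t1)))
  expect_gt(length(sp1), 0)
  expect_lt(rest_didt / spike_didt, 1e-3)
})

test_that("a drive at twice threshold fires 1:1 with short latency", {
  m <- test_axon_30()
  tr <- three_pulse_train()
  ve <- point_source_ve(m, 2.5)
  th <- find_threshold(m, ve, tr, tol = 0.01)
  expect_false(isTRUE(attr(th, "no_activation")))
  # threshold bracket: th activates, th - tol does not
  sp_hi <- simulate_axon(m, ve, tr, amplitude_scale = th)
  sp_lo <- simulate_axon(m, ve, tr, amplitude_scale = th - 0.011)
  expect_true(fires_one_to_one(sp_hi, tr))
  expect_false(fires_one_to_one(sp_lo, tr))

  sp <- simulate_axon(m, ve, tr, amplitude_scale = 2 * th,
                      return_vm = TRUE)
  expect_length(sp, 3)
  onsets <- pulse_onsets(tr)
  expect_true(all(sp - onsets > 0 & sp - onsets < 2))
  expect_true(fires_one_to_one(sp, tr))
  # action-potential peak at the recording node in the physiological band
  expect_gt(max(attr(sp, "vm")), 10)
  expect_lt(max(attr(sp, "vm")), 50)
})

test_that("threshold rises with distance from the source", {
  m <- test_axon_30()
  tr <- three_pulse_train()
  th <- vapply(c(1.5, 2.5, 3.5), function(d) {
    as.numeric(find_threshold(m, point_source_ve(m, d), tr, tol = 0.01))
  }, 0)
  expect_true(all(diff(th) > 0))
})

test_that("threshold falls as the pulse widens (strength-duration)", {
  m <- test_axon_30()
  th <- vapply(c(0.1, 0.25, 0.5), function(pw) {
    tr <- stim_config("monopolar", 0, pulse_width_ms = pw,
                      duration_ms = 3 * 1000 / 14)
    as.numeric(find_threshold(m, point_source_ve(m, 2.5), tr, tol = 0.01))
  }, 0)
  expect_true(all(diff(th) < 0))
})

test_that("all-zero potentials give the distinct no-activation signal", {
  m <- test_axon_30()
  tr <- three_pulse_train()
  th <- find_threshold(m, rep(0, m$n_comp), tr)
  expect_true(is.na(th))
  expect_true(attr(th, "no_activation"))
})

test_that("paired pulses 1 ms apart at 1.1x threshold show refractoriness", {
  m <- test_axon_30()
  tr <- stim_config("monopolar", 0, duration_ms = 30)
  ve <- point_source_ve(m, 2.5)
  th <- find_threshold(m, ve, three_pulse_train(), tol = 0.01)
  sp <- simulate_axon(m, ve, tr, amplitude_scale = 1.1 * th,
                      onsets_ms = c(0, 1))
  expect_lt(length(sp), 2)
})

test_that("spikes propagate at a constant, finite conduction velocity", {
  m <- build_axon(5.7, 40)
  tr <- stim_config("monopolar", 0, duration_ms = 30)
  ve <- point_source_ve(m, 2, x0 = 5)  # source near the proximal end
  rec <- c(30L, 50L, 70L)               # nodes 10 internodes apart
  sp <- simulate_axon(m, ve, tr, amplitude_scale = 2,
                      record_nodes = rec)
  all_sp <- attr(sp, "all_spikes")
  t1 <- all_sp[[1]][1]; t2 <- all_sp[[2]][1]; t3 <- all_sp[[3]][1]
  dt1 <- t2 - t1; dt2 <- t3 - t2
  expect_gt(dt1, 0)
  expect_gt(dt2, 0)
  expect_lt(abs(dt2 - dt1) / dt1, 0.1)  # constant along the fibre
  cv <- 10 * 0.5 / dt1  # mm per ms = m/s over 10 internodes
  expect_gt(cv, 10)     # finite, physiological for a 5.7 um fibre
  expect_lt(cv, 80)
})

test_that("quiet-span acceleration does not change the simulated response", {
  m <- test_axon_30()
  tr <- three_pulse_train()
  ve <- point_source_ve(m, 2.5)
  for (scale in c(0.5, 1.5)) {
    fast <- simulate_axon(m, ve, tr, amplitude_scale = scale,
                          fast_forward = TRUE, dt_quiet = 0.025)
    slow <- simulate_axon(m, ve, tr, amplitude_scale = scale,
                          fast_forward = FALSE, dt_quiet = 0.005)
    expect_equal(length(fast), length(slow))
    if (length(fast) > 0) {
      expect_lt(max(abs(fast - slow)), 0.15)  # spike times agree
    }
  }
})

test_that("the 1:1 outcome is duration-invariant for a periodic drive", {
  m <- build_axon(5.7, 20)
  ve <- point_source_ve(m, 2.5)
  tr3 <- three_pulse_train()
  tr14 <- stim_config("monopolar", 0, duration_ms = 1000)
  th <- find_threshold(m, ve, tr3, tol = 0.01)
  for (scale in c(1.5 * th, 0.8 * th)) {
    sp3 <- simulate_axon(m, ve, tr3, amplitude_scale = scale)
    sp14 <- simulate_axon(m, ve, tr14, amplitude_scale = scale)
    expect_length(pulse_onsets(tr14), 14)
    expect_equal(fires_one_to_one(sp14, tr14), fires_one_to_one(sp3, tr3))
  }
})

test_that("the 1:1 criterion counts one spike per pulse window", {
  tr <- stim_config("monopolar", 0, duration_ms = 1000)
  onsets <- pulse_onsets(tr)
  expect_length(onsets, 14)
  expect_true(fires_one_to_one(onsets + 2, tr))          # one spike each
  expect_false(fires_one_to_one((onsets + 2)[1:7], tr))  # 7 spikes for 14
  doublet <- sort(c(onsets + 2, onsets[1] + 4))
  expect_false(fires_one_to_one(doublet, tr))            # doublet violates 1:1
  expect_false(fires_one_to_one(numeric(0), tr))
})
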