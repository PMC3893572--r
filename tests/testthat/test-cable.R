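test_that("axial conductances match the half-cylinder formula and are symmetric", {
  cell <- compartmentalize(make_stick(200, 2, 2),
                           nseg_override = list(dend = 2))
  g <- axial_conductances(cell)
  # d = 2 um, ds = 100 um, Ra = 150 Ohm-cm -> full-segment R ~ 47.7 MOhm
  R_full <- 4 * 150 * 100 / (pi * 2^2) * 1e4
  expect_equal(R_full, 47.75e6, tolerance = 1e-3)
  expect_equal(g$g_uS, 1e6 / R_full, tolerance = 1e-12)
  # halving ds doubles each half-resistance's conductance
  cell4 <- compartmentalize(make_stick(200, 2, 2),
                            nseg_override = list(dend = 4))
  expect_equal(axial_conductances(cell4)$g_uS, rep(2e6 / R_full, 3),
               tolerance = 1e-12)
})

test_that("a passive cell at rest stays at rest and relaxes monotonically", {
  cell <- ball_stick_cell(nseg_dend = 9)
  res <- simulate_cell(cell, sim_control(0, 20, 0.0625, v_init = -65))
  expect_equal(max(abs(res$v - -65)), 0, tolerance = 1e-12)
  expect_equal(max(abs(res$imem)), 0, tolerance = 1e-12)
  # perturbed start: deviation from rest is non-increasing
  res2 <- simulate_cell(cell, sim_control(0, 50, 0.0625, v_init = -55))
  dev <- apply(abs(res2$v - -65), 2, max)
  expect_true(all(diff(dev) <= 1e-12))
})

test_that("solver converges to the RC closed form at its order", {
  m <- morphology3d(0, 0, 0, 20, 1, -1)
  err_at <- function(method, dt) {
    cell <- compartmentalize(m)
    cell <- attach_current_clamp(cell, 1, 0.05, delay = 0, duration = Inf)
    res <- simulate_cell(cell, sim_control(0, 20, dt), method = method)
    gL <- cell$g_leak
    vex <- cell$e_pas + (0.05 / gL) * (1 - exp(-res$t * gL / cell$cap))
    max(abs(res$v[1, ] - vex))
  }
  for (spec in list(list(m = "backward_euler", ord = 2),
                    list(m = "crank_nicolson", ord = 4))) {
    errs <- vapply(c(0.2, 0.1, 0.05), err_at, numeric(1), method = spec$m)
    expect_true(all(diff(errs) < 0))
    ratios <- errs[-3] / errs[-1]
    expect_equal(ratios, rep(spec$ord, 2), tolerance = 0.15)
  }
})

test_that("synapse currents vanish without spikes and at the reversal", {
  cell <- ball_stick_cell(nseg_dend = 9)
  tgt <- comp_index_at(cell, "dend", 0.5)
  c0 <- attach_exp_synapse(cell, tgt, weight = 0.01, spike_times = numeric(0))
  r0 <- simulate_cell(c0, sim_control(0, 20, 0.0625), rec_isyn = TRUE)
  expect_equal(max(abs(r0$isyn)), 0)
  expect_equal(max(abs(r0$v - -65)), 0, tolerance = 1e-12)

  # with V pinned at the reversal (e_pas = e_rev = v_init), conductance is
  # nonzero but the driving force -- and hence the current -- is zero
  p <- comp_params(e_pas = 0)
  cr <- compartmentalize(make_ball_and_stick(), p,
                         nseg_override = list(dend = 9))
  cr <- attach_exp_synapse(cr, 5, weight = 0.01, e_rev = 0,
                           spike_times = c(5, 10))
  rr <- simulate_cell(cr, sim_control(0, 20, 0.0625, v_init = 0),
                      rec_isyn = TRUE)
  expect_equal(max(abs(rr$isyn)), 0, tolerance = 1e-12)
})

test_that("a synaptic input makes a sink near the synapse and a source near the soma", {
  cell <- ball_stick_cell(nseg_dend = 31)
  tgt <- comp_index_at(cell, "dend", 0.9)      # distal input
  cell <- attach_exp_synapse(cell, tgt, weight = 0.005, e_rev = 0,
                             spike_times = 20)
  res <- simulate_cell(cell, sim_control(0, 40, 0.0625),
                       method = "crank_nicolson")
  z_syn <- cell$mid[tgt, 3]
  phi_syn <- lfp_line_source(cell, res$imem, c(30, 0, z_syn), 0.3)
  phi_soma <- lfp_line_source(cell, res$imem, c(30, 0, 0), 0.3)
  expect_lt(min(phi_syn), 0)                    # negative transient at the sink
  expect_gt(max(phi_soma), 0)                   # positive return current
  expect_lt(abs(phi_syn[1]), 1e-12)             # silent before the spike
})

test_that("electrode currents are monopoles: injected charge exits the membrane", {
  cell <- ball_stick_cell(nseg_dend = 15)
  amp <- 0.2
  cc <- attach_current_clamp(cell, 1, amp, delay = 5, duration = 30)
  res <- simulate_cell(cc, sim_control(0, 60, 0.0625))
  on_pulse <- res$t >= 5 + 0.0625 & res$t < 35
  expect_equal(colSums(res$imem)[on_pulse],
               rep(amp, sum(on_pulse)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # far field during the steady pulse decays as amp/(4 pi sigma r)
  k <- which(res$t == 30)
  for (r in c(5e4, 2e5)) {
    phi <- lfp_line_source(cell, res$imem[, k], c(r, 0, 0), 0.3)
    expect_equal(phi, amp / (4 * pi * 0.3 * r), tolerance = 2e-3)
  }
  # zero-amplitude clamp is a no-op
  c0 <- attach_current_clamp(cell, 1, 0, delay = 5, duration = 30)
  r0 <- simulate_cell(c0, sim_control(0, 60, 0.0625))
  rnone <- simulate_cell(cell, sim_control(0, 60, 0.0625))
  expect_identical(r0$v, rnone$v)
})

test_that("Kirchhoff conservation holds at every step with mixed stimuli", {
  cell <- ball_stick_cell(nseg_dend = 15)
  cell <- attach_exp_synapse(cell, comp_index_at(cell, "dend", 0.8),
                             weight = 0.002, spike_times = c(3, 7, 11))
  cell <- attach_current_clamp(cell, 1, 0.1, delay = 10, duration = 15)
  cell <- attach_sine_clamp(cell, 5, amplitude = 0.05, freq = 50)
  for (meth in c("backward_euler", "crank_nicolson")) {
    res <- simulate_cell(cell, sim_control(-10, 40, 0.0625), method = meth)
    imbalance <- max(abs(colSums(res$imem) - colSums(res$iinj)))
    expect_lt(imbalance, 1e-9 * cell$n)
  }
})

test_that("a single-compartment cell generates no extracellular potential", {
  cell <- soma_only_cell()
  cell <- attach_exp_synapse(cell, 1, weight = 0.01, spike_times = c(2, 4))
  res <- simulate_cell(cell, sim_control(0, 20, 0.0625))
  expect_equal(res$imem, res$iinj, tolerance = 1e-14)
  expect_equal(max(abs(res$imem)), 0, tolerance = 1e-12)
  pts <- rbind(c(50, 0, 0), c(0, 120, 30), c(-40, -40, -40))
  for (i in 1:3) {
    expect_equal(max(abs(lfp_point_source(cell, res$imem, pts[i, ]))), 0,
                 tolerance = 1e-15)
  }
})

test_that("warm-up runs are simulated but recorded only from t = 0", {
  cell <- ball_stick_cell(nseg_dend = 9)
  cell <- attach_sine_clamp(cell, 1, amplitude = 0.1, freq = 100)
  res <- simulate_cell(cell, sim_control(-159, 20, 0.0625))
  expect_equal(res$t[1], 0)
  expect_equal(res$t[length(res$t)], 20)
  # commensurability of the recording grid is enforced
  expect_error(simulate_cell(cell, sim_control(-0.03, 0.97, 0.05)),
               "commensurate")
})

test_that("identical runs are bit-identical", {
  cell <- ball_stick_cell(nseg_dend = 9)
  cell <- attach_exp_synapse(cell, 5, weight = 0.003, spike_times = c(2, 9))
  r1 <- simulate_cell(cell, sim_control(0, 30, 0.0625))
  r2 <- simulate_cell(cell, sim_control(0, 30, 0.0625))
  expect_identical(r1, r2)
})

test_that("imposed extracellular fields act only through their gradients", {
  cell <- compartmentalize(make_stick(400, 2, 5),
                           nseg_override = list(dend = 8))
  ctl <- sim_control(0, 150, 0.0625)
  base <- simulate_cell(cell, ctl)
  tv <- c(0, 150)

  zero <- insert_v_ext(cell, matrix(0, cell$n, 2), tv)
  expect_equal(simulate_cell(zero, ctl)$v, base$v, tolerance = 1e-14)

  unif <- insert_v_ext(cell, matrix(3, cell$n, 2), tv)
  expect_equal(simulate_cell(unif, ctl)$v, base$v, tolerance = 1e-10)

  # linear gradient along the cable: polarization antisymmetric about the
  # midpoint (the discrete system is mirror-symmetric)
  grad <- insert_v_ext(cell, matrix(rep(0.01 * cell$mid[, 3], 2), ncol = 2),
                       tv)
  rg <- simulate_cell(grad, ctl)
  dv <- rg$v[, ncol(rg$v)] - -65
  expect_gt(max(abs(dv)), 1e-3)               # it does polarize
  expect_equal(dv + rev(dv), rep(0, cell$n), tolerance = 1e-10)
  # shape mismatch is rejected
  expect_error(insert_v_ext(cell, matrix(0, cell$n + 1, 2), tv), "rows")
})
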