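test_that("point-source potentials match the hand-evaluated kernel", {
  cell <- soma_only_cell(diam = 10)
  # 1 nA at 100 um in sigma = 0.3 S/m -> 1/(4 pi 0.3 100) mV
  expect_equal(lfp_point_source(cell, 1, c(100, 0, 0), 0.3),
               1 / (4 * pi * 0.3 * 100), tolerance = 1e-12)
  expect_equal(lfp_point_source(cell, 1, c(100, 0, 0), 0.3), 2.653e-3,
               tolerance = 1e-3)
  # antisymmetry: +/- currents seen from the bisector plane cancel
  cc <- two_comp_cell(sep = 20)
  zmid <- mean(cc$mid[, 3])
  expect_equal(lfp_point_source(cc, c(1, -1), c(60, 0, zmid)), 0,
               tolerance = 1e-15)
  # inside the compartment radius the distance is clamped to the radius
  r_soma <- sqrt(cell$area / (4 * pi))
  expect_equal(lfp_point_source(cell, 1, c(r_soma / 3, 0, 0)),
               lfp_point_source(cell, 1, c(r_soma, 0, 0)), tolerance = 1e-12)
})

test_that("the line-source closed form matches dense quadrature", {
  set.seed(101)
  sigma <- 0.3
  worst <- 0
  for (i in 1:300) {
    s <- runif(3, -100, 100)
    e <- s + runif(3, -100, 100)
    ds <- sqrt(sum((e - s)^2))
    if (ds < 1) next
    radius <- runif(1, 0.1, 1)
    # off-axis point at perpendicular distance >= max(2, ds/100), so the
    # clamp is inactive and the Simpson oracle resolves the integrand
    ax <- (e - s) / ds
    perp <- c(ax[2] - ax[3], ax[3] - ax[1], ax[1] - ax[2])
    if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
    perp <- perp / sqrt(sum(perp^2))
    rho <- max(2, ds / 100) * runif(1, 1, 20)
    pt <- s + runif(1, -0.5, 1.5) * ds * ax + rho * perp
    v_closed <- lfp_line_source(segment_cell(s, e, radius), 1, pt, sigma)
    v_quad <- line_quad_oracle(s, e, pt, sigma)
    worst <- max(worst, abs(v_closed - v_quad) / abs(v_quad))
  }
  expect_lt(worst, 1e-6)
})

test_that("on-axis evaluation is clamped to the compartment radius and finite", {
  s <- c(0, 0, 0); e <- c(0, 0, 40)
  cell <- segment_cell(s, e, radius = 1.5)
  on_axis <- lfp_line_source(cell, 1, c(0, 0, 100), 0.3)   # rho = 0, beyond end
  at_radius <- lfp_line_source(cell, 1, c(1.5, 0, 100), 0.3)
  expect_true(is.finite(on_axis))
  expect_equal(on_axis, at_radius, tolerance = 1e-12)
  # even through the segment itself
  inside <- lfp_line_source(cell, 1, c(0, 0, 20), 0.3)
  expect_true(is.finite(inside))
  expect_equal(inside, lfp_line_source(cell, 1, c(1.5, 0, 20), 0.3),
               tolerance = 1e-12)
})

test_that("all three methods agree far from the cell", {
  cell <- ball_stick_cell(nseg_dend = 15)
  set.seed(7)
  imem <- rnorm(cell$n)
  imem <- imem - mean(imem)              # current-conserving snapshot
  extent <- 1100                          # soma to stick tip
  dirs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  for (i in seq_len(nrow(dirs))) {
    pt <- cell$soma_center + 100 * extent * dirs[i, ]
    p1 <- lfp_point_source(cell, imem, pt)
    p2 <- lfp_line_source(cell, imem, pt)
    p3 <- lfp_soma_as_point(cell, imem, pt)
    expect_lt(abs(p2 - p1) / abs(p1), 1e-3)
    expect_lt(abs(p3 - p1) / abs(p1), 1e-3)
  }
})

test_that("soma-as-sphere requires a single-compartment root soma", {
  # degenerate: soma-only cell equals the point source
  cell <- soma_only_cell()
  expect_equal(lfp_soma_as_point(cell, 1, c(300, 10, -20)),
               lfp_point_source(cell, 1, c(300, 10, -20)), tolerance = 1e-12)
  # soma split into 3 compartments -> precondition error
  m3 <- morphology3d(x = rep(0, 5), y = rep(0, 5),
                     z = c(0, 10, 20, 40, 80), diam = c(10, 10, 10, 2, 2),
                     type = c(1L, 1L, 1L, 3L, 3L),
                     parent = c(-1L, 1L, 2L, 3L, 4L))
  c3 <- compartmentalize(m3, nseg_override = list(soma = 3))
  expect_error(lfp_soma_as_point(c3, rep(0, c3$n), c(100, 0, 0)),
               class = "lfpsim_precondition_error")
  # soma not at the root -> precondition error
  mnr <- morphology3d(x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 40, 60),
                      diam = c(2, 2, 10), type = c(3L, 3L, 1L),
                      parent = c(-1L, 1L, 2L))
  cnr <- compartmentalize(mnr)
  expect_error(lfp_soma_as_point(cnr, rep(0, cnr$n), c(100, 0, 0)),
               class = "lfpsim_precondition_error")
})

test_that("zero-net-current sources decay like a dipole and match its far field", {
  sep <- 10
  cc <- two_comp_cell(sep = sep)
  I <- 0.5
  imem <- c(I, -I)
  p_mom <- I * sep                       # nA um, axis along -z (sink distal)
  # 1/r^2 decay along an oblique ray
  dir <- c(1, 0, 1) / sqrt(2)
  center <- colMeans(cc$mid)
  r1 <- 100 * 2 * sep
  phi1 <- lfp_point_source(cc, imem, center + r1 * dir)
  phi2 <- lfp_point_source(cc, imem, center + 2 * r1 * dir)
  expect_equal(phi1 / phi2, 4, tolerance = 0.02)
  # dipole formula at r >= 100 d, within 1%
  axis <- c(0, 0, -1)                    # from sink (distal) to source
  for (theta in c(0.3, 1.0, 2.5)) {
    dir <- c(sin(theta), 0, -cos(theta))  # polar angle from the dipole axis
    pt <- center + 100 * sep * dir
    phi <- lfp_line_source(cc, imem, pt)
    ref <- dipole_far_field(p_mom, 100 * sep, theta)
    expect_equal(phi, ref, tolerance = 0.01)
  }
})

test_that("forward maps are superpositions", {
  cell <- ball_stick_cell(nseg_dend = 9)
  set.seed(3)
  I1 <- rnorm(cell$n); I2 <- rnorm(cell$n)
  pt <- c(-70, 40, 300)
  for (fn in list(lfp_point_source, lfp_line_source, lfp_soma_as_point)) {
    expect_equal(fn(cell, 2 * I1 - 3 * I2, pt),
                 2 * fn(cell, I1, pt) - 3 * fn(cell, I2, pt),
                 tolerance = 1e-12)
  }
})

test_that("surface averaging: degenerate cases and 1/sqrt(m) error scaling", {
  cell <- two_comp_cell(sep = 30)
  imem <- c(1, -1)
  pos <- c(40, 0, 30)
  nrm <- c(1, 0, 0)
  # radius 0 equals the single-point evaluation exactly
  expect_equal(contact_average(cell, imem, pos, radius = 0),
               lfp_line_source(cell, imem, pos), tolerance = 1e-15)
  # far field: potential nearly constant over the disc -> average ~ point value
  far <- c(5000, 0, 30)
  expect_equal(contact_average(cell, imem, far, radius = 5, normal = nrm,
                               m = 20, seed = 11),
               lfp_line_source(cell, imem, far), tolerance = 1e-3)
  # missing normal with finite radius is an error
  expect_error(contact_average(cell, imem, pos, radius = 5), "normal")
  # MC standard error over seeds scales as 1/sqrt(m)
  sd_at <- function(m) {
    vals <- vapply(1:100, function(s)
      contact_average(cell, imem, pos, radius = 15, normal = nrm,
                      m = m, seed = s), numeric(1))
    sd(vals)
  }
  ratio <- sd_at(8) / sd_at(128)
  expect_gt(ratio, 2.6)     # ideal sqrt(16) = 4
  expect_lt(ratio, 6)
})

test_that("the coefficient matrix is the identity-current forward map", {
  cell <- ball_stick_cell(nseg_dend = 9)
  el <- electrode_array(c(-130, -220, 50), c(0, 0, 20), c(0, 700, 300),
                        method = "line_source")
  C <- compute_coefficient_matrix(cell, el)
  expect_equal(dim(C$C), c(3, cell$n))
  # explicit identity-matrix construction, column by column
  C_id <- sapply(seq_len(cell$n), function(n) {
    I <- numeric(cell$n); I[n] <- 1
    sapply(seq_len(3), function(k)
      lfp_line_source(cell, I, el$pos[k, ], el$sigma))
  })
  expect_equal(C$C, C_id, tolerance = 1e-14)
  # applying C to currents equals the direct forward computation
  set.seed(5)
  I <- matrix(rnorm(cell$n * 4), cell$n)
  direct <- t(sapply(1:3, function(k)
    lfp_line_source(cell, I, el$pos[k, ], el$sigma)))
  expect_equal(apply_coefficients(C, I), direct, tolerance = 1e-12)
  expect_equal(apply_coefficients(C, diag(cell$n)), C$C)
  expect_equal(apply_coefficients(C, matrix(0, cell$n, 2)),
               matrix(0, 3, 2))
  # linearity
  I2 <- matrix(rnorm(cell$n * 4), cell$n)
  expect_equal(apply_coefficients(C, 2 * I - 3 * I2),
               2 * apply_coefficients(C, I) - 3 * apply_coefficients(C, I2),
               tolerance = 1e-12)
  expect_error(apply_coefficients(C, rnorm(cell$n + 1)), "columns")
})

test_that("surface-averaged coefficient rows use a fixed per-contact sample", {
  cell <- ball_stick_cell(nseg_dend = 9)
  el <- electrode_array(c(-30, -30), c(0, 0), c(100, 500), radius = 7.5,
                        normal = c(1, 0, 0), n_average = 25, seed = 42)
  C1 <- compute_coefficient_matrix(cell, el)
  C2 <- compute_coefficient_matrix(cell, el)
  expect_identical(C1$C, C2$C)
  # and the sampling does not disturb the global RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(compute_coefficient_matrix(cell, el))
  expect_identical(runif(1), before)
})

test_that("runtime-sink potentials equal post-hoc potentials", {
  cell <- ball_stick_cell(nseg_dend = 15)
  cell <- attach_exp_synapse(cell, comp_index_at(cell, "dend", 0.7),
                             weight = 0.002, spike_times = c(4, 9))
  el <- electrode_array(c(-130, -220), c(0, 0), c(0, 700))
  C <- compute_coefficient_matrix(cell, el)
  res <- simulate_cell(cell, sim_control(0, 30, 0.0625),
                       method = "crank_nicolson", runtime_sinks = list(C))
  posthoc <- apply_coefficients(C, res$imem)
  expect_equal(res$sinks[[1]], posthoc, tolerance = 1e-13)
})
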