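# Shared fixtures and independent oracles, built in code at test time.

soma_only_cell <- function(diam = 20) {
  compartmentalize(morphology3d(0, 0, 0, diam, 1, -1))
}

ball_stick_cell <- function(nseg_dend = NULL, ...) {
  m <- make_ball_and_stick(...)
  ov <- if (!is.null(nseg_dend)) list(dend = nseg_dend)
  compartmentalize(m, nseg_override = ov)
}

# two equal compartments along +z; midpoints separated by sep um
two_comp_cell <- function(sep = 10, diameter = 2) {
  m <- make_stick(length = 2 * sep, diameter = diameter, n_points = 2)
  compartmentalize(m, nseg_override = list(dend = 2))
}

# planar zig-zag dendrite, unit root at origin
zigzag_morph <- function(n = 7, step = 20) {
  x <- ifelse(seq_len(n) %% 2 == 0, step, 0)
  z <- (seq_len(n) - 1) * step
  morphology3d(x, rep(0, n), z, rep(2, n), rep(3L, n),
               c(-1L, seq_len(n - 1)))
}

total_chord_length <- function(cell) sum(sqrt(rowSums((cell$end - cell$start)^2)))

# independent dense-quadrature oracle for the single-segment line source:
# composite Simpson of the point kernel along the segment axis (no clamping;
# callers must keep the evaluation point off the axis).
line_quad_oracle <- function(s, e, pt, sigma, n = 10000) {
  u <- seq(0, 1, length.out = n + 1)
  px <- s[1] + u * (e[1] - s[1])
  py <- s[2] + u * (e[2] - s[2])
  pz <- s[3] + u * (e[3] - s[3])
  f <- 1 / sqrt((pt[1] - px)^2 + (pt[2] - py)^2 + (pt[3] - pz)^2)
  ds <- sqrt(sum((e - s)^2))
  h <- 1 / n
  w <- rep(c(4, 2), length.out = n - 1)
  integral <- h / 3 * (f[1] + f[n + 1] + sum(w * f[2:n]))  # of 1/d over u
  integral / (4 * pi * sigma)   # ds cancels: (1/ds) * integral over arc
}

# single-segment "cell" for kernel tests: one cylindrical compartment
segment_cell <- function(s, e, radius = 1) {
  ds <- sqrt(sum((e - s)^2))
  structure(list(
    n = 1L,
    start = matrix(s, 1), mid = matrix((s + e) / 2, 1), end = matrix(e, 1),
    radius = radius, length = ds, area = pi * 2 * radius * ds,
    cap = 1, g_leak = 1, e_pas = -65,
    parent = NA_integer_, g_axial = NA_real_,
    sec_name = "dend[0]", sec_pos = 0.5, is_sphere = FALSE,
    sections = data.frame(name = "dend[0]", type = 3L, first = 1L, nseg = 1L,
                          stringsAsFactors = FALSE),
    soma_center = (s + e) / 2, params = comp_params(),
    stimuli = list(), v_ext = NULL), class = "comp_cell")
}

write_swc_lines <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}
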