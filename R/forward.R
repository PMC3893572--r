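## Volume-conductor forward model: maps per-compartment transmembrane
## currents to extracellular potentials in an infinite, homogeneous,
## isotropic, ohmic medium of conductivity sigma (S/m). With currents in nA
## and distances in um, potentials come out in mV with no conversion factor:
## phi = I / (4 pi sigma r). Potentials reference zero at infinity.
##
## Three source models: point source (compartment current at its midpoint),
## line source (current spread uniformly along the segment axis, integrated
## in closed form) and the mixed soma-as-sphere method. Singularities are
## avoided by clamping the relevant distance (radial for point/sphere,
## perpendicular for line) to the compartment radius.

## effective clamp radius: cylinder radius, or equivalent-sphere radius for
## spherical compartments
.clamp_radius <- function(cell) {
  ifelse(cell$is_sphere, sqrt(cell$area / (4 * pi)), cell$radius)
}

.coerce_imem <- function(cell, imem) {
  if (is.null(dim(imem))) imem <- matrix(imem, ncol = 1)
  .assert(nrow(imem) == cell$n,
          sprintf("imem has %d rows but the cell has %d compartments",
                  nrow(imem), cell$n))
  imem
}

## per-compartment kernel weights (mV/nA) for one evaluation point
.weights_point <- function(cell, pt, sigma) {
  d <- .rownorm(sweep(cell$mid, 2, pt))
  d <- pmax(d, .clamp_radius(cell))
  1 / (4 * pi * sigma * d)
}

## closed-form line integral of 1/r along each segment, in the three-case
## form (projection beyond the far end / before the near end / alongside),
## algebraically equal to log|(sqrt(h^2+rho^2)-h)/(sqrt(l^2+rho^2)-l)| with
## h the longitudinal distance from the segment end and l = ds + h.
.weights_line <- function(cell, pt, sigma) {
  n <- cell$n
  w <- numeric(n)
  dvec <- cell$end - cell$start
  ds <- .rownorm(dvec)
  lin <- ds > 1e-9 & !cell$is_sphere
  if (any(!lin)) {
    d <- .rownorm(sweep(cell$mid[!lin, , drop = FALSE], 2, pt))
    d <- pmax(d, .clamp_radius(cell)[!lin])
    w[!lin] <- 1 / (4 * pi * sigma * d)
  }
  if (any(lin)) {
    dsl <- ds[lin]
    ax <- dvec[lin, , drop = FALSE] / dsl
    rel <- sweep(-cell$start[lin, , drop = FALSE], 2, pt, "+")  # pt - start
    x <- rowSums(rel * ax)
    rho2 <- pmax(rowSums(rel * rel) - x^2, 0)
    rmin <- cell$radius[lin]
    rho2 <- pmax(rho2, rmin^2)
    h <- x - dsl
    l <- x
    sh <- sqrt(h^2 + rho2)
    sl <- sqrt(l^2 + rho2)
    logterm <- ifelse(h >= 0, log((l + sl) / (h + sh)),
                      ifelse(l <= 0, log((sh - h) / (sl - l)),
                             log((l + sl) * (sh - h) / rho2)))
    w[lin] <- logterm / (4 * pi * sigma * dsl)
  }
  w
}

.weights_soma_as_point <- function(cell, pt, sigma) {
  .check_soma_root(cell)
  w <- .weights_line(cell, pt, sigma)
  d <- max(sqrt(sum((cell$mid[1, ] - pt)^2)), .clamp_radius(cell)[1])
  w[1] <- 1 / (4 * pi * sigma * d)
  w
}

.check_soma_root <- function(cell) {
  stype <- sub("\\[.*$", "", cell$sections$name)
  .assert(any(stype == "soma"),
          "soma_as_point requires a soma section",
          class = "lfpsim_precondition_error")
  s <- which(stype == "soma")
  .assert(length(s) == 1 && cell$sections$first[s] == 1L &&
            cell$sections$nseg[s] == 1L,
          paste("soma_as_point requires the soma to be the root of the",
                "morphology and represented by a single compartment"),
          class = "lfpsim_precondition_error")
  invisible(TRUE)
}

.method_weights <- function(cell, pt, sigma, method) {
  switch(method,
         point_source = .weights_point(cell, pt, sigma),
         line_source = .weights_line(cell, pt, sigma),
         soma_as_point = .weights_soma_as_point(cell, pt, sigma),
         stop(sprintf("unknown method: %s", method)))
}

#' Extracellular potential by the point-source approximation
#'
#' Each compartment's transmembrane current is treated as emanating from the
#' compartment midpoint; distances are clamped from below at the compartment
#' radius.
#'
#' @param cell a `comp_cell`.
#' @param imem transmembrane currents: length-N vector or N x T matrix (nA).
#' @param point evaluation point, length-3 (um).
#' @param sigma extracellular conductivity (S/m).
#' @return potential (mV): scalar/vector of length T.
#' @export
lfp_point_source <- function(cell, imem, point, sigma = 0.3) {
  imem <- .coerce_imem(cell, imem)
  drop(crossprod(.weights_point(cell, point, sigma), imem))
}

#' Extracellular potential by the line-source approximation
#'
#' Each compartment's current is spread uniformly along its straight axis and
#' the 1/r kernel is integrated in closed form. The perpendicular distance is
#' clamped from below at the compartment radius before evaluation, so the
#' result is finite even on the segment axis. Zero-length (or spherical)
#' compartments fall back to the point-source kernel.
#'
#' @inheritParams lfp_point_source
#' @return potential (mV): scalar/vector of length T.
#' @export
lfp_line_source <- function(cell, imem, point, sigma = 0.3) {
  imem <- .coerce_imem(cell, imem)
  drop(crossprod(.weights_line(cell, point, sigma), imem))
}

#' Extracellular potential by the mixed soma-as-sphere method
#'
#' The root soma compartment is treated as a spherical point source (distance
#' clamped at its equivalent-sphere radius); all other compartments use the
#' line-source formula. Errors unless the soma is the root of the morphology
#' and represented by a single compartment.
#'
#' @inheritParams lfp_point_source
#' @return potential (mV): scalar/vector of length T.
#' @export
lfp_soma_as_point <- function(cell, imem, point, sigma = 0.3) {
  imem <- .coerce_imem(cell, imem)
  drop(crossprod(.weights_soma_as_point(cell, point, sigma), imem))
}

## m sample points uniform on a flat disc (radial coordinate radius*sqrt(u))
.disc_points <- function(center, radius, normal, m, seed) {
  normal <- normal / sqrt(sum(normal^2))
  e <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- c(normal[2] * e[3] - normal[3] * e[2],
          normal[3] * e[1] - normal[1] * e[3],
          normal[1] * e[2] - normal[2] * e[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(normal[2] * t1[3] - normal[3] * t1[2],
          normal[3] * t1[1] - normal[1] * t1[3],
          normal[1] * t1[2] - normal[2] * t1[1])
  with_seed(seed, {
    r <- radius * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    sweep(outer(r * cos(th), t1) + outer(r * sin(th), t2), 2, center, "+")
  })
}

#' Surface-averaged potential of a finite circular contact
#'
#' Approximates the potential recorded by a flat circular contact as the mean
#' of the chosen method's point potential over `m` locations drawn uniformly
#' on the disc (fixed per contact by `seed`, so the sampled geometry is
#' time-invariant and reproducible). With `radius = 0` this degenerates to
#' the single-point evaluation.
#'
#' @param cell a `comp_cell`.
#' @param imem transmembrane currents (length-N vector or N x T matrix, nA).
#' @param position contact center, length-3 (um).
#' @param radius contact radius (um), >= 0.
#' @param normal unit surface normal (required when `radius > 0`).
#' @param m number of surface sample points, >= 1.
#' @param sigma conductivity (S/m).
#' @param method `"point_source"`, `"line_source"` or `"soma_as_point"`.
#' @param seed RNG seed for the disc sampling, independent of all
#'   simulation RNG streams.
#' @return potential (mV): scalar/vector of length T.
#' @export
contact_average <- function(cell, imem, position, radius = 0, normal = NULL,
                            m = 10, sigma = 0.3, method = "line_source",
                            seed = 1) {
  imem <- .coerce_imem(cell, imem)
  .assert(radius >= 0, "radius must be >= 0")
  .assert(m >= 1, "m must be >= 1")
  if (radius == 0) {
    w <- .method_weights(cell, position, sigma, method)
  } else {
    .assert(!is.null(normal), "a contact with radius > 0 requires a normal")
    pts <- .disc_points(position, radius, normal, m, seed)
    w <- numeric(cell$n)
    for (i in seq_len(nrow(pts))) {
      w <- w + .method_weights(cell, pts[i, ], sigma, method)
    }
    w <- w / nrow(pts)
  }
  drop(crossprod(w, imem))
}

#' Define an extracellular electrode array
#'
#' @param x,y,z contact coordinates (um), equal lengths; alternatively pass a
#'   single n x 3 matrix as `x`.
#' @param sigma extracellular conductivity (S/m), > 0.
#' @param method forward method: `"line_source"` (default),
#'   `"point_source"` or `"soma_as_point"`.
#' @param radius common contact radius (um); 0 for ideal point contacts.
#' @param normal common unit surface normal (required if `radius > 0`).
#' @param n_average number of surface sample points per contact.
#' @param seed seed for the surface-sampling RNG stream (independent of any
#'   simulation seed; each contact derives its own sub-seed).
#' @return an object of class `electrode_array`.
#' @export
electrode_array <- function(x, y = NULL, z = NULL, sigma = 0.3,
                            method = c("line_source", "point_source",
                                       "soma_as_point"),
                            radius = 0, normal = NULL, n_average = 10,
                            seed = 1) {
  method <- match.arg(method)
  pos <- if (is.matrix(x)) x else cbind(x, y, z)
  .assert(ncol(pos) == 3, "contact positions must be n x 3")
  .assert(sigma > 0, "sigma must be > 0")
  .assert(radius >= 0, "contact radius must be >= 0")
  .assert(n_average >= 1, "n_average must be >= 1")
  if (!is.null(normal)) {
    .assert(abs(sqrt(sum(normal^2)) - 1) < 1e-6, "normal must be unit length")
  }
  if (radius > 0) .assert(!is.null(normal),
                          "contacts with radius > 0 require a normal")
  structure(list(pos = unname(pos), sigma = sigma, method = method,
                 radius = radius, normal = normal, n_average = n_average,
                 seed = as.integer(seed)),
            class = "electrode_array")
}

#' Regular grid of electrode contacts
#'
#' Convenience generator for laminar/planar probes, e.g. a 9 x 9 grid with
#' 20 um pitch in the xz-plane.
#'
#' @param origin corner contact position, length-3 (um).
#' @param shape integer vector of length 2: contacts per grid axis.
#' @param pitch contact spacing (um).
#' @param plane `"xz"`, `"xy"` or `"yz"`: the plane spanned by the grid.
#' @return n x 3 matrix of contact positions.
#' @export
electrode_grid <- function(origin = c(0, 0, 0), shape = c(9, 9), pitch = 20,
                           plane = c("xz", "xy", "yz")) {
  plane <- match.arg(plane)
  ax <- switch(plane, xz = c(1, 3), xy = c(1, 2), yz = c(2, 3))
  g <- expand.grid(a = seq_len(shape[1]) - 1, b = seq_len(shape[2]) - 1)
  pos <- matrix(rep(origin, each = nrow(g)), ncol = 3)
  pos[, ax[1]] <- pos[, ax[1]] + g$a * pitch
  pos[, ax[2]] <- pos[, ax[2]] + g$b * pitch
  pos
}

#' Precompute the current-to-potential coefficient matrix
#'
#' `C[k, n]` is the potential at contact `k` produced by a unit current
#' (1 nA) in compartment `n` alone, including surface averaging --
#' equivalently, the result of running the forward model on an N x N identity
#' current matrix. Because the forward map is linear, `Phi(t) = C %*% I(t)`
#' reproduces the direct computation exactly while requiring only the
#' currents of one time step at a time; `C` needs to be computed once per
#' cell/electrode geometry.
#'
#' @param cell a `comp_cell`.
#' @param electrode an [electrode_array()].
#' @return an object of class `coef_matrix` with element `C`
#'   (N_contacts x N, mV/nA) and provenance fields.
#' @export
compute_coefficient_matrix <- function(cell, electrode) {
  .assert(inherits(electrode, "electrode_array"),
          "electrode must be an electrode_array")
  nc <- nrow(electrode$pos)
  C <- matrix(0, nc, cell$n)
  for (k in seq_len(nc)) {
    pt <- electrode$pos[k, ]
    if (electrode$radius > 0) {
      pts <- .disc_points(pt, electrode$radius, electrode$normal,
                          electrode$n_average,
                          derive_seed(electrode$seed, k))
      w <- numeric(cell$n)
      for (i in seq_len(nrow(pts))) {
        w <- w + .method_weights(cell, pts[i, ], electrode$sigma,
                                 electrode$method)
      }
      C[k, ] <- w / nrow(pts)
    } else {
      C[k, ] <- .method_weights(cell, pt, electrode$sigma, electrode$method)
    }
  }
  structure(list(C = C, method = electrode$method, sigma = electrode$sigma,
                 n_comp = cell$n,
                 geometry_hash = sum(cell$mid) + sum(cell$start) +
                   sum(cell$end) + cell$n),
            class = "coef_matrix")
}

#' Apply a coefficient matrix to membrane currents
#'
#' Pure linear map: `Phi(t) = C %*% I(t)` for a single current vector or a
#' full N x T current matrix.
#'
#' @param C a `coef_matrix` (or plain N_contacts x N matrix).
#' @param imem length-N vector or N x T matrix of currents (nA).
#' @return N_contacts x T matrix (or length-N_contacts vector) of potentials
#'   (mV).
#' @export
apply_coefficients <- function(C, imem) {
  m <- if (inherits(C, "coef_matrix")) C$C else as.matrix(C)
  vec <- is.null(dim(imem))
  if (vec) imem <- matrix(imem, ncol = 1)
  .assert(nrow(imem) == ncol(m),
          sprintf("current matrix has %d rows but C has %d columns",
                  nrow(imem), ncol(m)))
  out <- m %*% imem
  if (vec) drop(out) else out
}

#' Extracellular potentials of a simulation at an electrode array
#'
#' Convenience wrapper: computes the coefficient matrix for the electrode and
#' applies it to the recorded membrane currents of a [simulate_cell()] result
#' (or to a raw current matrix).
#'
#' @param cell a `comp_cell`.
#' @param imem a `sim_result` or an N x T current matrix (nA).
#' @param electrode an [electrode_array()].
#' @return N_contacts x T matrix of potentials (mV).
#' @export
lfp_electrode <- function(cell, imem, electrode) {
  if (inherits(imem, "sim_result")) {
    .assert(!is.null(imem$imem),
            "sim_result has no stored membrane currents (store_imem = FALSE)")
    imem <- imem$imem
  }
  apply_coefficients(compute_coefficient_matrix(cell, electrode), imem)
}
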