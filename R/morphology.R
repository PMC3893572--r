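## Morphologies: SWC reading/writing, synthetic generators, d_lambda
## compartmentalization into indexed line-source compartments, and rigid
## transforms. Units: um throughout; Ra in Ohm-cm, cm in uF/cm^2, g_pas in
## S/cm^2, so that capacitances come out in nF and conductances in uS.

.swc_type_names <- c("1" = "soma", "2" = "axon", "3" = "dend", "4" = "apic")

.type_name <- function(code) {
  nm <- .swc_type_names[as.character(code)]
  ifelse(is.na(nm), paste0("sec", code), nm)
}

#' Construct a raw 3D morphology
#'
#' Low-level constructor for a tree of 3D sample points with diameters. Most
#' users will call [read_swc()], [make_ball_and_stick()] or [make_stick()]
#' instead. Points are partitioned into unbranched sections: a new section
#' starts at the root, wherever the parent is not the preceding point, at
#' branch points, and on type changes.
#'
#' @param x,y,z coordinates (um).
#' @param diam diameters (um), all > 0.
#' @param type integer SWC type codes (1 soma, 2 axon, 3 dend, 4 apic).
#' @param parent 1-based parent point indices, -1 for the single root. Every
#'   parent must precede its child (no cycles, no forward references).
#' @param default_rotation optional named numeric (x, y, z) radians applied
#'   automatically by [compartmentalize()], e.g. from a `.rot` sidecar file.
#' @return an object of class `morphology3d` with elements `points`
#'   (data.frame x, y, z, diam, type, parent) and `sections` (data.frame
#'   name, type, first, last).
#' @export
morphology3d <- function(x, y, z, diam, type, parent, default_rotation = NULL) {
  n <- length(x)
  .assert(n >= 1, "morphology must contain at least one point")
  .assert(all(lengths(list(y, z, diam, type, parent)) == n),
          "coordinate, diameter, type and parent vectors must have equal length")
  .assert(all(is.finite(x)) && all(is.finite(y)) && all(is.finite(z)),
          "coordinates must be finite")
  .assert(all(diam > 0), "all diameters must be > 0")
  roots <- which(parent == -1)
  .assert(length(roots) == 1,
          sprintf("morphology must have exactly one root, found %d", length(roots)),
          class = "lfpsim_structural_error")
  bad <- which(parent != -1 & (parent >= seq_len(n) | parent < 1))
  .assert(length(bad) == 0,
          sprintf("point %d refers to parent %d which is not an earlier point",
                  bad[1], parent[bad[1]]),
          class = "lfpsim_structural_error")
  pts <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                    diam = as.numeric(diam), type = as.integer(type),
                    parent = as.integer(parent))
  m <- structure(list(points = pts,
                      sections = .build_sections(pts),
                      default_rotation = default_rotation),
                 class = "morphology3d")
  m
}

## Partition points into contiguous unbranched sections and name them
## NEURON-style per type: soma[0], dend[0], dend[1], ...
.build_sections <- function(pts) {
  n <- nrow(pts)
  nchild <- tabulate(pts$parent[pts$parent > 0], nbins = n)
  new_sec <- logical(n)
  for (i in seq_len(n)) {
    p <- pts$parent[i]
    new_sec[i] <- (p == -1) ||
      (p != i - 1L) ||
      (nchild[p] > 1L) ||
      (pts$type[p] != pts$type[i])
  }
  first <- which(new_sec)
  last <- c(first[-1] - 1L, n)
  type <- pts$type[first]
  cnt <- integer(0)
  name <- character(length(first))
  for (k in seq_along(first)) {
    tn <- .type_name(type[k])
    idx <- sum(.type_name(type[seq_len(k)]) == tn) - 1L
    name[k] <- sprintf("%s[%d]", tn, idx)
  }
  data.frame(name = name, type = type, first = first, last = last,
             stringsAsFactors = FALSE)
}

#' @export
print.morphology3d <- function(x, ...) {
  cat(sprintf("morphology3d: %d points, %d sections (%s)\n",
              nrow(x$points), nrow(x$sections),
              paste(unique(.type_name(x$sections$type)), collapse = ", ")))
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments). The radius column is doubled into diameters. If a `.rot`
#' sidecar file with lines like `x = 4.729` exists alongside the morphology,
#' its angles (radians) are stored as the default rotation and applied about
#' the soma center by [compartmentalize()], before any user rotation.
#'
#' @param path path to an SWC file.
#' @return a [morphology3d()] object.
#' @export
read_swc <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  .assert(length(lines) > 0, sprintf("no data lines in %s", path))
  toks <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(toks)
  bad <- which(nfield != 7)
  if (length(bad)) {
    stop(structure(class = c("lfpsim_parse_error", "error", "condition"),
                   list(message = sprintf(
                     "%s line %d: expected 7 whitespace-separated fields, got %d",
                     path, lineno[bad[1]], nfield[bad[1]]), call = NULL)))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(toks)), ncol = 7, byrow = TRUE))
  bad <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    stop(structure(class = c("lfpsim_parse_error", "error", "condition"),
                   list(message = sprintf("%s line %d: non-numeric field",
                                          path, lineno[bad[1]]), call = NULL)))
  }
  ids <- m[, 1]
  .assert(!anyDuplicated(ids), "duplicate SWC sample ids",
          class = "lfpsim_structural_error")
  idx <- match(m[, 7], ids)                # parent id -> row, NA for -1
  parent <- ifelse(m[, 7] == -1, -1L, idx)
  .assert(!anyNA(parent), "SWC parent id not present in file",
          class = "lfpsim_structural_error")
  rot <- NULL
  rot_path <- sub("\\.[sS][wW][cC]$", ".rot", path)
  if (rot_path != path && file.exists(rot_path)) rot <- .read_rot(rot_path)
  morphology3d(x = m[, 3], y = m[, 4], z = m[, 5], diam = 2 * m[, 6],
               type = m[, 2], parent = parent, default_rotation = rot)
}

.read_rot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ang <- c(x = 0, y = 0, z = 0)
  for (ln in lines) {
    mm <- regmatches(ln, regexec("^\\s*([xyz])\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(mm) == 3) ang[mm[2]] <- as.numeric(mm[3])
  }
  ang
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: writes the standard 7 columns with sequential ids,
#' so a write/read cycle reproduces the point set and topology exactly.
#'
#' @param m a [morphology3d()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  p <- m$points
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   seq_len(nrow(p)), p$type, p$x, p$y, p$z, p$diam / 2, p$parent)
  writeLines(c("# SWC written by lfpsim", lines), path)
  invisible(path)
}

#' Synthetic ball-and-stick morphology
#'
#' A single spherical soma point at the origin with an unbranched dendritic
#' stick of evenly spaced points running along +z from the soma surface.
#' Deterministic; used as the standard small test cell.
#'
#' @param soma_diameter soma diameter (um).
#' @param stick_length total stick arc length (um).
#' @param stick_diameter stick diameter (um).
#' @param n_points number of stick points (>= 2).
#' @return a [morphology3d()] with `n_points + 1` points.
#' @export
make_ball_and_stick <- function(soma_diameter = 20, stick_length = 1000,
                                stick_diameter = 2, n_points = 11) {
  .assert(soma_diameter > 0 && stick_length > 0 && stick_diameter > 0,
          "all dimensions must be > 0", class = "lfpsim_argument_error")
  .assert(n_points >= 2, "n_points must be >= 2", class = "lfpsim_argument_error")
  z <- soma_diameter / 2 + seq(0, stick_length, length.out = n_points)
  morphology3d(x = c(0, rep(0, n_points)),
               y = c(0, rep(0, n_points)),
               z = c(0, z),
               diam = c(soma_diameter, rep(stick_diameter, n_points)),
               type = c(1L, rep(3L, n_points)),
               parent = c(-1L, 1L, seq_len(n_points - 1) + 1L))
}

#' Synthetic uniform stick morphology
#'
#' A pure unbranched dendritic cable along +z starting at the origin: the
#' degenerate ball-and-stick with no soma, matching the geometry of the
#' analytic cable oracle ([analytic_stick_lfp()]).
#'
#' @param length stick length (um).
#' @param diameter stick diameter (um).
#' @param n_points number of points (>= 2).
#' @return a [morphology3d()].
#' @export
make_stick <- function(length = 1000, diameter = 2, n_points = 11) {
  .assert(length > 0 && diameter > 0, "all dimensions must be > 0",
          class = "lfpsim_argument_error")
  .assert(n_points >= 2, "n_points must be >= 2", class = "lfpsim_argument_error")
  z <- seq(0, length, length.out = n_points)
  morphology3d(x = rep(0, n_points), y = rep(0, n_points), z = z,
               diam = rep(diameter, n_points), type = rep(3L, n_points),
               parent = c(-1L, seq_len(n_points - 1)))
}

#' Passive membrane and compartmentalization parameters
#'
#' Defaults are the field-standard passive set: Ra = 150 Ohm-cm,
#' cm = 1 uF/cm^2, g_pas = 1/30000 S/cm^2 (membrane time constant 30 ms),
#' e_pas = -65 mV, with the d_lambda rule evaluated at f = 100 Hz with
#' d_lambda = 0.1.
#'
#' @param d_lambda maximum inter-node spacing as a fraction of the AC length
#'   constant, in (0, 1].
#' @param f reference frequency for the length constant (Hz).
#' @param Ra specific axial resistivity (Ohm-cm).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param g_pas leak conductance density (S/cm^2).
#' @param e_pas leak reversal potential (mV).
#' @return a classed parameter list.
#' @export
comp_params <- function(d_lambda = 0.1, f = 100, Ra = 150, cm = 1,
                        g_pas = 1 / 30000, e_pas = -65) {
  .assert(d_lambda > 0 && d_lambda <= 1, "d_lambda must be in (0, 1]")
  .assert(f > 0 && Ra > 0 && cm > 0 && g_pas > 0,
          "f, Ra, cm and g_pas must be > 0")
  structure(list(d_lambda = d_lambda, f = f, Ra = Ra, cm = cm,
                 g_pas = g_pas, e_pas = e_pas),
            class = "comp_params")
}

#' Number of compartments by the d_lambda rule
#'
#' The AC length constant at frequency `f` is
#' `lambda_f = 1e5 * sqrt(diam / (4 * pi * f * Ra * cm))` um, and the section
#' is split into `int((L / (d_lambda * lambda_f) + 0.9) / 2) * 2 + 1`
#' compartments -- always an odd count, at least 1.
#'
#' @param L section arc length (um).
#' @param diam section diameter (um).
#' @param Ra axial resistivity (Ohm-cm).
#' @param cm specific capacitance (uF/cm^2).
#' @param f reference frequency (Hz).
#' @param d_lambda spacing fraction.
#' @return odd positive integer.
#' @export
nseg_d_lambda <- function(L, diam, Ra = 150, cm = 1, f = 100, d_lambda = 0.1) {
  .assert(all(c(diam, Ra, cm, f, d_lambda) > 0) && L >= 0,
          "all arguments must be > 0")
  lambda_f <- 1e5 * sqrt(diam / (4 * pi * f * Ra * cm))
  as.integer(trunc((L / (d_lambda * lambda_f) + 0.9) / 2) * 2 + 1)
}

## Exact integral of the piecewise-linear diameter profile over [a, b] of the
## arc, and the frustum lateral area over the same span.
.span_diam_area <- function(arc, diam, a, b) {
  knots <- sort(unique(c(a, b, arc[arc > a & arc < b])))
  d <- stats::approx(arc, diam, xout = knots, rule = 2)$y
  h <- diff(knots)
  r1 <- d[-length(d)] / 2
  r2 <- d[-1] / 2
  mean_diam <- sum((d[-length(d)] + d[-1]) / 2 * h) / (b - a)
  area <- sum(pi * (r1 + r2) * sqrt(h^2 + (r2 - r1)^2))
  list(diam = mean_diam, area = area)
}

#' Discretize a morphology into an indexed compartmental cell
#'
#' Splits each section into `nseg` compartments of equal arc length (the
#' d_lambda rule by default), with straight line-source start/end points
#' obtained by linear interpolation of the 3D path at the arc-length
#' breakpoints. On curved sections the summed line-segment length is therefore
#' at most the section arc length, converging to it as `nseg` grows. The
#' compartment diameter is the arc-length-weighted mean of the diameter
#' profile over its span; the membrane area is the frustum-formula area over
#' the same span. A single-point soma becomes one spherical compartment with
#' area `pi * d^2`. Electrical parameters are densities times areas; axial
#' conductances follow the half-cylinder resistance formula. Global
#' compartment indices are a counter in a nested loop over sections (in
#' declaration order) then within-section compartments, starting at 1.
#'
#' @param m a [morphology3d()].
#' @param params a [comp_params()] object.
#' @param nseg_override optional named list mapping section names (e.g.
#'   `"dend[0]"`) or type names (e.g. `"dend"`) to fixed compartment counts.
#' @return an object of class `comp_cell`.
#' @export
compartmentalize <- function(m, params = comp_params(), nseg_override = NULL) {
  .assert(inherits(m, "morphology3d"), "m must be a morphology3d")
  .assert(nrow(m$points) >= 1, "empty morphology")
  if (!is.null(nseg_override)) {
    .assert(all(unlist(nseg_override) >= 1), "override counts must be >= 1")
  }
  pts <- m$points
  secs <- m$sections
  ns <- nrow(secs)

  ## first pass: per-section geometry and nseg
  sec_geom <- vector("list", ns)
  nseg <- integer(ns)
  for (s in seq_len(ns)) {
    rng <- secs$first[s]:secs$last[s]
    sp <- pts[rng, ]
    tname <- .type_name(secs$type[s])
    sphere <- (nrow(sp) == 1)
    .assert(!sphere || tname == "soma",
            sprintf("section %s has a single point but is not a soma", secs$name[s]))
    if (sphere) {
      nseg[s] <- 1L
      sec_geom[[s]] <- list(sphere = TRUE, sp = sp)
      next
    }
    seg <- cbind(diff(sp$x), diff(sp$y), diff(sp$z))
    arc <- c(0, cumsum(.rownorm(seg)))
    L <- arc[length(arc)]
    .assert(L > 0, sprintf("section %s has zero arc length", secs$name[s]))
    ov <- nseg_override[[secs$name[s]]] %||% nseg_override[[tname]]
    if (is.null(ov)) {
      dbar <- .span_diam_area(arc, sp$diam, 0, L)$diam
      nseg[s] <- nseg_d_lambda(L, dbar, params$Ra, params$cm, params$f,
                               params$d_lambda)
    } else {
      nseg[s] <- as.integer(ov)
    }
    sec_geom[[s]] <- list(sphere = FALSE, sp = sp, arc = arc, L = L)
  }

  N <- sum(nseg)
  first_idx <- cumsum(c(1L, nseg[-ns]))
  start <- mid <- end <- matrix(0, N, 3)
  radius <- len <- area <- sec_pos <- numeric(N)
  is_sphere <- logical(N)
  sec_name <- character(N)
  parent <- rep(NA_integer_, N)

  ## find the global compartment index owning a given point index
  comp_of_point <- function(pidx) {
    s <- max(which(secs$first <= pidx))
    g <- sec_geom[[s]]
    if (g$sphere) return(first_idx[s])
    local <- pidx - secs$first[s] + 1L
    pos <- g$arc[local] / g$L
    j <- min(max(1L, ceiling(pos * nseg[s])), nseg[s])
    if (pos <= 0) j <- 1L
    first_idx[s] + j - 1L
  }

  for (s in seq_len(ns)) {
    g <- sec_geom[[s]]
    i0 <- first_idx[s]
    if (g$sphere) {
      p <- as.numeric(g$sp[1, c("x", "y", "z")])
      start[i0, ] <- mid[i0, ] <- end[i0, ] <- p
      d <- g$sp$diam[1]
      radius[i0] <- d / 2
      len[i0] <- d
      area[i0] <- pi * d^2
      sec_pos[i0] <- 0.5
      is_sphere[i0] <- TRUE
      sec_name[i0] <- secs$name[s]
    } else {
      sp <- g$sp; arc <- g$arc; L <- g$L
      breaks <- seq(0, L, length.out = nseg[s] + 1)
      bx <- stats::approx(arc, sp$x, xout = breaks)$y
      by <- stats::approx(arc, sp$y, xout = breaks)$y
      bz <- stats::approx(arc, sp$z, xout = breaks)$y
      for (j in seq_len(nseg[s])) {
        i <- i0 + j - 1L
        start[i, ] <- c(bx[j], by[j], bz[j])
        end[i, ] <- c(bx[j + 1], by[j + 1], bz[j + 1])
        mid[i, ] <- (start[i, ] + end[i, ]) / 2
        da <- .span_diam_area(arc, sp$diam, breaks[j], breaks[j + 1])
        radius[i] <- da$diam / 2
        area[i] <- da$area
        len[i] <- L / nseg[s]
        sec_pos[i] <- (j - 0.5) / nseg[s]
        sec_name[i] <- secs$name[s]
        if (j > 1) parent[i] <- i - 1L
      }
    }
    ## connect section root compartment to its parent compartment
    ppt <- pts$parent[secs$first[s]]
    if (ppt != -1) parent[i0] <- comp_of_point(ppt)
  }

  ## axial conductances: g = 1/(Rh(n) + Rh(parent)),
  ## Rh = Ra * (len/2) / (pi d^2 / 4) with the 1e4 um/cm unit factor
  half_res <- function(i) {
    d <- 2 * radius[i]
    (4 * params$Ra * (len[i] / 2) / (pi * d^2)) * 1e4   # Ohm
  }
  g_axial <- rep(NA_real_, N)
  for (i in seq_len(N)) {
    if (!is.na(parent[i])) {
      g_axial[i] <- 1e6 / (half_res(i) + half_res(parent[i]))  # uS
    }
  }

  soma_secs <- which(.type_name(secs$type) == "soma")
  soma_center <- if (length(soma_secs)) {
    s <- soma_secs[1]
    g <- sec_geom[[s]]
    if (g$sphere) as.numeric(g$sp[1, c("x", "y", "z")]) else {
      mpt <- c(stats::approx(g$arc, g$sp$x, xout = g$L / 2)$y,
               stats::approx(g$arc, g$sp$y, xout = g$L / 2)$y,
               stats::approx(g$arc, g$sp$z, xout = g$L / 2)$y)
      mpt
    }
  } else {
    as.numeric(pts[which(pts$parent == -1)[1], c("x", "y", "z")])
  }

  cell <- structure(list(
    n = N,
    start = start, mid = mid, end = end,
    radius = radius, length = len, area = area,
    cap = params$cm * area * 1e-5,          # nF
    g_leak = params$g_pas * area * 1e-2,    # uS
    e_pas = params$e_pas,
    parent = parent,
    g_axial = g_axial,
    sec_name = sec_name,
    sec_pos = sec_pos,
    is_sphere = is_sphere,
    sections = data.frame(name = secs$name, type = secs$type,
                          first = first_idx, nseg = nseg,
                          stringsAsFactors = FALSE),
    soma_center = soma_center,
    params = params,
    stimuli = list(),
    v_ext = NULL
  ), class = "comp_cell")
  if (!is.null(m$default_rotation)) {
    r <- m$default_rotation
    cell <- set_rotation(cell, r[["x"]] %||% 0, r[["y"]] %||% 0, r[["z"]] %||% 0)
  }
  cell
}

#' @export
print.comp_cell <- function(x, ...) {
  cat(sprintf("comp_cell: %d compartments in %d sections; soma center (%g, %g, %g) um\n",
              x$n, nrow(x$sections),
              x$soma_center[1], x$soma_center[2], x$soma_center[3]))
  invisible(x)
}

.rot_mat <- function(x, y, z) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(x), -sin(x)), c(0, sin(x), cos(x)))
  Ry <- rbind(c(cos(y), 0, sin(y)), c(0, 1, 0), c(-sin(y), 0, cos(y)))
  Rz <- rbind(c(cos(z), -sin(z), 0), c(sin(z), cos(z), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotate a cell about its soma center
#'
#' Right-handed rotations about the fixed x, then y, then z axes, applied
#' about the soma center. Geometry only: lengths, areas and all electrical
#' parameters are untouched.
#'
#' @param cell a `comp_cell`.
#' @param x,y,z rotation angles (radians).
#' @return the rotated cell.
#' @export
set_rotation <- function(cell, x = 0, y = 0, z = 0) {
  .assert(all(is.finite(c(x, y, z))), "angles must be finite")
  R <- .rot_mat(x, y, z)
  c0 <- cell$soma_center
  rot <- function(mat) t(R %*% (t(mat) - c0) + c0)
  cell$start <- rot(cell$start)
  cell$mid <- rot(cell$mid)
  cell$end <- rot(cell$end)
  cell
}

#' Translate a cell so its soma center sits at a target position
#'
#' @param cell a `comp_cell`.
#' @param x,y,z target soma-center coordinates (um).
#' @return the translated cell.
#' @export
set_position <- function(cell, x = 0, y = 0, z = 0) {
  .assert(all(is.finite(c(x, y, z))), "target position must be finite")
  d <- c(x, y, z) - cell$soma_center
  shift <- function(mat) sweep(mat, 2, d, "+")
  cell$start <- shift(cell$start)
  cell$mid <- shift(cell$mid)
  cell$end <- shift(cell$end)
  cell$soma_center <- c(x, y, z)
  cell
}

#' Look up compartments by section, or sections by compartment index
#'
#' With a character query, returns the sorted global indices of the
#' compartments in that section (an exact name like `"dend[0]"`) or in all
#' sections of that type (a bare name like `"dend"`). With a numeric query,
#' returns the section name and relative position (in (0,1)) of that
#' compartment.
#'
#' @param cell a `comp_cell`.
#' @param query section name, type name, or compartment index.
#' @return integer indices, or `list(section =, pos =)`.
#' @export
index_lookup <- function(cell, query) {
  if (is.character(query)) {
    if (grepl("\\[", query)) {
      idx <- which(cell$sec_name == query)
    } else {
      idx <- which(sub("\\[.*$", "", cell$sec_name) == query)
    }
    .assert(length(idx) > 0, sprintf("unknown section: %s", query),
            class = "lfpsim_lookup_error")
    return(sort(idx))
  }
  i <- as.integer(query)
  .assert(length(i) == 1 && !is.na(i) && i >= 1 && i <= cell$n,
          sprintf("compartment index out of range: %s", as.character(query)),
          class = "lfpsim_lookup_error")
  list(section = cell$sec_name[i], pos = cell$sec_pos[i])
}

#' Compartment index at a relative position within a section
#'
#' Convenience lookup mirroring the usual section/relative-position addressing
#' of compartmental simulators: returns the global index of the compartment of
#' `section` whose center is nearest to relative arc position `pos`.
#'
#' @param cell a `comp_cell`.
#' @param section section (or type) name.
#' @param pos relative position in \[0, 1\].
#' @return global compartment index.
#' @export
comp_index_at <- function(cell, section, pos = 0.5) {
  idx <- index_lookup(cell, section)
  idx[which.min(abs(cell$sec_pos[idx] - pos))]
}
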