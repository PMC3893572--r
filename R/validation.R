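## Independent analytic and semi-analytic oracles. These deliberately share
## no code with the cable solver or the forward kernels: the stick oracle is
## the closed-form frequency-domain solution of the continuous passive cable
## integrated against the 1/(4 pi sigma r) kernel by its own quadrature, so
## agreement with the simulation pipeline is evidence, not tautology.

#' Specification of the sinusoidally driven passive stick
#'
#' @param length stick length (um).
#' @param diameter stick diameter (um).
#' @param Ra axial resistivity (Ohm-cm).
#' @param cm specific capacitance (uF/cm^2).
#' @param g_pas leak conductance density (S/cm^2).
#' @param freq drive frequency (Hz); 0 gives the DC steady state.
#' @param amp drive current amplitude (nA).
#' @param end injection end: 0 (the x = 0 end) or `length`.
#' @return a classed list.
#' @export
stick_spec <- function(length = 1000, diameter = 2, Ra = 150, cm = 1,
                       g_pas = 1 / 30000, freq = 100, amp = 0.1, end = 0) {
  .assert(all(c(length, diameter, Ra, cm, g_pas) > 0),
          "all physical parameters must be > 0")
  .assert(freq >= 0, "freq must be >= 0")
  .assert(end %in% c(0, length), "injection end must be 0 or length")
  structure(list(length = length, diameter = diameter, Ra = Ra, cm = cm,
                 g_pas = g_pas, freq = freq, amp = amp, end = end),
            class = "stick_spec")
}

## Complex transmembrane current density (nA/um, phasor for drive
## amp * exp(i w t) at x = end) of the finite sealed-end cable:
##   i_m(x) = amp * cosh((L - x)/lambda_c) / (lambda_c sinh(L/lambda_c)),
## with complex length constant lambda_c = lambda / sqrt(1 + i w tau),
## lambda = 1e2 sqrt(diam / (4 Ra g_pas)) um, tau = cm/g_pas membrane time
## constant. Integrates to amp exactly (all injected current crosses the
## membrane).
.stick_im_density <- function(spec, x) {
  tau_s <- spec$cm * 1e-6 / spec$g_pas                    # s
  omega <- 2 * pi * spec$freq                             # rad/s
  lambda <- 1e2 * sqrt(spec$diameter / (4 * spec$Ra * spec$g_pas))  # um
  lam_c <- lambda / sqrt(1 + 1i * omega * tau_s)
  xi <- if (spec$end == 0) x else spec$length - x
  spec$amp * cosh((spec$length - xi) / lam_c) /
    (lam_c * sinh(spec$length / lam_c))
}

#' Analytic extracellular potential of the sinusoidally driven passive stick
#'
#' Solves the frequency-domain passive cable equation for a finite stick with
#' sealed ends under sinusoidal point-current injection at one end, derives
#' the transmembrane current density in closed form, and integrates the
#' point-source kernel along the stick by adaptive composite-Simpson
#' quadrature (panels doubled until successive estimates differ by less than
#' `tol` mV). The stick runs along +z from the origin; evaluation points are
#' arbitrary. Returns the complex phasor of the potential at the drive
#' frequency (for drive `amp * exp(i w t)`); its modulus is the amplitude of
#' the sinusoidal potential.
#'
#' @param spec a [stick_spec()].
#' @param eval_points n x 3 matrix of evaluation points (um).
#' @param sigma extracellular conductivity (S/m).
#' @param tol successive-refinement tolerance (mV).
#' @return complex vector of length n: potential phasors (mV).
#' @export
analytic_stick_lfp <- function(spec, eval_points, sigma = 0.3, tol = 1e-9) {
  .assert(inherits(spec, "stick_spec"), "spec must be a stick_spec")
  pts <- if (is.null(dim(eval_points))) matrix(eval_points, ncol = 3)
         else as.matrix(eval_points)
  L <- spec$length
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    f <- function(x) {
      .stick_im_density(spec, x) /
        sqrt(p[1]^2 + p[2]^2 + (p[3] - x)^2)
    }
    n <- 64L
    est <- .csimpson(f, 0, L, n)
    repeat {
      n <- n * 2L
      est2 <- .csimpson(f, 0, L, n)
      if (Mod(est2 - est) < tol * 4 * pi * sigma || n >= 2^20) break
      est <- est2
    }
    est2 / (4 * pi * sigma)
  }, complex(1))
}

## composite Simpson for complex-valued integrands, n panels (n even)
.csimpson <- function(f, a, b, n) {
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  h <- (b - a) / n
  w <- rep(c(4, 2), length.out = n - 1)
  h / 3 * (y[1] + y[n + 1] + sum(w * y[2:n]))
}

#' Total analytic transmembrane current of the driven stick
#'
#' Integral of the closed-form current-density phasor over the stick; equals
#' the injected current phasor exactly by charge conservation. Exposed for
#' consistency checks of the oracle itself.
#'
#' @param spec a [stick_spec()].
#' @param n quadrature panels.
#' @return complex total current (nA phasor).
#' @export
stick_total_current <- function(spec, n = 4096) {
  .csimpson(function(x) .stick_im_density(spec, x), 0, spec$length, n)
}

#' Far-field potential of a current dipole
#'
#' `phi = p cos(theta) / (4 pi sigma r^2)`: the leading multipole of any
#' current-conserving (zero net membrane current) source configuration. A
#' two-compartment cell with equal and opposite currents +/-I separated by
#' distance d has moment `p = I d`.
#'
#' @param p current dipole moment (nA um).
#' @param r distance from the dipole (um), > 0.
#' @param theta polar angle from the dipole axis (radians).
#' @param sigma conductivity (S/m).
#' @return potential (mV).
#' @export
dipole_far_field <- function(p, r, theta, sigma = 0.3) {
  .assert(all(r > 0), "r must be > 0")
  p * cos(theta) / (4 * pi * sigma * r^2)
}
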