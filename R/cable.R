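## Passive multicompartment cable dynamics. The membrane potential of every
## compartment follows the branched cable equation (Kirchhoff's current law
## per node): C_n dV_n/dt = -g_L,n (V_n - e_pas) - sum_s g_s(t) (V_n - e_s)
##            + I_inj,n(t) + sum_adj g_axial (V_adj - V_n),
## advanced with an unconditionally stable implicit scheme (backward Euler by
## default, Crank-Nicolson as an option). The recorded transmembrane current
## I_mem is computed from the discrete node identity
##   I_mem = (axial inflow) + I_inj,
## which makes the Kirchhoff sum rule sum(I_mem) == sum(I_inj) hold to solver
## precision at every step (exactly zero net membrane current without
## electrode injection).

#' Simulation control parameters
#'
#' Recording always starts at t = 0; a negative `tstart` runs a warm-up that
#' is simulated but not recorded, the standard way to discard start-up
#' transients.
#'
#' @param tstart simulation start (ms), must be <= 0.
#' @param tstop simulation end (ms), > 0.
#' @param dt time step (ms). The default 0.0625 is a power of two, exactly
#'   representable in binary.
#' @param v_init initial membrane potential (mV) in all compartments.
#' @return a classed list.
#' @export
sim_control <- function(tstart = 0, tstop = 100, dt = 0.0625, v_init = -65) {
  .assert(tstart < tstop, "tstart must be < tstop")
  .assert(dt > 0, "dt must be > 0")
  .assert(tstart <= 0, "recordings start at t = 0, so tstart must be <= 0")
  structure(list(tstart = tstart, tstop = tstop, dt = dt, v_init = v_init),
            class = "sim_control")
}

.check_idx <- function(cell, idx) {
  .assert(length(idx) == 1 && !is.na(idx) && idx >= 1 && idx <= cell$n,
          sprintf("invalid compartment index: %s", as.character(idx)))
  as.integer(idx)
}

#' Attach a single-exponential conductance synapse
#'
#' Registers a conductance-based exponential synapse on the target
#' compartment: `g(t) = weight * sum_spikes exp(-(t - t_s)/tau)` for
#' `t >= t_s`, with current `g(t) * (V - e_rev)` (outward positive). The
#' synaptic current is a true membrane current and is part of `I_mem`.
#'
#' @param cell a `comp_cell`.
#' @param idx target compartment index.
#' @param weight peak conductance increment per spike (uS), >= 0.
#' @param tau decay time constant (ms), > 0.
#' @param e_rev reversal potential (mV).
#' @param spike_times spike times (ms).
#' @return the cell with the synapse appended to its stimulus list.
#' @export
attach_exp_synapse <- function(cell, idx, weight = 0.001, tau = 2,
                               e_rev = 0, spike_times = numeric(0)) {
  idx <- .check_idx(cell, idx)
  .assert(tau > 0, "tau must be > 0")
  .assert(weight >= 0, "weight must be >= 0")
  cell$stimuli <- c(cell$stimuli, list(list(
    type = "exp_synapse", idx = idx, weight = weight, tau = tau,
    e_rev = e_rev, spike_times = as.numeric(spike_times))))
  cell
}

#' Attach a current-clamp step electrode
#'
#' Injects `amplitude` nA into the target compartment for
#' `t` in `[delay, delay + duration)`. An electrode current is not a
#' transmembrane current: it is recorded in `I_inj`, and because the injected
#' charge leaves the cell through the membrane, the summed membrane current
#' equals the injected current during the pulse -- a monopole contribution to
#' the extracellular potential.
#'
#' @param cell a `comp_cell`.
#' @param idx target compartment index.
#' @param amplitude injected current (nA).
#' @param delay pulse onset (ms).
#' @param duration pulse length (ms), >= 0.
#' @return the cell with the clamp appended.
#' @export
attach_current_clamp <- function(cell, idx, amplitude, delay = 0,
                                 duration = Inf) {
  idx <- .check_idx(cell, idx)
  .assert(duration >= 0, "duration must be >= 0")
  cell$stimuli <- c(cell$stimuli, list(list(
    type = "current_clamp", idx = idx, amplitude = amplitude,
    delay = delay, duration = duration)))
  cell
}

#' Attach a sinusoidal current-clamp electrode
#'
#' Injects `amplitude * sin(2*pi*freq*t/1000 + phase)` nA while active. Like
#' the step clamp, the current is an electrode current (recorded in `I_inj`,
#' monopole source). Used for the frequency-domain stick validation.
#'
#' @param cell a `comp_cell`.
#' @param idx target compartment index.
#' @param amplitude peak current (nA).
#' @param freq drive frequency (Hz); t is in ms.
#' @param phase phase offset (radians).
#' @param delay onset (ms); defaults to always-on.
#' @param duration window length (ms).
#' @return the cell with the clamp appended.
#' @export
attach_sine_clamp <- function(cell, idx, amplitude, freq, phase = 0,
                              delay = -Inf, duration = Inf) {
  idx <- .check_idx(cell, idx)
  .assert(freq >= 0, "freq must be >= 0")
  cell$stimuli <- c(cell$stimuli, list(list(
    type = "sine_clamp", idx = idx, amplitude = amplitude, freq = freq,
    phase = phase, delay = delay, duration = duration)))
  cell
}

#' Impose an external extracellular potential on the cell
#'
#' Axial currents are then computed from `V_n + v_ext_n` instead of `V_n`
#' alone, so only spatial gradients of the imposed field polarize the cell; a
#' spatially uniform `v_ext` leaves the membrane potentials unchanged. Used to
#' study externally applied fields (e.g. stimulation electrodes).
#'
#' @param cell a `comp_cell`.
#' @param v_ext N x T matrix of imposed extracellular potentials (mV).
#' @param t time axis of `v_ext` (ms), strictly increasing; linearly
#'   interpolated onto the simulation grid (constant beyond its ends).
#' @return the cell with the field attached.
#' @export
insert_v_ext <- function(cell, v_ext, t) {
  v_ext <- as.matrix(v_ext)
  .assert(nrow(v_ext) == cell$n,
          sprintf("v_ext has %d rows but the cell has %d compartments",
                  nrow(v_ext), cell$n))
  .assert(ncol(v_ext) == length(t), "ncol(v_ext) must equal length(t)")
  .assert(all(diff(t) > 0), "t must be strictly increasing")
  cell$v_ext <- list(v = v_ext, t = as.numeric(t))
  cell
}

#' Axial conductances of a cell
#'
#' The conductance between a compartment and its parent is
#' `1 / (Rh(n) + Rh(parent))` with half-cylinder resistance
#' `Rh = Ra * (L/2) / (pi d^2 / 4)`; it is single-valued per edge (symmetric
#' by construction).
#'
#' @param cell a `comp_cell`.
#' @return data.frame with columns `comp`, `parent`, `g_uS`.
#' @export
axial_conductances <- function(cell) {
  i <- which(!is.na(cell$parent))
  data.frame(comp = i, parent = cell$parent[i], g_uS = cell$g_axial[i])
}

## Sparse branched-cable Laplacian (uS): row sums zero, SPD when added to a
## positive diagonal.
.laplacian <- function(cell) {
  i <- which(!is.na(cell$parent))
  if (!length(i)) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                              dims = c(cell$n, cell$n)))
  p <- cell$parent[i]
  g <- cell$g_axial[i]
  Matrix::sparseMatrix(
    i = c(i, p, i, p), j = c(p, i, i, p), x = c(-g, -g, g, g),
    dims = c(cell$n, cell$n))
}

## conductance time series of one synapse on the simulation grid, by exact
## event-decay recursion g_{k+1} = g_k exp(-dt/tau) + (spikes in (t_k,t_{k+1}])
.syn_g_series <- function(s, times, dt) {
  nt1 <- length(times)
  sp <- sort(s$spike_times)
  sp <- sp[sp <= times[nt1] + 1e-12]
  g0 <- 0
  pre <- sp[sp <= times[1] + 1e-12]
  if (length(pre)) g0 <- s$weight * sum(exp(-(times[1] - pre) / s$tau))
  imp <- numeric(nt1)
  post <- sp[sp > times[1] + 1e-12]
  if (length(post)) {
    kk <- pmin(ceiling((post - times[1]) / dt - 1e-9) + 1L, nt1)
    w <- s$weight * exp(-(times[kk] - post) / s$tau)
    agg <- rowsum(w, kk)
    imp[as.integer(rownames(agg))] <- agg
  }
  x <- imp
  x[1] <- g0
  as.numeric(stats::filter(x, exp(-dt / s$tau), method = "recursive"))
}

#' Simulate the passive cable dynamics of a cell
#'
#' Advances the branched cable equation for all compartments with an implicit
#' scheme and records, for `t >= 0`, the membrane potentials, the
#' transmembrane currents `I_mem` (outward positive, capacitive + ionic +
#' synaptic; the source term of the extracellular forward model) and the
#' electrode-injected currents `I_inj`. When coefficient matrices are passed
#' as `runtime_sinks`, each recorded step's contact potentials
#' `Phi = C I_mem` are accumulated on the fly, so full current storage can be
#' disabled (`store_imem = FALSE`) for large simulations.
#'
#' @param cell a `comp_cell`, with stimuli attached via [attach_exp_synapse()],
#'   [attach_current_clamp()] or [attach_sine_clamp()].
#' @param control a [sim_control()] object.
#' @param method `"backward_euler"` (first order, default) or
#'   `"crank_nicolson"` (second order).
#' @param runtime_sinks optional list of [compute_coefficient_matrix()]
#'   results (or plain matrices with `n` columns) evaluated at run time.
#' @param rec_isyn record per-synapse currents (post-step voltage).
#' @param store_imem keep the full N x T membrane-current matrix.
#' @param store_v keep the full N x T voltage matrix.
#' @return an object of class `sim_result`: list with `t`, `v`, `imem`,
#'   `iinj`, `isyn`, and `sinks` (list of contacts x T potential matrices).
#' @export
simulate_cell <- function(cell, control = sim_control(),
                          method = c("backward_euler", "crank_nicolson"),
                          runtime_sinks = NULL, rec_isyn = FALSE,
                          store_imem = TRUE, store_v = TRUE) {
  method <- match.arg(method)
  .assert(inherits(cell, "comp_cell"), "cell must be a comp_cell")
  .assert(inherits(control, "sim_control"), "control must be a sim_control")
  N <- cell$n
  dt <- control$dt
  nt <- round((control$tstop - control$tstart) / dt)
  .assert(abs(nt * dt - (control$tstop - control$tstart)) <= 1e-9 * max(1, nt),
          "dt does not evenly divide [tstart, tstop]")
  k0 <- round(-control$tstart / dt) + 1
  .assert(abs((k0 - 1) * dt + control$tstart) <= 1e-9,
          "dt is not commensurate with the recording grid: t = 0 must lie on the time grid")
  times <- control$tstart + dt * (0:nt)

  syns <- Filter(function(s) s$type == "exp_synapse", cell$stimuli)
  injs <- Filter(function(s) s$type %in% c("current_clamp", "sine_clamp"),
                 cell$stimuli)
  nsyn <- length(syns)

  L <- .laplacian(cell)
  gL <- cell$g_leak
  Cdt <- cell$cap / dt
  bbase <- gL * cell$e_pas

  ## injected-current series per electrode stimulus
  inj_series <- lapply(injs, function(s) {
    tend <- if (is.finite(s$duration)) s$delay + s$duration else Inf
    act <- times >= s$delay - 1e-12 & times < tend - 1e-12
    v <- if (s$type == "current_clamp") {
      ifelse(act, s$amplitude, 0)
    } else {
      s$amplitude * sin(2 * pi * s$freq * times / 1000 + s$phase) * act
    }
    list(idx = s$idx, v = v)
  })
  iinj_at <- function(k) {
    out <- numeric(N)
    for (s in inj_series) out[s$idx] <- out[s$idx] + s$v[k]
    out
  }

  ## synapse conductances, aggregated per compartment
  if (nsyn) {
    Gs <- do.call(rbind, lapply(syns, .syn_g_series, times = times, dt = dt))
    tg <- vapply(syns, function(s) s$idx, integer(1))
    er <- vapply(syns, function(s) s$e_rev, numeric(1))
    Map01 <- Matrix::sparseMatrix(i = tg, j = seq_len(nsyn), x = 1,
                                  dims = c(N, nsyn))
    Gcomp <- as.matrix(Map01 %*% Gs)          # N x (nt+1) conductance
    Brev <- as.matrix(Map01 %*% (Gs * er))    # N x (nt+1) g*e_rev
  }

  ## imposed extracellular field
  has_vext <- !is.null(cell$v_ext)
  if (has_vext) {
    Vx <- t(apply(cell$v_ext$v, 1, function(row)
      stats::approx(cell$v_ext$t, row, xout = times, rule = 2)$y))
    if (N == 1) Vx <- matrix(Vx, nrow = 1)
    LVx <- -as.matrix(L %*% Vx)
  }

  b_at <- function(k) {
    b <- bbase + iinj_at(k)
    if (nsyn) b <- b + Brev[, k]
    if (has_vext) b <- b + LVx[, k]
    b
  }

  baseA <- L + Matrix::Diagonal(x = gL)
  be <- method == "backward_euler"
  half <- if (be) 1 else 0.5
  fac <- NULL
  if (!nsyn) {
    Mleft <- Matrix::Diagonal(x = Cdt) + baseA * half
    fac <- Matrix::Cholesky(Matrix::forceSymmetric(Mleft), LDL = FALSE)
  }
  if (!be) Mright <- Matrix::Diagonal(x = Cdt) - baseA * 0.5

  Trec <- nt + 1 - (k0 - 1)
  trec <- times[k0:(nt + 1)]
  Vr <- if (store_v) matrix(NA_real_, N, Trec) else NULL
  IM <- if (store_imem) matrix(NA_real_, N, Trec) else NULL
  IJ <- matrix(0, N, Trec)
  IS <- if (rec_isyn && nsyn) matrix(0, nsyn, Trec) else NULL
  sink_mats <- NULL
  if (!is.null(runtime_sinks)) {
    sink_mats <- lapply(runtime_sinks, function(sk) {
      m <- if (inherits(sk, "coef_matrix")) sk$C else as.matrix(sk)
      .assert(ncol(m) == N, "runtime sink has wrong number of columns")
      m
    })
  }
  Phi <- lapply(sink_mats, function(m) matrix(0, nrow(m), Trec))

  record <- function(k, v) {
    col <- k - k0 + 1L
    iinj <- iinj_at(k)
    vx <- if (has_vext) Vx[, k] else 0
    imem <- -as.numeric(L %*% (v + vx)) + iinj
    if (store_v) Vr[, col] <<- v
    if (store_imem) IM[, col] <<- imem
    IJ[, col] <<- iinj
    if (!is.null(IS)) {
      for (s in seq_len(nsyn)) {
        IS[s, col] <<- Gs[s, k] * (v[syns[[s]]$idx] - syns[[s]]$e_rev)
      }
    }
    if (length(Phi)) {
      for (j in seq_along(Phi)) Phi[[j]][, col] <<- sink_mats[[j]] %*% imem
    }
  }

  v <- rep(control$v_init, N)
  if (k0 == 1) record(1L, v)

  for (k in seq_len(nt)) {
    b_new <- b_at(k + 1L)
    if (be) {
      rhs <- Cdt * v + b_new
    } else {
      rhs <- as.numeric(Mright %*% v) + 0.5 * (b_at(k) + b_new)
      if (nsyn) rhs <- rhs - 0.5 * Gcomp[, k] * v
    }
    if (nsyn) {
      M <- baseA * half + Matrix::Diagonal(x = Cdt + half * Gcomp[, k + 1L])
      v <- as.numeric(Matrix::solve(M, rhs))
    } else {
      v <- as.numeric(Matrix::solve(fac, rhs))
    }
    if (any(!is.finite(v))) {
      stop(sprintf("numerical error: non-finite state at step %d (t = %g ms)",
                   k + 1L, times[k + 1L]))
    }
    if (k + 1L >= k0) record(k + 1L, v)
  }

  structure(list(t = trec, v = Vr, imem = IM, iinj = IJ, isyn = IS,
                 sinks = Phi, method = method, dt = dt, n = N),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d compartments, %d samples (dt = %g ms, %s)\n",
              x$n, length(x$t), x$dt, x$method))
  invisible(x)
}
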