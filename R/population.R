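## Populations of independent cells sharing a presynaptic spike-train pool.
## Pairwise input correlation is controlled by the fraction of shared inputs:
## each cell selects n_select of the pool's n_trains trains uniformly without
## replacement, giving an expected pairwise correlation of the summed inputs
## of n_select / n_trains. Single-cell potentials add linearly into the
## population extracellular potential.

#' Generate a pool of homogeneous Poisson spike trains
#'
#' Independent homogeneous Poisson processes, deterministic for a given seed:
#' identical `(n_trains, rate, window, seed)` reproduce the pool bit for bit.
#' The same pool seed is shared by every cell of a population so that all
#' cells draw from identical trains.
#'
#' @param n_trains number of trains, >= 1.
#' @param rate firing rate (events/s), >= 0.
#' @param window length-2 numeric, (tstart, tstop) in ms.
#' @param seed integer seed.
#' @return an object of class `spike_pool`: list with `trains` (list of
#'   sorted spike-time vectors, ms) and the generating parameters.
#' @export
generate_poisson_pool <- function(n_trains, rate, window = c(0, 1000),
                                  seed = 1) {
  .assert(n_trains >= 1, "n_trains must be >= 1")
  .assert(rate >= 0, "rate must be >= 0", class = "lfpsim_argument_error")
  .assert(length(window) == 2 && window[2] > window[1], "invalid window")
  dur_s <- (window[2] - window[1]) / 1000
  trains <- with_seed(seed, {
    counts <- stats::rpois(n_trains, rate * dur_s)
    all_t <- stats::runif(sum(counts), window[1], window[2])
    lapply(split(all_t, rep.int(seq_len(n_trains), counts)), sort)
  })
  out <- rep(list(numeric(0)), n_trains)
  out[as.integer(names(trains))] <- trains
  structure(list(trains = out, n_trains = n_trains, rate = rate,
                 window = window, seed = seed),
            class = "spike_pool")
}

#' @export
print.spike_pool <- function(x, ...) {
  cat(sprintf("spike_pool: %d trains at %g events/s on [%g, %g] ms (seed %d)\n",
              x$n_trains, x$rate, x$window[1], x$window[2], x$seed))
  invisible(x)
}

#' Select input trains for one cell
#'
#' Uniform sample without replacement from the pool, deterministic per cell
#' seed. The expected overlap of two cells' selections is
#' `n_select^2 / n_trains` (hypergeometric mean), which is what sets the
#' population input correlation `n_select / n_trains`.
#'
#' @param pool a [generate_poisson_pool()] result.
#' @param n_select trains per cell, <= `pool$n_trains`.
#' @param cell_seed integer seed for this cell's selection.
#' @return sorted integer train indices.
#' @export
select_inputs <- function(pool, n_select, cell_seed) {
  .assert(n_select <= pool$n_trains,
          sprintf("n_select (%d) exceeds the pool size (%d)",
                  as.integer(n_select), pool$n_trains))
  .assert(n_select >= 1, "n_select must be >= 1")
  sort(with_seed(cell_seed, sample.int(pool$n_trains, n_select)))
}

#' Bin spike times into counts
#'
#' @param times spike times (ms).
#' @param window length-2 numeric (ms).
#' @param bin_ms bin width (ms).
#' @return integer vector of counts per bin.
#' @export
bin_spike_counts <- function(times, window, bin_ms = 5) {
  nb <- ceiling((window[2] - window[1]) / bin_ms)
  idx <- floor((times - window[1]) / bin_ms) + 1
  idx <- idx[idx >= 1 & idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Pairwise input correlation of two cells' pooled inputs
#'
#' Pearson correlation between the binned (default 5 ms) spike counts of the
#' two cells' merged selected trains. This is the operational definition of
#' the population input correlation; for selections of `n_select` from
#' `n_trains` shared Poisson trains its expectation is
#' `n_select / n_trains`.
#'
#' @param pool a [generate_poisson_pool()] result.
#' @param sel_a,sel_b integer train indices of the two cells.
#' @param bin_ms bin width (ms).
#' @return Pearson correlation coefficient.
#' @export
input_correlation <- function(pool, sel_a, sel_b, bin_ms = 5) {
  ca <- bin_spike_counts(unlist(pool$trains[sel_a]), pool$window, bin_ms)
  cb <- bin_spike_counts(unlist(pool$trains[sel_b]), pool$window, bin_ms)
  stats::cor(ca, cb)
}

#' Uniform cell placement in a horizontal disc
#'
#' Fig.-4-style column placement: soma centers uniform over a disc of radius
#' `R` in the xy-plane at height `z`.
#'
#' @param n_cells number of cells.
#' @param R disc radius (um).
#' @param z common z coordinate (um).
#' @param seed integer seed.
#' @return n x 3 matrix of positions.
#' @export
place_disc <- function(n_cells, R = 100, z = 0, seed = 1) {
  with_seed(seed, {
    r <- R * sqrt(stats::runif(n_cells))
    th <- stats::runif(n_cells, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th), rep(z, n_cells))
  })
}

#' Population run configuration
#'
#' Describes a population of morphologically identical, independently
#' simulated cells driven from a shared Poisson spike-train pool. All
#' per-cell randomness (train selection, synapse placement) derives
#' deterministically from `master_seed` and the cell index, so a run is fully
#' reproducible and independent of the execution mode.
#'
#' @param n_cells number of cells.
#' @param morphology a [morphology3d()] (shared by all cells).
#' @param passive a [comp_params()].
#' @param nseg_override optional override passed to [compartmentalize()].
#' @param positions n x 3 matrix of soma positions, or `NULL` to place cells
#'   uniformly in a disc of radius `placement_radius` (seeded from
#'   `master_seed`).
#' @param placement_radius disc radius (um) used when `positions` is `NULL`.
#' @param rotations n x 3 matrix of per-cell rotation angles (radians), or
#'   `NULL` for none.
#' @param synapse list with fields `section`, `tau`, `e_rev`, `weight`:
#'   synapses are placed on compartments of `section` (uniformly, per-cell
#'   seeded).
#' @param n_select pool trains (= synapses) per cell.
#' @param pool list with fields `n_trains`, `rate`; the pool window is the
#'   simulation window.
#' @param control a [sim_control()].
#' @param electrode an [electrode_array()].
#' @param master_seed master seed for all derived streams.
#' @param mode `"serial"` or `"parallel"`.
#' @param workers worker processes for parallel mode.
#' @return a classed configuration list.
#' @export
population_config <- function(n_cells, morphology, passive = comp_params(),
                              nseg_override = NULL, positions = NULL,
                              placement_radius = 100, rotations = NULL,
                              synapse = list(section = "dend", tau = 2,
                                             e_rev = 0, weight = 0.001),
                              n_select = 10,
                              pool = list(n_trains = 100, rate = 5),
                              control = sim_control(),
                              electrode = electrode_array(0, 0, 0),
                              master_seed = 1,
                              mode = c("serial", "parallel"), workers = 2) {
  mode <- match.arg(mode)
  .assert(n_cells >= 1, "n_cells must be >= 1")
  .assert(n_select >= 1 && n_select <= pool$n_trains,
          "need 1 <= n_select <= pool$n_trains")
  structure(list(n_cells = n_cells, morphology = morphology,
                 passive = passive, nseg_override = nseg_override,
                 positions = positions, placement_radius = placement_radius,
                 rotations = rotations, synapse = synapse,
                 n_select = n_select, pool = pool, control = control,
                 electrode = electrode, master_seed = master_seed,
                 mode = mode, workers = workers),
            class = "population_config")
}

#' Simulate a population and sum its extracellular potentials
#'
#' Each cell is built, stimulated and simulated independently with seeds
#' derived from `(master_seed, cell index)`; its contact potentials are
#' computed through the coefficient-matrix runtime scheme and summed into the
#' population potential. Serial and parallel execution give bit-identical
#' results for the same master seed because no randomness crosses cell
#' boundaries.
#'
#' @param config a [population_config()].
#' @return an object of class `population_result`: list with `t`,
#'   `phi` (summed contacts x T), `phi_cells` (per-cell list), `selections`
#'   (per-cell train indices) and `positions`.
#' @export
run_population <- function(config) {
  .assert(inherits(config, "population_config"),
          "config must be a population_config")
  cfg <- config
  ctl <- cfg$control
  pool <- generate_poisson_pool(cfg$pool$n_trains, cfg$pool$rate,
                                window = c(ctl$tstart, ctl$tstop),
                                seed = derive_seed(cfg$master_seed, 0, 1))
  positions <- cfg$positions %||%
    place_disc(cfg$n_cells, cfg$placement_radius,
               seed = derive_seed(cfg$master_seed, 0, 2))
  base_cell <- compartmentalize(cfg$morphology, cfg$passive,
                                cfg$nseg_override)

  run_one <- function(i) {
    seed_i <- derive_seed(cfg$master_seed, i)
    sel <- select_inputs(pool, cfg$n_select, derive_seed(seed_i, 1))
    cell <- base_cell
    if (!is.null(cfg$rotations)) {
      cell <- set_rotation(cell, cfg$rotations[i, 1], cfg$rotations[i, 2],
                           cfg$rotations[i, 3])
    }
    cell <- set_position(cell, positions[i, 1], positions[i, 2],
                         positions[i, 3])
    cand <- index_lookup(cell, cfg$synapse$section)
    targets <- with_seed(derive_seed(seed_i, 2),
                         cand[sample.int(length(cand), length(sel),
                                         replace = TRUE)])
    for (j in seq_along(sel)) {
      cell <- attach_exp_synapse(cell, targets[j],
                                 weight = cfg$synapse$weight,
                                 tau = cfg$synapse$tau,
                                 e_rev = cfg$synapse$e_rev,
                                 spike_times = pool$trains[[sel[j]]])
    }
    C <- compute_coefficient_matrix(cell, cfg$electrode)
    res <- tryCatch(
      simulate_cell(cell, ctl, runtime_sinks = list(C),
                    store_imem = FALSE, store_v = FALSE),
      error = function(e) {
        stop(sprintf("cell %d failed: %s", i, conditionMessage(e)))
      })
    list(phi = res$sinks[[1]], t = res$t, sel = sel)
  }

  per_cell <- if (cfg$mode == "parallel" && cfg$workers > 1 &&
                  .Platform$OS.type == "unix") {
    out <- parallel::mclapply(seq_len(cfg$n_cells), run_one,
                              mc.cores = cfg$workers, mc.preschedule = TRUE)
    errs <- vapply(out, inherits, logical(1), "try-error")
    if (any(errs)) stop(attr(out[[which(errs)[1]]], "condition")$message)
    out
  } else {
    lapply(seq_len(cfg$n_cells), run_one)
  }

  phi_cells <- lapply(per_cell, `[[`, "phi")
  phi <- Reduce(`+`, phi_cells)
  structure(list(t = per_cell[[1]]$t, phi = phi, phi_cells = phi_cells,
                 selections = lapply(per_cell, `[[`, "sel"),
                 positions = positions),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("population_result: %d cells, %d contacts, %d samples\n",
              length(x$phi_cells), nrow(x$phi), ncol(x$phi)))
  invisible(x)
}
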