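#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number generator seeded to `seed`, then
#' restores the previous RNG state so surrounding stochastic code is not
#' perturbed. All seeded draws in the package (spike-train pools, train
#' selection, electrode disc sampling, cell placement) go through this helper,
#' which is what makes every result reproducible from its logged seeds.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Fixed linear-congruential mix, exact in double arithmetic, so that per-cell
#' and per-stream seeds are reproducible across platforms and stay below
#' 2^31. Changing `index` (e.g. the cell index) or `stream` (e.g. selection vs.
#' synapse placement) yields an unrelated child seed.
#'
#' @param master integer master seed (< 2^31).
#' @param index non-negative integer, e.g. a cell index.
#' @param stream non-negative integer sub-stream selector.
#' @return integer seed in \[1, 2^31).
#' @export
derive_seed <- function(master, index = 0, stream = 0) {
  m <- 2147483647
  s <- ((master %% m) * 69069 + 30103 * (index %% m) + 7919 * (stream %% m) + 1) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## row-wise euclidean norms of a n x 3 matrix
.rownorm <- function(m) sqrt(rowSums(m * m))

.assert <- function(cond, msg, class = "lfpsim_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}
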