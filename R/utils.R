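# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# seeded Latin-hypercube start points inside a box; optional anchor point is
# prepended (and counted against n)
multistart_points <- function(anchor, lower, upper, n, seed) {
  p <- length(lower)
  n_lhs <- if (is.null(anchor)) n else n - 1L
  pts <- NULL
  if (n_lhs > 0) {
    u <- with_seed_local(seed, lhs::randomLHS(n_lhs, p))
    pts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  }
  if (!is.null(anchor)) pts <- rbind(matrix(anchor, nrow = 1), pts)
  colnames(pts) <- names(lower)
  pts
}
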