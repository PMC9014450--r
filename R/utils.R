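## Internal helpers shared across modules.

## Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Dirichlet draws via normalized gamma variates; n x length(alpha).
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  sweep(g, 1L, rowSums(g), "/")
}

## Gamma-Poisson counts around a mean matrix; dispersion 0 degenerates to
## Poisson (size = 1/dispersion is the NB size parameter).
.rcounts <- function(mu, dispersion) {
  n <- length(mu)
  draws <- if (dispersion <= 0) stats::rpois(n, lambda = as.numeric(mu))
           else stats::rnbinom(n, size = 1 / dispersion, mu = as.numeric(mu))
  matrix(draws, nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
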