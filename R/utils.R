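#' Evaluate an expression under a local, restorable RNG seed
#'
#' All stochastic stages in the package funnel their randomness through this
#' helper so that a single integer seed fixes every generated quantity without
#' clobbering the caller's RNG state.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# sdlog for a lognormal with unit mean and coefficient of variation cv
lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative lognormal noise with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- lnorm_sdlog(cv)
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# symmetric Dirichlet (or rescaled-mean Dirichlet when alpha is a vector)
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
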