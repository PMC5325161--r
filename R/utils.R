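# internal helpers shared across modules

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Column means/sds over observed cells only; sd of a single value is NA -> 1.
observed_moments <- function(values, missing_mask) {
  obs <- values
  obs[missing_mask] <- NA_real_
  mu <- colMeans(obs, na.rm = TRUE)
  sigma <- apply(obs, 2, stats::sd, na.rm = TRUE)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  list(mean = mu, sd = sigma)
}

standardize_observed <- function(values, missing_mask) {
  m <- observed_moments(values, missing_mask)
  z <- sweep(sweep(values, 2, m$mean, "-"), 2, m$sd, "/")
  z[missing_mask] <- NA_real_
  list(z = z, mean = m$mean, sd = m$sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
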