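## Internal helpers shared across modules.

#' @importFrom stats rnorm rlnorm runif rgamma approx quantile sd coef lm
#' @importFrom utils read.delim write.table head tail packageVersion
#' @import methods
NULL

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package route through this,
## which is what makes fixed-seed outputs byte-identical.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Lower-interpolation empirical quantile: the order statistic at
## ceiling(q * n), clamped to [1, n]. Deliberately simpler than
## stats::quantile() so that a brute-force sort-and-index oracle can
## reproduce it exactly.
quantileLower <- function(x, q) {
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(q)))
  xs <- sort(x)
  idx <- pmin(pmax(ceiling(q * n), 1L), n)
  xs[idx]
}

## Intensity-weighted lower quantile: smallest sorted x whose cumulative
## weight reaches q * total. Used by balanced-intensity boundary placement.
weightedQuantileLower <- function(x, w, q) {
  if (length(x) == 0L) return(rep(NA_real_, length(q)))
  o <- order(x)
  xs <- x[o]
  cw <- cumsum(w[o])
  tot <- cw[length(cw)]
  vapply(q, function(qq) {
    if (tot <= 0) return(xs[1L])
    xs[which(cw >= qq * tot)[1L]]
  }, numeric(1))
}

## Gaussian elution factor at time t for a peak with apex `apex` and full
## width at half maximum `fwhm` (both seconds); equals 1 at the apex and
## 1/2 at apex +/- fwhm/2.
elutionFactor <- function(t, apex, fwhm) {
  exp(-4 * log(2) * (t - apex)^2 / fwhm^2)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Cheap deterministic checksum of an R object, for provenance logs.
paramHash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  sprintf("%08x", sum(as.integer(bytes) * (seq_along(bytes) %% 251)) %%
            .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
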