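# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, staying inside
# the 32-bit integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 12007) %% 2147483629)
}

# Population (denominator N) standard deviation.
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Truncated-normal dwell/gap laws
#'
#' A lightweight description of a normal distribution truncated below at
#' `lower`, used for event dwell times and inter-event gaps (both must be
#' positive quantities in seconds).
#'
#' @param mean Mean of the parent (untruncated) normal, seconds.
#' @param sd Standard deviation of the parent normal, seconds.
#' @param lower Lower truncation bound, seconds (default 0).
#' @return An object of class `"tnorm_law"`.
#' @examples
#' law <- tnorm_law(0.9, 0.46)
#' tnorm_mean(law)       # closed-form mean of the truncated law
#' rtnorm(5, law, seed = 1)
#' @export
tnorm_law <- function(mean, sd, lower = 0) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, lower < Inf)
  structure(list(mean = mean, sd = sd, lower = lower), class = "tnorm_law")
}

#' @rdname tnorm_law
#' @param n Number of draws.
#' @param law A `tnorm_law` object.
#' @param seed Optional integer seed.
#' @export
rtnorm <- function(n, law, seed = NULL) {
  stopifnot(inherits(law, "tnorm_law"))
  with_seed(seed, {
    if (law$sd == 0) return(rep(max(law$mean, law$lower), n))
    p_lo <- stats::pnorm(law$lower, law$mean, law$sd)
    u <- stats::runif(n, p_lo, 1)
    # guard against u == 1 returning Inf
    pmin(stats::qnorm(pmin(u, 1 - 1e-16), law$mean, law$sd), law$mean + 10 * law$sd)
  })
}

#' @rdname tnorm_law
#' @export
tnorm_mean <- function(law) {
  stopifnot(inherits(law, "tnorm_law"))
  if (law$sd == 0) return(max(law$mean, law$lower))
  a <- (law$lower - law$mean) / law$sd
  law$mean + law$sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}
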