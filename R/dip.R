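.dip_cache <- new.env(parent = emptyenv())

#' Hartigan's dip statistic
#'
#' Maximum difference, over all sample points, between the empirical CDF and
#' the closest unimodal CDF. By the package convention (shared with the
#' classical implementation) the statistic is floored at 1/(2n), its value
#' for a constant sample.
#'
#' @param x Numeric vector (n >= 2, finite).
#' @return The dip statistic D, with 1/(2n) <= D <= 0.25.
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("dip statistic needs at least 2 observations")
  if (any(!is.finite(x))) stop("dip statistic requires finite values")
  .dip_stat_cpp(x)
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the sample comes from a unimodal
#' distribution, using a Monte Carlo p-value: the dip of the sample is
#' compared against the dips of `n_boot` uniform(0, 1) samples of the same
#' size (the least favorable unimodal null). The null reference table is
#' cached per (n, n_boot, seed) within the session, so repeated tests of
#' equally sized samples reuse it.
#'
#' @param x Numeric vector; n >= 4 recommended for a meaningful p-value.
#' @param n_boot Number of Monte Carlo null samples (default 10000).
#' @param seed Integer seed for the null reference draws.
#' @return A list of class `dip_result`: `D`, `p_value`, `n`, `n_boot`,
#'   `seed`.
#' @export
dip_test <- function(x, n_boot = 10000L, seed = 1L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("dip test needs at least 2 observations")
  if (any(!is.finite(x))) stop("dip test requires finite values")
  D <- .dip_stat_cpp(x)
  if (length(unique(x)) == 1L) {
    res <- list(D = D, p_value = 1, n = n, n_boot = as.integer(n_boot),
                seed = as.integer(seed))
    class(res) <- "dip_result"
    return(res)
  }
  key <- paste(n, n_boot, seed, sep = "_")
  if (is.null(.dip_cache[[key]])) {
    old <- .Random.seed_save()
    set.seed(seed)
    .dip_cache[[key]] <- .dip_null_cpp(n, as.integer(n_boot))
    .Random.seed_restore(old)
  }
  null_dips <- .dip_cache[[key]]
  p <- (1 + sum(null_dips >= D)) / (n_boot + 1)
  res <- list(D = D, p_value = p, n = n, n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  class(res) <- "dip_result"
  res
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.4f, p = %.4g (n = %d, %d Monte Carlo nulls)\n",
              x$D, x$p_value, x$n, x$n_boot))
  invisible(x)
}

# save/restore the global RNG state so cached null-table generation does not
# perturb a caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
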