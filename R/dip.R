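# Hartigan dip statistic of unimodality.
#
# The dip of an empirical CDF F_n is the smallest sup-norm distance between
# F_n and any unimodal CDF (convex up to a mode, concave after it, with an
# atom allowed at the mode). The computation (src/dip.cpp) decides, by an
# exact sweep over the distinct sorted values, whether a unimodal CDF exists
# within a given half-band of F_n, and bisects on the band width; see the
# methods vignette for the construction.

.dip_stat <- function(x) .dip_stat_cpp(as.numeric(x))

#' Hartigan dip test of unimodality
#'
#' Computes the dip statistic (the maximal distance between the empirical
#' CDF and the closest unimodal CDF) and a bootstrap p-value obtained by
#' comparing the observed dip to dips of uniform samples of the same size
#' (the standard calibration). The dip is invariant under affine maps and
#' reflection of the sample.
#'
#' @param samples numeric vector, at least 4 values.
#' @param n_boot number of bootstrap null samples (default 2000).
#' @param seed optional seed for the bootstrap draw.
#' @param null_dips optional precomputed vector of null dip statistics at
#'   the same sample size (e.g. from [dip_null_distribution()]); when given,
#'   no fresh bootstrap is drawn.
#' @return an object of class \code{dip_result}: list with \code{dip},
#'   \code{p_value}, \code{n}, \code{n_boot}.
#' @seealso [dip_null_distribution()]
#' @examples
#' d <- dip_statistic(c(rnorm(100, 0, 0.5), rnorm(100, 5, 0.5)), n_boot = 200)
#' d$p_value  # small: clearly bimodal
#' @export
dip_statistic <- function(samples, n_boot = 2000, seed = NULL,
                          null_dips = NULL) {
  d <- .dip_stat(samples)
  n <- length(samples)
  if (is.null(null_dips)) {
    null_dips <- dip_null_distribution(n, n_boot = n_boot, seed = seed)
  }
  p <- mean(null_dips >= d)
  structure(list(dip = d, p_value = p, n = n, n_boot = length(null_dips)),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("<dip_result> Dip = %.4f, p = %.3f (n = %d, %d bootstrap draws)\n",
              x$dip, x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' Bootstrap null distribution of the dip statistic
#'
#' Dip statistics of \code{n_boot} uniform samples of size \code{n}.
#' Precomputing this reference once and passing it to [dip_statistic()]
#' avoids re-simulating the null when many tests share a sample size.
#'
#' @param n sample size.
#' @param n_boot number of uniform null samples.
#' @param seed optional seed.
#' @return numeric vector of \code{n_boot} dip values.
#' @export
dip_null_distribution <- function(n, n_boot = 2000, seed = NULL) {
  with_seed(seed, replicate(n_boot, .dip_stat(stats::runif(n))))
}
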