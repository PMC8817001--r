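#' Amplitude-parameterized Gaussian mixture curve fit
#'
#' Fits the curve \deqn{f(x) = \sum_{i=1}^{k} a_i \exp(-((x-b_i)/c_i)^2)}
#' to the histogram density of a sample by least squares
#' (Levenberg-Marquardt via \pkg{minpack.lm}), with multi-start
#' initialization. This is a curve-fit (amplitude) parameterization of a
#' Gaussian mixture, not a normalized probability density: the amplitudes
#' \eqn{a_i} are free, so the fit is directly comparable across histograms
#' and is not renormalized.
#'
#' Initial centers are placed at sample quantiles and jittered across
#' restarts; widths start at a fraction of the sample range. Amplitudes are
#' constrained non-negative and widths strictly positive. An optional
#' \code{init} (a previous \code{mixture_fit} with fewer components) is used
#' as an additional warm start with a zero-amplitude extra component, which
#' makes the residual sum of squares non-increasing in \code{k} when fits
#' are obtained sequentially, as [select_k()] does.
#'
#' @param samples numeric vector (at least 10 values).
#' @param k number of components (1 to 10).
#' @param bins number of histogram bins (default 20).
#' @param limits histogram range; defaults to [0, 1] (extended if the data
#'   fall outside).
#' @param n_starts number of random restarts (default 20).
#' @param seed optional seed for the restarts.
#' @param init optional \code{mixture_fit} used as a warm start.
#' @return an object of class \code{mixture_fit}: list with \code{k},
#'   \code{components} (data frame amplitude/center/width), \code{rss},
#'   \code{bins}, \code{limits}, \code{hist_x}, \code{hist_y},
#'   \code{converged}.
#' @export
fit_mixture <- function(samples, k, bins = 20, limits = c(0, 1),
                        n_starts = 20, seed = NULL, init = NULL) {
  if (length(samples) < 10) stop_("need at least 10 samples to fit a mixture")
  if (k < 1 || k > 10) stop_("k must be between 1 and 10")
  limits <- c(min(limits[1], min(samples)), max(limits[2], max(samples)))
  breaks <- seq(limits[1], limits[2], length.out = bins + 1)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$density

  model_y <- function(par) {
    a <- par[1:k]; b <- par[k + 1:k]; cc <- par[2 * k + 1:k]
    rowSums(vapply(seq_len(k),
                   function(i) a[i] * exp(-((x - b[i]) / cc[i])^2),
                   numeric(length(x))))
  }
  # Levenberg-Marquardt needs at least as many residuals as parameters;
  # with many components and few bins the fit is underdetermined, so the
  # residual vector is padded with zeros (RSS is unchanged).
  pad <- max(0, 3 * k + 1 - length(x))
  resid_fn <- function(par) c(y - model_y(par), rep(0, pad))
  lower <- c(rep(0, k), rep(limits[1] - diff(limits), k), rep(1e-4, k))
  upper <- c(rep(Inf, k), rep(limits[2] + diff(limits), k), rep(Inf, k))

  rng <- diff(limits)
  starts <- with_seed(seed, {
    qs <- stats::quantile(samples, probs = seq_len(k) / (k + 1), names = FALSE)
    lapply(seq_len(n_starts), function(s) {
      b0 <- if (s == 1) qs else qs + stats::rnorm(k, 0, rng / (4 * k))
      c0 <- rep(stats::sd(samples) / sqrt(k) + rng / (10 * k), k) *
        stats::runif(k, 0.5, 2)
      a0 <- rep(max(y), k) * stats::runif(k, 0.3, 1)
      c(a0, pmin(pmax(b0, limits[1]), limits[2]), c0)
    })
  })
  if (!is.null(init)) {
    stopifnot(inherits(init, "mixture_fit"))
    kp <- init$k
    if (kp < k) {
      extra <- k - kp
      starts <- c(starts, list(c(init$components$amplitude, rep(0, extra),
                                 init$components$center,
                                 rep(stats::quantile(samples, 0.5,
                                                     names = FALSE), extra),
                                 init$components$width,
                                 rep(rng / 10, extra))))
    }
  }

  best <- NULL
  for (par0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop_("mixture fit failed to converge from any start")
  ord <- order(best$par[k + 1:k])
  comp <- data.frame(amplitude = best$par[1:k][ord],
                     center = best$par[k + 1:k][ord],
                     width = abs(best$par[2 * k + 1:k])[ord])
  structure(list(k = k, components = comp, rss = best$rss,
                 bins = bins, limits = limits, hist_x = x, hist_y = y,
                 converged = TRUE),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> k = %d, RSS = %.5g\n", x$k, x$rss))
  print(x$components, digits = 4)
  invisible(x)
}

#' Evaluate a fitted mixture curve
#'
#' @param fit a \code{mixture_fit}.
#' @param x numeric vector of evaluation points.
#' @return numeric vector of fitted curve values.
#' @export
mixture_density <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  comp <- fit$components
  out <- numeric(length(x))
  for (i in seq_len(nrow(comp))) {
    out <- out + comp$amplitude[i] * exp(-((x - comp$center[i]) / comp$width[i])^2)
  }
  out
}

#' @export
plot.mixture_fit <- function(x, ...) {
  graphics::plot(x$hist_x, x$hist_y, type = "h", lwd = 3, col = "grey70",
                 xlab = "score", ylab = "density", ...)
  xx <- seq(x$limits[1], x$limits[2], length.out = 400)
  graphics::lines(xx, mixture_density(x, xx), lwd = 2)
  invisible(x)
}

#' Choose the number of mixture components
#'
#' Fits the amplitude-Gaussian curve for each k in \code{k_range} and
#' reports two selections based on the residual sum of squares and,
#' separately, the silhouette-optimal k from hard one-dimensional k-means
#' clustering (silhouette is undefined at k = 1, so it is evaluated for
#' k >= 2 only).
#'
#' The RSS-based choice is the smallest k whose RSS reaches the sampling
#' noise floor of the histogram. If the fitted curve were the true density,
#' the expected RSS would be the summed multinomial variance of the bin
#' density estimates, \eqn{\sum_i y_i (1 - y_i w) / (n w)} with bin width
#' w; a fit whose RSS falls below \code{rss_tol} times this floor explains
#' all structure distinguishable from bin noise, and further components
#' only interpolate that noise. (A relative-improvement elbow --- stop when
#' the RSS improvement falls below \code{elbow_threshold} --- is used as a
#' fallback if no k reaches the floor; on histogram least squares alone it
#' systematically overfits, because extra components cut the noise RSS by
#' large factors until the bins are interpolated.)
#'
#' Fits are warm-started from the previous k so the RSS sequence is
#' non-increasing.
#'
#' @param samples numeric vector (at least 10 values).
#' @param k_range integer range of k values (default 1:10).
#' @param bins,limits,n_starts passed to [fit_mixture()].
#' @param rss_tol multiple of the histogram noise floor at which the RSS is
#'   considered converged (default 1.5).
#' @param elbow_threshold relative RSS improvement below which the fallback
#'   elbow stops (default 0.1).
#' @param seed optional seed (restarts and k-means).
#' @return list with \code{k} (the RSS-based choice), \code{k_silhouette},
#'   \code{rss} (named vector), \code{noise_floor}, \code{silhouette}
#'   (named vector, k >= 2), \code{fits} (list of \code{mixture_fit}),
#'   \code{best_fit}.
#' @export
select_k <- function(samples, k_range = 1:10, bins = 20, limits = c(0, 1),
                     n_starts = 20, rss_tol = 1.5, elbow_threshold = 0.1,
                     seed = NULL) {
  if (length(samples) < 10) stop_("need at least 10 samples")
  k_range <- sort(unique(as.integer(k_range)))
  seeds <- if (is.null(seed)) rep(list(NULL), length(k_range)) else
    as.list(split_seed(seed, length(k_range) + 1))
  fits <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    fits[[i]] <- fit_mixture(samples, k_range[i], bins = bins, limits = limits,
                             n_starts = n_starts, seed = seeds[[i]],
                             init = prev)
    prev <- fits[[i]]
  }
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  names(rss) <- k_range
  # sampling noise floor of the histogram density (multinomial variance)
  f1 <- fits[[1]]
  w <- diff(f1$limits) / f1$bins
  n <- length(samples)
  floor_rss <- sum(f1$hist_y * pmax(1 - f1$hist_y * w, 0)) / (n * w)
  reached <- which(rss <= rss_tol * floor_rss)
  if (length(reached)) {
    k_elbow <- k_range[reached[1]]
  } else {
    k_elbow <- k_range[length(k_range)]
    for (i in seq_len(length(k_range) - 1)) {
      impr <- (rss[i] - rss[i + 1]) / rss[i]
      if (!is.finite(impr) || impr < elbow_threshold) {
        k_elbow <- k_range[i]; break
      }
    }
  }
  ks <- k_range[k_range >= 2]
  sil <- rep(NA_real_, length(ks))
  names(sil) <- ks
  km_seed <- if (is.null(seed)) NULL else seeds[[length(k_range) + 1]]
  sil <- with_seed(km_seed, {
    vapply(ks, function(k) {
      km <- stats::kmeans(samples, centers = k, nstart = 10, iter.max = 50)
      mean(cluster::silhouette(km$cluster, stats::dist(samples))[, "sil_width"])
    }, numeric(1))
  })
  names(sil) <- ks
  k_sil <- if (length(ks)) ks[which.max(sil)] else NA_integer_
  list(k = k_elbow, k_silhouette = k_sil, rss = rss,
       noise_floor = floor_rss, silhouette = sil,
       fits = fits, best_fit = fits[[match(k_elbow, k_range)]])
}
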