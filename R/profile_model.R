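sr_cols <- c("sr_closeness", "sr_equality", "sr_accession")

profile_matrix <- function(profiles) {
  if (is.data.frame(profiles)) {
    stopifnot(all(sr_cols %in% names(profiles)))
    m <- as.matrix(profiles[, sr_cols])
  } else {
    m <- as.matrix(profiles)
    if (ncol(m) != 3) stop_("strategic profiles must have 3 columns")
    colnames(m) <- sr_cols
  }
  m
}

#' Principal component analysis of strategic profiles
#'
#' Standardizes each strategy-rate dimension (z-score) and eigendecomposes
#' the covariance matrix of the standardized data. Components are sorted by
#' descending eigenvalue magnitude; each component's sign is fixed so that
#' its largest-magnitude loading is positive, which makes the result
#' reproducible across linear-algebra backends.
#'
#' @param profiles data frame with columns \code{sr_closeness},
#'   \code{sr_equality}, \code{sr_accession} (as from [strategy_rates()]),
#'   or a 3-column numeric matrix. Rows with missing values are dropped
#'   with a warning.
#' @return an object of class \code{sr_pca}: list with \code{center},
#'   \code{scale}, \code{components} (3 x 3, rows U1..U3), \code{eigenvalues}.
#' @export
fit_pca <- function(profiles) {
  m <- profile_matrix(profiles)
  ok <- stats::complete.cases(m)
  if (!all(ok)) {
    warning(sprintf("%d profile(s) with undefined strategy rates dropped", sum(!ok)))
    m <- m[ok, , drop = FALSE]
  }
  if (nrow(m) < 3) stop_("need at least 3 complete strategic profiles")
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  zero <- scl <= 0 | !is.finite(scl)
  if (any(zero))
    stop_("zero variance in dimension(s): %s", paste(sr_cols[zero], collapse = ", "))
  z <- scale(m, center = ctr, scale = scl)
  e <- eigen(stats::cov(z), symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  vals <- e$values[ord]
  comp <- t(e$vectors[, ord, drop = FALSE])  # rows are components
  for (i in 1:3) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  dimnames(comp) <- list(paste0("U", 1:3), sr_cols)
  structure(list(center = ctr, scale = scl, components = comp,
                 eigenvalues = vals, n = nrow(m)),
            class = "sr_pca")
}

#' @export
print.sr_pca <- function(x, ...) {
  cat(sprintf("<sr_pca> fitted on %d profiles; eigenvalues: %s\n", x$n,
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  print(round(x$components, 3))
  invisible(x)
}

standardize_profiles <- function(profiles, pca) {
  m <- profile_matrix(profiles)
  if (anyNA(m)) stop_("incomplete strategic profile(s)")
  scale(m, center = pca$center, scale = pca$scale)
}

#' Compress strategic profiles onto the leading components
#'
#' Projects standardized strategy-rate vectors onto the principal
#' directions: \eqn{s_i = U_i \cdot z} for the standardized profile z.
#'
#' @param profiles data frame or matrix of strategic profiles (see
#'   [fit_pca()]).
#' @param pca a fitted \code{sr_pca}.
#' @param m number of components to keep (default 2, giving S1 and S2).
#' @return matrix with one column per retained component (S1, S2, ...).
#' @export
compress_profiles <- function(profiles, pca, m = 2) {
  stopifnot(inherits(pca, "sr_pca"))
  if (m < 1 || m > 3) stop_("m must be 1, 2 or 3")
  z <- standardize_profiles(profiles, pca)
  s <- z %*% t(pca$components[seq_len(m), , drop = FALSE])
  colnames(s) <- paste0("S", seq_len(m))
  s
}

#' Retained variance after dimensionality reduction
#'
#' Reconstructs each standardized profile from its top-m principal
#' projections and reports the retained variance percentage
#' \deqn{100 (1 - \sum_i ||z_i - \hat z_i||^2 / \sum_i ||z_i||^2).}
#' With all three components the reconstruction is exact and the retained
#' variance is 100.
#'
#' @param profiles data frame or matrix of strategic profiles.
#' @param pca a fitted \code{sr_pca}.
#' @param m number of components used for the reconstruction (1 to 3).
#' @return retained variance in percent.
#' @export
retained_variance <- function(profiles, pca, m) {
  stopifnot(inherits(pca, "sr_pca"))
  if (m < 1 || m > 3) stop_("m must be 1, 2 or 3")
  z <- standardize_profiles(profiles, pca)
  u <- pca$components[seq_len(m), , drop = FALSE]
  approx <- (z %*% t(u)) %*% u
  100 * (1 - sum((z - approx)^2) / sum(z^2))
}

#' Linear model of coordination ability on compressed profiles
#'
#' Ordinary least squares of the iCA score on the two leading profile
#' projections: \eqn{iCA = \beta_0 + \beta_1 S_1 + \beta_2 S_2}.
#'
#' @param compressed matrix with columns S1, S2 (from [compress_profiles()]).
#' @param scores numeric vector of iCA scores, same length.
#' @return an object of class \code{ability_model}: list with
#'   \code{intercept}, \code{coef_s1}, \code{coef_s2}, \code{r_squared},
#'   \code{f_stat}, \code{p_value}, \code{var_error} (residual variance)
#'   and the underlying \code{lm} fit.
#' @export
fit_ability_model <- function(compressed, scores) {
  s <- as.matrix(compressed)
  if (ncol(s) < 2) stop_("need S1 and S2 columns")
  if (nrow(s) != length(scores)) stop_("scores and profiles differ in length")
  if (nrow(s) < 4) stop_("need at least 4 paired observations")
  df <- data.frame(ica = as.numeric(scores), s1 = s[, 1], s2 = s[, 2])
  qr_rank <- qr(cbind(1, s[, 1:2]))$rank
  if (qr_rank < 3) stop_("collinear predictors: S1/S2 do not span two dimensions")
  fit <- stats::lm(ica ~ s1 + s2, data = df)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 coef_s1 = unname(stats::coef(fit)[2]),
                 coef_s2 = unname(stats::coef(fit)[3]),
                 r_squared = sm$r.squared,
                 f_stat = fstat[1],
                 p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                     lower.tail = FALSE),
                 var_error = sm$sigma^2,
                 n = nrow(s), fit = fit),
            class = "ability_model")
}

#' @export
print.ability_model <- function(x, ...) {
  cat(sprintf("<ability_model> iCA = %.5f + %.5f*S1 + %.5f*S2\n",
              x$intercept, x$coef_s1, x$coef_s2))
  cat(sprintf("  R^2 = %.4f; F = %.4f; p = %.3g; VAR_error = %.4g (n = %d)\n",
              x$r_squared, x$f_stat, x$p_value, x$var_error, x$n))
  invisible(x)
}

#' Predict coordination ability from strategic profiles
#'
#' Compresses profiles with the fitted PCA and applies the linear ability
#' model.
#'
#' @param profiles data frame or matrix of strategic profiles.
#' @param pca a fitted \code{sr_pca}.
#' @param model a fitted \code{ability_model}.
#' @return numeric vector of predicted iCA scores.
#' @export
predict_ica <- function(profiles, pca, model) {
  stopifnot(inherits(model, "ability_model"))
  s <- compress_profiles(profiles, pca, m = 2)
  model$intercept + model$coef_s1 * s[, 1] + model$coef_s2 * s[, 2]
}

#' Relative-error validation of ability predictions
#'
#' Per-player relative absolute error
#' \eqn{100 |iCA_{real} - iCA_{pred}| / iCA_{real}} and its 25th/50th/75th
#' percentiles (linear-interpolation convention). Players with a real score
#' of zero are excluded with a warning.
#'
#' @param predictions numeric vector of predicted scores.
#' @param real_scores numeric vector of observed scores, same length.
#' @return an object of class \code{validation_report}: list with
#'   \code{errors} (percent), \code{percentiles} (named: p25, p50, p75),
#'   \code{n}, \code{n_excluded}.
#' @export
validate_predictions <- function(predictions, real_scores) {
  if (length(predictions) != length(real_scores))
    stop_("predictions and real scores differ in length")
  keep <- real_scores != 0
  if (!all(keep))
    warning(sprintf("%d player(s) with zero real score excluded", sum(!keep)))
  err <- abs(real_scores[keep] - predictions[keep]) / real_scores[keep] * 100
  q <- stats::quantile(err, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(errors = err,
                 percentiles = c(p25 = q[1], p50 = q[2], p75 = q[3]),
                 n = sum(keep), n_excluded = sum(!keep)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n = %d; relative |error| percentiles: 25%% = %.3f, 50%% = %.3f, 75%% = %.3f\n",
    x$n, x$percentiles["p25"], x$percentiles["p50"], x$percentiles["p75"]))
  invisible(x)
}
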