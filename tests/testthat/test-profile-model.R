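rand_profiles <- function(n, seed) {
  set.seed(seed)
  data.frame(sr_closeness = runif(n), sr_equality = runif(n),
             sr_accession = runif(n))
}

test_that("PCA produces an orthonormal basis with descending eigenvalues", {
  p <- rand_profiles(60, 101)
  pca <- fit_pca(p)
  expect_equal(pca$components %*% t(pca$components), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(abs(pca$eigenvalues)) <= 1e-12))
  expect_true(all(pca$eigenvalues >= -1e-12))
  # trace identity: standardized data has total variance 3
  expect_equal(sum(pca$eigenvalues), 3, tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (i in 1:3) {
    expect_gt(pca$components[i, which.max(abs(pca$components[i, ]))], 0)
  }
})

test_that("PCA agrees with an independent SVD up to sign", {
  p <- rand_profiles(50, 102)
  pca <- fit_pca(p)
  z <- scale(as.matrix(p))
  sv <- svd(z)
  for (i in 1:3) {
    v <- sv$v[, i]
    cosang <- abs(sum(v * pca$components[i, ]))
    expect_equal(cosang, 1, tolerance = 1e-8)
    expect_equal(sv$d[i]^2 / (nrow(p) - 1), pca$eigenvalues[i],
                 tolerance = 1e-8)
  }
})

test_that("exactly planar data has a vanishing third eigenvalue", {
  set.seed(103)
  a <- runif(40); b <- runif(40)
  p <- data.frame(sr_closeness = a, sr_equality = b,
                  sr_accession = 0.3 * a + 0.7 * b)
  pca <- fit_pca(p)
  expect_lt(pca$eigenvalues[3], 1e-10)
  expect_equal(retained_variance(p, pca, 2), 100, tolerance = 1e-8)
})

test_that("PCA errors on degenerate input", {
  p <- data.frame(sr_closeness = c(0.5, 0.5, 0.5, 0.5),
                  sr_equality = runif(4), sr_accession = runif(4))
  expect_error(fit_pca(p), "sr_closeness")
  expect_error(fit_pca(rand_profiles(2, 104)), "at least 3")
})

test_that("retained variance is 100% with all components and monotone in m", {
  for (seed in 105:109) {
    p <- rand_profiles(30, seed)
    pca <- fit_pca(p)
    rv <- vapply(1:3, function(m) retained_variance(p, pca, m), numeric(1))
    expect_equal(rv[3], 100, tolerance = 1e-8)
    expect_true(all(diff(rv) >= -1e-10))
    expect_true(all(rv >= 0 & rv <= 100 + 1e-8))
  }
  expect_error(retained_variance(rand_profiles(10, 110),
                                 fit_pca(rand_profiles(10, 110)), 4), "m must")
})

test_that("compression projects standardized profiles isometrically", {
  p <- rand_profiles(40, 111)
  pca <- fit_pca(p)
  s3 <- compress_profiles(p, pca, m = 3)
  z <- scale(as.matrix(p), center = pca$center, scale = pca$scale)
  # the mean profile maps to the origin
  mean_prof <- as.data.frame(t(colMeans(as.matrix(p))))
  names(mean_prof) <- names(p)
  expect_equal(unname(compress_profiles(mean_prof, pca)[1, ]), c(0, 0),
               tolerance = 1e-10)
  # norm preservation
  expect_equal(rowSums(s3^2), rowSums(z^2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # displacement along U1 has no S2 component
  u1_prof <- as.data.frame(t(colMeans(as.matrix(p)) +
                               0.1 * pca$scale * pca$components[1, ]))
  names(u1_prof) <- names(p)
  s <- compress_profiles(u1_prof, pca)
  expect_equal(unname(s[1, 2]), 0, tolerance = 1e-10)
})

test_that("ability model recovers exact linear structure", {
  p <- rand_profiles(50, 112)
  pca <- fit_pca(p)
  s <- compress_profiles(p, pca)
  truth <- c(0.52, 0.09, 0.05)
  y <- truth[1] + truth[2] * s[, 1] + truth[3] * s[, 2]
  m <- suppressWarnings(fit_ability_model(s, y))  # exact fit
  expect_equal(c(m$intercept, m$coef_s1, m$coef_s2), truth, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
  expect_lt(m$var_error, 1e-15)
  # R^2 equals squared correlation of fitted and observed
  y2 <- y + rnorm(50, 0, 0.02)
  m2 <- fit_ability_model(s, y2)
  expect_equal(m2$r_squared, cor(fitted(m2$fit), y2)^2, tolerance = 1e-10)
})

test_that("coefficients are recovered within 3 SE under Gaussian noise", {
  set.seed(113)
  truth <- c(0.5, 0.1, 0.04)
  for (rep in 1:10) {
    p <- rand_profiles(120, 1130 + rep)
    pca <- fit_pca(p)
    s <- compress_profiles(p, pca)
    y <- truth[1] + truth[2] * s[, 1] + truth[3] * s[, 2] + rnorm(120, 0, 0.03)
    m <- fit_ability_model(s, y)
    ses <- summary(m$fit)$coefficients[, "Std. Error"]
    expect_lt(abs(m$intercept - truth[1]), 3 * ses[1] + 1e-12)
    expect_lt(abs(m$coef_s1 - truth[2]), 3 * ses[2] + 1e-12)
    expect_lt(abs(m$coef_s2 - truth[3]), 3 * ses[3] + 1e-12)
  }
})

test_that("collinear compressed predictors raise an error", {
  s <- cbind(S1 = 1:10, S2 = 2 * (1:10))
  expect_error(fit_ability_model(s, rnorm(10)), "collinear")
})

test_that("prediction is affine in each strategy-rate coordinate", {
  p <- rand_profiles(40, 114)
  pca <- fit_pca(p)
  s <- compress_profiles(p, pca)
  y <- 0.5 + 0.1 * s[, 1] + 0.04 * s[, 2]
  m <- suppressWarnings(fit_ability_model(s, y))  # exact fit
  # prediction at the training mean equals the intercept
  mean_prof <- as.data.frame(t(colMeans(as.matrix(p))))
  names(mean_prof) <- names(p)
  expect_equal(unname(predict_ica(mean_prof, pca, m)), m$intercept,
               tolerance = 1e-10)
  # noiseless linear data predicts truth
  expect_equal(unname(predict_ica(p, pca, m)), unname(y), tolerance = 1e-8)
  # finite differences in each coordinate are constant
  base <- data.frame(sr_closeness = 0.5, sr_equality = 0.5,
                     sr_accession = 0.5)
  for (col in names(base)) {
    probe <- function(delta) {
      q <- base; q[[col]] <- q[[col]] + delta
      unname(predict_ica(q, pca, m))
    }
    d1 <- probe(0.1) - probe(0)
    d2 <- probe(0.2) - probe(0.1)
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("validation reports relative errors and order-statistic percentiles", {
  v <- validate_predictions(c(0.45, 0.5), c(0.5, 0.5))
  expect_equal(unname(v$errors), c(10, 0))
  v0 <- validate_predictions(rep(0.4, 5), rep(0.4, 5))
  expect_equal(unname(v0$percentiles), c(0, 0, 0))
  set.seed(115)
  real <- runif(31, 0.2, 0.8)
  pred <- real * (1 + rnorm(31, 0, 0.1))
  v2 <- validate_predictions(pred, real)
  err <- sort(abs(real - pred) / real * 100)
  # independent sort-and-interpolate percentile oracle (type 7)
  oracle_q <- function(p) {
    hlo <- (length(err) - 1) * p
    i <- floor(hlo) + 1
    if (i >= length(err)) err[length(err)]
    else err[i] + (hlo - floor(hlo)) * (err[i + 1] - err[i])
  }
  expect_equal(unname(v2$percentiles),
               c(oracle_q(0.25), oracle_q(0.5), oracle_q(0.75)),
               tolerance = 1e-12)
  expect_warning(validate_predictions(c(0.5, 0.4), c(0.5, 0)), "zero real")
})

test_that("the profile-to-ability pipeline is invariant to player order", {
  p <- rand_profiles(45, 116)
  set.seed(117)
  y <- 0.5 + 0.1 * compress_profiles(p, fit_pca(p))[, 1] + rnorm(45, 0, 0.02)
  pca1 <- fit_pca(p); m1 <- fit_ability_model(compress_profiles(p, pca1), y)
  perm <- sample(45)
  p2 <- p[perm, ]; y2 <- y[perm]
  pca2 <- fit_pca(p2); m2 <- fit_ability_model(compress_profiles(p2, pca2), y2)
  expect_equal(pca2$components, pca1$components, tolerance = 1e-8)
  expect_equal(c(m2$intercept, m2$coef_s1, m2$coef_s2),
               c(m1$intercept, m1$coef_s1, m1$coef_s2), tolerance = 1e-8)
})

test_that("held-out error vanishes as noise goes to zero", {
  set.seed(118)
  p <- rand_profiles(80, 118)
  train <- 1:40; test <- 41:80
  pca_t <- fit_pca(p[train, ])
  s <- compress_profiles(p, pca_t)  # ability is affine in this basis
  medians <- vapply(c(0.05, 0.01, 0), function(sig) {
    y <- 0.5 + 0.1 * s[, 1] + 0.04 * s[, 2] + rnorm(80, 0, sig)
    m <- suppressWarnings(fit_ability_model(s[train, ], y[train]))
    v <- validate_predictions(predict_ica(p[test, ], pca_t, m), y[test])
    unname(v$percentiles["p50"])
  }, numeric(1))
  expect_true(all(diff(medians) <= 1e-8))
  expect_lt(medians[3], 1e-6)
})
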