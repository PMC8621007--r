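test_that("log transform maps transmittance to absorbance", {
  expect_equal(log_transform(matrix(c(1, 0.1, 0.5), 1)),
               matrix(c(0, 1, log10(2)), 1))
  expect_error(log_transform(matrix(c(0.5, -1), 1)),
               class = "nirmilk_domain_error")
})

test_that("baseline correction subtracts the per-spectrum minimum", {
  expect_equal(baseline_correct(matrix(c(2, 3, 5), 1)), matrix(c(0, 1, 3), 1))
  x <- matrix(c(0, 1, 2), 1)
  expect_equal(baseline_correct(x), x)                 # idempotent at zero-min
  set.seed(1)
  out <- baseline_correct(matrix(rnorm(50), 5))
  expect_equal(unname(apply(out, 1, min)), rep(0, 5))
})

test_that("detrend removes quadratic trends and matches the normal-equations oracle", {
  wl <- seq(1100, 1400, by = 10)
  quad <- 2 + 0.01 * wl - 1e-5 * wl^2
  expect_lt(max(abs(detrend(rbind(quad), wl))), 1e-9)
  expect_lt(max(abs(detrend(rbind(rep(3, length(wl))), wl))), 1e-12)
  set.seed(2)
  X <- matrix(rnorm(3 * length(wl)), 3)
  oracle <- t(apply(X, 1, function(x) {
    stats::residuals(stats::lm(x ~ wl + I(wl^2)))
  }))
  expect_equal(unname(detrend(X, wl)), unname(oracle), tolerance = 1e-9)
})

test_that("SNV standardizes rows and is affine invariant", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(3)
  x <- matrix(rnorm(5), 1)
  expect_equal(snv(x), (x - mean(x)) / sd(x))
  expect_equal(snv(2.5 * x + 7), snv(x))
  expect_error(snv(matrix(rep(1, 4), 1)), class = "nirmilk_degenerate_spectrum")
})

test_that("MSC inverts affine distortions and matches the regression oracle", {
  set.seed(4)
  Xcal <- random_spectra(6, 30, seed = 4)
  ref <- msc_fit(Xcal)
  expect_equal(ref, colMeans(Xcal))
  expect_equal(msc_apply(rbind(ref), ref), rbind(ref))         # a=1, b=0
  expect_equal(unname(msc_apply(rbind(2 * ref + 3), ref)), unname(rbind(ref)),
               tolerance = 1e-12)
  # slope/intercept against the closed-form simple-regression oracle
  x <- Xcal[3, ]
  a <- sum((ref - mean(ref)) * (x - mean(x))) / sum((ref - mean(ref))^2)
  b <- mean(x) - a * mean(ref)
  expect_equal(unname(msc_apply(rbind(x), ref)), rbind((x - b) / a),
               tolerance = 1e-12)
})

test_that("SNV and MSC both remove pure multiplicative/additive effects", {
  X <- random_spectra(5, 25, seed = 5)
  a <- 1.7; b <- 0.3
  expect_equal(snv(a * X + b), snv(X), tolerance = 1e-12)
  ref <- msc_fit(X)
  expect_equal(msc_apply(a * X + b, ref), msc_apply(X, ref), tolerance = 1e-9)
})

test_that("SG derivative is exact for polynomials and matches the windowed polyfit oracle", {
  n <- 40
  lin <- matrix(2 * seq_len(n), 1)
  d1 <- savgol_derivative(lin, 1, 9)
  expect_equal(unname(d1[1, ]), rep(2, n), tolerance = 1e-9)
  quad <- matrix(seq_len(n)^2, 1)
  d2 <- savgol_derivative(quad, 2, 13)
  expect_equal(unname(d2[1, ]), rep(2, n), tolerance = 1e-8)
  # brute-force oracle at interior points, window 13
  set.seed(6)
  x <- rnorm(n)
  out <- savgol_derivative(rbind(x), 1, 13)
  h <- 6
  for (i in c(7, 15, 28, 34)) {
    idx <- (i - h):(i + h)
    fit <- stats::lm(x[idx] ~ I(idx - i) + I((idx - i)^2))
    expect_equal(unname(out[1, i]), unname(coef(fit)[2]), tolerance = 1e-9)
  }
  out2 <- savgol_derivative(rbind(x), 2, 13)
  for (i in c(7, 20, 33)) {
    idx <- (i - h):(i + h)
    fit <- stats::lm(x[idx] ~ I(idx - i) + I((idx - i)^2))
    expect_equal(unname(out2[1, i]), 2 * unname(coef(fit)[3]), tolerance = 1e-9)
  }
  expect_error(savgol_derivative(rbind(x), 1, 12), class = "nirmilk_parameter_error")
  expect_error(savgol_derivative(rbind(x), 1, 1), class = "nirmilk_parameter_error")
  expect_error(savgol_derivative(rbind(x), 3, 13), class = "nirmilk_parameter_error")
})

test_that("OSC scores are uncorrelated with y and match a literal Wold transcription", {
  set.seed(7)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- rnorm(6)
  st <- osc_fit(X, y, n_comp = 1)
  expect_lt(abs(cor(st$scores[[1]], y)), 1e-6)
  # zero components: identity
  st0 <- osc_fit(X, y, n_comp = 0)
  expect_equal(osc_apply(X, st0), X)
  # literal step-by-step Wold reference (MASS::ginv pseudo-inverse per
  # iteration), run once on the toy matrix
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  sv <- svd(Xc)
  t_sc <- sv$u[, 1] * sv$d[1]
  w <- NULL
  for (it in 1:500) {
    t_orth <- t_sc - yc * sum(yc * t_sc) / sum(yc^2)
    w_new <- drop(MASS::ginv(Xc) %*% t_orth)
    w_new <- w_new / sqrt(sum(w_new^2))
    t_sc <- drop(Xc %*% w_new)
    if (!is.null(w) && sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; break }
    w <- w_new
  }
  t_sc <- t_sc - yc * sum(yc * t_sc) / sum(yc^2)
  p_load <- drop(crossprod(Xc, t_sc)) / sum(t_sc^2)
  X_ref <- Xc - tcrossprod(t_sc, p_load)
  deflated <- osc_apply(X, st)
  expect_equal(unname(sweep(deflated, 2, colMeans(X))), unname(X_ref),
               tolerance = 1e-8)
})

test_that("mean centering uses calibration state only", {
  set.seed(8)
  Xcal <- matrix(rnorm(40), 8, 5)
  mu <- mean_center_fit(Xcal)
  centered <- mean_center_apply(Xcal, mu)
  expect_lt(max(abs(colMeans(centered))), 1e-12)
  expect_equal(unname(mean_center_apply(rbind(mu), mu)), rbind(rep(0, 5)))
  Xnew <- matrix(rnorm(10), 2, 5)
  expect_equal(mean_center_apply(Xnew, mu), sweep(Xnew, 2, mu))
  expect_error(mean_center_apply(Xnew[, 1:3], mu))
})
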