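make_folds_1per <- function(n, k = 5, seed = 1) {
  make_cv_folds(as.character(seq_len(n)), k = k, seed = seed)
}

test_that("VIP retains everything for exchangeable identical columns", {
  set.seed(60)
  x <- rnorm(40)
  X <- cbind(x, x, x, x)
  y <- 2 * x + rnorm(40, 0, 0.1)
  folds <- make_folds_1per(40)
  cfg <- selection_config(max_latent = 1)
  s <- vip_select(X, y, folds, cfg)
  expect_equal(s$diagnostics$vip, rep(1, 4), tolerance = 1e-10)
  expect_equal(s$n_retained, 4L)
})

test_that("VIP keeps informative wavelengths and threshold 0 keeps all", {
  set.seed(61)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- 3 * X[, 4] + rnorm(50, 0, 0.2)
  folds <- make_folds_1per(50)
  s <- vip_select(X, y, folds, selection_config(max_latent = 3))
  expect_true(4 %in% s$indices)
  expect_lt(s$n_retained, 10)
  s0 <- vip_select(X, y, folds, selection_config(max_latent = 3,
                                                 vip_threshold = 0))
  expect_equal(s0$n_retained, 10L)
})

test_that("jack-knife keeps a strong stable wavelength and treats duplicates alike", {
  set.seed(62)
  X <- matrix(rnorm(60 * 8), 60, 8)
  X[, 7] <- X[, 2]                               # exact duplicate
  y <- 4 * X[, 2] + rnorm(60, 0, 0.3)
  folds <- make_folds_1per(60, k = 10)
  s <- jackknife_select(X, y, folds, selection_config(max_latent = 3))
  expect_true(all(c(2, 7) %in% s$indices))
  expect_equal(2 %in% s$diagnostics$significant, 7 %in% s$diagnostics$significant)
  expect_equal(s$diagnostics$t[2], s$diagnostics$t[7], tolerance = 1e-8)
})

test_that("jack-knife retention under the null matches its nominal level", {
  set.seed(42)
  rates <- replicate(200, {
    n <- 60
    X <- matrix(rnorm(n * 12), n, 12)
    y <- rnorm(n)
    folds <- make_cv_folds(as.character(1:n), k = 10, seed = sample.int(1e6, 1))
    cfg <- selection_config(max_latent = 3, jk_alpha = 0.05)
    s <- suppressWarnings(jackknife_select(X, y, folds, cfg))
    length(s$diagnostics$significant) / 12
  })
  # 99% binomial band around 5% with 200 x 12 decisions
  half_width <- 2.576 * sqrt(0.05 * 0.95 / (200 * 12))
  expect_gt(mean(rates), 0.05 - half_width)
  expect_lt(mean(rates), 0.05 + half_width)
})

test_that("a single configured interval is returned by both iPLS directions", {
  set.seed(63)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(X %*% rnorm(10)) + rnorm(30, 0, 0.2)
  folds <- make_folds_1per(30)
  cfg <- selection_config(max_latent = 3, n_intervals = 1)
  r <- ripls(X, y, folds, cfg)
  f <- fipls(X, y, folds, cfg)
  expect_equal(r$indices, 1:10)
  expect_equal(f$indices, 1:10)
  expect_error(ripls(X, y, folds, selection_config(n_intervals = 11)),
               class = "nirmilk_parameter_error")
})

test_that("forward iPLS first adds the interval that carries the signal", {
  set.seed(64)
  X <- matrix(rnorm(60 * 20), 60, 20)
  y <- drop(X[, 9:12] %*% c(1, 2, 1.5, 1)) + rnorm(60, 0, 0.2)  # interval 3 of 5
  folds <- make_folds_1per(60)
  cfg <- selection_config(max_latent = 4, n_intervals = 5)
  f <- fipls(X, y, folds, cfg)
  expect_equal(f$diagnostics$order_added[1], 3L)
  expect_true(3 %in% f$diagnostics$selected_intervals)
  # retained sets are unions of contiguous intervals
  spans <- subset_spans(f, seq(1000, 1190, by = 10))
  expect_true(all(spans$n_wavelengths >= 4))
})

test_that("backward iPLS never ends worse than the full model", {
  set.seed(65)
  X <- matrix(rnorm(40 * 16), 40, 16)
  y <- drop(X[, 5:8] %*% rep(1, 4)) + rnorm(40, 0, 0.5)
  folds <- make_folds_1per(40)
  cfg <- selection_config(max_latent = 3, n_intervals = 4)
  out <- select_wavelengths(X, y, folds, cfg)
  rep_tbl <- out$report
  expect_lte(rep_tbl$rmsecv[rep_tbl$method == "RiPLS"],
             rep_tbl$rmsecv[rep_tbl$method == "FULL"] + 1e-12)
  expect_setequal(rep_tbl$method, c("FULL", "VIP", "JK", "RiPLS", "FiPLS"))
})

mock_subset <- function(method, n_retained, n_latent, residuals) {
  structure(list(method = method, indices = seq_len(n_retained),
                 n_retained = n_retained, p_total = 100,
                 n_latent = n_latent, rmsecv = sqrt(mean(residuals^2)),
                 r2cv = NA_real_, residuals = residuals),
            class = "wavelength_subset")
}

test_that("selection choice prefers the smallest equivalent wavelength set", {
  r <- c(0.2, -0.1, 0.15, -0.05, 0.1, -0.2, 0.12, -0.08)
  cands <- list(mock_subset("FULL", 100, 3, r),
                mock_subset("VIP", 40, 3, r),
                mock_subset("RiPLS", 25, 4, r))
  out <- choose_selection(cands)
  expect_equal(out$chosen$method, "RiPLS")       # identical residuals: fewest WLs
  # dominant FULL wins outright
  cands2 <- list(mock_subset("FULL", 100, 3, r / 10),
                 mock_subset("VIP", 40, 3, r))
  expect_equal(choose_selection(cands2)$chosen$method, "FULL")
})

test_that("the three-candidate fixture matches the manual paired-t oracle", {
  b <- c(0.10, 0.12, 0.09, 0.11, 0.10, 0.13, 0.08, 0.12, 0.10, 0.11, 0.09, 0.10)
  rBest <- b
  rOK <- b + rep(c(0.02, 0.01, -0.02, -0.01), 3)
  rBad <- b + 0.06 + rep(c(0.01, -0.01), 6)
  cands <- list(mock_subset("FULL", 100, 5, rBest),
                mock_subset("FiPLS", 30, 3, rOK),
                mock_subset("JK", 10, 2, rBad))
  pOK <- manual_paired_p(abs(rOK), abs(rBest))
  pBad <- manual_paired_p(abs(rBad), abs(rBest))
  expect_gt(pOK, 0.05)
  expect_lt(pBad, 0.05)
  out <- choose_selection(cands)
  expect_equal(out$chosen$method, "FiPLS")       # smallest not-worse candidate
  expect_equal(out$report$p_vs_best[out$report$method == "JK"], pBad,
               tolerance = 1e-8)
})
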