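test_that("48 cows deal into 10 folds of four to five cows each", {
  cow_ids <- rep(sprintf("c%02d", 1:48), each = 3)
  folds <- make_cv_folds(cow_ids, k = 10, seed = 5)
  per_fold <- tapply(folds$cow_id, folds$fold, dplyr::n_distinct)
  expect_equal(as.vector(sort(per_fold)), c(4, 4, 5, 5, 5, 5, 5, 5, 5, 5))
  # every cow in exactly one fold; folds partition all samples
  expect_true(all(tapply(folds$fold, folds$cow_id,
                         function(f) length(unique(f))) == 1))
  expect_equal(sort(folds$sample), seq_along(cow_ids))
  expect_identical(make_cv_folds(cow_ids, k = 10, seed = 5), folds)
  expect_error(make_cv_folds(c("a", "b"), k = 10), "at least k")
})

test_that("cross-validated error on pure noise stays near the response SD", {
  set.seed(50)
  X <- abs(random_spectra(60, 40, seed = 51)) + 0.2
  y <- rnorm(60)
  folds <- make_cv_folds(as.character(rep(1:20, each = 3)), k = 10, seed = 1)
  for (lab in c("Raw|No|No|No|MNCN", "Log|SNV|No|OSC|MNCN")) {
    cv <- cross_validate(lab, X, y, folds, max_latent = 6)
    expect_true(all(cv$rmsecv > 0.8 * sd(y)))
  }
})

test_that("RMSECV bookkeeping is exact", {
  sim <- tiny_sim(n_cows = 12, samples_per_cow = 3, seed = 52)
  y <- sim$composition$fat_pct
  folds <- make_cv_folds(sim$composition$cow_id, k = 4, seed = 2)
  cv <- cross_validate("Log|No|No|No|MNCN", sim$dataset$intensities, y, folds,
                       max_latent = 5)
  expect_false(anyNA(cv$pred))                       # each sample predicted once
  expect_equal(cv$rmsecv^2 * length(y), colSums(cv$residuals^2),
               tolerance = 1e-12)
  expect_equal(cv$residuals, y - cv$pred)
})

test_that("reassigning a cow to another fold leaves untouched folds unchanged", {
  sim <- tiny_sim(n_cows = 12, samples_per_cow = 3, seed = 53)
  y <- sim$composition$fat_pct
  f1 <- make_cv_folds(sim$composition$cow_id, k = 4, seed = 2)
  f2 <- f1
  moved_cow <- f1$cow_id[1]
  from <- f1$fold[1]
  to <- setdiff(1:4, from)[1]
  f2$fold[f2$cow_id == moved_cow] <- to
  cv1 <- cross_validate("Raw|No|No|No|MNCN", sim$dataset$intensities, y, f1, 4)
  cv2 <- cross_validate("Raw|No|No|No|MNCN", sim$dataset$intensities, y, f2, 4)
  untouched <- !f1$fold %in% c(from, to)
  expect_equal(cv1$pred[untouched, ], cv2$pred[untouched, ])
  expect_false(isTRUE(all.equal(cv1$pred, cv2$pred)))
})

test_that("latent-count parsimony follows the one-sided paired t-test", {
  # 12-sample fixture: A=3 lowest RMSECV, A=2 statistically indistinguishable,
  # A=1 uniformly worse by ~0.05
  b <- c(0.10, 0.12, 0.09, 0.11, 0.10, 0.13, 0.08, 0.12, 0.10, 0.11, 0.09, 0.10)
  d2 <- rep(c(0.02, 0.01, -0.02, -0.01), 3)
  d1 <- rep(c(0.01, -0.01), 6)
  R <- cbind(b + 0.05 + d1, b + d2, b)
  cv <- mock_cv(R)
  expect_equal(unname(which.min(cv$rmsecv)), 3L)
  # manual oracle p-values
  p1 <- manual_paired_p(abs(R[, 1]), abs(R[, 3]))
  p2 <- manual_paired_p(abs(R[, 2]), abs(R[, 3]))
  expect_lt(p1, 0.05)
  expect_gt(p2, 0.05)
  sel <- select_n_latent(cv, alpha = 0.05)
  expect_equal(sel$n_latent, 2L)
  expect_equal(sel$a_min, 3L)
  expect_equal(unname(sel$p_values[1:2]), c(p1, p2), tolerance = 1e-8)
})

test_that("latent selection never exceeds the RMSECV argmin and handles ties", {
  r <- c(0.2, -0.1, 0.15, -0.05, 0.1)
  cv <- mock_cv(cbind(r, r, r))
  expect_equal(select_n_latent(cv)$n_latent, 1L)     # identical residuals
  cv1 <- mock_cv(cbind(r))
  expect_equal(select_n_latent(cv1)$n_latent, 1L)    # single candidate
  set.seed(54)
  for (i in 1:5) {
    R <- matrix(rnorm(60), 12, 5)
    sel <- select_n_latent(mock_cv(R))
    expect_lte(sel$n_latent, sel$a_min)
  }
})

mock_grid <- function(labels, n_latent, residual_cols) {
  tibble::tibble(
    label = labels,
    n_latent = as.integer(n_latent),
    has_osc = grepl("OSC", labels),
    rmsecv = apply(residual_cols, 2, function(r) sqrt(mean(r^2))),
    r2cv = NA_real_,
    residuals = lapply(seq_len(ncol(residual_cols)), function(i) residual_cols[, i]),
    effective_latent = as.integer(n_latent) + as.integer(grepl("OSC", labels))
  )
}

test_that("chain parsimony prefers fewest latent variables among equivalent chains", {
  r <- c(0.2, -0.1, 0.15, -0.05, 0.1, -0.2, 0.12, -0.08)
  g <- mock_grid(c("Log|SNV|No|No|MNCN", "Log|Base|No|No|MNCN",
                   "Raw|No|No|No|MNCN"),
                 c(4, 2, 2), cbind(r, r, r))
  sel <- select_chain(g)
  # identical residuals: fewest latent variables, then lexicographic label
  expect_equal(sel$label, "Log|Base|No|No|MNCN")
  expect_equal(sel$n_latent, 2L)
})

test_that("a strictly dominant chain is always selected", {
  set.seed(55)
  r_bad <- rnorm(10, 0, 1)
  r_good <- r_bad / 10
  g <- mock_grid(c("Log|SNV|No|No|MNCN", "Raw|No|No|No|MNCN"),
                 c(1, 5), cbind(r_bad, r_good))
  expect_equal(select_chain(g)$label, "Raw|No|No|No|MNCN")
})

test_that("the three-chain fixture matches the manual t-test oracle", {
  b <- c(0.10, 0.12, 0.09, 0.11, 0.10, 0.13, 0.08, 0.12, 0.10, 0.11, 0.09, 0.10)
  rA <- b                                   # best RMSECV, 6 latent variables
  rB <- b + rep(c(0.02, 0.01, -0.02, -0.01), 3)   # indistinguishable, 2 LVs
  rC <- b + 0.06 + rep(c(0.01, -0.01), 6)         # significantly worse, 1 LV
  g <- mock_grid(c("Log|No|No|No|MNCN", "Log|SNV|No|No|MNCN", "Raw|No|No|No|MNCN"),
                 c(6, 2, 1), cbind(rA, rB, rC))
  pB <- manual_paired_p(abs(rB), abs(rA))
  pC <- manual_paired_p(abs(rC), abs(rA))
  expect_gt(pB, 0.05)
  expect_lt(pC, 0.05)
  sel <- select_chain(g)
  expect_equal(sel$label, "Log|SNV|No|No|MNCN")
  rank <- sel$ranking
  expect_equal(rank$p_vs_best[rank$label == "Raw|No|No|No|MNCN"], pC,
               tolerance = 1e-8)
})

test_that("the OSC preprocessing component is reported but not counted", {
  r <- c(0.2, -0.1, 0.15, -0.05, 0.1, -0.2)
  g <- mock_grid(c("Log|No|No|OSC|MNCN", "Log|No|No|No|MNCN"),
                 c(2, 2), cbind(r, r))
  expect_equal(g$effective_latent, c(3L, 2L))
  sel <- select_chain(g)
  expect_equal(sel$n_latent, 2L)            # parsimony count excludes OSC
  expect_equal(sel$label, "Log|No|No|No|MNCN")  # label tie-break
})
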