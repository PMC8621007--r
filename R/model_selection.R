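#' Selection configuration
#'
#' Parameters of the parsimony selections: significance level of the
#' one-sided paired t-tests on cross-validated absolute residuals, the
#' latent-variable ceiling, the VIP retention threshold, the interval count
#' of the interval-PLS searches and the jack-knife significance level.
#'
#' @param alpha significance level of the parsimony t-tests (default 0.05).
#' @param max_latent latent-variable ceiling (default 20).
#' @param vip_threshold retain wavelengths with VIP at or above this value
#'   (default 1, the greater-than-average-importance rule).
#' @param n_intervals contiguous intervals for RiPLS/FiPLS (default 20; the
#'   last interval absorbs the remainder).
#' @param jk_alpha jack-knife coefficient-significance level (default 0.05).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, max_latent = 20, vip_threshold = 1,
                             n_intervals = 20, jk_alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, is_count(max_latent))
  structure(list(alpha = alpha, max_latent = as.integer(max_latent),
                 vip_threshold = vip_threshold,
                 n_intervals = as.integer(n_intervals), jk_alpha = jk_alpha),
            class = "selection_config")
}

#' Cow-blocked cross-validation folds
#'
#' Cows are shuffled deterministically by the seed and dealt round-robin
#' into `k` folds, so fold cow-counts differ by at most one and every cow's
#' samples share one fold.
#'
#' @param cow_ids per-sample cow identifiers.
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return object of class `cv_folds`: tibble with `sample` (row index),
#'   `cow_id`, `fold`, plus attributes `k` and `seed`.
#' @export
make_cv_folds <- function(cow_ids, k = 10, seed = 1L) {
  cow_ids <- as.character(cow_ids)
  cows <- unique(cow_ids)
  if (length(cows) < k) {
    stopf("need at least k = %d cows, got %d", k, length(cows))
  }
  shuffled <- with_rng(seed, sample(cows))
  fold_of_cow <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  out <- tibble::tibble(
    sample = seq_along(cow_ids),
    cow_id = cow_ids,
    fold = unname(fold_of_cow[cow_ids])
  )
  structure(out, k = as.integer(k), seed = as.integer(seed),
            class = c("cv_folds", class(out)))
}

#' Cow-blocked cross-validation of a preprocessing chain + PLSR
#'
#' For every fold, the full preprocessing chain and the PLSR factorization
#' are refitted on the remaining folds only, and out-of-fold predictions are
#' assembled for every latent-variable count 1..`max_latent`.  If a training
#' split supports fewer components than requested (rank or sample limit),
#' predictions for the unreachable counts repeat the largest reachable
#' sub-model.
#'
#' @param chain chain label (see [chains]).
#' @param X raw calibration spectra (n x p, unprocessed).
#' @param y calibration response.
#' @param folds a [make_cv_folds()] result aligned with rows of `X`.
#' @param max_latent latent-variable ceiling.
#' @param wavelengths wavelength axis for the detrend step.
#' @return object of class `cv_result`: list with `pred` (n x A matrix of
#'   out-of-fold predictions), `residuals`, `rmsecv` and `r2cv` (length-A
#'   vectors), `y`, `chain`, `folds`.
#' @export
cross_validate <- function(chain, X, y, folds, max_latent = 20,
                           wavelengths = NULL) {
  X <- as_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  stopifnot(length(y) == n, nrow(folds) == n)
  A <- as.integer(max_latent)
  pred <- matrix(NA_real_, n, A)
  for (f in sort(unique(folds$fold))) {
    test <- folds$fold == f
    if (!any(test)) stopf("fold %d has no test samples", f, class = "nirmilk_fold_error")
    train <- !test
    proc <- apply_chain(chain, X[train, , drop = FALSE], y[train],
                        X[test, , drop = FALSE], wavelengths)
    A_f <- min(A, sum(train) - 1L, ncol(proc$X_cal))
    m <- fit_plsr(proc$X_cal, y[train], A_f, strict = FALSE)
    pf <- predict(m, proc$X_new, all_components = TRUE)
    if (A_f < A) pf <- cbind(pf, matrix(pf[, A_f], sum(test), A - A_f))
    pred[test, ] <- pf
  }
  residuals <- y - pred
  rmsecv <- sqrt(colMeans(residuals^2))
  sst <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums(residuals^2) / sst
  structure(list(pred = pred, residuals = residuals, rmsecv = rmsecv,
                 r2cv = r2cv, y = y, chain = chain, folds = folds,
                 max_latent = A),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  a <- which.min(x$rmsecv)
  cat(sprintf("<cv_result> chain %s, A = 1..%d; min RMSECV %.4g at A = %d\n",
              x$chain, x$max_latent, x$rmsecv[a], a))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x a `cv_result`.
#' @param ... unused.
#' @return tibble with `n_latent`, `rmsecv`, `r2cv`.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(n_latent = seq_len(x$max_latent), rmsecv = x$rmsecv,
                 r2cv = x$r2cv)
}

# One-sided paired t-test p-value for "candidate absolute residuals are
# greater than the best model's".  A zero-variance difference vector is
# decided by its sign: identical performance -> p = 1, uniformly worse by a
# constant -> p = 0.
parsimony_p_value <- function(abs_res_candidate, abs_res_best) {
  d <- abs_res_candidate - abs_res_best
  if (stats::sd(d) == 0) {
    return(if (mean(d) > 0) 0 else 1)
  }
  stats::t.test(abs_res_candidate, abs_res_best, paired = TRUE,
                alternative = "greater")$p.value
}

#' Select the number of latent variables parsimoniously
#'
#' Finds the latent count with the lowest RMSECV, then returns the smallest
#' count whose cross-validated absolute residuals are not significantly
#' greater (one-sided paired t-test at `alpha`).
#'
#' @param cv a [cross_validate()] result.
#' @param alpha significance level (default 0.05).
#' @return list: `n_latent` (the chosen A), `a_min` (the RMSECV argmin),
#'   `p_values` (vs the argmin, for A = 1..argmin).
#' @export
select_n_latent <- function(cv, alpha = 0.05) {
  stopifnot(inherits(cv, "cv_result"))
  a_min <- which.min(cv$rmsecv)
  abs_best <- abs(cv$residuals[, a_min])
  p <- vapply(seq_len(a_min), function(a) {
    parsimony_p_value(abs(cv$residuals[, a]), abs_best)
  }, numeric(1))
  chosen <- which(p > alpha)[1]
  if (is.na(chosen)) chosen <- a_min    # a_min itself always qualifies (p = 1)
  list(n_latent = as.integer(chosen), a_min = as.integer(a_min), p_values = p)
}

#' Cross-validate a set of preprocessing chains
#'
#' Runs [cross_validate()] for every chain label (in deterministic label
#' order as given) and applies the latent-count parsimony selection to each.
#'
#' @param chains character vector of chain labels (e.g.
#'   `enumerate_chains()$label` or [fast_chains()]).
#' @inheritParams cross_validate
#' @param alpha parsimony significance level.
#' @return tibble (class `chain_grid`) with one row per chain: `label`,
#'   `n_latent` (selected), `has_osc`, `effective_latent` (selected +
#'   1 if the chain includes OSC; reporting only), `rmsecv`, `r2cv` at the
#'   selected count, and `residuals` (list column of out-of-fold residual
#'   vectors at the selected count).
#' @export
run_chain_grid <- function(chains, X, y, folds, max_latent = 20, alpha = 0.05,
                           wavelengths = NULL) {
  rows <- purrr::map(chains, function(lab) {
    cv <- cross_validate(lab, X, y, folds, max_latent, wavelengths)
    sel <- select_n_latent(cv, alpha)
    a <- sel$n_latent
    tibble::tibble(
      label = lab,
      n_latent = a,
      has_osc = parse_chain(lab)$step4 == "OSC",
      rmsecv = cv$rmsecv[a],
      r2cv = cv$r2cv[a],
      residuals = list(cv$residuals[, a])
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(effective_latent = .data$n_latent + as.integer(.data$has_osc))
  class(out) <- c("chain_grid", class(out))
  out
}

#' Select the preprocessing chain parsimoniously
#'
#' Chains are ranked by RMSECV at their own selected latent count; the
#' candidate set contains every chain whose absolute residuals are not
#' significantly worse (one-sided paired t-test at `alpha`) than the
#' lowest-RMSECV chain's.  Among candidates the chain with the fewest latent
#' variables wins (the OSC preprocessing component is not counted); ties
#' break by lower RMSECV, then lexicographically smaller label.
#'
#' @param grid a [run_chain_grid()] tibble.
#' @param alpha significance level.
#' @return list: `label`, `n_latent`, `rmsecv`, and `ranking` (the grid with
#'   `p_vs_best` and `candidate` columns, ranked by RMSECV).
#' @export
select_chain <- function(grid, alpha = 0.05) {
  stopifnot(nrow(grid) >= 1)
  best <- which.min(grid$rmsecv)
  abs_best <- abs(grid$residuals[[best]])
  ranking <- grid |>
    dplyr::mutate(
      p_vs_best = purrr::map_dbl(.data$residuals,
                                 ~ parsimony_p_value(abs(.x), abs_best)),
      candidate = .data$p_vs_best > alpha | dplyr::row_number() == best
    ) |>
    dplyr::arrange(.data$rmsecv, .data$label)
  pick <- ranking |>
    dplyr::filter(.data$candidate) |>
    dplyr::arrange(.data$n_latent, .data$rmsecv, .data$label) |>
    dplyr::slice(1)
  list(label = pick$label, n_latent = pick$n_latent, rmsecv = pick$rmsecv,
       ranking = dplyr::select(ranking, -"residuals"))
}
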