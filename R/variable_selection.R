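#' Wavelength selection methods
#'
#' Four selectors operate on the chain-preprocessed spectra: VIP thresholding,
#' Martens-style jack-knife coefficient testing, and the two greedy interval
#' searches (RiPLS backward, FiPLS forward).  The preprocessing chain is
#' refitted per CV fold on the full wavelength grid; candidate subsets then
#' index columns of the processed matrices, so no fitted state ever sees
#' validation data and interval candidates remain contiguous on the
#' instrument grid.
#'
#' @name variable_selection
NULL

# Per-fold chain-processed matrices, computed once and reused across all
# candidate subsets (the chain state depends only on the training fold, not
# on the subset).
fold_processed <- function(chain, X, y, folds, wavelengths = NULL) {
  lapply(sort(unique(folds$fold)), function(f) {
    test <- folds$fold == f
    proc <- apply_chain(chain, X[!test, , drop = FALSE], y[!test],
                        X[test, , drop = FALSE], wavelengths)
    list(test = which(test), train = which(!test),
         X_train = proc$X_cal, X_test = proc$X_new)
  })
}

# Cross-validation restricted to a column subset of pre-processed folds;
# returns a cv_result-compatible object.
cv_on_subset <- function(fp, y, idx, max_latent) {
  n <- length(y)
  A <- as.integer(max_latent)
  pred <- matrix(NA_real_, n, A)
  for (fold in fp) {
    Xtr <- fold$X_train[, idx, drop = FALSE]
    Xte <- fold$X_test[, idx, drop = FALSE]
    A_f <- min(A, nrow(Xtr) - 1L, ncol(Xtr))
    m <- fit_plsr(Xtr, y[fold$train], A_f, strict = FALSE)
    pf <- predict(m, Xte, all_components = TRUE)
    if (A_f < A) pf <- cbind(pf, matrix(pf[, A_f], length(fold$test), A - A_f))
    pred[fold$test, ] <- pf
  }
  residuals <- y - pred
  structure(list(pred = pred, residuals = residuals,
                 rmsecv = sqrt(colMeans(residuals^2)),
                 r2cv = 1 - colSums(residuals^2) / sum((y - mean(y))^2),
                 y = y, chain = "subset", folds = NULL, max_latent = A),
            class = "cv_result")
}

# package a selector outcome, running the subset CV + latent selection
subset_result <- function(method, idx, p_total, fp, y, cfg, diagnostics = NULL) {
  idx <- sort(unique(as.integer(idx)))
  cv <- cv_on_subset(fp, y, idx, min(cfg$max_latent, length(idx),
                                     length(y) - 1L))
  sel <- select_n_latent(cv, cfg$alpha)
  structure(
    list(method = method, indices = idx, n_retained = length(idx),
         p_total = p_total, n_latent = sel$n_latent,
         rmsecv = cv$rmsecv[sel$n_latent],
         r2cv = cv$r2cv[sel$n_latent],
         residuals = cv$residuals[, sel$n_latent],
         diagnostics = diagnostics),
    class = "wavelength_subset"
  )
}

#' @export
print.wavelength_subset <- function(x, ...) {
  cat(sprintf("<wavelength_subset> %s: %d/%d wavelengths, A = %d, RMSECV = %.4g\n",
              x$method, x$n_retained, x$p_total, x$n_latent, x$rmsecv))
  invisible(x)
}

#' VIP wavelength selection
#'
#' Fits the full-spectrum model (chain + PLSR at the parsimonious latent
#' count) on all calibration samples, retains wavelengths with VIP at or
#' above `cfg$vip_threshold`, and re-cross-validates the subset.  An empty
#' retained set falls back to the single highest-VIP wavelength with a
#' warning.
#'
#' @param X raw calibration spectra.
#' @param y calibration response.
#' @param folds a [make_cv_folds()] result.
#' @param cfg a [selection_config()].
#' @param chain chain label applied upstream (default: mean centering only).
#' @param wavelengths wavelength axis for the detrend step.
#' @return a `wavelength_subset`.
#' @export
vip_select <- function(X, y, folds, cfg = selection_config(),
                       chain = "Raw|No|No|No|MNCN", wavelengths = NULL) {
  X <- as_matrix(X)
  fp <- fold_processed(chain, X, y, folds, wavelengths)
  full_cv <- cv_on_subset(fp, y, seq_len(ncol(X)), min(cfg$max_latent,
                                                       ncol(X), length(y) - 1L))
  a <- select_n_latent(full_cv, cfg$alpha)$n_latent
  proc <- apply_chain(chain, X, y, wavelengths = wavelengths)
  model <- fit_plsr(proc$X_cal, y, a)
  vip <- vip_scores(model)
  keep <- which(vip >= cfg$vip_threshold)
  if (length(keep) == 0) {
    warn("VIP selection retained no wavelength; falling back to the top-1")
    keep <- which.max(vip)
  }
  subset_result("VIP", keep, ncol(X), fp, y, cfg,
                diagnostics = list(vip = vip, threshold = cfg$vip_threshold,
                                   full_n_latent = a))
}

#' Jack-knife wavelength selection
#'
#' Martens-style uncertainty test: the regression coefficient vector is
#' re-estimated on each of the k leave-fold-out training sets; each
#' coefficient's variance across segments (relative to the all-data
#' coefficient) gives a t-statistic with k - 1 degrees of freedom, and
#' wavelengths significant at `cfg$jk_alpha` are retained.  A coefficient
#' with zero segment variance is retained iff it is nonzero.
#'
#' @inheritParams vip_select
#' @return a `wavelength_subset`.
#' @export
jackknife_select <- function(X, y, folds, cfg = selection_config(),
                             chain = "Raw|No|No|No|MNCN", wavelengths = NULL) {
  X <- as_matrix(X)
  fp <- fold_processed(chain, X, y, folds, wavelengths)
  full_cv <- cv_on_subset(fp, y, seq_len(ncol(X)), min(cfg$max_latent,
                                                       ncol(X), length(y) - 1L))
  a <- select_n_latent(full_cv, cfg$alpha)$n_latent
  proc <- apply_chain(chain, X, y, wavelengths = wavelengths)
  b_full <- fit_plsr(proc$X_cal, y, a)$coefficients
  g <- length(fp)
  B <- vapply(fp, function(fold) {
    A_f <- min(a, nrow(fold$X_train) - 1L, ncol(fold$X_train))
    fit_plsr(fold$X_train, y[fold$train], A_f, strict = FALSE)$coefficients
  }, numeric(ncol(X)))
  s2 <- rowSums((B - b_full)^2) * (g - 1) / g
  se <- sqrt(s2)
  t_stat <- ifelse(se > 0, abs(b_full) / se, Inf)
  p_val <- 2 * stats::pt(-t_stat, df = g - 1)
  significant <- which(ifelse(se > 0, p_val <= cfg$jk_alpha, b_full != 0))
  keep <- significant
  if (length(keep) == 0) {
    warn("jack-knife retained no wavelength; falling back to the top-1")
    keep <- which.max(abs(t_stat))
  }
  subset_result("JK", keep, ncol(X), fp, y, cfg,
                diagnostics = list(t = t_stat, p = p_val, df = g - 1,
                                   significant = significant,
                                   full_n_latent = a))
}

# contiguous interval map: list of index vectors; the last interval absorbs
# the remainder
make_intervals <- function(p, n_intervals) {
  if (n_intervals > p) {
    stopf("n_intervals (%d) exceeds the number of wavelengths (%d)",
          n_intervals, p, class = "nirmilk_parameter_error")
  }
  size <- p %/% n_intervals
  starts <- (seq_len(n_intervals) - 1L) * size + 1L
  ends <- c(starts[-1L] - 1L, p)
  purrr::map2(starts, ends, seq)
}

ipls_rmsecv <- function(fp, y, idx, cfg) {
  A <- min(cfg$max_latent, length(idx), length(y) - 1L)
  cv <- cv_on_subset(fp, y, idx, A)
  sel <- select_n_latent(cv, cfg$alpha)
  list(rmsecv = cv$rmsecv[sel$n_latent], n_latent = sel$n_latent)
}

#' Interval PLS wavelength selection
#'
#' The wavelength grid is divided into `cfg$n_intervals` contiguous
#' intervals.  `ripls()` starts from all intervals and greedily removes the
#' interval whose removal most lowers the cross-validated RMSECV (each
#' candidate re-selects its own latent count), stopping when no removal
#' lowers it; `fipls()` starts empty and greedily adds the most improving
#' interval.  Ties break to the lowest interval index, so the search is
#' deterministic.
#'
#' @inheritParams vip_select
#' @return a `wavelength_subset` whose retained set is a union of contiguous
#'   intervals (`diagnostics$intervals` maps interval id to indices,
#'   `diagnostics$selected_intervals` lists the retained ids).
#' @export
ripls <- function(X, y, folds, cfg = selection_config(),
                  chain = "Raw|No|No|No|MNCN", wavelengths = NULL) {
  X <- as_matrix(X)
  fp <- fold_processed(chain, X, y, folds, wavelengths)
  intervals <- make_intervals(ncol(X), cfg$n_intervals)
  current <- seq_along(intervals)
  cur <- ipls_rmsecv(fp, y, unlist(intervals[current]), cfg)
  repeat {
    if (length(current) == 1) break
    cand <- purrr::map(current, function(drop_id) {
      keep <- setdiff(current, drop_id)
      ipls_rmsecv(fp, y, unlist(intervals[keep]), cfg)
    })
    rms <- purrr::map_dbl(cand, "rmsecv")
    best <- which.min(rms)                 # lowest interval index on ties
    if (rms[best] < cur$rmsecv) {
      current <- setdiff(current, current[best])
      cur <- cand[[best]]
    } else break
  }
  subset_result("RiPLS", unlist(intervals[current]), ncol(X), fp, y, cfg,
                diagnostics = list(intervals = intervals,
                                   selected_intervals = current))
}

#' @rdname ripls
#' @export
fipls <- function(X, y, folds, cfg = selection_config(),
                  chain = "Raw|No|No|No|MNCN", wavelengths = NULL) {
  X <- as_matrix(X)
  fp <- fold_processed(chain, X, y, folds, wavelengths)
  intervals <- make_intervals(ncol(X), cfg$n_intervals)
  current <- integer(0)
  order_added <- integer(0)
  cur_rmsecv <- Inf
  repeat {
    pool <- setdiff(seq_along(intervals), current)
    if (length(pool) == 0) break
    cand <- purrr::map(pool, function(add_id) {
      ipls_rmsecv(fp, y, unlist(intervals[c(current, add_id)]), cfg)
    })
    rms <- purrr::map_dbl(cand, "rmsecv")
    best <- which.min(rms)
    if (rms[best] < cur_rmsecv) {
      current <- sort(c(current, pool[best]))
      order_added <- c(order_added, pool[best])
      cur_rmsecv <- rms[best]
    } else break
  }
  subset_result("FiPLS", unlist(intervals[current]), ncol(X), fp, y, cfg,
                diagnostics = list(intervals = intervals,
                                   selected_intervals = current,
                                   order_added = order_added))
}

#' Choose among wavelength-selection candidates
#'
#' Candidates (the four selectors plus the full-spectrum model, all
#' cross-validated on identical folds) are compared with the lowest-RMSECV
#' candidate by one-sided paired t-tests on absolute residuals; among those
#' not significantly worse, the fewest retained wavelengths wins, ties by
#' fewer latent variables, then lower RMSECV.
#'
#' @param candidates list of `wavelength_subset` objects.
#' @param alpha significance level.
#' @return list: `chosen` (the winning `wavelength_subset`) and `report`
#'   (tibble: method, retained count, latent count, RMSECV, p vs best,
#'   candidate flag).
#' @export
choose_selection <- function(candidates, alpha = 0.05) {
  stopifnot(length(candidates) >= 1)
  rms <- purrr::map_dbl(candidates, "rmsecv")
  best <- which.min(rms)
  abs_best <- abs(candidates[[best]]$residuals)
  report <- purrr::map_dfr(candidates, function(cand) {
    tibble::tibble(
      method = cand$method,
      n_retained = cand$n_retained,
      n_latent = cand$n_latent,
      rmsecv = cand$rmsecv,
      p_vs_best = parsimony_p_value(abs(cand$residuals), abs_best)
    )
  })
  report$candidate <- report$p_vs_best > alpha
  report$candidate[best] <- TRUE
  ord <- order(!report$candidate, report$n_retained, report$n_latent,
               report$rmsecv, report$method)
  chosen <- candidates[[ord[1]]]
  list(chosen = chosen, report = dplyr::arrange(report, .data$rmsecv))
}

#' Run all wavelength selectors and pick one
#'
#' Convenience wrapper running FULL (all wavelengths), VIP, JK, RiPLS and
#' FiPLS on the same folds and applying [choose_selection()].
#'
#' @inheritParams vip_select
#' @return list: `chosen`, `report`, `candidates` (named list of all five
#'   `wavelength_subset`s).
#' @export
select_wavelengths <- function(X, y, folds, cfg = selection_config(),
                               chain = "Raw|No|No|No|MNCN", wavelengths = NULL) {
  X <- as_matrix(X)
  fp <- fold_processed(chain, X, y, folds, wavelengths)
  full <- subset_result("FULL", seq_len(ncol(X)), ncol(X), fp, y, cfg)
  cands <- list(
    FULL = full,
    VIP = vip_select(X, y, folds, cfg, chain, wavelengths),
    JK = jackknife_select(X, y, folds, cfg, chain, wavelengths),
    RiPLS = ripls(X, y, folds, cfg, chain, wavelengths),
    FiPLS = fipls(X, y, folds, cfg, chain, wavelengths)
  )
  sel <- choose_selection(cands, cfg$alpha)
  list(chosen = sel$chosen, report = sel$report, candidates = cands)
}

#' Report interval spans of a wavelength subset
#'
#' Reassembles a retained index set into contiguous runs and reports their
#' physical nm spans.
#'
#' @param subset a `wavelength_subset`.
#' @param wavelengths wavelength axis of the instrument grid.
#' @return tibble with `from_nm`, `to_nm`, `n_wavelengths` per contiguous run.
#' @export
subset_spans <- function(subset, wavelengths) {
  idx <- subset$indices
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  purrr::map_dfr(runs, function(r) {
    tibble::tibble(from_nm = wavelengths[min(r)], to_nm = wavelengths[max(r)],
                   n_wavelengths = length(r))
  })
}
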