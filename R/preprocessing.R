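#' Spectral preprocessing operations
#'
#' The calibration grid composes five ordered steps:
#' (1) `Raw` or `Log` (log10(1/T) transform to absorbance);
#' (2) none, baseline offset (`Base`), detrending (`Detr`), standard normal
#'     variate (`SNV`) or multiplicative scatter correction (`MSC`);
#' (3) none, or a Savitzky-Golay derivative `SGxDyy` (order x in 1:2, odd
#'     window yy, second-order polynomial);
#' (4) none, or one-component orthogonal signal correction (`OSC`);
#' (5) mean centering (`MNCN`, always).
#'
#' Steps with fitted state (MSC reference, OSC weights/loadings, centering
#' mean) are estimated on calibration data only and applied unchanged to new
#' spectra.
#'
#' @name preprocessing
NULL

#' Log transform to absorbance
#'
#' `A = log10(1/T)` elementwise; requires strictly positive transmittance or
#' reflectance values.
#'
#' @param X numeric matrix of spectra (rows = samples).
#' @return matrix of absorbance values.
#' @export
log_transform <- function(X) {
  X <- as_matrix(X)
  bad <- which(X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("log transform needs values > 0; first offender sample %d, wavelength %d",
          bad[1, 1], bad[1, 2], class = "nirmilk_domain_error")
  }
  -log10(X)
}

#' Baseline (offset) correction
#'
#' Subtracts each spectrum's minimum so the per-spectrum minimum becomes 0.
#'
#' @inheritParams log_transform
#' @export
baseline_correct <- function(X) {
  X <- as_matrix(X)
  if (ncol(X) == 0) stopf("empty spectra", class = "nirmilk_empty_input")
  X - apply(X, 1, min)
}

#' Detrend against a second-order polynomial in wavelength
#'
#' Removes, per spectrum, its least-squares quadratic trend over the
#' wavelength axis.
#'
#' @inheritParams log_transform
#' @param wavelengths numeric wavelength axis (nm), one per column.
#' @export
detrend <- function(X, wavelengths) {
  X <- as_matrix(X)
  p <- ncol(X)
  if (length(wavelengths) != p) stopf("wavelengths length != ncol(X)")
  if (p < 3) stopf("detrend needs at least 3 wavelengths")
  z <- (wavelengths - mean(wavelengths)) / stats::sd(wavelengths)
  B <- cbind(1, z, z^2)
  H <- B %*% solve(crossprod(B), t(B))   # symmetric hat matrix
  X - X %*% H
}

#' Standard normal variate
#'
#' Per spectrum, subtract the mean and divide by the sample standard
#' deviation (n - 1 denominator); each row leaves with mean 0, SD 1.
#'
#' @inheritParams log_transform
#' @export
snv <- function(X) {
  X <- as_matrix(X)
  mu <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  if (any(s == 0)) {
    stopf("constant spectrum (zero SD) in row %s: SNV undefined",
          paste(which(s == 0), collapse = ", "),
          class = "nirmilk_degenerate_spectrum")
  }
  (X - mu) / s
}

#' Multiplicative scatter correction
#'
#' `msc_fit()` stores the mean calibration spectrum as reference;
#' `msc_apply()` regresses each spectrum `x` on the reference
#' (`x ~ a * ref + b`, ordinary least squares) and returns `(x - b) / a`.
#'
#' @param X_cal calibration spectra matrix (>= 2 rows).
#' @return `msc_fit()`: the reference spectrum (numeric vector).
#' @export
msc_fit <- function(X_cal) {
  X_cal <- as_matrix(X_cal)
  if (nrow(X_cal) < 2) stopf("MSC needs >= 2 calibration spectra")
  colMeans(X_cal)
}

#' @rdname msc_fit
#' @param X spectra to correct.
#' @param reference reference spectrum from [msc_fit()].
#' @export
msc_apply <- function(X, reference) {
  X <- as_matrix(X)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(X)) stopf("reference length != ncol(X)")
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss == 0) stopf("MSC reference has zero variance",
                     class = "nirmilk_degenerate_spectrum")
  a <- drop(X %*% rc) / ss                       # per-row slope
  b <- rowMeans(X) - a * mean(reference)
  if (any(a == 0)) {
    stopf("MSC slope is 0 for sample %s (spectrum orthogonal to reference)",
          paste(which(a == 0), collapse = ", "),
          class = "nirmilk_correction_error")
  }
  (X - b) / a
}

# Coefficient matrix turning a spectrum into its SG derivative: row i holds
# the weights of the order-th derivative at point i of a local least-squares
# quadratic over the window centred at i, truncated one-sided at the edges.
# When a truncated window has too few points for the quadratic, the
# polynomial order drops to m - 1 (derivative 0 if the order exceeds it).
sg_cache <- new.env(parent = emptyenv())

sg_coef_matrix <- function(n, window, order, poly = 2) {
  key <- paste(n, window, order, poly, sep = "|")
  hit <- sg_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- (window - 1L) / 2L
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - h):min(n, i + h)
    m <- length(idx)
    p_eff <- min(poly, m - 1L)
    if (order > p_eff) next                      # derivative of lower-order fit is 0
    z <- idx - i
    V <- outer(z, 0:p_eff, `^`)
    A <- solve(crossprod(V), t(V))
    C[i, idx] <- factorial(order) * A[order + 1L, ]
  }
  sg_cache[[key]] <- C
  C
}

#' Savitzky-Golay derivative
#'
#' First- or second-order derivative (per index step) of a local second-order
#' polynomial least-squares fit in a sliding window.  Edge points are handled
#' by fitting the polynomial on the truncated one-sided window.
#'
#' @inheritParams log_transform
#' @param order derivative order, 1 or 2.
#' @param window odd window length, `window > poly`, `window <= ncol(X)`.
#' @param poly polynomial order of the local fit (fixed at 2 in the grid).
#' @export
savgol_derivative <- function(X, order, window, poly = 2) {
  X <- as_matrix(X)
  if (!order %in% c(1, 2)) stopf("order must be 1 or 2", class = "nirmilk_parameter_error")
  if (window %% 2 == 0 || window <= poly) {
    stopf("window must be odd and > poly (got window=%d, poly=%d)", window, poly,
          class = "nirmilk_parameter_error")
  }
  if (window > ncol(X)) {
    stopf("window (%d) exceeds the number of wavelengths (%d)", window, ncol(X),
          class = "nirmilk_parameter_error")
  }
  C <- sg_coef_matrix(ncol(X), as.integer(window), as.integer(order), as.integer(poly))
  X %*% t(C)
}

#' Orthogonal signal correction (one Wold-style component)
#'
#' Removes from the spectra the dominant variance direction that is
#' orthogonal (uncorrelated) to the response: starting from the first
#' principal-component score, the score is repeatedly orthogonalized against
#' `y` and regressed back onto the spectra until the weight vector converges;
#' the converged component is then deflated.  Fitted scores satisfy
#' `|cor(t, y)| < 1e-6`.
#'
#' @param X calibration spectra matrix.
#' @param y response vector (variance > 0).
#' @param n_comp number of OSC components (0 or 1 in the grid).
#' @param tol relative convergence tolerance on the score vector.
#' @param max_iter iteration cap.
#' @return `osc_fit()`: an `osc_state` with weights/loadings, the centering
#'   mean and the fitted scores; `osc_apply()`: the deflated matrix.
#' @export
osc_fit <- function(X, y, n_comp = 1, tol = 1e-10, max_iter = 500) {
  X <- as_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stopf("y length != nrow(X)")
  state <- structure(list(n_comp = 0L, x_mean = colMeans(X),
                          W = NULL, P = NULL, scores = NULL),
                     class = "osc_state")
  if (n_comp == 0) return(state)
  if (stats::var(y) == 0) stopf("y has zero variance", class = "nirmilk_degenerate_response")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  yc <- y - mean(y)
  W <- P <- list()
  scores <- list()
  for (a in seq_len(n_comp)) {
    sv <- svd(Xc)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    # minimal-norm least-squares inverse, reused across iterations
    pinv_apply <- function(v) {
      sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], v) / sv$d[pos])
    }
    t_score <- sv$u[, 1] * sv$d[1]
    w <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t_orth <- t_score - yc * sum(yc * t_score) / sum(yc^2)
      w_new <- drop(pinv_apply(t_orth))
      w_new <- w_new / sqrt(sum(w_new^2))
      t_new <- drop(Xc %*% w_new)
      delta <- if (is.null(w)) Inf else sqrt(sum((w_new - w)^2))
      w <- w_new
      t_score <- t_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stopf("OSC did not converge after %d iterations", max_iter,
            class = "nirmilk_convergence_error")
    }
    # final exact orthogonalization so the stored score is uncorrelated with y
    t_score <- t_score - yc * sum(yc * t_score) / sum(yc^2)
    p_load <- drop(crossprod(Xc, t_score)) / sum(t_score^2)
    Xc <- Xc - tcrossprod(t_score, p_load)
    W[[a]] <- w; P[[a]] <- p_load; scores[[a]] <- t_score
  }
  state$n_comp <- as.integer(n_comp)
  state$W <- W; state$P <- P; state$scores <- scores
  state
}

#' @rdname osc_fit
#' @param state an `osc_state` from [osc_fit()].
#' @export
osc_apply <- function(X, state) {
  stopifnot(inherits(state, "osc_state"))
  X <- as_matrix(X)
  if (state$n_comp == 0) return(X)
  if (length(state$x_mean) != ncol(X)) stopf("wavelength count mismatch")
  Xc <- sweep(X, 2, state$x_mean)
  for (a in seq_len(state$n_comp)) {
    t_new <- drop(Xc %*% state$W[[a]])
    Xc <- Xc - tcrossprod(t_new, state$P[[a]])
  }
  sweep(Xc, 2, state$x_mean, `+`)
}

#' Mean centering with calibration state
#'
#' @param X_cal calibration spectra; the stored state is its column mean.
#' @export
mean_center_fit <- function(X_cal) {
  colMeans(as_matrix(X_cal))
}

#' @rdname mean_center_fit
#' @param X spectra to center.
#' @param center column-mean vector from [mean_center_fit()].
#' @export
mean_center_apply <- function(X, center) {
  X <- as_matrix(X)
  if (length(center) != ncol(X)) stopf("wavelength count mismatch")
  sweep(X, 2, center)
}
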