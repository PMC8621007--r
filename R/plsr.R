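#' Partial least squares regression (single response, NIPALS)
#'
#' Deterministic NIPALS factorization for one response: components maximize
#' covariance between spectral scores and the response; the fitted model is
#' affine in the processed spectrum, `yhat = y_mean + (x - x_mean) %*% b`.
#' X and y are centered inside the fit using the calibration means (harmless
#' double-centering after an upstream MNCN step; makes the fit safe
#' standalone).
#'
#' @param X processed calibration spectra (n x p).
#' @param y calibration response vector.
#' @param n_latent number of latent variables A, `1 <= A <= min(n - 1, p)`.
#' @param wavelengths optional wavelength axis stored for reporting.
#' @param chain_label optional label of the upstream preprocessing chain.
#' @param wavelength_mask optional logical/integer mask recording which
#'   columns of the instrument grid `X` represents.
#' @return an object of class `plsr_model` with weights `W`, loadings `P`,
#'   response loadings `q`, score sums of squares `tt`, coefficients for
#'   every sub-model 1..A, and centering state.
#' @export
fit_plsr <- function(X, y, n_latent, wavelengths = NULL, chain_label = NULL,
                     wavelength_mask = NULL, strict = TRUE) {
  X <- as_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("y length != nrow(X)")
  if (!is_count(n_latent)) stopf("n_latent must be a positive integer")
  A <- as.integer(n_latent)
  if (A > min(n - 1L, p)) {
    stopf("n_latent = %d exceeds min(n - 1, p) = %d", A, min(n - 1L, p),
          class = "nirmilk_rank_error")
  }
  if (stats::var(y) == 0) {
    stopf("y has zero variance", class = "nirmilk_degenerate_response")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  W <- P <- matrix(0, p, A)
  q <- tt <- numeric(A)
  norm0 <- sqrt(sum(crossprod(Xc, yc)^2))
  a_eff <- 0L
  for (a in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw <= max(norm0, 1) * 1e-14) {
      if (strict) {
        stopf("X has fewer than %d informative dimensions for this response (rank exhausted at component %d)",
              A, a, class = "nirmilk_rank_error")
      }
      break                       # rank exhausted: later sub-models repeat a_eff
    }
    w <- w / nw
    t_score <- drop(Xc %*% w)
    tta <- sum(t_score^2)
    p_load <- drop(crossprod(Xc, t_score)) / tta
    q_a <- sum(yc * t_score) / tta
    Xc <- Xc - tcrossprod(t_score, p_load)
    yc <- yc - t_score * q_a
    W[, a] <- w; P[, a] <- p_load; q[a] <- q_a; tt[a] <- tta
    a_eff <- a
  }
  # R = W (P'W)^-1 maps processed spectra to scores; coefficients are R q
  if (a_eff == 0L) {
    coefs <- matrix(0, p, A)
    R <- matrix(0, p, A)
  } else {
    We <- W[, seq_len(a_eff), drop = FALSE]
    Pe <- P[, seq_len(a_eff), drop = FALSE]
    Re <- We %*% solve(crossprod(Pe, We))
    coefs <- Re %*% (q[seq_len(a_eff)] * upper_tri_cum(a_eff))
    R <- Re
    if (a_eff < A) {
      coefs <- cbind(coefs, matrix(coefs[, a_eff], p, A - a_eff))
      R <- cbind(R, matrix(0, p, A - a_eff))
    }
  }
  structure(
    list(
      n_latent = A, W = W, P = P, q = q, tt = tt, R = R,
      coefficients = coefs[, A],
      coef_path = coefs,
      x_mean = x_mean, y_mean = y_mean,
      wavelengths = wavelengths,
      wavelength_mask = wavelength_mask,
      chain_label = chain_label,
      n_samples = n
    ),
    class = "plsr_model"
  )
}

# upper-triangular 0/1 matrix: column a selects components 1..a
upper_tri_cum <- function(A) {
  M <- matrix(0, A, A)
  M[upper.tri(M, diag = TRUE)] <- 1
  M
}

#' Predict from a PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix of processed spectra with the model's wavelength
#'   count.
#' @param n_latent number of latent variables to use (defaults to the fitted
#'   A).
#' @param all_components if `TRUE`, return an n x A matrix with predictions
#'   from every sub-model 1..A.
#' @param ... unused.
#' @export
predict.plsr_model <- function(object, newdata, n_latent = object$n_latent,
                               all_components = FALSE, ...) {
  X <- as_matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stopf("newdata has %d columns; model expects %d", ncol(X),
          length(object$x_mean))
  }
  Xc <- sweep(X, 2, object$x_mean)
  if (all_components) {
    object$y_mean + Xc %*% object$coef_path
  } else {
    if (n_latent < 1 || n_latent > object$n_latent) {
      stopf("n_latent must be in 1..%d", object$n_latent)
    }
    drop(object$y_mean + Xc %*% object$coef_path[, n_latent])
  }
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a * w_ja^2) / sum_a(SSY_a))` with unit-norm
#' weight vectors and `SSY_a = q_a^2 * t_a' t_a` the response variance
#' captured by component a.  Squared VIPs average to 1 over the retained
#' wavelengths.
#'
#' @param model a fitted `plsr_model`.
#' @return numeric vector of VIP scores, one per retained wavelength.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsr_model"))
  ssy <- model$q^2 * model$tt
  if (sum(ssy) <= 0) {
    stopf("model explains no response variance: VIP undefined",
          class = "nirmilk_degenerate_response")
  }
  p <- nrow(model$W)
  sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d wavelengths, n = %d\n",
              x$n_latent, nrow(x$W), x$n_samples))
  if (!is.null(x$chain_label)) cat("  chain:", x$chain_label, "\n")
  invisible(x)
}

#' Tidy a PLSR model
#'
#' @param x a `plsr_model`.
#' @param ... unused.
#' @return tibble with one row per retained wavelength: `term` (wavelength in
#'   nm, or column index), `estimate` (regression coefficient at the fitted
#'   number of latent variables) and `vip`.
#' @export
tidy.plsr_model <- function(x, ...) {
  term <- if (!is.null(x$wavelengths)) x$wavelengths else seq_along(x$coefficients)
  tibble::tibble(term = term,
                 estimate = as.numeric(x$coefficients),
                 vip = vip_scores(x))
}

#' Glance at a PLSR model
#'
#' @inheritParams tidy.plsr_model
#' @return one-row tibble: `n_latent`, `n_samples`, `n_wavelengths`.
#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(n_latent = x$n_latent, n_samples = x$n_samples,
                 n_wavelengths = nrow(x$W))
}

#' Serialize / restore a PLSR model
#'
#' Writes the model (chain label, wavelength mask, coefficients, centering
#' state, factor matrices) as JSON with full decimal precision, so that a
#' restored model predicts identically.
#'
#' @param model a `plsr_model`.
#' @param path JSON file path.
#' @export
write_plsr <- function(model, path) {
  stopifnot(inherits(model, "plsr_model"))
  payload <- list(
    n_latent = model$n_latent,
    n_wavelengths = nrow(model$W),
    W = as.numeric(model$W), P = as.numeric(model$P),
    q = model$q, tt = model$tt, R = as.numeric(model$R),
    coef_path = as.numeric(model$coef_path),
    x_mean = model$x_mean, y_mean = model$y_mean,
    wavelengths = model$wavelengths,
    wavelength_mask = model$wavelength_mask,
    chain_label = model$chain_label,
    n_samples = model$n_samples
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_plsr
#' @export
read_plsr <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr) matrix(as.numeric(m), nrow = nr)
  p <- length(raw$x_mean)
  model <- list(
    n_latent = as.integer(raw$n_latent),
    W = as_mat(raw$W, p), P = as_mat(raw$P, p),
    q = as.numeric(raw$q), tt = as.numeric(raw$tt),
    R = as_mat(raw$R, p), coef_path = as_mat(raw$coef_path, p),
    x_mean = as.numeric(raw$x_mean), y_mean = as.numeric(raw$y_mean),
    wavelengths = if (is.null(raw$wavelengths)) NULL else as.numeric(raw$wavelengths),
    wavelength_mask = if (is.null(raw$wavelength_mask)) NULL else as.integer(raw$wavelength_mask),
    chain_label = raw$chain_label,
    n_samples = as.integer(raw$n_samples)
  )
  model$coefficients <- model$coef_path[, model$n_latent]
  structure(model, class = "plsr_model")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
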