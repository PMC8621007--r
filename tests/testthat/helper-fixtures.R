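# Small in-code fixtures shared across test files.

# a tiny default-structure synthetic dataset (noise + scatter at defaults)
tiny_sim <- function(n_cows = 20, samples_per_cow = 3, seed = 7, ...) {
  simulate_milk(synthetic_config(n_cows = n_cows,
                                 samples_per_cow = samples_per_cow,
                                 seed = seed, ...))
}

# moments/band library for a 4-component noise-free Beer-Lambert world
four_component_moments <- function() {
  tibble::tibble(
    component = c("fat_pct", "protein_pct", "lactose_pct", "urea_pct"),
    mean = c(4.715, 3.899, 4.62, 3.0),
    sd = c(1.107, 0.415, 0.154, 0.5),
    min = c(1.71, 2.99, 4.09, 1.2),
    max = c(7.70, 5.07, 5.10, 4.8)
  )
}

four_component_bands <- function() {
  bl <- default_band_library()
  bl$urea_pct <- tibble::tibble(center_nm = c(1650, 1850),
                                width_nm = c(40, 35),
                                absorptivity = c(0.009, 0.012))
  bl
}

noise_free_config <- function(n_cows = 50, samples_per_cow = 4, seed = 11) {
  synthetic_config(
    n_cows = n_cows, samples_per_cow = samples_per_cow,
    composition_moments = four_component_moments(),
    band_library = four_component_bands(),
    scatter_slope_sd = 0, scatter_offset_sd = 0, noise_sd = 0,
    seed = seed
  )
}

# random spectra-like matrix with smooth structure plus noise
random_spectra <- function(n, p, seed = 1) {
  set.seed(seed)
  wl <- seq_len(p)
  base <- exp(-0.5 * ((wl - p / 3) / (p / 8))^2)
  t(sapply(seq_len(n), function(i) {
    runif(1, 0.5, 2) * base + rnorm(1, 0, 0.1) + rnorm(p, 0, 0.02)
  }))
}

# one-sided paired t-test p-value computed from first principles (the manual
# oracle used against the parsimony machinery)
manual_paired_p <- function(a, b) {
  d <- a - b
  tv <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  1 - stats::pt(tv, df = length(d) - 1)
}

# wrap residual matrices as a cv_result for the selection functions
mock_cv <- function(residual_matrix, y = NULL) {
  if (is.null(y)) y <- rep(0, nrow(residual_matrix))
  structure(list(
    pred = y - residual_matrix,
    residuals = residual_matrix,
    rmsecv = sqrt(colMeans(residual_matrix^2)),
    r2cv = 1 - colSums(residual_matrix^2) / sum((y - mean(y))^2),
    y = y, chain = "mock", folds = NULL,
    max_latent = ncol(residual_matrix)
  ), class = "cv_result")
}
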