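test_that("identical config and seed give bit-identical datasets", {
  a <- tiny_sim(seed = 31)
  b <- tiny_sim(seed = 31)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$composition, b$composition)
  expect_identical(a$truth$scatter, b$truth$scatter)
  c <- tiny_sim(seed = 32)
  expect_false(identical(a$dataset$intensities, c$dataset$intensities))
})

test_that("compositions hit the target moments and honour the bounds", {
  cfg <- synthetic_config(n_cows = 2500, samples_per_cow = 4, seed = 33)
  cs <- sample_compositions(cfg)
  mom <- milk_composition_moments()
  for (i in seq_len(nrow(mom))) {
    v <- cs$composition[[mom$component[i]]]
    se <- mom$sd[i] / sqrt(length(v))
    # exact expectation of the generative law (cow-level normal, sample-level
    # truncated normal), by numeric integration: the per-cow truncation pulls
    # the mean a few thousandths towards the centre of [min, max]
    csd <- mom$sd[i] / 2
    rsd <- sqrt(mom$sd[i]^2 - csd^2)
    tmean <- function(mu) {
      a <- (mom$min[i] - mu) / rsd; b <- (mom$max[i] - mu) / rsd
      Z <- pnorm(b) - pnorm(a)
      mu + rsd * (dnorm(a) - dnorm(b)) / Z
    }
    e_exact <- stats::integrate(function(mu) {
      dnorm(mu, mom$mean[i], csd) * tmean(mu)
    }, mom$mean[i] - 8 * csd, mom$mean[i] + 8 * csd, rel.tol = 1e-10)$value
    expect_lt(abs(e_exact - mom$mean[i]), 0.02)        # target essentially met
    expect_lt(abs(mean(v) - e_exact), 3 * se)
    expect_true(all(v >= mom$min[i] & v <= mom$max[i]))
  }
})

test_that("with no cow effect the samples follow the truncated normal law", {
  mom <- milk_composition_moments()[1, ]                 # fat
  cfg <- synthetic_config(
    n_cows = 20000, samples_per_cow = 1,
    composition_moments = mom,
    cow_effect_sd = c(fat_pct = 0),
    band_library = default_band_library(), seed = 34
  )
  v <- sample_compositions(cfg)$composition$fat_pct
  # closed-form truncated-normal mean and variance
  mu <- mom$mean; s <- mom$sd
  a <- (mom$min - mu) / s; b <- (mom$max - mu) / s
  Z <- pnorm(b) - pnorm(a)
  m_tr <- mu + s * (dnorm(a) - dnorm(b)) / Z
  v_tr <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                   ((dnorm(a) - dnorm(b)) / Z)^2)
  expect_lt(abs(mean(v) - m_tr), 3 * sqrt(v_tr / length(v)))
  expect_equal(var(v), v_tr, tolerance = 0.05)
})

test_that("infeasible moment configurations are rejected", {
  expect_error(
    synthetic_config(cow_effect_sd = c(fat_pct = 2, protein_pct = 0.1,
                                       lactose_pct = 0.05)),
    class = "nirmilk_config_error"
  )
  mom <- milk_composition_moments()
  mom$min[1] <- 10                                       # min > mean
  expect_error(synthetic_config(composition_moments = mom),
               class = "nirmilk_config_error")
})

test_that("noise-free spectra obey Beer-Lambert linearity", {
  mom <- tibble::tibble(component = "fat_pct", mean = 4, sd = 1,
                        min = 1, max = 8)
  bl <- list(fat_pct = tibble::tibble(center_nm = 1750, width_nm = 30,
                                      absorptivity = 0.01),
             water = NULL)
  cfg <- synthetic_config(n_cows = 2, samples_per_cow = 1,
                          composition_moments = mom, cow_effect_sd = c(fat_pct = 0),
                          band_library = bl, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, noise_sd = 0,
                          mode = "absorbance", seed = 35)
  comp <- composition_table(tibble::tibble(
    sample_id = c("s1", "s2"), cow_id = c("c1", "c2"),
    fat_pct = c(2, 4)
  ))
  ds <- generate_spectra(cfg, comp, list())$dataset
  expect_equal(ds$intensities[2, ], 2 * ds$intensities[1, ], tolerance = 1e-12)
  peak <- which.min(abs(ds$wavelengths_nm - 1750))
  expect_equal(unname(ds$intensities[1, peak]), 1.5 * 2 * 0.01, tolerance = 1e-6)
})

test_that("noise-free cross-validation recovers each component to machine precision", {
  sim <- simulate_milk(noise_free_config(seed = 36))
  X <- sim$dataset$intensities
  folds <- make_cv_folds(sim$composition$cow_id, k = 10, seed = 2)
  for (comp in four_component_moments()$component) {
    y <- sim$composition[[comp]]
    cv <- cross_validate("Log|No|No|No|MNCN", X, y, folds, max_latent = 4,
                         wavelengths = sim$dataset$wavelengths_nm)
    expect_lt(cv$rmsecv[4], 1e-6 * diff(range(y)))
  }
})

test_that("scatter-corrected chains beat uncorrected chains on scattered data", {
  sim <- tiny_sim(n_cows = 30, samples_per_cow = 4, seed = 37)
  X <- sim$dataset$intensities
  y <- sim$composition$fat_pct
  folds <- make_cv_folds(sim$composition$cow_id, k = 5, seed = 3)
  labs <- fast_chains()
  grid <- run_chain_grid(labs, X, y, folds, max_latent = 6,
                         wavelengths = sim$dataset$wavelengths_nm)
  step2 <- vapply(grid$label, function(l) parse_chain(l)$step2, "")
  corrected <- grid$rmsecv[step2 %in% c("SNV", "MSC")]
  uncorrected <- grid$rmsecv[step2 == "No"]
  expect_lt(median(corrected), median(uncorrected))
})
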