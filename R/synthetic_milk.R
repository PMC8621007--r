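#' Reference moments of raw-milk composition
#'
#' Mean, SD, minimum and maximum (% w/w) of fat, protein and lactose typical
#' of a farm study herd; used as the default targets of the synthetic
#' generator.
#'
#' @return tibble with columns `component`, `mean`, `sd`, `min`, `max`.
#' @export
milk_composition_moments <- function() {
  tibble::tibble(
    component = c("fat_pct", "protein_pct", "lactose_pct"),
    mean = c(4.715, 3.899, 4.62),
    sd   = c(1.107, 0.415, 0.154),
    min  = c(1.71, 2.99, 4.09),
    max  = c(7.70, 5.07, 5.10)
  )
}

#' Default absorption band library
#'
#' Plausible Gaussian NIR band parameters per milk component (CH overtones of
#' fat near 1210/1725/2310 nm, protein and lactose combination bands in the
#' 2000-2300 nm region, amide/OH features lower down) and water (1450 and
#' 1940 nm OH bands).  These are generator configuration, freely
#' overridable, not claims about any measured spectrum; absorptivity is in
#' absorbance units per (% w/w) per mm.
#'
#' @return named list: one tibble (`center_nm`, `width_nm`, `absorptivity`)
#'   per component, plus `water`.
#' @export
default_band_library <- function() {
  band <- function(center_nm, width_nm, absorptivity) {
    tibble::tibble(center_nm = center_nm, width_nm = width_nm,
                   absorptivity = absorptivity)
  }
  list(
    fat_pct = band(c(1210, 1725, 1760, 2310, 2350),
                   c(35, 30, 25, 30, 28),
                   c(0.010, 0.014, 0.009, 0.016, 0.012)),
    protein_pct = band(c(1190, 1510, 1690, 2055, 2180, 2290),
                       c(45, 40, 35, 35, 40, 35),
                       c(0.006, 0.010, 0.008, 0.014, 0.016, 0.010)),
    lactose_pct = band(c(1250, 1590, 1780, 2100, 2270),
                       c(50, 45, 40, 40, 38),
                       c(0.005, 0.008, 0.007, 0.013, 0.011)),
    water = band(c(1450, 1940, 1150),
                 c(55, 65, 45),
                 c(0.0020, 0.0032, 0.0008))
  )
}

#' Synthetic raw-milk dataset configuration
#'
#' Defines the statistical structure the generator emulates: compositions
#' with target moments and within-cow clustering, Beer-Lambert component
#' absorption over an instrument window, multiplicative/additive scatter and
#' detector noise.
#'
#' @param n_cows number of cows.
#' @param samples_per_cow samples per cow (scalar, or length-2 range sampled
#'   uniformly per cow).
#' @param window an [instrument_window()]; default the 1550-1950 nm
#'   transmittance module.
#' @param grid_step_nm wavelength grid spacing (nm).
#' @param composition_moments tibble like [milk_composition_moments()]
#'   (`component`, `mean`, `sd`, `min`, `max`).
#' @param cow_effect_sd named numeric vector of between-cow SDs per
#'   component; default half of each component SD (the between/within split
#'   is an assumption of the generator, not an observed quantity).
#' @param pathlength_mm cuvette thickness (mm); default 1.5.
#' @param band_library named list of Gaussian band tables per component, see
#'   [default_band_library()]; the `water` entry models the background
#'   absorption of the aqueous phase (concentration `100 - sum(components)`
#'   % w/w).  Set `water = NULL` to omit the water term.
#' @param scatter_slope_sd SD of the per-sample multiplicative scatter effect
#'   (unitless; `A' = (1 + slope) * A + offset`).
#' @param scatter_offset_sd SD of the per-sample additive offset (absorbance
#'   units).
#' @param noise_sd detector noise SD (absorbance units), i.i.d. per point.
#' @param mode emit `"transmittance"` (`10^-A`) or `"absorbance"`.
#' @param seed integer seed; identical configs and seeds give bit-identical
#'   datasets.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cows = 60,
                             samples_per_cow = 4,
                             window = instrument_windows()$nirone_2.0_T,
                             grid_step_nm = 4,
                             composition_moments = milk_composition_moments(),
                             cow_effect_sd = NULL,
                             pathlength_mm = 1.5,
                             band_library = default_band_library(),
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 0.002,
                             mode = c("transmittance", "absorbance"),
                             seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is_count(n_cows), pathlength_mm > 0, grid_step_nm > 0,
            inherits(window, "instrument_window"))
  cm <- tibble::as_tibble(composition_moments)
  if (!all(c("component", "mean", "sd", "min", "max") %in% names(cm))) {
    stopf("composition_moments needs columns component, mean, sd, min, max",
          class = "nirmilk_config_error")
  }
  if (any(cm$sd < 0) || any(!(cm$min < cm$mean & cm$mean < cm$max))) {
    stopf("need sd >= 0 and min < mean < max for every component",
          class = "nirmilk_config_error")
  }
  if (is.null(cow_effect_sd)) {
    cow_effect_sd <- stats::setNames(cm$sd / 2, cm$component)
  }
  if (!all(cm$component %in% names(cow_effect_sd))) {
    stopf("cow_effect_sd must name every component", class = "nirmilk_config_error")
  }
  if (any(cow_effect_sd[cm$component] > cm$sd)) {
    stopf("cow_effect_sd exceeds the total SD for component(s): %s",
          paste(cm$component[cow_effect_sd[cm$component] > cm$sd], collapse = ", "),
          class = "nirmilk_config_error")
  }
  for (comp in cm$component) {
    if (is.null(band_library[[comp]])) {
      stopf("band_library has no entry for component '%s'", comp,
            class = "nirmilk_config_error")
    }
  }
  for (tab in band_library) {
    if (!is.null(tab) && anyNA(as.matrix(tab))) {
      stopf("NaN/NA in band library", class = "nirmilk_config_error")
    }
  }
  structure(
    list(n_cows = as.integer(n_cows), samples_per_cow = samples_per_cow,
         window = window, grid_step_nm = grid_step_nm,
         composition_moments = cm, cow_effect_sd = cow_effect_sd,
         pathlength_mm = pathlength_mm, band_library = band_library,
         scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         noise_sd = noise_sd, mode = mode, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Draw synthetic milk compositions with within-cow clustering
#'
#' Per cow, a cow-level mean is drawn from a normal around the component mean
#' with SD `cow_effect_sd`; samples are drawn around the cow mean with
#' residual SD `sqrt(sd^2 - cow_effect_sd^2)` so the total SD matches the
#' target, then truncated to `[min, max]` by rejection (out-of-bounds draws
#' are redrawn, preserving the truncated-normal law).
#'
#' @param cfg a [synthetic_config()].
#' @return `list(composition, truth)`: the composition table (with `cow_id`)
#'   and a ground-truth list carrying the per-cow random effects.
#' @export
sample_compositions <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cm <- cfg$composition_moments
  with_rng(cfg$seed, {
    spc <- cfg$samples_per_cow
    n_per_cow <- if (length(spc) == 2) {
      sample(spc[1]:spc[2], cfg$n_cows, replace = TRUE)
    } else {
      rep(as.integer(spc), cfg$n_cows)
    }
    cow_ids <- sprintf("cow%03d", seq_len(cfg$n_cows))
    cow_of_sample <- rep(cow_ids, n_per_cow)
    n <- length(cow_of_sample)
    sample_ids <- sprintf("s%04d", seq_len(n))
    comp_vals <- list()
    cow_effects <- list()
    for (i in seq_len(nrow(cm))) {
      comp <- cm$component[i]
      csd <- cfg$cow_effect_sd[[comp]]
      rsd <- sqrt(cm$sd[i]^2 - csd^2)
      cow_mu <- cm$mean[i] + rnorm(cfg$n_cows, 0, csd)
      mu_of_sample <- rep(cow_mu, n_per_cow)
      v <- mu_of_sample + rnorm(n, 0, rsd)
      # rejection sampling for the truncation bounds
      for (guard in 1:10000) {
        bad <- v < cm$min[i] | v > cm$max[i]
        if (!any(bad)) break
        v[bad] <- mu_of_sample[bad] + rnorm(sum(bad), 0, rsd)
      }
      if (any(v < cm$min[i] | v > cm$max[i])) {
        stopf("truncation bounds for '%s' are unreachable from the cow means",
              comp, class = "nirmilk_config_error")
      }
      comp_vals[[comp]] <- v
      cow_effects[[comp]] <- cow_mu - cm$mean[i]
    }
    composition <- tibble::tibble(sample_id = sample_ids,
                                  cow_id = cow_of_sample,
                                  !!!comp_vals)
    truth <- list(
      composition = composition,
      cow_effects = tibble::tibble(cow_id = cow_ids, !!!cow_effects),
      scatter = NULL
    )
    list(composition = composition_table(composition), truth = truth)
  })
}

gaussian_bands <- function(wl, bands) {
  if (is.null(bands) || nrow(bands) == 0) return(numeric(length(wl)))
  eps <- numeric(length(wl))
  for (i in seq_len(nrow(bands))) {
    eps <- eps + bands$absorptivity[i] *
      exp(-0.5 * ((wl - bands$center_nm[i]) / bands$width_nm[i])^2)
  }
  eps
}

#' Generate synthetic NIR spectra from compositions
#'
#' Beer-Lambert mixing: `A(wl) = pathlength * (sum_i c_i eps_i(wl) +
#' c_water * eps_water(wl))` with `c_water = 100 - sum_i c_i` (% w/w), then a
#' per-sample affine scatter distortion `A' = (1 + slope) * A + offset` and
#' i.i.d. Gaussian detector noise; emitted as absorbance or transmittance
#' `10^(-A')` per the config.
#'
#' @param cfg a [synthetic_config()].
#' @param composition composition table from [sample_compositions()] (with
#'   `cow_id`).
#' @param truth ground-truth list from [sample_compositions()]; returned
#'   augmented with the drawn scatter parameters.
#' @return `list(dataset, truth)`.
#' @export
generate_spectra <- function(cfg, composition, truth) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cm <- cfg$composition_moments
  wl <- seq(cfg$window$lo_nm, cfg$window$hi_nm, by = cfg$grid_step_nm)
  n <- nrow(composition)
  E <- sapply(cm$component, function(comp) gaussian_bands(wl, cfg$band_library[[comp]]))
  C <- as.matrix(composition[cm$component])
  if (any(C < cm$min[col(C)] - 1e-9) || any(C > cm$max[col(C)] + 1e-9)) {
    stopf("compositions outside the configured bounds", class = "nirmilk_config_error")
  }
  A <- C %*% t(E)
  if (!is.null(cfg$band_library$water)) {
    eps_w <- gaussian_bands(wl, cfg$band_library$water)
    water_c <- 100 - rowSums(C)
    A <- A + water_c %*% t(eps_w)
  }
  A <- cfg$pathlength_mm * A
  # scatter and noise are drawn from a stream offset from the composition
  # stream so composition draws stay identical across modes
  with_rng(cfg$seed + 104729L, {
    slope <- rnorm(n, 0, cfg$scatter_slope_sd)
    offset <- rnorm(n, 0, cfg$scatter_offset_sd)
    A <- (1 + slope) * A + offset
    if (cfg$noise_sd > 0) {
      A <- A + matrix(rnorm(length(A), 0, cfg$noise_sd), nrow = n)
    }
  })
  X <- if (cfg$mode == "transmittance") 10^(-A) else A
  ds <- spectral_dataset(
    intensities = X, wavelengths_nm = wl,
    sample_ids = composition$sample_id, cow_ids = composition$cow_id,
    mode = cfg$mode, instrument_label = paste0("synthetic ", cfg$window$name)
  )
  truth$scatter <- tibble::tibble(sample_id = composition$sample_id,
                                  slope = slope, offset = offset)
  list(dataset = ds, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [sample_compositions()] then [generate_spectra()].
#'
#' @param cfg a [synthetic_config()].
#' @return `list(dataset, composition, truth)`.
#' @export
simulate_milk <- function(cfg) {
  cs <- sample_compositions(cfg)
  gs <- generate_spectra(cfg, cs$composition, cs$truth)
  list(dataset = gs$dataset, composition = cs$composition, truth = gs$truth)
}
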