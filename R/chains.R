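#' Preprocessing chains
#'
#' A chain is identified by a label of the form
#' `"<Raw|Log>|<No|Base|Detr|SNV|MSC>|<No|SG{1,2}D{ww}>|<No|OSC>|MNCN"`,
#' e.g. `"Log|Detr|SG1D13|OSC|MNCN"`.  The final mean-centering step is
#' always present.
#'
#' @name chains
NULL

# the ten odd SG window lengths used in the grid
sg_windows <- function() c(3, 5, 7, 9, 11, 13, 15, 17, 19, 21)

#' Parse a chain label
#'
#' @param label chain label string (see [chains]).
#' @return list with elements `step1`, `step2`, `step3` (either `"No"` or
#'   `list(order, window)`), `step4`, and `label`.
#' @export
parse_chain <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  if (length(parts) != 5 || parts[5] != "MNCN") {
    stopf("malformed chain label '%s'", label, class = "nirmilk_parameter_error")
  }
  if (!parts[1] %in% c("Raw", "Log")) {
    stopf("bad step 1 '%s' in '%s'", parts[1], label, class = "nirmilk_parameter_error")
  }
  if (!parts[2] %in% c("No", "Base", "Detr", "SNV", "MSC")) {
    stopf("bad step 2 '%s' in '%s'", parts[2], label, class = "nirmilk_parameter_error")
  }
  step3 <- parts[3]
  if (step3 != "No") {
    m <- regmatches(step3, regexec("^SG([12])D([0-9]{2})$", step3))[[1]]
    if (length(m) == 0) {
      stopf("bad step 3 '%s' in '%s'", step3, label, class = "nirmilk_parameter_error")
    }
    step3 <- list(order = as.integer(m[2]), window = as.integer(m[3]))
  }
  if (!parts[4] %in% c("No", "OSC")) {
    stopf("bad step 4 '%s' in '%s'", parts[4], label, class = "nirmilk_parameter_error")
  }
  list(step1 = parts[1], step2 = parts[2], step3 = step3, step4 = parts[4],
       label = label)
}

#' Serialize chain components into a label
#'
#' @param step1 `"Raw"` or `"Log"`.
#' @param step2 `"No"`, `"Base"`, `"Detr"`, `"SNV"` or `"MSC"`.
#' @param step3 `"No"` or `list(order =, window =)`.
#' @param step4 `"No"` or `"OSC"`.
#' @export
chain_label <- function(step1, step2, step3, step4) {
  s3 <- if (is.list(step3)) sprintf("SG%dD%02d", step3$order, step3$window) else step3
  paste(step1, step2, s3, step4, "MNCN", sep = "|")
}

#' Enumerate the full preprocessing grid
#'
#' Cartesian product of the five steps: 2 x 5 x (1 + 2 x 10) x 2 = 420
#' chains, each ending in mean centering.
#'
#' @return tibble with columns `label`, `step1`, `step2`, `step3`, `step4`,
#'   `has_osc`; one row per chain, ordered by the enumeration.
#' @export
enumerate_chains <- function() {
  s3_labels <- c("No",
                 as.vector(outer(1:2, sg_windows(),
                                 function(o, w) sprintf("SG%dD%02d", o, w))))
  grid <- tidyr::expand_grid(
    step1 = c("Raw", "Log"),
    step2 = c("No", "Base", "Detr", "SNV", "MSC"),
    step3 = s3_labels,
    step4 = c("No", "OSC")
  )
  grid |>
    dplyr::mutate(
      label = paste(.data$step1, .data$step2, .data$step3, .data$step4, "MNCN",
                    sep = "|"),
      has_osc = .data$step4 == "OSC"
    ) |>
    dplyr::select("label", "step1", "step2", "step3", "step4", "has_osc")
}

#' A small deterministic chain subset for fast grid runs
#'
#' Sixteen chains spanning all five steps (both Log states, every scatter
#' treatment, SG orders 1 and 2, with and without OSC), used by the pipeline's
#' fast mode and in tests.
#'
#' @return character vector of chain labels.
#' @export
fast_chains <- function() {
  c("Raw|No|No|No|MNCN",
    "Log|No|No|No|MNCN",
    "Raw|SNV|No|No|MNCN",
    "Log|SNV|No|No|MNCN",
    "Raw|MSC|No|No|MNCN",
    "Log|MSC|No|No|MNCN",
    "Log|Base|No|No|MNCN",
    "Log|Detr|No|No|MNCN",
    "Log|No|SG1D13|No|MNCN",
    "Log|SNV|SG1D13|No|MNCN",
    "Log|No|SG2D13|No|MNCN",
    "Raw|No|SG1D09|No|MNCN",
    "Log|No|No|OSC|MNCN",
    "Log|SNV|No|OSC|MNCN",
    "Log|MSC|SG1D13|No|MNCN",
    "Log|Detr|SG2D09|OSC|MNCN")
}

#' Fit and apply a preprocessing chain
#'
#' Applies the five steps in order.  All fitted state (MSC reference, OSC
#' weights/loadings, centering mean) is estimated from `X_cal` only and
#' applied identically to `X_new`, so processing a new spectrum never depends
#' on other new spectra.
#'
#' @param chain a chain label or the result of [parse_chain()].
#' @param X_cal calibration spectra matrix.
#' @param y_cal calibration response; required iff the chain contains OSC.
#' @param X_new optional new spectra to process with the fitted state.
#' @param wavelengths wavelength axis (needed by the detrend step; defaults
#'   to the column index).
#' @return list with `X_cal`, `X_new` (or `NULL`) and `state` (the fitted
#'   chain: chain spec plus `msc_reference`, `osc`, `center`).
#' @export
apply_chain <- function(chain, X_cal, y_cal = NULL, X_new = NULL,
                        wavelengths = NULL) {
  ch <- if (is.character(chain)) parse_chain(chain) else chain
  X_cal <- as_matrix(X_cal)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(X_cal))
  if (!is.null(X_new)) X_new <- as_matrix(X_new)
  if (ch$step4 == "OSC" && is.null(y_cal)) {
    stopf("chain '%s' contains OSC: y_cal is required", ch$label)
  }
  step <- function(what, f) {
    X_cal <<- f(X_cal)
    if (!is.null(X_new)) X_new <<- f(X_new)
  }
  wrap <- function(i, expr) {
    tryCatch(expr, error = function(e) {
      stopf("chain '%s' failed at step %d: %s", ch$label, i, conditionMessage(e),
            class = "nirmilk_chain_error")
    })
  }
  state <- list(chain = ch)

  if (ch$step1 == "Log") wrap(1, step("log", log_transform))
  wrap(2, switch(ch$step2,
    No = NULL,
    Base = step("base", baseline_correct),
    Detr = step("detr", function(X) detrend(X, wavelengths)),
    SNV = step("snv", snv),
    MSC = {
      state$msc_reference <- msc_fit(X_cal)
      step("msc", function(X) msc_apply(X, state$msc_reference))
    }
  ))
  if (is.list(ch$step3)) {
    wrap(3, step("sg", function(X) {
      savgol_derivative(X, ch$step3$order, ch$step3$window)
    }))
  }
  if (ch$step4 == "OSC") {
    wrap(4, {
      state$osc <- osc_fit(X_cal, y_cal, n_comp = 1)
      step("osc", function(X) osc_apply(X, state$osc))
    })
  }
  wrap(5, {
    state$center <- mean_center_fit(X_cal)
    step("mncn", function(X) mean_center_apply(X, state$center))
  })

  list(X_cal = X_cal, X_new = X_new, state = state)
}

#' Apply an already-fitted chain to new spectra
#'
#' @param state fitted chain state from [apply_chain()].
#' @param X new spectra matrix.
#' @param wavelengths wavelength axis for the detrend step.
#' @return processed matrix.
#' @export
apply_fitted_chain <- function(state, X, wavelengths = NULL) {
  ch <- state$chain
  X <- as_matrix(X)
  if (is.null(wavelengths)) wavelengths <- seq_len(ncol(X))
  if (ch$step1 == "Log") X <- log_transform(X)
  X <- switch(ch$step2,
    No = X,
    Base = baseline_correct(X),
    Detr = detrend(X, wavelengths),
    SNV = snv(X),
    MSC = msc_apply(X, state$msc_reference)
  )
  if (is.list(ch$step3)) {
    X <- savgol_derivative(X, ch$step3$order, ch$step3$window)
  }
  if (ch$step4 == "OSC") X <- osc_apply(X, state$osc)
  mean_center_apply(X, state$center)
}
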