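#' Root mean squared error
#'
#' @param residuals numeric vector of residuals (reference minus prediction).
#' @return `sqrt(mean(residuals^2))`.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0) stopf("no residuals", class = "nirmilk_empty_input")
  sqrt(mean(residuals^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`, with SST about the mean of the reference values in the
#' evaluated set.
#'
#' @param y_ref reference values.
#' @param y_pred predicted values.
#' @export
r_squared <- function(y_ref, y_pred) {
  stopifnot(length(y_ref) == length(y_pred))
  sst <- sum((y_ref - mean(y_ref))^2)
  if (sst == 0) {
    stopf("reference values have zero variance: R^2 undefined",
          class = "nirmilk_degenerate_response")
  }
  1 - sum((y_ref - y_pred)^2) / sst
}

#' Williams R-squared quality class
#'
#' Classifies a determination coefficient into the Williams calibration
#' quality bands: approximate quantitative (0.66-0.81), good (0.82-0.90),
#' excellent (> 0.91), below 0.66 insufficient.  The printed bands leave the
#' gaps 0.81-0.82 and 0.90-0.91 open; each is closed by extending the lower
#' band upward (so approximate quantitative covers [0.66, 0.82) and good
#' covers [0.82, 0.91]).
#'
#' @param r2 numeric vector of R-squared values (each <= 1).
#' @return character vector in `{"insufficient", "approximate_quantitative",
#'   "good", "excellent"}`.
#' @export
williams_class <- function(r2) {
  stopifnot(all(r2 <= 1 + 1e-12))
  # closures: [0.66, 0.82) approximate, [0.82, 0.91] good, > 0.91 excellent
  ifelse(r2 < 0.66, "insufficient",
         ifelse(r2 < 0.82, "approximate_quantitative",
                ifelse(r2 <= 0.91, "good", "excellent")))
}

#' ICAR accuracy thresholds
#'
#' RMSEP limits (% w/w, identical for fat, protein and lactose) published by
#' the International Committee for Animal Recording: in-line 0.25, at-line
#' 0.20, laboratory 0.10.
#'
#' @return named list `in_line`, `at_line`, `laboratory`.
#' @export
icar_thresholds <- function() {
  list(in_line = 0.25, at_line = 0.20, laboratory = 0.10)
}

#' Check an RMSEP against the ICAR limits
#'
#' @param rmsep non-negative RMSEP (% w/w).
#' @param thresholds list as from [icar_thresholds()].
#' @return tibble with logical columns `in_line`, `at_line`, `laboratory`
#'   (`TRUE` = `rmsep <= limit`), one row per input value.
#' @export
icar_check <- function(rmsep, thresholds = icar_thresholds()) {
  stopifnot(all(rmsep >= 0),
            thresholds$laboratory < thresholds$at_line,
            thresholds$at_line < thresholds$in_line)
  tibble::tibble(
    rmsep = rmsep,
    in_line = rmsep <= thresholds$in_line,
    at_line = rmsep <= thresholds$at_line,
    laboratory = rmsep <= thresholds$laboratory
  )
}

#' Evaluate predictions on a validation set
#'
#' @param y_ref reference compositions of the validation samples (% w/w).
#' @param y_pred model predictions.
#' @param component component name (reporting).
#' @param rmsecv,r2cv optional cross-validation metrics carried through to
#'   the report.
#' @param spectrometer instrument label (reporting).
#' @return object of class `eval_result`: list with per-sample `predictions`
#'   tibble, `rmsep`, `r2p`, `williams`, `icar` flags and the carried CV
#'   metrics.
#' @export
evaluate_predictions <- function(y_ref, y_pred, component = NA_character_,
                                 rmsecv = NA_real_, r2cv = NA_real_,
                                 spectrometer = NA_character_) {
  res <- y_ref - y_pred
  rp <- rmse(res)
  structure(
    list(
      predictions = tibble::tibble(reference = y_ref, predicted = y_pred,
                                   residual = res),
      rmsep = rp,
      r2p = r_squared(y_ref, y_pred),
      rmsecv = rmsecv, r2cv = r2cv,
      component = component, spectrometer = spectrometer,
      williams = williams_class(r_squared(y_ref, y_pred)),
      icar = icar_check(rp)
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s / %s: RMSEP = %.4g, R2p = %.4g (%s)\n",
              x$spectrometer, x$component, x$rmsep, x$r2p, x$williams))
  invisible(x)
}

#' Glance at an evaluation result
#'
#' @param x an `eval_result`.
#' @param ... unused.
#' @return one-row tibble: component, spectrometer, n_val, RMSEP, R2p,
#'   RMSECV, R2cv, Williams class and the three ICAR flags.
#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(
    component = x$component, spectrometer = x$spectrometer,
    n_val = nrow(x$predictions),
    rmsep = x$rmsep, r2p = x$r2p, rmsecv = x$rmsecv, r2cv = x$r2cv,
    williams = x$williams,
    icar_in_line = x$icar$in_line, icar_at_line = x$icar$at_line,
    icar_laboratory = x$icar$laboratory
  )
}

#' Compare spectrometers by two-way ANOVA and Tukey HSD
#'
#' Squared validation residuals (one column per spectrometer, one row per
#' sample; the design must be complete) are analysed with a two-way ANOVA
#' without interaction, treating the sample as a blocking factor (for this
#' balanced complete design the F-test for the spectrometer effect is
#' identical to the repeated-measures/randomized-complete-block analysis).
#' If the spectrometer effect is significant at `alpha`, Tukey's HSD on the
#' spectrometer means (using the ANOVA error term) yields pairwise adjusted
#' p-values; a compact letter display is assigned by insert-and-absorb from
#' the lowest mean squared residual upward.  Spectrometers sharing a letter
#' are not significantly different.
#'
#' @param squared_residuals numeric matrix, samples x spectrometers, complete
#'   (no missing cells), with spectrometer names as column names.
#' @param alpha significance level (default 0.05).
#' @return object of class `spectrometer_comparison`: list with `anova`
#'   (tibble of the ANOVA table), `tukey` (tibble of pairwise comparisons)
#'   and `letters` (tibble: spectrometer, mean squared residual, letters).
#' @export
compare_spectrometers <- function(squared_residuals, alpha = 0.05) {
  M <- as_matrix(squared_residuals)
  if (anyNA(M)) stopf("missing cells: the design must be complete (no imputation)")
  if (is.null(colnames(M))) colnames(M) <- paste0("spec", seq_len(ncol(M)))
  long <- tibble::tibble(
    sq = as.vector(M),
    sample = factor(rep(seq_len(nrow(M)), times = ncol(M))),
    spectrometer = factor(rep(colnames(M), each = nrow(M)), levels = colnames(M))
  )
  fit <- stats::aov(sq ~ spectrometer + sample, data = long)
  an <- as.data.frame(summary(fit)[[1]])
  anova_tbl <- tibble::tibble(
    term = trimws(rownames(an)),
    df = an$Df, sumsq = an$`Sum Sq`, meansq = an$`Mean Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  p_spec <- anova_tbl$p_value[anova_tbl$term == "spectrometer"]
  # degenerate case: spectrometer effect numerically zero (e.g. identical
  # columns) leaves a 0/0 F ratio; there is no evidence of a difference
  ss_total <- sum(anova_tbl$sumsq)
  if (anova_tbl$sumsq[anova_tbl$term == "spectrometer"] <=
      1e-12 * max(ss_total, .Machine$double.xmin)) {
    p_spec <- 1
  }
  tk <- stats::TukeyHSD(fit, which = "spectrometer")$spectrometer
  tukey_tbl <- tibble::tibble(
    comparison = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  means <- colMeans(M)
  if (p_spec <= alpha) {
    # pairwise significance matrix in mean-ascending order
    ord <- names(sort(means))
    sig <- matrix(FALSE, length(ord), length(ord), dimnames = list(ord, ord))
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      sig[a, b] <- sig[b, a] <- tk[i, "p adj"] <= alpha
    }
    letters_of <- compact_letters(ord, sig)
  } else {
    letters_of <- stats::setNames(rep("a", ncol(M)), names(sort(means)))
  }
  letters_tbl <- tibble::tibble(
    spectrometer = colnames(M),
    mean_squared_residual = unname(means),
    letters = unname(letters_of[colnames(M)])
  )
  structure(list(anova = anova_tbl, tukey = tukey_tbl, letters = letters_tbl,
                 alpha = alpha, p_spectrometer = p_spec),
            class = "spectrometer_comparison")
}

# Standard insert-and-absorb compact letter display.  `groups` are ordered by
# ascending mean; `sig[a, b]` is TRUE when a and b differ significantly.
compact_letters <- function(groups, sig) {
  k <- length(groups)
  cols <- list(rep(TRUE, k))                       # start: one letter for all
  names_idx <- stats::setNames(seq_len(k), groups)
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      if (!sig[groups[a], groups[b]]) next
      # every letter containing both a and b must be split
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (!is.null(col) && col[a] && col[b]) {
          c1 <- col; c1[b] <- FALSE
          c2 <- col; c2[a] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb letters fully contained in another
      keep <- rep(TRUE, length(cols))
      for (i in seq_along(cols)) {
        for (j in seq_along(cols)) {
          if (i != j && keep[j] &&
              all(cols[[i]] <= cols[[j]]) && any(cols[[i]] < cols[[j]])) {
            keep[i] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  # order letters by the first (best) group they contain
  first_member <- purrr::map_int(cols, ~ which(.x)[1])
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(purrr::map_lgl(cols, ~ .x[i]))], collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}

#' @export
print.spectrometer_comparison <- function(x, ...) {
  cat(sprintf("<spectrometer_comparison> spectrometer effect p = %.4g\n",
              x$p_spectrometer))
  print(x$letters)
  invisible(x)
}
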