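#' Spectral dataset container
#'
#' Bundles a samples-by-wavelengths intensity matrix with its wavelength grid
#' (nm), per-sample metadata (sample and cow identifiers) and the acquisition
#' mode.  Wavelengths are always physical nanometre values at the interface,
#' never column indices.
#'
#' @param intensities numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths
#'   (nm), one per column of `intensities`.
#' @param sample_ids unique character identifiers, one per row.
#' @param cow_ids per-sample group (animal) identifier; samples from one cow
#'   form a block in all partitioning downstream.
#' @param mode one of `"raw"`, `"transmittance"`, `"reflectance"`,
#'   `"absorbance"`.
#' @param instrument_label free-text instrument description.
#'
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavelengths_nm`, `intensities`, `meta` (tibble of `sample_id`,
#'   `cow_id`), `mode`, `instrument_label`.
#' @export
spectral_dataset <- function(intensities, wavelengths_nm, sample_ids, cow_ids,
                             mode = c("raw", "transmittance", "reflectance",
                                      "absorbance"),
                             instrument_label = "") {
  mode <- match.arg(mode)
  intensities <- as_matrix(intensities)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (anyNA(wavelengths_nm)) {
    stopf("wavelengths_nm contains non-numeric values", class = "nirmilk_schema_error")
  }
  if (length(wavelengths_nm) != ncol(intensities)) {
    stopf("got %d wavelengths for %d intensity columns",
          length(wavelengths_nm), ncol(intensities),
          class = "nirmilk_schema_error")
  }
  if (length(wavelengths_nm) > 1 && any(diff(wavelengths_nm) <= 0)) {
    stopf("wavelengths_nm must be strictly increasing (no duplicates)",
          class = "nirmilk_schema_error")
  }
  sample_ids <- as.character(sample_ids)
  cow_ids <- as.character(cow_ids)
  if (length(sample_ids) != nrow(intensities) ||
      length(cow_ids) != nrow(intensities)) {
    stopf("sample_ids/cow_ids length must equal the number of spectra (%d)",
          nrow(intensities), class = "nirmilk_schema_error")
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample_id: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
          class = "nirmilk_schema_error")
  }
  if (mode != "raw" && !all(is.finite(intensities))) {
    stopf("mode '%s' requires all intensities finite", mode,
          class = "nirmilk_schema_error")
  }
  rownames(intensities) <- sample_ids
  colnames(intensities) <- NULL
  structure(
    list(
      wavelengths_nm = wavelengths_nm,
      intensities = intensities,
      meta = tibble::tibble(sample_id = sample_ids, cow_id = cow_ids),
      mode = mode,
      instrument_label = instrument_label
    ),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %d samples x %d wavelengths (%.6g-%.6g nm), mode=%s%s\n",
    nrow(x$intensities), length(x$wavelengths_nm),
    min(x$wavelengths_nm), max(x$wavelengths_nm), x$mode,
    if (nzchar(x$instrument_label)) paste0(", ", x$instrument_label) else ""
  ))
  cat(sprintf("  %d cows\n", dplyr::n_distinct(x$meta$cow_id)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Validate a composition table
#'
#' A composition table is a tibble with a `sample_id` column and one numeric
#' column per milk component (conventionally `fat_pct`, `protein_pct`,
#' `lactose_pct`, all % w/w).  Values must lie strictly between 0 and 100 and
#' sample identifiers must be unique.
#'
#' @param comp data frame with `sample_id` plus numeric component columns.
#' @return The validated table as a tibble (invisibly unchanged content).
#' @export
composition_table <- function(comp) {
  comp <- tibble::as_tibble(comp)
  if (!"sample_id" %in% names(comp)) {
    stopf("composition table must have a 'sample_id' column",
          class = "nirmilk_schema_error")
  }
  comp$sample_id <- as.character(comp$sample_id)
  if (anyDuplicated(comp$sample_id)) {
    stopf("duplicate sample_id in composition table: %s",
          paste(unique(comp$sample_id[duplicated(comp$sample_id)]), collapse = ", "),
          class = "nirmilk_schema_error")
  }
  comps <- composition_components(comp)
  if (length(comps) == 0) {
    stopf("composition table has no component columns",
          class = "nirmilk_schema_error")
  }
  for (cc in comps) {
    v <- comp[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v <= 0) || any(v >= 100)) {
      stopf("component '%s' must be numeric, strictly between 0 and 100 %% w/w",
            cc, class = "nirmilk_schema_error")
    }
  }
  comp
}

composition_components <- function(comp) {
  setdiff(names(comp), c("sample_id", "cow_id", "set"))
}

#' Instrument wavelength window
#'
#' @param name label, e.g. `"NIRONE 2.0 T"`.
#' @param lo_nm,hi_nm window bounds in nm, `lo_nm < hi_nm`.
#' @param geometry `"transmittance"` or `"reflectance"`.
#' @return list of class `instrument_window`.
#' @export
instrument_window <- function(name, lo_nm, hi_nm,
                              geometry = c("transmittance", "reflectance")) {
  geometry <- match.arg(geometry)
  if (!(is.numeric(lo_nm) && is.numeric(hi_nm) && lo_nm < hi_nm)) {
    stopf("need lo_nm < hi_nm")
  }
  structure(list(name = name, lo_nm = lo_nm, hi_nm = hi_nm,
                 geometry = geometry),
            class = "instrument_window")
}

#' Wavelength windows of the five emulated spectrometer configurations
#'
#' Miniature MEMS modules cover narrow NIR windows (1100-1400, 1550-1950 and
#' 2000-2450 nm, transmittance, plus 1550-1950 nm reflectance); the benchtop
#' reference covers 960-1690 nm.
#'
#' @return named list of [instrument_window()] objects.
#' @export
instrument_windows <- function() {
  list(
    nirone_1.4_T = instrument_window("NIRONE 1.4 T", 1100, 1400, "transmittance"),
    nirone_2.0_T = instrument_window("NIRONE 2.0 T", 1550, 1950, "transmittance"),
    nirone_2.5_T = instrument_window("NIRONE 2.5 T", 2000, 2450, "transmittance"),
    nirone_2.0_R = instrument_window("NIRONE 2.0 R", 1550, 1950, "reflectance"),
    tec5_T       = instrument_window("TEC5 T",        960, 1690, "transmittance")
  )
}

#' White/dark standard correction
#'
#' Converts raw detector counts to transmittance (or reflectance) using the
#' most recent white and dark reference spectra:
#' `(S - D) / (W - D)` elementwise.
#'
#' @param sample_raw numeric matrix (or vector) of raw sample spectra.
#' @param white_raw,dark_raw numeric vectors on the same wavelength grid.
#' @return corrected matrix with the dimensions of `sample_raw`.
#' @export
standard_correct <- function(sample_raw, white_raw, dark_raw) {
  S <- as_matrix(sample_raw)
  white_raw <- as.numeric(white_raw)
  dark_raw <- as.numeric(dark_raw)
  if (length(white_raw) != ncol(S) || length(dark_raw) != ncol(S)) {
    stopf("white/dark references must share the sample wavelength grid (%d points)",
          ncol(S))
  }
  denom <- white_raw - dark_raw
  bad <- which(denom == 0)
  if (length(bad)) {
    stopf("degenerate white/dark reference (W == D) at wavelength index %s",
          paste(bad, collapse = ", "), class = "nirmilk_degenerate_reference")
  }
  sweep(sweep(S, 2, dark_raw, `-`), 2, denom, `/`)
}

#' Average replicate scans
#'
#' Elementwise arithmetic mean of k replicate spectra of one sample (typically
#' 20 subsequent scans).
#'
#' @param scans matrix with one row per replicate scan.
#' @return numeric vector, the mean spectrum.
#' @export
average_scans <- function(scans) {
  scans <- as_matrix(scans)
  if (nrow(scans) == 0) stopf("no scans to average", class = "nirmilk_empty_input")
  colMeans(scans)
}

#' Restrict a dataset to an instrument window
#'
#' Keeps the wavelengths lying in the closed interval `[lo_nm, hi_nm]`.
#'
#' @param ds a [spectral_dataset()].
#' @param window an [instrument_window()].
#' @return a `spectral_dataset` on the restricted grid.
#' @export
restrict_wavelengths <- function(ds, window) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(window, "instrument_window"))
  keep <- ds$wavelengths_nm >= window$lo_nm & ds$wavelengths_nm <= window$hi_nm
  if (!any(keep)) {
    stopf("window [%g, %g] nm does not overlap the dataset grid (%g-%g nm)",
          window$lo_nm, window$hi_nm,
          min(ds$wavelengths_nm), max(ds$wavelengths_nm),
          class = "nirmilk_empty_window")
  }
  ds$wavelengths_nm <- ds$wavelengths_nm[keep]
  ds$intensities <- ds$intensities[, keep, drop = FALSE]
  ds
}

#' Read / write the canonical CSV interchange format
#'
#' Spectra CSV: header `sample_id,cow_id,mode,<wl1>,<wl2>,...` with wavelength
#' headers as decimal nm, one row per sample.  Composition CSV: header
#' `sample_id,<component>_pct,...`.
#'
#' @param spectra_path,composition_path CSV file paths.
#' @param strict if `TRUE` (default) samples present in only one of the two
#'   files raise an error; if `FALSE` they are dropped with a warning.
#' @return `read_dataset()` returns `list(dataset, composition)` with samples
#'   aligned in file order of the spectra file.
#' @export
read_dataset <- function(spectra_path, composition_path, strict = TRUE) {
  ds <- read_spectra(spectra_path)
  comp <- read_compositions(composition_path)
  only_s <- setdiff(ds$meta$sample_id, comp$sample_id)
  only_c <- setdiff(comp$sample_id, ds$meta$sample_id)
  if (length(only_s) || length(only_c)) {
    msg <- sprintf("unmatched samples: %d spectra-only, %d composition-only",
                   length(only_s), length(only_c))
    if (strict) stopf("%s", msg, class = "nirmilk_schema_error")
    warn(msg)
    keep <- ds$meta$sample_id %in% comp$sample_id
    ds$intensities <- ds$intensities[keep, , drop = FALSE]
    ds$meta <- ds$meta[keep, ]
  }
  comp <- comp[match(ds$meta$sample_id, comp$sample_id), ]
  list(dataset = ds, composition = comp)
}

#' @rdname read_dataset
#' @export
read_spectra <- function(spectra_path) {
  df <- readr::read_csv(spectra_path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "cow_id", "mode")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stopf("spectra CSV missing column(s): %s", paste(miss, collapse = ", "),
          class = "nirmilk_schema_error")
  }
  wl_cols <- setdiff(names(df), need)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stopf("non-numeric wavelength header(s): %s",
          paste(wl_cols[is.na(wl)], collapse = ", "),
          class = "nirmilk_schema_error")
  }
  mode <- unique(df$mode)
  if (length(mode) != 1) {
    stopf("spectra CSV mixes acquisition modes: %s",
          paste(mode, collapse = ", "), class = "nirmilk_schema_error")
  }
  spectral_dataset(
    intensities = as.matrix(df[wl_cols]),
    wavelengths_nm = wl,
    sample_ids = df$sample_id,
    cow_ids = df$cow_id,
    mode = mode
  )
}

#' @rdname read_dataset
#' @export
read_compositions <- function(composition_path) {
  df <- readr::read_csv(composition_path, show_col_types = FALSE, progress = FALSE)
  composition_table(df)
}

#' @rdname read_dataset
#' @param ds a [spectral_dataset()] to write.
#' @param path output CSV path.
#' @export
write_spectra <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  X <- ds$intensities
  colnames(X) <- format(ds$wavelengths_nm, trim = TRUE, digits = 15,
                        scientific = FALSE)
  out <- dplyr::bind_cols(
    ds$meta,
    tibble::tibble(mode = ds$mode),
    tibble::as_tibble(X, .name_repair = "minimal")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname read_dataset
#' @param comp a composition table to write.
#' @export
write_compositions <- function(comp, path) {
  readr::write_csv(composition_table(comp), path)
  invisible(path)
}
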