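#' Autoscale a composition table
#'
#' Each component column is centered to mean 0 and scaled to SD 1 (sample
#' SD).
#'
#' @param composition a composition table (see [composition_table()]).
#' @return numeric matrix, one column per component.
#' @export
autoscale <- function(composition) {
  comp <- tibble::as_tibble(composition)
  comps <- composition_components(comp)
  M <- as.matrix(comp[comps])
  s <- apply(M, 2, stats::sd)
  if (any(s == 0)) {
    stopf("zero-variance component column: %s",
          paste(comps[s == 0], collapse = ", "),
          class = "nirmilk_degenerate_response")
  }
  scale(M, center = TRUE, scale = s)[, , drop = FALSE]
}

# Snee-style duplex assignment on a points matrix (rows = cows, in autoscaled
# composition space).  Calibration is seeded with the farthest pair, the
# validation set with the farthest remaining pair; thereafter points are
# assigned in repeating rounds of (2 to calibration, 1 to validation), each
# assignment taking the unassigned point with the largest minimum Euclidean
# distance to the receiving set.  A set stops receiving once it reaches its
# target size (n_val = floor(n / 3), leftover to calibration).  Ties break to
# the lowest row index.
duplex_assign <- function(points) {
  n <- nrow(points)
  n_val <- floor(n / 3)
  n_cal <- n - n_val
  D <- as.matrix(stats::dist(points))
  assigned <- rep(NA_character_, n)
  remaining <- function() which(is.na(assigned))

  farthest_pair <- function(idx) {
    sub <- D[idx, idx, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # lowest indices on ties
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    idx[best[1, ]]
  }
  seed_set <- function(set, target) {
    idx <- remaining()
    take <- min(2L, target, length(idx))
    if (take == 2L && length(idx) >= 2L) {
      assigned[farthest_pair(idx)] <<- set
    } else if (take >= 1L) {
      assigned[idx[1]] <<- set
    }
  }
  assign_next <- function(set) {
    idx <- remaining()
    if (length(idx) == 0) return(invisible())
    members <- which(assigned == set)
    d_min <- apply(D[idx, members, drop = FALSE], 1, min)
    pick <- idx[which.max(d_min)]          # which.max -> lowest index on ties
    assigned[pick] <<- set
  }

  seed_set("cal", n_cal)
  seed_set("val", n_val)
  while (length(remaining()) > 0) {
    for (k in 1:2) {
      if (sum(assigned == "cal", na.rm = TRUE) < n_cal) assign_next("cal")
    }
    if (sum(assigned == "val", na.rm = TRUE) < n_val) assign_next("val")
  }
  assigned
}

#' Cow-blocked duplex split into calibration and validation sets
#'
#' Each cow is represented by the mean of its autoscaled sample
#' compositions; the Snee duplex algorithm assigns cows (not samples) to the
#' two sets in a 2:1 cycle after farthest-pair seeding, so roughly 2/3 of
#' cows calibrate and 1/3 validate, both sets spanning the composition space.
#' All samples of a cow follow the cow (block integrity).  Deterministic:
#' ties break to the lowest cow index in input order.
#'
#' @param composition composition table including a `cow_id` column (as
#'   produced by [simulate_milk()]), or a plain composition table plus
#'   `cow_ids`.
#' @param cow_ids per-sample cow identifiers (ignored if `composition` has a
#'   `cow_id` column).
#' @return object of class `split_result`: list with
#'   `assignment` (tibble `sample_id`, `cow_id`, `set`), `calibration_cows`,
#'   `validation_cows`, and `stats` (per set x component descriptive
#'   statistics).
#' @export
duplex_split <- function(composition, cow_ids = NULL) {
  comp <- tibble::as_tibble(composition)
  if (!"cow_id" %in% names(comp)) {
    if (is.null(cow_ids)) stopf("need a cow_id column or cow_ids")
    comp$cow_id <- as.character(cow_ids)
  }
  cows <- unique(comp$cow_id)
  if (length(cows) < 3) stopf("duplex needs at least 3 cows")
  Z <- autoscale(comp)
  cow_means <- rowsum(Z, group = comp$cow_id, reorder = FALSE) /
    as.vector(table(factor(comp$cow_id, levels = unique(comp$cow_id))))
  cow_means <- cow_means[cows, , drop = FALSE]
  set_of_cow <- duplex_assign(cow_means)
  names(set_of_cow) <- cows
  assignment <- tibble::tibble(
    sample_id = comp$sample_id,
    cow_id = comp$cow_id,
    set = unname(set_of_cow[comp$cow_id])
  )
  stats <- comp |>
    dplyr::mutate(set = assignment$set) |>
    split_stats()
  structure(
    list(assignment = assignment,
         calibration_cows = cows[set_of_cow == "cal"],
         validation_cows = cows[set_of_cow == "val"],
         stats = stats),
    class = "split_result"
  )
}

# descriptive statistics per set and component, mirroring the usual
# calibration-report layout (mean, SD, min, max)
split_stats <- function(comp_with_set) {
  comps <- composition_components(comp_with_set)
  comp_with_set |>
    dplyr::bind_rows(dplyr::mutate(comp_with_set, set = "all")) |>
    tidyr::pivot_longer(dplyr::all_of(comps), names_to = "component") |>
    dplyr::group_by(.data$set, .data$component) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      min = min(.data$value), max = max(.data$value),
      .groups = "drop"
    )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration cows (%d samples), %d validation cows (%d samples)\n",
              length(x$calibration_cows), sum(x$assignment$set == "cal"),
              length(x$validation_cows), sum(x$assignment$set == "val")))
  print(x$stats)
  invisible(x)
}

#' Write a split assignment CSV
#'
#' Two columns, `sample_id` and `set` (`cal`/`val`).
#'
#' @param split a `split_result`.
#' @param path output path.
#' @export
write_split <- function(split, path) {
  readr::write_csv(split$assignment[c("sample_id", "set")], path)
  invisible(path)
}
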