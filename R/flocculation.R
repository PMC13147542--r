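#' Multi-point scan of a single well
#'
#' A plate reader measuring optical density at `n x n` locations inside one
#' well (up to 15 x 15 = 225 points). Flocs distribute cells unevenly, so
#' the spatial heterogeneity of these readings carries the flocculation
#' signal.
#'
#' @param well_id well label, e.g. `"A1"` .. `"H12"`.
#' @param readings numeric vector of length `n^2` or an `n x n` matrix of
#'   OD600 values (finite).
#' @param n declared side length (>= 2).
#' @return An object of class `well_scan`.
#' @export
well_scan <- function(well_id, readings, n) {
  readings <- matrix(as.numeric(readings), n, n)
  stopifnot(n >= 2, all(is.finite(readings)))
  structure(list(well_id = well_id, readings = readings, n = n),
            class = "well_scan")
}

#' Plate of well scans
#'
#' @param wells list of [well_scan()]s with unique ids.
#' @param control_well id of the negative-control (empty media) well.
#' @return An object of class `plate_scan`.
#' @export
plate_scan <- function(wells, control_well) {
  ids <- vapply(wells, `[[`, character(1), "well_id")
  if (anyDuplicated(ids)) stop("duplicated well ids")
  if (!control_well %in% ids)
    stop("control well ", control_well, " not present on the plate")
  names(wells) <- ids
  structure(list(wells = wells, control_well = control_well),
            class = "plate_scan")
}

#' Parse a multi-point plate-reader scan CSV
#'
#' One row per well: the well id followed by `n^2` comma-separated OD600
#' readings (row-major within the well). `n` is the square root of the
#' number of measurements per well, e.g. 15 for a 15 x 15 scan, and is used
#' to validate the rows.
#'
#' @param path CSV path.
#' @param n side length of the per-well measurement grid.
#' @param control_well id of the negative-control well (default `"H12"`).
#' @return A [plate_scan()].
#' @export
parse_scan_csv <- function(path, n, control_well = "H12") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  wells <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, ",")[[1]])
    id <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (length(vals) != n * n || anyNA(vals))
      stop(sprintf("well %s: expected %d numeric readings, got %d",
                   id, n * n, length(vals)))
    well_scan(id, vals, n)
  })
  plate_scan(wells, control_well)
}

#' Write a plate scan in the package's CSV dialect
#'
#' @param plate a [plate_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(plate, path) {
  lines <- vapply(plate$wells, function(w) {
    paste(c(w$well_id, format(as.vector(w$readings), trim = TRUE,
                              scientific = FALSE, digits = 15)),
          collapse = ",")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Subtract the negative-control background from every well
#'
#' The mean OD600 of the negative-control well estimates background light
#' absorption of media and plastic; it is subtracted from every reading of
#' every well, so the corrected control well has mean 0.
#'
#' @param plate a [plate_scan()].
#' @return A [plate_scan()] with corrected readings.
#' @export
background_subtract <- function(plate) {
  stopifnot(inherits(plate, "plate_scan"))
  bg <- mean(plate$wells[[plate$control_well]]$readings)
  wells <- lapply(plate$wells, function(w) {
    w$readings <- w$readings - bg
    w
  })
  plate_scan(wells, plate$control_well)
}

#' Flocculation score of one well: the coefficient of variation
#'
#' CV = standard deviation / mean of the background-corrected multi-point
#' OD600 readings. Flocs concentrate biomass in a few spots, inflating the
#' spatial standard deviation relative to the mean. The well's readings are
#' treated as the complete measurement population, so the population
#' standard deviation (divisor `n^2`) is used by default.
#'
#' @param well a [well_scan()] with background-corrected readings.
#' @param population use the population standard deviation (default `TRUE`);
#'   set `FALSE` for the sample (n-1) convention.
#' @return list of class `floc_score`: `well_id`, `mean_od`, `cv` (NA when
#'   the corrected mean is not positive), `flagged`.
#' @export
flocculation_cv <- function(well, population = TRUE) {
  stopifnot(inherits(well, "well_scan"))
  x <- as.vector(well$readings)
  m <- mean(x)
  if (m <= 0) {
    message("well ", well$well_id,
            ": non-positive corrected mean OD; CV undefined")
    return(structure(list(well_id = well$well_id, mean_od = m,
                          cv = NA_real_, flagged = TRUE),
                     class = "floc_score"))
  }
  s <- if (population) sqrt(mean((x - m)^2)) else sd(x)
  structure(list(well_id = well$well_id, mean_od = m, cv = s / m,
                 flagged = FALSE),
            class = "floc_score")
}

#' Score flocculation for a whole plate
#'
#' Background-subtracts the plate, computes the per-well CV, and joins
#' strain labels from the plate map.
#'
#' @param plate a [plate_scan()].
#' @param strain_map optional 8 x 12 character matrix ([read_strain_map()]);
#'   well ids are interpreted as letter-row + number-column (`"A1"`).
#' @return data.frame with columns `well`, `strain`, `mean_od`, `cv`,
#'   `flagged`.
#' @export
score_plate_flocculation <- function(plate, strain_map = NULL) {
  corrected <- background_subtract(plate)
  rows <- lapply(corrected$wells, function(w) {
    s <- suppressMessages(flocculation_cv(w))
    data.frame(well = s$well_id, mean_od = s$mean_od, cv = s$cv,
               flagged = s$flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(strain_map)) {
    r <- match(substr(out$well, 1, 1), LETTERS[1:8])
    c <- as.integer(substring(out$well, 2))
    out$strain <- strain_map[cbind(r, c)]
    out <- out[, c("well", "strain", "mean_od", "cv", "flagged")]
  }
  out
}

#' Flocculating fraction from the filtering assay
#'
#' In the filter-based assay a culture is poured through a 30 um filter:
#' free cells pass into tube A, flocs are retained and resuspended into
#' tube B. The flocculating fraction is `OD(B) / (OD(A) + OD(B))`.
#'
#' @param od_a OD600 of the flow-through (nonflocculating cells).
#' @param od_b OD600 of the retained, resuspended flocs.
#' @return fraction in `[0, 1]`.
#' @export
filtering_fraction <- function(od_a, od_b) {
  stopifnot(od_a >= 0, od_b >= 0)
  if (od_a + od_b == 0) stop("both OD readings are zero: no biomass")
  od_b / (od_a + od_b)
}
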