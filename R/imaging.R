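#' Grayscale plate image
#'
#' Lightweight container for a scanned plate: a matrix of pixel intensities
#' plus the maximum representable intensity (`white_level`, e.g. 255 for
#' 8-bit scans). High cell density corresponds to *low* intensity on a
#' transmitted-light flatbed scan, so all downstream densitometry works on
#' the inverse intensity `white_level - pixel`.
#'
#' @param pixels numeric matrix of intensities, values in `[0, white_level]`.
#' @param white_level maximum representable intensity (default 255).
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(pixels, white_level = 255) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), length(pixels) > 0, white_level > 0)
  if (min(pixels) < 0 || max(pixels) > white_level)
    stop("pixel values must lie in [0, white_level]")
  structure(list(pixels = pixels, white_level = white_level),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, white_level %g>\n",
              nrow(x$pixels), ncol(x$pixels), x$white_level))
  invisible(x)
}

#' Read a plate scan from PNG or TIFF
#'
#' RGB images are converted to luminance (0.2126 R + 0.7152 G + 0.0722 B)
#' before anything else; an alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param white_level intensity scale of the returned image (default 255).
#' @return A [gray_image()].
#' @export
read_plate_image <- function(path, white_level = 255) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3) {
      0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  gray_image(arr * white_level, white_level = white_level)
}

#' Write a plate image to PNG
#'
#' @param image a [gray_image()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(image$pixels / image$white_level, path)
  invisible(path)
}

#' Normalized inverse pixel intensity
#'
#' Converts a scan into a density image: each pixel becomes
#' `(white_level - pixel) / max(white_level - pixel)`, so the darkest pixel
#' on the image maps to exactly 1 and a pure-white pixel to 0. Rescaling by
#' the per-image maximum makes colony densities comparable between scans
#' (including the rare case where a scanner reports slightly darker colonies
#' after washing).
#'
#' @param image a [gray_image()].
#' @return numeric matrix with values in `[0, 1]`.
#' @export
invert_normalize <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  inv <- image$white_level - image$pixels
  m <- max(inv)
  if (m <= 0) {
    warning("image is uniformly at white_level; returning all zeros")
    return(inv * 0)
  }
  inv / m
}

#' 96-position plate layout
#'
#' The pixel-space segmentation grid: `n_rows * n_cols` non-overlapping
#' rectangular boxes (half-open, 0-based pixel coordinates) plus a logical
#' mask marking the perimeter positions. Colonies grown at plate edges are
#' more adhesive and less reliable, so analyses can restrict to the interior
#' (the "middle 60" of a 96-position plate).
#'
#' @param boxes data.frame with columns `row`, `col` (1-based grid indices)
#'   and `top`, `left`, `bottom`, `right` (half-open, 0-based pixels).
#' @param n_rows,n_cols grid dimensions (default 8 x 12).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(boxes, n_rows = 8, n_cols = 12) {
  stopifnot(nrow(boxes) == n_rows * n_cols,
            all(boxes$bottom > boxes$top), all(boxes$right > boxes$left))
  boxes$edge <- boxes$row %in% c(1L, n_rows) | boxes$col %in% c(1L, n_cols)
  structure(list(n_rows = n_rows, n_cols = n_cols, boxes = boxes),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout %d x %d, %d boxes (%d edge)>\n",
              x$n_rows, x$n_cols, nrow(x$boxes), sum(x$boxes$edge)))
  invisible(x)
}

# run detection on a 1-D projection profile: contiguous stretches above the
# mid-level between the profile's min and max
.profile_runs <- function(profile) {
  thr <- (min(profile) + max(profile)) / 2
  above <- profile > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(which(keep), function(i) {
               sum(profile[starts[i]:ends[i]])
             }, numeric(1)))
}

# pick the n most massive runs; centers (0-based) sorted by position, plus
# the median run width (the apparent colony extent along this axis)
.run_centers <- function(runs, n, axis) {
  if (nrow(runs) < n)
    stop(sprintf("layout construction failed: found %d density peaks along the %s axis, need %d",
                 nrow(runs), axis, n))
  runs <- runs[order(runs$mass, decreasing = TRUE), , drop = FALSE][seq_len(n), ]
  list(centers = sort((runs$start + runs$end) / 2 - 1),
       width = median(runs$end - runs$start + 1))
}

#' Build the raw 96-position layout from a filled-out plate
#'
#' Takes an example plate on which every position carries a growing colony,
#' projects the inverted image onto each axis, detects the `n_rows`
#' (`n_cols`) strongest periodic density peaks, and places an equal-pitch
#' grid of boxes centred on them. The resulting raw layout is then fitted to
#' each analysis image with [fit_layout()].
#'
#' @param filled_image a [gray_image()] with colonies at every position.
#' @param n_rows,n_cols grid dimensions (default 8 x 12).
#' @return A [plate_layout()].
#' @export
build_reference_layout <- function(filled_image, n_rows = 8, n_cols = 12) {
  inv <- invert_normalize(filled_image)
  smooth5 <- function(x) as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2,
                                                  circular = TRUE))
  rprof <- smooth5(rowMeans(inv))
  cprof <- smooth5(colMeans(inv))
  rruns <- .run_centers(.profile_runs(rprof), n_rows, "row")
  cruns <- .run_centers(.profile_runs(cprof), n_cols, "column")
  # enforce an exactly regular pitch by least-squares line through the centers
  regularize <- function(centers) {
    idx <- seq_along(centers)
    fit <- stats::lm.fit(cbind(1, idx), centers)
    as.numeric(cbind(1, idx) %*% fit$coefficients)
  }
  rc <- regularize(rruns$centers)
  cc <- regularize(cruns$centers)
  # boxes hug the detected colony extent (never overlapping the next box):
  # a box matched to the colony makes the translation fit sharply peaked
  rhalf <- min(floor(rruns$width / 2), floor(min(diff(rc)) / 2))
  chalf <- min(floor(cruns$width / 2), floor(min(diff(cc)) / 2))
  if (rhalf < 1 || chalf < 1) stop("detected grid pitch is degenerate")
  grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  boxes <- data.frame(
    row = grid$row, col = grid$col,
    top = round(rc[grid$row]) - rhalf,
    left = round(cc[grid$col]) - chalf,
    bottom = round(rc[grid$row]) + rhalf,
    right = round(cc[grid$col]) + chalf
  )
  boxes$top <- pmax(boxes$top, 0)
  boxes$left <- pmax(boxes$left, 0)
  boxes$bottom <- pmin(boxes$bottom, nrow(inv))
  boxes$right <- pmin(boxes$right, ncol(inv))
  plate_layout(boxes, n_rows, n_cols)
}

# summed-area table; .sat_box_sums returns per-box sums for boxes shifted by
# (dy, dx), half-open 0-based coordinates
.sat <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

.sat_box_sums <- function(S, boxes, dy = 0, dx = 0) {
  t <- boxes$top + dy; b <- boxes$bottom + dy
  l <- boxes$left + dx; r <- boxes$right + dx
  S[cbind(b + 1, r + 1)] - S[cbind(t + 1, r + 1)] -
    S[cbind(b + 1, l + 1)] + S[cbind(t + 1, l + 1)]
}

#' Fit a reference layout to an image
#'
#' Searches integer-pixel translations up to `max_shift_px` per axis and
#' returns the layout shifted by the offset that maximizes total in-box
#' inverse intensity. Flatbed scans are rigid, so no rotation or scaling is
#' attempted. Fit the layout to each *prewash* image and reuse the fitted
#' layout for the matching postwash image: pre/post pairs are assumed not to
#' be misaligned with respect to each other.
#'
#' @param layout a [plate_layout()] from [build_reference_layout()].
#' @param image the [gray_image()] to fit to.
#' @param max_shift_px maximum translation searched per axis (default 20).
#' @return The shifted [plate_layout()]; the chosen `(dy, dx)` offset is
#'   attached as attribute `"offset"`. A warning is raised when the best
#'   offset lies on the search boundary (possible larger misalignment).
#' @export
fit_layout <- function(layout, image, max_shift_px = 20) {
  stopifnot(inherits(layout, "plate_layout"), inherits(image, "gray_image"))
  inv <- image$white_level - image$pixels
  S <- .sat(inv)
  b <- layout$boxes
  nr <- nrow(inv); nc <- ncol(inv)
  offs <- expand.grid(dy = -max_shift_px:max_shift_px,
                      dx = -max_shift_px:max_shift_px)
  # deterministic tie-break: prefer small offsets
  offs <- offs[order(abs(offs$dy) + abs(offs$dx), offs$dy, offs$dx), ]
  best <- c(0, 0); best_score <- -Inf
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    if (min(b$top) + dy < 0 || max(b$bottom) + dy > nr ||
        min(b$left) + dx < 0 || max(b$right) + dx > nc) next
    score <- sum(.sat_box_sums(S, b, dy, dx))
    if (score > best_score) {
      best_score <- score
      best <- c(dy, dx)
    }
  }
  if (!is.finite(best_score))
    stop("layout does not fit inside the image at any searched offset")
  if (any(abs(best) == max_shift_px))
    warning("best-fitting offset lies on the search boundary; ",
            "the image may be misaligned by more than max_shift_px")
  b$top <- b$top + best[1]; b$bottom <- b$bottom + best[1]
  b$left <- b$left + best[2]; b$right <- b$right + best[2]
  out <- plate_layout(b, layout$n_rows, layout$n_cols)
  attr(out, "offset") <- best
  out
}

#' Per-position density grid
#'
#' @param values matrix of background-corrected normalized densities.
#' @param control_positions 2-column matrix of (row, col) control positions.
#' @param background scalar background that was subtracted.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, control_positions, background) {
  stopifnot(is.matrix(values), nrow(control_positions) >= 1)
  structure(list(values = values,
                 control_positions = control_positions,
                 background = background),
            class = "density_grid")
}

#' Measure colony densities on a fitted layout
#'
#' Computes the mean normalized inverse intensity inside each layout box,
#' then subtracts the mean over the negative-control (empty) boxes as a
#' background estimate, flooring at 0. At least one empty control square per
#' plate is required.
#'
#' @param image a [gray_image()].
#' @param layout a fitted [plate_layout()].
#' @param controls 2-column matrix or data.frame of (row, col) grid indices
#'   of the empty control positions.
#' @param inner_margin pixels eroded from every box side before averaging
#'   (default 2), so means are taken over the colony interior and are
#'   insensitive to soft colony edges and residual 1-px misalignment.
#' @return A [density_grid()] with values in `[0, 1]`.
#' @export
measure_grid <- function(image, layout, controls, inner_margin = 2) {
  stopifnot(inherits(image, "gray_image"), inherits(layout, "plate_layout"))
  controls <- as.matrix(controls)
  if (nrow(controls) == 0)
    stop("at least one negative control (empty square) is required per plate")
  norm <- invert_normalize(image)
  b <- layout$boxes
  shrink <- min(inner_margin,
                floor((min(b$bottom - b$top) - 2) / 2),
                floor((min(b$right - b$left) - 2) / 2))
  if (shrink > 0) {
    b$top <- b$top + shrink; b$bottom <- b$bottom - shrink
    b$left <- b$left + shrink; b$right <- b$right - shrink
  }
  if (min(b$top) < 0 || min(b$left) < 0 ||
      max(b$bottom) > nrow(norm) || max(b$right) > ncol(norm))
    stop("layout does not fit inside the image")
  sums <- .sat_box_sums(.sat(norm), b)
  areas <- (b$bottom - b$top) * (b$right - b$left)
  means <- matrix(NA_real_, layout$n_rows, layout$n_cols)
  means[cbind(b$row, b$col)] <- sums / areas
  ctrl_idx <- cbind(as.integer(controls[, 1]), as.integer(controls[, 2]))
  if (any(ctrl_idx[, 1] < 1 | ctrl_idx[, 1] > layout$n_rows |
          ctrl_idx[, 2] < 1 | ctrl_idx[, 2] > layout$n_cols))
    stop("control position outside the grid")
  background <- mean(means[ctrl_idx])
  density_grid(pmax(means - background, 0), ctrl_idx, background)
}

#' Adhesion ratios from a pre/post-wash pair
#'
#' The adhesion ratio of a position is its background-corrected density
#' after washing divided by the density before washing -- the fraction of
#' colony material that stuck to the agar. Positions with prewash density
#' below `growth_min` are flagged as not growing and get no ratio. Ratios
#' above 1 (scanner artefact) are reported as-is and flagged.
#'
#' @param pre,post [density_grid()]s measured with the *same* fitted layout.
#' @param growth_min minimum prewash normalized density for a position to
#'   count as growing (default 0.1).
#' @return data.frame with one row per position: `row`, `col`,
#'   `pre_density`, `post_density`, `grew`, `ratio`, `flagged_gt1`.
#' @export
adhesion_from_pair <- function(pre, post, growth_min = 0.1) {
  stopifnot(inherits(pre, "density_grid"), inherits(post, "density_grid"))
  if (!identical(dim(pre$values), dim(post$values)))
    stop("pre and post grids have mismatched shapes")
  nr <- nrow(pre$values); nc <- ncol(pre$values)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  p <- pre$values[cbind(grid$row, grid$col)]
  q <- post$values[cbind(grid$row, grid$col)]
  grew <- p >= growth_min
  ratio <- ifelse(grew, q / p, NA_real_)
  data.frame(row = grid$row, col = grid$col,
             pre_density = p, post_density = q,
             grew = grew, ratio = ratio,
             flagged_gt1 = !is.na(ratio) & ratio > 1)
}

#' Read a 96-well strain map
#'
#' An 8-row by 12-column CSV of strain labels; the reserved token `EMPTY`
#' marks negative-control squares.
#'
#' @param path CSV path (no header).
#' @return 8 x 12 character matrix.
#' @export
read_strain_map <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE, colClasses = "character"))
  dimnames(m) <- NULL
  if (nrow(m) != 8 || ncol(m) != 12)
    stop("strain map must be 8 rows x 12 columns")
  trimws(m)
}

#' Summarize adhesion records per strain
#'
#' Aggregates per-position adhesion records across replicate plates into
#' per-strain summaries. Strains whose mean prewash density falls below
#' `growth_min` are marked excluded from downstream analysis; with
#' `interior_only = TRUE`, perimeter positions (the 36 edge squares of a
#' 96-position plate) are dropped before summarizing because edge colonies
#' are unreliably adhesive.
#'
#' @param records data.frame as returned by [adhesion_from_pair()], with an
#'   additional `plate` column when several plates are combined.
#' @param strain_map 8 x 12 character matrix from [read_strain_map()];
#'   `EMPTY` squares are dropped.
#' @param growth_min exclusion threshold on the strain's mean prewash
#'   density (default 0.1).
#' @param interior_only drop perimeter positions first (default `FALSE`).
#' @return data.frame with one row per strain: `strain`, `n_replicates`,
#'   `n_valid`, `mean_pre`, `mean_ratio`, `excluded`.
#' @export
summarize_strain <- function(records, strain_map, growth_min = 0.1,
                             interior_only = FALSE) {
  stopifnot(is.matrix(strain_map))
  bad <- records$row < 1 | records$row > nrow(strain_map) |
    records$col < 1 | records$col > ncol(strain_map)
  if (any(bad))
    stop("records at positions outside the strain map: ",
         paste(sprintf("(%d,%d)", records$row[bad], records$col[bad]),
               collapse = ", "))
  records$strain <- strain_map[cbind(records$row, records$col)]
  unmapped <- is.na(records$strain) | records$strain == ""
  if (any(unmapped))
    stop("no strain mapped at positions: ",
         paste(sprintf("(%d,%d)", records$row[unmapped],
                       records$col[unmapped]), collapse = ", "))
  if (interior_only) {
    edge <- records$row %in% c(1L, nrow(strain_map)) |
      records$col %in% c(1L, ncol(strain_map))
    records <- records[!edge, , drop = FALSE]
  }
  records <- records[records$strain != "EMPTY", , drop = FALSE]
  out <- do.call(rbind, lapply(split(records, records$strain), function(d) {
    valid <- d$grew
    data.frame(strain = d$strain[1],
               n_replicates = nrow(d),
               n_valid = sum(valid),
               mean_pre = mean(d$pre_density),
               mean_ratio = if (any(valid)) mean(d$ratio[valid]) else NA_real_)
  }))
  out$excluded <- out$mean_pre < growth_min
  rownames(out) <- NULL
  out[order(out$strain), ]
}

#' Quantify adhesion for folders of pre/post-wash scans
#'
#' End-to-end wrapper: builds the raw layout from the filled-out example
#' plate, fits it to each prewash image, reuses the fitted layout for the
#' lexicographically matching postwash image, measures background-corrected
#' densities (controls taken from the `EMPTY` squares of the strain map),
#' and returns per-position adhesion records.
#'
#' @param pre_dir,post_dir folders of prewash/postwash images; file names
#'   must match one-to-one between the folders.
#' @param strain_map 8 x 12 character matrix from [read_strain_map()].
#' @param filled_image [gray_image()] of the filled-out example plate.
#' @param growth_min not-growing threshold (default 0.1).
#' @param max_shift_px layout fitting search radius (default 20).
#' @return data.frame with columns `plate`, `row`, `col`, `strain`,
#'   `pre_density`, `post_density`, `ratio`, `grew`, `excluded_edge`.
#' @export
quantify_adhesion <- function(pre_dir, post_dir, strain_map, filled_image,
                              growth_min = 0.1, max_shift_px = 20) {
  pre_files <- sort(list.files(pre_dir, pattern = "\\.(png|tiff?)$",
                               ignore.case = TRUE))
  post_files <- sort(list.files(post_dir, pattern = "\\.(png|tiff?)$",
                                ignore.case = TRUE))
  if (!identical(pre_files, post_files))
    stop("pre and post folders do not contain matching file names")
  if (length(pre_files) == 0) stop("no images found")
  layout0 <- build_reference_layout(filled_image)
  controls <- which(strain_map == "EMPTY", arr.ind = TRUE)
  out <- lapply(pre_files, function(f) {
    pre_img <- read_plate_image(file.path(pre_dir, f))
    post_img <- read_plate_image(file.path(post_dir, f))
    fitted <- fit_layout(layout0, pre_img, max_shift_px)
    pre_g <- measure_grid(pre_img, fitted, controls)
    post_g <- measure_grid(post_img, fitted, controls)
    rec <- adhesion_from_pair(pre_g, post_g, growth_min)
    rec$plate <- f
    rec$strain <- strain_map[cbind(rec$row, rec$col)]
    rec$excluded_edge <- rec$row %in% c(1L, nrow(strain_map)) |
      rec$col %in% c(1L, ncol(strain_map))
    rec
  })
  out <- do.call(rbind, out)
  out[, c("plate", "row", "col", "strain", "pre_density", "post_density",
          "ratio", "grew", "excluded_edge")]
}
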