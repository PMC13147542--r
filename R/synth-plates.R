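#' Specification of a synthetic plate-image pair
#'
#' Describes a rendered 96-position plate: each position is a 7 x 7 grid of
#' square colony patches pinned onto an agar background, with a planted
#' cell density in `[0, 1]` and a planted adhesion ratio (the fraction of
#' density surviving the wash). By default position (1,1) carries a
#' saturated, fully adhesive positive-control colony (density 1, ratio 1)
#' -- so the darkest pixel used for per-image normalization is the same on
#' the pre- and postwash scans -- and position (8,12) is an `EMPTY`
#' negative-control square; remaining positions get densities drawn
#' uniformly from `[0.25, 0.95]` and ratios from the grid `0, 0.1, ..., 1`.
#'
#' @param densities,ratios optional 8 x 12 matrices of planted values; when
#'   `NULL` they are drawn as described above using `seed`.
#' @param pitch box-to-box distance in pixels (default 44).
#' @param patch side of one colony patch in pixels (default 5; the 7 x 7
#'   patch block is then 35 px wide).
#' @param margin image margin around the grid (default 30 px).
#' @param background_inv inverse-intensity level of bare agar (default 3).
#' @param noise_sd Gaussian pixel noise standard deviation on the 0-255
#'   scale (default 3).
#' @param seed integer seed used for default densities/ratios and noise.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(densities = NULL, ratios = NULL, pitch = 44,
                       patch = 5, margin = 30, background_inv = 3,
                       noise_sd = 3, seed = 1) {
  n_rows <- 8; n_cols <- 12
  if (is.null(densities) || is.null(ratios)) {
    planted <- withr::with_seed(seed, {
      d <- matrix(runif(n_rows * n_cols, 0.25, 0.95), n_rows, n_cols)
      r <- matrix(sample(seq(0, 1, 0.1), n_rows * n_cols, replace = TRUE),
                  n_rows, n_cols)
      list(d = d, r = r)
    })
    if (is.null(densities)) {
      densities <- planted$d
      densities[1, 1] <- 1    # saturated positive control
      densities[8, 12] <- 0   # EMPTY negative control
    }
    if (is.null(ratios)) {
      ratios <- planted$r
      ratios[1, 1] <- 1
      ratios[8, 12] <- 0
    }
  }
  stopifnot(all(dim(densities) == c(n_rows, n_cols)),
            all(dim(ratios) == c(n_rows, n_cols)),
            all(densities >= 0 & densities <= 1),
            all(ratios >= 0 & ratios <= 1),
            patch >= 1, pitch > 7 * patch, margin >= 0, noise_sd >= 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, densities = densities,
                 ratios = ratios, pitch = pitch, patch = patch,
                 margin = margin, background_inv = background_inv,
                 noise_sd = noise_sd, seed = seed),
            class = "plate_spec")
}

# separable [0.25, 0.5, 0.25] blur for soft colony edges
.soft_blur <- function(m) {
  pad_rows <- rbind(m[1, ], m, m[nrow(m), ])
  v <- 0.25 * pad_rows[-c(nrow(pad_rows) - 1, nrow(pad_rows)), ] +
    0.5 * pad_rows[-c(1, nrow(pad_rows)), ] +
    0.25 * pad_rows[-c(1, 2), ]
  pad_cols <- cbind(v[, 1], v, v[, ncol(v)])
  0.25 * pad_cols[, -c(ncol(pad_cols) - 1, ncol(pad_cols))] +
    0.5 * pad_cols[, -c(1, ncol(pad_cols))] +
    0.25 * pad_cols[, -c(1, 2)]
}

# render one plate image from a density matrix (noise-free inverse image,
# then blur, noise, quantization)
.render_plate <- function(spec, densities, offset = c(0, 0)) {
  block <- 7 * spec$patch
  nr <- 2 * spec$margin + (spec$n_rows - 1) * spec$pitch + block
  nc <- 2 * spec$margin + (spec$n_cols - 1) * spec$pitch + block
  inv <- matrix(spec$background_inv, nr, nc)
  for (r in seq_len(spec$n_rows)) {
    for (c in seq_len(spec$n_cols)) {
      d <- densities[r, c]
      if (d <= 0) next
      top <- spec$margin + (r - 1) * spec$pitch + offset[1]
      left <- spec$margin + (c - 1) * spec$pitch + offset[2]
      level <- spec$background_inv + d * (255 - spec$background_inv)
      inv[(top + 1):(top + block), (left + 1):(left + block)] <- level
    }
  }
  inv <- .soft_blur(inv)
  pixels <- 255 - inv
  if (spec$noise_sd > 0)
    pixels <- pixels + rnorm(length(pixels), 0, spec$noise_sd)
  gray_image(pmin(pmax(round(pixels), 0), 255), white_level = 255)
}

#' Render a synthetic pre/post-wash plate-image pair
#'
#' The prewash image draws each position's 7 x 7 colony-patch block at a
#' darkness proportional to its planted density over the agar background;
#' the postwash image scales each position's density by its planted
#' adhesion ratio. Colony edges are softened with a 1-px blur and Gaussian
#' pixel noise is added. The sidecar truth table records the planted values
#' and the geometry records the ground-truth box centers for layout tests.
#'
#' @param spec a [plate_spec()].
#' @param offset integer `(dy, dx)` pixel translation applied to the whole
#'   grid (for layout-fitting tests); default `c(0, 0)`.
#' @return list with `pre` and `post` ([gray_image()]s), `truth`
#'   (data.frame `row`, `col`, `density`, `ratio`, `is_empty`) and
#'   `geometry` (`centers_r`, `centers_c` 1-based pixel centers, `block`,
#'   `pitch`, `offset`).
#' @export
render_plate_pair <- function(spec, offset = c(0, 0)) {
  stopifnot(inherits(spec, "plate_spec"), length(offset) == 2)
  block <- 7 * spec$patch
  imgs <- withr::with_seed(spec$seed, {
    pre <- .render_plate(spec, spec$densities, offset)
    post <- .render_plate(spec, spec$densities * spec$ratios, offset)
    list(pre = pre, post = post)
  })
  grid <- expand.grid(row = seq_len(spec$n_rows), col = seq_len(spec$n_cols))
  truth <- data.frame(
    row = grid$row, col = grid$col,
    density = spec$densities[cbind(grid$row, grid$col)],
    ratio = spec$ratios[cbind(grid$row, grid$col)],
    is_empty = spec$densities[cbind(grid$row, grid$col)] == 0
  )
  geometry <- list(
    centers_r = spec$margin + (seq_len(spec$n_rows) - 1) * spec$pitch +
      (block + 1) / 2 + offset[1],
    centers_c = spec$margin + (seq_len(spec$n_cols) - 1) * spec$pitch +
      (block + 1) / 2 + offset[2],
    block = block, pitch = spec$pitch, offset = offset
  )
  list(pre = imgs$pre, post = imgs$post, truth = truth, geometry = geometry)
}

#' Render a filled-out example plate
#'
#' Every position carries a dense colony; used to build the raw reference
#' layout.
#'
#' @param spec a [plate_spec()].
#' @param density uniform planted density (default 0.9).
#' @param offset integer `(dy, dx)` translation, as in [render_plate_pair()].
#' @return A [gray_image()].
#' @export
render_filled_plate <- function(spec, density = 0.9, offset = c(0, 0)) {
  stopifnot(inherits(spec, "plate_spec"))
  densities <- matrix(density, spec$n_rows, spec$n_cols)
  withr::with_seed(spec$seed + 1L, .render_plate(spec, densities, offset))
}

#' Simulate a multi-point plate-reader scan with tunable clumping
#'
#' Each well's `n x n` readings are a baseline OD with small measurement
#' noise plus `k` clump spikes placed uniformly over the grid; the number
#' of spikes is Poisson with mean `2 * clump` and each spike adds an
#' exponential mass with mean `0.05 * (1 + clump)`, so both the number and
#' the mass of flocs grow with the clump parameter. A shared background
#' absorbance is added to every reading; the control well contains
#' background only.
#'
#' @param mean_od per-well baseline OD600 (recycled over wells).
#' @param clump per-well clump parameter, >= 0 (recycled over wells).
#' @param n side length of the per-well grid (default 15).
#' @param n_wells number of sample wells, <= 95 (default 95; the control
#'   well is added as the 96th).
#' @param background shared background absorbance (default 0.04).
#' @param noise_sd measurement noise sd (default 0.01).
#' @param control_well id of the empty control well (default `"H12"`).
#' @param seed integer seed.
#' @return list with `plate` (a [plate_scan()]) and `truth` (data.frame
#'   `well`, `mean_od`, `clump`).
#' @export
simulate_plate_scan <- function(mean_od = 0.4, clump = 0, n = 15,
                                n_wells = 95, background = 0.04,
                                noise_sd = 0.01, control_well = "H12",
                                seed = 1) {
  stopifnot(n >= 2, n_wells >= 1, n_wells <= 95, all(clump >= 0))
  ids <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  ids <- setdiff(ids, control_well)[seq_len(n_wells)]
  mean_od <- rep_len(mean_od, n_wells)
  clump <- rep_len(clump, n_wells)
  wells <- withr::with_seed(seed, {
    ws <- lapply(seq_len(n_wells), function(i) {
      x <- pmax(rnorm(n * n, mean_od[i], noise_sd), 0)
      k <- rpois(1, 2 * clump[i])
      if (k > 0) {
        at <- sample.int(n * n, k, replace = TRUE)
        mass <- rexp(k, rate = 1 / (0.05 * (1 + clump[i])))
        for (s in seq_len(k)) x[at[s]] <- x[at[s]] + mass[s]
      }
      well_scan(ids[i], x + background, n)
    })
    ctrl <- well_scan(control_well,
                      pmax(rnorm(n * n, background, noise_sd), 0), n)
    c(ws, list(ctrl))
  })
  list(plate = plate_scan(wells, control_well),
       truth = data.frame(well = ids, mean_od = mean_od, clump = clump))
}

#' Simulate a deletion-screen replicate table
#'
#' Emulates the confirmation stage of a genome-wide deletion screen: a few
#' percent of strains are planted adhesives with wash ratios well above the
#' nonadhesive background, every strain is measured in several replicate
#' plates, and prewash densities vary strain-to-strain so that a small
#' fraction of replicates fails the robust-quantification thresholds.
#'
#' @param n_strains number of deletion strains (default 3600).
#' @param frac_adhesive fraction of planted adhesive strains (default
#'   0.05).
#' @param n_replicates replicates per strain (default 6).
#' @param adhesive_ratio,null_ratio mean wash ratio of planted adhesives
#'   and of the nonadhesive background (defaults 0.4 and 0.03).
#' @param seed integer seed.
#' @return list with `replicates` (data.frame `strain`, `pre`, `post`,
#'   `ratio`) and `truth` (data.frame `strain`, `adhesive`).
#' @export
simulate_screen <- function(n_strains = 3600, frac_adhesive = 0.05,
                            n_replicates = 6, adhesive_ratio = 0.4,
                            null_ratio = 0.03, seed = 1) {
  stopifnot(n_strains >= 2, frac_adhesive > 0, frac_adhesive < 1)
  withr::with_seed(seed, {
    n_pos <- round(n_strains * frac_adhesive)
    strains <- sprintf("d%04d", seq_len(n_strains))
    adhesive <- seq_len(n_strains) <= n_pos
    rows <- data.frame(
      strain = rep(strains, each = n_replicates),
      adhesive = rep(adhesive, each = n_replicates)
    )
    n <- nrow(rows)
    ratio <- ifelse(rows$adhesive,
                    pmax(rnorm(n, adhesive_ratio, 0.08), 0.15),
                    pmax(rnorm(n, null_ratio, 0.015), 0))
    pre <- pmax(rnorm(n, 0.5, 0.1), 0.02)
    post <- pmax(ratio * pre + rnorm(n, 0, 0.005), 0)
    list(replicates = data.frame(strain = rows$strain, pre = pre,
                                 post = post,
                                 ratio = ifelse(pre > 0, post / pre, NA)),
         truth = data.frame(strain = strains, adhesive = adhesive))
  })
}
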