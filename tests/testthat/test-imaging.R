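test_that("invert_normalize maps intensity endpoints and degenerate images correctly", {
  img <- gray_image(matrix(c(0, 255, 128, 255), 2, 2), 255)
  norm <- invert_normalize(img)
  expect_equal(norm[1, 1], 1)
  expect_equal(norm[2, 1], 0)
  expect_true(all(norm >= 0 & norm <= 1))

  white <- gray_image(matrix(255, 4, 4), 255)
  expect_warning(z <- invert_normalize(white), "white_level")
  expect_true(all(z == 0))
})

test_that("invert_normalize matches element-wise brute force on a rendered plate", {
  sp <- plate_spec(seed = 7)
  img <- render_plate_pair(sp)$pre
  norm <- invert_normalize(img)
  inv <- 255 - img$pixels
  expect_equal(norm, inv / max(inv))
})

test_that("reference layout recovers planted box geometry and the perimeter mask", {
  sp <- plate_spec(seed = 2)
  pp <- render_plate_pair(sp)
  layout <- build_reference_layout(render_filled_plate(sp))
  expect_s3_class(layout, "plate_layout")
  expect_equal(sum(layout$boxes$edge), 36)
  expect_equal(sum(!layout$boxes$edge), 60)
  centers_r <- (layout$boxes$top + layout$boxes$bottom + 1) / 2
  centers_c <- (layout$boxes$left + layout$boxes$right + 1) / 2
  expect_lt(max(abs(centers_r - pp$geometry$centers_r[layout$boxes$row])), 3)
  expect_lt(max(abs(centers_c - pp$geometry$centers_c[layout$boxes$col])), 3)
})

test_that("reference layout is equivariant under image translation", {
  sp <- plate_spec(seed = 2)
  l0 <- build_reference_layout(render_filled_plate(sp))
  l1 <- build_reference_layout(render_filled_plate(sp, offset = c(10, 7)))
  expect_lt(max(abs((l1$boxes$top - l0$boxes$top) - 10)), 3)
  expect_lt(max(abs((l1$boxes$left - l0$boxes$left) - 7)), 3)
})

test_that("layout construction fails informatively on a blank image", {
  blank <- gray_image(matrix(200, 400, 600), 255)
  expect_error(build_reference_layout(blank), "row|column")
})

test_that("layout fitting recovers planted shifts and flags the search boundary", {
  sp <- plate_spec(seed = 4)
  layout <- build_reference_layout(render_filled_plate(sp))
  # identity
  fit0 <- fit_layout(layout, render_plate_pair(sp)$pre, 10)
  expect_lte(max(abs(attr(fit0, "offset"))), 1)
  # planted shift
  shifted <- render_plate_pair(sp, offset = c(-6, 4))
  fit1 <- fit_layout(layout, shifted$pre, 20)
  expect_lte(max(abs(attr(fit1, "offset") - c(-6, 4))), 1)
  # shift beyond the search radius ends on the boundary
  far <- render_plate_pair(sp, offset = c(9, 0))
  expect_warning(fit_layout(layout, far$pre, 5), "boundary")
})

test_that("measured densities match planted values after background correction", {
  sp <- plate_spec(seed = 5)
  mp <- measure_pair(sp)
  truth <- sp$densities
  expect_lt(max(abs(mp$pre$values - truth)), 0.02)
  # control position self-subtracts to ~0
  expect_lt(mp$pre$values[8, 12], 0.005)
  expect_error(
    measure_grid(render_plate_pair(sp)$pre, mp$fitted,
                 matrix(numeric(0), 0, 2)),
    "negative control")
})

test_that("background offsets are absorbed by the control square", {
  sp <- plate_spec(seed = 6)
  mp <- measure_pair(sp)
  img <- render_plate_pair(sp)$pre
  darker <- gray_image(pmax(img$pixels - 3, 0), 255)
  g2 <- measure_grid(darker, mp$fitted, which(sp$densities == 0, arr.ind = TRUE))
  expect_lt(max(abs(g2$values - mp$pre$values)), 0.01)
})

test_that("adhesion records apply the growth threshold and ratio rules", {
  v <- matrix(0.5, 2, 2)
  ctrl <- cbind(1, 1)
  pre <- density_grid(matrix(c(0.5, 0.05, 0.3, 0.5), 2, 2), ctrl, 0)
  post <- density_grid(matrix(c(0.1, 0.04, 0.6, 0.5), 2, 2), ctrl, 0)
  rec <- adhesion_from_pair(pre, post)
  r11 <- rec[rec$row == 1 & rec$col == 1, ]
  expect_equal(r11$ratio, 0.2)  # the strong-adhesion boundary value
  expect_false(strong_adhesion_call(r11$ratio))
  r21 <- rec[rec$row == 2 & rec$col == 1, ]
  expect_false(r21$grew)
  expect_true(is.na(r21$ratio))
  r12 <- rec[rec$row == 1 & rec$col == 2, ]
  expect_true(r12$flagged_gt1)
  expect_equal(r12$ratio, 2)
  # identical grids give ratio 1 everywhere that grew
  same <- adhesion_from_pair(pre, pre)
  expect_true(all(same$ratio[same$grew] == 1))
  # shape mismatch
  small <- density_grid(matrix(0.5, 1, 2), ctrl, 0)
  expect_error(adhesion_from_pair(pre, small), "mismatch")
})

test_that("strain summaries apply the exclusion and interior-only rules", {
  map <- matrix("EMPTY", 8, 12)
  map[cbind(rep(1:8, 12), rep(1:12, each = 8))] <-
    paste0("s", seq_len(96))
  rec <- expand.grid(row = 1:8, col = 1:12)
  rec$pre_density <- 0.5
  rec$post_density <- 0.25
  rec$ratio <- 0.5
  rec$grew <- TRUE
  out <- summarize_strain(rec, map)
  expect_equal(nrow(out), 96)
  expect_true(all(!out$excluded))
  expect_equal(out$mean_ratio, rep(0.5, 96))  # single replicate = identity

  interior <- summarize_strain(rec, map, interior_only = TRUE)
  expect_equal(nrow(interior), 60)

  # a strain with replicate pre-densities 0.05 and 0.08 is excluded
  two <- data.frame(row = 2, col = 2, pre_density = c(0.05, 0.08),
                    post_density = 0.01, ratio = NA, grew = FALSE)
  s <- summarize_strain(two, map)
  expect_true(s$excluded)
  expect_equal(s$mean_pre, 0.065)

  bad <- data.frame(row = 9, col = 1, pre_density = 1, post_density = 1,
                    ratio = 1, grew = TRUE)
  expect_error(summarize_strain(bad, map), "outside")
})

test_that("translation at fit time leaves per-position measurements unchanged", {
  sp <- plate_spec(seed = 8)
  m0 <- measure_pair(sp)
  m1 <- measure_pair(sp, offset = c(5, -5))
  expect_lt(max(abs(m0$pre$values - m1$pre$values)), 0.01)
})

test_that("the folder-level pipeline pairs files and maps strains end to end", {
  sp <- plate_spec(seed = 9)
  pp <- render_plate_pair(sp)
  tmp <- withr::local_tempdir()
  dir.create(file.path(tmp, "pre")); dir.create(file.path(tmp, "post"))
  write_plate_image(pp$pre, file.path(tmp, "pre", "plate1.png"))
  write_plate_image(pp$post, file.path(tmp, "post", "plate1.png"))
  map <- matrix(paste0("s", seq_len(96)), 8, 12)
  map[8, 12] <- "EMPTY"
  out <- quantify_adhesion(file.path(tmp, "pre"), file.path(tmp, "post"),
                           map, render_filled_plate(sp))
  expect_equal(nrow(out), 96)
  m <- merge(out, pp$truth, by = c("row", "col"))
  ok <- m$density >= 0.2 & m$grew
  expect_lt(max(abs(m$ratio.x[ok] - m$ratio.y[ok])), 0.05)
  # mismatched folders error
  file.rename(file.path(tmp, "post", "plate1.png"),
              file.path(tmp, "post", "plate2.png"))
  expect_error(
    quantify_adhesion(file.path(tmp, "pre"), file.path(tmp, "post"),
                      map, render_filled_plate(sp)),
    "matching")
})
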