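test_that("movies round-trip through TIFF bit-exactly and carry metadata", {
  set.seed(11)
  fr <- array(sample(0:65535, 40 * 8 * 12, replace = TRUE), dim = c(40, 8, 12))
  mv <- movie_stack(fr, frame_period_ms = 2)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(mv, path, bits = 16)
  back <- load_movie(path, frame_period_ms = 2)
  expect_identical(dim(back$frames), dim(fr))
  expect_equal(back$frames, fr + 0)          # every sample bit-exact
  expect_equal(movie_duration_ms(back), 80)

  # a single-frame TIFF is a valid (degenerate) movie
  one <- movie_stack(array(5, dim = c(1, 4, 4)))
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_movie(one, p1, bits = 8)
  expect_equal(dim(load_movie(p1)$frames)[1], 1)
})

test_that("RGB input is rejected as not single-channel", {
  path <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(runif(6 * 6 * 3), dim = c(6, 6, 3))
  tiff::writeTIFF(rgb, path)
  expect_error(load_movie(path), "single-channel")
  expect_error(load_movie(tempfile()), "cannot read")
})

make_dataset <- function(root, coverslips = 2, areas = 3, movies = 6,
                         drop_brightfield = character()) {
  for (cs in paste0("cs", seq_len(coverslips))) {
    for (ar in paste0("area", seq_len(areas))) {
      d <- file.path(root, cs, ar)
      dir.create(d, recursive = TRUE)
      id <- file.path(cs, ar)
      if (!(id %in% drop_brightfield)) {
        write_movie(movie_stack(array(1L, c(1, 4, 4))),
                    file.path(d, "brightfield.tif"), bits = 8)
      }
      for (m in seq_len(movies)) {
        write_movie(movie_stack(array(1L, c(2, 4, 4))),
                    file.path(d, sprintf("movie_%02d.tif", m)), bits = 8)
      }
    }
  }
}

test_that("scan_dataset walks the coverslip/area tree deterministically", {
  root <- withr::local_tempdir()
  make_dataset(root)
  areas <- scan_dataset(root)
  expect_length(areas, 6)
  expect_true(all(vapply(areas, function(a) length(a$movie_paths), 1L) == 6))
  # order-stable and idempotent
  expect_identical(vapply(areas, `[[`, "", "area_id"),
                   vapply(scan_dataset(root), `[[`, "", "area_id"))
  # movies sorted by filename
  expect_identical(basename(areas[[1]]$movie_paths),
                   sprintf("movie_%02d.tif", 1:6))
  # ROI mask TIFFs are geometry, not movies
  d1 <- dirname(areas[[1]]$brightfield_path)
  write_movie(movie_stack(array(1L, c(1, 4, 4))),
              file.path(d1, "rois_n1_mask.tif"), bits = 8)
  expect_length(scan_dataset(root)[[1]]$movie_paths, 6)
})

test_that("areas without a brightfield are skipped with a warning", {
  root <- withr::local_tempdir()
  make_dataset(root, coverslips = 1, areas = 2,
               drop_brightfield = file.path("cs1", "area1"))
  expect_warning(areas <- scan_dataset(root), "no brightfield")
  expect_length(areas, 1)
  expect_equal(areas[[1]]$area_id, file.path("cs1", "area2"))

  empty <- withr::local_tempdir()
  expect_warning(expect_length(scan_dataset(empty), 0), "empty")
})

test_that("field-of-view geometry matches the printed worked examples", {
  # 2048 x 400 px at 0.325 um: ~0.086 mm^2 imaged on a ~113 mm^2 coverslip
  expect_equal(fov_area_mm2(2048, 400, 0.325), 0.086528)
  expect_equal(fov_area_mm2(1, 1, 1000), 1)
  # 650 x 120 um island expressed in pixels
  expect_equal(fov_area_mm2(2000, 369, 0.325), 650 * 369 * 0.325 / 1e6)
  expect_error(fov_area_mm2(-1, 1, 1), "positive")

  # quadratic scaling in pixel size
  set.seed(2)
  for (i in 1:20) {
    w <- runif(1, 1, 4000); h <- runif(1, 1, 4000); p <- runif(1, 0.05, 2)
    expect_equal(fov_area_mm2(w, h, 2 * p), 4 * fov_area_mm2(w, h, p))
  }
})

test_that("ROI sets round-trip through JSON with geometry intact", {
  set.seed(3)
  rois <- lapply(1:10, function(i) {
    cx <- runif(1, 5, 25); cy <- runif(1, 5, 15)
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    roi(paste0("n", i), "neuron",
        polygon = cbind(cx + 3 * cos(ang), cy + 3 * sin(ang)),
        cell_type = sample(cell_types(), 1))
  })
  bg_mask <- matrix(FALSE, 20, 30); bg_mask[1:3, 1:3] <- TRUE
  rs <- roi_set("a1", c(rois, list(roi("bg", "background", mask = bg_mask))))
  path <- file.path(withr::local_tempdir(), "rois.json")
  back <- roundtrip_rois(rs, path)
  expect_equal(back$area_id, "a1")
  expect_length(back$neurons, 10)
  for (i in 1:10) {
    expect_equal(back$neurons[[i]]$polygon, rs$neurons[[i]]$polygon,
                 ignore_attr = TRUE)
    expect_equal(back$neurons[[i]]$cell_type, rs$neurons[[i]]$cell_type)
  }
  expect_equal(back$background$mask, bg_mask)
})

test_that("polygon and equivalent mask ROIs rasterize to the same pixels", {
  poly <- rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8))
  m_poly <- roi_mask(roi("p", "neuron", polygon = poly), c(20, 30))
  m_direct <- matrix(FALSE, 20, 30); m_direct[3:8, 3:8] <- TRUE
  expect_equal(m_poly, m_direct)
  # both representations survive a JSON round trip identically
  rs <- roi_set("x", list(
    roi("p", "neuron", polygon = poly),
    roi("m", "neuron", mask = m_direct),
    roi("bg", "background", mask = !m_direct)))
  back <- roundtrip_rois(rs, file.path(withr::local_tempdir(), "r.json"))
  expect_equal(roi_mask(back$neurons[[1]], c(20, 30)),
               back$neurons[[2]]$mask)
})

test_that("ROI-set invariants are enforced", {
  nr <- roi("n1", "neuron", polygon = rbind(c(0, 0), c(2, 0), c(2, 2)))
  expect_error(roi_set("a", list(nr)), "background")
  bg <- roi("bg", "background", mask = matrix(TRUE, 2, 2))
  expect_error(roi_set("a", list(nr, nr, bg)), "duplicate")
  expect_error(roi("e", "neuron"), "polygon or mask")
  expect_error(roi("e", "neuron", mask = matrix(FALSE, 3, 3)), "at least one")
})
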