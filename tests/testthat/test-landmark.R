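test_that("the exact oracle reproduces phantom truth through the crop frame", {
  case <- generate_phantom(small_spec())
  backend <- landmark_backend_oracle(case, noise_sd = 0)
  res <- measure_radiograph(case$image, backend, side = 96)
  expect_equal(nrow(res), 5)
  truth <- case$truth_landmarks
  # detection order is cranial to caudal, matching the truth table
  expect_equal(as.matrix(res[landmark_cols()]),
               as.matrix(truth[landmark_cols()]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the noisy oracle is deterministic for a fixed seed", {
  case <- generate_phantom(small_spec())
  b1 <- landmark_backend_oracle(case, noise_sd = 2, seed = 5)
  b2 <- landmark_backend_oracle(case, noise_sd = 2, seed = 5)
  cw <- crop_vertebra(case$image, c(x = 64, y = 60), side = 96)
  p1 <- predict_landmarks(cw$crop, b1, cw$window)
  p2 <- predict_landmarks(cw$crop, b1, cw$window)   # same backend, same crop
  p3 <- predict_landmarks(cw$crop, b2, cw$window)   # fresh backend, same seed
  expect_identical(p1, p2)
  expect_identical(p1, p3)
  b3 <- landmark_backend_oracle(case, noise_sd = 2, seed = 6)
  expect_false(identical(p1, predict_landmarks(cw$crop, b3, cw$window)))
})

test_that("mean normalized landmark error matches the folded-normal closed form", {
  # |N(0, sd)| has mean sd * sqrt(2/pi); with many vertebrae the simulated
  # mean x/y errors (percent of width/height) must match it
  case <- generate_phantom(phantom_spec(image_size = c(1600L, 256L),
                                        n_vertebrae = 40, base_width = 30,
                                        base_height = 16, noise_sd = 0))
  sd_px <- 2
  backend <- landmark_backend_oracle(case, noise_sd = sd_px, seed = 31)
  res <- measure_radiograph(case$image, backend, side = 128)
  res <- label_by_nearest(res, case$truth_landmarks)
  errs <- landmark_errors(res, case$truth_landmarks)
  dims <- vertebra_dimensions(case$truth_landmarks)
  expected_x <- mean(100 * sd_px * sqrt(2 / pi) / dims$width)
  expected_y <- mean(100 * sd_px * sqrt(2 / pi) / dims$height)
  # 40 vertebrae x 6 landmarks = 240 draws per axis: ~8% Monte-Carlo slack
  expect_equal(mean(errs$x_error_pct), expected_x, tolerance = 0.08)
  expect_equal(mean(errs$y_error_pct), expected_y, tolerance = 0.08)
})

test_that("crop/image frame mapping round-trips and validates frames", {
  lms <- rect_landmarks(x0 = 20, y0 = 30, frame = "crop")
  window <- crop_vertebra(matrix(0.5, 400, 400), c(x = 300, y = 200),
                          side = 96)$window
  img_lms <- to_image_coords(lms, window)
  expect_equal(img_lms$frame, "image")
  back <- to_crop_coords(img_lms, window)
  expect_equal(as.matrix(back[landmark_cols()]),
               as.matrix(lms[landmark_cols()]), tolerance = 1e-9)
  # crop center maps to the window's rounded center
  mid <- vertemorph:::crop_to_image_xy(48, 48, window)
  expect_equal(c(mid$x, mid$y), c(300, 200))
  expect_error(to_image_coords(img_lms, window), class = "vm_validation_error")
  expect_error(to_crop_coords(lms, window), class = "vm_validation_error")
})

test_that("backends returning bad coordinates are rejected", {
  crop <- matrix(0.5, 96, 96)
  bad_nan <- function(crop, window) {
    stats::setNames(c(NaN, rep(10, 11)), landmark_cols())
  }
  expect_error(predict_landmarks(crop, bad_nan), class = "vm_backend_error")
  bad_oob <- function(crop, window) {
    stats::setNames(rep(200, 12), landmark_cols())
  }
  expect_error(predict_landmarks(crop, bad_oob), class = "vm_backend_error")
  incomplete <- function(crop, window) c(AU_x = 1, AU_y = 2)
  expect_error(predict_landmarks(crop, incomplete), class = "vm_backend_error")
})

test_that("translating the image translates all pipeline landmarks equally", {
  spec <- small_spec()
  case <- generate_phantom(spec)
  dx <- 12L; dy <- 9L
  h <- nrow(case$image); w <- ncol(case$image)
  shifted <- matrix(spec$background_intensity, h, w)
  shifted[(1 + dy):h, (1 + dx):w] <- case$image[1:(h - dy), 1:(w - dx)]
  truth_shift <- case$truth_landmarks
  for (nm in landmark_names()) {
    truth_shift[[paste0(nm, "_x")]] <- truth_shift[[paste0(nm, "_x")]] + dx
    truth_shift[[paste0(nm, "_y")]] <- truth_shift[[paste0(nm, "_y")]] + dy
  }
  res0 <- measure_radiograph(case$image, landmark_backend_oracle(case), side = 96)
  res1 <- measure_radiograph(shifted, landmark_backend_oracle(truth_shift),
                             side = 96)
  expect_equal(res1$x, res0$x + dx, tolerance = 1e-6)
  expect_equal(res1$y, res0$y + dy, tolerance = 1e-6)
  m0 <- as.matrix(res0[landmark_cols()])
  m1 <- as.matrix(res1[landmark_cols()])
  shift <- matrix(rep(c(dx, dy), 6), nrow(m0), 12, byrow = TRUE)
  expect_equal(m1, m0 + shift, tolerance = 1e-6)
})
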