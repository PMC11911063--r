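test_that("heights are Euclidean distances between paired edge landmarks", {
  expect_equal(unname(compute_heights(rect_landmarks())), c(10, 10, 10))

  skewed <- rect_landmarks()
  skewed$AL_x <- 3; skewed$AL_y <- 4; skewed$AU_x <- 0; skewed$AU_y <- 0
  expect_equal(unname(compute_heights(skewed)["A"]), 5)  # 3-4-5 triangle

  wedge <- tibble::tibble(
    AU_x = 0, AU_y = 4, AL_x = 0, AL_y = 10, CU_x = 5, CU_y = 2,
    CL_x = 5, CL_y = 10, PU_x = 10, PU_y = 0, PL_x = 10, PL_y = 10
  )
  expect_equal(unname(compute_heights(wedge)), c(6, 8, 10))

  degenerate <- rect_landmarks()
  degenerate$AL_x <- degenerate$AU_x; degenerate$AL_y <- degenerate$AU_y
  expect_error(compute_heights(degenerate), class = "vm_validation_error")
})

test_that("ratios, collapse percent and QM bins follow their definitions", {
  r <- compute_ratios(10, 10, 10)
  expect_equal(unlist(r), c(ratio_CA = 1, ratio_CP = 1, ratio_AP = 1))
  r2 <- compute_ratios(6, 8, 10)
  expect_equal(unlist(r2), c(ratio_CA = 8 / 6, ratio_CP = 0.8, ratio_AP = 0.6))
  expect_error(compute_ratios(0, 8, 10), class = "vm_validation_error")

  expect_equal(collapse_percent(1, 1), 0)
  expect_equal(collapse_percent(0.8, 0.6), 40)   # wedge: 1 - min(0.6, 0.8)
  expect_equal(collapse_percent(0.7, 1.0), 30)   # biconcave
  expect_equal(collapse_percent(1.2, 1.1), 0)    # floored at zero

  expect_equal(as.character(qm_status(c(10, 25, 45))), c("<20", "25-40", ">40"))
  # half-open convention: boundary values go to the upper bin
  expect_equal(as.character(qm_status(c(0, 20, 40))), c("<20", "20-25", ">40"))
  expect_error(qm_status(-1), class = "vm_validation_error")
})

test_that("QM bins partition the nonnegative collapse axis", {
  withr::with_seed(42, {
    x <- c(runif(500, 0, 80), 0, 20, 25, 40, 19.999999, 39.999999)
    bins <- qm_status(x)
    expect_false(anyNA(bins))                       # exhaustive
    expect_setequal(levels(bins), qm_bins())
    manual <- ifelse(x < 20, "<20",
              ifelse(x < 25, "20-25", ifelse(x < 40, "25-40", ">40")))
    expect_equal(as.character(bins), manual)        # disjoint and consistent
  })
})

test_that("discrepancy flag uses the inclusive 0.2 threshold", {
  ref <- tibble::tibble(ratio_CA = 0.60, ratio_CP = 0.9, ratio_AP = 0.8)
  pred <- tibble::tibble(ratio_CA = 0.85, ratio_CP = 0.9, ratio_AP = 0.8)
  f <- flag_discrepancy(pred, ref)
  expect_true(f$flagged)
  expect_equal(f$offending, "ratio_CA")
  expect_equal(f$max_delta, 0.25)

  near <- dplyr::mutate(ref, dplyr::across(dplyr::everything(), ~ .x + 0.19))
  expect_false(flag_discrepancy(near, ref)$flagged)
  expect_false(flag_discrepancy(ref, ref)$flagged)
  # threshold is inclusive
  at <- dplyr::mutate(ref, ratio_AP = ratio_AP + 0.2)
  expect_true(flag_discrepancy(at, ref)$flagged)
})

test_that("heights scale linearly and ratios are similarity-invariant", {
  base <- tibble::tibble(
    AU_x = 0, AU_y = 4, AL_x = 0.5, AL_y = 10, CU_x = 5, CU_y = 2,
    CL_x = 5.2, CL_y = 10.3, PU_x = 10, PU_y = 0, PL_x = 10.4, PL_y = 10,
    frame = "image"
  )
  m0 <- vertebra_morphometry(base)
  withr::with_seed(7, {
    for (i in 1:20) {
      theta <- runif(1, 0, 2 * pi); s <- runif(1, 0.2, 5)
      tx <- runif(1, -50, 50); ty <- runif(1, -50, 50)
      tr <- base
      for (nm in landmark_names()) {
        x <- base[[paste0(nm, "_x")]]; y <- base[[paste0(nm, "_y")]]
        tr[[paste0(nm, "_x")]] <- s * (cos(theta) * x - sin(theta) * y) + tx
        tr[[paste0(nm, "_y")]] <- s * (sin(theta) * x + cos(theta) * y) + ty
      }
      m1 <- vertebra_morphometry(tr)
      expect_equal(m1$A, s * m0$A, tolerance = 1e-10)
      expect_equal(m1$C, s * m0$C, tolerance = 1e-10)
      expect_equal(m1$P, s * m0$P, tolerance = 1e-10)
      expect_equal(
        unlist(m1[c("ratio_CA", "ratio_CP", "ratio_AP", "collapse_pct")]),
        unlist(m0[c("ratio_CA", "ratio_CP", "ratio_AP", "collapse_pct")]),
        tolerance = 1e-9
      )
    }
  })
})

test_that("crush collapse is visible only with the adjacent-level reference", {
  spec <- small_spec(deformities = tibble::tibble(
    level = "V3", type = "crush", severity = 0.3
  ))
  truth <- generate_phantom(spec)$truth_landmarks
  within <- vertebra_morphometry(truth)
  expect_equal(within$collapse_pct[3], 0)          # ratios all 1 under crush
  withref <- vertebra_morphometry(truth, crush_reference = TRUE)
  expect_gt(withref$collapse_pct[3], 25)           # posterior loss vs neighbours
  # undeformed levels see only the caudal size gradient (~3% pseudo-loss)
  expect_lt(withref$collapse_pct[1], 5)
})
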