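test_that("greedy matching follows the distance-and-threshold contract", {
  ref <- tibble::tibble(x = c(10, 50), y = c(10, 10))
  # prediction exactly on a reference
  m <- match_detections(tibble::tibble(x = 10, y = 10), ref, tau = 5)
  expect_equal(m$labels$status, "TP")
  expect_equal(m$labels$distance, 0)
  # two predictions near one reference: the nearer wins
  m2 <- match_detections(tibble::tibble(x = c(11, 13), y = c(10, 10)),
                         tibble::tibble(x = 10, y = 10), tau = 5)
  expect_equal(m2$labels$status, c("TP", "FP"))
  # beyond tau from everything: FP
  m3 <- match_detections(tibble::tibble(x = 100, y = 100), ref, tau = 5)
  expect_equal(m3$labels$status, "FP")
  # empty reference: all FP, no error
  m4 <- match_detections(tibble::tibble(x = 1, y = 1),
                         tibble::tibble(x = numeric(0), y = numeric(0)),
                         tau = 5)
  expect_equal(m4$counts$FP, 1)
  expect_equal(m4$counts$TP, 0)
})

test_that("greedy matching achieves the assignment-optimal TP count", {
  # Vertebra-like geometry: references separated by more than 2 * tau, so
  # every prediction has at most one admissible reference. In this regime
  # the greedy result must coincide with the optimal one-to-one assignment
  # (checked by exhaustive enumeration); on arbitrary point clouds greedy is
  # only a lower bound, also asserted.
  withr::with_seed(17, {
    for (trial in 1:25) {
      nr <- sample(2:6, 1)
      tau <- runif(1, 4, 10)
      ref <- tibble::tibble(x = runif(nr, 0, 30),
                            y = cumsum(runif(nr, 2.2 * tau, 3 * tau)))
      hits <- sample(nr, sample(nr, 1))
      pred <- ref[hits, ]
      pred$x <- pred$x + runif(length(hits), -tau / 2, tau / 2)
      pred$y <- pred$y + runif(length(hits), -tau / 2, tau / 2)
      if (trial %% 3 == 0) {
        pred <- dplyr::bind_rows(pred, tibble::tibble(x = 200, y = 200))
      }
      got <- match_detections(pred, ref, tau = tau)$counts$TP
      best <- matching_oracle_tp(pred, ref, tau)
      expect_equal(got, best)
    }
    # arbitrary clouds: greedy never exceeds the optimum
    for (trial in 1:10) {
      np <- sample(1:5, 1); nr <- sample(1:5, 1)
      pred <- tibble::tibble(x = runif(np, 0, 40), y = runif(np, 0, 40))
      ref <- tibble::tibble(x = runif(nr, 0, 40), y = runif(nr, 0, 40))
      tau <- runif(1, 5, 25)
      got <- match_detections(pred, ref, tau = tau)$counts$TP
      expect_lte(got, matching_oracle_tp(pred, ref, tau))
    }
  })
})

test_that("detection metrics are exact quotients with NA for empty denominators", {
  counts <- tibble::tibble(n_reference = 10, TP = 9, FP = 3, n_images = 2)
  m <- detection_metrics(counts)
  expect_equal(m$sensitivity_pct, 90)
  expect_equal(m$precision_pct, 100 * 9 / 12)
  expect_equal(m$fp_per_image, 1.5)
  empty <- detection_metrics(tibble::tibble(n_reference = 0, TP = 0, FP = 0,
                                            n_images = 1))
  expect_true(is.na(empty$sensitivity_pct))
  expect_true(is.na(empty$precision_pct))
  expect_error(detection_metrics(tibble::tibble(n_reference = 1, TP = 2,
                                                FP = 0, n_images = 1)),
               class = "vm_validation_error")
})

test_that("vertebra dimensions are edge-span and height means", {
  expect_equal(vertebra_dimensions(rect_landmarks()),
               tibble::tibble(width = 10, height = 10))
  wedge <- tibble::tibble(
    AU_x = 0, AU_y = 4, AL_x = 0, AL_y = 10, CU_x = 5, CU_y = 2,
    CL_x = 5, CL_y = 10, PU_x = 10, PU_y = 0, PL_x = 10, PL_y = 10
  )
  d <- vertebra_dimensions(wedge)
  expect_equal(d$width, (sqrt(10^2 + 4^2) + 10) / 2, tolerance = 1e-9)
  expect_equal(d$height, 8)
  scaled <- wedge
  for (cc in landmark_cols()) scaled[[cc]] <- 2 * scaled[[cc]]
  d2 <- vertebra_dimensions(scaled)
  expect_equal(d2$width, 2 * d$width)
  expect_equal(d2$height, 2 * d$height)
})

test_that("landmark errors are percentages of the reference dimensions", {
  ref <- rect_landmarks()
  pred <- ref
  pred$AU_x <- pred$AU_x + 0.5
  e <- landmark_errors(pred, ref)
  au <- e[e$landmark == "AU", ]
  expect_equal(au$x_error_pct, 5)
  expect_equal(au$y_error_pct, 0)
  expect_true(all(e$x_error_pct[e$landmark != "AU"] == 0))

  # identity: all zero
  e0 <- landmark_errors(ref, ref)
  expect_true(all(e0$x_error_pct == 0) && all(e0$y_error_pct == 0))

  # y shift of 1 px against height 8
  ref8 <- rect_landmarks(h = 8)
  pred8 <- ref8; pred8$CL_y <- pred8$CL_y + 1
  e8 <- landmark_errors(pred8, ref8)
  expect_equal(e8$y_error_pct[e8$landmark == "CL"], 100 / 8)

  # scale invariance of the percentages
  s_pred <- pred; s_ref <- ref
  for (cc in landmark_cols()) {
    s_pred[[cc]] <- 3.7 * s_pred[[cc]]; s_ref[[cc]] <- 3.7 * s_ref[[cc]]
  }
  expect_equal(landmark_errors(s_pred, s_ref)[c("x_error_pct", "y_error_pct")],
               e[c("x_error_pct", "y_error_pct")], tolerance = 1e-9)
})

test_that("the normality gate picks Pearson and Spearman appropriately", {
  withr::with_seed(8, {
    a <- rnorm(100)
    b <- a + rnorm(100, 0, 0.2)
    res <- qm_correlation(a, b)
    expect_equal(res$method, "pearson")
    expect_gt(res$estimate, 0.9)

    # identity on non-constant data: coefficient 1
    expect_equal(qm_correlation(a, a)$estimate, 1)

    # heavy-tailed monotone nonlinear relation: Spearman, rank identity
    h <- exp(rnorm(80, 0, 1.5))^2
    res2 <- qm_correlation(h, h^3)
    expect_equal(res2$method, "spearman")
    expect_equal(res2$estimate, 1)

    # independent normals: near-zero coefficient
    x <- rnorm(1000); y <- rnorm(1000)
    expect_lt(abs(qm_correlation(x, y)$estimate), 0.1)

    # constant series: undefined marker, not an error
    expect_equal(qm_correlation(rep(1, 10), rnorm(10))$method, "undefined")
  })
})

test_that("Bland-Altman reproduces its closed-form pieces", {
  # identity: MD 0, collapsed LOA, everything within
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$md, 0)
  expect_equal(unname(ba0$loa), c(0, 0))
  expect_true(all(ba0$data$within_loa))
  expect_true(is.na(ba0$trend$slope))        # zero-variance differences

  # d = {-1, 0, 1}: MD 0, sample SD 1, LOA [-1.96, 1.96]
  ba1 <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba1$md, 0)
  expect_equal(ba1$sd_diff, 1)
  expect_equal(unname(ba1$loa), c(-1.96, 1.96))

  # LOA symmetry about MD
  withr::with_seed(12, {
    a <- rnorm(50, 1, 0.3); b <- rnorm(50, 1, 0.3)
    ba <- bland_altman(a, b)
    expect_equal(ba$loa[["upper"]] - ba$md, ba$md - ba$loa[["lower"]],
                 tolerance = 1e-12)
  })
  expect_error(bland_altman(1, 1), class = "vm_validation_error")
})

test_that("subgroup rows use the global LOA", {
  withr::with_seed(19, {
    n <- 200
    bins <- sample(qm_bins(), n, replace = TRUE, prob = c(0.7, 0.15, 0.1, 0.05))
    b <- runif(n, 0.5, 1)
    noise_scale <- c("<20" = 0.01, "20-25" = 0.03, "25-40" = 0.06, ">40" = 0.12)
    a <- b + rnorm(n, 0, noise_scale[bins])
    ba <- bland_altman(a, b, bins = bins)
    expect_equal(sum(ba$subgroups$n), n)
    # within-LOA flags recomputed against the global LOA by hand
    manual <- tapply(ba$data$diff >= ba$loa[["lower"]] &
                     ba$data$diff <= ba$loa[["upper"]], ba$data$bin, mean)
    expect_equal(ba$subgroups$within_loa_pct,
                 100 * as.numeric(manual[as.character(ba$subgroups$bin)]))
    # heteroscedastic differences: the most collapsed bin falls out of the
    # global LOA most often
    expect_lt(ba$subgroups$within_loa_pct[ba$subgroups$bin == ">40"],
              ba$subgroups$within_loa_pct[ba$subgroups$bin == "<20"])
  })
})

test_that("evaluate_pipeline on identical annotations is a perfect report", {
  case <- generate_phantom(small_spec(deformities = tibble::tibble(
    level = c("V2", "V4"), type = c("wedge", "biconcave"), severity = c(0.3, 0.5)
  )))
  truth <- case$truth_landmarks
  rep <- evaluate_pipeline(truth, truth)
  expect_equal(rep$detection$sensitivity_pct, 100)
  expect_equal(rep$detection$FP, 0)
  expect_true(all(rep$landmark_errors$x_error_pct == 0))
  expect_true(all(rep$landmark_errors$y_error_pct == 0))
  for (r in names(rep$correlations)) {
    expect_equal(rep$correlations[[r]]$estimate, 1)
  }
  expect_false(any(rep$discrepancies$flagged))
  g <- glance(rep)
  expect_equal(g$n_paired, 5)
  expect_equal(g$n_discrepancies, 0)
})

test_that("missing predictions count as reference non-detections", {
  case <- generate_phantom(small_spec())
  truth <- case$truth_landmarks
  pred <- truth[-3, ]
  rep <- evaluate_pipeline(pred, truth)
  expect_equal(rep$detection$TP, 4)
  expect_equal(rep$detection$n_reference, 5)
  expect_equal(rep$detection$FP, 0)
  expect_equal(nrow(rep$paired), 4)
  expect_error(evaluate_pipeline(dplyr::mutate(pred, image_id = "other"), truth),
               class = "vm_validation_error")
})

test_that("tidiers return the documented shapes", {
  withr::with_seed(5, {
    a <- rnorm(40, 1, 0.1); b <- a + rnorm(40, 0, 0.05)
    ba <- bland_altman(a, b, bins = sample(qm_bins()[1:2], 40, replace = TRUE))
    td <- tidy(ba)
    expect_true(all(c("bin", "n", "md", "sd", "within_loa_pct") %in% names(td)))
    gl <- glance(ba)
    expect_equal(nrow(gl), 1)
    expect_equal(gl$loa_upper - gl$md, gl$md - gl$loa_lower, tolerance = 1e-12)

    ctr <- tibble::tibble(x = c(5, 7, 9, 12), y = c(0, 10, 20, 30))
    fit <- fit_spinal_curve(ctr, residual_threshold = 1)
    expect_equal(nrow(tidy(fit)), fit$degree + 1)
    expect_equal(glance(fit)$n_centers, 4)
  })
})
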