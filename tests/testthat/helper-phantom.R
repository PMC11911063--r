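# Shared fixtures: small phantoms and an independent polynomial-RANSAC
# oracle used to cross-check the package's fit.

# A compact 5-vertebra phantom spec (fast to render in unit tests).
small_spec <- function(deformities = NULL, noise_sd = 0, confusers = character(0),
                       seed = 1L, n_vertebrae = 5, ...) {
  phantom_spec(
    image_size = c(256L, 128L), n_vertebrae = n_vertebrae, base_width = 26,
    base_height = 16, gap = 8, noise_sd = noise_sd, confusers = confusers,
    deformities = deformities, seed = seed, ...
  )
}

# Axis-aligned rectangular landmark set (one row), for arithmetic tests.
rect_landmarks <- function(x0 = 0, y0 = 0, w = 10, h = 10, frame = "image") {
  tibble::tibble(
    AU_x = x0, AU_y = y0, AL_x = x0, AL_y = y0 + h,
    CU_x = x0 + w / 2, CU_y = y0, CL_x = x0 + w / 2, CL_y = y0 + h,
    PU_x = x0 + w, PU_y = y0, PL_x = x0 + w, PL_y = y0 + h,
    frame = frame
  )
}

# Independent exhaustive RANSAC oracle: enumerate every minimal sample of
# every degree, fit by normal-equation least squares, and apply the same
# model-selection rule (max inliers, then lower degree, then lower inlier
# SSE). Returns the winning consensus inlier set.
ransac_oracle <- function(x, y, max_degree, threshold) {
  n <- length(x)
  best <- NULL
  for (degree in seq_len(min(max_degree, n - 1))) {
    for (idx in utils::combn(n, degree + 1, simplify = FALSE)) {
      V <- outer(y[idx], 0:degree, `^`)
      if (qr(V)$rank < degree + 1) next
      cf <- qr.solve(V, x[idx])
      res <- abs(x - drop(outer(y, 0:degree, `^`) %*% cf))
      inl <- res <= threshold
      cand <- list(n_in = sum(inl), degree = degree, sse = sum(res[inl]^2),
                   inliers = inl)
      if (is.null(best) || cand$n_in > best$n_in ||
          (cand$n_in == best$n_in && cand$degree < best$degree) ||
          (cand$n_in == best$n_in && cand$degree == best$degree &&
           cand$sse < best$sse)) {
        best <- cand
      }
    }
  }
  best
}

# Independent matching oracle: best one-to-one assignment by exhaustive
# permutation, maximizing the number of pairs within tau (ties by total
# distance). Returns the maximal TP count.
matching_oracle_tp <- function(pred, ref, tau) {
  np <- nrow(pred); nr <- nrow(ref)
  if (np == 0 || nr == 0) return(0L)
  dmat <- sqrt(outer(pred$x, ref$x, `-`)^2 + outer(pred$y, ref$y, `-`)^2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  k <- min(np, nr)
  best_tp <- 0L
  for (ps in perms(seq_len(nr))) {
    assign <- ps[seq_len(k)]          # prediction i -> reference assign[i]
    if (np > nr) next                 # handled by symmetry below
    tp <- sum(dmat[cbind(seq_len(k), assign)] <= tau)
    best_tp <- max(best_tp, tp)
  }
  if (np > nr) {
    for (ps in perms(seq_len(np))) {
      assign <- ps[seq_len(nr)]       # reference j -> prediction assign[j]
      tp <- sum(dmat[cbind(assign, seq_len(nr))] <= tau)
      best_tp <- max(best_tp, tp)
    }
  }
  best_tp
}
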