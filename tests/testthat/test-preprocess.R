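test_that("the focus score behaves like a sharpness metric", {
  expect_equal(sharpness_score(matrix(7, 32, 32)), 0)
  set.seed(1)
  checker <- matrix(rep(c(0, 100), length.out = 40 * 40), 40, 40)
  blurred <- embryoscreen:::gauss_blur_cpp(checker, 1.5)
  expect_gt(sharpness_score(checker), sharpness_score(blurred))
  # additive offsets leave the Laplacian, hence the score, unchanged
  img <- matrix(runif(30 * 30, 0, 100), 30, 30)
  expect_equal(sharpness_score(img + 50), sharpness_score(img))
  # cross-check against an explicit variance-of-Laplacian computation
  lap <- function(m) {
    nr <- nrow(m); nc <- ncol(m); out <- c()
    for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
      out <- c(out, 4 * m[i, j] - m[i - 1, j] - m[i + 1, j] -
                 m[i, j - 1] - m[i, j + 1])
    }
    out
  }
  expect_equal(sharpness_score(img), var(lap(img)))
  expect_error(sharpness_score(matrix(numeric(0), 0, 0)), "empty")
})

test_that("best-slice selection is the exhaustive argmax with low-index ties", {
  set.seed(2)
  base <- matrix(runif(48 * 48, 0, 100), 48, 48)
  stack <- lapply(0:4, function(z) {
    if (z == 2) base else embryoscreen:::gauss_blur_cpp(base, abs(z - 2) * 1.2)
  })
  b <- select_best_slice(stack)
  expect_equal(b$z_index, 2L)
  expect_identical(b$image, stack[[3]])
  scores <- vapply(stack, sharpness_score, numeric(1))
  expect_equal(b$z_index, which.max(scores) - 1L)

  expect_equal(select_best_slice(list(base))$z_index, 0L)
  expect_equal(select_best_slice(list(base, base, base))$z_index, 0L)
  expect_error(select_best_slice(list()), "empty")
})

test_that("maximum projection equals the per-pixel brute-force maximum", {
  expect_equal(max_project(list(matrix(0, 4, 4), matrix(0, 4, 4))),
               matrix(0, 4, 4))
  one <- matrix(0, 5, 6); one[3, 4] <- 7
  expect_equal(max_project(list(matrix(0, 5, 6), one, matrix(0, 5, 6))), one)
  set.seed(3)
  s1 <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  s2 <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  mp <- max_project(list(s1, s2))
  for (i in seq_len(30)) for (j in seq_len(20)) {
    expect_identical(mp[i, j], max(s1[i, j], s2[i, j]))
  }
  expect_error(max_project(list(s1, matrix(0, 3, 3))), "mismatch")
  # idempotence and monotonicity
  expect_equal(max_project(list(mp)), mp)
  s3 <- matrix(sample(0:255, 30 * 20, TRUE), 30, 20)
  mp3 <- max_project(list(s1, s2, s3))
  expect_true(all(mp3 >= mp))
})

test_that("stitching obeys the length formula and copies exclusive pixels", {
  set.seed(4)
  L <- 96L
  tiles <- lapply(1:4, function(k) matrix(runif(40 * L, 0, 1000), 40, L))
  for (n in 1:4) {
    for (ov in c(0, 0.15, 0.3)) {
      st <- stitch_fields(tiles[seq_len(n)], ov)
      expect_equal(ncol(st$image), n * L - (n - 1) * round(ov * L))
    }
  }
  st <- stitch_fields(tiles[1], 0.15)
  expect_equal(st$image, tiles[[1]])
  expect_equal(st$offsets, 0L)

  # pixels outside any overlap equal their source tile exactly
  ov <- 0.15
  step <- L - as.integer(round(ov * L))
  olap <- L - step
  st <- stitch_fields(tiles[1:2], ov)
  expect_equal(st$image[, 1:step], tiles[[1]][, 1:step])
  expect_equal(st$image[, (L + 1):(L + step)],
               tiles[[2]][, (olap + 1):L])
  stm <- stitch_fields(tiles[1:2], ov, blend = "max")
  expect_equal(stm$image[, (step + 1):L],
               pmax(tiles[[1]][, (step + 1):L], tiles[[2]][, 1:olap]))
  expect_error(stitch_fields(list(tiles[[1]], matrix(0, 3, 3)), 0.1),
               "unequal")
})

test_that("registration refinement recovers a known tile shift", {
  rw <- lateral_well()
  canvas <- rw$canvas$BF[[rw$layout$z_focus + 1]]
  L <- 120L
  true_shift <- 97L   # instead of the nominal step 102 = L - round(0.15 L)
  t1 <- canvas[, 1:L]
  t2 <- canvas[, (true_shift + 1):(true_shift + L)]
  st <- stitch_fields(list(t1, t2), 0.15, refine = TRUE, search_radius = 10)
  expect_equal(st$offsets[2], true_shift)
  # exhaustive-search oracle over the same radius
  nominal <- L - as.integer(round(0.15 * L))
  errs <- vapply((nominal - 10):(nominal + 10), function(cand) {
    ovw <- L - cand
    mean((canvas[, (cand + 1):(cand + ovw)] - t2[, 1:ovw])^2)
  }, numeric(1))
  expect_equal(st$offsets[2], ((nominal - 10):(nominal + 10))[which.min(errs)])
})

test_that("stitching the generator tiles reproduces the seamless canvas", {
  rw <- lateral_well()
  spec <- rw$spec
  stacks <- fields_to_stacks(rw$fields, spec)
  sw <- preprocess_well(stacks, spec)
  mip_canvas <- round(Reduce(pmax, rw$canvas$GFP))
  expect_lt(max(abs(sw$images$GFP - mip_canvas)), 1 + 1e-8)
  expect_equal(dim(sw$images$BF), dim(sw$images$GFP))
  expect_equal(sw$best_z, rep(rw$layout$z_focus, spec$fields_per_well))
  # granule detection on stitched tiles matches detection on the canvas
  cfg <- run_config(spec)
  mask <- matrix(TRUE, nrow(mip_canvas), ncol(mip_canvas))
  n_stitched <- nrow(detect_granules(sw$images$GFP, cfg$granule_params$GFP, mask))
  n_canvas <- nrow(detect_granules(mip_canvas, cfg$granule_params$GFP, mask))
  expect_equal(n_stitched, n_canvas)
})
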