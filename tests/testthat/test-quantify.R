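test_that("disc fixtures are counted with area constraints applied", {
  set.seed(70)
  img <- matrix(0, 64, 64)
  centres <- expand.grid(x = c(10, 26, 42, 58), y = c(10, 30, 50))[1:10, ]
  for (k in 1:10) {
    r <- if (k <= 2) 1 else 3    # two discs below the minimum area
    img <- draw_disc(img, centres$x[k], centres$y[k], r, 100)
  }
  mask <- matrix(TRUE, 64, 64)
  p <- granule_params(smoothing_sigma = 0, background_radius = 0,
                      threshold_mode = "absolute", threshold_value = 50,
                      min_area = 10, max_area = 200)
  gr <- detect_granules(img, p, mask)
  expect_equal(nrow(gr), 8L)
  orc <- oracle_detect(img, 50, 10, 200, mask)
  expect_equal(sort(gr$area), sort(orc$area))
  expect_equal(sort(gr$integrated_intensity), sort(orc$integrated_intensity))
})

test_that("granules whose centroid leaves the fish are disregarded", {
  img <- matrix(0, 40, 40)
  img <- draw_disc(img, 10, 10, 3, 100)   # inside
  img <- draw_disc(img, 30, 30, 3, 100)   # outside
  mask <- matrix(FALSE, 40, 40); mask[1:20, 1:20] <- TRUE
  p <- granule_params(0, 0, "absolute", 50, 3, 100)
  gr <- detect_granules(img, p, mask)
  expect_equal(nrow(gr), 1L)
  expect_lt(gr$x, 20)
  expect_equal(nrow(detect_granules(matrix(0, 40, 40), p, mask)), 0L)
  expect_error(detect_granules(img, p, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("local-background thresholding suppresses haze that fools an absolute cut", {
  spec <- spec_half()
  hz <- fixture("haze_well", function() {
    set.seed(71)
    lay <- embryo_layout("lateral_left", spec)
    rw <- render_well(lay, sample_spots(lay, spec, spot_laws_preset("none", spec)),
                      spec, noise = noise_params(enabled = FALSE), seed = 72,
                      keep_masks = TRUE)
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec), spec)
    list(rw = rw, sw = sw)
  })
  mask <- hz$rw$masks$body
  ksig <- run_config(spec)$granule_params$GFP
  expect_equal(nrow(detect_granules(hz$sw$images$GFP, ksig, mask)), 0L)
  lv <- embryoscreen:::render_levels(2^spec$bit_depth - 1)
  naive <- granule_params(smoothing_sigma = 0, background_radius = 0,
                          threshold_mode = "absolute",
                          threshold_value = lv$fl_bg + 0.4 * lv$haze_amp,
                          min_area = 3, max_area = Inf)
  expect_gt(nrow(detect_granules(hz$sw$images$GFP, naive, mask)), 0L)
})

test_that("granules inherit the region of their centroid pixel", {
  pr <- processed_lateral()
  gr <- detect_granules(pr$sw$images$GFP, pr$cfg$granule_params$GFP,
                        pr$seg$fish_mask)
  gr <- assign_regions(gr, pr$seg)
  spots <- pr$rw$spots
  tail_truth <- spots[spots$region == "tail", ]
  for (k in seq_len(min(5, nrow(tail_truth)))) {
    d <- sqrt((gr$x - tail_truth$x[k])^2 + (gr$y - tail_truth$y[k])^2)
    expect_equal(gr$region[which.min(d)], "tail")
  }
  # boundary centroid: the label-map pixel decides, deterministically
  bpx <- which(pr$seg$region_map == 2L &
                 cbind(pr$seg$region_map[, -1], 0L) == 3L)[1]
  by <- (bpx - 1) %% nrow(pr$seg$region_map)
  bx <- (bpx - 1) %/% nrow(pr$seg$region_map)
  fake <- structure(data.frame(x = bx, y = by, area = 5,
                               integrated_intensity = 10, mean_intensity = 2,
                               region = NA_character_),
                    class = c("granule_set", "data.frame"))
  expect_equal(assign_regions(fake, pr$seg)$region, "trunk")
  empty <- fake[0, ]
  expect_equal(nrow(assign_regions(empty, pr$seg)), 0L)
})

test_that("region metrics aggregate correctly and sum to the whole fish", {
  g <- structure(data.frame(x = 1:3, y = 1:3, area = c(10, 20, 30),
                            integrated_intensity = c(100, 200, 300),
                            mean_intensity = c(10, 10, 10),
                            region = c("tail", "tail", "trunk")),
                 class = c("granule_set", "data.frame"))
  m <- region_metrics(g)
  expect_equal(m$total_granule_area[m$region == "tail"], 30)
  expect_equal(m$mean_granule_area[m$region == "tail"], 15)
  expect_equal(m$count[m$region == "fish"], 3)
  expect_equal(m$total_granule_area[m$region == "fish"], 60)
  expect_equal(m$mean_granule_area[m$region == "fish"], 20)
  expect_true(is.na(m$mean_granule_area[m$region == "head"]))
  expect_equal(m$count[m$region == "head"], 0)
  # additivity holds on a real well too
  pr <- processed_lateral(noisy = TRUE)
  gr <- assign_regions(detect_granules(pr$sw$images$GFP,
                                       pr$cfg$granule_params$GFP,
                                       pr$seg$fish_mask), pr$seg)
  mm <- region_metrics(gr)
  expect_equal(mm$count[mm$region == "fish"],
               sum(mm$count[mm$region != "fish"]))
  expect_equal(mm$integrated_intensity[mm$region == "fish"],
               sum(mm$integrated_intensity[mm$region != "fish"]))
})

test_that("one added well-separated disc increases the count by exactly one", {
  set.seed(73)
  img <- matrix(0, 96, 96)
  img <- draw_disc(img, 20, 20, 3, 100)
  img <- draw_disc(img, 60, 40, 3, 100)
  p <- granule_params(smoothing_sigma = 1, background_radius = 6,
                      threshold_mode = "absolute", threshold_value = 20,
                      min_area = 3, max_area = 200)
  mask <- matrix(TRUE, 96, 96)
  n0 <- nrow(detect_granules(img, p, mask))
  img2 <- draw_disc(img, 25, 75, 3, 100)   # > 4 sigma + radius from others
  expect_equal(nrow(detect_granules(img2, p, mask)), n0 + 1L)
})

test_that("QC reports the first failing check in the fixed order", {
  pr <- processed_lateral()
  crit <- pr$cfg$qc
  expect_equal(apply_qc(pr$seg, crit), list(included = TRUE, reason = "ok"))
  expect_equal(apply_qc(NULL, crit)$reason, "empty_well")
  s <- pr$seg
  s$eye_count <- 2L
  expect_equal(apply_qc(s, crit)$reason, "eye_count")
  s$eye_count <- 1L; s$tail_count <- 0L
  expect_equal(apply_qc(s, crit)$reason, "tail_count")
  s$tail_count <- 1L
  big <- qc_criteria(min_fish_area = s$fish_area + 1,
                     min_tail_area = crit$min_tail_area)
  expect_equal(apply_qc(s, big)$reason, "fish_area")
  bigger <- qc_criteria(min_fish_area = crit$min_fish_area,
                        min_tail_area = s$region_areas[["tail"]] + 1)
  expect_equal(apply_qc(s, bigger)$reason, "tail_area")
  # a dorsal embryo fails on the eye count
  expect_equal(apply_qc(dorsal_seg()$seg, crit)$reason, "eye_count")
})

test_that("granule parameters validate their invariants", {
  expect_error(granule_params(min_area = 10, max_area = 5), "min_area")
  expect_error(granule_params(threshold_value = 0), "threshold_value")
  expect_error(granule_params(smoothing_sigma = -1), "smoothing_sigma")
})
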