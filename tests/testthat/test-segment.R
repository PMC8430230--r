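test_that("the fish mask recovers the true silhouette", {
  pr <- processed_lateral()
  seg <- pr$seg
  truth_area <- pr$rw$truth$fish_area
  expect_false(is.null(seg))
  expect_lt(abs(seg$fish_area - truth_area) / truth_area, 0.10)
  # the mask is a single 8-connected component
  expect_equal(max(label_components(seg$fish_mask, 8)), 1L)
})

test_that("empty wells and sub-threshold debris give no fish", {
  spec <- spec_half()
  rw <- render_presentation("absent", seed = 31)
  sw <- preprocess_well(fields_to_stacks(rw$fields, spec), spec)
  cons <- size_constraints(spec)
  expect_null(segment_fish(sw$images$BF, cons))
  expect_null(segment_embryo(sw$images$BF, cons))

  # two dark blobs far below the minimum fish area
  cs <- canvas_shape(spec)
  img <- matrix(10000, cs[1], cs[2])
  img <- draw_disc(img, 100, 60, 8, 6000)
  img <- draw_disc(img, 300, 200, 10, 6000)
  expect_null(segment_fish(img, cons))
})

test_that("eye detection counts one eye on-side and two on-back", {
  pr <- processed_lateral()
  expect_equal(pr$seg$eye_count, 1L)
  truth_eye <- pr$rw$layout$eyes[[1]]
  pos <- layout_point(pr$rw$layout, truth_eye$u, truth_eye$v)
  cen <- pr$seg$anatomy$eye[[1]]$centroid
  expect_lt(sqrt(sum((cen - pos)^2)), 5)

  dr <- dorsal_seg()
  expect_equal(dr$seg$eye_count, 2L)
  expect_equal(detect_eyes(matrix(1, 4, 4), NULL, size_constraints(spec_half())),
               list())
})

test_that("the yolk caudal tip lands near the generator's extension tip", {
  pr <- processed_lateral()
  yolk <- pr$seg$anatomy$yolk_sac
  expect_length(yolk, 1L)
  tip_truth <- layout_point(pr$rw$layout, pr$rw$layout$yolk$tip_u,
                            pr$rw$layout$yolk$tip_v)
  expect_lt(sqrt(sum((yolk[[1]]$caudal_tip - tip_truth)^2)), 10)

  # eyes alone must not masquerade as yolk
  spec <- spec_half()
  cs <- canvas_shape(spec)
  img <- matrix(10000, cs[1], cs[2])
  mask <- matrix(FALSE, cs[1], cs[2])
  mask[80:180, 80:600] <- TRUE
  img[80:180, 80:600] <- 7000
  img <- draw_disc(img, 120, 128, 10, 1500)   # one dark eye-like disc
  cons <- size_constraints(spec)
  expect_null(detect_yolk(img, mask, cons))
  expect_null(detect_yolk(img, NULL, cons))
})

test_that("the tail terminus flags partially imaged fish", {
  pr <- processed_lateral()
  expect_equal(pr$seg$tail_count, 1L)
  pp <- fixture("partial_seg", function() {
    rw <- render_presentation("partial", seed = 35)
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec_half()), spec_half())
    segment_embryo(sw$images$BF, size_constraints(spec_half()))
  })
  expect_equal(pp$tail_count, 0L)
  td <- detect_tail(matrix(1, 4, 4), NULL, size_constraints(spec_half()))
  expect_null(td$region)
  expect_equal(td$tail_count, 0L)
})

test_that("the head/trunk/tail partition is sound and matches the truth tail", {
  pr <- processed_lateral()
  rm_ <- pr$seg$region_map
  mask <- pr$seg$fish_mask
  expect_true(all(rm_[mask] %in% 1:3))
  expect_true(all(rm_[!mask] == 0L))
  expect_equal(sum(pr$seg$region_areas), pr$seg$fish_area)

  truth_tail <- pr$rw$masks$region_map == 3L
  overlap <- sum(rm_ == 3L & truth_tail) / sum(truth_tail)
  expect_gte(overlap, 0.95)

  # stability under intensity rescaling
  sw2 <- lapply(pr$sw$images, function(m) m * 1.7)
  seg2 <- segment_embryo(sw2$BF, pr$cfg$constraints)
  expect_equal(seg2$region_map, rm_)
})

test_that("partition falls back to fixed fractions without landmarks", {
  pr <- processed_lateral()
  mask <- pr$seg$fish_mask
  axis <- pr$seg$body_axis
  rm_ <- partition_regions(mask, axis, landmarks = list())
  u <- c(0, cumsum(sqrt(diff(axis[, 1])^2 + diff(axis[, 2])^2)))
  total <- u[length(u)]
  # boundary columns: nearest axis vertex to each requested fraction
  x_head <- axis[which.min(abs(u - 0.25 * total)), 1]
  x_tail <- axis[which.min(abs(u - 0.55 * total)), 1]
  cols_head <- which(apply(rm_ == 1L, 2, any)) - 1
  cols_trunk <- which(apply(rm_ == 2L, 2, any)) - 1
  expect_lt(abs(max(cols_head) - x_head), 3)
  expect_lt(abs(max(cols_trunk) - x_tail), 3)
  expect_error(partition_regions(mask, axis[c(3, 1, 2), ], list()),
               "ordered")
})

test_that("a one-pixel-wide mask partitions into three contiguous runs", {
  mask <- matrix(FALSE, 5, 60)
  mask[3, 6:55] <- TRUE
  axis <- cbind(x = 5:54, y = rep(2, 50))
  rm_ <- partition_regions(mask, axis, list())
  labs <- rm_[3, 6:55]
  expect_true(all(labs %in% 1:3))
  expect_equal(labs, sort(labs))       # 1s, then 2s, then 3s: contiguous
  expect_setequal(unique(labs), 1:3)
})

test_that("morphometrics track analytic truth and scale with pixel size", {
  spec <- spec_half()
  H <- canvas_shape(spec)[1]
  areas <- vapply(c(9, 12), function(rpx) {
    set.seed(40 + rpx)
    lay <- embryo_layout("lateral_left", spec, eye_radius_frac = rpx / H)
    rw <- render_well(lay, sample_spots(lay, spec, spot_laws_preset("none", spec)),
                      spec, noise = noise_params(enabled = FALSE), seed = rpx)
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec), spec)
    seg <- segment_embryo(sw$images$BF, size_constraints(spec))
    seg$eye_area
  }, numeric(1))
  expect_lt(abs(areas[2] - pi * 12^2) / (pi * 12^2), 0.10)
  expect_lt(areas[1], areas[2])

  pr <- processed_lateral()
  m_px <- measure_morphology(pr$seg)
  m_um <- measure_morphology(pr$seg, pixel_size = 3.25)
  expect_equal(m_um$fish_area, m_px$fish_area * 3.25^2)
  expect_equal(m_um$fish_length, m_px$fish_length * 3.25)
  expect_equal(sum(m_px$region_areas), m_px$fish_area)
})

test_that("fish area grows with the generator's body-size parameter", {
  spec <- spec_quarter_bf()
  areas <- vapply(c(0.85, 1, 1.1), function(sf) {
    set.seed(50)
    lay <- embryo_layout("lateral_left", spec, size_factor = sf)
    rw <- render_well(lay, sample_spots(lay, spec, spot_laws_preset("none", spec)),
                      spec, seed = 51)
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec), spec)
    segment_fish(sw$images$BF, size_constraints(spec))
    sum(segment_fish(sw$images$BF, size_constraints(spec)))
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("the QC overlay writer produces a PNG with painted outlines", {
  pr <- processed_lateral()
  f <- withr::local_tempfile(fileext = ".png")
  write_qc_overlay(pr$sw$images$BF, pr$seg, f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], dim(pr$sw$images$BF))
  # outline pixels are saturated colour, so channels must differ somewhere
  expect_gt(max(abs(img[, , 1] - img[, , 2])), 0.5)
})

test_that("an oracle segmenter slots into the pipeline and is exact", {
  spec <- spec_half()
  plate <- fixture("oracle_plate", function() {
    generate_plate(4, spec, seed = 61, noise = noise_params(enabled = FALSE),
                   presentation_mix = c(lateral_left = 1, lateral_right = 0,
                                        dorsal = 0, partial = 0, absent = 0),
                   keep_masks = TRUE)
  })
  cfg <- run_config(spec)
  rec <- run_plate(plate, cfg, segmenter = oracle_segmenter(plate))
  expect_true(all(rec$qc_included))
  tr <- plate$truth_counts
  for (w in rec$well) {
    expect_equal(rec$GFP_tail_count[rec$well == w],
                 tr$count[tr$well == w & tr$channel == "GFP" & tr$region == "tail"])
    expect_equal(rec$fish_area[rec$well == w],
                 plate$truth_layout$fish_area[plate$truth_layout$well == w])
  }
})
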