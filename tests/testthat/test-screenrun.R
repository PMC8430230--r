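small_plate <- function() {
  fixture("small_plate", function() {
    generate_plate(8, spec_quarter_bf(), seed = 80,
                   presentation_mix = c(lateral_left = 5 / 8,
                                        lateral_right = 1 / 8, dorsal = 1 / 8,
                                        partial = 0, absent = 1 / 8))
  })
}

test_that("a plate run yields one record per well with truthful QC", {
  plate <- small_plate()
  cfg <- run_config(spec_quarter_bf())
  rec <- run_plate(plate, cfg)
  expect_equal(nrow(rec), 8L)
  expect_equal(sort(rec$well[!rec$qc_included]), misoriented_wells(plate))
  expect_true(all(rec$qc_reason[rec$qc_included] == "ok"))
  expect_true(all(is.na(rec$fish_area[!rec$qc_included])))
})

test_that("results are invariant to well processing order", {
  plate <- small_plate()
  cfg <- run_config(spec_quarter_bf())
  rec1 <- run_plate(plate, cfg)
  shuffled <- plate
  set.seed(81)
  shuffled$wells <- shuffled$wells[sample(names(shuffled$wells))]
  rec2 <- run_plate(shuffled, cfg)
  expect_identical(rec1, rec2)
})

test_that("two identical disk runs produce byte-identical results files", {
  spec <- plate_spec(tile_shape = c(128L, 174L))
  dir <- withr::local_tempdir()
  generate_plate(6, spec, seed = 82, dir = dir)
  cfg <- run_config(spec)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_plate(dir, cfg, out = out1, dump_granules = TRUE)
  run_plate(dir, cfg, out = out2)
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
  # the optional per-granule dump has one row per detected granule
  g <- utils::read.csv(file.path(out1, "granules.csv"))
  rec <- read_results(file.path(out1, "results.csv"))
  expect_equal(nrow(g), sum(rec$GFP_fish_count, na.rm = TRUE))
  expect_true(all(c("well", "channel", "x", "y", "area", "region") %in% names(g)))
  # the area unit travels with the table: px^2 while uncalibrated
  expect_true(all(rec$area_unit == "px2"))
})

test_that("an all-empty plate yields only empty_well exclusions", {
  spec <- spec_quarter_bf()
  plate <- generate_plate(4, spec, seed = 83,
                          presentation_mix = c(lateral_left = 0,
                                               lateral_right = 0, dorsal = 0,
                                               partial = 0, absent = 1))
  rec <- run_plate(plate, run_config(spec))
  expect_true(all(!rec$qc_included))
  expect_true(all(rec$qc_reason == "empty_well"))
})

test_that("missing tiles abort the plate with a per-well report", {
  spec <- spec_quarter_bf()
  dir <- withr::local_tempdir()
  generate_plate(3, spec, seed = 84, dir = dir)
  file.remove(file.path(dir, "A02_f1_BF_z3.tif"))
  expect_error(run_plate(dir, run_config(spec)), "A02")
})

test_that("group summaries match the pooled-variance t-test by hand", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  rec <- data.frame(well = sprintf("A%02d", 1:10), qc_included = TRUE,
                    qc_reason = "ok", value = c(a, b))
  grp <- data.frame(well = rec$well, condition = rep(c("ctl", "trt"), each = 5))
  gs <- summarize_groups(rec, "value", grp)
  cmp <- attr(gs, "comparisons")
  # closed-form pooled-variance oracle
  sp2 <- ((5 - 1) * var(a) + (5 - 1) * var(b)) / (5 + 5 - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 8)
  expect_equal(cmp$t, t_oracle)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$p, p_oracle)
  expect_equal(gs$mean, c(mean(a), mean(b)))
  expect_equal(gs$sd, c(sd(a), sd(b)))

  # identical groups: t = 0, p = 1
  rec2 <- rec; rec2$value <- rep(c(1, 2, 3, 4, 5), 2)
  cmp2 <- attr(summarize_groups(rec2, "value", grp), "comparisons")
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$p, 1)
})

test_that("excluded wells never reach a group summary", {
  rec <- data.frame(well = sprintf("A%02d", 1:6),
                    qc_included = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                    qc_reason = c("ok", "ok", "eye_count", "ok", "ok",
                                  "empty_well"),
                    value = c(1, 2, 1000, 3, 4, -1000))
  grp <- data.frame(well = rec$well, condition = rep(c("x", "y"), 3))
  gs <- summarize_groups(rec, "value", grp)
  expect_equal(gs$n, c(2L, 2L))
  expect_equal(gs$mean[gs$condition == "x"], mean(c(1, 4)))   # A03 excluded
  # fewer than two included wells per side: not computable
  rec$qc_included <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  cmp <- attr(summarize_groups(rec, "value", grp), "comparisons")
  expect_true(is.na(cmp$t) && is.na(cmp$p))
})

test_that("dual-fluorophore wells quantify each colour independently", {
  spec <- plate_spec(tile_shape = c(256L, 348L),
                     channels = list(channel_role("BF", "brightfield"),
                                     channel_role("GFP", "fluorescence"),
                                     channel_role("mCherry", "fluorescence")))
  plate <- generate_plate(1, spec, seed = 90,
                          presentation_mix = c(lateral_left = 1,
                                               lateral_right = 0, dorsal = 0,
                                               partial = 0, absent = 0),
                          laws = spot_laws_preset("dual", spec),
                          noise = noise_params(enabled = FALSE))
  rec <- run_plate(plate, run_config(spec, preset = "dual"))
  tr <- plate$truth_counts
  expect_equal(rec$GFP_tail_count,
               tr$count[tr$channel == "GFP" & tr$region == "tail"])
  expect_equal(rec$mCherry_tail_count,
               tr$count[tr$channel == "mCherry" & tr$region == "tail"])
  expect_gt(rec$GFP_tail_count, 0)
  expect_gt(rec$mCherry_tail_count, 0)
})

test_that("run configurations survive a YAML round trip", {
  spec <- plate_spec(tile_shape = c(128L, 174L), pixel_size = 3.25)
  cfg <- run_config(spec, preset = "haircell", seed = 7L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_equal(back$spec$tile_shape, spec$tile_shape)
  expect_equal(back$spec$pixel_size, 3.25)
  expect_equal(back$preset$name, "haircell")
  expect_equal(back$qc, cfg$qc)
  expect_equal(back$granule_params, cfg$granule_params)
  expect_equal(back$seed, 7L)
  expect_equal(vapply(back$spec$channels, `[[`, character(1), "projection"),
               vapply(cfg$spec$channels, `[[`, character(1), "projection"))
})
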