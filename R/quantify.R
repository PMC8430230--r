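#' Parameters of the fluorescent granule detector
#'
#' The detector applies, in this fixed order: Gaussian smoothing, background
#' subtraction (morphological opening with a disc — a rolling-ball
#' equivalent that removes structures narrower than the disc while leaving
#' the broad autofluorescence haze in the background estimate), thresholding,
#' 8-connected component labelling, area constraints and the containment
#' rule (a granule counts only if its centroid lies inside the fish mask).
#'
#' Two threshold modes exist. `"absolute"` cuts the background-subtracted
#' image at a fixed intensity. `"k_sigma_above_local_background"` cuts at
#' `k` robust standard deviations (MAD) of the background-subtracted
#' residual, with a small absolute floor guarding the noise-free limit; this
#' is what makes the dim (GFP-lo) cell class detectable over head/yolk
#' autofluorescence that a naive global threshold cannot separate.
#'
#' @param smoothing_sigma Gaussian sigma in px (0 disables smoothing).
#' @param background_radius Disc radius in px for the opening (0 disables
#'   background subtraction).
#' @param threshold_mode `"absolute"` or `"k_sigma_above_local_background"`.
#' @param threshold_value Intensity cut (absolute mode) or the multiplier
#'   `k` (k-sigma mode); must be positive.
#' @param min_area,max_area Component area bounds in px^2.
#' @param threshold_floor Minimum threshold in intensity counts for the
#'   k-sigma mode (guards quantization-level residuals when noise is absent).
#' @return An object of class `granule_params`.
#' @export
granule_params <- function(smoothing_sigma = 1.5, background_radius = 10,
                           threshold_mode = c("k_sigma_above_local_background",
                                              "absolute"),
                           threshold_value = 4, min_area = 3,
                           max_area = 500, threshold_floor = 2) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(smoothing_sigma >= 0, background_radius >= 0,
            threshold_value > 0, min_area <= max_area, min_area >= 0)
  structure(list(smoothing_sigma = smoothing_sigma,
                 background_radius = background_radius,
                 threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_area = min_area, max_area = max_area,
                 threshold_floor = threshold_floor),
            class = "granule_params")
}

#' Detect fluorescent granules
#'
#' Runs the operator chain of [granule_params()] on a fluorescence image.
#' Granule metrics (integrated and mean intensity) are computed on the
#' original, unprocessed image so they do not depend on the smoothing or
#' background parameters. Components whose centroid falls outside the fish
#' mask are disregarded.
#'
#' @param fluor Numeric matrix (stitched fluorescence well image).
#' @param params A [granule_params()].
#' @param fish_mask Logical matrix of identical dimensions (the containment
#'   reference); pass a matrix of `TRUE` to disable containment.
#' @return An object of class `granule_set`: data frame with one row per
#'   granule (`x`, `y`, `area`, `integrated_intensity`, `mean_intensity`,
#'   `region`), region `NA` until [assign_regions()].
#' @export
detect_granules <- function(fluor, params, fish_mask) {
  stopifnot(inherits(params, "granule_params"))
  if (!identical(dim(fluor), dim(fish_mask))) {
    stop("fluorescence image and fish mask dimensions differ")
  }
  img <- matrix(as.numeric(fluor), nrow(fluor), ncol(fluor))
  sm <- if (params$smoothing_sigma > 0) {
    gauss_blur_cpp(img, params$smoothing_sigma)
  } else img
  if (params$background_radius > 0) {
    bg <- gray_opening_cpp(sm, params$background_radius)
    resid <- sm - bg
  } else {
    resid <- sm
  }
  thr <- if (params$threshold_mode == "absolute") {
    params$threshold_value
  } else {
    # the opening residual sits above zero even in background (the opening
    # is a lower envelope), so centre the cut on its median
    stats::median(resid) +
      max(params$threshold_value * stats::mad(resid), params$threshold_floor)
  }
  fg <- resid > thr
  labels <- label_components(fg, 8)
  stats_ <- component_stats(labels)
  rows <- list()
  nr <- nrow(img)
  for (cmp in stats_) {
    if (cmp$area < params$min_area || cmp$area > params$max_area) next
    ci <- as.integer(round(cmp$centroid["y"])) + 1L
    cj <- as.integer(round(cmp$centroid["x"])) + 1L
    ci <- min(max(ci, 1L), nr); cj <- min(max(cj, 1L), ncol(img))
    if (!isTRUE(fish_mask[ci, cj])) next
    vals <- img[cmp$pixels]
    rows[[length(rows) + 1]] <- data.frame(
      x = unname(cmp$centroid["x"]), y = unname(cmp$centroid["y"]),
      area = cmp$area, integrated_intensity = sum(vals),
      mean_intensity = mean(vals), region = NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), area = numeric(0),
               integrated_intensity = numeric(0), mean_intensity = numeric(0),
               region = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("granule_set", "data.frame"))
}

#' Assign granules to fish regions
#'
#' Each granule receives the region of the label-map pixel containing its
#' centroid (deterministic, including boundary pixels). Centroids inside the
#' fish mask but on an unlabelled pixel (possible only with a degenerate
#' map) fall back to `whole_fish_only`.
#'
#' @param granules A `granule_set`.
#' @param segmentation An `embryo_segmentation`.
#' @return The granule set with `region` filled in.
#' @export
assign_regions <- function(granules, segmentation) {
  stopifnot(inherits(segmentation, "embryo_segmentation"))
  if (nrow(granules) == 0) return(granules)
  rm_ <- segmentation$region_map
  ci <- pmin(pmax(as.integer(round(granules$y)) + 1L, 1L), nrow(rm_))
  cj <- pmin(pmax(as.integer(round(granules$x)) + 1L, 1L), ncol(rm_))
  lab <- rm_[cbind(ci, cj)]
  granules$region <- c("whole_fish_only", "head", "trunk", "tail")[lab + 1L]
  granules
}

#' Per-region granule metrics
#'
#' Counts, integrated intensity, mean granule area and total granule area
#' per region, plus whole-fish totals (the sum over regions). The mean area
#' of an empty region is reported missing, not zero.
#'
#' @param granules A `granule_set` with regions assigned.
#' @param segmentation An `embryo_segmentation` (consistency check only).
#' @param fluor Original fluorescence image (unused by the summary itself;
#'   kept for interface symmetry with callers that recompute intensities).
#' @return Data frame with rows head, trunk, tail, fish and columns `count`,
#'   `integrated_intensity`, `mean_granule_area`, `total_granule_area`.
#' @export
region_metrics <- function(granules, segmentation = NULL, fluor = NULL) {
  regions <- c("head", "trunk", "tail")
  one <- function(sel) {
    n <- sum(sel)
    data.frame(count = n,
               integrated_intensity = sum(granules$integrated_intensity[sel]),
               mean_granule_area = if (n > 0) mean(granules$area[sel]) else NA_real_,
               total_granule_area = sum(granules$area[sel]))
  }
  per <- do.call(rbind, lapply(regions, function(r) one(granules$region %in% r)))
  fish <- one(granules$region %in% c(regions, "whole_fish_only"))
  out <- rbind(per, fish)
  out$region <- c(regions, "fish")
  out[, c("region", "count", "integrated_intensity", "mean_granule_area",
          "total_granule_area")]
}

#' On-side orientation and quality criteria
#'
#' A well is analyzable when the embryo lies on its side with the whole body
#' in view: exactly one visible eye, exactly one tail terminus, and fish and
#' tail areas above their minima (which excludes partially imaged fish).
#'
#' @param min_fish_area,min_tail_area Minimum areas in px^2.
#' @param required_eye_count,required_tail_count Required counts (1).
#' @return A `qc_criteria` object.
#' @export
qc_criteria <- function(min_fish_area = 0, min_tail_area = 0,
                        required_eye_count = 1L, required_tail_count = 1L) {
  stopifnot(min_fish_area >= 0, min_tail_area >= 0)
  structure(list(required_eye_count = as.integer(required_eye_count),
                 required_tail_count = as.integer(required_tail_count),
                 min_fish_area = min_fish_area,
                 min_tail_area = min_tail_area), class = "qc_criteria")
}

#' Default QC criteria for a plate geometry
#' @param spec A [plate_spec()].
#' @param constraints Optional [size_constraints()] to reuse.
#' @return A [qc_criteria()] with area minima derived from the geometry.
#' @export
default_qc_criteria <- function(spec, constraints = size_constraints(spec)) {
  qc_criteria(min_fish_area = constraints$fish[1],
              min_tail_area = constraints$tail[1])
}

#' Apply the orientation/quality filter to a segmentation
#'
#' Checks run in a fixed order and the first failure is reported:
#' empty well, eye count, tail count, fish area, tail region area.
#'
#' @param segmentation An `embryo_segmentation` or `NULL` (empty well).
#' @param criteria A [qc_criteria()].
#' @return `list(included = logical, reason = one of "ok", "empty_well",
#'   "eye_count", "tail_count", "fish_area", "tail_area")`.
#' @export
apply_qc <- function(segmentation, criteria) {
  stopifnot(inherits(criteria, "qc_criteria"))
  fail <- function(reason) list(included = FALSE, reason = reason)
  if (is.null(segmentation)) return(fail("empty_well"))
  if (segmentation$eye_count != criteria$required_eye_count) {
    return(fail("eye_count"))
  }
  if (segmentation$tail_count != criteria$required_tail_count) {
    return(fail("tail_count"))
  }
  if (segmentation$fish_area < criteria$min_fish_area) {
    return(fail("fish_area"))
  }
  if (segmentation$region_areas[["tail"]] < criteria$min_tail_area) {
    return(fail("tail_area"))
  }
  list(included = TRUE, reason = "ok")
}

#' Assay presets
#'
#' Bundles granule-detection parameters, the target region and the headline
#' metric for the supported assay flavours. Pixel-valued parameters scale
#' with the plate resolution (via the tile height) so the same preset works
#' at any tile size. The numeric values are tuned on the synthetic fixtures
#' bundled with this package, not taken from any vendor configuration.
#'
#' * `hspc` — stem/progenitor cell count in the tail.
#' * `dual` — per-channel counts in the tail (two fluorophores).
#' * `apoptosis` — stained-granule count over the whole fish.
#' * `haircell` — whole-fish integrated intensity and mean granule area.
#' * `angiogenesis` — total fluorescent area over the whole fish (vessel
#'   signal treated as one large granule; the area cap is lifted).
#'
#' @param name Preset name.
#' @param spec A [plate_spec()].
#' @return List with `name`, `params` (a [granule_params()]), `region`
#'   (`"tail"` or `"fish"`), `metric` (column of [region_metrics()]).
#' @export
assay_preset <- function(name = c("hspc", "dual", "apoptosis", "haircell",
                                  "angiogenesis"), spec) {
  name <- match.arg(name)
  H <- canvas_shape(spec)[1]
  r <- max(1.2, 0.008 * H)   # expected granule radius at this resolution
  base <- granule_params(smoothing_sigma = max(0.8, 0.6 * r),
                         background_radius = ceiling(4 * r),
                         threshold_mode = "k_sigma_above_local_background",
                         threshold_value = 3.5,
                         min_area = max(3, round(0.15 * pi * r^2)),
                         max_area = ceiling(60 * pi * r^2),
                         threshold_floor = 5 * (2^spec$bit_depth - 1) / 65535)
  switch(name,
    hspc = list(name = name, params = base, region = "tail",
                metric = "count"),
    dual = list(name = name, params = base, region = "tail",
                metric = "count"),
    apoptosis = list(name = name, params = base, region = "fish",
                     metric = "count"),
    haircell = list(name = name, params = base, region = "fish",
                    metric = "integrated_intensity"),
    angiogenesis = {
      p <- base
      p$max_area <- Inf
      p$min_area <- max(6, round(0.5 * pi * r^2))
      list(name = name, params = p, region = "fish",
           metric = "total_granule_area")
    })
}
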