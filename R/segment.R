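#' Minimum/maximum size constraints for detectable objects
#'
#' The analysis needs only minimum and maximum size bounds per object class;
#' defaults are derived from the plate geometry (tile height `H`, stitched
#' width `W`) so the same relative anatomy is accepted at any resolution:
#' the expected fish silhouette covers about 9% of the stitched canvas, an
#' eye about `pi * (0.04 H)^2`, and the tail terminus (the last stretch of
#' the body used to decide whether the tail is fully in view) a sliver of
#' the body area.
#'
#' @param spec A [plate_spec()].
#' @param fish,eye,yolk,tail Optional `c(min, max)` overrides in px^2.
#' @return An object of class `size_constraints`.
#' @export
size_constraints <- function(spec, fish = NULL, eye = NULL, yolk = NULL,
                             tail = NULL) {
  cs <- canvas_shape(spec)
  H <- cs[1]; W <- cs[2]
  a_fish <- 0.103 * H * W
  a_eye <- pi * (0.040 * H)^2
  a_yolk <- pi * (0.072 * H) * (0.050 * H) * 1.6  # ball + caudal extension
  a_tail <- 0.0035 * 0.80 * W * H
  cls <- list(
    fish = if (is.null(fish)) c(0.40 * a_fish, 2.2 * a_fish) else fish,
    eye = if (is.null(eye)) c(0.30 * a_eye, 3.0 * a_eye) else eye,
    yolk = if (is.null(yolk)) c(0.20 * a_yolk, 3.5 * a_yolk) else yolk,
    tail = if (is.null(tail)) c(0.25 * a_tail, Inf) else tail)
  for (k in names(cls)) {
    v <- cls[[k]]
    if (!(length(v) == 2 && v[1] >= 0 && v[1] <= v[2])) {
      stop(sprintf("constraints for '%s' must satisfy 0 <= min <= max", k))
    }
  }
  structure(cls, class = "size_constraints")
}

#' Label connected components of a binary mask
#'
#' 8-connected by default, matching the granule detector's convention.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.logical(mask) & !is.na(mask), nrow(mask), ncol(mask))
  label_components_cpp(m, as.integer(connectivity))
}

# summary records (centroid, area, pixel indices) for each label
component_stats <- function(labels) {
  n <- max(labels)
  if (n == 0) return(list())
  idx <- which(labels > 0)
  lab <- labels[idx]
  nr <- nrow(labels)
  ii <- (idx - 1) %% nr + 1   # row (y + 1)
  jj <- (idx - 1) %/% nr + 1  # col (x + 1)
  out <- vector("list", n)
  sp <- split(seq_along(idx), lab)
  for (k in seq_along(sp)) {
    s <- sp[[k]]
    out[[as.integer(names(sp)[k])]] <- list(
      centroid = c(x = mean(jj[s]) - 1, y = mean(ii[s]) - 1),
      area = length(s), pixels = idx[s])
  }
  out
}

# boundary-pixel count as a perimeter estimate (4-neighbourhood)
component_perimeter <- function(labels, pixels) {
  nr <- nrow(labels); nc <- ncol(labels)
  ii <- (pixels - 1) %% nr + 1
  jj <- (pixels - 1) %/% nr + 1
  lab <- labels[pixels[1]]
  nb <- function(di, dj) {
    i2 <- ii + di; j2 <- jj + dj
    inb <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    out <- rep(FALSE, length(pixels))
    out[inb] <- labels[cbind(i2[inb], j2[inb])] != lab
    out | !inb
  }
  sum(nb(1, 0) | nb(-1, 0) | nb(0, 1) | nb(0, -1))
}

#' Segment the fish outline from a stitched brightfield image
#'
#' Classical reference segmenter: the image is normalized by its background
#' level (median intensity; the fish occupies a minority of the well), dark
#' pixels are thresholded, gaps are closed morphologically, holes filled,
#' and the largest 8-connected component whose area satisfies the fish size
#' constraints is returned. Absence of a qualifying component (an empty
#' well, or debris only) is a valid outcome, not an error.
#'
#' @param brightfield Numeric matrix (stitched brightfield well image).
#' @param constraints A [size_constraints()].
#' @param dark_fraction Threshold as a fraction of the background level;
#'   transmitted light renders the fish darker than the background.
#' @return Logical fish mask, or `NULL` when no component qualifies.
#' @export
segment_fish <- function(brightfield, constraints, dark_fraction = 0.85) {
  stopifnot(length(brightfield) > 0)
  bg <- stats::median(brightfield)
  raw <- brightfield < dark_fraction * bg
  if (!any(raw)) return(NULL)
  r <- max(3L, as.integer(round(nrow(brightfield) / 85)))
  if (r %% 2 == 0) r <- r + 1L
  closed <- EBImage::closing(matrix(as.numeric(raw), nrow(raw), ncol(raw)),
                             EBImage::makeBrush(r, "disc"))
  filled <- EBImage::fillHull(closed)
  labels <- label_components(EBImage::imageData(filled) > 0.5, 8)
  if (max(labels) == 0) return(NULL)
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  ok <- which(areas >= constraints$fish[1] & areas <= constraints$fish[2])
  if (length(ok) == 0) return(NULL)
  best <- ok[which.max(areas[ok])]
  labels == best
}

#' Extract the body axis of a fish mask
#'
#' For the near-horizontal embryos the alignment plate produces, the axis is
#' the smoothed midline of the mask: one point per occupied image column at
#' the mean row of the mask in that column. Returned left-to-right
#' (unoriented); [segment_embryo()] orients it anterior-to-posterior.
#'
#' @param fish_mask Logical matrix.
#' @return n x 2 matrix with columns `x`, `y` (0-based pixel coordinates).
#' @export
mask_axis <- function(fish_mask) {
  cols <- which(colSums(fish_mask) > 0)
  if (length(cols) == 0) return(matrix(numeric(0), 0, 2,
                                       dimnames = list(NULL, c("x", "y"))))
  ymid <- vapply(cols, function(j) mean(which(fish_mask[, j])) - 1, numeric(1))
  k <- min(11L, length(ymid))
  if (k >= 3) {
    if (k %% 2 == 0) k <- k - 1L
    sm <- stats::filter(ymid, rep(1 / k, k), sides = 2)
    ymid[!is.na(sm)] <- sm[!is.na(sm)]
  }
  cbind(x = cols - 1, y = ymid)
}

axis_arclength <- function(axis) {
  if (nrow(axis) < 2) return(0)
  sum(sqrt(diff(axis[, 1])^2 + diff(axis[, 2])^2))
}

# cumulative axis parameter (arc length) at each axis vertex
axis_param <- function(axis) {
  if (nrow(axis) == 0) return(numeric(0))
  c(0, cumsum(sqrt(diff(axis[, 1])^2 + diff(axis[, 2])^2)))
}

# axis parameter of arbitrary x coordinates by interpolation along the axis
axis_u_of_x <- function(axis, x) {
  u <- axis_param(axis)
  stats::approx(axis[, 1], u, xout = x, rule = 2)$y
}

#' Detect eyes in the brightfield image
#'
#' Eyes are the darkest compact structures of the embryo. Candidates are
#' very dark 8-connected blobs inside the fish whose areas satisfy the eye
#' constraints and whose circularity exceeds `min_circularity`; the anterior
#' half of the fish is then identified as the axis end nearer the candidate
#' mass, and candidates in the posterior half are dropped. On-side embryos
#' show one eye (the second is hidden behind it); embryos on their back show
#' two, which is what the orientation QC keys on.
#'
#' @param brightfield Numeric matrix.
#' @param fish_mask Logical matrix, or `NULL` (returns an empty list).
#' @param constraints A [size_constraints()].
#' @param dark_fraction Eye threshold as a fraction of the background level.
#' @param min_circularity Minimum `4 pi A / P^2`.
#' @return List of eye regions, each `list(centroid, area, pixels)`.
#' @export
detect_eyes <- function(brightfield, fish_mask, constraints,
                        dark_fraction = 0.35, min_circularity = 0.45) {
  if (is.null(fish_mask)) return(list())
  bg <- stats::median(brightfield)
  cand <- brightfield < dark_fraction * bg & fish_mask
  labels <- label_components(cand, 8)
  stats_ <- component_stats(labels)
  keep <- list()
  for (cmp in stats_) {
    if (cmp$area < constraints$eye[1] || cmp$area > constraints$eye[2]) next
    per <- component_perimeter(labels, cmp$pixels)
    circ <- 4 * pi * cmp$area / max(per, 1)^2
    if (circ < min_circularity) next
    keep[[length(keep) + 1]] <- cmp
  }
  if (length(keep) == 0) return(keep)
  axis <- mask_axis(fish_mask)
  if (nrow(axis) < 2) return(keep)
  cx <- sum(vapply(keep, function(e) e$centroid["x"] * e$area, numeric(1))) /
    sum(vapply(keep, function(e) e$area, numeric(1)))
  # anterior end of the axis = the end nearer the eye mass
  anterior_left <- abs(cx - axis[1, 1]) <= abs(cx - axis[nrow(axis), 1])
  xmid <- (axis[1, 1] + axis[nrow(axis), 1]) / 2
  keep[vapply(keep, function(e) {
    if (anterior_left) e$centroid["x"] <= xmid else e$centroid["x"] >= xmid
  }, logical(1))]
}

#' Detect the yolk sac and its caudal tip
#'
#' The yolk (ball plus thin caudal extension) is the largest dark compact
#' region in the anterior-ventral body once the even darker eyes are
#' excluded. Its caudal-most point along the body axis is the anatomical
#' landmark for the trunk/tail boundary: the stem-cell niche sits at the
#' base of the tail immediately caudal of the yolk extension's tip.
#'
#' @param brightfield Numeric matrix.
#' @param fish_mask Logical matrix or `NULL`.
#' @param constraints A [size_constraints()].
#' @param eyes Eye regions from [detect_eyes()]; detected when missing.
#' @param anterior_left Logical; orientation of the fish along the image
#'   x axis (determined from the eyes when missing).
#' @param dark_fraction Yolk threshold as a fraction of the background.
#' @return `list(centroid, area, pixels, caudal_tip = c(x, y))`, or `NULL`.
#' @export
detect_yolk <- function(brightfield, fish_mask, constraints, eyes = NULL,
                        anterior_left = NULL, dark_fraction = 0.58) {
  if (is.null(fish_mask)) return(NULL)
  if (is.null(eyes)) eyes <- detect_eyes(brightfield, fish_mask, constraints)
  bg <- stats::median(brightfield)
  cand <- brightfield < dark_fraction * bg & fish_mask
  labels <- label_components(cand, 8)
  stats_ <- component_stats(labels)
  if (length(stats_) == 0) return(NULL)
  eye_px <- unlist(lapply(eyes, `[[`, "pixels"))
  axis <- mask_axis(fish_mask)
  if (is.null(anterior_left)) {
    anterior_left <- anterior_is_left(fish_mask, eyes, axis)
  }
  xr <- range(axis[, 1])
  best <- NULL
  for (cmp in stats_) {
    if (cmp$area < constraints$yolk[1] || cmp$area > constraints$yolk[2]) next
    if (length(eye_px) && mean(cmp$pixels %in% eye_px) > 0.3) next
    # anterior 65% of the body
    relx <- if (anterior_left) (cmp$centroid["x"] - xr[1]) / diff(xr)
            else (xr[2] - cmp$centroid["x"]) / diff(xr)
    if (is.finite(relx) && relx > 0.65) next
    if (is.null(best) || cmp$area > best$area) best <- cmp
  }
  if (is.null(best)) return(NULL)
  nr <- nrow(brightfield)
  jj <- (best$pixels - 1) %/% nr
  ii <- (best$pixels - 1) %% nr
  tip_idx <- if (anterior_left) which.max(jj) else which.min(jj)
  best$caudal_tip <- c(x = jj[tip_idx], y = ii[tip_idx])
  best
}

anterior_is_left <- function(fish_mask, eyes, axis = NULL) {
  if (is.null(axis)) axis <- mask_axis(fish_mask)
  if (length(eyes) > 0 && nrow(axis) >= 2) {
    cx <- mean(vapply(eyes, function(e) e$centroid["x"], numeric(1)))
    return(abs(cx - axis[1, 1]) <= abs(cx - axis[nrow(axis), 1]))
  }
  # no eye: the wider body end is anterior
  n <- nrow(axis)
  if (n < 4) return(TRUE)
  width_at <- function(cols) mean(colSums(fish_mask)[cols + 1])
  q <- max(2L, n %/% 4)
  width_at(axis[seq_len(q), 1]) >= width_at(axis[(n - q + 1):n, 1])
}

#' Decide whether the tail terminus is fully in view
#'
#' Looks at the posterior terminus of the fish (the last stretch of the
#' body axis): the tail count is 1 when the terminus lies fully inside the
#' image (the mask does not touch the distal border) and its area meets the
#' tail minimum, otherwise 0. Partially imaged fish therefore fail QC even
#' when a large part of the body is visible.
#'
#' @param brightfield Numeric matrix (unused by the reference rule; part of
#'   the segmenter contract).
#' @param fish_mask Logical matrix or `NULL`.
#' @param constraints A [size_constraints()].
#' @param anterior_left Logical orientation; derived from eyes when missing.
#' @param terminus_fraction Fraction of the axis span treated as terminus.
#' @return `list(region = list(centroid, area, pixels) | NULL,
#'   tail_count = 0L | 1L)`.
#' @export
detect_tail <- function(brightfield, fish_mask, constraints,
                        anterior_left = NULL, terminus_fraction = 0.12) {
  if (is.null(fish_mask)) return(list(region = NULL, tail_count = 0L))
  axis <- mask_axis(fish_mask)
  if (nrow(axis) < 2) return(list(region = NULL, tail_count = 0L))
  if (is.null(anterior_left)) {
    eyes <- detect_eyes(brightfield, fish_mask, constraints)
    anterior_left <- anterior_is_left(fish_mask, eyes, axis)
  }
  nc <- ncol(fish_mask)
  xr <- range(axis[, 1])
  span <- diff(xr)
  if (anterior_left) {
    x0 <- xr[2] - terminus_fraction * span
    sel_cols <- which(seq_len(nc) - 1 >= x0)
    touches <- any(fish_mask[, nc]) || any(fish_mask[, nc - 1])
  } else {
    x1 <- xr[1] + terminus_fraction * span
    sel_cols <- which(seq_len(nc) - 1 <= x1)
    touches <- any(fish_mask[, 1]) || any(fish_mask[, 2])
  }
  sub <- fish_mask[, sel_cols, drop = FALSE]
  area <- sum(sub)
  region <- NULL
  if (area > 0) {
    idx <- which(sub)
    nr <- nrow(fish_mask)
    ii <- (idx - 1) %% nr + 1
    jj <- sel_cols[(idx - 1) %/% nr + 1]
    region <- list(centroid = c(x = mean(jj) - 1, y = mean(ii) - 1),
                   area = area,
                   pixels = (jj - 1) * nr + ii)
  }
  ok <- !touches && area >= constraints$tail[1]
  list(region = region, tail_count = if (ok) 1L else 0L)
}

#' Partition the fish into head, trunk and tail
#'
#' Every fish pixel is assigned the region of its projection onto the body
#' axis. The head/trunk boundary sits at the axis position of the posterior
#' eye edge plus a small fraction of the body length (the eye being the only
#' reliably detected anterior landmark); the trunk/tail boundary sits at the
#' axis position of the yolk's caudal tip. When landmarks are missing the
#' boundaries fall back to fixed fractions of the axis length.
#'
#' @param fish_mask Logical matrix.
#' @param body_axis n x 2 matrix ordered anterior to posterior; its x
#'   coordinates must be monotone.
#' @param landmarks `list(eye_posterior_x =, yolk_tip_x =)`; either element
#'   may be `NULL`.
#' @param head_offset_frac Offset past the eye edge, as a fraction of axis
#'   length.
#' @param fallback Fractions of axis length for the head/trunk and
#'   trunk/tail boundaries when the respective landmark is missing.
#' @return Integer region map (0 outside fish, 1 head, 2 trunk, 3 tail);
#'   regions are disjoint and cover the mask exactly.
#' @export
partition_regions <- function(fish_mask, body_axis, landmarks = list(),
                              head_offset_frac = 0.05,
                              fallback = c(0.25, 0.55)) {
  if (nrow(body_axis) < 2) stop("body axis must contain at least two points")
  dx <- diff(body_axis[, 1])
  if (!(all(dx >= 0) || all(dx <= 0))) {
    stop("body axis is not ordered along the anterior-posterior direction")
  }
  u <- axis_param(body_axis)
  total <- u[length(u)]
  u_head <- if (!is.null(landmarks$eye_posterior_x)) {
    axis_u_of_x(body_axis, landmarks$eye_posterior_x) + head_offset_frac * total
  } else fallback[1] * total
  u_tail <- if (!is.null(landmarks$yolk_tip_x)) {
    axis_u_of_x(body_axis, landmarks$yolk_tip_x)
  } else fallback[2] * total
  u_head <- min(u_head, u_tail)   # keep the three regions ordered

  nr <- nrow(fish_mask); nc <- ncol(fish_mask)
  # per-column axis parameter; pixels project onto the axis by column
  ucol <- stats::approx(body_axis[, 1], u, xout = seq_len(nc) - 1,
                        rule = 2)$y
  region_map <- matrix(0L, nr, nc)
  lab <- ifelse(ucol < u_head, 1L, ifelse(ucol < u_tail, 2L, 3L))
  region_map[fish_mask] <- matrix(rep(lab, each = nr), nr, nc)[fish_mask]
  region_map
}

#' Morphometrics of a segmentation
#'
#' Areas are pixel counts scaled by `pixel_size^2` (um^2 when calibrated,
#' px^2 otherwise); the fish length is the arc length of the body axis.
#'
#' @param segmentation An `embryo_segmentation`.
#' @param pixel_size Micrometres per pixel, or `NA` for pixel units.
#' @return List with `fish_area`, `fish_length`, `eye_areas`, `eye_area`
#'   (mean), `region_areas` (named head/trunk/tail).
#' @export
measure_morphology <- function(segmentation, pixel_size = NA_real_) {
  stopifnot(inherits(segmentation, "embryo_segmentation"))
  s <- if (is.na(pixel_size)) 1 else pixel_size
  eye_areas <- vapply(segmentation$anatomy$eye, `[[`, numeric(1), "area") * s^2
  ra <- vapply(1:3, function(k) sum(segmentation$region_map == k), numeric(1)) * s^2
  names(ra) <- c("head", "trunk", "tail")
  list(fish_area = sum(segmentation$fish_mask) * s^2,
       fish_length = axis_arclength(segmentation$body_axis) * s,
       eye_areas = eye_areas,
       eye_area = if (length(eye_areas)) mean(eye_areas) else NA_real_,
       region_areas = ra)
}

#' Segment an embryo and all downstream anatomy
#'
#' Reference implementation of the segmenter contract: fish outline, eyes,
#' yolk sac, tail terminus, body axis oriented anterior to posterior, and
#' the head/trunk/tail region map. Learned segmenters can replace this
#' function anywhere a `segmenter` argument is accepted, as long as they
#' return the same structure.
#'
#' @param brightfield Stitched brightfield image (numeric matrix).
#' @param constraints A [size_constraints()].
#' @return An object of class `embryo_segmentation`, or `NULL` for an empty
#'   well: list with `fish_mask`, `anatomy` (named lists of regions for
#'   `eye`, `yolk_sac`, `tail_fin`; remaining anatomy labels are legal but
#'   unpopulated by the reference segmenter), `region_map`, `body_axis`,
#'   `fish_area`, `fish_length`, `eye_count`, `tail_count`, `landmarks`.
#' @export
segment_embryo <- function(brightfield, constraints) {
  fish_mask <- segment_fish(brightfield, constraints)
  if (is.null(fish_mask)) return(NULL)
  eyes <- detect_eyes(brightfield, fish_mask, constraints)
  axis <- mask_axis(fish_mask)
  ant_left <- anterior_is_left(fish_mask, eyes, axis)
  if (!ant_left) axis <- axis[rev(seq_len(nrow(axis))), , drop = FALSE]
  yolk <- detect_yolk(brightfield, fish_mask, constraints, eyes = eyes,
                      anterior_left = ant_left)
  tail <- detect_tail(brightfield, fish_mask, constraints,
                      anterior_left = ant_left)
  landmarks <- list(
    eye_posterior_x = if (length(eyes)) {
      xs <- vapply(eyes, function(e) e$centroid["x"], numeric(1))
      # posterior edge of the eye(s): centroid plus effective radius
      r <- sqrt(max(vapply(eyes, `[[`, numeric(1), "area")) / pi)
      if (ant_left) max(xs) + r else min(xs) - r
    } else NULL,
    yolk_tip_x = if (!is.null(yolk)) unname(yolk$caudal_tip["x"]) else NULL)
  region_map <- partition_regions(fish_mask, axis, landmarks)
  seg <- structure(list(
    fish_mask = fish_mask,
    anatomy = list(eye = eyes,
                   yolk_sac = if (is.null(yolk)) list() else list(yolk),
                   tail_fin = if (is.null(tail$region)) list()
                              else list(tail$region)),
    region_map = region_map, body_axis = axis,
    eye_count = length(eyes), tail_count = tail$tail_count,
    landmarks = landmarks), class = "embryo_segmentation")
  m <- measure_morphology(seg)
  seg$fish_area <- m$fish_area
  seg$fish_length <- m$fish_length
  seg$eye_area <- m$eye_area
  seg$region_areas <- m$region_areas
  seg
}

#' @export
print.embryo_segmentation <- function(x, ...) {
  cat(sprintf("<embryo_segmentation> area %d px^2, length %.0f px, %d eye(s), tail count %d\n",
              as.integer(x$fish_area), x$fish_length, x$eye_count,
              x$tail_count))
  cat(sprintf("  regions head/trunk/tail: %s px^2\n",
              paste(as.integer(x$region_areas), collapse = "/")))
  invisible(x)
}

#' Build an oracle segmenter from generator ground truth
#'
#' Returns a segmenter function with the same contract as
#' [segment_embryo()] that ignores the image and returns the generator's
#' truth masks for the requested well. Running the pipeline with it checks
#' that everything downstream of segmentation is exact when segmentation is
#' perfect (segmenter-contract substitutability).
#'
#' @param plate A `synth_plate` generated with `keep_masks = TRUE`.
#' @return `function(brightfield, constraints, well)` returning an
#'   `embryo_segmentation` or `NULL`.
#' @export
oracle_segmenter <- function(plate) {
  stopifnot(inherits(plate, "synth_plate"))
  function(brightfield, constraints, well) {
    w <- plate$wells[[well]]
    if (is.null(w) || is.null(w$masks)) {
      stop(sprintf("no truth masks for well %s (generate with keep_masks = TRUE)", well))
    }
    masks <- w$masks
    if (!any(masks$body)) return(NULL)
    layout <- w$truth$layout
    axis <- masks$axis
    if (layout$headward < 0) axis <- axis[rev(seq_len(nrow(axis))), , drop = FALSE]
    eye_labels <- label_components(masks$eye, 8)
    eyes <- component_stats(eye_labels)
    yolk_stats <- component_stats(label_components(masks$yolk, 8))
    tail_ok <- layout$presentation %in% c("lateral_left", "lateral_right",
                                          "dorsal")
    seg <- structure(list(
      fish_mask = masks$body,
      anatomy = list(eye = eyes, yolk_sac = yolk_stats,
                     tail_fin = list()),
      region_map = masks$region_map, body_axis = axis,
      eye_count = length(eyes),
      tail_count = if (tail_ok) 1L else 0L,
      landmarks = list()), class = "embryo_segmentation")
    m <- measure_morphology(seg)
    seg$fish_area <- m$fish_area
    seg$fish_length <- m$fish_length
    seg$eye_area <- m$eye_area
    seg$region_areas <- m$region_areas
    seg
  }
}
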