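# Rendering of synthetic wells: brightfield anatomy with focus-dependent
# blur across z, fluorescent Gaussian spots distributed across z, smooth
# head/yolk autofluorescence haze, and camera noise.

#' Camera noise model for the synthetic generator
#'
#' Shot noise with variance equal to the signal (the Gaussian limit of
#' photon counting, accurate at the intensities simulated) plus additive
#' Gaussian read noise, applied independently per field tile.
#'
#' @param read_sd Read-noise standard deviation in intensity counts.
#' @param shot Logical; include signal-dependent shot noise.
#' @param enabled Logical; `FALSE` renders noise-free tiles.
#' @return A `noise_params` list.
#' @export
noise_params <- function(read_sd = 12, shot = TRUE, enabled = TRUE) {
  stopifnot(read_sd >= 0)
  structure(list(read_sd = read_sd, shot = isTRUE(shot),
                 enabled = isTRUE(enabled)), class = "noise_params")
}

# intensity levels as fractions of the bit-depth maximum
render_levels <- function(maxval) {
  list(bf_bg = 0.55 * maxval,     # transmitted-light background
       bf_body = 0.70,            # x bf_bg: fish darker than background
       bf_yolk = 0.45, bf_eye = 0.15, bf_fin = 0.93,
       fl_bg = 0.006 * maxval,    # fluorescence camera offset
       haze_amp = 0.0023 * maxval,
       blur_per_plane_frac = 1 / 170)  # x tile height, px of sigma per plane
}

# local background sd used to anchor the dim/bright amplitude classes;
# anchored to the configured noise model (not the enabled flag), so the
# noise-free variant of a scene keeps the same amplitudes
fluor_background_sd <- function(spec, noise) {
  maxval <- 2^spec$bit_depth - 1
  lv <- render_levels(maxval)
  level <- lv$fl_bg + lv$haze_amp / 2
  sqrt((if (noise$shot) level else 0) + noise$read_sd^2 + 1)
}

#' Spot amplitude for a class
#'
#' Dim spots sit ~3 local-background standard deviations above the
#' autofluorescence haze and bright spots ~10, reproducing the screening
#' dilemma that a global threshold clearing the haze also removes the dim
#' (GFP-lo) cell class.
#'
#' @param class `"dim"` or `"bright"`.
#' @param spec A [plate_spec()].
#' @param noise A [noise_params()].
#' @param factor Extra multiplier (assay variants).
#' @return Amplitude in intensity counts.
#' @export
spot_amplitude <- function(class, spec, noise = noise_params(), factor = 1) {
  sdb <- fluor_background_sd(spec, noise)
  k <- c(dim = 3, bright = 10)[[class]]
  k * sdb * factor
}

default_spot_radius <- function(spec) max(1.2, 0.008 * canvas_shape(spec)[1])

#' Sample ground-truth spots for one well
#'
#' Draws spot counts per (channel, region) from the given laws and places
#' the spots with rejection sampling: inside the body for fish regions (with
#' a margin so the full profile fits), outside it for `outside_fish`, and at
#' least `min_separation` apart. Each spot is assigned the z-plane of its
#' maximal intensity uniformly over the stack, so no single slice sees every
#' spot and the maximum projection is genuinely needed.
#'
#' @param layout An [embryo_layout()].
#' @param spec A [plate_spec()].
#' @param laws Data frame with columns `channel`, `region`, `law`
#'   (`"poisson"` or `"constant"`), `mean`, `class` (`"dim"`/`"bright"`);
#'   see [spot_laws_preset()].
#' @param noise A [noise_params()] (anchors the amplitude classes).
#' @param amplitude_factor,radius_factor Multipliers for assay variants
#'   (e.g. degraded staining).
#' @param min_separation Minimum centre-to-centre distance in px; default
#'   5 spot radii.
#' @return Data frame of class `spot_truth`: columns `x`, `y`, `u`,
#'   `radius`, `class`, `amplitude`, `channel`, `region`, `z_peak`.
#' @export
sample_spots <- function(layout, spec, laws, noise = noise_params(),
                         amplitude_factor = 1, radius_factor = 1,
                         min_separation = NULL) {
  r0 <- default_spot_radius(spec) * radius_factor
  if (is.null(min_separation)) min_separation <- 5.5 * default_spot_radius(spec)
  cols <- c("x", "y", "u", "radius", "class", "amplitude", "channel",
            "region", "z_peak")
  empty <- data.frame(x = numeric(0), y = numeric(0), u = numeric(0),
                      radius = numeric(0), class = character(0),
                      amplitude = numeric(0), channel = character(0),
                      region = character(0), z_peak = integer(0),
                      stringsAsFactors = FALSE)
  if (layout$presentation == "absent") {
    laws <- laws[laws$region == "outside_fish", , drop = FALSE]
  }
  if (nrow(laws) == 0) return(structure(empty, class = c("spot_truth", "data.frame")))

  H <- layout$canvas[1]; W <- layout$canvas[2]
  placed_x <- numeric(0); placed_y <- numeric(0)
  out <- list()
  for (i in seq_len(nrow(laws))) {
    lw <- laws[i, ]
    n <- switch(lw$law,
                poisson = rpois(1, lw$mean),
                constant = as.integer(round(lw$mean)),
                stop(sprintf("unknown spot count law '%s'", lw$law)))
    if (n == 0) next
    amp <- spot_amplitude(lw$class, spec, noise, amplitude_factor)
    pts <- place_spots(layout, lw$region, n, r0, min_separation,
                       placed_x, placed_y)
    # the spatial exclusion constraint (spots must not crowd) may truncate
    # the drawn count in a saturated niche; the ground truth is the placed
    # set, so truth counts stay self-consistent
    n <- nrow(pts)
    if (n == 0) next
    placed_x <- c(placed_x, pts$x); placed_y <- c(placed_y, pts$y)
    out[[length(out) + 1]] <- data.frame(
      x = pts$x, y = pts$y, u = pts$u, radius = r0, class = lw$class,
      amplitude = amp, channel = lw$channel, region = lw$region,
      z_peak = sample.int(spec$z_planes, n, replace = TRUE) - 1L,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, class = c("spot_truth", "data.frame"))
}

# rejection sampling of spot centres within a named region
place_spots <- function(layout, region, n, radius, min_sep,
                        placed_x, placed_y) {
  H <- layout$canvas[1]; W <- layout$canvas[2]
  margin <- radius + 2
  dxv <- layout$headward * cos(layout$theta); dyv <- sin(layout$theta)
  nxv <- -layout$headward * sin(layout$theta); nyv <- cos(layout$theta)
  ok_x <- numeric(0); ok_y <- numeric(0); ok_u <- numeric(0)
  tries <- 0L
  while (length(ok_x) < n && tries < 4000L * n) {
    tries <- tries + 1L
    if (region == "outside_fish") {
      x <- runif(1, margin, W - 1 - margin)
      y <- runif(1, margin, H - 1 - margin)
      px <- x - layout$anchor["x"]; py <- y - layout$anchor["y"]
      u <- px * dxv + py * dyv
      v <- px * nxv + py * nyv
      if (layout$presentation != "absent") {
        hw <- body_halfwidth_frac(u / layout$body_length) * H * layout$size_factor
        inside <- u >= 0 & u <= layout$body_length & abs(v) <= hw + 3 * margin
        if (inside) next
      }
    } else {
      rng_u <- switch(region,
                      head = c(0, layout$u_head),
                      trunk = c(layout$u_head, layout$u_tail),
                      tail = c(layout$u_tail, layout$body_length),
                      stop(sprintf("unknown region '%s'", region)))
      # stay clear of the region boundaries along the axis so that small
      # landmark-detection errors cannot flip a spot's region
      bmargin <- max(margin, 0.02 * layout$body_length)
      u <- runif(1, rng_u[1] + bmargin, rng_u[2] - bmargin)
      hw <- body_halfwidth_frac(u / layout$body_length) * H * layout$size_factor
      if (hw <= margin + 0.5) next
      v <- runif(1, -(hw - margin), hw - margin)
      x <- layout$anchor["x"] + u * dxv + v * nxv
      y <- layout$anchor["y"] + u * dyv + v * nyv
      if (x < margin || x > W - 1 - margin || y < margin || y > H - 1 - margin) next
    }
    allx <- c(placed_x, ok_x); ally <- c(placed_y, ok_y)
    if (length(allx) && min((allx - x)^2 + (ally - y)^2) < min_sep^2) next
    ok_x <- c(ok_x, x); ok_y <- c(ok_y, y); ok_u <- c(ok_u, u)
  }
  data.frame(x = ok_x, y = ok_y, u = ok_u)
}

# draw a Gaussian-profile spot into a canvas, windowed to +-3.5 sigma
add_spot <- function(canvas, x, y, sigma, amplitude) {
  H <- nrow(canvas); W <- ncol(canvas)
  r <- ceiling(3.5 * sigma)
  j0 <- max(1, floor(x) + 1 - r); j1 <- min(W, floor(x) + 1 + r)
  i0 <- max(1, floor(y) + 1 - r); i1 <- min(H, floor(y) + 1 + r)
  if (j0 > j1 || i0 > i1) return(canvas)
  xs <- (j0:j1) - 1 - x; ys <- (i0:i1) - 1 - y
  g <- amplitude * outer(exp(-0.5 * ys^2 / sigma^2),
                         exp(-0.5 * xs^2 / sigma^2))
  canvas[i0:i1, j0:j1] <- canvas[i0:i1, j0:j1] + g
  canvas
}

# smooth low-frequency autofluorescence over the head and yolk footprints
render_haze <- function(layout, amplitude) {
  H <- layout$canvas[1]; W <- layout$canvas[2]
  if (layout$presentation == "absent" || amplitude <= 0) {
    return(matrix(0, H, W))
  }
  fr <- layout_axis_frame(layout)
  Lb <- layout$body_length
  sh <- 0.09 * Lb; sy <- 0.07 * Lb
  head_u <- 0.09 * Lb
  g1 <- exp(-0.5 * ((fr$U - head_u)^2 + (1.5 * fr$V)^2) / sh^2)
  g2 <- exp(-0.5 * ((fr$U - layout$yolk$centre_u)^2 +
                      (1.5 * (fr$V - layout$yolk$centre_v))^2) / sy^2)
  amplitude * pmin(g1 + g2, 1.2)
}

#' Render one synthetic well
#'
#' Produces the full set of field tiles for a well: per z-slice brightfield
#' (body darker than background, eyes and yolk darkest, thin bright-ish tail
#' fin, blurred with a Gaussian of width proportional to the distance from
#' the focus plane) and per z-slice fluorescence (offset + autofluorescence
#' haze over head and yolk + Gaussian spots whose intensity peaks at their
#' own z-plane), cropped into `fields_per_well` overlapping tiles and
#' quantized to the plate bit depth, with per-tile camera noise.
#'
#' @param layout An [embryo_layout()].
#' @param spots A `spot_truth` data frame from [sample_spots()] (may have
#'   zero rows).
#' @param spec A [plate_spec()].
#' @param noise A [noise_params()].
#' @param seed Optional integer; when given, the RNG is seeded so the output
#'   is bit-identical across calls.
#' @param well Well identifier stored on the tiles.
#' @param haze Haze peak amplitude in counts; `NULL` uses the default level.
#' @param vessel Optional list `list(channel =, fraction =, amplitude =)`
#'   adding an elongated vessel-like fluorescent structure along the dorsal
#'   trunk; `fraction` in (0, 1] scales its extent.
#' @param keep_canvas,keep_masks Keep the seamless per-channel canvases /
#'   truth masks on the result (memory-heavy; off by default).
#' @return List with elements `fields` (list of field-image records with
#'   `well`, `field_index`, `channel`, `z_index`, `pixels`), `truth`
#'   (ground-truth entry: layout, spots, per-(channel, region) counts, true
#'   areas), plus optionally `canvas` and `masks`.
#' @export
render_well <- function(layout, spots, spec, noise = noise_params(),
                        seed = NULL, well = "A01", haze = NULL,
                        vessel = NULL, keep_canvas = FALSE,
                        keep_masks = FALSE) {
  stopifnot(inherits(layout, "embryo_layout"), inherits(spec, "plate_spec"))
  if (!is.null(seed)) set.seed(seed)
  cs <- canvas_shape(spec)
  H <- cs[1]; W <- cs[2]
  if (nrow(spots)) {
    if (any(spots$x < 0 | spots$x > W - 1 | spots$y < 0 | spots$y > H - 1)) {
      stop("spot centre outside the stitched-well canvas")
    }
  }
  maxval <- 2^spec$bit_depth - 1
  lv <- render_levels(maxval)
  masks <- layout_masks(layout)

  # brightfield base canvas with a mild radial well vignette
  xs <- (seq_len(W) - 1) / (W - 1) - 0.5
  ys <- (seq_len(H) - 1) / (H - 1) - 0.5
  vign <- 1 - 0.06 * outer(ys^2 * 4, xs^2 * 4, `+`) / 2
  bf <- matrix(lv$bf_bg, H, W)
  bf[masks$fin] <- lv$bf_bg * lv$bf_fin
  bf[masks$body] <- lv$bf_bg * lv$bf_body
  bf[masks$yolk] <- lv$bf_bg * lv$bf_yolk
  bf[masks$eye] <- lv$bf_bg * lv$bf_eye
  bf <- bf * vign

  haze_amp <- if (is.null(haze)) lv$haze_amp else haze
  fl_channels <- fluorescence_channels(spec)
  haze_canvas <- render_haze(layout, haze_amp)

  blur_pp <- lv$blur_per_plane_frac * spec$tile_shape[1]
  offs <- field_offsets(spec)
  L <- spec$tile_shape[2]
  bf_name <- brightfield_channel(spec)

  fields <- list()
  canvases <- list()
  for (ch in names(spec$channels)) {
    role <- spec$channels[[ch]]
    if (keep_canvas) canvases[[ch]] <- vector("list", spec$z_planes)
    for (z in seq_len(spec$z_planes) - 1L) {
      if (role$modality == "brightfield") {
        sig <- blur_pp * abs(z - layout$z_focus)
        cz <- if (sig > 0) box_blur_cpp(bf, sig) else bf
      } else {
        cz <- matrix(lv$fl_bg, H, W) + haze_canvas
        if (nrow(spots)) {
          sel <- which(spots$channel == ch)
          for (s in sel) {
            fz <- exp(-0.5 * (z - spots$z_peak[s])^2 / 0.75^2)
            if (fz < 0.005) next
            cz <- add_spot(cz, spots$x[s], spots$y[s],
                           spots$radius[s] / 1.6, spots$amplitude[s] * fz)
          }
        }
        if (!is.null(vessel) && identical(vessel$channel, ch)) {
          cz <- add_vessel(cz, layout, vessel)
        }
      }
      cz <- pmin(pmax(cz, 0), maxval)
      if (keep_canvas) canvases[[ch]][[z + 1L]] <- cz
      for (f in seq_along(offs)) {
        tile <- cz[, (offs[f] + 1):(offs[f] + L), drop = FALSE]
        if (noise$enabled) {
          sdn <- sqrt((if (noise$shot) tile else 0) + noise$read_sd^2)
          tile <- tile + rnorm(length(tile)) * sdn
        }
        tile <- matrix(as.integer(round(pmin(pmax(tile, 0), maxval))),
                       nrow(tile), ncol(tile))
        fields[[length(fields) + 1]] <- list(
          well = well, field_index = f - 1L, channel = ch,
          z_index = z, pixels = tile)
      }
    }
  }

  truth <- list(
    layout = layout, spots = spots,
    counts = tally_spot_counts(spots, names(spec$channels)),
    fish_area = sum(masks$body),
    eye_area = sum(masks$eye) / max(1L, layout$n_eyes),
    total_spot_area = vapply(fl_channels, function(ch)
      sum(pi * spots$radius[spots$channel == ch]^2), numeric(1)))
  out <- list(fields = fields, truth = truth)
  if (keep_canvas) out$canvas <- canvases
  if (keep_masks) out$masks <- masks
  out
}

# elongated vessel-like structure along the dorsal body margin
add_vessel <- function(canvas, layout, vessel) {
  fr <- layout_axis_frame(layout)
  H <- layout$canvas[1]
  Lb <- layout$body_length
  u0 <- 0.20 * Lb
  u1 <- u0 + vessel$fraction * 0.65 * Lb
  hw <- matrix(body_halfwidth_frac(as.vector(fr$U) / Lb),
               nrow(canvas), ncol(canvas)) * H * layout$size_factor
  vc <- -0.55 * hw
  sig <- max(1.5, 0.006 * H)
  band <- exp(-0.5 * ((fr$V - vc) / sig)^2)
  band[fr$U < u0 | fr$U > u1] <- 0
  canvas + vessel$amplitude * band
}

#' Tally ground-truth spot counts per channel and region
#' @param spots A `spot_truth` data frame.
#' @param channels Channel names to report (zeros where absent).
#' @return Data frame with columns `channel`, `region`, `count`.
#' @export
tally_spot_counts <- function(spots, channels) {
  regions <- c("head", "trunk", "tail", "outside_fish")
  grid <- expand.grid(region = regions, channel = channels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- mapply(function(ch, rg) {
    sum(spots$channel == ch & spots$region == rg)
  }, grid$channel, grid$region)
  grid[, c("channel", "region", "count")]
}
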