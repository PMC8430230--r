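# Shared fixtures, generated once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (!exists(key, envir = .fx)) assign(key, fn(), envir = .fx)
  get(key, envir = .fx)
}

# half-resolution two-channel spec used for detection-quality checks
spec_half <- function() plate_spec(tile_shape = c(256L, 348L))

# quarter-resolution brightfield-only spec used for QC-scale checks
spec_quarter_bf <- function() {
  plate_spec(tile_shape = c(128L, 174L),
             channels = list(channel_role("BF", "brightfield")))
}

# one rendered lateral well at half scale, with truth masks
lateral_well <- function(noisy = FALSE) {
  key <- paste0("lateral_", noisy)
  fixture(key, function() {
    spec <- spec_half()
    set.seed(11)
    lay <- embryo_layout("lateral_left", spec)
    spots <- sample_spots(lay, spec, spot_laws_preset("hspc", spec))
    np <- if (noisy) noise_params() else noise_params(enabled = FALSE)
    rw <- render_well(lay, spots, spec, noise = np, seed = 12,
                      keep_masks = TRUE, keep_canvas = TRUE)
    rw$layout <- lay; rw$spots <- spots; rw$spec <- spec
    rw
  })
}

render_presentation <- function(presentation, seed = 21, spec = spec_half(),
                                noisy = FALSE) {
  set.seed(seed)
  lay <- embryo_layout(presentation, spec)
  np <- if (noisy) noise_params() else noise_params(enabled = FALSE)
  rw <- render_well(lay, sample_spots(lay, spec, spot_laws_preset("none", spec)),
                    spec, noise = np, seed = seed + 1, keep_masks = TRUE)
  rw$layout <- lay; rw$spec <- spec
  rw
}

# stacks[[channel]][[field]][[z]] from a render_well result
fields_to_stacks <- function(fields, spec) {
  stacks <- list()
  for (f in fields) {
    ch <- f$channel
    if (is.null(stacks[[ch]])) {
      stacks[[ch]] <- lapply(seq_len(spec$fields_per_well),
                             function(i) vector("list", spec$z_planes))
    }
    stacks[[ch]][[f$field_index + 1]][[f$z_index + 1]] <- f$pixels
  }
  stacks
}

# processed (stitched + segmented) lateral well
processed_lateral <- function(noisy = FALSE) {
  key <- paste0("processed_", noisy)
  fixture(key, function() {
    rw <- lateral_well(noisy)
    spec <- rw$spec
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec), spec)
    cfg <- run_config(spec)
    seg <- segment_embryo(sw$images$BF, cfg$constraints)
    list(rw = rw, sw = sw, seg = seg, cfg = cfg, spec = spec)
  })
}

# the reference screening plate: 96 wells at half resolution, default
# presentation mix and spot laws, written to disk (memory stays bounded and
# the full file round trip is exercised); the noise-free variant shares the
# seed, so the scene (layouts, spots) is identical
hspc_plate <- function(noisy = TRUE) {
  fixture(paste0("hspc_plate_", noisy), function() {
    dir <- file.path(tempdir(), paste0("hspc_plate_", if (noisy) "n" else "nf"))
    np <- if (noisy) noise_params() else noise_params(enabled = FALSE)
    generate_plate(96, spec_half(), seed = 101, noise = np, dir = dir)
  })
}

hspc_records <- function(noisy = TRUE) {
  fixture(paste0("hspc_records_", noisy), function() {
    run_plate(hspc_plate(noisy), run_config(spec_half()))
  })
}

# a segmented dorsal (on-back) well at half scale
dorsal_seg <- function() {
  fixture("dorsal_seg", function() {
    rw <- render_presentation("dorsal", seed = 33)
    sw <- preprocess_well(fields_to_stacks(rw$fields, spec_half()), spec_half())
    list(rw = rw, seg = segment_embryo(sw$images$BF,
                                       size_constraints(spec_half())))
  })
}

# canvas-frame coordinates of a layout point given in axis coordinates
layout_point <- function(layout, u, v) {
  d <- c(layout$headward * cos(layout$theta), sin(layout$theta))
  n <- c(-layout$headward * sin(layout$theta), cos(layout$theta))
  c(x = unname(layout$anchor["x"] + u * d[1] + v * n[1]),
    y = unname(layout$anchor["y"] + u * d[2] + v * n[2]))
}

# independent flood-fill connected-component labelling (pure R, queue-based)
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        qi <- p[1] + nb[k, 1]; qj <- p[2] + nb[k, 2]
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# oracle granule detection: flood fill on an absolute-thresholded image
# (no smoothing, no background subtraction), with area + centroid rules
oracle_detect <- function(img, threshold, min_area, max_area, fish_mask) {
  lab <- oracle_label(img > threshold, 8)
  out <- list()
  if (max(lab) > 0) {
    for (k in seq_len(max(lab))) {
      px <- which(lab == k)
      if (length(px) < min_area || length(px) > max_area) next
      ii <- (px - 1) %% nrow(img) + 1
      jj <- (px - 1) %/% nrow(img) + 1
      ci <- as.integer(round(mean(ii - 1))) + 1
      cj <- as.integer(round(mean(jj - 1))) + 1
      if (!isTRUE(fish_mask[ci, cj])) next
      out[[length(out) + 1]] <- data.frame(
        area = length(px), integrated_intensity = sum(img[px]))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(area = numeric(0), integrated_intensity = numeric(0))
}

# draw a hard disc of a given value into an image
draw_disc <- function(img, x, y, r, value) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if ((j - 1 - x)^2 + (i - 1 - y)^2 <= r^2) img[i, j] <- value
  }
  img
}
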