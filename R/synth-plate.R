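#' Default spot-count laws per assay
#'
#' Bundles the ground-truth spot population the generator draws for each
#' assay flavour. The `hspc` preset mirrors a stem-cell counting screen:
#' a dim (GFP-lo) population of mean 30 in the tail (the caudal
#' haematopoietic tissue), a few bright (GFP-hi) cells in the trunk, and a
#' couple of bright objects outside the fish (circulating cells, debris)
#' that the containment rule must discard.
#'
#' @param preset One of `"hspc"`, `"dual"`, `"apoptosis"`, `"haircell"`,
#'   `"angiogenesis"`, `"none"`.
#' @param spec A [plate_spec()] (supplies the fluorescence channel names).
#' @param tail_mean Mean tail spot count for count-based presets.
#' @return Data frame with columns `channel`, `region`, `law`, `mean`,
#'   `class`.
#' @export
spot_laws_preset <- function(preset = c("hspc", "dual", "apoptosis",
                                        "haircell", "angiogenesis", "none"),
                             spec, tail_mean = 30) {
  preset <- match.arg(preset)
  fl <- fluorescence_channels(spec)
  if (length(fl) == 0) preset <- "none"   # brightfield-only plates carry no spots
  law <- function(channel, region, law, mean, class)
    data.frame(channel = channel, region = region, law = law, mean = mean,
               class = class, stringsAsFactors = FALSE)
  switch(preset,
    none = law(character(0), character(0), character(0), numeric(0), character(0)),
    hspc = rbind(law(fl[1], "tail", "poisson", tail_mean, "dim"),
                 law(fl[1], "trunk", "poisson", 4, "bright"),
                 law(fl[1], "outside_fish", "poisson", 2, "bright")),
    dual = {
      if (length(fl) < 2) stop("dual preset needs two fluorescence channels")
      rbind(law(fl[1], "tail", "poisson", tail_mean, "dim"),
            law(fl[2], "tail", "poisson", 20, "dim"),
            law(fl[1], "outside_fish", "poisson", 2, "bright"))
    },
    apoptosis = rbind(law(fl[1], "head", "poisson", 12, "dim"),
                      law(fl[1], "trunk", "poisson", 10, "dim"),
                      law(fl[1], "tail", "poisson", 8, "dim")),
    haircell = rbind(law(fl[1], "trunk", "poisson", 9, "bright"),
                     law(fl[1], "tail", "poisson", 6, "bright")),
    angiogenesis = law(fl[1], "outside_fish", "constant", 0, "bright"))
}

#' Default presentation mix of a synthetic plate
#'
#' About 95% of embryos settle on-side in the alignment plate; the remainder
#' are misoriented (on their back, partially out of the imaged strip) or the
#' well is empty. Misoriented here means dorsal + partial + absent.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
default_presentation_mix <- function() {
  c(lateral_left = 90 / 96, lateral_right = 1 / 96,
    dorsal = 2 / 96, partial = 2 / 96, absent = 1 / 96)
}

# largest-remainder integer allocation of n wells over proportions
allocate_presentations <- function(n_wells, mix) {
  if (any(mix < 0)) stop("impossible allocation: negative proportions")
  if (abs(sum(mix) - 1) > 1e-8) stop("presentation proportions must sum to 1")
  raw <- mix * n_wells
  base <- floor(raw)
  rem <- n_wells - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

well_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 7919 + i * 104729) %% 2147483629)
}

#' Generate a synthetic plate with exhaustive ground truth
#'
#' Renders `n_wells` wells with the requested presentation mix and per-region
#' spot-count laws. Each well gets an independent seed derived from the
#' master seed, so output is bit-identical for identical arguments and
#' wells are reproducible individually. When `dir` is given, tiles are
#' written as TIFFs under the plate naming convention together with
#' `truth_counts.csv` (one row per well, channel and region) and
#' `truth_layout.csv` (one row per well); otherwise tiles stay in memory.
#'
#' @param n_wells Number of wells to render (first wells in row-major order).
#' @param spec A [plate_spec()].
#' @param seed Master seed (integer).
#' @param presentation_mix Named proportions over the five presentations;
#'   must sum to 1.
#' @param laws Spot-count laws, see [spot_laws_preset()].
#' @param noise A [noise_params()].
#' @param dir Output directory (created), or `NULL` for an in-memory plate.
#' @param keep_masks Keep truth masks per well (memory-heavy).
#' @param amplitude_factor,radius_factor,haze,vessel Passed to the renderer
#'   / spot sampler for assay variants.
#' @param pattern Filename template used when writing tiles.
#' @return An object of class `synth_plate`: list with `spec`, `wells`
#'   (per-well list of `fields`, `truth`, `presentation`), `truth_counts`
#'   (data frame well x channel x region), `truth_layout` (data frame) and
#'   `dir`.
#' @export
generate_plate <- function(n_wells = 96, spec = plate_spec(), seed = 1,
                           presentation_mix = default_presentation_mix(),
                           laws = spot_laws_preset("hspc", spec),
                           noise = noise_params(), dir = NULL,
                           keep_masks = FALSE, amplitude_factor = 1,
                           radius_factor = 1, haze = NULL, vessel = NULL,
                           pattern = "{well}_f{field}_{channel}_z{z}.tif") {
  stopifnot(n_wells >= 1, n_wells <= spec$rows * spec$cols)
  counts <- allocate_presentations(n_wells, presentation_mix)
  wells <- well_ids(spec)[seq_len(n_wells)]
  set.seed(well_seed(seed, 0L))
  pres <- sample(rep(names(presentation_mix), counts))

  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  out_wells <- vector("list", n_wells)
  names(out_wells) <- wells
  truth_counts <- vector("list", n_wells)
  truth_layout <- vector("list", n_wells)
  for (i in seq_len(n_wells)) {
    ws <- well_seed(seed, i)
    set.seed(ws)
    layout <- embryo_layout(pres[i], spec)
    spots <- sample_spots(layout, spec, laws, noise,
                          amplitude_factor = amplitude_factor,
                          radius_factor = radius_factor)
    rw <- render_well(layout, spots, spec, noise, seed = NULL,
                      well = wells[i], haze = haze, vessel = vessel,
                      keep_masks = keep_masks)
    tc <- rw$truth$counts
    tc$well <- wells[i]
    truth_counts[[i]] <- tc[, c("well", "channel", "region", "count")]
    truth_layout[[i]] <- data.frame(
      well = wells[i], presentation = pres[i],
      z_focus = layout$z_focus,
      fish_area = rw$truth$fish_area, eye_area = rw$truth$eye_area,
      n_eyes = layout$n_eyes, seed = ws, stringsAsFactors = FALSE)
    if (!is.null(dir)) {
      for (fi in rw$fields) {
        fn <- format_field_filename(fi$well, fi$field_index, fi$channel,
                                    fi$z_index, pattern)
        write_field_image(fi$pixels, file.path(dir, fn), spec$bit_depth)
      }
      rw$fields <- NULL
    }
    out_wells[[i]] <- list(well = wells[i], presentation = pres[i],
                           fields = rw$fields, truth = rw$truth,
                           masks = rw$masks)
  }
  truth_counts <- do.call(rbind, truth_counts)
  truth_layout <- do.call(rbind, truth_layout)
  if (!is.null(dir)) {
    utils::write.csv(truth_counts, file.path(dir, "truth_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(truth_layout, file.path(dir, "truth_layout.csv"),
                     row.names = FALSE)
  }
  structure(list(spec = spec, wells = out_wells,
                 truth_counts = truth_counts, truth_layout = truth_layout,
                 dir = dir, pattern = pattern),
            class = "synth_plate")
}

#' @export
print.synth_plate <- function(x, ...) {
  tab <- table(vapply(x$wells, `[[`, character(1), "presentation"))
  cat(sprintf("<synth_plate> %d wells (%s)%s\n", length(x$wells),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              if (is.null(x$dir)) " [in memory]" else paste0(" at ", x$dir)))
  invisible(x)
}

#' Misoriented wells of a synthetic plate
#'
#' The wells the orientation QC is supposed to exclude: presentation
#' `absent`, `dorsal` or `partial`.
#'
#' @param plate A `synth_plate`.
#' @return Character vector of well identifiers.
#' @export
misoriented_wells <- function(plate) {
  stopifnot(inherits(plate, "synth_plate"))
  lay <- plate$truth_layout
  sort(lay$well[lay$presentation %in% c("absent", "dorsal", "partial")])
}
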