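#' Describe one imaging channel
#'
#' A channel is identified by its name and carries its modality
#' (transmitted-light brightfield or fluorescence) and the z-collapse rule
#' applied to its stacks. By convention brightfield stacks are collapsed by
#' best-focus slice selection and fluorescence stacks by maximum intensity
#' projection, so that all labelled cells through the embryo volume remain
#' visible while the brightfield anatomy stays in focus.
#'
#' @param name Channel identifier used in filenames and result columns.
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @param projection `"best_slice"` or `"max_projection"`. Defaults to
#'   `"best_slice"` for brightfield and `"max_projection"` for fluorescence.
#' @return An object of class `channel_role`.
#' @export
channel_role <- function(name,
                         modality = c("brightfield", "fluorescence"),
                         projection = NULL) {
  modality <- match.arg(modality)
  if (is.null(projection)) {
    projection <- if (modality == "brightfield") "best_slice" else "max_projection"
  }
  projection <- match.arg(projection, c("best_slice", "max_projection"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, modality = modality, projection = projection),
            class = "channel_role")
}

#' Plate geometry and acquisition layout
#'
#' Describes a screening plate as acquired: the well grid, the number of
#' overlapping fields imaged along each well's long axis, the z-stack depth
#' and inter-plane distance, the nominal along-well field overlap, and the
#' channel set. The defaults describe a 96-well plate imaged with four
#' overlapping fields per well and five z-planes 50.6 um apart.
#'
#' @param rows,cols Well grid dimensions (8 x 12 for a 96-well plate).
#' @param fields_per_well Number of overlapping fields along the well.
#' @param z_planes Number of z-slices per field.
#' @param z_step Inter-plane distance in micrometres.
#' @param overlap_fraction Nominal along-well overlap between neighbouring
#'   fields, in `[0, 1)`.
#' @param pixel_size Physical pixel pitch in micrometres per pixel; areas are
#'   reported in um^2 when set, in px^2 when `NA`.
#' @param tile_shape Integer `c(height, width)` of one field tile in pixels.
#' @param bit_depth Image bit depth, 8 or 16.
#' @param channels List of [channel_role()] objects; exactly one must be
#'   brightfield.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(rows = 8L, cols = 12L, fields_per_well = 4L,
                       z_planes = 5L, z_step = 50.6,
                       overlap_fraction = 0.15, pixel_size = NA_real_,
                       tile_shape = c(512L, 696L), bit_depth = 16L,
                       channels = list(channel_role("BF", "brightfield"),
                                       channel_role("GFP", "fluorescence"))) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  fields_per_well <- as.integer(fields_per_well)
  z_planes <- as.integer(z_planes)
  tile_shape <- as.integer(tile_shape)
  stopifnot(rows >= 1L, cols >= 1L, fields_per_well >= 1L, z_planes >= 1L)
  if (!(overlap_fraction >= 0 && overlap_fraction < 1)) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  if (!is.na(pixel_size) && pixel_size <= 0) stop("pixel_size must be > 0")
  stopifnot(length(tile_shape) == 2L, all(tile_shape >= 8L))
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth %in% c(8L, 16L))
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, logical(1), "channel_role")))
  mods <- vapply(channels, `[[`, character(1), "modality")
  if (sum(mods == "brightfield") != 1L) {
    stop("exactly one channel must have modality 'brightfield'")
  }
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("channel names must be unique")
  names(channels) <- nms
  structure(list(rows = rows, cols = cols,
                 fields_per_well = fields_per_well,
                 z_planes = z_planes, z_step = z_step,
                 overlap_fraction = overlap_fraction,
                 pixel_size = pixel_size,
                 tile_shape = tile_shape, bit_depth = bit_depth,
                 channels = channels),
            class = "plate_spec")
}

#' @export
print.plate_spec <- function(x, ...) {
  cat(sprintf("<plate_spec> %d x %d wells, %d fields/well, %d z-planes (%g um apart)\n",
              x$rows, x$cols, x$fields_per_well, x$z_planes, x$z_step))
  cat(sprintf("  tiles %d x %d px (%d-bit), overlap %.0f%%, pixel size %s\n",
              x$tile_shape[1], x$tile_shape[2], x$bit_depth,
              100 * x$overlap_fraction,
              if (is.na(x$pixel_size)) "unset" else sprintf("%g um", x$pixel_size)))
  for (ch in x$channels) {
    cat(sprintf("  channel %s: %s, %s\n", ch$name, ch$modality, ch$projection))
  }
  invisible(x)
}

#' All well identifiers of a plate, row-major ("A01", "A02", ...)
#' @param spec A [plate_spec()].
#' @return Character vector of length `rows * cols`.
#' @export
well_ids <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  rows <- LETTERS[seq_len(spec$rows)]
  as.vector(t(outer(rows, seq_len(spec$cols),
                    function(r, c) sprintf("%s%02d", r, c))))
}

#' Stitched canvas dimensions of one well
#'
#' The stitched well image is `tile_height` rows by
#' `n * L - (n - 1) * round(overlap * L)` columns, where `L` is the tile
#' width and `n` the number of fields.
#'
#' @param spec A [plate_spec()].
#' @return Integer `c(height, width)` in pixels.
#' @export
canvas_shape <- function(spec) {
  L <- spec$tile_shape[2]
  n <- spec$fields_per_well
  step <- L - as.integer(round(spec$overlap_fraction * L))
  c(spec$tile_shape[1], as.integer(n * L - (n - 1) * round(spec$overlap_fraction * L)))
}

#' Column offsets of each field tile inside the stitched canvas
#' @param spec A [plate_spec()].
#' @return Integer vector of 0-based column offsets, one per field.
#' @export
field_offsets <- function(spec) {
  L <- spec$tile_shape[2]
  step <- L - as.integer(round(spec$overlap_fraction * L))
  as.integer((seq_len(spec$fields_per_well) - 1L) * step)
}

brightfield_channel <- function(spec) {
  mods <- vapply(spec$channels, `[[`, character(1), "modality")
  names(spec$channels)[mods == "brightfield"][1]
}

fluorescence_channels <- function(spec) {
  mods <- vapply(spec$channels, `[[`, character(1), "modality")
  names(spec$channels)[mods == "fluorescence"]
}
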