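#' Parse a field-image filename
#'
#' Filenames are matched against a template with the four placeholders
#' `{well}`, `{field}`, `{channel}` and `{z}`, e.g. the default
#' `"{well}_f{field}_{channel}_z{z}.tif"`. Parsing and [format_field_filename()]
#' are mutual inverses for valid keys.
#'
#' @param name Filename (basename, not a path).
#' @param pattern Template string containing all four placeholders.
#' @return A list with elements `well` (character), `field_index` (0-based
#'   integer), `channel` (character) and `z_index` (0-based integer).
#' @export
parse_field_filename <- function(name, pattern = "{well}_f{field}_{channel}_z{z}.tif") {
  rx <- filename_regex(pattern)
  m <- regmatches(name, regexec(rx$regex, name))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("filename '%s' does not match pattern '%s'", name, pattern))
  }
  vals <- m[-1]
  names(vals) <- rx$keys
  list(well = unname(vals["well"]),
       field_index = as.integer(vals["field"]),
       channel = unname(vals["channel"]),
       z_index = as.integer(vals["z"]))
}

#' Format a field-image filename
#' @param well Well identifier, e.g. `"A01"`.
#' @param field_index 0-based field index.
#' @param channel Channel name.
#' @param z_index 0-based z index.
#' @inheritParams parse_field_filename
#' @return Filename string.
#' @export
format_field_filename <- function(well, field_index, channel, z_index,
                                  pattern = "{well}_f{field}_{channel}_z{z}.tif") {
  out <- pattern
  out <- gsub("{well}", well, out, fixed = TRUE)
  out <- gsub("{field}", as.integer(field_index), out, fixed = TRUE)
  out <- gsub("{channel}", channel, out, fixed = TRUE)
  gsub("{z}", as.integer(z_index), out, fixed = TRUE)
}

filename_regex <- function(pattern) {
  keys <- c(well = "\\{well\\}", field = "\\{field\\}",
            channel = "\\{channel\\}", z = "\\{z\\}")
  pos <- vapply(keys, function(k) regexpr(k, pattern), integer(1))
  if (any(pos < 0L)) {
    stop("pattern must contain {well}, {field}, {channel} and {z} placeholders")
  }
  # escape regex metacharacters outside the placeholders, then substitute
  esc <- gsub("([][{}()+*^$|\\\\?.=!<>:#-])", "\\\\\\1", pattern)
  esc <- gsub("\\\\\\{(well|field|channel|z)\\\\\\}", "{\\1}", esc)
  caps <- c(well = "([A-Za-z]+[0-9]+)", field = "([0-9]+)",
            channel = "([A-Za-z0-9]+)", z = "([0-9]+)")
  for (k in names(caps)) {
    esc <- sub(paste0("{", k, "}"), caps[[k]], esc, fixed = TRUE)
  }
  list(regex = paste0("^", esc, "$"), keys = names(sort(pos)))
}

#' Index the field images of a plate directory
#'
#' Scans `directory` for files matching the naming template and builds the
#' (well, field, channel, z) index expected from `spec`. Every expected key
#' must map to exactly one file; wells with no files at all are flagged
#' empty-on-disk rather than treated as errors, and partially present wells
#' are reported key by key.
#'
#' @param directory Plate directory.
#' @param spec A [plate_spec()].
#' @inheritParams parse_field_filename
#' @return An object of class `plate_index`: a data frame with columns
#'   `well`, `field_index`, `channel`, `z_index`, `path`, with attributes
#'   `missing` (data frame of absent keys for partially present wells),
#'   `empty_wells` (character) and `spec`.
#' @export
discover_plate <- function(directory, spec,
                           pattern = "{well}_f{field}_{channel}_z{z}.tif") {
  stopifnot(dir.exists(directory), inherits(spec, "plate_spec"))
  files <- list.files(directory, full.names = FALSE)
  rx <- filename_regex(pattern)
  hits <- grepl(rx$regex, files)
  parsed <- lapply(files[hits], parse_field_filename, pattern = pattern)
  idx <- if (length(parsed)) {
    data.frame(well = vapply(parsed, `[[`, character(1), "well"),
               field_index = vapply(parsed, `[[`, integer(1), "field_index"),
               channel = vapply(parsed, `[[`, character(1), "channel"),
               z_index = vapply(parsed, `[[`, integer(1), "z_index"),
               path = file.path(directory, files[hits]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(well = character(0), field_index = integer(0),
               channel = character(0), z_index = integer(0),
               path = character(0), stringsAsFactors = FALSE)
  }
  key <- with(idx, paste(well, field_index, channel, z_index))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("duplicate field-image key (%s) in %s", dup, directory))
  }
  expected <- expand.grid(z_index = seq_len(spec$z_planes) - 1L,
                          channel = names(spec$channels),
                          field_index = seq_len(spec$fields_per_well) - 1L,
                          well = well_ids(spec),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ekey <- with(expected, paste(well, field_index, channel, z_index))
  present <- ekey %in% key
  wells_with_files <- unique(idx$well)
  empty_wells <- setdiff(well_ids(spec), wells_with_files)
  missing <- expected[!present & expected$well %in% wells_with_files,
                      c("well", "field_index", "channel", "z_index")]
  rownames(missing) <- NULL
  extra <- setdiff(key, ekey)
  if (length(extra)) {
    stop(sprintf("file key (%s) does not belong to the plate layout", extra[1]))
  }
  structure(idx[order(idx$well, idx$channel, idx$field_index, idx$z_index), ,
                drop = FALSE],
            missing = missing, empty_wells = empty_wells, spec = spec,
            class = c("plate_index", "data.frame"))
}

#' Read one field image from disk
#'
#' Reads a grayscale 8- or 16-bit TIFF as an integer intensity matrix.
#'
#' @param path Path to the TIFF file.
#' @return Integer matrix of raw intensities.
#' @export
read_field_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path))
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                 error = function(e) stop(sprintf("unreadable image '%s': %s",
                                                  path, conditionMessage(e))))
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) stop(sprintf("expected grayscale image: %s", path))
    px <- px[, , 1]
  }
  storage.mode(px) <- "integer"
  px
}

write_field_image <- function(pixels, path, bit_depth) {
  maxv <- 2^bit_depth - 1
  m <- pmin(pmax(pixels, 0), maxv) / maxv
  tiff::writeTIFF(m, path, bits.per.sample = as.integer(bit_depth),
                  compression = "none")
  invisible(path)
}

#' Column order of a per-well results table
#' @keywords internal
record_columns <- function(channels, regions = c("head", "trunk", "tail", "fish")) {
  metric_cols <- unlist(lapply(channels, function(ch) {
    unlist(lapply(regions, function(rg) {
      paste0(ch, "_", rg, "_", c("count", "intensity", "mean_area", "total_area"))
    }))
  }))
  c("well", "qc_included", "qc_reason", "area_unit",
    "fish_area", "fish_length", "eye_count", "eye_area",
    metric_cols, "headline_metric", "headline_value")
}

#' Write per-well results to CSV
#'
#' One row per well; excluded wells carry their exclusion reason and empty
#' metric cells. Numeric cells are written in a canonical fixed format so
#' that reading the file back and rewriting it reproduces the bytes exactly.
#' If the records carry an `area_unit` column (um^2 when the plate's pixel
#' size is calibrated, px^2 otherwise) it is written like any other column,
#' keeping the file a plain RFC-4180 CSV with a mandatory header row.
#'
#' @param records Data frame of well records (possibly zero rows).
#' @param destination Output CSV path.
#' @return `destination`, invisibly.
#' @export
write_results <- function(records, destination) {
  stopifnot(is.data.frame(records))
  dir <- dirname(destination)
  if (!dir.exists(dir)) stop(sprintf("unwritable destination: %s", destination))
  out <- records
  # canonical formatting: fixed notation with at most 6 decimals, trailing
  # zeros stripped, so read-after-write is an identity on the text form
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    v <- out[[j]]
    s <- sprintf("%.6f", v)
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    out[[j]] <- ifelse(is.na(v), NA_character_, s)
  }
  utils::write.csv(out, destination, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = TRUE)
  invisible(destination)
}

#' Read a per-well results CSV written by [write_results()]
#' @param path CSV path.
#' @return Data frame of well records.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  if ("qc_included" %in% names(df)) df$qc_included <- as.logical(df$qc_included)
  df
}
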