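#' Run configuration for a plate analysis
#'
#' Collects everything [run_plate()] needs: plate geometry and channels,
#' assay preset, granule parameters per fluorescence channel, QC criteria,
#' size constraints, an optional well-to-condition group map and a seed.
#'
#' @param spec A [plate_spec()].
#' @param preset Assay preset name (see [assay_preset()]).
#' @param granule_params Named list (by channel) of [granule_params()];
#'   defaults to the preset's parameters for every fluorescence channel.
#' @param qc A [qc_criteria()]; defaults derived from the geometry.
#' @param constraints A [size_constraints()]; defaults from the geometry.
#' @param groups Optional data frame `well`, `condition`.
#' @param seed Integer seed recorded with the run.
#' @param refine_stitch Logical; registration-refined stitching.
#' @param pattern Filename template for on-disk plates.
#' @return A `run_config` object.
#' @export
run_config <- function(spec = plate_spec(), preset = "hspc",
                       granule_params = NULL, qc = NULL, constraints = NULL,
                       groups = NULL, seed = 1L, refine_stitch = FALSE,
                       pattern = "{well}_f{field}_{channel}_z{z}.tif") {
  stopifnot(inherits(spec, "plate_spec"))
  ap <- assay_preset(preset, spec)
  if (is.null(constraints)) constraints <- size_constraints(spec)
  if (is.null(qc)) qc <- default_qc_criteria(spec, constraints)
  fl <- fluorescence_channels(spec)
  if (is.null(granule_params)) {
    granule_params <- setNames(rep(list(ap$params), length(fl)), fl)
  }
  if (!all(names(granule_params) %in% names(spec$channels))) {
    stop("granule_params refers to channels absent from the plate spec")
  }
  if (!is.null(groups)) {
    stopifnot(is.data.frame(groups), all(c("well", "condition") %in% names(groups)))
    if (!all(groups$well %in% well_ids(spec))) {
      stop("group map refers to wells absent from the plate")
    }
  }
  structure(list(spec = spec, preset = ap, granule_params = granule_params,
                 qc = qc, constraints = constraints, groups = groups,
                 seed = as.integer(seed), refine_stitch = isTRUE(refine_stitch),
                 pattern = pattern),
            class = "run_config")
}

# ---- well-stack access over the two plate sources -------------------------

# stacks[[channel]][[field]][[z]] for one well, from a plate_index (disk)
# or a synth_plate (memory)
well_stacks <- function(plate, well, spec) {
  if (inherits(plate, "synth_plate")) {
    w <- plate$wells[[well]]
    fields <- if (!is.null(w)) w$fields else NULL
    if (is.null(fields) && !is.null(plate$dir)) {
      idx <- discover_plate(plate$dir, spec, plate$pattern)
      return(well_stacks(idx, well, spec))
    }
    stacks <- list()
    for (ch in names(spec$channels)) {
      stacks[[ch]] <- lapply(seq_len(spec$fields_per_well) - 1L, function(f) {
        lapply(seq_len(spec$z_planes) - 1L, function(z) {
          hit <- Filter(function(fi) fi$channel == ch &&
                          fi$field_index == f && fi$z_index == z, fields)
          if (length(hit) != 1) stop(sprintf("missing tile %s f%d %s z%d",
                                             well, f, ch, z))
          hit[[1]]$pixels
        })
      })
    }
    return(stacks)
  }
  stopifnot(inherits(plate, "plate_index"))
  sub <- plate[plate$well == well, , drop = FALSE]
  stacks <- list()
  for (ch in names(spec$channels)) {
    stacks[[ch]] <- lapply(seq_len(spec$fields_per_well) - 1L, function(f) {
      lapply(seq_len(spec$z_planes) - 1L, function(z) {
        p <- sub$path[sub$channel == ch & sub$field_index == f & sub$z_index == z]
        if (length(p) != 1) stop(sprintf("missing tile %s f%d %s z%d",
                                         well, f, ch, z))
        read_field_image(p)
      })
    })
  }
  stacks
}

plate_wells_present <- function(plate, spec) {
  if (inherits(plate, "synth_plate")) return(names(plate$wells))
  setdiff(unique(plate$well), character(0))
}

empty_record <- function(well, spec, reason) {
  cols <- record_columns(fluorescence_channels(spec))
  rec <- as.list(rep(NA_real_, length(cols)))
  names(rec) <- cols
  rec$well <- well
  rec$qc_included <- FALSE
  rec$qc_reason <- reason
  rec$area_unit <- if (is.na(spec$pixel_size)) "px2" else "um2"
  rec$headline_metric <- NA_character_
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# ---- the per-well pipeline ------------------------------------------------

analyze_well <- function(stacks, well, config, segmenter = NULL) {
  spec <- config$spec
  sw <- preprocess_well(stacks, spec, refine = config$refine_stitch)
  bf <- sw$images[[brightfield_channel(spec)]]
  seg <- tryCatch({
    if (is.null(segmenter)) segment_embryo(bf, config$constraints)
    else segmenter(bf, config$constraints, well)
  }, error = function(e) NULL)   # a failed segmentation excludes the well
  qc <- apply_qc(seg, config$qc)
  if (!qc$included) {
    return(list(record = empty_record(well, spec, qc$reason),
                granules = NULL))
  }

  rec <- empty_record(well, spec, "ok")
  rec$qc_included <- TRUE
  px <- spec$pixel_size
  s2 <- if (is.na(px)) 1 else px^2
  rec$fish_area <- seg$fish_area * s2
  rec$fish_length <- seg$fish_length * (if (is.na(px)) 1 else px)
  rec$eye_count <- seg$eye_count
  rec$eye_area <- seg$eye_area * s2
  granules <- list()
  for (ch in fluorescence_channels(spec)) {
    gp <- config$granule_params[[ch]]
    if (is.null(gp)) gp <- config$preset$params
    gr <- detect_granules(sw$images[[ch]], gp, seg$fish_mask)
    gr <- assign_regions(gr, seg)
    if (nrow(gr)) {
      granules[[ch]] <- cbind(well = well, channel = ch,
                              as.data.frame(gr), stringsAsFactors = FALSE)
    }
    met <- region_metrics(gr, seg, sw$images[[ch]])
    for (i in seq_len(nrow(met))) {
      rg <- met$region[i]
      rec[[paste0(ch, "_", rg, "_count")]] <- met$count[i]
      rec[[paste0(ch, "_", rg, "_intensity")]] <- met$integrated_intensity[i]
      rec[[paste0(ch, "_", rg, "_mean_area")]] <- met$mean_granule_area[i] * s2
      rec[[paste0(ch, "_", rg, "_total_area")]] <- met$total_granule_area[i] * s2
    }
  }
  fl <- fluorescence_channels(spec)
  if (length(fl)) {
    metric_col <- c(count = "count", integrated_intensity = "intensity",
                    mean_granule_area = "mean_area",
                    total_granule_area = "total_area")[[config$preset$metric]]
    hl <- paste0(fl[1], "_", config$preset$region, "_", metric_col)
    rec$headline_metric <- hl
    rec$headline_value <- rec[[hl]]
  }
  list(record = rec,
       granules = if (length(granules)) do.call(rbind, unname(granules))
                  else NULL)
}

#' Analyze a whole plate
#'
#' For every well: collapse z-stacks, stitch fields, segment the embryo,
#' apply the orientation/quality filter and, for included wells, detect and
#' quantify granules per fluorescence channel. Wells are processed
#' independently, so results do not depend on processing order; a single
#' well's segmentation failure excludes that well rather than aborting the
#' plate. All wells are exported with their QC status; filtering happens at
#' summary time.
#'
#' @param plate A plate directory path, a `plate_index` from
#'   [discover_plate()], or an in-memory `synth_plate`.
#' @param config A [run_config()].
#' @param out Optional output directory; when given, `results.csv` and
#'   `run_log.txt` are written there.
#' @param segmenter Optional replacement segmenter
#'   `function(brightfield, constraints, well)`, e.g. [oracle_segmenter()].
#' @param quiet Suppress per-well log lines on the console.
#' @param dump_granules Also write `granules.csv` (one row per detected
#'   granule, for debugging) when `out` is given.
#' @return Data frame of well records (one row per well on the plate).
#' @export
run_plate <- function(plate, config, out = NULL, segmenter = NULL,
                      quiet = TRUE, dump_granules = FALSE) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  if (is.character(plate)) {
    plate <- discover_plate(plate, spec, config$pattern)
  }
  if (inherits(plate, "plate_index")) {
    miss <- attr(plate, "missing")
    if (nrow(miss) > 0) {
      per_well <- table(miss$well)
      stop(sprintf("plate incomplete: missing tiles in %d well(s): %s",
                   length(per_well),
                   paste(sprintf("%s (%d)", names(per_well), per_well),
                         collapse = ", ")))
    }
  }
  present <- plate_wells_present(plate, spec)
  all_wells <- well_ids(spec)
  if (inherits(plate, "synth_plate")) {
    wells <- present
  } else if (length(present) == 0) {
    wells <- all_wells
  } else {
    # report wells up to the acquired extent: wells with files, plus
    # empty-on-disk wells interleaved among them
    wells <- all_wells[seq_len(max(match(present, all_wells)))]
  }
  log_lines <- character(0)
  records <- vector("list", length(wells))
  granule_rows <- list()
  for (i in seq_along(wells)) {
    w <- wells[i]
    if (inherits(plate, "plate_index") && !(w %in% present)) {
      rec <- empty_record(w, spec, "empty_well")
    } else {
      aw <- analyze_well(well_stacks(plate, w, spec), w, config, segmenter)
      rec <- aw$record
      if (!is.null(aw$granules)) {
        granule_rows[[length(granule_rows) + 1]] <- aw$granules
      }
    }
    records[[i]] <- rec
    line <- sprintf("well=%s qc=%s%s", w, rec$qc_reason,
                    if (isTRUE(rec$qc_included))
                      sprintf(" %s=%s", rec$headline_metric,
                              format(rec$headline_value)) else "")
    log_lines <- c(log_lines, line)
    if (!quiet) message(line)
  }
  res <- do.call(rbind, records)
  res <- res[order(match(res$well, all_wells)), , drop = FALSE]
  rownames(res) <- NULL
  n_inc <- sum(res$qc_included)
  log_lines <- c(log_lines, sprintf("plate: %d wells, %d included, %d excluded",
                                    nrow(res), n_inc, nrow(res) - n_inc))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_results(res, file.path(out, "results.csv"))
    writeLines(log_lines, file.path(out, "run_log.txt"))
    if (dump_granules) {
      gdf <- if (length(granule_rows)) do.call(rbind, granule_rows) else
        data.frame(well = character(0), channel = character(0),
                   x = numeric(0), y = numeric(0), area = numeric(0),
                   integrated_intensity = numeric(0),
                   mean_intensity = numeric(0), region = character(0))
      utils::write.csv(gdf, file.path(out, "granules.csv"), row.names = FALSE)
    }
  }
  res
}

#' Summarize a metric per experimental group
#'
#' Mean and sample (n-1) standard deviation of a metric over QC-included
#' wells per condition, with unpaired two-tailed t-tests for every condition
#' pair. The pooled-variance (Student) form is the default; Welch's
#' correction is available behind `var_equal = FALSE`. p values are reported
#' per comparison without multiplicity correction.
#'
#' @param records Well records from [run_plate()].
#' @param metric Column name to summarize (e.g. `"headline_value"`).
#' @param groups Data frame `well`, `condition`.
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return A `group_summary` data frame (condition, n, mean, sd) with a
#'   `comparisons` attribute (data frame: condition_a, condition_b, t, df,
#'   p); comparisons with fewer than 2 included wells on either side are
#'   reported as not computable (`NA`).
#' @export
summarize_groups <- function(records, metric, groups, var_equal = TRUE) {
  stopifnot(metric %in% names(records),
            all(c("well", "condition") %in% names(groups)))
  inc <- records[records$qc_included %in% TRUE, , drop = FALSE]
  inc <- merge(inc, groups, by = "well")
  conds <- unique(groups$condition)
  summ <- do.call(rbind, lapply(conds, function(cd) {
    v <- inc[[metric]][inc$condition == cd]
    v <- v[!is.na(v)]
    data.frame(condition = cd, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  comps <- list()
  if (length(conds) >= 2) {
    for (a in seq_len(length(conds) - 1)) {
      for (b in (a + 1):length(conds)) {
        va <- inc[[metric]][inc$condition == conds[a]]
        vb <- inc[[metric]][inc$condition == conds[b]]
        va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
        if (length(va) < 2 || length(vb) < 2) {
          comps[[length(comps) + 1]] <- data.frame(
            condition_a = conds[a], condition_b = conds[b],
            t = NA_real_, df = NA_real_, p = NA_real_,
            stringsAsFactors = FALSE)
          next
        }
        tt <- stats::t.test(va, vb, var.equal = var_equal)
        comps[[length(comps) + 1]] <- data.frame(
          condition_a = conds[a], condition_b = conds[b],
          t = unname(tt$statistic), df = unname(tt$parameter),
          p = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  structure(summ, comparisons = do.call(rbind, comps),
            class = c("group_summary", "data.frame"))
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (QC-included wells, mean ± s.d.):\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: n=%d, %.3f ± %.3f\n", x$condition[i], x$n[i],
                x$mean[i], x$sd[i]))
  }
  cmp <- attr(x, "comparisons")
  if (!is.null(cmp) && nrow(cmp)) {
    cat("Unpaired two-tailed t-tests:\n")
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("  %s vs %s: t=%.3f, df=%g, p=%.4g\n",
                  cmp$condition_a[i], cmp$condition_b[i], cmp$t[i],
                  cmp$df[i], cmp$p[i]))
    }
  }
  invisible(x)
}

# ---- config file round-trip ----------------------------------------------

#' Write a run configuration to a YAML file
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  x <- list(
    plate = list(rows = spec$rows, cols = spec$cols,
                 fields_per_well = spec$fields_per_well,
                 z_planes = spec$z_planes, z_step = spec$z_step,
                 overlap_fraction = spec$overlap_fraction,
                 pixel_size = if (is.na(spec$pixel_size)) NULL else spec$pixel_size,
                 tile_shape = spec$tile_shape, bit_depth = spec$bit_depth,
                 channels = lapply(unname(spec$channels), function(ch)
                   list(name = ch$name, modality = ch$modality,
                        projection = ch$projection))),
    preset = config$preset$name,
    granule_params = lapply(config$granule_params, unclass),
    qc = unclass(config$qc),
    constraints = lapply(unclass(config$constraints), as.numeric),
    seed = config$seed,
    refine_stitch = config$refine_stitch,
    pattern = config$pattern)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#' @param path YAML path written by [write_run_config()] (or hand-written
#'   with the same keys).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  p <- x$plate
  spec <- plate_spec(
    rows = p$rows, cols = p$cols, fields_per_well = p$fields_per_well,
    z_planes = p$z_planes, z_step = p$z_step,
    overlap_fraction = p$overlap_fraction,
    pixel_size = if (is.null(p$pixel_size)) NA_real_ else p$pixel_size,
    tile_shape = unlist(p$tile_shape), bit_depth = p$bit_depth,
    channels = lapply(p$channels, function(ch)
      channel_role(ch$name, ch$modality, ch$projection)))
  gp <- lapply(x$granule_params, function(g) {
    g$max_area <- if (is.character(g$max_area) || is.null(g$max_area)) Inf
                  else g$max_area
    do.call(granule_params, g)
  })
  qc <- do.call(qc_criteria, x$qc)
  cons <- do.call(size_constraints,
                  c(list(spec = spec),
                    lapply(x$constraints, function(v) {
                      v <- as.numeric(v); v[is.na(v)] <- Inf; v
                    })))
  run_config(spec = spec, preset = x$preset, granule_params = gp, qc = qc,
             constraints = cons, seed = x$seed,
             refine_stitch = isTRUE(x$refine_stitch), pattern = x$pattern)
}
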