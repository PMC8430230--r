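#' Write a QC overlay image for one well
#'
#' Renders the stitched brightfield image with the fish outline, region
#' boundaries and anatomy outlines (eyes, yolk) painted over it, one PNG per
#' well, for visual inspection of segmentation and QC decisions.
#'
#' @param brightfield Stitched brightfield image (numeric matrix).
#' @param segmentation An `embryo_segmentation` or `NULL`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(brightfield, segmentation, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for QC overlays")
  }
  g <- brightfield / max(brightfield, 1)
  rgb <- array(rep(g, 3), c(dim(g), 3))
  paint <- function(mask, col) {
    edge <- mask & !(shift_mask(mask, 1, 0) & shift_mask(mask, -1, 0) &
                       shift_mask(mask, 0, 1) & shift_mask(mask, 0, -1))
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[edge] <- col[k]
      rgb[, , k] <<- ch
    }
  }
  if (!is.null(segmentation)) {
    paint(segmentation$fish_mask, c(0, 1, 0))
    paint(segmentation$region_map == 3L, c(1, 0, 0))
    paint(segmentation$region_map == 1L, c(1, 1, 1))
    for (e in segmentation$anatomy$eye) {
      m <- matrix(FALSE, nrow(g), ncol(g)); m[e$pixels] <- TRUE
      paint(m, c(1, 0.4, 0.8))
    }
    for (y in segmentation$anatomy$yolk_sac) {
      m <- matrix(FALSE, nrow(g), ncol(g)); m[y$pixels] <- TRUE
      paint(m, c(1, 1, 0))
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

shift_mask <- function(m, di, dj) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  src_i <- seq_len(nrow(m)) - di
  src_j <- seq_len(ncol(m)) - dj
  ok_i <- src_i >= 1 & src_i <= nrow(m)
  ok_j <- src_j >= 1 & src_j <= ncol(m)
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}
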