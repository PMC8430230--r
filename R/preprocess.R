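#' Focus score of an image
#'
#' Variance of the discrete Laplacian, a standard parameter-free sharpness
#' metric: defocus blur suppresses high spatial frequencies, lowering the
#' Laplacian's variance, while an additive intensity offset leaves it
#' unchanged (the Laplacian of a constant is zero).
#'
#' @param image Numeric matrix.
#' @return Non-negative scalar; 0 for a constant image.
#' @export
sharpness_score <- function(image) {
  if (is.null(dim(image)) || any(dim(image) < 1) || length(image) == 0) {
    stop("empty image")
  }
  image <- matrix(as.numeric(image), nrow(image), ncol(image))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) return(0)
  core <- image[2:(nr - 1), 2:(nc - 1)]
  lap <- 4 * core - image[1:(nr - 2), 2:(nc - 1)] -
    image[3:nr, 2:(nc - 1)] - image[2:(nr - 1), 1:(nc - 2)] -
    image[2:(nr - 1), 3:nc]
  stats::var(as.vector(lap))
}

#' Select the sharpest z-slice of a brightfield stack
#'
#' Scores every slice with [sharpness_score()] and returns the argmax;
#' ties are broken in favour of the lowest index. The returned image is the
#' unmodified slice.
#'
#' @param stack List of numeric matrices, ordered by z.
#' @return List with `z_index` (0-based) and `image`.
#' @export
select_best_slice <- function(stack) {
  if (length(stack) == 0) stop("empty stack")
  scores <- vapply(stack, sharpness_score, numeric(1))
  i <- which.max(scores)   # which.max returns the first maximum
  list(z_index = as.integer(i - 1L), image = stack[[i]])
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses the stack to its per-pixel maximum, retaining fluorescent
#' signal from every depth.
#'
#' @param stack List of numeric matrices with identical dimensions.
#' @return Matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (length(stack) == 0) stop("empty stack")
  d <- dim(stack[[1]])
  for (s in stack) {
    if (!identical(dim(s), d)) stop("slice dimension mismatch")
  }
  Reduce(pmax, stack)
}

#' Stitch the overlapping field tiles of a well
#'
#' Composes `n` equal-size tiles along the well's long axis (image columns)
#' at the nominal offsets implied by the overlap fraction, producing an
#' image of width `n * L - (n - 1) * round(overlap * L)`. Pixels outside any
#' overlap region are copied from their source tile unchanged. Two blend
#' rules are available for the overlaps: a linear feather (brightfield, no
#' visible seams) and the pixel-wise maximum (fluorescence, preserves spot
#' peak intensity). With `refine = TRUE` each consecutive tile's offset along
#' the stitch axis is adjusted by exhaustive translation registration of the
#' overlap strips within `search_radius` pixels of nominal.
#'
#' @param field_images Ordered list of numeric matrices (one per field).
#' @param nominal_overlap Overlap fraction in `[0, 1)`.
#' @param blend `"feather"` or `"max"`.
#' @param refine Logical; refine offsets by registration.
#' @param search_radius Maximum deviation from the nominal offset, px.
#' @return List with `image` (matrix) and `offsets` (0-based column offsets
#'   actually used, one per tile).
#' @export
stitch_fields <- function(field_images, nominal_overlap,
                          blend = c("feather", "max"), refine = FALSE,
                          search_radius = 10) {
  blend <- match.arg(blend)
  n <- length(field_images)
  if (n == 0) stop("no field images")
  d <- dim(field_images[[1]])
  for (t in field_images) {
    if (!identical(dim(t), d)) stop("tiles of unequal size")
  }
  if (!(nominal_overlap >= 0 && nominal_overlap < 1)) {
    stop("overlap must lie in [0, 1)")
  }
  H <- d[1]; L <- d[2]
  step <- L - as.integer(round(nominal_overlap * L))
  offsets <- (seq_len(n) - 1L) * step

  if (refine && n > 1) {
    for (k in 2:n) {
      nominal <- offsets[k - 1] + step
      best <- nominal; best_err <- Inf
      for (cand in (nominal - search_radius):(nominal + search_radius)) {
        ov <- offsets[k - 1] + L - cand   # overlap width at this offset
        if (ov < 4 || ov > L || cand < 0) next
        a <- field_images[[k - 1]][, (L - ov + 1):L, drop = FALSE]
        b <- field_images[[k]][, 1:ov, drop = FALSE]
        err <- mean((a - b)^2)
        if (err < best_err) { best_err <- err; best <- cand }
      }
      offsets[k] <- best
    }
  }

  W <- offsets[n] + L
  acc <- matrix(0, H, W)
  wts <- matrix(0, H, W)
  is_max <- blend == "max"
  if (is_max) acc[] <- -Inf
  for (k in seq_len(n)) {
    cols <- (offsets[k] + 1):(offsets[k] + L)
    tile <- field_images[[k]]
    if (is_max) {
      acc[, cols] <- pmax(acc[, cols], tile)
    } else {
      # linear feather: ramps over the overlap with the previous/next tile,
      # weight 1 elsewhere; opposing ramps sum to 1 so overlaps are a
      # convex blend and exclusive pixels keep their source value exactly
      w <- rep(1, L)
      ov_l <- if (k > 1) max(0L, offsets[k - 1] + L - offsets[k]) else 0L
      ov_r <- if (k < n) max(0L, offsets[k] + L - offsets[k + 1]) else 0L
      if (ov_l > 0) w[seq_len(min(ov_l, L))] <-
          seq_len(min(ov_l, L)) / (min(ov_l, L) + 1)
      if (ov_r > 0) {
        idx <- (L - min(ov_r, L) + 1):L
        w[idx] <- pmin(w[idx], rev(seq_along(idx)) / (length(idx) + 1))
      }
      acc[, cols] <- acc[, cols] + tile * rep(w, each = H)
      wts[, cols] <- wts[, cols] + rep(w, each = H)
    }
  }
  img <- if (is_max) acc else acc / pmax(wts, .Machine$double.eps)
  list(image = img, offsets = as.integer(offsets))
}

#' Collapse and stitch one well
#'
#' Applies the per-channel z-collapse (best-focus slice for brightfield,
#' maximum projection for fluorescence) to each field's stack, then stitches
#' the fields into a single pixel-aligned multi-channel well image, feather-
#' blended for brightfield and max-blended for fluorescence.
#'
#' @param stacks Nested list `stacks[[channel]][[field]][[z]]` of numeric
#'   matrices.
#' @param spec A [plate_spec()].
#' @param refine Logical; refine stitch offsets by registration.
#' @return An object of class `stitched_well`: list with `images` (named
#'   list of matrices, one per channel, identical dimensions), `best_z`
#'   (brightfield chosen z per field) and `offsets`.
#' @export
preprocess_well <- function(stacks, spec, refine = FALSE) {
  stopifnot(inherits(spec, "plate_spec"))
  images <- list()
  best_z <- NULL
  offsets <- NULL
  for (ch in names(spec$channels)) {
    role <- spec$channels[[ch]]
    fs <- stacks[[ch]]
    if (is.null(fs)) stop(sprintf("missing channel '%s' in well stacks", ch))
    collapsed <- vector("list", length(fs))
    if (role$projection == "best_slice") {
      zsel <- integer(length(fs))
      for (f in seq_along(fs)) {
        b <- select_best_slice(fs[[f]])
        collapsed[[f]] <- b$image
        zsel[f] <- b$z_index
      }
      best_z <- zsel
    } else {
      for (f in seq_along(fs)) collapsed[[f]] <- max_project(fs[[f]])
    }
    st <- stitch_fields(collapsed, spec$overlap_fraction,
                        blend = if (role$modality == "brightfield")
                          "feather" else "max",
                        refine = refine && role$modality == "brightfield")
    images[[ch]] <- st$image
    if (role$modality == "brightfield") offsets <- st$offsets
  }
  dims <- lapply(images, dim)
  if (length(unique(dims)) != 1L) {
    # refined brightfield offsets may shift width; crop all to the minimum
    w <- min(vapply(images, ncol, integer(1)))
    images <- lapply(images, function(m) m[, seq_len(w), drop = FALSE])
  }
  structure(list(images = images, best_z = best_z, offsets = offsets),
            class = "stitched_well")
}
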