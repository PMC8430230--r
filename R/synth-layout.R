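# Synthetic embryo geometry. All lengths are fractions of the stitched-well
# canvas (H = tile height, W = stitched width, Lb = body length), so the same
# embryo model renders consistently at any tile resolution.

# half-width of the body silhouette as a fraction of H, along t = u / Lb;
# the tail depth includes the larval fin fold, so the posterior silhouette
# stays deep before tapering at the very tip
body_halfwidth_frac <- function(t) {
  knots_t <- c(0, 0.06, 0.16, 0.30, 0.45, 0.62, 0.80, 0.92, 1)
  knots_h <- c(0.050, 0.105, 0.100, 0.072, 0.058, 0.056, 0.052, 0.035, 0.008)
  stats::approx(knots_t, knots_h, xout = pmin(pmax(t, 0), 1), rule = 2)$y
}

#' Synthetic embryo layout for one well
#'
#' Places an embryo in the stitched-well coordinate frame. The alignment
#' plate used for acquisition physically constrains embryos to lie roughly
#' horizontal with limited angular jitter, which the generator reproduces;
#' the presentation describes how the embryo actually settled:
#' `lateral_left`/`lateral_right` (on-side, one visible eye, analyzable),
#' `dorsal` (on its back, two visible eyes), `partial` (tail outside the
#' imaged strip) and `absent` (empty well).
#'
#' Randomness (vertical offset, angle, focus plane) is drawn from the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param presentation One of `"lateral_left"`, `"lateral_right"`,
#'   `"dorsal"`, `"partial"`, `"absent"`.
#' @param spec A [plate_spec()].
#' @param size_factor Multiplier on body length and width (default 1).
#' @param eye_radius_frac Eye radius as a fraction of tile height; default
#'   0.040 for lateral, 0.034 per eye for dorsal.
#' @param angle_jitter_deg Half-range of the uniform angular jitter, capped
#'   at 10 degrees.
#' @return An object of class `embryo_layout`.
#' @export
embryo_layout <- function(presentation = c("lateral_left", "lateral_right",
                                           "dorsal", "partial", "absent"),
                          spec, size_factor = 1, eye_radius_frac = NULL,
                          angle_jitter_deg = 4) {
  presentation <- match.arg(presentation)
  stopifnot(inherits(spec, "plate_spec"))
  cs <- canvas_shape(spec)
  H <- cs[1]; W <- cs[2]
  angle_jitter_deg <- min(abs(angle_jitter_deg), 10)
  z_focus <- sample.int(spec$z_planes, 1L) - 1L
  if (spec$z_planes >= 3L) z_focus <- sample(seq(1L, spec$z_planes - 2L), 1L)

  if (presentation == "absent") {
    return(structure(list(presentation = presentation, canvas = cs,
                          z_focus = z_focus, body_length = 0,
                          anchor = c(x = 0.5 * W, y = 0.5 * H),
                          theta = 0, headward = 1,
                          n_eyes = 0L), class = "embryo_layout"))
  }

  theta <- runif(1, -angle_jitter_deg, angle_jitter_deg) * pi / 180
  Lb <- 0.80 * W * size_factor
  x0 <- if (presentation == "partial") 0.42 * W else 0.08 * W
  y0 <- 0.5 * H + runif(1, -0.03, 0.03) * H
  headward <- if (presentation == "lateral_right") -1 else 1
  if (presentation == "lateral_right") x0 <- W - 1 - x0

  eyes <- switch(presentation,
    dorsal = {
      r <- if (is.null(eye_radius_frac)) 0.034 else eye_radius_frac
      list(list(u = 0.08 * Lb, v = -0.050 * H, r = r * H * size_factor),
           list(u = 0.08 * Lb, v = 0.050 * H, r = r * H * size_factor))
    },
    {
      r <- if (is.null(eye_radius_frac)) 0.040 else eye_radius_frac
      list(list(u = 0.10 * Lb, v = -0.015 * H, r = r * H * size_factor))
    })

  yolk <- list(centre_u = 0.30 * Lb, centre_v = 0.030 * H,
               a_u = 0.072 * H * size_factor, a_v = 0.050 * H * size_factor,
               tip_u = 0.55 * Lb, tip_v = 0.035 * H,
               ext_hw0 = 0.022 * H, ext_hw1 = 0.010 * H)
  if (presentation == "dorsal") {
    yolk$centre_v <- 0; yolk$tip_v <- 0
  }

  eye_post_u <- max(vapply(eyes, function(e) e$u + e$r, numeric(1)))
  structure(list(
    presentation = presentation, canvas = cs, z_focus = z_focus,
    anchor = c(x = x0, y = y0), theta = theta, headward = headward,
    body_length = Lb, size_factor = size_factor,
    eyes = eyes, yolk = yolk,
    fin_width = 0.018 * H,
    u_head = eye_post_u + 0.05 * Lb,   # head/trunk boundary on the axis
    u_tail = yolk$tip_u,               # trunk/tail boundary (yolk caudal tip)
    n_eyes = length(eyes)
  ), class = "embryo_layout")
}

# axis-frame coordinates (u along body, v perpendicular; +v = ventral/down)
# for every canvas pixel; returns list(U, V) matrices of dim H x W
layout_axis_frame <- function(layout) {
  H <- layout$canvas[1]; W <- layout$canvas[2]
  X <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  Y <- matrix(rep(seq_len(H) - 1, times = W), H, W)
  dx <- layout$headward * cos(layout$theta)
  dy <- sin(layout$theta)
  px <- X - layout$anchor["x"]; py <- Y - layout$anchor["y"]
  list(U = px * dx + py * dy, V = (-px * dy + py * dx) * layout$headward)
}

#' Ground-truth masks and region map for a synthetic layout
#'
#' Rasterizes the layout into the masks the analysis is supposed to recover:
#' body, eye(s), yolk (ball plus caudal extension), tail-fin margin band, the
#' head/trunk/tail region map (0 = outside fish, 1 = head, 2 = trunk,
#' 3 = tail) and the body-axis polyline ordered anterior to posterior.
#'
#' @param layout An [embryo_layout()].
#' @return List with elements `body`, `eye`, `yolk`, `fin` (logical
#'   matrices), `region_map` (integer matrix), `axis` (n x 2 matrix of x, y).
#' @export
layout_masks <- function(layout) {
  H <- layout$canvas[1]; W <- layout$canvas[2]
  empty <- matrix(FALSE, H, W)
  if (layout$presentation == "absent") {
    return(list(body = empty, eye = empty, yolk = empty, fin = empty,
                region_map = matrix(0L, H, W),
                axis = matrix(numeric(0), 0, 2)))
  }
  fr <- layout_axis_frame(layout)
  U <- fr$U; V <- fr$V
  Lb <- layout$body_length
  hw <- matrix(body_halfwidth_frac(as.vector(U) / Lb), H, W) * H *
    layout$size_factor
  body <- U >= 0 & U <= Lb & abs(V) <= hw

  eye <- empty
  for (e in layout$eyes) {
    eye <- eye | ((U - e$u)^2 + (V - e$v)^2 <= e$r^2)
  }
  eye <- eye & body

  yk <- layout$yolk
  ball <- ((U - yk$centre_u) / yk$a_u)^2 + ((V - yk$centre_v) / yk$a_v)^2 <= 1
  tt <- (U - yk$centre_u) / (yk$tip_u - yk$centre_u)
  ext_hw <- yk$ext_hw0 + (yk$ext_hw1 - yk$ext_hw0) * pmin(pmax(tt, 0), 1)
  vline <- yk$centre_v + (yk$tip_v - yk$centre_v) * pmin(pmax(tt, 0), 1)
  ext <- tt >= 0 & tt <= 1 & abs(V - vline) <= ext_hw
  yolk <- (ball | ext) & body & !eye

  fin_t <- U / Lb
  fin <- U >= 0.50 * Lb & U <= Lb & abs(V) > hw &
    abs(V) <= hw + layout$fin_width
  cap <- U > Lb & sqrt((U - Lb)^2 + V^2) <= 2 * layout$fin_width
  fin <- (fin | cap) & U >= 0 & abs(V) <= 0.25 * H

  region_map <- matrix(0L, H, W)
  region_map[body] <- 2L
  region_map[body & U < layout$u_head] <- 1L
  region_map[body & U >= layout$u_tail] <- 3L

  us <- seq(0, Lb, by = max(2, Lb / 400))
  dxv <- layout$headward * cos(layout$theta); dyv <- sin(layout$theta)
  axis <- cbind(x = layout$anchor["x"] + us * dxv,
                y = layout$anchor["y"] + us * dyv)
  keep <- axis[, 1] >= 0 & axis[, 1] <= W - 1
  list(body = body, eye = eye, yolk = yolk, fin = fin,
       region_map = region_map, axis = axis[keep, , drop = FALSE])
}

# true region label of a point given in axis coordinates
layout_region_of_u <- function(layout, u, inside_body) {
  out <- rep("outside_fish", length(u))
  out[inside_body & u < layout$u_head] <- "head"
  out[inside_body & u >= layout$u_head & u < layout$u_tail] <- "trunk"
  out[inside_body & u >= layout$u_tail] <- "tail"
  out
}
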