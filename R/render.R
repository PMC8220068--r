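#' Rendering specification for impoverished two-agent stimuli
#'
#' Display conventions: agent 1 is a filled circle (default blue),
#' agent 2 a filled rectangle (default red) oriented along its heading,
#' on a plain background. Shape size defaults to 2.5% of canvas width.
#'
#' @param canvas pixel dimensions `c(width, height)`.
#' @param frame_rate frames per second, `> 0`.
#' @param background background colour (any R colour spec).
#' @param agent1_color circle fill colour.
#' @param agent2_color rectangle fill colour.
#' @param agent_size shape size as a fraction of canvas width (circle
#'   diameter and rectangle length).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(canvas = c(320, 320), frame_rate = 25,
                        background = "white", agent1_color = "blue",
                        agent2_color = "red", agent_size = 0.025) {
  if (length(canvas) != 2L || any(canvas < 1) || any(!is.finite(canvas)))
    stop("canvas must be positive c(width, height)")
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0")
  if (!is.finite(agent_size) || agent_size <= 0 || agent_size > 0.5)
    stop("agent_size must be in (0, 0.5]")
  structure(list(canvas = as.integer(canvas), frame_rate = frame_rate,
                 background = background, agent1_color = agent1_color,
                 agent2_color = agent2_color, agent_size = agent_size),
            class = "render_spec")
}

#' Affine arena-to-pixel transform
#'
#' Uniform scale (aspect-ratio preserving), centred, y-axis flipped to
#' screen convention, with a margin of one shape size so agents at the
#' arena edge stay fully on canvas. The transform is
#' `px = offset_x + scale * (x - xmin)`,
#' `py = offset_y - scale * (y - ymin)`; it is recorded in the render
#' sidecar so a render is exactly reproducible and invertible.
#'
#' @param arena `c(xmin, xmax, ymin, ymax)`.
#' @param spec a [render_spec()].
#' @return A list with `scale`, `offset_x`, `offset_y`, `arena`,
#'   `canvas`.
#' @export
arena_transform <- function(arena, spec) {
  w <- spec$canvas[1]; h <- spec$canvas[2]
  m <- ceiling(spec$agent_size * w) + 1
  aw <- arena[2] - arena[1]; ah <- arena[4] - arena[3]
  scale <- min((w - 1 - 2 * m) / aw, (h - 1 - 2 * m) / ah)
  if (!is.finite(scale) || scale <= 0)
    stop("canvas ", w, "x", h, " too small to contain the arena mapping")
  off_x <- 1 + m + ((w - 1 - 2 * m) - scale * aw) / 2
  off_y <- h - m - ((h - 1 - 2 * m) - scale * ah) / 2
  list(scale = scale, offset_x = off_x, offset_y = off_y,
       arena = as.numeric(arena), canvas = c(w, h))
}

# Interpolate the pair onto the frame-time grid. Headings are unwrapped
# before linear interpolation so the rectangle does not spin through
# the +/- pi seam, then re-wrapped.
.frame_states <- function(pair, times) {
  interp <- function(df) {
    phi_unwrapped <- df$phi[1] + c(0, cumsum(wrap_angle(diff(df$phi))))
    data.frame(
      x = stats::approx(pair$t, df$x, times)$y,
      y = stats::approx(pair$t, df$y, times)$y,
      phi = wrap_angle(stats::approx(pair$t, phi_unwrapped, times)$y))
  }
  list(agent1 = interp(pair$agent1), agent2 = interp(pair$agent2))
}

#' Rasterize one stimulus frame
#'
#' Pure function of the pair, a time point and the render spec; used by
#' [render_frames()] and directly useful for inspection in tests.
#'
#' @param pair a `trajectory_pair`.
#' @param time time point within the trajectory.
#' @param spec a [render_spec()].
#' @return A `height x width x 3` numeric array in `[0, 1]`.
#' @export
render_frame <- function(pair, time, spec = render_spec()) {
  st <- .frame_states(pair, time)
  .rasterize(st$agent1[1, ], st$agent2[1, ],
             arena_transform(pair$arena, spec), spec)
}

.col01 <- function(col) as.numeric(grDevices::col2rgb(col)) / 255

.rasterize <- function(a1, a2, tr, spec) {
  w <- spec$canvas[1]; h <- spec$canvas[2]
  bg <- .col01(spec$background)
  img <- array(rep(bg, each = h * w), dim = c(h, w, 3))
  jj <- matrix(seq_len(w), h, w, byrow = TRUE)   # pixel x
  ii <- matrix(seq_len(h), h, w)                 # pixel y (screen-down)

  paint <- function(img, mask, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }

  # agent 1: circle, diameter agent_size * width
  p1 <- c(tr$offset_x + tr$scale * (a1$x - tr$arena[1]),
          tr$offset_y - tr$scale * (a1$y - tr$arena[3]))
  r <- spec$agent_size * w / 2
  img <- paint(img, (jj - p1[1])^2 + (ii - p1[2])^2 <= r^2,
               .col01(spec$agent1_color))

  # agent 2: rectangle, length agent_size * width along heading,
  # aspect 0.6; heading y-component flips sign in screen coordinates
  p2 <- c(tr$offset_x + tr$scale * (a2$x - tr$arena[1]),
          tr$offset_y - tr$scale * (a2$y - tr$arena[3]))
  hl <- spec$agent_size * w / 2
  hw <- 0.6 * hl
  dxp <- jj - p2[1]; dyp <- ii - p2[2]
  u <- dxp * cos(a2$phi) - dyp * sin(a2$phi)
  v <- dxp * sin(a2$phi) + dyp * cos(a2$phi)
  paint(img, abs(u) <= hl & abs(v) <= hw, .col01(spec$agent2_color))
}

#' Render a trajectory pair to PNG frames
#'
#' Resamples the trajectory from its integration grid to the frame-rate
#' grid by linear interpolation (frame `k` shows time `(k-1)/fps`) and
#' writes one PNG per frame plus a `render.meta.json` sidecar recording
#' the arena-to-pixel transform and render settings. Rendering is a pure
#' function of `(pair, spec)`: identical inputs give byte-identical
#' frames.
#'
#' @param pair a `trajectory_pair`.
#' @param spec a [render_spec()].
#' @param out_dir output directory (created if needed).
#' @return Character vector of frame file paths, invisibly.
#' @export
render_frames <- function(pair, spec = render_spec(), out_dir) {
  if (!inherits(pair, "trajectory_pair")) stop("pair must be a trajectory_pair")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  duration <- max(pair$t)
  n_frames <- max(1L, as.integer(floor(duration * spec$frame_rate + 1e-9)))
  times <- (seq_len(n_frames) - 1) / spec$frame_rate
  tr <- arena_transform(pair$arena, spec)
  st <- .frame_states(pair, times)
  paths <- file.path(out_dir, sprintf("frame_%04d.png", seq_len(n_frames)))
  for (k in seq_len(n_frames)) {
    img <- .rasterize(st$agent1[k, ], st$agent2[k, ], tr, spec)
    png::writePNG(img, paths[k])
  }
  meta <- list(class_name = pair$class_name, seed = pair$seed,
               frame_rate = spec$frame_rate, n_frames = n_frames,
               canvas = spec$canvas, agent_size = spec$agent_size,
               transform = tr[c("scale", "offset_x", "offset_y")],
               arena = pair$arena)
  jsonlite::write_json(meta, file.path(out_dir, "render.meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
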