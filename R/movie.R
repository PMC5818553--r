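#' Frame stack container
#'
#' A time-ordered stack of grayscale frames with a frame rate and channel
#' tag; the unit of imaging I/O. Stored as a numeric array
#' \code{[rows, cols, frames]}. Frame timestamps are exposure midpoints:
#' \code{(i - 0.5) / frame_rate}.
#'
#' @param data Numeric array \code{[rows, cols, frames]} (a matrix is
#'   treated as a single frame).
#' @param frame_rate Frames per second.
#' @param channel Channel tag, e.g. "green" or "red".
#' @return An object of class \code{frame_stack}.
#' @export
frame_stack <- function(data, frame_rate = 25, channel = "green") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L, frame_rate > 0)
  structure(list(data = data, frame_rate = frame_rate, channel = channel),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Frame stack: %d x %d px, %d frames @ %g Hz (%s channel)\n",
              d[1], d[2], d[3], x$frame_rate, x$channel))
  invisible(x)
}

#' Frame midpoint times of a stack
#' @param stack A \code{frame_stack}.
#' @return Numeric vector of exposure-midpoint times, s.
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$data)[3]) - 0.5) / stack$frame_rate
}

# Footprint of one bouton: 0-based pixel coords, matrix indices and the
# radial taper weight w = 1 - (r/R)^2 on r <= R.
.bouton_footprint <- function(x, y, radius, frame_shape) {
  xs <- seq(max(0, floor(x - radius)), min(frame_shape[2] - 1, ceiling(x + radius)))
  ys <- seq(max(0, floor(y - radius)), min(frame_shape[1] - 1, ceiling(y + radius)))
  g <- expand.grid(px = xs, py = ys)
  r2 <- (g$px - x)^2 + (g$py - y)^2
  keep <- r2 <= radius^2
  g <- g[keep, , drop = FALSE]
  w <- 1 - r2[keep] / radius^2
  # row-major 0-based (px, py) -> R matrix index (row = py + 1, col = px + 1)
  idx <- (g$px) * frame_shape[1] + g$py + 1L
  list(idx = as.integer(idx), weight = w, px = g$px, py = g$py)
}

#' Bouton footprints of an imaging model
#'
#' @param imaging An [imaging_model()] with \code{bouton_specs}.
#' @return List (one per bouton) of lists with linear matrix indices
#'   \code{idx}, taper weights \code{weight} and 0-based pixel coordinates.
#'   Overlapping footprints trigger a warning (they bias extraction).
#' @export
bouton_footprints <- function(imaging) {
  stopifnot(inherits(imaging, "imaging_model"),
            !is.null(imaging$bouton_specs))
  bs <- imaging$bouton_specs
  fps <- lapply(seq_len(nrow(bs)), function(i)
    .bouton_footprint(bs$x[i], bs$y[i], bs$radius[i], imaging$frame_shape))
  all_idx <- unlist(lapply(fps, `[[`, "idx"))
  if (anyDuplicated(all_idx))
    warning("overlapping bouton footprints; extracted traces will mix signals")
  fps
}

#' Render a synthetic fluorescence movie
#'
#' Each bouton is drawn as a radially tapered disk of brightness
#' \code{f0 * (1 + dF/F(t)) * w(r)} on top of a uniform background, with
#' additive Gaussian read noise. Deterministic for a given
#' \code{rng_seed}; with \code{noise_sigma = 0} rendering is exact.
#'
#' @param dff_traces Numeric matrix \code{[frames, boutons]} of dF/F (a
#'   vector is accepted for a single bouton).
#' @param imaging An [imaging_model()]; \code{nrow(bouton_specs)} must match
#'   the number of trace columns.
#' @param channel Channel tag for the output stack.
#' @return A [frame_stack()].
#' @export
render_movie <- function(dff_traces, imaging, channel = "green") {
  if (is.vector(dff_traces)) dff_traces <- matrix(dff_traces, ncol = 1L)
  bs <- imaging$bouton_specs
  stopifnot(!is.null(bs), ncol(dff_traces) == nrow(bs))
  fps <- bouton_footprints(imaging)
  nf <- nrow(dff_traces)
  sh <- imaging$frame_shape
  arr <- array(imaging$background_level, dim = c(sh[1], sh[2], nf))
  base <- matrix(imaging$background_level, sh[1], sh[2])
  for (t in seq_len(nf)) {
    fr <- base
    for (b in seq_len(nrow(bs))) {
      fp <- fps[[b]]
      fr[fp$idx] <- fr[fp$idx] + bs$f0[b] * (1 + dff_traces[t, b]) * fp$weight
    }
    arr[, , t] <- fr
  }
  if (imaging$noise_sigma > 0) {
    old <- .Random.seed_save()
    set.seed(imaging$rng_seed)
    arr <- arr + array(stats::rnorm(length(arr), 0, imaging$noise_sigma),
                       dim = dim(arr))
    .Random.seed_restore(old)
  }
  frame_stack(arr, imaging$frame_rate, channel)
}

# save/restore the global RNG state so seeded rendering does not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Render a two-channel colocalization pair
#'
#' Green channel: all boutons at resting brightness. Red channel:
#' punctate mitochondrial staining placed only inside boutons flagged
#' occupied. Returns both single-frame stacks and the ground-truth
#' occupancy table.
#'
#' @param imaging An [imaging_model()] with \code{bouton_specs}.
#' @param occupied Logical vector, one flag per bouton.
#' @param n_puncta Integer punctum count per occupied bouton (recycled).
#' @param punctum_radius Punctum radius, px; must not exceed the host
#'   bouton radius.
#' @param punctum_intensity Red-channel punctum brightness.
#' @param seed Integer seed for punctum placement and noise.
#' @return List with \code{green}, \code{red} (frame stacks) and
#'   \code{truth} (data frame: bouton, occupied, n_puncta).
#' @export
render_coloc_pair <- function(imaging, occupied, n_puncta = 1L,
                              punctum_radius = 1.5, punctum_intensity = 150,
                              seed = 1L) {
  bs <- imaging$bouton_specs
  stopifnot(!is.null(bs), length(occupied) == nrow(bs))
  if (any(punctum_radius > bs$radius))
    stop("punctum larger than its host bouton")
  n_puncta <- rep_len(as.integer(n_puncta), nrow(bs))
  sh <- imaging$frame_shape

  quiet <- imaging
  quiet$noise_sigma <- 0
  green <- render_movie(matrix(0, 1, nrow(bs)), quiet, channel = "green")

  old <- .Random.seed_save()
  set.seed(seed)
  red <- matrix(imaging$background_level, sh[1], sh[2])
  for (b in which(occupied)) {
    for (p in seq_len(n_puncta[b])) {
      # place punctum fully inside the host bouton
      rmax <- bs$radius[b] - punctum_radius
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * max(rmax, 0)
      fp <- .bouton_footprint(bs$x[b] + rad * cos(ang),
                              bs$y[b] + rad * sin(ang),
                              punctum_radius, sh)
      red[fp$idx] <- red[fp$idx] + punctum_intensity * fp$weight
    }
  }
  if (imaging$noise_sigma > 0) {
    red <- red + matrix(stats::rnorm(length(red), 0, imaging$noise_sigma),
                        sh[1], sh[2])
    g <- green$data[, , 1] +
      matrix(stats::rnorm(prod(sh), 0, imaging$noise_sigma), sh[1], sh[2])
    green <- frame_stack(g, imaging$frame_rate, "green")
  }
  .Random.seed_restore(old)

  list(green = green,
       red = frame_stack(red, imaging$frame_rate, "red"),
       truth = data.frame(bouton = seq_len(nrow(bs)),
                          occupied = occupied,
                          n_puncta = ifelse(occupied, n_puncta, 0L)))
}
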