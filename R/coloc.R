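#' Threshold a single-channel image
#'
#' Binarizes one channel so as to remove background and outline boutons
#' (green) or strongly stained mitochondria (red). Methods: Otsu's rule
#' (default; delegated to EBImage), an intensity percentile, or an absolute
#' cutoff. Each channel is thresholded independently of the other.
#'
#' @param image Numeric matrix, or a [frame_stack()] (averaged over frames).
#' @param method "otsu", "percentile" or "absolute".
#' @param value Percentile in [0, 1] for \code{method = "percentile"};
#'   absolute cutoff for \code{method = "absolute"}.
#' @return List with \code{mask} (logical matrix, pixels strictly above the
#'   cutoff), \code{threshold}, \code{method}. An empty foreground yields a
#'   warning, not an error.
#' @export
threshold_channel <- function(image, method = c("otsu", "percentile",
                                                "absolute"), value = NULL) {
  method <- match.arg(method)
  if (inherits(image, "frame_stack"))
    image <- apply(image$data, c(1, 2), mean)
  stopifnot(is.matrix(image))
  thr <- switch(method,
    otsu = {
      rng <- range(image)
      if (diff(rng) == 0) rng[2]  # flat image: empty mask
      else EBImage::otsu(image, range = rng, levels = 256L)
    },
    percentile = {
      stopifnot(!is.null(value), value >= 0, value <= 1)
      stats::quantile(image, value, names = FALSE)
    },
    absolute = {
      stopifnot(!is.null(value))
      value
    })
  mask <- image > thr
  if (!any(mask)) warning("empty foreground after thresholding")
  list(mask = mask, threshold = thr, method = method)
}

#' Per-bouton mitochondrial occupancy
#'
#' Labels the green-channel bouton mask into connected components and calls
#' a bouton occupied iff at least \code{min_overlap_px} mitochondrial
#' pixels fall inside it. The fraction of occupied boutons is the summary
#' statistic; per-NMJ grouping is supported through \code{nmj_of_bouton}.
#'
#' @param bouton_mask Logical matrix (green channel).
#' @param mito_mask Logical matrix (red channel), same shape.
#' @param min_overlap_px Minimum mito pixels inside a bouton to count it
#'   occupied (default 2, rejecting single-pixel noise).
#' @param min_bouton_px Connected components smaller than this are dropped
#'   from the bouton mask before counting (noise specks, default 5).
#' @param nmj_of_bouton Optional integer vector mapping bouton label to an
#'   NMJ id (labels are EBImage connected components, row-major order).
#' @return Object of class \code{coloc_result}: list with
#'   \code{per_bouton} (data frame: label, n_pixels, mito_px, occupied,
#'   nmj), \code{fraction_occupied} (NA when no boutons),
#'   \code{n_boutons}, \code{min_overlap_px}.
#' @export
occupancy <- function(bouton_mask, mito_mask, min_overlap_px = 2L,
                      min_bouton_px = 5L, nmj_of_bouton = NULL) {
  stopifnot(is.matrix(bouton_mask), all(dim(bouton_mask) == dim(mito_mask)))
  labels <- EBImage::bwlabel(bouton_mask * 1L)
  sizes <- tabulate(as.integer(labels), nbins = max(labels))
  if (any(sizes < min_bouton_px)) {
    keep <- which(sizes >= min_bouton_px)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    labels <- matrix(c(0L, relab)[as.integer(labels) + 1L],
                     nrow(labels), ncol(labels))
  }
  nb <- max(labels)
  if (nb == 0)
    return(structure(list(per_bouton = data.frame(), n_boutons = 0L,
                          fraction_occupied = NA_real_,
                          min_overlap_px = min_overlap_px),
                     class = "coloc_result"))
  lab_v <- as.integer(labels)
  n_pix <- tabulate(lab_v, nbins = nb)
  mito_px <- tabulate(lab_v[as.logical(mito_mask)], nbins = nb)
  occ <- mito_px >= min_overlap_px
  per <- data.frame(label = seq_len(nb), n_pixels = n_pix,
                    mito_px = mito_px, occupied = occ)
  per$nmj <- if (is.null(nmj_of_bouton)) 1L else nmj_of_bouton[per$label]
  structure(list(per_bouton = per, n_boutons = nb,
                 fraction_occupied = mean(occ),
                 min_overlap_px = min_overlap_px),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  if (x$n_boutons == 0) {
    cat("Colocalization: no boutons found (fraction undefined)\n")
  } else {
    cat(sprintf("Colocalization: %d/%d boutons occupied (%.1f%%), min overlap %d px\n",
                sum(x$per_bouton$occupied), x$n_boutons,
                100 * x$fraction_occupied, x$min_overlap_px))
  }
  invisible(x)
}

#' Two-channel colocalization analysis
#'
#' Thresholds the green (bouton) and red (mitochondria) channels separately
#' and computes per-bouton occupancy. An optional integer-pixel shift
#' search aligns the red mask to the green mask by maximizing overlap
#' (identity shift by default).
#'
#' @param green,red Numeric matrices or [frame_stack()]s.
#' @param method Threshold method per [threshold_channel()]; a single
#'   method for both channels or a list with elements \code{green} and
#'   \code{red}.
#' @param min_overlap_px,min_bouton_px See [occupancy()].
#' @param max_shift Integer: search radius (px) for mask alignment; 0
#'   disables registration.
#' @param value Threshold parameter(s); a list with elements \code{green}
#'   and \code{red}, or a single value used for both.
#' @return A \code{coloc_result} with \code{thresholds} and \code{shift}
#'   recorded.
#' @export
coloc_analysis <- function(green, red, method = "otsu",
                           min_overlap_px = 2L, min_bouton_px = 5L,
                           max_shift = 0L, value = NULL) {
  vg <- if (is.list(value)) value$green else value
  vr <- if (is.list(value)) value$red else value
  mg <- if (is.list(method)) method$green else method
  mr <- if (is.list(method)) method$red else method
  tg <- threshold_channel(green, mg, vg)
  tr <- threshold_channel(red, mr, vr)
  shift <- c(0L, 0L)
  mito <- tr$mask
  if (max_shift > 0) {
    best <- -1
    for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
      shifted <- .shift_mask(tr$mask, dy, dx)
      ov <- sum(shifted & tg$mask)
      if (ov > best) { best <- ov; shift <- c(dy, dx); mito <- shifted }
    }
  }
  res <- occupancy(tg$mask, mito, min_overlap_px, min_bouton_px)
  res$thresholds <- list(green = tg$threshold, red = tr$threshold,
                         method = list(green = mg, red = mr))
  res$shift <- shift
  res
}

.shift_mask <- function(m, dy, dx) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
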