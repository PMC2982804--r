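#' Measure adhesive line-pattern width by horizontal scanning
#'
#' Scans the binary pattern mask row by row (each row is one horizontal
#' scanning line crossing the vertical stripe), takes the pattern pixel
#' count per row times the pixel size, and averages over all rows that
#' intersect the pattern.
#'
#' @param line_mask logical/0-1 matrix of the pattern.
#' @param pixel_size um per pixel.
#' @return width in um.
#' @export
measure_pattern_width <- function(line_mask, pixel_size = 1) {
  m <- line_mask > 0
  counts <- rowSums(m)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty pattern mask", call. = FALSE)
  mean(counts) * pixel_size
}

#' Measure cell length from a binary cell mask
#'
#' Patterned mode fits the cell's extent along the line axis (the length of
#' the bounding rectangle side parallel to the patterned line); non-
#' patterned mode returns the Feret diameter, the greatest distance between
#' any two boundary points, computed over the convex hull of the mask
#' pixels. Cells whose nucleus mask does not contain exactly one connected
#' component are rejected (only mononucleate cells are measured).
#'
#' @param cell_mask logical/0-1 matrix.
#' @param nucleus_mask logical/0-1 matrix of the same shape, or NULL to
#'   skip the mononucleate filter.
#' @param mode "patterned" or "nonpatterned".
#' @param pixel_size um per pixel.
#' @return list with \code{length_um} (NA when rejected), \code{rejected},
#'   \code{reason}.
#' @export
measure_cell_length <- function(cell_mask, nucleus_mask = NULL,
                                mode = c("patterned", "nonpatterned"),
                                pixel_size = 1) {
  mode <- match.arg(mode)
  m <- cell_mask > 0
  if (!any(m)) stop("empty cell mask", call. = FALSE)
  if (!is.null(nucleus_mask)) {
    if (!all(dim(nucleus_mask) == dim(cell_mask))) {
      stop("masks must share the same shape", call. = FALSE)
    }
    ncomp <- max(EBImage::bwlabel(nucleus_mask > 0))
    if (ncomp != 1L) {
      return(list(length_um = NA_real_, rejected = TRUE,
                  reason = sprintf(
                    "not mononucleate: %d nucleus components", ncomp)))
    }
  }
  len <- if (mode == "patterned") {
    rows <- which(rowSums(m) > 0)
    (max(rows) - min(rows) + 1) * pixel_size
  } else {
    idx <- which(m, arr.ind = TRUE)
    hull <- grDevices::chull(idx[, 2], idx[, 1])
    pts <- idx[hull, , drop = FALSE]
    max(stats::dist(pts)) * pixel_size
  }
  list(length_um = len, rejected = FALSE, reason = NA_character_)
}

# shift a matrix by (dy, dx), zero-filling exposed cells
shift_matrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  ys <- max(1, 1 - dy):min(nr, nr - dy)
  xs <- max(1, 1 - dx):min(nc, nc - dx)
  if (!length(ys) || !length(xs)) return(out)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

# bilinearly sample a matrix at offsets (dy, dx) from every pixel
sample_shifted <- function(m, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  (1 - fy) * (1 - fx) * shift_matrix(m, y0, x0) +
    fy * (1 - fx) * shift_matrix(m, y0 + 1L, x0) +
    (1 - fy) * fx * shift_matrix(m, y0, x0 + 1L) +
    fy * fx * shift_matrix(m, y0 + 1L, x0 + 1L)
}

#' Angular distribution of linear filament polymer
#'
#' The measurement pipeline of the polarisation analysis: median filter,
#' threshold (Otsu by default), then score each polymer pixel against
#' straight-line kernels oriented at every angular bin (subpixel bilinear
#' sampling) and assign it to the best-matching orientation, ties resolving
#' towards the axis; bin masses are polymer pixel counts normalised by the
#' total amount of linear polymer. Only pixels on a straight stretch (best
#' kernel coverage at least \code{min_coverage} of the kernel length)
#' count as linear polymer; blob ends below that coverage are excluded,
#' mirroring the normalisation by linear (not total) polymer. Angles are measured from the (vertical)
#' line axis; -90 and 90 denote the same orientation and share the
#' 90-degree bin.
#'
#' @param channel grayscale filament channel (matrix).
#' @param cell_mask logical matrix of the same shape.
#' @param bin_width angular bin width, degrees (default 5).
#' @param kernel_length oriented line-kernel length, px (odd; default 13).
#' @param median_size median-filter half-window, px (default 1, i.e. 3x3).
#' @param threshold "otsu" or a numeric grey-level threshold.
#' @param min_coverage minimum fraction of the kernel that must overlap
#'   polymer for a pixel to count as linear polymer (default 0.85).
#' @param tie_tol score margin (kernel samples) within which bins count
#'   as tied with the per-pixel maximum, the most axial tied bin winning
#'   (default 0.25).
#' @return An object of class \code{orientation_distribution}:
#'   \code{bin_centres} (degrees), \code{mass} (sums to 1), \code{n_pixels},
#'   \code{threshold}, \code{empty} flag (TRUE when no polymer detected).
#' @export
orientation_distribution <- function(channel, cell_mask, bin_width = 5,
                                     kernel_length = 13,
                                     median_size = 1,
                                     threshold = "otsu",
                                     min_coverage = 0.85,
                                     tie_tol = 0.25) {
  stopifnot(all(dim(channel) == dim(cell_mask)))
  ch <- channel
  lo <- min(ch); hi <- max(ch)
  if (hi > lo) ch <- (ch - lo) / (hi - lo) else ch <- ch * 0
  ch <- EBImage::medianFilter(ch, median_size)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(ch), range = c(0, 1))
  } else {
    (threshold - lo) / max(hi - lo, .Machine$double.eps)
  }
  polymer <- (ch > thr) & (cell_mask > 0)
  centres <- seq(-90 + bin_width, 90, by = bin_width)
  if (!any(polymer)) {
    return(structure(list(bin_centres = centres,
                          mass = rep(0, length(centres)),
                          n_pixels = 0L,
                          threshold = thr * (hi - lo) + lo,
                          empty = TRUE),
                     class = "orientation_distribution"))
  }
  pm <- polymer * 1
  half <- (kernel_length - 1) / 2
  scores <- array(0, c(nrow(pm), ncol(pm), length(centres)))
  for (b in seq_along(centres)) {
    th <- centres[b] * pi / 180
    acc <- matrix(0, nrow(pm), ncol(pm))
    for (t in seq(-half, half)) {
      # subpixel kernel positions, sampled bilinearly: keeps nearby angles
      # distinguishable and avoids integer-rounding ties
      acc <- acc + sample_shifted(pm, t * cos(th), t * sin(th))
    }
    scores[, , b] <- acc
  }
  # per-pixel best orientation: thick strokes give a plateau of near-
  # maximal bins, so bins within tie_tol of the per-pixel maximum count
  # as tied and the most axial tied bin wins (then lower bin index)
  idx <- which(polymer)
  sc_mat <- matrix(0, length(idx), length(centres))
  for (b in seq_along(centres)) sc_mat[, b] <- scores[, , b][idx]
  best_score <- do.call(pmax, as.data.frame(sc_mat))
  ord <- order(abs(centres), seq_along(centres))
  best <- rep(NA_integer_, length(idx))
  for (b in ord) {
    upd <- is.na(best) & sc_mat[, b] >= best_score - tie_tol
    best[upd] <- b
  }
  linear <- best_score >= min_coverage * kernel_length
  if (!any(linear)) {
    return(structure(list(bin_centres = centres,
                          mass = rep(0, length(centres)),
                          n_pixels = 0L,
                          threshold = thr * (hi - lo) + lo,
                          empty = TRUE),
                     class = "orientation_distribution"))
  }
  counts <- tabulate(best[linear], nbins = length(centres))
  structure(list(bin_centres = centres, mass = counts / sum(counts),
                 n_pixels = sum(linear),
                 threshold = thr * (hi - lo) + lo,
                 empty = FALSE),
            class = "orientation_distribution")
}

#' @export
print.orientation_distribution <- function(x, ...) {
  if (x$empty) {
    cat("Orientation distribution: no polymer above threshold\n")
    return(invisible(x))
  }
  peak <- x$bin_centres[which.max(x$mass)]
  cat(sprintf(
    "Orientation distribution over %d px of polymer: modal bin %g deg (mass %.2f)\n",
    x$n_pixels, peak, max(x$mass)))
  invisible(x)
}

#' @export
plot.orientation_distribution <- function(x, ...) {
  plot(x$bin_centres, x$mass, type = "h", xlab = "angle to line axis (deg)",
       ylab = "probability mass", ...)
  invisible(x)
}

#' Axial circular variance of an angular sample or distribution
#'
#' Computed on doubled angles (orientation data): 1 - |E exp(2 i theta)|;
#' 0 for a point mass, 1 for a uniform orientation distribution.
#'
#' @param angles_deg angles in degrees, or bin centres when \code{mass}
#'   given.
#' @param mass optional probability masses matching \code{angles_deg}.
#' @return circular variance in [0, 1].
#' @export
circular_variance_axial <- function(angles_deg, mass = NULL) {
  phi <- 2 * angles_deg * pi / 180
  if (is.null(mass)) mass <- rep(1 / length(phi), length(phi))
  1 - Mod(sum(mass * exp(1i * phi)))
}

#' Classify cortical contact fates from track geometry
#'
#' Measures each contact angle from the track's direction of motion just
#' before cortical contact, optionally corrupts it with Gaussian
#' measurement noise, applies the fate rule deterministically, and compares
#' against the ground-truth fates carried by the track set. Events whose
#' measured angle falls in the ambiguous band are recorded as such and not
#' counted against agreement (either outcome is acceptable there).
#'
#' @param tracks a \code{\link{simulate_comet_tracks}} object.
#' @param rule an \code{\link{mt_fate_rule}}.
#' @param angle_noise_sd measurement noise on the contact angle, degrees.
#' @return list: \code{events} data.frame (measured_angle_deg, predicted,
#'   truth, ambiguous), \code{agreement} fraction over non-ambiguous
#'   events, \code{n_ambiguous}, \code{n_skipped}.
#' @export
classify_contact_fates <- function(tracks, rule, angle_noise_sd = 0) {
  stopifnot(inherits(tracks, "comet_track_set"),
            inherits(rule, "mt_fate_rule"))
  ev <- tracks$events
  measured <- rep(NA_real_, nrow(ev))
  skipped <- 0L
  for (k in seq_len(nrow(ev))) {
    tr <- tracks$tracks[[k]]
    # contact sample: the recorded contact position; direction taken from
    # the preceding track sample
    ic <- which(abs(tr$x_um - ev$x_um[k]) < 1e-9 &
                  abs(tr$y_um - ev$y_um[k]) < 1e-9)[1]
    if (is.na(ic) || ic < 2) { skipped <- skipped + 1L; next }
    dx <- tr$x_um[ic] - tr$x_um[ic - 1]
    dy <- tr$y_um[ic] - tr$y_um[ic - 1]
    measured[k] <- atan2(dx, dy) * 180 / pi
  }
  if (angle_noise_sd > 0) {
    measured <- measured + stats::rnorm(length(measured), 0, angle_noise_sd)
    measured <- pmax(-90, pmin(90, measured))
  }
  predicted <- apply_fate_rule(rule, measured)
  ok <- !is.na(measured)
  ambiguous <- ok & predicted == "ambiguous"
  det <- ok & !ambiguous
  agreement <- if (any(det)) {
    mean(predicted[det] == ev$fate[det])
  } else NA_real_
  list(events = data.frame(track = ev$track,
                           measured_angle_deg = measured,
                           predicted = predicted,
                           truth = ev$fate,
                           ambiguous = ambiguous),
       agreement = agreement,
       n_ambiguous = sum(ambiguous),
       n_skipped = skipped)
}

#' Intensity-based microtubule count in a region
#'
#' Converts background-subtracted integrated fluorescence in a region into
#' a filament count by normalising with the single-filament calibration
#' unit: count = integrated intensity / (unit intensity per pixel of length
#' x mean filament length in the region, px).
#'
#' @param channel grayscale channel (matrix, grey levels).
#' @param region_mask logical matrix of the same shape.
#' @param single_filament_intensity calibration: grey levels deposited per
#'   pixel of length by one filament.
#' @param mean_filament_length_px mean filament length in the region, px
#'   (from the rendering calibration or ground truth).
#' @param background background grey level; NULL estimates it as the median
#'   intensity outside the region.
#' @return list with \code{count} (nearest integer) and \code{raw} ratio.
#' @export
estimate_mt_count <- function(channel, region_mask,
                              single_filament_intensity,
                              mean_filament_length_px,
                              background = NULL) {
  stopifnot(single_filament_intensity > 0, mean_filament_length_px > 0)
  if (!all(dim(channel) == dim(region_mask))) {
    stop("region mask does not match the image shape", call. = FALSE)
  }
  m <- region_mask > 0
  if (is.null(background)) {
    background <- if (all(m)) 0 else stats::median(channel[!m])
  }
  integrated <- sum(channel[m] - background)
  raw <- integrated / (single_filament_intensity * mean_filament_length_px)
  raw <- max(raw, 0)
  list(count = as.integer(round(raw)), raw = raw)
}

#' Lateral edge-band mask of a cell
#'
#' The band adjacent to each lateral cell edge spanning the given fraction
#' of the cell width, mirroring the edge regions in which leading
#' microtubules are counted.
#'
#' @param cell_mask logical matrix.
#' @param fraction band width as a fraction of cell width (default 0.3).
#' @return logical matrix.
#' @export
edge_band_mask <- function(cell_mask, fraction = 0.3) {
  m <- cell_mask > 0
  cols <- which(colSums(m) > 0)
  w <- max(cols) - min(cols) + 1
  band <- ceiling(fraction * w)
  keep <- cols[cols < min(cols) + band | cols > max(cols) - band]
  out <- matrix(FALSE, nrow(m), ncol(m))
  out[, keep] <- TRUE
  out & m
}
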