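# Raster convention: plain R matrices, origin top-left, row-major; row index
# is the coordinate along the patterned line (the "vertical" line axis),
# column index is the lateral coordinate. Pixel centres sit at integer
# (row, col) coordinates. Filament angles are measured from the line axis,
# signed, in degrees within [-90, 90].

#' Sample filament/comet angles from a named angular model
#'
#' Supported models: \code{list(name = "point", angle = )} (point mass),
#' \code{list(name = "uniform", min = , max = )}, and
#' \code{list(name = "vonmises", mu = , kappa = )}. The von Mises model is
#' axial: the doubled angle 2*theta follows a von Mises distribution centred
#' at 2*mu, the standard treatment of orientation (axis, not direction)
#' data; draws outside [-90, 90] cannot occur by construction.
#'
#' @param n number of draws.
#' @param model named list as above; angles in degrees.
#' @return numeric vector of angles in degrees within [-90, 90].
#' @export
sample_angles <- function(n, model) {
  if (!is.list(model) || is.null(model$name)) {
    stop("angle model must be a named list with a 'name' element",
         call. = FALSE)
  }
  switch(model$name,
    point = {
      stopifnot(abs(model$angle) <= 90)
      rep(as.numeric(model$angle), n)
    },
    uniform = {
      lo <- if (is.null(model$min)) -90 else model$min
      hi <- if (is.null(model$max)) 90 else model$max
      stopifnot(lo >= -90, hi <= 90, lo < hi)
      stats::runif(n, lo, hi)
    },
    vonmises = {
      mu <- if (is.null(model$mu)) 0 else model$mu
      phi <- rvonmises(n, 2 * mu * pi / 180, model$kappa)
      phi * 90 / pi
    },
    stop("unsupported angle model: ", model$name, call. = FALSE))
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean direction mu (radians), concentration kappa; kappa = 0 is uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))) + mu
    }
  }
  atan2(sin(out), cos(out))
}

# bilinear (area-weighted) deposit of weights at continuous (row, col)
# positions into a matrix, accumulating duplicates
deposit_bilinear <- function(img, ry, cx, w) {
  nr <- nrow(img); nc <- ncol(img)
  y0 <- floor(ry); x0 <- floor(cx)
  fy <- ry - y0; fx <- cx - x0
  iy <- c(y0, y0 + 1, y0, y0 + 1)
  ix <- c(x0, x0, x0 + 1, x0 + 1)
  ww <- c(w * (1 - fy) * (1 - fx), w * fy * (1 - fx),
          w * (1 - fy) * fx, w * fy * fx)
  ok <- iy >= 1 & iy <= nr & ix >= 1 & ix <= nc & ww > 0
  if (!any(ok)) return(img)
  idx <- (ix[ok] - 1L) * nr + iy[ok]
  add <- rowsum(ww[ok], idx)
  img[as.integer(rownames(add))] <- img[as.integer(rownames(add))] + add[, 1]
  img
}

#' Render a synthetic micropatterned cell image with ground truth
#'
#' Generates the four rasters the measurement procedures consume: a filament
#' fluorescence channel, a binary cell mask (a rectangular cell confined to
#' the adhesive line), the line-pattern mask, and a nucleus mask; plus exact
#' ground truth for every generated quantity. Filaments are straight
#' segments rendered as 1-px-wide anti-aliased strokes depositing
#' \code{intensity_unit} grey levels per pixel of length (times an integer
#' bundling multiplicity), then blurred with a Gaussian (sigma 1 px) and
#' overlaid with additive Gaussian noise.
#'
#' @param length_um,width_um cell length (along the line) and width, um.
#' @param pixel_size um per pixel.
#' @param n_filaments number of filament segments.
#' @param angle_model angular model for filament orientation, see
#'   \code{\link{sample_angles}}.
#' @param noise_sd additive Gaussian noise, grey levels (0 disables noise
#'   and blur for exact-geometry fixtures).
#' @param seed RNG seed; output is deterministic given the seed.
#' @param intensity_unit single-filament calibration intensity, grey levels
#'   deposited per pixel of filament length.
#' @param filament_length_frac range of filament lengths as a fraction of
#'   cell length.
#' @param multiplicity_max filaments carry an integer intensity multiplicity
#'   drawn uniformly from 1..multiplicity_max (1 = all single filaments).
#' @param margin_px blank margin around the cell, px.
#' @param blur_sigma Gaussian blur sigma in px (applied when noise_sd > 0
#'   or \code{force_blur}).
#' @param force_blur apply the blur even when noise_sd = 0.
#' @return An object of class \code{synthetic_cell_image}: channel,
#'   cell_mask, line_mask, nucleus_mask (matrices of equal shape),
#'   pixel_size, and \code{ground_truth} (cell/pattern geometry, per-
#'   filament endpoints in (row, col) px, angles, intensity multiplicities,
#'   lengths, nucleus count, intensity_unit).
#' @export
render_patterned_cell <- function(length_um, width_um, pixel_size = 1,
                                  n_filaments = 0,
                                  angle_model = list(name = "point", angle = 0),
                                  noise_sd = 0, seed = 1,
                                  intensity_unit = 100,
                                  filament_length_frac = c(0.25, 0.6),
                                  multiplicity_max = 1,
                                  margin_px = 8,
                                  blur_sigma = 1,
                                  force_blur = FALSE) {
  stopifnot(length_um > 0, width_um > 0, pixel_size > 0, n_filaments >= 0)
  set.seed(seed)
  len_px <- max(1L, as.integer(round(length_um / pixel_size)))
  wid_px <- max(1L, as.integer(round(width_um / pixel_size)))
  nr <- len_px + 2L * margin_px
  nc <- wid_px + 2L * margin_px

  r0 <- margin_px + 1L; r1 <- margin_px + len_px
  c0 <- margin_px + 1L; c1 <- margin_px + wid_px
  cell_mask <- matrix(FALSE, nr, nc)
  cell_mask[r0:r1, c0:c1] <- TRUE
  line_mask <- matrix(FALSE, nr, nc)
  line_mask[, c0:c1] <- TRUE  # adhesive stripe spans the full image height

  nucleus_mask <- matrix(FALSE, nr, nc)
  ny <- (r0 + r1) / 2; nx <- (c0 + c1) / 2
  nrad <- max(1.5, min(len_px, wid_px) / 4)
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  nucleus_mask[(yy - ny)^2 + (xx - nx)^2 <= nrad^2] <- TRUE

  channel <- matrix(0, nr, nc)
  gt_fil <- data.frame(row0 = numeric(0), col0 = numeric(0),
                       row1 = numeric(0), col1 = numeric(0),
                       angle_deg = numeric(0), intensity_units = integer(0),
                       length_um = numeric(0))
  if (n_filaments > 0) {
    angles <- sample_angles(n_filaments, angle_model)
    for (k in seq_len(n_filaments)) {
      placed <- FALSE
      for (try in 1:100) {
        flen_px <- stats::runif(1, filament_length_frac[1],
                                filament_length_frac[2]) * len_px
        cy <- stats::runif(1, r0 + 1, r1 - 1)
        cx <- stats::runif(1, c0 + 1, c1 - 1)
        th <- angles[k] * pi / 180
        dy <- cos(th) * flen_px / 2
        dx <- sin(th) * flen_px / 2
        p0 <- c(cy - dy, cx - dx); p1 <- c(cy + dy, cx + dx)
        inside <- function(p) {
          p[1] >= r0 && p[1] <= r1 && p[2] >= c0 && p[2] <= c1
        }
        if (inside(p0) && inside(p1)) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place filament ", k, " inside the cell mask after ",
             "100 attempts (filament too long for the cell?)", call. = FALSE)
      }
      mult <- if (multiplicity_max > 1) {
        sample.int(multiplicity_max, 1)
      } else 1L
      step <- 0.25
      tvals <- seq(0, flen_px, by = step)
      ry <- p0[1] + (p1[1] - p0[1]) * tvals / flen_px
      cx2 <- p0[2] + (p1[2] - p0[2]) * tvals / flen_px
      channel <- deposit_bilinear(channel, ry, cx2,
                                  rep(intensity_unit * mult * step,
                                      length(tvals)))
      gt_fil <- rbind(gt_fil, data.frame(
        row0 = p0[1], col0 = p0[2], row1 = p1[1], col1 = p1[2],
        angle_deg = angles[k], intensity_units = mult,
        length_um = flen_px * pixel_size))
    }
  }

  if (noise_sd > 0 || force_blur) {
    channel <- EBImage::gblur(channel, sigma = blur_sigma)
  }
  if (noise_sd > 0) {
    channel <- channel + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }

  structure(list(
    channel = channel, cell_mask = cell_mask, line_mask = line_mask,
    nucleus_mask = nucleus_mask, pixel_size = pixel_size,
    ground_truth = list(
      cell_length_um = len_px * pixel_size,
      pattern_width_um = wid_px * pixel_size,
      filaments = gt_fil,
      nucleus_count = 1L,
      intensity_unit = intensity_unit,
      noise_sd = noise_sd,
      seed = seed)),
    class = "synthetic_cell_image")
}

#' @export
print.synthetic_cell_image <- function(x, ...) {
  cat(sprintf(
    "Synthetic patterned-cell image %d x %d px (%g um/px): cell %g x %g um, %d filaments\n",
    nrow(x$channel), ncol(x$channel), x$pixel_size,
    x$ground_truth$cell_length_um, x$ground_truth$pattern_width_um,
    nrow(x$ground_truth$filaments)))
  invisible(x)
}

#' @export
plot.synthetic_cell_image <- function(x, ...) {
  ch <- x$channel
  rng <- range(ch)
  if (diff(rng) == 0) rng <- c(0, 1)
  graphics::image(t(ch[nrow(ch):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(ch) / ncol(ch),
                  zlim = rng, ...)
  invisible(x)
}

#' Cortical contact fate rule for growing plus ends
#'
#' A plus end meeting the lateral cortex at a shallow angle (|angle| <=
#' \code{bend_max}) bends to grow along the cell edge; a steep contact
#' (|angle| >= \code{cat_min}) triggers catastrophe; in the ambiguous band
#' between the two thresholds either outcome occurs, a bend with
#' probability \code{mixed_bend_prob}.
#'
#' @param bend_max largest guaranteed-bend contact angle, degrees
#'   (default 25).
#' @param cat_min smallest guaranteed-catastrophe angle, degrees
#'   (default 32).
#' @param mixed_bend_prob bend probability in the ambiguous band.
#' @return an object of class \code{mt_fate_rule}.
#' @export
mt_fate_rule <- function(bend_max = 25, cat_min = 32, mixed_bend_prob = 0.5) {
  stopifnot(bend_max > 0, bend_max <= cat_min, cat_min <= 90,
            mixed_bend_prob >= 0, mixed_bend_prob <= 1)
  structure(list(bend_max = bend_max, cat_min = cat_min,
                 mixed_bend_prob = mixed_bend_prob),
            class = "mt_fate_rule")
}

apply_fate_rule <- function(rule, angle) {
  a <- abs(angle)
  ifelse(a <= rule$bend_max, "bend",
         ifelse(a >= rule$cat_min, "catastrophe", "ambiguous"))
}

#' Simulate EB-comet tracks with ground-truth cortical contact fates
#'
#' Straight plus-end trajectories emanate from the cell centre at sampled
#' angles to the line axis and are followed until they meet the cell
#' cortex (the lateral edge, or the cell tip for near-axial angles). The
#' ground-truth fate at contact follows the \code{\link{mt_fate_rule}};
#' bending tracks continue parallel to the boundary for a short tail,
#' catastrophes end the track at the contact point.
#'
#' @param cell_length_um,cell_width_um cell geometry, um.
#' @param rule an \code{\link{mt_fate_rule}}.
#' @param n_tracks number of tracks.
#' @param angle_model angular model for launch angles, see
#'   \code{\link{sample_angles}}.
#' @param seed RNG seed.
#' @param v_g comet speed, um/min.
#' @param dt sampling interval of the track positions, min.
#' @param tail_um length of the post-bend tail, um.
#' @return An object of class \code{comet_track_set}: \code{tracks} (list
#'   of data.frames t_min, x_um, y_um; x lateral, y along the axis) and
#'   \code{events} (track, angle_deg, fate, boundary, contact position).
#' @export
simulate_comet_tracks <- function(cell_length_um, cell_width_um, rule,
                                  n_tracks, angle_model, seed = 1,
                                  v_g = 15, dt = 0.02, tail_um = 2) {
  stopifnot(inherits(rule, "mt_fate_rule"), n_tracks > 0)
  set.seed(seed)
  angles <- sample_angles(n_tracks, angle_model)
  half_w <- cell_width_um / 2
  half_l <- cell_length_um / 2
  tracks <- vector("list", n_tracks)
  ev <- data.frame(track = seq_len(n_tracks), angle_deg = angles,
                   fate = NA_character_, boundary = NA_character_,
                   x_um = NA_real_, y_um = NA_real_)
  for (k in seq_len(n_tracks)) {
    th <- angles[k] * pi / 180
    dx <- sin(th); dy <- cos(th)
    t_lat <- if (abs(dx) > 1e-12) half_w / (v_g * abs(dx)) else Inf
    t_tip <- if (dy > 1e-12) half_l / (v_g * dy) else Inf
    t_hit <- min(t_lat, t_tip)
    side <- if (t_lat <= t_tip) "lateral" else "tip"
    tt <- seq(0, t_hit, by = dt)
    if (tt[length(tt)] < t_hit) tt <- c(tt, t_hit)
    df <- data.frame(t_min = tt, x_um = v_g * dx * tt, y_um = v_g * dy * tt)
    band <- apply_fate_rule(rule, angles[k])
    fate <- if (band == "ambiguous") {
      if (stats::runif(1) < rule$mixed_bend_prob) "bend" else "catastrophe"
    } else band
    if (fate == "bend") {
      # continue parallel to the boundary: along the line axis at a lateral
      # edge, towards the nearest tip along the cell end
      n_tail <- max(2L, ceiling(tail_um / (v_g * dt)))
      tt2 <- t_hit + seq_len(n_tail) * dt
      last <- df[nrow(df), ]
      if (side == "lateral") {
        df2 <- data.frame(t_min = tt2, x_um = last$x_um,
                          y_um = last$y_um + v_g * (tt2 - t_hit))
      } else {
        dir <- if (dx >= 0) 1 else -1
        df2 <- data.frame(t_min = tt2,
                          x_um = last$x_um + dir * v_g * (tt2 - t_hit),
                          y_um = last$y_um)
      }
      df <- rbind(df, df2)
    }
    tracks[[k]] <- df
    ev$fate[k] <- fate
    ev$boundary[k] <- side
    ev$x_um[k] <- v_g * dx * t_hit
    ev$y_um[k] <- v_g * dy * t_hit
  }
  structure(list(tracks = tracks, events = ev, rule = rule,
                 cell_length_um = cell_length_um,
                 cell_width_um = cell_width_um, v_g = v_g, dt = dt,
                 seed = seed),
            class = "comet_track_set")
}

#' @export
print.comet_track_set <- function(x, ...) {
  tab <- table(x$events$fate)
  cat(sprintf("Comet track set: %d tracks (%s)\n", length(x$tracks),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Write or read a synthetic cell image on disk
#'
#' The filament channel is written as a 16-bit TIFF (scaled into [0, 1] by
#' a factor recorded in the JSON sidecar), the three masks as PNGs, and the
#' ground truth plus pixel size as \code{<basename>_truth.json}.
#'
#' @param img a \code{\link{render_patterned_cell}} object.
#' @param dir output directory.
#' @param basename file basename.
#' @return invisibly (write) / a \code{synthetic_cell_image} (read; channel
#'   restored to grey levels, ground-truth list as recorded).
#' @export
write_synthetic_image <- function(img, dir, basename = "cell") {
  stopifnot(inherits(img, "synthetic_cell_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lo <- min(img$channel, 0)
  hi <- max(img$channel, 1)
  scale <- hi - lo
  EBImage::writeImage((img$channel - lo) / scale,
                      file.path(dir, paste0(basename, "_channel.tif")),
                      type = "tiff", bits.per.sample = 16L)
  for (m in c("cell_mask", "line_mask", "nucleus_mask")) {
    EBImage::writeImage(img[[m]] * 1,
                        file.path(dir, paste0(basename, "_", m, ".png")),
                        type = "png")
  }
  meta <- img$ground_truth
  meta$pixel_size <- img$pixel_size
  meta$channel_scale <- scale
  meta$channel_offset <- lo
  jsonlite::write_json(meta, file.path(dir, paste0(basename, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(file.path(dir, basename))
}

#' @rdname write_synthetic_image
#' @export
read_synthetic_image <- function(dir, basename = "cell") {
  meta <- jsonlite::read_json(
    file.path(dir, paste0(basename, "_truth.json")), simplifyVector = TRUE)
  plain <- function(x) {
    x <- EBImage::imageData(x)
    attributes(x) <- list(dim = dim(x))
    x
  }
  ch <- plain(EBImage::readImage(
    file.path(dir, paste0(basename, "_channel.tif"))))
  ch <- ch * meta$channel_scale + meta$channel_offset
  masks <- lapply(c("cell_mask", "line_mask", "nucleus_mask"), function(m) {
    plain(EBImage::readImage(
      file.path(dir, paste0(basename, "_", m, ".png")))) > 0.5
  })
  pixel_size <- meta$pixel_size
  meta$pixel_size <- NULL
  meta$channel_scale <- NULL
  meta$channel_offset <- NULL
  structure(list(channel = ch, cell_mask = masks[[1]],
                 line_mask = masks[[2]], nucleus_mask = masks[[3]],
                 pixel_size = pixel_size, ground_truth = meta),
            class = "synthetic_cell_image")
}
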