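#' Imaging field specification for the synthetic renderer
#'
#' Geometry and noise model for rendered fields. Positions are given as
#' (row, col) pixel centers; nuclear disks must lie inside the frame and
#' may not overlap. The cytoplasm is rendered as an annulus of
#' `cyto_width_um` beyond the nucleus so that the 2-10 um measurement ring
#' always lies inside true cytoplasm.
#'
#' @param height,width Field size in pixels.
#' @param um_per_px Pixel size (um); default 0.65.
#' @param background_level Constant background intensity added everywhere.
#' @param nuclear_radius_um Nuclear disk radius (um).
#' @param cyto_width_um Width of the rendered cytoplasmic annulus (um).
#' @param positions Matrix or data frame with columns `row`, `col` (pixel
#'   centers), one row per cell.
#' @param poisson If `TRUE`, Poisson noise is applied to the signal.
#' @param read_noise_sd Gaussian read noise sd (intensity units).
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(height, width, um_per_px = 0.65,
                       background_level = 100,
                       nuclear_radius_um = 8, cyto_width_um = 15,
                       positions, poisson = TRUE, read_noise_sd = 3) {
  positions <- as.data.frame(positions)
  stopifnot(all(c("row", "col") %in% names(positions)), um_per_px > 0)
  r_px <- nuclear_radius_um / um_per_px
  if (nrow(positions) > 0) {
    if (any(positions$row < r_px + 1 | positions$row > height - r_px |
            positions$col < r_px + 1 | positions$col > width - r_px)) {
      stop("a nuclear disk extends beyond the frame")
    }
    if (nrow(positions) > 1) {
      d <- as.matrix(stats::dist(positions[, c("row", "col")]))
      diag(d) <- Inf
      if (any(d < 2 * r_px)) stop("nuclear disks overlap")
    }
  }
  structure(list(height = height, width = width, um_per_px = um_per_px,
                 background_level = background_level,
                 nuclear_radius_um = nuclear_radius_um,
                 cyto_width_um = cyto_width_um,
                 positions = positions,
                 poisson = poisson, read_noise_sd = read_noise_sd),
            class = "field_spec")
}

# squared distance of every pixel of an h x w field to a center (row, col)
pixel_dist <- function(height, width, row, col) {
  dr <- (seq_len(height) - row)^2
  dc <- (seq_len(width) - col)^2
  sqrt(outer(dr, dc, `+`))
}

#' Render one multi-channel frame from per-cell states
#'
#' Builds named intensity channels from per-cell states: the nuclear
#' marker channel (`h2b`) is a disk per cell; the reporter channel (`dhb`)
#' places the nuclear intensity inside the disk and `ratio` times that
#' intensity in the cytoplasmic annulus; `degron` (and any extra stain
#' columns such as `edu`, `brdu`, `h2ax`) are rendered as nuclear disks.
#' A constant background is added everywhere; noise, when requested, is
#' applied last. Per-cell ground truth (label mask and the input states)
#' is attached.
#'
#' @param states Data frame with one row per cell: `cell_id`, `ratio`,
#'   `nuc` (nuclear reporter intensity), and optionally `h2b`, `degron`,
#'   `edu`, `brdu`, `h2ax`.
#' @param spec A [field_spec()]; `spec$positions` must have one row per
#'   state row.
#' @param channels Channel names to render.
#' @param noise Apply the spec's noise model (default `TRUE`).
#' @return An object of class `rendered_frame`: list with `channels`
#'   (named matrices) and `ground_truth` (label matrix, states, per-cell
#'   puncta pixel counts).
#' @export
render_frame <- function(states, spec,
                         channels = c("h2b", "dhb", "degron"),
                         noise = TRUE) {
  stopifnot(nrow(states) == nrow(spec$positions))
  h <- spec$height; w <- spec$width
  r_nuc <- spec$nuclear_radius_um / spec$um_per_px
  r_cyto <- r_nuc + spec$cyto_width_um / spec$um_per_px
  labels <- matrix(0L, h, w)
  chans <- stats::setNames(
    lapply(channels, function(x) matrix(0, h, w)), channels)
  margin <- ceiling(r_cyto) + 1
  for (i in seq_len(nrow(states))) {
    # rasterize in a local window around the cell for speed
    row_i <- spec$positions$row[i]; col_i <- spec$positions$col[i]
    rows <- max(1, floor(row_i - margin)):min(h, ceiling(row_i + margin))
    cols <- max(1, floor(col_i - margin)):min(w, ceiling(col_i + margin))
    d <- sqrt(outer((rows - row_i)^2, (cols - col_i)^2, `+`))
    nucm <- d <= r_nuc
    cytom <- d > r_nuc & d <= r_cyto
    lab_w <- labels[rows, cols]
    lab_w[nucm] <- i
    labels[rows, cols] <- lab_w
    st <- states[i, ]
    put <- function(ch, m, value) {
      win <- ch[rows, cols]
      win[m] <- value
      ch[rows, cols] <- win
      ch
    }
    if ("h2b" %in% channels) {
      chans$h2b <- put(chans$h2b, nucm, if (!is.null(st$h2b)) st$h2b else 400)
    }
    if ("dhb" %in% channels) {
      chans$dhb <- put(chans$dhb, nucm, st$nuc)
      chans$dhb <- put(chans$dhb, cytom, st$ratio * st$nuc)
    }
    for (stain in intersect(c("degron", "edu", "brdu", "h2ax"), channels)) {
      if (!is.null(st[[stain]])) {
        chans[[stain]] <- put(chans[[stain]], nucm, st[[stain]])
      }
    }
  }
  chans <- lapply(chans, function(x) x + spec$background_level)
  truth <- list(labels = labels, states = states,
                puncta_px = stats::setNames(rep(0L, nrow(states)),
                                            states$cell_id))
  frame <- structure(list(channels = chans, ground_truth = truth,
                          spec = spec), class = "rendered_frame")
  if (noise) frame <- apply_noise(frame) else frame
}

#' Apply the field's noise model to a rendered frame
#'
#' Poisson noise on the signal (if enabled in the spec) followed by
#' additive Gaussian read noise. Call after all structure (including
#' puncta) has been rendered.
#'
#' @param frame A `rendered_frame`.
#' @return The frame with noisy channels.
#' @export
apply_noise <- function(frame) {
  spec <- frame$spec
  frame$channels <- lapply(frame$channels, function(ch) {
    out <- if (spec$poisson) {
      matrix(stats::rpois(length(ch), lambda = pmax(ch, 0)),
             nrow(ch), ncol(ch))
    } else ch
    if (spec$read_noise_sd > 0) {
      out <- out + stats::rnorm(length(ch), 0, spec$read_noise_sd)
    }
    pmax(out, 0)
  })
  frame
}

#' Add gamma-H2AX puncta to a cell's nucleus in a rendered frame
#'
#' Samples `n_puncta` non-overlapping disk centers inside the nuclear mask
#' (with a margin of one punctum radius from the boundary) and adds
#' `punctum_intensity` to the `h2ax` channel over each disk. The cell's
#' ground-truth puncta pixel count is set to the rasterized union area.
#' Apply before [apply_noise()].
#'
#' @param frame A `rendered_frame` (must contain an `h2ax` channel).
#' @param cell Integer cell label.
#' @param n_puncta Number of puncta.
#' @param punctum_radius_um Punctum radius (um).
#' @param punctum_intensity Added intensity per punctum.
#' @param max_tries Bounded retries for non-overlapping placement.
#' @return The updated frame.
#' @export
render_puncta <- function(frame, cell, n_puncta, punctum_radius_um = 0.65,
                          punctum_intensity = 200, max_tries = 500) {
  if (!"h2ax" %in% names(frame$channels)) stop("frame has no h2ax channel")
  if (n_puncta == 0) return(frame)
  spec <- frame$spec
  r_p <- max(1, round(punctum_radius_um / spec$um_per_px))
  labels <- frame$ground_truth$labels
  nuc_idx <- which(labels == cell, arr.ind = TRUE)
  if (nrow(nuc_idx) == 0) stop("cell not present in the frame")
  # candidate centers: nucleus pixels at least r_p inside the boundary
  pos <- spec$positions[cell, ]
  d <- sqrt((nuc_idx[, 1] - pos$row)^2 + (nuc_idx[, 2] - pos$col)^2)
  r_nuc <- spec$nuclear_radius_um / spec$um_per_px
  inner <- nuc_idx[d <= r_nuc - r_p - 1, , drop = FALSE]
  if (nrow(inner) == 0) stop("nucleus too small for the punctum radius")
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n_puncta) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop("could not place non-overlapping puncta within the retry budget")
    }
    cand <- inner[sample.int(nrow(inner), 1), ]
    if (nrow(centers) > 0) {
      dd <- sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)
      if (any(dd < 2 * r_p + 1)) next
    }
    centers <- rbind(centers, cand)
  }
  union_mask <- matrix(FALSE, spec$height, spec$width)
  for (k in seq_len(nrow(centers))) {
    dk <- pixel_dist(spec$height, spec$width, centers[k, 1], centers[k, 2])
    m <- dk <= r_p
    frame$channels$h2ax[m] <- frame$channels$h2ax[m] + punctum_intensity
    union_mask <- union_mask | m
  }
  id <- as.character(frame$ground_truth$states$cell_id[cell])
  frame$ground_truth$puncta_px[id] <-
    frame$ground_truth$puncta_px[id] + sum(union_mask)
  frame
}

#' Render a time-lapse of a simulated population
#'
#' Renders one multi-channel frame per requested time point from a list of
#' simulated cells, laying the cells out on the positions of `spec`.
#' Degron intensities are scaled to `degron_level`.
#'
#' @param cells List of `simulated_cell` objects (one per spec position).
#' @param spec A [field_spec()].
#' @param frames Integer frame indices to render (default: all).
#' @param channels Channels to render.
#' @param degron_level Peak degron intensity (intensity units).
#' @return A list of `rendered_frame` objects.
#' @export
render_population_frames <- function(cells, spec, frames = NULL,
                                     channels = c("h2b", "dhb", "degron"),
                                     degron_level = 300) {
  stopifnot(length(cells) == nrow(spec$positions))
  n_frames <- length(cells[[1]]$trace$time)
  if (is.null(frames)) frames <- seq_len(n_frames)
  lapply(frames, function(f) {
    states <- do.call(rbind, lapply(seq_along(cells), function(i) {
      tr <- cells[[i]]$trace
      data.frame(cell_id = tr$cell_id,
                 ratio = max(tr$ratio[f], 0),
                 nuc = tr$nuc[f],
                 degron = max(tr$degron[f], 0) * degron_level,
                 h2b = 400)
    }))
    render_frame(states, spec, channels = channels)
  })
}

#' Write rendered frames as per-channel multi-page TIFF stacks
#'
#' Each channel is written as `<prefix>_<channel>.tif` (frame-major,
#' 16-bit), with ground truth in `<prefix>_truth.json`.
#'
#' @param frames List of `rendered_frame` objects.
#' @param dir Output directory.
#' @param prefix File name prefix (e.g. a well name).
#' @param scale Intensity scale mapped to the 16-bit range.
#' @return Invisibly, the paths written.
#' @export
write_frames_tiff <- function(frames, dir, prefix = "well1", scale = 4096) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- names(frames[[1]]$channels)
  paths <- character(0)
  for (ch in channels) {
    imgs <- lapply(frames, function(f) {
      pmin(pmax(f$channels[[ch]] / scale, 0), 1)
    })
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(imgs, p, bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  truth <- lapply(frames, function(f) {
    list(states = f$ground_truth$states,
         puncta_px = as.list(f$ground_truth$puncta_px))
  })
  jp <- file.path(dir, sprintf("%s_truth.json", prefix))
  jsonlite::write_json(truth, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read a per-channel TIFF stack written by [write_frames_tiff()]
#'
#' @param path Path to one channel's TIFF.
#' @param scale Intensity scale used at write time.
#' @return A list of intensity matrices, one per frame.
#' @export
read_frames_tiff <- function(path, scale = 4096) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * scale)
}
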