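#' Label mask container
#'
#' @param labels 2-D integer matrix; 0 is background, `k` marks cell `k`.
#' @param um_per_px Pixel size (um).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, um_per_px) {
  stopifnot(all(labels >= 0), um_per_px > 0)
  structure(list(labels = labels, um_per_px = um_per_px),
            class = "label_mask")
}

#' Perinuclear ring parameters
#'
#' Defaults follow the standard ring measurement: an annulus with inner
#' radius 2 um and outer radius 10 um outside the nuclear mask, excluding
#' any pixel within 10 um of another nucleus.
#'
#' @param inner_offset,outer_offset Ring offsets from the nuclear mask (um).
#' @param neighbor_exclusion Exclusion distance from other nuclei (um).
#' @return An object of class `ring_params`.
#' @export
ring_params <- function(inner_offset = 2, outer_offset = 10,
                        neighbor_exclusion = 10) {
  stopifnot(inner_offset > 0, inner_offset < outer_offset)
  structure(list(inner_offset = inner_offset, outer_offset = outer_offset,
                 neighbor_exclusion = neighbor_exclusion),
            class = "ring_params")
}

#' Segment nuclei from a nuclear-marker channel
#'
#' Otsu threshold on the log-transformed intensity, hole filling,
#' distance-transform watershed declumping, and area gating. A blank or
#' degenerate image yields an empty mask.
#'
#' @param nuclear_channel 2-D intensity matrix.
#' @param um_per_px Pixel size (um).
#' @param min_area,max_area Area gate (px).
#' @param watershed_tolerance Minimum object-height separation for the
#'   declumping watershed.
#' @return A [label_mask()].
#' @export
segment_nuclei <- function(nuclear_channel, um_per_px = 0.65,
                           min_area = 40, max_area = 5000,
                           watershed_tolerance = 1) {
  img <- log1p(pmax(nuclear_channel, 0))
  rng <- range(img)
  if (diff(rng) < 1e-10) {
    return(label_mask(matrix(0L, nrow(nuclear_channel),
                             ncol(nuclear_channel)), um_per_px))
  }
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > th
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labels <- EBImage::imageData(EBImage::watershed(dm,
                                                  tolerance = watershed_tolerance))
  areas <- tabulate(labels[labels > 0])
  bad <- which(areas < min_area | areas > max_area)
  labels[labels %in% bad] <- 0L
  # relabel consecutively
  keep <- sort(unique(labels[labels > 0]))
  relab <- integer(max(labels, 1))
  relab[keep] <- seq_along(keep)
  labels[labels > 0] <- relab[labels[labels > 0]]
  label_mask(matrix(as.integer(labels), nrow(labels), ncol(labels)),
             um_per_px)
}

#' Global background estimate for a channel
#'
#' Dilates all nuclear masks by `dilation_um` and returns the median pixel
#' intensity over the remaining (non-masked) region.
#'
#' @param image 2-D intensity matrix.
#' @param mask A [label_mask()].
#' @param dilation_um Dilation distance (um), default 50.
#' @return Median background intensity.
#' @export
estimate_background <- function(image, mask, dilation_um = 50) {
  labels <- mask$labels
  if (all(labels == 0)) return(stats::median(image))
  dil_px <- dilation_um / mask$um_per_px
  # distance of every background pixel to the nearest nuclear pixel
  d <- EBImage::imageData(EBImage::distmap(labels == 0))
  far <- labels == 0 & d > dil_px
  if (!any(far)) {
    stop("no background pixels remain after dilation; ",
         "use a larger field or a smaller dilation")
  }
  stats::median(image[far])
}

# distance of every pixel to the nearest pixel of `target` (logical matrix)
dist_to_mask <- function(target) {
  if (!any(target)) return(matrix(Inf, nrow(target), ncol(target)))
  EBImage::imageData(EBImage::distmap(!target))
}

#' Perinuclear ring mask for one cell
#'
#' Pixels whose distance to the cell's nuclear mask lies in
#' `(inner_offset, outer_offset]`, excluding every nuclear pixel and every
#' pixel within `neighbor_exclusion` of another nucleus. Distances are
#' Euclidean in um. Computed on a cropped window around the cell for
#' speed; the result is a full-size logical matrix.
#'
#' @param mask A [label_mask()].
#' @param cell Integer cell label.
#' @param params A [ring_params()].
#' @return Logical matrix of ring pixels.
#' @export
ring_mask <- function(mask, cell, params = ring_params()) {
  labels <- mask$labels
  upp <- mask$um_per_px
  idx <- which(labels == cell, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cell not present in the mask")
  margin <- ceiling((params$outer_offset + params$neighbor_exclusion) / upp) + 2
  r0 <- max(1, min(idx[, 1]) - margin); r1 <- min(nrow(labels), max(idx[, 1]) + margin)
  c0 <- max(1, min(idx[, 2]) - margin); c1 <- min(ncol(labels), max(idx[, 2]) + margin)
  crop <- labels[r0:r1, c0:c1]
  d_cell <- dist_to_mask(crop == cell) * upp
  ring <- d_cell > params$inner_offset & d_cell <= params$outer_offset
  ring[crop > 0] <- FALSE
  other <- crop > 0 & crop != cell
  if (any(other)) {
    d_other <- dist_to_mask(other) * upp
    ring[d_other < params$neighbor_exclusion] <- FALSE
  }
  out <- matrix(FALSE, nrow(labels), ncol(labels))
  out[r0:r1, c0:c1] <- ring
  out
}

#' Measure one cell's reporter and stain signals
#'
#' Background-subtracted nuclear median, ring 75th percentile (over ring
#' pixels with strictly positive background-subtracted intensity; linear
#' interpolation between order statistics), and their ratio for the
#' reporter channel; nuclear medians for all other channels. If no ring
#' pixel is above background the ratio is `NA` and the measurement is
#' flagged.
#'
#' @param channels Named list of 2-D intensity matrices.
#' @param mask A [label_mask()].
#' @param cell Integer cell label.
#' @param params A [ring_params()].
#' @param backgrounds Named per-channel background levels (as from
#'   [estimate_background()]).
#' @param reporter Name of the translocation reporter channel.
#' @return A one-row data frame: `cell_id`, `nuc_median`, `cyto_p75`,
#'   `ratio`, `flag`, plus one `<stain>` column per non-reporter channel.
#' @export
measure_cell <- function(channels, mask, cell, params = ring_params(),
                         backgrounds, reporter = "dhb") {
  nucm <- mask$labels == cell
  if (!any(nucm)) stop("cell not present in the mask")
  out <- data.frame(cell_id = cell, nuc_median = NA_real_,
                    cyto_p75 = NA_real_, ratio = NA_real_, flag = "")
  if (reporter %in% names(channels)) {
    ch <- channels[[reporter]] - backgrounds[[reporter]]
    out$nuc_median <- stats::median(ch[nucm])
    ringm <- ring_mask(mask, cell, params)
    vals <- ch[ringm]
    vals <- vals[vals > 0]
    if (length(vals) == 0) {
      out$flag <- "no_ring_foreground"
    } else {
      out$cyto_p75 <- stats::quantile(vals, 0.75, names = FALSE, type = 7)
      if (out$nuc_median > 0) out$ratio <- out$cyto_p75 / out$nuc_median
    }
  }
  for (stain in setdiff(names(channels), c(reporter, "h2b"))) {
    ch <- channels[[stain]] - backgrounds[[stain]]
    out[[stain]] <- stats::median(ch[nucm])
  }
  out
}

#' Count gamma-H2AX puncta pixels in one nucleus
#'
#' White-top-hat transform of the channel with a circular structuring
#' element of radius `kernel_radius_um` (rounded to whole pixels), then a
#' binary foreground at `filtered value > abs_threshold`; returns the
#' number of foreground pixels inside the cell's nuclear mask. Before
#' filtering, pixels outside the cell's nucleus are replaced by the
#' nuclear median so that the filter responds to intranuclear structure
#' only (the nucleus/background intensity step would otherwise leave
#' boundary artifacts). The filter runs on a cropped window around the
#' cell.
#'
#' @param h2ax_channel 2-D intensity matrix (raw).
#' @param mask A [label_mask()].
#' @param cell Integer cell label.
#' @param kernel_radius_um Structuring-element radius (um), default 4.
#' @param abs_threshold Absolute intensity threshold on the filtered
#'   image; defaults to [h2ax_default_threshold()].
#' @return Foreground pixel count (integer).
#' @export
quantify_h2ax <- function(h2ax_channel, mask, cell, kernel_radius_um = 4,
                          abs_threshold = NULL) {
  r_px <- max(1, round(kernel_radius_um / mask$um_per_px))
  labels <- mask$labels
  idx <- which(labels == cell, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("cell not present in the mask")
  margin <- 2 * r_px + 2
  r0 <- max(1, min(idx[, 1]) - margin); r1 <- min(nrow(labels), max(idx[, 1]) + margin)
  c0 <- max(1, min(idx[, 2]) - margin); c1 <- min(ncol(labels), max(idx[, 2]) + margin)
  work <- h2ax_channel[r0:r1, c0:c1]
  lab_w <- labels[r0:r1, c0:c1]
  in_nuc <- lab_w == cell
  work[!in_nuc] <- stats::median(work[in_nuc])
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  sc <- max(work, 1)
  filt <- sc * EBImage::imageData(
    EBImage::whiteTopHat(work / sc, EBImage::makeBrush(2 * r_px + 1, "disc")))
  if (is.null(abs_threshold)) {
    abs_threshold <- stats::median(filt[in_nuc]) + 5 * stats::mad(filt[in_nuc])
  }
  sum(filt > abs_threshold & in_nuc)
}

#' Default absolute threshold for puncta detection
#'
#' Median plus five times the robust noise sd (median absolute deviation)
#' of the top-hat-filtered intensity over the nuclear region: puncta
#' occupy a small fraction of nuclear area, so the median/MAD of the
#' filtered nucleoplasm estimate the noise floor at nuclear intensity
#' (where Poisson noise is largest) robustly. [quantify_h2ax()] applies
#' this rule per cell on its cropped window.
#'
#' @param filtered Top-hat-filtered 2-D intensity matrix.
#' @param mask A [label_mask()] (or any matrix where `> 0` marks nuclei).
#' @return Threshold (intensity units).
#' @export
h2ax_default_threshold <- function(filtered, mask) {
  labels <- if (inherits(mask, "label_mask")) mask$labels else mask
  nucv <- filtered[labels > 0]
  if (length(nucv) == 0) nucv <- as.vector(filtered)
  stats::median(nucv) + 5 * stats::mad(nucv)
}

# per-label centroids of a label matrix: data.frame(label, row, col)
mask_centroids <- function(labels) {
  idx <- which(labels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  }
  lab <- labels[idx]
  data.frame(label = sort(unique(lab)),
             row = tapply(idx[, 1], lab, mean),
             col = tapply(idx[, 2], lab, mean))
}

#' Track cells across frames by greedy nearest-centroid linking
#'
#' Links nuclei between consecutive frames by repeatedly matching the
#' globally closest centroid pair within a maximum displacement gate;
#' unmatched nuclei start new tracks (tracks of disappearing cells simply
#' end). The gate prevents identity swaps: an implied jump larger than the
#' gate terminates the track instead.
#'
#' @param masks List of [label_mask()] objects in temporal order.
#' @param gate_um Maximum displacement per frame (um), default 20.
#' @return Data frame with `frame`, `label`, `cell_id`, `row`, `col`.
#' @export
track_cells <- function(masks, gate_um = 20) {
  out <- list()
  next_id <- 1L
  prev <- NULL
  for (f in seq_along(masks)) {
    cen <- mask_centroids(masks[[f]]$labels)
    cen$frame <- f
    cen$cell_id <- NA_integer_
    gate_px <- gate_um / masks[[f]]$um_per_px
    if (!is.null(prev) && nrow(prev) > 0 && nrow(cen) > 0) {
      d <- outer(prev$row, cen$row, `-`)^2 + outer(prev$col, cen$col, `-`)^2
      d <- sqrt(d)
      repeat {
        m <- which.min(d)
        if (length(m) == 0 || d[m] > gate_px) break
        i <- (m - 1) %% nrow(d) + 1
        j <- (m - 1) %/% nrow(d) + 1
        cen$cell_id[j] <- prev$cell_id[i]
        d[i, ] <- Inf
        d[, j] <- Inf
        if (all(!is.finite(d))) break
      }
    }
    new <- is.na(cen$cell_id)
    if (any(new)) {
      cen$cell_id[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out[[f]] <- cen[, c("frame", "label", "cell_id", "row", "col")]
    prev <- cen
  }
  do.call(rbind, out)
}

#' Quantify a rendered (or loaded) time-lapse into per-cell measurements
#'
#' Full measurement chain per frame: nuclear segmentation on the marker
#' channel, per-channel global background estimation, per-cell reporter
#' and stain measurement, then frame-to-frame tracking so that rows carry
#' persistent `cell_id`s.
#'
#' @param frames List of `rendered_frame` objects (or lists with a
#'   `channels` element of named matrices).
#' @param um_per_px Pixel size (um).
#' @param nuclear_channel Name of the segmentation channel.
#' @param params A [ring_params()].
#' @param reporter Reporter channel name.
#' @param dilation_um Background dilation (um).
#' @param ... Passed to [segment_nuclei()].
#' @return Data frame of per-frame per-cell measurements with persistent
#'   `cell_id`, frame index, and time-invariant label.
#' @export
quantify_frames <- function(frames, um_per_px = 0.65,
                            nuclear_channel = "h2b",
                            params = ring_params(), reporter = "dhb",
                            dilation_um = 50, ...) {
  masks <- lapply(frames, function(f) {
    segment_nuclei(f$channels[[nuclear_channel]], um_per_px = um_per_px, ...)
  })
  tracks <- track_cells(masks)
  res <- list()
  for (f in seq_along(frames)) {
    chans <- frames[[f]]$channels
    mask <- masks[[f]]
    n_cells <- max(mask$labels)
    if (n_cells == 0) next
    bgs <- lapply(chans, estimate_background, mask = mask,
                  dilation_um = dilation_um)
    rows <- do.call(rbind, lapply(seq_len(n_cells), function(k) {
      measure_cell(chans, mask, k, params = params, backgrounds = bgs,
                   reporter = reporter)
    }))
    rows$frame <- f
    rows$label <- rows$cell_id
    tk <- tracks[tracks$frame == f, ]
    rows$cell_id <- tk$cell_id[match(rows$label, tk$label)]
    res[[length(res) + 1]] <- rows
  }
  do.call(rbind, res)
}
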