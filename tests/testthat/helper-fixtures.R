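# shared fixtures built in code

# noise-free cycling configuration for exactness checks
quiet_config <- function(...) {
  regime_config("cycling", noise_sd = 0, degron_noise_sd = 0, ...)
}

# a single-cell field spec for render/quantify round trips
tile_spec <- function(side = 120, um_per_px = 0.65, noise = TRUE, ...) {
  field_spec(side, side, um_per_px = um_per_px,
             positions = data.frame(row = side / 2, col = side / 2),
             poisson = noise, read_noise_sd = if (noise) 3 else 0, ...)
}

# brute-force perinuclear ring oracle: per-pixel distances to the nearest
# pixel of each nucleus, computed directly (independent of distmap)
ring_oracle <- function(labels, cell, inner = 2, outer = 10, excl = 10,
                        um_per_px = 1) {
  h <- nrow(labels); w <- ncol(labels)
  allpix <- as.matrix(expand.grid(r = seq_len(h), c = seq_len(w)))
  mind <- function(mask_idx) {
    apply(allpix, 1, function(p) {
      min(sqrt((mask_idx[, 1] - p[1])^2 + (mask_idx[, 2] - p[2])^2))
    }) * um_per_px
  }
  d_cell <- mind(which(labels == cell, arr.ind = TRUE))
  out <- matrix(d_cell > inner & d_cell <= outer, h, w)
  other <- labels > 0 & labels != cell
  if (any(other)) {
    d_other <- mind(which(other, arr.ind = TRUE))
    out[matrix(d_other < excl, h, w)] <- FALSE
  }
  out[labels > 0] <- FALSE
  out
}

# toy trace with given ratio series on a 12-min grid
toy_trace <- function(ratio, dt = 0.2, ...) {
  cell_trace(1, seq(0, by = dt, length.out = length(ratio)), ratio, ...)
}
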