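test_that("segmentation finds well-separated nuclei and declumps bridges", {
  expect_equal(max(segment_nuclei(matrix(100, 64, 64))$labels), 0)

  set.seed(21)
  pos <- expand.grid(row = c(60, 160, 260), col = c(60, 160))[1:5, ]
  sp <- field_spec(320, 220, positions = pos)
  st <- data.frame(cell_id = 1:5, ratio = runif(5, 0.5, 2), nuc = 300)
  fr <- render_frame(st, sp, channels = c("h2b", "dhb"))
  mask <- segment_nuclei(fr$channels$h2b, sp$um_per_px)
  expect_equal(max(mask$labels), 5)
  found <- mask_centroids(mask$labels)
  d <- sqrt(outer(found$row, pos$row, `-`)^2 + outer(found$col, pos$col, `-`)^2)
  expect_true(all(apply(d, 2, min) < 2))

  # two disks merged by a 1-px bridge are split by the watershed
  img <- matrix(100, 80, 80)
  d1 <- sqrt(outer((1:80 - 40)^2, (1:80 - 25)^2, `+`))
  d2 <- sqrt(outer((1:80 - 40)^2, (1:80 - 55)^2, `+`))
  img[d1 <= 10 | d2 <= 10] <- 400
  img[40, 35:45] <- 400
  m2 <- segment_nuclei(img, um_per_px = 1)
  expect_equal(max(m2$labels), 2)
})

test_that("background is the median outside the dilated masks", {
  m <- label_mask(matrix(0L, 40, 40), 1)
  expect_equal(estimate_background(matrix(7.5, 40, 40), m), 7.5)

  sp <- tile_spec(side = 200, noise = FALSE)
  fr <- render_frame(data.frame(cell_id = 1, ratio = 1, nuc = 300),
                     sp, channels = c("h2b", "dhb"), noise = FALSE)
  mask <- segment_nuclei(fr$channels$h2b, sp$um_per_px)
  expect_equal(estimate_background(fr$channels$dhb, mask, dilation_um = 40),
               100)
  expect_error(estimate_background(fr$channels$dhb, mask, dilation_um = 500),
               "background pixels")

  # within 1% under the default Poisson-Gaussian noise
  set.seed(8)
  spn <- tile_spec(side = 200)
  frn <- render_frame(data.frame(cell_id = 1, ratio = 1, nuc = 300),
                      spn, channels = c("h2b", "dhb"))
  maskn <- segment_nuclei(frn$channels$h2b, spn$um_per_px)
  expect_equal(estimate_background(frn$channels$dhb, maskn, dilation_um = 40),
               100, tolerance = 0.01)
})

test_that("ring masks match the brute-force pixel-distance oracle", {
  h <- 60; w <- 60
  d <- sqrt(outer((1:h - 31)^2, (1:w - 31)^2, `+`))
  labels <- matrix(0L, h, w); labels[d <= 8] <- 1L
  m <- label_mask(labels, 1)
  ring <- ring_mask(m, 1)
  expect_identical(ring, ring_oracle(labels, 1))
  expect_true(all(!(ring & labels > 0)))

  # isolated cell: unaffected by the neighbor-exclusion rule
  expect_equal(sum(ring), sum(ring_oracle(labels, 1, excl = 1e9)))

  # two nuclei closer than the exclusion distance lose the facing arcs
  labels2 <- matrix(0L, h, w)
  d1 <- sqrt(outer((1:h - 30)^2, (1:w - 20)^2, `+`))
  d2 <- sqrt(outer((1:h - 30)^2, (1:w - 44)^2, `+`))
  labels2[d1 <= 8] <- 1L; labels2[d2 <= 8] <- 2L
  m2 <- label_mask(labels2, 1)
  ring1 <- ring_mask(m2, 1)
  expect_identical(ring1, ring_oracle(labels2, 1))
  expect_lt(sum(ring1), sum(ring))
})

test_that("cell measurement implements the background-subtracted ratio", {
  sp <- field_spec(140, 140, positions = data.frame(row = 70, col = 70),
                   poisson = FALSE, read_noise_sd = 0)
  # nucleus 200, cytoplasm 300, background 100 -> ratio (300-100)/(200-100)
  fr <- render_frame(data.frame(cell_id = 1, ratio = 2, nuc = 100),
                     sp, channels = c("h2b", "dhb"), noise = FALSE)
  mask <- segment_nuclei(fr$channels$h2b, sp$um_per_px)
  bg <- estimate_background(fr$channels$dhb, mask, dilation_um = 15)
  meas <- measure_cell(fr$channels, mask, 1, backgrounds = list(dhb = bg))
  expect_equal(meas$nuc_median, 100)
  expect_equal(meas$cyto_p75, 200)
  expect_equal(meas$ratio, 2)

  # scaling intensities after background removal leaves the ratio unchanged
  scaled <- lapply(fr$channels, function(ch) (ch - 100) * 3 + 100)
  bg_s <- estimate_background(scaled$dhb, mask, dilation_um = 15)
  expect_equal(measure_cell(scaled, mask, 1,
                            backgrounds = list(dhb = bg_s))$ratio, 2)

  # a ring with nothing above background flags instead of fabricating
  dark <- fr$channels
  dark$dhb[fr$ground_truth$labels == 0] <- 100
  dark$dhb[mask$labels == 1] <- 200
  meas_dark <- measure_cell(dark, mask, 1, backgrounds = list(dhb = 100))
  expect_true(is.na(meas_dark$ratio))
  expect_equal(meas_dark$flag, "no_ring_foreground")
})

test_that("top-hat puncta counting matches the rasterization oracle", {
  sp <- field_spec(90, 90, um_per_px = 1,
                   positions = data.frame(row = 45, col = 45),
                   poisson = FALSE, read_noise_sd = 0)
  st <- data.frame(cell_id = 1, ratio = 1, nuc = 300, h2ax = 120)
  fr <- render_frame(st, sp, channels = c("h2b", "h2ax"), noise = FALSE)
  mask <- segment_nuclei(fr$channels$h2b, 1)
  # punctum-free nucleus scores zero
  expect_equal(quantify_h2ax(fr$channels$h2ax, mask, 1, abs_threshold = 50), 0)
  # one high-contrast punctum of radius 2 px counts its 13 pixels
  set.seed(4)
  fr1 <- render_puncta(fr, 1, 1, punctum_radius_um = 2,
                       punctum_intensity = 400)
  expect_equal(quantify_h2ax(fr1$channels$h2ax, mask, 1, abs_threshold = 50),
               13)
  # a smooth large-scale gradient contributes nothing
  grad <- fr$channels$h2ax +
    outer(seq(0, 200, length.out = 90), seq(0, 100, length.out = 90), `+`) / 2
  expect_equal(quantify_h2ax(grad, mask, 1, abs_threshold = 50), 0)
})

test_that("tracking links static and slowly moving cells but never swaps", {
  disk_labels <- function(centers, h = 100, w = 100, r = 8) {
    lab <- matrix(0L, h, w)
    for (k in seq_len(nrow(centers))) {
      d <- sqrt(outer((1:h - centers[k, 1])^2, (1:w - centers[k, 2])^2, `+`))
      lab[d <= r] <- k
    }
    label_mask(lab, 1)
  }
  # static scene: one track spanning all frames
  static <- lapply(1:5, function(f) disk_labels(cbind(50, 50)))
  tk <- track_cells(static)
  expect_equal(unique(tk$cell_id), 1)
  expect_equal(nrow(tk), 5)
  # 3 px/frame with a 10 px gate: a single unbroken track
  moving <- lapply(1:6, function(f) disk_labels(cbind(30 + 3 * f, 50)))
  tk2 <- track_cells(moving, gate_um = 10)
  expect_equal(unique(tk2$cell_id), 1)
  # exchanging positions needs a jump beyond the gate: tracks terminate
  # and restart (four short tracks) instead of swapping identities
  swap <- list(disk_labels(rbind(c(30, 30), c(70, 70))),
               disk_labels(rbind(c(70, 30), c(30, 70)))) # mid-swap frame
  tk3 <- track_cells(swap, gate_um = 10)
  expect_equal(length(unique(tk3$cell_id)), 4)
})
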