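test_that("compactness matches hand computations and scales inversely", {
  # three collinear pixels, unit intensity: centroid in the middle, sum = 2
  px <- cbind(c(5, 5, 5), c(4, 5, 6))
  expect_equal(compactness(px, c(1, 1, 1)), 0.5)

  # multiplying intensities by k divides C by k
  expect_equal(compactness(px, c(3, 3, 3)), 0.5 / 3)

  # single pixel: degenerate moment
  expect_true(is.na(compactness(cbind(2, 2), 10)))

  expect_error(compactness(matrix(numeric(), 0, 2), numeric()), "no pixels")

  for (seed in 1:20) {
    set.seed(500 + seed)
    k <- sample(3:12, 1)
    p <- unique(cbind(sample(1:20, k, replace = TRUE),
                      sample(1:20, k, replace = TRUE)))
    ints <- runif(nrow(p), 1, 255)
    if (nrow(p) < 2) next
    expect_equal(compactness(p, ints), bf_compactness(p, ints))
  }
})

test_that("channel score follows the ratio-product form", {
  expect_equal(channel_oep(30, 10, 20, 0.5), 30)
  expect_equal(channel_oep(30, 10, 0, 0.5), 0)
  # anti-blob response is clamped, never negative
  expect_equal(channel_oep(30, 10, -5, 0.5), 0)
  expect_error(channel_oep(30, 0, 20, 0.5), "positive")
})

test_that("channel weight is the nucleus sd ratio", {
  n <- 30; mask <- fx_disc_mask(n, 15, 15, 10)
  set.seed(11)
  red <- matrix(runif(n * n, 20, 120), n, n)
  cell_same <- fx_cell(red, red, mask)
  expect_equal(weight_factor(cell_same), 1)

  # green as affine rescale of red with half the spread: w = 2
  green <- 40 + 0.5 * red
  cell_half <- fx_cell(red, green, mask)
  expect_equal(weight_factor(cell_half), 2)

  cell_const <- fx_cell(red, matrix(9, n, n), mask)
  expect_warning(w <- weight_factor(cell_const), "degenerate")
  expect_true(is.na(w))
})

test_that("combined score is the weighted geometric form", {
  expect_equal(combined_oep(4, 16, 2), 64)
  expect_equal(combined_oep(3, 5, 1), 15)   # w = 1 reduces to the product
  expect_equal(combined_oep(1, 1, 0.37), 1)
  expect_equal(combined_oep(0, 5, 1.3), 0)
  expect_error(combined_oep(1, 1, 0), "positive")
})

test_that("scores increase with each positive factor and with w when red dominates", {
  base <- channel_oep(10, 5, 100, 0.01)
  expect_gt(channel_oep(12, 5, 100, 0.01), base)
  expect_gt(channel_oep(10, 5, 120, 0.01), base)
  expect_gt(channel_oep(10, 5, 100, 0.02), base)
  # OEP_red > 1 > OEP_green: combined score grows with w
  ws <- seq(0.5, 3, by = 0.1)
  vals <- combined_oep(4, 0.5, ws)
  expect_true(all(diff(vals) > 0))
})

test_that("the combined score is invariant under intensity rescaling", {
  # un-quantized synthetic crop run through detection + scoring at two gains
  n <- 60
  mask <- fx_disc_mask(n, 30, 30, 24)
  set.seed(21)
  red <- matrix(12, n, n)
  red <- fx_blob(red, 25, 30, 150, 1.5)
  red <- fx_blob(red, 38, 22, 60, 1.2)
  green <- matrix(14, n, n)
  green <- fx_blob(green, 25, 30, 140, 1.5)
  green <- fx_blob(green, 40, 35, 50, 1.1)
  cell1 <- fx_cell(red, green, mask)
  cellk <- fx_cell(3.7 * red, 3.7 * green, mask)
  o1 <- score_objects(detect_objects(cell1), cell1)
  ok <- score_objects(detect_objects(cellk), cellk)
  expect_equal(nrow(o1), nrow(ok))
  expect_gt(nrow(o1), 0)
  expect_equal(ok$oep, o1$oep, tolerance = 1e-9)
  expect_equal(ok$w, o1$w, tolerance = 1e-12)
})

test_that("scoring fills per-object features consistently", {
  n <- 50
  mask <- fx_disc_mask(n, 25, 25, 20)
  img <- matrix(10, n, n)
  img <- fx_blob(img, 25, 25, 180, 1.5)
  img <- round(img)
  cell <- fx_cell(img, img, mask)
  obj <- detect_objects(cell)
  sc <- score_objects(obj, cell)
  expect_equal(nrow(sc), nrow(obj))
  # identical channels: w = 1, per-channel scores equal, combined = product
  expect_equal(sc$w, rep(1, nrow(sc)))
  expect_equal(sc$oep_red, sc$oep_green)
  expect_equal(sc$oep, sc$oep_red * sc$oep_green)
  # I_TH of the bright blob: three brightest top-hat pixels by hand
  th <- top_hat(cell$red)
  px <- obj$pixels[[which.max(sc$area)]]
  expect_equal(sc$i_th_red[which.max(sc$area)],
               mean(sort(th[px], decreasing = TRUE)[1:3]))
})

test_that("planted foci outscore planted speckles on synthetic cells", {
  sim <- fx_small_sim(seed = 91, n_nuclei = 4, foci_per_cell = 3)
  labels <- segment_nuclei(sim$field$dapi)
  cells <- crop_cells(sim$field, labels)
  obj <- score_cells(cells)
  man <- cells_manifest(cells)
  lab <- fx_label_objects(obj, man, list(sim$truth))
  expect_gt(sum(lab$is_focus), 0)
  expect_gt(sum(!lab$is_focus), 0)
  m_focus <- mean(obj$log_oep[lab$is_focus])
  m_bg <- mean(obj$log_oep[!lab$is_focus])
  expect_gt(m_focus, m_bg)

  # rank agreement with planted amplitude (direction only)
  foci_obj <- obj[lab$is_focus, ]
  amp <- numeric(nrow(foci_obj))
  for (i in seq_len(nrow(foci_obj))) {
    ci <- which(man$cell_id == foci_obj$cell_id[i])
    d <- sqrt((sim$truth$foci$row - (man$origin_row[ci] + foci_obj$seed_row[i]))^2 +
              (sim$truth$foci$col - (man$origin_col[ci] + foci_obj$seed_col[i]))^2)
    amp[i] <- sim$truth$foci$amplitude[which.min(d)]
  }
  if (nrow(foci_obj) >= 5) {
    expect_gt(cor(foci_obj$oep, amp, method = "spearman"), 0)
  }
})
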