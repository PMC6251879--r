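test_that("nucleus segmentation finds planted nuclei and splits neighbours", {
  expect_equal(max(segment_nuclei(matrix(0, 50, 50))), 0)

  sim <- fx_small_sim(seed = 19, n_nuclei = 3)
  labels <- segment_nuclei(sim$field$dapi)
  expect_equal(max(labels), 3)
  info <- label_summary(labels)
  for (i in seq_len(nrow(info))) {
    d <- sqrt((sim$truth$nuclei$row - info$row[i])^2 +
              (sim$truth$nuclei$col - info$col[i])^2)
    expect_lt(min(d), 2)
  }

  # two nuclei overlapping slightly: watershed still yields two labels
  dapi <- matrix(0, 160, 160)
  for (ctr in list(c(70, 70), c(70, 118))) {
    d <- sqrt(outer((1:160 - ctr[1])^2, (1:160 - ctr[2])^2, "+"))
    dapi <- dapi + 110 * plogis((26 - d) / 1.5)
  }
  dapi <- pmin(round(dapi + 8), 255)
  two <- segment_nuclei(dapi)
  expect_equal(max(two), 2)
})

test_that("cropping preserves pixels, computes stats, and drops border cells", {
  sim <- fx_small_sim(seed = 23, n_nuclei = 3)
  labels <- segment_nuclei(sim$field$dapi)
  cells <- crop_cells(sim$field, labels, crop_size = 120)
  expect_gt(length(cells), 0)
  for (cl in cells) {
    rr <- (cl$origin[["row"]] + 1):(cl$origin[["row"]] + 120)
    cc <- (cl$origin[["col"]] + 1):(cl$origin[["col"]] + 120)
    # bit-exact pixel conservation
    expect_identical(cl$dapi, sim$field$dapi[rr, cc])
    expect_identical(cl$red_stack, sim$field$red_stack[rr, cc, , drop = FALSE])
    # I_nucl equals the brute-force mean under the mask
    expect_equal(cl$stats$i_nucl_red, mean(cl$red[cl$mask]))
    expect_gt(cl$stats$i_nucl_red, 0)
    # origin arithmetic: centroid minus half window
    w <- which(labels == cl$id, arr.ind = TRUE)
    expect_equal(cl$origin[["row"]], round(mean(w[, 1])) - 60)
  }

  # a mask close to the field edge is dropped with a border reason
  small_labels <- matrix(0L, 200, 200)
  small_labels[3:40, 90:130] <- 1L
  field <- field_image(matrix(10, 200, 200),
                       array(10, c(200, 200, 5)), array(10, c(200, 200, 5)))
  dropped <- crop_cells(field, small_labels, crop_size = 120)
  expect_equal(length(dropped), 0)
  expect_equal(attr(dropped, "dropped")$reason, "border_clip")
})

test_that("best-plane selection maximizes the Sobel-to-raw ratio", {
  n <- 60
  mask <- fx_disc_mask(n, 30, 30, 20)
  sharp <- fx_blob(matrix(10, n, n), 30, 30, 120, 1.5)
  blur1 <- fx_blob(matrix(10, n, n), 30, 30, 120 * 1.5^2 / (1.5^2 + 2^2), sqrt(1.5^2 + 2^2))
  blur2 <- fx_blob(matrix(10, n, n), 30, 30, 120 * 1.5^2 / (1.5^2 + 4^2), sqrt(1.5^2 + 4^2))
  stack <- array(c(blur2, blur1, sharp, blur1, blur2), c(n, n, 5))
  expect_equal(select_best_plane(stack, mask), 3)

  # the winning ratio equals the brute-force Sobel-sum over raw-sum
  ratios <- vapply(1:5, function(p) {
    sum(bf_sobel(stack[, , p])[mask]) / sum(stack[, , p][mask])
  }, 0)
  expect_equal(which.max(ratios), 3)

  # ties break to the lowest index; gain invariance
  same <- array(rep(sharp, 5), c(n, n, 5))
  expect_equal(select_best_plane(same, mask), 1)
  expect_equal(select_best_plane(stack * 7.5, mask), 3)

  # all-zero stack: no valid plane
  expect_true(is.na(select_best_plane(array(0, c(n, n, 5)), mask)))
})

test_that("the G1 gate removes doubled-DNA and pan-nuclear cells", {
  expect_equal(nrow(filter_g1(cells_manifest(list()))), 0)

  set.seed(3)
  n_g1 <- 90; n_sg2 <- 10
  manifest <- tibble::tibble(
    cell_id = 1:(n_g1 + n_sg2 + 1),
    origin_row = 0, origin_col = 0, area = 3000,
    best_red = 3L, best_green = 3L,
    i_nucl_red = 30, i_nucl_green = c(rep(25, n_g1 + n_sg2), 130),
    i_std_red = 10, i_std_green = 10,
    dapi_sum = c(rnorm(n_g1, 3e5, 1.5e4), rnorm(n_sg2, 6e5, 2e4), 3e5))
  gated <- filter_g1(manifest)
  # all 2x-DNA cells rejected, G1 cells overwhelmingly kept
  expect_true(all(!gated$retained[(n_g1 + 1):(n_g1 + n_sg2)]))
  expect_gt(mean(gated$retained[1:n_g1]), 0.9)
  # the pan-nuclear (gamma-H2AX-bright) cell is rejected despite G1 DNA content
  expect_false(gated$retained[n_g1 + n_sg2 + 1])
  expect_false(gated$gate_h2ax[n_g1 + n_sg2 + 1])
  expect_type(attr(gated, "gate"), "list")

  # too few cells: gating refused, everything flagged ungated
  expect_warning(refused <- filter_g1(manifest[1:5, ]), "refused")
  expect_true(all(is.na(refused$retained)))
})

test_that("gating on synthetic fields removes S/G2 and dying cells", {
  sim <- synth_field(synth_spec(field_size_px = c(700L, 700L), n_nuclei = 12,
                                cycle_fractions = c(g1 = 0.6, sg2 = 0.25, dying = 0.15),
                                rng_seed = 57))
  labels <- segment_nuclei(sim$field$dapi)
  cells <- crop_cells(sim$field, labels)
  man <- filter_g1(cells_manifest(cells), min_cells = 5)
  # match each analyzed cell to its planted class
  classes <- vapply(seq_len(nrow(man)), function(i) {
    d <- sqrt((sim$truth$nuclei$row - (man$origin_row[i] + 60))^2 +
              (sim$truth$nuclei$col - (man$origin_col[i] + 60))^2)
    sim$truth$nuclei$cycle_class[which.min(d)]
  }, "")
  if (any(classes == "sg2")) {
    expect_true(all(!man$retained[classes == "sg2"]))
  }
  if (any(classes == "g1")) {
    expect_gt(mean(man$retained[classes == "g1"]), 0.7)
  }
})
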