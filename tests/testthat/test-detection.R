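test_that("local maxima follow the strict-neighbourhood definition", {
  expect_equal(nrow(find_local_maxima(matrix(5, 10, 10))), 0)

  # two unit impulses 10 px apart with radius 3: both reported
  img <- matrix(0, 20, 20); img[5, 5] <- 1; img[5, 15] <- 1
  mx <- find_local_maxima(img, radius = 3)
  expect_equal(sorted_px(mx[, 1:2]), rbind(c(5, 5), c(5, 15)))

  # peaks 100 and 90 at distance 2: only the taller survives
  img2 <- matrix(0, 15, 15); img2[7, 7] <- 100; img2[7, 9] <- 90
  mx2 <- find_local_maxima(img2, radius = 3)
  expect_equal(sorted_px(mx2[, 1:2]), rbind(c(7, 7)))

  # plateau: only the lexicographically smallest pixel is kept
  img3 <- matrix(0, 9, 9); img3[4:5, 4:5] <- 7
  mx3 <- find_local_maxima(img3, radius = 3)
  expect_equal(sorted_px(mx3[, 1:2]), rbind(c(4, 4)))
})

test_that("local maxima match the exhaustive scan on random images", {
  for (seed in 1:25) {
    set.seed(300 + seed)
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    img <- matrix(sample(0:40, nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.2, nr, nc)
    for (radius in c(1, 2, 3)) {
      got <- find_local_maxima(img, mask, radius)
      expect_equal(sorted_px(got[, 1:2]), unname(bf_maxima(img, mask, radius)))
    }
  }
})

test_that("area growing implements the at-least-half rule", {
  # cone decaying by 10 per Chebyshev ring: flood of everything >= 50
  img <- outer(1:15, 1:15, function(r, c) 100 - 10 * pmax(abs(r - 8), abs(c - 8)))
  got <- grow_object(img, c(8, 8))
  expect_equal(sorted_px(as.matrix(got[, 1:2])), bf_flood(img, c(8, 8)))
  expect_true(all(got$intensity >= 50))

  # isolated pixel
  iso <- matrix(0, 7, 7); iso[4, 4] <- 100
  expect_equal(nrow(grow_object(iso, c(4, 4))), 1)

  # boundary case: a neighbour at exactly half the seed is included
  b <- matrix(0, 5, 5); b[3, 3] <- 100; b[3, 4] <- 50
  expect_equal(nrow(grow_object(b, c(3, 3))), 2)
})

test_that("area growing matches the brute-force flood on random images", {
  for (seed in 1:25) {
    set.seed(400 + seed)
    nr <- sample(10:30, 1); nc <- sample(10:30, 1)
    img <- matrix(sample(0:60, nr * nc, replace = TRUE), nr, nc)
    seed_px <- c(sample(2:(nr - 1), 1), sample(2:(nc - 1), 1))
    img[seed_px[1], seed_px[2]] <- 61  # make it a genuine maximum
    got <- grow_object(img, seed_px)
    expect_equal(sorted_px(as.matrix(got[, 1:2])), bf_flood(img, seed_px))
  }
})

test_that("object detection applies area and intensity-floor rules", {
  cfg <- run_config()
  n <- 40
  mask <- fx_disc_mask(n, 20, 20, 15)

  # flat nucleus: no objects
  flat <- matrix(50, n, n)
  cell <- fx_cell(flat, flat, mask)
  expect_equal(nrow(detect_objects(cell, cfg)), 0)

  # an object whose pixels sit at 1.05 x the nucleus mean is excluded by the
  # 1.1 factor, the same object at 1.2 x is kept
  for (fac in c(1.05, 1.2)) {
    base <- matrix(50, n, n)
    i_nucl <- mean(base[mask])
    base[19:21, 19:21] <- fac * i_nucl
    cellf <- fx_cell(base, base, mask)
    cellf$stats$i_nucl_red <- i_nucl  # nucleus mean before the bump, as configured
    found <- detect_objects(cellf, cfg)
    if (fac < cfg$pixel_intensity_factor) {
      expect_equal(nrow(found), 0)
    } else {
      expect_equal(nrow(found), 1)
    }
  }
})

test_that("objects from multiple seeds stay disjoint and respect min area", {
  cfg <- run_config()
  n <- 40
  mask <- matrix(TRUE, n, n)
  img <- matrix(10, n, n)
  img <- fx_blob(img, 12, 12, 200, 1.5)
  img <- fx_blob(img, 12, 20, 150, 1.5)
  img <- fx_blob(img, 28, 28, 180, 1.5)
  img <- round(img)
  cell <- fx_cell(img, img, mask)
  obj <- detect_objects(cell, cfg)
  expect_gte(nrow(obj), 2)
  all_px <- do.call(rbind, lapply(obj$pixels, function(p) p))
  expect_equal(nrow(all_px), nrow(unique(as.data.frame(all_px))))
  expect_true(all(obj$area >= cfg$min_object_area_px))
  # every pixel of every object is at least half its seed and above the floor
  for (i in seq_len(nrow(obj))) {
    px <- obj$pixels[[i]]
    seed_val <- img[obj$seed_row[i], obj$seed_col[i]]
    expect_true(all(img[px] >= 0.5 * seed_val))
    expect_true(all(img[px] >= cfg$pixel_intensity_factor * cell$stats$i_nucl_red))
  }
})

test_that("planted foci are covered by detected objects", {
  sim <- fx_small_sim(seed = 77, n_nuclei = 3, foci_per_cell = 5)
  labels <- segment_nuclei(sim$field$dapi)
  cells <- crop_cells(sim$field, labels)
  expect_gt(length(cells), 0)
  man <- cells_manifest(cells)
  obj <- dplyr::bind_rows(lapply(cells, detect_objects))
  lab <- fx_label_objects(obj, man, list(sim$truth))
  foci_red <- sim$truth$foci[sim$truth$foci$in_red, ]
  # every analyzed nucleus's planted foci should be hit by an object seed
  hit <- 0; tot <- 0
  for (i in seq_len(nrow(man))) {
    d <- sqrt((sim$truth$nuclei$row - (man$origin_row[i] + 60))^2 +
              (sim$truth$nuclei$col - (man$origin_col[i] + 60))^2)
    ni <- sim$truth$nuclei$nucleus[which.min(d)]
    fo <- foci_red[foci_red$nucleus == ni, ]
    oi <- which(obj$cell_id == man$cell_id[i])
    for (j in seq_len(nrow(fo))) {
      tot <- tot + 1
      if (length(oi) && any(sqrt((obj$seed_row[oi] - (fo$row[j] - man$origin_row[i]))^2 +
                                 (obj$seed_col[oi] - (fo$col[j] - man$origin_col[i]))^2) <= 3)) {
        hit <- hit + 1
      }
    }
  }
  expect_gte(hit / tot, 0.9)
  # background signals present but bounded
  expect_lte(nrow(obj), tot + 65 * length(cells))
})
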