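test_that("score histograms bin, conserve and transform correctly", {
  h1 <- oep_histogram(5, bins = 10)
  expect_equal(sum(h1$count), 1)

  mix <- synth_oep_mixture(2000, 150, seed = 7)
  h <- oep_histogram(mix$oep, "log")
  expect_equal(sum(h$count), attr(h, "n_included"))
  expect_equal(attr(h, "n_included"), sum(mix$oep > 0))

  hb <- oep_histogram(mix$oep, "log", bins = 40, smooth = 7)
  expect_true(histogram_bimodality(hb)$bimodal)

  # inverse-log mode keeps only scores above 1
  hi <- oep_histogram(mix$oep, "inverse_log")
  expect_equal(attr(hi, "n_included"), sum(mix$oep > 1))

  expect_error(oep_histogram(numeric(0)), class = "focimetry_empty_histogram")
  expect_error(oep_histogram(c(-1, 0)), class = "focimetry_empty_histogram")
})

test_that("the starting threshold lands between separated components", {
  mix <- synth_oep_mixture(2000, 150, bg_logmean = log(0.5), bg_logsd = 0.4,
                           foci_logmean = log(80), foci_logsd = 0.4, seed = 9)
  est <- estimate_start_threshold(mix$oep)
  # strictly between the component log10-means
  expect_gt(est$log_threshold, log(0.5) / log(10))
  expect_lt(est$log_threshold, log(80) / log(10))
  # the returned value is the mean of the used estimates
  expect_equal(est$log_threshold,
               mean(est$estimates$value[est$estimates$used]))

  # misclassification at the estimate below 5% for >= 4 pooled sds separation
  pred_focus <- mix$oep >= est$threshold
  mis <- mean(pred_focus != (mix$label == "focus"))
  expect_lt(mis, 0.05)
})

test_that("the in-package mixture fit agrees with an independent EM on separated data", {
  mix <- synth_oep_mixture(1500, 400, bg_logmean = 0, bg_logsd = 0.45,
                           foci_logmean = 4, foci_logsd = 0.45, seed = 15)
  logs <- log10(mix$oep)
  v <- focimetry:::log_hist_valley(logs)
  fit <- focimetry:::fit_gmm2(logs, v$valley)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves it in the caller frame
  ref <- mclust::Mclust(logs, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(fit$pr), sort(as.numeric(ref$parameters$pro)),
               tolerance = 0.02)
})

test_that("foci counting is exact and monotone in the threshold", {
  set.seed(8)
  objects <- tibble::tibble(oep = runif(20, 0.1, 100))
  expect_equal(count_foci(objects, max(objects$oep) * 1.01, 10), 0)
  expect_equal(count_foci(objects, min(objects$oep) * 0.99, 10), 2)
  for (t in c(0.5, 1, 5, 20, 80)) {
    expect_equal(count_foci(objects, t, 7), sum(objects$oep >= t) / 7)
  }
  ts <- sort(runif(30, 0, 110))
  counts <- vapply(ts, function(t) count_foci(objects, t, 5), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(count_foci(objects, 1, 0), "positive")
})

test_that("threshold adjustment converges under the trailing-spread rule", {
  mix <- synth_oep_mixture(1500, 120, bg_logmean = log(0.4), bg_logsd = 0.5,
                           foci_logmean = log(70), foci_logsd = 0.5, seed = 21)
  objects <- tibble::tibble(cell_id = rep(1:100, length.out = nrow(mix)),
                            object = seq_len(nrow(mix)), oep = mix$oep,
                            log_oep = log10(mix$oep))
  labels <- dplyr::mutate(objects, is_focus = mix$label == "focus")

  ses <- adjust_threshold(objects, 100, oracle_from_labels(labels))
  expect_s3_class(ses, "foci_session")
  if (ses$converged) {
    last6 <- tail(ses$foci_per_cell, 6)
    expect_lt(sd(last6) / mean(last6), 0.05)
  }
  planted <- sum(mix$label == "focus") / 100
  expect_lt(abs(ses$final_foci_per_cell - planted) / planted, 0.10)

  # tidy/glance views agree with the session state
  td <- tidy(ses)
  expect_equal(nrow(td), ses$iterations)
  expect_equal(glance(ses)$final_foci_per_cell, ses$final_foci_per_cell)
})

test_that("a one-sided rater pushes the threshold monotonically", {
  mix <- synth_oep_mixture(400, 50, seed = 33)
  objects <- tibble::tibble(cell_id = 1, object = seq_len(nrow(mix)),
                            oep = mix$oep, log_oep = log10(mix$oep))
  always_focus <- function(batch) rep(TRUE, nrow(batch))
  ses <- adjust_threshold(objects, 50, always_focus, max_iter = 15)
  expect_true(all(diff(ses$thresholds) < 0))
  expect_false(ses$converged && length(unique(ses$foci_per_cell)) > 1 &&
                 any(diff(ses$thresholds) >= 0))
})

test_that("a noiseless boundary rater steers the threshold to its boundary", {
  # small fixture: the inter-object score gaps around the boundary are wide
  mix <- synth_oep_mixture(60, 15, bg_logmean = log(0.4), bg_logsd = 0.5,
                           foci_logmean = log(60), foci_logsd = 0.5, seed = 41)
  objects <- tibble::tibble(cell_id = rep(1:15, length.out = nrow(mix)),
                            object = seq_len(nrow(mix)), oep = mix$oep,
                            log_oep = log10(mix$oep))
  t_star <- 3.5   # linear-scale boundary inside the valley region
  ses <- adjust_threshold(objects, 15, oracle_threshold(t_star),
                          start = log10(t_star) + 0.8)
  # converges into the inter-object score gap containing the boundary: any
  # point of that gap classifies the objects exactly as the rater does
  logs <- sort(objects$log_oep)
  lower <- max(logs[logs < log10(t_star)])
  upper <- min(logs[logs >= log10(t_star)])
  expect_gt(ses$final_log_threshold, lower)
  expect_lte(ses$final_log_threshold, upper)

  # foci per cell at the final threshold equals the boundary count
  target <- count_foci(objects, t_star, 15)
  expect_equal(ses$final_foci_per_cell, target)
})
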