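test_that("tile ratios are HER2/CK, order-preserving and scale-invariant", {
  m <- make_measurements(ck = c(0.6, 0.5, 0.4), her2 = c(0.3, 0.5, 0.2))
  r <- ratio_per_tile(m)
  expect_equal(r, c(0.5, 1.0, 0.5))
  # a common staining-quality factor on both channels cancels
  m2 <- m
  m2$ck_mean <- m2$ck_mean * 1.7
  m2$her2_mean <- m2$her2_mean * 1.7
  expect_equal(ratio_per_tile(m2), r)
  bad <- make_measurements(ck = c(0.5, 0), her2 = c(0.2, 0.2))
  expect_error(ratio_per_tile(bad), "consistency")
})

test_that("ratio histograms are normalised frequencies over [0, upper]", {
  cfg <- small_config()
  h <- build_histogram(rep(0.7, 100), cfg)
  expect_equal(sum(h$frequencies), 1)
  expect_identical(sum(h$frequencies > 0), 1L)  # single occupied bin
  set.seed(6)
  for (i in 1:5) {
    r <- abs(rnorm(500, 0.6, 0.1))
    h2 <- build_histogram(r, cfg)
    expect_equal(sum(h2$frequencies), 1)
    expect_identical(h2$bin_edges[1], 0)
    # histogram mode within one bin of the true mean
    mode_mid <- h2$mids[which.max(h2$frequencies)]
    expect_lt(abs(mode_mid - 0.6), 2 * diff(h2$bin_edges[1:2]))
  }
  expect_error(build_histogram(rep(0.5, 3), default_config()), "unscorable")
  expect_error(build_histogram(rnorm(100, 0.5, 0.01), cfg, upper = 0.2),
               "below the largest")
})

test_that("Gaussian fit recovers sample moments of a seeded normal sample", {
  set.seed(7)
  x <- rnorm(1e4, 0.6, 0.1)
  x <- x[x > 0]
  h <- build_histogram(x, default_config())
  fit <- fit_gaussian(h)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu - mean(x)), 0.01)
  expect_lt(abs(fit$sigma - sd(x)), 0.01)
  expect_gt(fit$adj_r2, 0.95)
  expect_identical(qc_case(fit, default_config()), "pass")
})

test_that("perfect Gaussian frequencies fit with adj R2 near 1; flat ones fail QC", {
  mids <- seq(0.05, 1.95, by = 0.05)
  freq <- dnorm(mids, 1, 0.2)
  freq <- freq / sum(freq)
  h <- structure(list(bin_edges = c(mids - 0.025, max(mids) + 0.025),
                      mids = mids, frequencies = freq, n_tiles = 1000L),
                 class = "ratio_histogram")
  fit <- fit_gaussian(h)
  expect_gt(fit$adj_r2, 0.99)
  # flat histogram: low adjusted R2, excluded at the 0.5 cut-off
  set.seed(8)
  flat <- runif(2000, 0, 1)
  hf <- build_histogram(flat, default_config())
  ff <- fit_gaussian(hf)
  expect_lt(ff$adj_r2, 0.5)
  expect_identical(qc_case(ff, default_config()), "excluded_low_r2")
})

test_that("QC statuses cover low R2, few tiles and non-convergence", {
  cfg <- default_config()
  # adjusted R2 just below the published exclusions brackets the cut-off
  expect_identical(qc_case(make_fit(1, 0.1, adj_r2 = 0.4837), cfg),
                   "excluded_low_r2")
  expect_identical(qc_case(make_fit(1, 0.1, adj_r2 = 0.95), cfg), "pass")
  expect_identical(
    qc_case(make_fit(NA, NA, converged = FALSE,
                     reason = "fewer than 3 occupied bins"), cfg),
    "excluded_few_tiles")
  expect_identical(
    qc_case(make_fit(NA, NA, converged = FALSE,
                     reason = "fit did not converge"), cfg),
    "excluded_no_convergence")
  # histograms with fewer than 3 occupied bins do not converge
  h <- build_histogram(rep(0.7, 100), small_config())
  expect_identical(qc_case(fit_gaussian(h), cfg), "excluded_few_tiles")
})

test_that("scores are control-normalised ratios with MTP = M * Sigma", {
  ctrl <- make_fit(1.2, 0.25)
  expect_equal(unlist(score_case(ctrl, ctrl)[1, 1:3]),
               c(m_score = 1, sigma_score = 1, mtp_score = 1))
  s <- score_case(make_fit(0.6, 0.1), ctrl)
  expect_equal(s$m_score, 0.5)
  expect_equal(s$sigma_score, 0.4)
  expect_equal(s$mtp_score, 0.2)
  s2 <- score_case(make_fit(1.2 * 0.9, 0.25 * 1.2), ctrl)
  expect_equal(s2$mtp_score, 1.08)
  set.seed(9)
  for (i in 1:10) {
    f <- make_fit(runif(1, 0.1, 2), runif(1, 0.01, 0.5))
    sc <- score_case(f, ctrl)
    expect_identical(sc$mtp_score, sc$m_score * sc$sigma_score)
  }
  expect_error(score_case(make_fit(1, 0.1),
                          make_fit(NA, NA, converged = FALSE)),
               "unscorable")
})

test_that("batch-wide intensity rescaling leaves every score unchanged", {
  set.seed(10)
  ids <- sprintf("case_%02d", 1:4)
  mk <- function(level) {
    make_measurements(ck = rnorm(60, 0.45, 0.01),
                      her2 = pmax(rnorm(60, level, 0.1 * level), 0.001))
  }
  meas <- setNames(lapply(c(0.5, 0.1, 0.25, 0.4), mk), ids)
  records <- data.frame(
    case_id = ids, batch_id = "batch_1",
    role = c("pos_control", "neg_control", "case", "case"),
    nfish_true = c(15, 1.9, 5, 10), ihc_score = c("3+", "0", "2+", "3+"),
    stringsAsFactors = FALSE)
  cfg <- small_config()
  res1 <- score_cohort(meas, records, cfg)
  meas_scaled <- lapply(meas, function(m) {
    m$ck_mean <- m$ck_mean * 0.37
    m$her2_mean <- m$her2_mean * 0.37
    m
  })
  res2 <- score_cohort(meas_scaled, records, cfg)
  cols <- c("m_score", "sigma_score", "mtp_score", "qc_status")
  expect_equal(res1$scores[, cols], res2$scores[, cols], tolerance = 1e-10)
  expect_equal(res1$scores$m_score[1], 1)
  expect_equal(res1$scores$sigma_score[1], 1)
})

test_that("fitted mu tracks the sample mean and M-scores increase with expression", {
  set.seed(11)
  levels <- c(0.1, 0.2, 0.3, 0.45, 0.6)
  ids <- sprintf("case_%02d", seq_along(levels))
  meas <- setNames(lapply(levels, function(lv) {
    make_measurements(ck = rnorm(80, 0.45, 0.005),
                      her2 = pmax(rnorm(80, lv, 0.12 * lv), 0.001))
  }), ids)
  records <- data.frame(
    case_id = ids, batch_id = "batch_1",
    role = c("case", "case", "case", "neg_control", "pos_control"),
    nfish_true = c(4, 6, 8, 1.9, 15),
    ihc_score = c("2+", "2+", "3+", "0", "3+"),
    stringsAsFactors = FALSE)
  res <- score_cohort(meas, records, small_config())
  expect_true(all(res$scores$qc_status == "pass"))
  # oracle equivalence: fitted mean within 2% of the sample ratio mean
  for (id in ids) {
    expect_equal(res$fits[[id]]$mu, mean(res$ratios[[id]]), tolerance = 0.02)
  }
  expect_true(all(diff(res$scores$m_score[match(ids, res$scores$case_id)]) > 0))
})
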