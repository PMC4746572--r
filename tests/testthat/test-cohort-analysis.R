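test_that("FISH classification follows the copy-number cut-offs", {
  expect_identical(classify_fish(c(1.9, 4.4, 9.4)),
                   c("Negative", "Equivocal", "Positive"))
  # closed lower bounds at 4 and 6
  expect_identical(classify_fish(c(3.999, 4, 5.999, 6)),
                   c("Negative", "Equivocal", "Equivocal", "Positive"))
  expect_error(classify_fish(0), "positive")
  expect_error(classify_fish(-1), "positive")
  # the rule partitions (0, Inf): every value gets exactly one class
  set.seed(12)
  x <- exp(runif(100, -2, 4))
  cls <- classify_fish(x)
  expect_true(all(cls %in% c("Negative", "Equivocal", "Positive")))
})

test_that("score correlations recover exact proportionality and power laws", {
  records <- data.frame(case_id = sprintf("c%d", 1:8),
                        nfish_true = seq(2, 9),
                        stringsAsFactors = FALSE)
  x <- records$nfish_true
  scores <- data.frame(case_id = records$case_id,
                       m_score = 2 * x, sigma_score = x^2, mtp_score = 2 * x^3,
                       role = "case", qc_status = "pass",
                       stringsAsFactors = FALSE)
  res <- correlate_scores(scores, records)
  expect_equal(res$rho[res$score_name == "M"], 1)
  expect_equal(res$alpha[res$score_name == "M"], 1)
  expect_equal(res$alpha[res$score_name == "Sigma"], 2)
  expect_equal(res$alpha[res$score_name == "MTP"], 3)
  # invariant to case ordering
  perm <- sample(nrow(scores))
  res2 <- correlate_scores(scores[perm, ], records)
  expect_equal(res, res2)
  # controls and QC failures are excluded
  scores$role[1] <- "pos_control"
  scores$qc_status[2] <- "excluded_low_r2"
  res3 <- correlate_scores(scores, records)
  expect_identical(res3$n_cases, rep(6L, 3))
  expect_error(correlate_scores(scores[1:3, ], records), "fewer than 3")
})

test_that("non-positive values are dropped from the log-log fit with a warning", {
  records <- data.frame(case_id = sprintf("c%d", 1:6), nfish_true = 1:6,
                        stringsAsFactors = FALSE)
  scores <- data.frame(case_id = records$case_id,
                       m_score = c(0, 2, 3, 4, 5, 6),
                       sigma_score = 1:6, mtp_score = 1:6,
                       stringsAsFactors = FALSE)
  expect_warning(res <- correlate_scores(scores, records), "non-positive")
  expect_true(is.finite(res$alpha[res$score_name == "M"]))
})

test_that("scatter export is long-format with per-tile retention flags", {
  set.seed(13)
  ids <- c("a", "b", "c")
  meas <- setNames(lapply(1:3, function(i) {
    make_measurements(ck = runif(100, 0.3, 0.6))
  }), ids)
  records <- data.frame(case_id = ids, batch_id = "b1",
                        role = c("pos_control", "neg_control", "case"),
                        stringsAsFactors = FALSE)
  retained <- lapply(meas, function(m) apply_filters(m, default_config())$retained)
  tab <- scatter_export(meas, records, retained)
  expect_identical(nrow(tab), 300L)
  for (id in ids) {
    sub <- tab[tab$case_id == id, ]
    expect_identical(sub$retained_flag,
                     sub$tile_id %in% retained[[id]]$tile_id)
  }
  # round-trip through CSV preserves values
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(tile_id = "character"))
  expect_equal(back$ck_mean, tab$ck_mean)
  expect_identical(back$tile_id, tab$tile_id)
})

test_that("two well-separated ratio populations are flagged heterogeneous", {
  set.seed(14)
  r <- c(rnorm(1000, 0.3, 0.05), rnorm(1000, 1.0, 0.05))
  het <- flag_heterogeneity(r, default_config())
  expect_true(het$flag)
  expect_equal(sort(het$means), c(0.3, 1.0), tolerance = 0.05)
  # a single normal population is not flagged
  uni <- flag_heterogeneity(rnorm(1000, 0.6, 0.1), default_config())
  expect_false(uni$flag)
  # deterministic: the same input gives the same answer
  het2 <- flag_heterogeneity(r, default_config())
  expect_identical(het$flag, het2$flag)
  expect_equal(het$means, het2$means)
  expect_error(flag_heterogeneity(rnorm(5), default_config()), "unscorable")
})

test_that("a generated two-subclone case carries the bimodal ratio signature", {
  ph <- case_phenotype(0.15, expression_cv = 0.05, n_tiles = 80,
                       epithelial_fraction = 1, artifact_rate = 0,
                       subclone = list(expression_level = 0.55,
                                       expression_cv = 0.05, fraction = 0.5),
                       seed = 21)
  m <- measure_case(generate_case_images(ph, small_imaging()), small_config())
  res <- apply_filters(m, small_config())
  ratios <- ratio_per_tile(res$retained)
  het <- flag_heterogeneity(ratios, small_config())
  expect_true(het$flag)
  # the component means sit near the two subclone ratio levels
  bg <- small_imaging()$background[["her2"]]
  truth <- (c(0.15, 0.55) + bg) / small_imaging()$ck_level
  expect_equal(sort(het$means), sort(truth), tolerance = 0.1)
})
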