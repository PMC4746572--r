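#' Score a cohort from per-tile measurement tables
#'
#' Runs the full per-case analysis on already-measured tiles: case-wise tile
#' filtering, tile-wise HER2/CK ratios, batch-shared ratio histograms, the
#' Gaussian fit with adjusted-R-squared QC, normalisation by the batch's
#' positive control into M-, Sigma- and MTP-scores, and heterogeneity
#' flagging. Cases that cannot be filtered (too few valid tiles) are
#' reported with `qc_status = "excluded_few_tiles"`; if a batch's positive
#' control fails QC the whole batch is marked
#' `"batch_control_failed"`, since the controls are the reference.
#'
#' @param measurements named list of [measure_case()] data frames; names are
#'   case ids.
#' @param records cohort metadata (see [read_cohort_csv()]) covering every
#'   measured case.
#' @param config a [default_config()] list.
#' @return list with `scores` (one row per case: `case_id, batch_id, role,
#'   n_tiles_retained, mu, sigma, adj_r2, m_score, sigma_score, mtp_score,
#'   qc_status, heterogeneity_flag`), `fits`, `histograms`, `ratios`,
#'   `filter_reports` (named lists).
#' @export
score_cohort <- function(measurements, records, config = default_config()) {
  stopifnot(is.list(measurements), !is.null(names(measurements)))
  validate_cohort_records(records)
  ids <- names(measurements)
  missing <- setdiff(ids, records$case_id)
  if (length(missing) > 0) {
    stop("cases absent from the cohort table: ", paste(missing, collapse = ", "))
  }
  meta <- records[match(ids, records$case_id), ]

  filtered <- setNames(vector("list", length(ids)), ids)
  ratios <- setNames(vector("list", length(ids)), ids)
  reports <- setNames(vector("list", length(ids)), ids)
  status <- setNames(rep("pass", length(ids)), ids)
  for (id in ids) {
    res <- tryCatch(apply_filters(measurements[[id]], config),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res$retained) < config$min_tiles) {
      status[id] <- "excluded_few_tiles"
      next
    }
    filtered[[id]] <- res$retained
    reports[[id]] <- res$report
    ratios[[id]] <- ratio_per_tile(res$retained)
  }

  fits <- setNames(vector("list", length(ids)), ids)
  hists <- setNames(vector("list", length(ids)), ids)
  for (b in unique(meta$batch_id)) {
    in_batch <- ids[meta$batch_id == b]
    scorable <- in_batch[status[in_batch] == "pass"]
    if (length(scorable) == 0) next
    upper <- max(unlist(ratios[scorable]))
    for (id in scorable) {
      hists[[id]] <- build_histogram(ratios[[id]], config, upper = upper)
      fits[[id]] <- fit_gaussian(hists[[id]])
      status[id] <- qc_case(fits[[id]], config)
    }
    ctrl <- in_batch[meta$role[match(in_batch, ids)] == "pos_control"]
    if (length(ctrl) != 1 || status[ctrl] != "pass") {
      warning("batch ", b, " unscorable: positive control failed QC")
      status[in_batch[status[in_batch] == "pass"]] <- "batch_control_failed"
    }
  }

  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    fit <- fits[[id]]
    scored <- status[id] == "pass"
    ctrl_id <- ids[meta$batch_id == meta$batch_id[i] &
                     meta$role == "pos_control"]
    sc <- if (scored) score_case(fit, fits[[ctrl_id]], meta$batch_id[i]) else
      data.frame(m_score = NA_real_, sigma_score = NA_real_,
                 mtp_score = NA_real_, batch_id = meta$batch_id[i])
    het <- if (!is.null(ratios[[id]])) {
      flag_heterogeneity(ratios[[id]], config)$flag
    } else NA
    data.frame(
      case_id = id, batch_id = meta$batch_id[i], role = meta$role[i],
      n_tiles_retained = if (is.null(filtered[[id]])) 0L else
        nrow(filtered[[id]]),
      mu = if (is.null(fit)) NA_real_ else fit$mu,
      sigma = if (is.null(fit)) NA_real_ else fit$sigma,
      adj_r2 = if (is.null(fit)) NA_real_ else fit$adj_r2,
      m_score = sc$m_score, sigma_score = sc$sigma_score,
      mtp_score = sc$mtp_score,
      qc_status = unname(status[id]), heterogeneity_flag = het,
      stringsAsFactors = FALSE
    )
  })
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  list(scores = scores, fits = fits, histograms = hists, ratios = ratios,
       filter_reports = reports, retained = filtered)
}

#' Run the tissue-scoring pipeline end to end
#'
#' Reads a cohort table and either per-case tile images (layout of
#' [write_case_images()], one `case_<id>` subdirectory per case) or a
#' pre-computed measurement CSV, scores every case with [score_cohort()],
#' correlates scores against the FISH readout, and writes `scores.csv`,
#' `scatter.csv` and `correlations.csv` into `out_dir`.
#'
#' @param cohort_csv path to the cohort metadata CSV.
#' @param out_dir output directory (created if needed).
#' @param images_dir directory containing `case_<id>` image folders, or
#'   `NULL` when `measurements_csv` is given.
#' @param measurements_csv path to a measurement CSV
#'   ([write_measurements_csv()] format), or `NULL`.
#' @param config a [default_config()] list.
#' @param x_variable cohort column to correlate scores against.
#' @return the [score_cohort()] result, with `correlations` and `scatter`
#'   added, invisibly.
#' @export
run_pipeline <- function(cohort_csv, out_dir,
                         images_dir = NULL, measurements_csv = NULL,
                         config = default_config(),
                         x_variable = "nfish_true") {
  records <- read_cohort_csv(cohort_csv)
  if (is.null(images_dir) == is.null(measurements_csv)) {
    stop("provide exactly one of images_dir or measurements_csv")
  }
  if (!is.null(images_dir)) {
    case_dirs <- file.path(images_dir, records$case_id)
    found <- dir.exists(case_dirs)
    if (!any(found)) stop("no case image directories under ", images_dir)
    measurements <- setNames(
      lapply(case_dirs[found], function(d) {
        measure_case(read_case_images(d), config)
      }),
      records$case_id[found]
    )
  } else {
    measurements <- read_measurements_csv(measurements_csv)
  }

  result <- score_cohort(measurements, records, config)
  if (all(result$scores$qc_status != "pass")) {
    stop("no scorable cases in the cohort")
  }
  result$scatter <- scatter_export(measurements, records,
                                   retained = result$retained)
  result$correlations <- tryCatch(
    correlate_scores(result$scores, records, x_variable),
    error = function(e) {
      warning("correlation skipped: ", conditionMessage(e))
      NULL
    })

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
  write.csv(result$scatter, file.path(out_dir, "scatter.csv"),
            row.names = FALSE)
  if (!is.null(result$correlations)) {
    write.csv(result$correlations, file.path(out_dir, "correlations.csv"),
              row.names = FALSE)
  }
  invisible(result)
}
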