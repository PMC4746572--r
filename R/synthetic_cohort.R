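#' Default map from gene copy number to expression level
#'
#' A monotone power law `scale * (n_fish / n_ref)^exponent` standing in for
#' the unknown biological relation between *HER2* copy number and membrane
#' protein expression. It is a simulation choice, not an inferred law: the
#' exponent and scale are configuration, and any strictly monotone map can be
#' substituted in [cohort_spec()].
#'
#' @param n_fish copy-number value(s), > 0.
#' @param exponent power-law exponent, default 1.
#' @param scale expression level at `n_fish = n_ref`, default 0.6 (keeps
#'   simulated intensities comfortably inside the \[0, 1\] camera range).
#' @param n_ref reference copy number, default 15.
#' @return expression level(s).
#' @export
default_expression_map <- function(n_fish, exponent = 1, scale = 0.6,
                                   n_ref = 15) {
  stopifnot(all(n_fish > 0))
  scale * (n_fish / n_ref)^exponent
}

#' Specification of a synthetic cohort
#'
#' Describes a batched cohort of simulated cases: every batch carries exactly
#' one positive (IHC 3+) and one negative (IHC 0) control in addition to its
#' study cases, mirroring batch-wise staining with on-slide references.
#' Ground-truth copy-number values of the study cases are spread evenly over
#' `nfish_range`; the positive control sits at the top of the range, the
#' negative control at the bottom.
#'
#' @param n_cases total number of cases including controls; >= `batch_size`.
#' @param batch_size cases per batch (>= 3: two controls plus at least one
#'   study case). The last batch may be smaller but not below 3.
#' @param nfish_range range of ground-truth copy-number values; default
#'   `c(1.9, 15)`.
#' @param expression_map monotone function from copy number to
#'   expression level; default [default_expression_map()].
#' @param expression_cv_map function from expression level to tile-to-tile
#'   CV; default [default_expression_cv()].
#' @param tiles_per_case tiles generated per case.
#' @param epithelial_fraction fraction of tiles containing epithelium.
#' @param artifact_rate saturating-artifact rate per tile.
#' @param stain_sd SD of the log-normal case-level staining-quality factor
#'   (0 disables staining variation).
#' @param imaging an [imaging_params()] list.
#' @param seed integer master seed; all case seeds derive from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 25L,
                        batch_size = 5L,
                        nfish_range = c(1.9, 15),
                        expression_map = default_expression_map,
                        expression_cv_map = default_expression_cv,
                        tiles_per_case = 100L,
                        epithelial_fraction = 0.7,
                        artifact_rate = 0.02,
                        stain_sd = 0.1,
                        imaging = imaging_params(),
                        seed = 1L) {
  stopifnot(n_cases >= batch_size, batch_size >= 3,
            length(nfish_range) == 2, all(nfish_range > 0),
            nfish_range[1] < nfish_range[2],
            is.function(expression_map), is.function(expression_cv_map),
            tiles_per_case >= 1, stain_sd >= 0,
            inherits(imaging, "imaging_params"))
  n_batches <- ceiling(n_cases / batch_size)
  sizes <- rep(batch_size, n_batches)
  sizes[n_batches] <- n_cases - batch_size * (n_batches - 1)
  if (sizes[n_batches] < 3) {
    stop("configuration error: last batch has ", sizes[n_batches],
         " cases; every batch needs two controls plus at least one case")
  }
  structure(list(n_cases = as.integer(n_cases),
                 batch_size = as.integer(batch_size),
                 batch_sizes = as.integer(sizes),
                 nfish_range = nfish_range,
                 expression_map = expression_map,
                 expression_cv_map = expression_cv_map,
                 tiles_per_case = as.integer(tiles_per_case),
                 epithelial_fraction = epithelial_fraction,
                 artifact_rate = artifact_rate,
                 stain_sd = stain_sd,
                 imaging = imaging,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Assigns batches, control roles and ground-truth copy-number values, draws
#' per-case staining factors, and builds one [case_phenotype()] per case.
#' The companion metadata table has one row per case with
#' `case_id, batch_id, role, nfish_true, her2_cep17, ihc_score, fish_class`
#' plus the ground-truth `expression_level` and `stain_factor`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `phenotypes` (named list of [case_phenotype()]) and
#'   `records` (data frame).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_batches <- length(spec$batch_sizes)
  roles <- unlist(lapply(spec$batch_sizes, function(sz) {
    c("pos_control", "neg_control", rep("case", sz - 2))
  }))
  batch_id <- rep(paste0("batch_", seq_len(n_batches)), spec$batch_sizes)
  n_study <- sum(roles == "case")

  withr::with_seed(mix_seed(spec$seed, 0L), {
    nfish_study <- seq(spec$nfish_range[1], spec$nfish_range[2],
                       length.out = n_study)
    nfish_study <- sample(nfish_study)  # spread levels across batches
    nfish <- numeric(length(roles))
    nfish[roles == "pos_control"] <- spec$nfish_range[2]
    nfish[roles == "neg_control"] <- spec$nfish_range[1]
    nfish[roles == "case"] <- nfish_study
    cep17 <- pmin(pmax(rnorm(length(roles), 2, 0.15), 1.5), 3)
    stain <- if (spec$stain_sd > 0) {
      exp(rnorm(length(roles), 0, spec$stain_sd))
    } else rep(1, length(roles))
  })

  fish_class <- classify_fish(nfish)
  ihc <- ifelse(roles == "pos_control", "3+",
         ifelse(roles == "neg_control", "0",
                c(Negative = "1+", Equivocal = "2+",
                  Positive = "3+")[fish_class]))
  expr <- spec$expression_map(nfish)
  if (is.unsorted(expr[order(nfish)])) {
    stop("expression_map must be monotone non-decreasing in copy number")
  }
  case_id <- sprintf("case_%02d", seq_along(roles))

  phenotypes <- lapply(seq_along(roles), function(i) {
    case_phenotype(
      expression_level = expr[i],
      expression_cv = spec$expression_cv_map(expr[i]),
      epithelial_fraction = spec$epithelial_fraction,
      n_tiles = spec$tiles_per_case,
      artifact_rate = spec$artifact_rate,
      stain_factor = stain[i],
      seed = mix_seed(spec$seed, i)
    )
  })
  names(phenotypes) <- case_id

  records <- data.frame(
    case_id = case_id, batch_id = batch_id, role = roles,
    nfish_true = nfish, her2_cep17 = nfish / cep17, ihc_score = unname(ihc),
    fish_class = unname(fish_class),
    expression_level = expr, stain_factor = stain,
    stringsAsFactors = FALSE
  )
  validate_cohort_records(records)
  list(phenotypes = phenotypes, records = records)
}

validate_cohort_records <- function(records) {
  for (b in unique(records$batch_id)) {
    sub <- records[records$batch_id == b, ]
    if (sum(sub$role == "pos_control") != 1 ||
        sum(sub$role == "neg_control") != 1) {
      stop("configuration error: batch ", b,
           " must contain exactly one positive and one negative control")
    }
  }
  invisible(records)
}
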