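CHANNELS <- c("dapi", "ck", "her2")

#' Write the tiles of a case as per-channel TIFFs
#'
#' One 16-bit (or 8-bit) grayscale TIFF per channel per tile, named
#' `tile_<row>_<col>_<channel>.tif`, into `case_dir`. Intensities in
#' \[0, 1\] are quantised to the chosen bit depth on write.
#'
#' @param tiles list of [tile_image()] objects.
#' @param case_dir output directory (created if needed).
#' @param bits 8 or 16.
#' @return `case_dir`, invisibly.
#' @export
write_case_images <- function(tiles, case_dir, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  for (tl in tiles) {
    stopifnot(inherits(tl, "tile_image"))
    for (ch in CHANNELS) {
      path <- file.path(case_dir, sprintf("tile_%d_%d_%s.tif",
                                          tl$tile_id[1], tl$tile_id[2], ch))
      tiff::writeTIFF(tl[[ch]], path, bits.per.sample = bits)
    }
  }
  invisible(case_dir)
}

#' Read the tiles of a case from per-channel TIFFs
#'
#' Expects the layout written by [write_case_images()]:
#' `tile_<row>_<col>_<channel>.tif` with channels `dapi`, `ck`, `her2`.
#' 8/16-bit images are returned normalised to \[0, 1\] (the `tiff` package
#' divides by the dtype maximum on read). Tiles are sorted by `(row, col)`;
#' a tile missing any channel is a hard error naming the tile.
#'
#' @param case_dir directory of one case.
#' @return list of [tile_image()] objects.
#' @export
read_case_images <- function(case_dir) {
  files <- list.files(case_dir, pattern = "^tile_\\d+_\\d+_(dapi|ck|her2)\\.tif$")
  if (length(files) == 0) stop("no tile TIFFs found in ", case_dir)
  parts <- regmatches(files, regexec("^tile_(\\d+)_(\\d+)_(dapi|ck|her2)\\.tif$",
                                     files))
  info <- data.frame(
    file = files,
    row = as.integer(vapply(parts, `[`, "", 2)),
    col = as.integer(vapply(parts, `[`, "", 3)),
    channel = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  keys <- unique(info[, c("row", "col")])
  keys <- keys[order(keys$row, keys$col), , drop = FALSE]
  lapply(seq_len(nrow(keys)), function(i) {
    r <- keys$row[i]; c0 <- keys$col[i]
    chans <- lapply(CHANNELS, function(ch) {
      f <- info$file[info$row == r & info$col == c0 & info$channel == ch]
      if (length(f) != 1) {
        stop(sprintf("tile (%d, %d): missing or duplicated %s channel",
                     r, c0, ch))
      }
      img <- tiff::readTIFF(file.path(case_dir, f))
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    })
    tile_image(chans[[1]], chans[[2]], chans[[3]], tile_id = c(r, c0))
  })
}

#' Write / read a cohort metadata table
#'
#' Column contract: `case_id, batch_id, role, nfish_true, ihc_score` (roles
#' in `{case, pos_control, neg_control}`), plus any extra columns such as
#' `her2_cep17` or ground-truth fields.
#'
#' @param records cohort data frame.
#' @param path CSV path.
#' @return `read_cohort_csv` returns the validated data frame.
#' @export
write_cohort_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  records <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("case_id", "batch_id", "role", "nfish_true", "ihc_score")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(records$role), c("case", "pos_control", "neg_control"))
  if (length(bad) > 0) stop("unknown role(s): ", paste(bad, collapse = ", "))
  validate_cohort_records(records)
  records
}

#' Write / read per-tile measurement tables
#'
#' The pipeline's interchange format: one CSV holding the [measure_case()]
#' tables of all cases, distinguished by a `case_id` column, so that the
#' scoring stages can run without access to the images.
#'
#' @param measurements named list of [measure_case()] data frames.
#' @param path CSV path.
#' @return `read_measurements_csv` returns a named list of data frames.
#' @export
write_measurements_csv <- function(measurements, path) {
  stopifnot(is.list(measurements), !is.null(names(measurements)))
  rows <- lapply(names(measurements), function(id) {
    cbind(case_id = id, measurements[[id]], stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(tile_id = "character"))
  needed <- c("case_id", "tile_id", "ck_mean", "her2_mean", "roi_area", "valid")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "))
  }
  split_df <- split(df[, setdiff(names(df), "case_id")], df$case_id)
  lapply(split_df, function(d) { rownames(d) <- NULL; d })
}
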