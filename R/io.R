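# On-disk cohort and feature-matrix layout.
#
# EEG cohorts: per subject one raw array container `sub-<id>_epochs.bin`
# (IEEE-754 doubles, little-endian, row-major trials x samples as documented
# in cohort.json) plus a sidecar `sub-<id>_trials.csv` with columns
# subject_id, trial_index, energy, rating. fMRI cohorts: per subject a 4-D
# BOLD NIfTI, a 3-D mask NIfTI (nonzero = in-brain) and a trials CSV with
# onset_s, energy, rating. `cohort.json` records mode, shapes and timing.
# Numeric CSV fields are written with 17 significant digits so round trips
# are exact.

#' Write a cohort to a directory
#'
#' @param cohort A `trial_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trial_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$subjects)
  header <- list(mode = cohort$mode, subjects = ids,
                 byte_order = "little", dtype = "float64")
  if (cohort$mode == "eeg") {
    header$fs <- cohort$fs
    header$t0_offset_ms <- cohort$t0_offset_ms
    header$shape <- lapply(cohort$subjects, function(s) dim(s$epochs))
    header$layout <- "row-major (trial fastest dimension last)"
    for (id in ids) {
      s <- cohort$subjects[[id]]
      con <- file(file.path(dir, paste0("sub-", id, "_epochs.bin")), "wb")
      # row-major: write each trial's samples contiguously
      writeBin(as.numeric(t(s$epochs)), con, size = 8, endian = "little")
      close(con)
      write_trials_csv(s$meta, file.path(dir, paste0("sub-", id, "_trials.csv")))
    }
  } else {
    header$tr_s <- cohort$tr_s
    for (id in ids) {
      s <- cohort$subjects[[id]]
      RNifti::writeNifti(s$bold, file.path(dir, paste0("sub-", id, "_bold.nii")),
                         datatype = "double")
      RNifti::writeNifti(s$mask + 0,
                         file.path(dir, paste0("sub-", id, "_mask.nii")),
                         datatype = "double")
      meta <- s$meta
      meta$onset_s <- s$onsets_s
      write_trials_csv(meta, file.path(dir, paste0("sub-", id, "_trials.csv")))
    }
  }
  jsonlite::write_json(header, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

write_trials_csv <- function(meta, path) {
  out <- meta
  for (col in intersect(c("rating", "onset_s"), names(out)))
    out[[col]] <- format_exact(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

read_trials_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$rating <- as.numeric(tr$rating)
  if ("onset_s" %in% names(tr)) tr$onset_s <- as.numeric(tr$onset_s)
  tr
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `trial_cohort` (without ground truth, which is an in-memory
#'   property of generated cohorts).
#' @export
read_cohort <- function(dir) {
  hpath <- file.path(dir, "cohort.json")
  if (!file.exists(hpath)) stop("not a cohort directory: missing cohort.json")
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  ids <- header$subjects
  expect <- if (header$mode == "eeg") {
    c(paste0("sub-", ids, "_epochs.bin"), paste0("sub-", ids, "_trials.csv"))
  } else {
    c(paste0("sub-", ids, "_bold.nii"), paste0("sub-", ids, "_mask.nii"),
      paste0("sub-", ids, "_trials.csv"))
  }
  missing <- expect[!file.exists(file.path(dir, expect))]
  if (length(missing) > 0L)
    stop("cohort directory is missing: ", paste(missing, collapse = ", "))

  subjects <- list()
  if (header$mode == "eeg") {
    for (id in ids) {
      shp <- unlist(header$shape[[id]])
      con <- file(file.path(dir, paste0("sub-", id, "_epochs.bin")), "rb")
      raw <- readBin(con, "double", n = prod(shp), size = 8, endian = "little")
      close(con)
      epochs <- t(matrix(raw, nrow = shp[2], ncol = shp[1]))
      meta <- read_trials_csv(file.path(dir, paste0("sub-", id, "_trials.csv")))
      subjects[[id]] <- list(epochs = epochs, meta = meta)
    }
    structure(list(mode = "eeg", fs = header$fs,
                   t0_offset_ms = header$t0_offset_ms, subjects = subjects,
                   config = NULL, ground_truth = NULL),
              class = "trial_cohort")
  } else {
    for (id in ids) {
      bold <- array(as.numeric(
        RNifti::readNifti(file.path(dir, paste0("sub-", id, "_bold.nii")))),
        dim = dim(RNifti::readNifti(file.path(dir, paste0("sub-", id, "_bold.nii")))))
      mask <- RNifti::readNifti(file.path(dir, paste0("sub-", id, "_mask.nii")))
      mask <- array(as.integer(mask != 0), dim = dim(mask))
      tr <- read_trials_csv(file.path(dir, paste0("sub-", id, "_trials.csv")))
      subjects[[id]] <- list(
        bold = bold, mask = mask, onsets_s = tr$onset_s, tr_s = header$tr_s,
        meta = tr[, c("subject_id", "trial_index", "energy", "rating")])
    }
    structure(list(mode = "fmri", tr_s = header$tr_s, subjects = subjects,
                   config = NULL, ground_truth = NULL),
              class = "trial_cohort")
  }
}

#' Serialize a feature matrix
#'
#' Writes `values.bin` (doubles, little-endian, column-major trials x
#' features) plus a JSON sidecar holding coordinates, phases, metadata, grid
#' and retained group means. The round trip through [read_feature_matrix()]
#' is lossless.
#'
#' @param fm A `feature_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  stopifnot(inherits(fm, "feature_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "values.bin"), "wb")
  writeBin(as.numeric(fm$values), con, size = 8, endian = "little")
  close(con)
  gm <- fm$group_means
  if (!is.null(gm)) {
    # binary container keeps group means exact (JSON would round the last ulp)
    con <- file(file.path(dir, "group_means.bin"), "wb")
    writeBin(c(as.numeric(gm$feature_means), as.numeric(gm$rating_means)),
             con, size = 8, endian = "little")
    close(con)
  }
  side <- list(
    dims = dim(fm$values), coords = fm$coords, phase = fm$phase,
    meta = fm$meta, grid = fm$grid, normalized = fm$normalized,
    byte_order = "little", layout = "column-major",
    group_means = if (is.null(gm)) NULL else list(
      energies = rownames(gm$feature_means))
  )
  jsonlite::write_json(side, file.path(dir, "features.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param dir Directory produced by [write_feature_matrix()].
#' @return The reconstructed `feature_matrix`.
#' @export
read_feature_matrix <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "features.json"),
                              simplifyVector = TRUE)
  dims <- unlist(side$dims)
  con <- file(file.path(dir, "values.bin"), "rb")
  values <- matrix(readBin(con, "double", n = prod(dims), size = 8,
                           endian = "little"),
                   nrow = dims[1], ncol = dims[2])
  close(con)
  grid <- side$grid
  grid$dims <- unlist(grid$dims)
  gm <- NULL
  if (!is.null(side$group_means) && length(side$group_means) > 0) {
    energies <- unlist(side$group_means$energies)
    ng <- length(energies)
    con <- file(file.path(dir, "group_means.bin"), "rb")
    raw <- readBin(con, "double", n = ng * (dims[2] + 1L), size = 8,
                   endian = "little")
    close(con)
    fmz <- matrix(raw[seq_len(ng * dims[2])], nrow = ng,
                  dimnames = list(energies, NULL))
    gm <- list(feature_means = fmz,
               rating_means = stats::setNames(raw[ng * dims[2] + seq_len(ng)],
                                              energies))
  }
  new_feature_matrix(values, as.data.frame(side$coords), side$phase,
                     as.data.frame(side$meta), grid,
                     normalized = isTRUE(side$normalized), group_means = gm)
}
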