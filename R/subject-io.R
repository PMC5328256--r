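#' Write / load a subject directory
#'
#' One directory per subject with fixed filenames: `fat.nii.gz`,
#' `water.nii.gz`, `body.nii.gz`, `bone.nii.gz`, `bodyparts.nii.gz` and
#' `landmarks.json` (plus `covariates.json` when covariates are present).
#'
#' @param subject A `wb_subject`.
#' @param dir Subject directory (created if missing).
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(subject$fat, file.path(dir, "fat.nii.gz"))
  write_volume(subject$water, file.path(dir, "water.nii.gz"))
  write_volume(subject$body, file.path(dir, "body.nii.gz"))
  write_volume(subject$bone, file.path(dir, "bone.nii.gz"))
  write_volume(subject$bodyparts, file.path(dir, "bodyparts.nii.gz"))
  lm <- as.list(as.data.frame(t(subject$landmarks)))
  jsonlite::write_json(lm, file.path(dir, "landmarks.json"),
                       auto_unbox = FALSE, digits = NA)
  if (length(subject$covariates))
    jsonlite::write_json(subject$covariates,
                         file.path(dir, "covariates.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_subject
#' @param id Subject identifier (defaults to the directory name).
#' @return `load_subject` returns a validated `wb_subject`.
#' @export
load_subject <- function(dir, id = basename(dir)) {
  need <- c("fat.nii.gz", "water.nii.gz", "body.nii.gz", "bone.nii.gz",
            "bodyparts.nii.gz", "landmarks.json")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing subject file '", f, "' in ", dir)
  fat <- read_volume(file.path(dir, "fat.nii.gz"))
  water <- read_volume(file.path(dir, "water.nii.gz"))
  body <- read_volume(file.path(dir, "body.nii.gz"), type = "mask")
  bone <- read_volume(file.path(dir, "bone.nii.gz"), type = "mask")
  parts <- read_volume(file.path(dir, "bodyparts.nii.gz"), type = "label")
  for (nm in c("water", "body", "bone", "parts")) {
    v <- get(nm)
    if (!same_geometry(fat, v)) {
      ga <- vol_geometry(fat); gb <- vol_geometry(v)
      bad <- c(paste0("dim axis ", which(ga$dim != gb$dim)),
               paste0("spacing axis ", which(abs(ga$spacing - gb$spacing) > 1e-6)),
               paste0("origin axis ", which(abs(ga$origin - gb$origin) > 1e-6)))
      stop("geometry mismatch between fat and ", nm, " (",
           paste(bad, collapse = "; "), ")")
    }
  }
  lm_raw <- jsonlite::read_json(file.path(dir, "landmarks.json"),
                                simplifyVector = TRUE)
  missing_names <- setdiff(landmark_names(), names(lm_raw))
  if (length(missing_names))
    stop("landmark file lacks: ", paste(missing_names, collapse = ", "))
  lm <- do.call(rbind, lm_raw[landmark_names()])
  cov_file <- file.path(dir, "covariates.json")
  covs <- if (file.exists(cov_file))
    jsonlite::read_json(cov_file, simplifyVector = TRUE) else list()
  subject_record(fat, water, body, bone, parts, lm, covs, id = id)
}

#' Load a cohort directory
#'
#' A cohort is a directory of per-subject subdirectories plus an optional
#' `covariates.csv` keyed by subject id.
#'
#' @param dir Cohort directory.
#' @return List with `subjects` and `covariates` (data.frame or NULL).
#' @export
load_cohort <- function(dir) {
  subdirs <- list.dirs(dir, recursive = FALSE)
  subjects <- lapply(subdirs, load_subject)
  cov_file <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cov_file))
    utils::read.csv(cov_file, stringsAsFactors = FALSE) else NULL
  list(subjects = subjects, covariates = covariates)
}
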