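# Readers/writers for the pipeline's interchange formats: NIfTI-1 volumes
# (via RNifti), ECG CSV with a JSON sidecar for the sampling rate,
# phenotype TSV tables, and provenance JSON.

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param data 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm isotropic voxel edge length, mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, voxel_mm = 1) {
  nd <- length(dim(data))
  stop_if(!(nd %in% c(3, 4)), "expected a 3D or 4D array")
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), if (nd == 4) 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii`/`.nii.gz` file.
#' @return list: `data` (plain array), `voxel_mm`, `dim`.
#' @export
read_volume <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("malformed NIfTI file '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  pd <- RNifti::pixdim(img)
  list(data = as.array(img), voxel_mm = pd[1], dim = dim(img))
}

#' Write an ECG recording as CSV plus a JSON sidecar
#'
#' One column per lead (header = lead names); the sampling rate goes into
#' `<path>.json`.
#'
#' @param rec an `ecg_recording`.
#' @param path output CSV path.
#' @export
write_ecg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ecg_recording"))
  utils::write.csv(as.data.frame(rec$samples), path, row.names = FALSE)
  jsonlite::write_json(list(sampling_hz = rec$sampling_hz),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an ECG recording from CSV (+ JSON sidecar)
#'
#' Leads may appear in any order; they are normalised to the canonical
#' 12-lead order. Unknown lead names are an error.
#'
#' @param path CSV path written by [write_ecg_csv()] (sidecar
#'   `<path>.json` must exist).
#' @return an `ecg_recording`.
#' @export
read_ecg_csv <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  side <- paste0(path, ".json")
  stop_if(!file.exists(side), sprintf("missing sidecar: %s", side))
  meta <- jsonlite::read_json(side)
  df <- utils::read.csv(path, check.names = FALSE)
  unknown <- setdiff(names(df), LEAD_NAMES)
  stop_if(length(unknown) > 0,
          paste("unknown lead name(s):", paste(unknown, collapse = ", ")))
  stop_if(!all(LEAD_NAMES %in% names(df)),
          paste("missing lead(s):",
                paste(setdiff(LEAD_NAMES, names(df)), collapse = ", ")))
  ecg_recording(as.matrix(df[LEAD_NAMES]), sampling_hz = meta$sampling_hz)
}

.pheno_required <- function() c("subject_id", "age", "gender", names(NEO_DIRECTIONS))

#' Write a phenotype table as TSV
#' @param pheno data.frame with at least subject_id, age, gender and the
#'   six NEO columns.
#' @param path output TSV path.
#' @export
write_phenotypes <- function(pheno, path) {
  missing_cols <- setdiff(.pheno_required(), names(pheno))
  stop_if(length(missing_cols) > 0,
          paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  write.table(pheno, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Validates the required columns and rejects duplicate subject ids.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  stop_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- read.delim(path, check.names = FALSE)
  missing_cols <- setdiff(.pheno_required(), names(df))
  stop_if(length(missing_cols) > 0,
          paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  dup <- duplicated(df$subject_id)
  stop_if(any(dup), paste("duplicate subject id(s):",
                          paste(unique(df$subject_id[dup]), collapse = ", ")))
  df
}

#' Write a provenance record for a pipeline run
#'
#' Records the full configuration and seeds as JSON, sufficient to
#' reproduce deterministic stages bit-identically.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seed integer seed(s) used.
#' @export
write_provenance <- function(path, config, seed) {
  jsonlite::write_json(list(config = config, seed = seed,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Voxel indices to world coordinates (mm)
#'
#' With no affine the world origin sits at voxel (1, 1, 1) and axes scale
#' by the voxel size.
#'
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param voxel_mm voxel edge length.
#' @return n x 3 matrix of mm coordinates.
#' @export
ijk_to_world <- function(ijk, voxel_mm = 1) {
  (as.matrix(ijk) - 1) * voxel_mm
}
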