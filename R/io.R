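# Volumetric and tabular I/O. Dose and masks travel as NIfTI rasters plus a
# JSON sidecar naming the dose unit and structure labels; DVH curves travel
# as CSV. The core always computes in Gy — unit conversion happens here.

#' Write a plan's volumes to disk
#'
#' One NIfTI volume for the dose, one per structure mask, plus a
#' `bundle.json` sidecar recording the dose unit, voxel spacing,
#' prescription and structure labels.
#'
#' @param plan a [plan_record()].
#' @param dir output directory (created if needed).
#' @param dose_unit `"Gy"` (default) or `"cGy"` for the written dose volume.
#' @return The directory path, invisibly.
#' @export
write_volume_bundle <- function(plan, dir, dose_unit = "Gy") {
  stopifnot(inherits(plan, "plan_record"))
  dose_unit <- match.arg(dose_unit, c("Gy", "cGy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- if (dose_unit == "cGy") 100 else 1
  RNifti::writeNifti(
    RNifti::asNifti(plan$dose$values * scale, pixdim = plan$dose$spacing),
    file.path(dir, "dose.nii.gz")
  )
  for (nm in names(plan$structures)) {
    s <- plan$structures[[nm]]
    RNifti::writeNifti(
      RNifti::asNifti(array(as.integer(s$mask), dim(s$mask)),
                      pixdim = plan$dose$spacing),
      file.path(dir, paste0("mask_", nm, ".nii.gz"))
    )
  }
  sidecar <- list(
    patient_id = plan$patient_id, modality = plan$modality,
    prescription_dose_gy = plan$prescription_dose,
    dose_unit = dose_unit, spacing_mm = plan$dose$spacing,
    structures = names(plan$structures)
  )
  jsonlite::write_json(sidecar, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a plan's volumes from disk
#'
#' Inverse of [write_volume_bundle()]: reads the sidecar, converts the dose
#' to Gy per the declared unit, validates every mask against the dose grid
#' shape and requires PTV and body masks to be present.
#'
#' @param dir bundle directory.
#' @return A [plan_record()].
#' @export
read_volume_bundle <- function(dir) {
  sidecar_path <- file.path(dir, "bundle.json")
  if (!file.exists(sidecar_path)) stop("no bundle.json sidecar in ", dir)
  sc <- jsonlite::fromJSON(sidecar_path)
  if (is.null(sc$dose_unit) || !sc$dose_unit %in% c("Gy", "cGy")) {
    stop("sidecar must name dose_unit as 'Gy' or 'cGy'")
  }
  vol <- RNifti::readNifti(file.path(dir, "dose.nii.gz"))
  scale <- if (sc$dose_unit == "cGy") 0.01 else 1
  dose <- dose_grid(array(as.numeric(vol) * scale, dim(vol)),
                    spacing = as.numeric(sc$spacing_mm))
  labels <- as.character(sc$structures)
  if (!all(c("ptv", "body") %in% labels)) {
    stop("bundle must contain 'ptv' and 'body' masks; found: ",
         paste(labels, collapse = ", "))
  }
  structures <- lapply(labels, function(nm) {
    m <- RNifti::readNifti(file.path(dir, paste0("mask_", nm, ".nii.gz")))
    m <- array(as.numeric(m), dim(m))
    if (!identical(dim(m), dim(dose$values))) {
      stop(sprintf("mask '%s' shape does not match the dose grid", nm))
    }
    structure_mask(m > 0.5, nm)
  })
  names(structures) <- labels
  plan_record(
    patient_id = sc$patient_id %||% "unknown",
    modality = sc$modality %||% "CRT",
    prescription_dose = sc$prescription_dose_gy,
    dose = dose, structures = structures
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read DVH curves as CSV
#'
#' Schema: columns `structure`, `dose_gy`, `cumulative_pct`,
#' `differential_cc`, one row per bin edge (the differential cell of the
#' last edge of each curve is 0). A `dose_cgy` column is accepted on read
#' and converted. Files whose cumulative column rises anywhere are rejected.
#'
#' @param curves a [dvh_curve()] or list of them.
#' @param path CSV file path.
#' @return `read_dvh_csv` returns a named list of [dvh_curve()] objects.
#' @export
write_dvh_csv <- function(curves, path) {
  if (inherits(curves, "dvh_curve")) curves <- list(curves)
  rows <- lapply(curves, function(cv) {
    data.frame(
      structure = cv$structure,
      dose_gy = cv$bin_edges,
      cumulative_pct = cv$cumulative,
      differential_cc = c(cv$differential, 0)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dvh_csv
#' @export
read_dvh_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("dose_cgy" %in% names(df) && !"dose_gy" %in% names(df)) {
    df$dose_gy <- df$dose_cgy / 100
  }
  need <- c("structure", "dose_gy", "cumulative_pct", "differential_cc")
  if (!all(need %in% names(df))) {
    stop("DVH CSV needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$structure), function(sub) {
    sub <- sub[order(sub$dose_gy), ]
    if (any(diff(sub$cumulative_pct) > 1e-9)) {
      stop(sprintf("cumulative column rises for structure '%s'",
                   sub$structure[1]))
    }
    n <- nrow(sub)
    dvh_curve(sub$dose_gy, sub$differential_cc[-n], sub$structure[1])
  })
  out[unique(df$structure)]
}
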