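#' Construct a voxel dose grid
#'
#' A `dose_grid` holds a 3-D array of absorbed dose per voxel together with
#' the voxel spacing. Dose is always stored in Gy internally; use
#' [read_volume_bundle()] for files recorded in cGy.
#'
#' @param values numeric 3-D array of per-voxel dose in Gy; all values must
#'   be non-negative and finite.
#' @param spacing numeric vector of length 3, voxel edge lengths in mm.
#' @return An object of class `dose_grid` with fields `values`, `spacing`
#'   (mm) and `shape` (voxel counts per axis).
#' @examples
#' g <- dose_grid(array(60, c(4, 4, 2)), spacing = c(2, 2, 2))
#' voxel_volume_cc(g)  # 0.008 cm^3
#' @export
dose_grid <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("dose values must be a 3-D array")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    stop("dose values must be finite and non-missing")
  }
  if (any(values < 0)) stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive voxel edge lengths in mm")
  }
  structure(
    list(values = values, spacing = spacing, shape = dim(values)),
    class = "dose_grid"
  )
}

#' Voxel volume of a dose grid in cm^3
#' @param grid a [dose_grid()].
#' @return Single voxel volume in cm^3 (product of spacings / 1000).
#' @export
voxel_volume_cc <- function(grid) {
  stopifnot(inherits(grid, "dose_grid"))
  prod(grid$spacing) / 1000
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %s voxels @ %s mm, dose range [%.3f, %.3f] Gy\n",
    paste(x$shape, collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Construct a binary structure mask
#'
#' A `structure_mask` marks the voxels belonging to one anatomical structure
#' on the same grid as a [dose_grid()]. Membership is whole-voxel (decided at
#' voxel centers); there is no partial-volume weighting.
#'
#' @param mask logical 3-D array; `TRUE` inside the structure.
#' @param label structure role, one of `"ptv"`, `"lung"`, `"heart"`,
#'   `"cord"`, `"body"` or another free-text label.
#' @return An object of class `structure_mask` with fields `mask`, `label`
#'   and `grid_shape`.
#' @export
structure_mask <- function(mask, label) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("mask must be a 3-D array")
  }
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1))) stop("mask must be logical or 0/1")
    mask <- array(as.logical(mask), dim(mask))
  }
  if (anyNA(mask)) stop("mask must not contain missing values")
  label <- as.character(label)[1]
  structure(
    list(mask = mask, label = label, grid_shape = dim(mask)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf(
    "<structure_mask> '%s': %d voxels on %s grid\n",
    x$label, sum(x$mask), paste(x$grid_shape, collapse = "x")
  ))
  invisible(x)
}

# Shared precondition: grid and mask describe the same voxel lattice and the
# structure is non-empty. Every DVH-facing operation funnels through this.
check_geometry <- function(dose, structure, require_nonempty = TRUE) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structure, "structure_mask"))
  if (!identical(as.integer(dose$shape), as.integer(structure$grid_shape))) {
    stop(sprintf(
      "geometry mismatch: dose grid is %s but structure '%s' is %s",
      paste(dose$shape, collapse = "x"), structure$label,
      paste(structure$grid_shape, collapse = "x")
    ))
  }
  if (require_nonempty && !any(structure$mask)) {
    stop(sprintf("structure '%s' is empty", structure$label))
  }
  invisible(TRUE)
}

#' Construct a treatment-plan record
#'
#' Bundles one composite dose distribution with its structure set, modality
#' tag and prescription dose. A valid plan carries exactly one `ptv` and one
#' `body` mask; organs at risk are optional.
#'
#' @param patient_id identifier for the (phantom) patient.
#' @param modality one of `"CRT"`, `"IMRT"`, `"VMAT"`.
#' @param prescription_dose prescription dose in Gy (> 0).
#' @param dose a [dose_grid()] (composite over phases for multi-phase plans).
#' @param structures named list of [structure_mask()] objects; names must
#'   equal the mask labels.
#' @return An object of class `plan_record`.
#' @export
plan_record <- function(patient_id, modality, prescription_dose, dose,
                        structures) {
  modality <- match.arg(toupper(modality), c("CRT", "IMRT", "VMAT"))
  prescription_dose <- as.numeric(prescription_dose)
  if (!is.finite(prescription_dose) || prescription_dose <= 0) {
    stop("prescription_dose must be a positive dose in Gy")
  }
  stopifnot(inherits(dose, "dose_grid"), is.list(structures))
  labels <- vapply(structures, function(s) s$label, character(1))
  if (is.null(names(structures))) names(structures) <- labels
  if (!identical(unname(names(structures)), unname(labels))) {
    stop("structure list names must match mask labels")
  }
  for (s in structures) check_geometry(dose, s, require_nonempty = FALSE)
  if (sum(labels == "ptv") != 1L) stop("plan must have exactly one 'ptv' mask")
  if (sum(labels == "body") != 1L) stop("plan must have exactly one 'body' mask")
  structure(
    list(
      patient_id = as.character(patient_id), modality = modality,
      prescription_dose = prescription_dose, dose = dose,
      structures = structures
    ),
    class = "plan_record"
  )
}

#' @export
print.plan_record <- function(x, ...) {
  cat(sprintf(
    "<plan_record> patient %s, %s, %.4g Gy prescription, structures: %s\n",
    x$patient_id, x$modality, x$prescription_dose,
    paste(names(x$structures), collapse = ", ")
  ))
  invisible(x)
}

#' Healthy tissue outside the target
#'
#' Body-minus-PTV mask: body voxels not belonging to the PTV, used for the
#' low-dose-bath metrics of normal tissue.
#'
#' @param plan a [plan_record()].
#' @return A [structure_mask()] labelled `"body_minus_ptv"`.
#' @export
body_minus_ptv <- function(plan) {
  stopifnot(inherits(plan, "plan_record"))
  m <- plan$structures$body$mask & !plan$structures$ptv$mask
  structure_mask(m, "body_minus_ptv")
}
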