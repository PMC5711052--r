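#' Default radiobiological parameter registry
#'
#' Niemierko-model constants per structure: the dose-volume-effect exponent
#' `a` (negative for tumors), the half-effect dose (`d50`: TCD50 for tumors,
#' TD50/5 for normal tissue, in Gy), the normalized response slope `gamma50`,
#' and, where published, an alternative slope in percent per Gy (`slope50`,
#' recorded and selectable via `slope_mode`, not used by default). Values
#' follow the Niemierko/Goitein and Okunieff et al. parameterizations for
#' esophageal tumor (mapped to the `ptv` row), brainstem, spinal cord, lung
#' and heart.
#'
#' @return Data frame with columns `structure`, `kind` (`"tumor"` or
#'   `"normal"`), `a`, `d50`, `gamma50`, `slope50`.
#' @export
default_radiobio_params <- function() {
  data.frame(
    structure = c("ptv", "brainstem", "cord", "lung", "heart"),
    kind = c("tumor", "normal", "normal", "normal", "normal"),
    a = c(-13, 7, 13, 1, 3),
    d50 = c(49.09, 65, 66.5, 24.5, 48),
    gamma50 = c(2.16, 3, 3, 2, 3),
    slope50 = c(4.14, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

validate_radiobio_params <- function(registry) {
  stopifnot(is.data.frame(registry))
  need <- c("structure", "kind", "a", "d50", "gamma50")
  if (!all(need %in% names(registry))) {
    stop("radiobiology registry needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(registry$kind %in% c("tumor", "normal"))) {
    stop("registry 'kind' must be 'tumor' or 'normal'")
  }
  if (any(registry$gamma50 <= 0) || any(registry$d50 <= 0) || any(registry$a == 0)) {
    stop("registry requires gamma50 > 0, d50 > 0 and a != 0")
  }
  if (anyDuplicated(registry$structure)) stop("duplicate structures in registry")
  invisible(registry)
}

#' Read / write a radiobiological parameter registry
#'
#' Human-editable JSON serialization of the registry data frame; the shipped
#' default file reproduces [default_radiobio_params()].
#'
#' @param path file path.
#' @param registry registry data frame (for writing).
#' @return `read_radiobio_params` returns the validated registry data frame.
#' @export
read_radiobio_params <- function(path) {
  reg <- jsonlite::fromJSON(path)
  if (!"slope50" %in% names(reg)) reg$slope50 <- NA_real_
  validate_radiobio_params(as.data.frame(reg))
}

#' @rdname read_radiobio_params
#' @export
write_radiobio_params <- function(registry, path) {
  validate_radiobio_params(registry)
  jsonlite::write_json(registry, path, dataframe = "columns", pretty = TRUE,
                       na = "null", auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Generalized equivalent uniform dose (gEUD)
#'
#' The volume-weighted power mean of the dose distribution,
#' EUD = (sum_i v_i D_i^a)^(1/a) with weights v_i summing to 1. With a = 1
#' this is the mean dose; large positive a approaches Dmax (serial organs),
#' large negative a approaches Dmin (tumors, where a cold spot dominates).
#'
#' For a < 0 doses are floored at `floor_gy` first (with a warning when any
#' voxel is affected): a single zero-dose voxel would otherwise annihilate a
#' tumor EUD through the negative power.
#'
#' @param doses per-voxel doses in Gy, or bin doses when `volumes` is given.
#' @param a dose-volume-effect exponent (nonzero).
#' @param volumes optional relative volumes (e.g. differential-DVH bin
#'   volumes); defaults to equal weights.
#' @param floor_gy dose floor in Gy applied before negative-a power means.
#' @param structure label used in error messages.
#' @return EUD in Gy; always between the minimum and maximum dose.
#' @examples
#' eud(c(30, 40), a = 2)   # 35.355 Gy
#' eud(c(10, 20, 30), a = 1)  # 20 Gy, the mean
#' @export
eud <- function(doses, a, volumes = NULL, floor_gy = 0.01,
                structure = "structure") {
  doses <- as.numeric(doses)
  if (length(doses) == 0L) stop("at least one dose value is required")
  if (anyNA(doses) || any(doses < 0)) stop("doses must be non-negative")
  a <- as.numeric(a)
  if (!is.finite(a) || a == 0) stop("exponent a must be nonzero")
  if (is.null(volumes)) {
    volumes <- rep(1 / length(doses), length(doses))
  } else {
    volumes <- as.numeric(volumes)
    if (length(volumes) != length(doses) || any(volumes < 0) || sum(volumes) <= 0) {
      stop("volumes must be non-negative weights matching doses")
    }
    keep <- volumes > 0
    doses <- doses[keep]
    volumes <- volumes[keep] / sum(volumes[keep])
  }
  if (a < 0) {
    if (any(doses < floor_gy)) {
      warning(sprintf(
        "flooring %d dose value(s) below %.3g Gy in '%s' before negative-exponent EUD",
        sum(doses < floor_gy), floor_gy, structure
      ))
      doses <- pmax(doses, floor_gy)
    }
    if (any(doses <= 0)) {
      stop(sprintf("non-positive doses in '%s' with a < 0 after flooring", structure))
    }
  }
  # log-space power mean for numerical stability at large |a|
  pos <- doses > 0
  if (!any(pos)) return(0)
  w <- volumes[pos] / sum(volumes)
  m <- max(doses[pos])
  s <- sum(w * exp(a * (log(doses[pos]) - log(m))))
  if (a > 0) {
    m * s^(1 / a)
  } else {
    # with a < 0 all doses are positive and every weight contributes
    m * s^(1 / a)
  }
}

#' EUD from a differential DVH
#'
#' Bin-midpoint evaluation of [eud()]; agrees with the voxel path to within
#' the DVH bin tolerance.
#'
#' @param dvh a [dvh_curve()].
#' @inheritParams eud
#' @export
eud_from_dvh <- function(dvh, a, floor_gy = 0.01) {
  stopifnot(inherits(dvh, "dvh_curve"))
  mids <- (dvh$bin_edges[-1] + dvh$bin_edges[-length(dvh$bin_edges)]) / 2
  eud(mids, a, volumes = dvh$differential, floor_gy = floor_gy,
      structure = dvh$structure)
}

sigmoid_response <- function(eud_gy, d50, gamma) {
  ifelse(eud_gy <= 0, 0, 1 / (1 + (d50 / eud_gy)^(4 * gamma)))
}

resolve_gamma <- function(params, slope_mode) {
  slope_mode <- match.arg(slope_mode, c("gamma50", "slope50"))
  if (slope_mode == "slope50") {
    if (is.na(params$slope50)) {
      stop(sprintf("no slope50 value recorded for '%s'", params$structure))
    }
    params$slope50
  } else {
    params$gamma50
  }
}

#' Tumor control probability (Niemierko model)
#'
#' TCP = 1 / (1 + (TCD50 / EUD)^(4 gamma50)): a sigmoid in EUD with midpoint
#' at the 50-percent-control dose TCD50 and slope set by gamma50. Strictly
#' increasing in EUD; EUD = 0 maps to 0.
#'
#' @param eud_gy equivalent uniform dose in Gy (>= 0).
#' @param params single registry row with `kind == "tumor"` (see
#'   [default_radiobio_params()]).
#' @param slope_mode `"gamma50"` (default) uses the normalized slope;
#'   `"slope50"` substitutes the percent-per-Gy slope value where recorded.
#' @return Probability in `[0, 1)`.
#' @export
tcp <- function(eud_gy, params, slope_mode = "gamma50") {
  params <- as.list(params)
  if (!identical(params$kind, "tumor")) {
    stop(sprintf("TCP requires tumor parameters; '%s' is kind '%s'",
                 params$structure, params$kind))
  }
  if (any(eud_gy < 0)) stop("EUD must be >= 0")
  sigmoid_response(eud_gy, params$d50, resolve_gamma(params, slope_mode))
}

#' Normal-tissue complication probability (Niemierko model)
#'
#' NTCP = 1 / (1 + (TD50 / EUD)^(4 gamma50)), the same sigmoid as [tcp()]
#' with the 50-percent-complication dose TD50 as midpoint.
#'
#' @inheritParams tcp
#' @param params single registry row with `kind == "normal"`.
#' @return Probability in `[0, 1)`.
#' @export
ntcp <- function(eud_gy, params, slope_mode = "gamma50") {
  params <- as.list(params)
  if (!identical(params$kind, "normal")) {
    stop(sprintf("NTCP requires normal-tissue parameters; '%s' is kind '%s'",
                 params$structure, params$kind))
  }
  if (any(eud_gy < 0)) stop("EUD must be >= 0")
  sigmoid_response(eud_gy, params$d50, resolve_gamma(params, slope_mode))
}

#' Radiobiological indices for one plan
#'
#' Per structure, computes the EUD from that structure's voxel doses with
#' its own exponent, then TCP for the target and NTCP for organs at risk.
#' Structures without a registry entry are reported unevaluable (NA) rather
#' than dropped.
#'
#' @param plan a [plan_record()].
#' @param registry parameter registry (default [default_radiobio_params()]).
#' @param structures structure labels to evaluate; defaults to the plan's
#'   structures that radiobiological models cover.
#' @inheritParams tcp
#' @return Data frame with columns `structure`, `eud_gy`, `probability`
#'   (TCP for the target, NTCP otherwise), `model`, `evaluable`.
#' @export
plan_radiobiology <- function(plan, registry = default_radiobio_params(),
                              structures = NULL, slope_mode = "gamma50") {
  stopifnot(inherits(plan, "plan_record"))
  validate_radiobio_params(registry)
  if (is.null(structures)) {
    structures <- intersect(names(plan$structures), c("ptv", "cord", "lung", "heart", "brainstem"))
  }
  rows <- lapply(structures, function(lab) {
    s <- plan$structures[[lab]]
    if (is.null(s) || !any(s$mask)) {
      return(data.frame(structure = lab, eud_gy = NA_real_,
                        probability = NA_real_, model = NA_character_,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    p <- registry[registry$structure == lab, , drop = FALSE]
    if (nrow(p) != 1L) {
      return(data.frame(structure = lab, eud_gy = NA_real_,
                        probability = NA_real_, model = NA_character_,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    e <- eud(plan$dose$values[s$mask], a = p$a, structure = lab)
    if (p$kind == "tumor") {
      data.frame(structure = lab, eud_gy = e,
                 probability = tcp(e, p, slope_mode), model = "TCP",
                 evaluable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(structure = lab, eud_gy = e,
                 probability = ntcp(e, p, slope_mode), model = "NTCP",
                 evaluable = TRUE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
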