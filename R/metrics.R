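#' Full plan-quality metric panel for one plan
#'
#' Evaluates the standard comparison panel from a plan's dose grid and
#' structures:
#' \itemize{
#'   \item PTV: Dmax, Dmean, V93, V95 (volumes at 93 / 95 percent of the
#'     prescription dose), CI, CN, HI, EUD, TCP;
#'   \item spinal cord: Dmax, Dmean, EUD, NTCP;
#'   \item lung: Dmean, V5, V10, V13, V20, V30, NTCP;
#'   \item heart: Dmean, V25, V30, V50, EUD, NTCP;
#'   \item body-minus-PTV (healthy tissue): V5, V10, V15.
#' }
#' Doses are in Gy, VxGy volumes in percent of the structure volume,
#' CI/CN/HI and probabilities unitless (HI in percent). Rows whose structure
#' is missing from the plan are emitted with `available = FALSE` and NA
#' values, never silently dropped.
#'
#' @param plan a [plan_record()].
#' @param bin_width DVH bin width in Gy.
#' @param isodose_fraction fraction of the prescription dose defining the
#'   conformity isodose (default 1, i.e. the prescription dose itself).
#' @param registry radiobiological parameter registry.
#' @param slope_mode see [tcp()].
#' @return Data frame with columns `structure`, `metric`, `value`, `unit`,
#'   `available`.
#' @export
metric_panel <- function(plan, bin_width = 0.05, isodose_fraction = 1,
                         registry = default_radiobio_params(),
                         slope_mode = "gamma50") {
  stopifnot(inherits(plan, "plan_record"))
  if (!is.finite(isodose_fraction) || isodose_fraction <= 0) {
    stop("isodose_fraction must be > 0")
  }
  rx <- plan$prescription_dose
  rb <- plan_radiobiology(plan, registry, slope_mode = slope_mode)
  rb_get <- function(lab, col) {
    v <- rb[rb$structure == lab, col]
    if (length(v) == 1L) v else NA_real_
  }

  rows <- list()
  add <- function(structure, metric, value, unit, available = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, metric = metric,
      value = as.numeric(value), unit = unit, available = available,
      stringsAsFactors = FALSE
    )
  }
  absent <- function(structure, metrics, units) {
    for (i in seq_along(metrics)) add(structure, metrics[i], NA_real_, units[i], FALSE)
  }

  ptv <- plan$structures$ptv
  body <- plan$structures$body
  ptv_dvh <- compute_dvh(plan$dose, ptv, bin_width)
  pm <- dose_point_metrics(plan$dose, ptv)
  conf <- conformity_measures(plan$dose, ptv, body, isodose_fraction * rx)
  add("ptv", "Dmax", pm$Dmax, "Gy")
  add("ptv", "Dmean", pm$Dmean, "Gy")
  add("ptv", "V93", volume_at_dose(ptv_dvh, 0.93 * rx), "%")
  add("ptv", "V95", volume_at_dose(ptv_dvh, 0.95 * rx), "%")
  add("ptv", "CI", conf$CI, "")
  add("ptv", "CN", conf$CN, "")
  add("ptv", "HI", homogeneity_index(ptv_dvh, rx), "%")
  add("ptv", "EUD", rb_get("ptv", "eud_gy"), "Gy")
  add("ptv", "TCP", rb_get("ptv", "probability"), "")

  if (!is.null(plan$structures$cord) && any(plan$structures$cord$mask)) {
    cm <- dose_point_metrics(plan$dose, plan$structures$cord)
    add("cord", "Dmax", cm$Dmax, "Gy")
    add("cord", "Dmean", cm$Dmean, "Gy")
    add("cord", "EUD", rb_get("cord", "eud_gy"), "Gy")
    add("cord", "NTCP", rb_get("cord", "probability"), "")
  } else {
    absent("cord", c("Dmax", "Dmean", "EUD", "NTCP"), c("Gy", "Gy", "Gy", ""))
  }

  if (!is.null(plan$structures$lung) && any(plan$structures$lung$mask)) {
    ld <- compute_dvh(plan$dose, plan$structures$lung, bin_width)
    lm <- dose_point_metrics(plan$dose, plan$structures$lung)
    add("lung", "Dmean", lm$Dmean, "Gy")
    for (v in c(5, 10, 13, 20, 30)) {
      add("lung", paste0("V", v), volume_at_dose(ld, v), "%")
    }
    add("lung", "NTCP", rb_get("lung", "probability"), "")
  } else {
    absent("lung", c("Dmean", "V5", "V10", "V13", "V20", "V30", "NTCP"),
           c("Gy", "%", "%", "%", "%", "%", ""))
  }

  if (!is.null(plan$structures$heart) && any(plan$structures$heart$mask)) {
    hd <- compute_dvh(plan$dose, plan$structures$heart, bin_width)
    hm <- dose_point_metrics(plan$dose, plan$structures$heart)
    add("heart", "Dmean", hm$Dmean, "Gy")
    for (v in c(25, 30, 50)) {
      add("heart", paste0("V", v), volume_at_dose(hd, v), "%")
    }
    add("heart", "EUD", rb_get("heart", "eud_gy"), "Gy")
    add("heart", "NTCP", rb_get("heart", "probability"), "")
  } else {
    absent("heart", c("Dmean", "V25", "V30", "V50", "EUD", "NTCP"),
           c("Gy", "%", "%", "%", "Gy", ""))
  }

  bmp <- body_minus_ptv(plan)
  if (any(bmp$mask)) {
    bd <- compute_dvh(plan$dose, bmp, bin_width)
    for (v in c(5, 10, 15)) {
      add("body_minus_ptv", paste0("V", v), volume_at_dose(bd, v), "%")
    }
  } else {
    absent("body_minus_ptv", c("V5", "V10", "V15"), c("%", "%", "%"))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
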