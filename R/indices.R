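#' Homogeneity index of a target DVH
#'
#' HI = (D1 - D99) / prescription x 100: the spread between the near-maximum
#' and near-minimum target dose as a percentage of the prescription. Smaller
#' is more homogeneous; a uniformly irradiated target has HI = 0.
#'
#' @param dvh target [dvh_curve()] (normally the PTV).
#' @param prescription prescription dose in Gy (> 0).
#' @return HI in percent (>= 0 for any valid cumulative curve).
#' @export
homogeneity_index <- function(dvh, prescription) {
  stopifnot(inherits(dvh, "dvh_curve"))
  prescription <- as.numeric(prescription)
  if (!is.finite(prescription) || prescription <= 0) {
    stop("prescription must be a positive dose in Gy")
  }
  d <- dose_at_volume(dvh, c(1, 99))
  (d[1] - d[2]) / prescription * 100
}

#' Conformity index, conformation number and target coverage
#'
#' Counts, at a given isodose level, the target volume inside the isodose
#' (V_T_Pi), the body volume inside the isodose (V_Pi) and the target volume
#' (V_T), then forms
#' CI = V_T_Pi / V_Pi, coverage = V_T_Pi / V_T and CN = coverage x CI.
#' All three lie in `[0, 1]`; 1 is ideal. V_Pi is restricted to body voxels,
#' and the target is intersected with the body. A plan whose isodose region
#' is empty gets CI = CN = 0 rather than an error, so cohort runs never
#' abort on an underdosed plan.
#'
#' @param dose a [dose_grid()].
#' @param target target [structure_mask()] (non-empty).
#' @param body body [structure_mask()].
#' @param isodose isodose level in Gy (> 0); conventionally the prescription
#'   dose, or a fraction of it (see `isodose_fraction` in [metric_panel()]).
#' @return Named list `CI`, `CN`, `coverage`, plus the raw volumes
#'   `V_T`, `V_Pi`, `V_T_Pi` in cm^3.
#' @export
conformity_measures <- function(dose, target, body, isodose) {
  check_geometry(dose, target)
  check_geometry(dose, body)
  isodose <- as.numeric(isodose)
  if (!is.finite(isodose) || isodose <= 0) stop("isodose must be > 0")
  tmask <- target$mask & body$mask
  if (!any(tmask)) stop(sprintf("target '%s' is empty within the body", target$label))
  hot <- dose$values >= isodose
  vox <- voxel_volume_cc(dose)
  v_t <- sum(tmask) * vox
  v_pi <- sum(hot & body$mask) * vox
  v_t_pi <- sum(hot & tmask) * vox
  ci <- if (v_pi > 0) v_t_pi / v_pi else 0
  coverage <- v_t_pi / v_t
  cn <- if (v_pi > 0) coverage * ci else 0
  list(CI = ci, CN = cn, coverage = coverage,
       V_T = v_t, V_Pi = v_pi, V_T_Pi = v_t_pi)
}

# Clinical plan-acceptance rules: observed metric, limit, and comparator.
# "less than" limits are strict; the coverage requirement is >=.
compliance_rules <- function() {
  data.frame(
    rule = c("ptv_v95", "cord_dmax", "lung_v20", "lung_v30"),
    structure = c("ptv", "cord", "lung", "lung"),
    metric = c("V95", "Dmax", "V20", "V30"),
    limit = c(95, 45, 30, 20),
    comparator = c(">=", "<", "<", "<"),
    unit = c("%", "Gy", "%", "%"),
    stringsAsFactors = FALSE
  )
}

#' Check a plan's metric panel against clinical acceptance constraints
#'
#' Rules: at least 95 percent of the PTV covered by 95 percent of the
#' prescription dose (PTV V95 >= 95 percent), spinal cord maximum dose
#' strictly below 45 Gy, lung V20 strictly below 30 percent and lung V30
#' strictly below 20 percent. Rules are evaluated independently; a rule
#' whose metric is missing from the panel is reported unevaluable and fails
#' the overall check.
#'
#' @param panel metric table from [metric_panel()] (columns `structure`,
#'   `metric`, `value`).
#' @return Data frame with one row per rule (`rule`, `observed`, `limit`,
#'   `comparator`, `pass`) and attribute `overall` (logical conjunction).
#' @export
check_compliance <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("structure", "metric", "value") %in% names(panel)))
  rules <- compliance_rules()
  observed <- mapply(function(s, m) {
    v <- panel$value[panel$structure == s & panel$metric == m]
    if (length(v) == 1L && is.finite(v)) v else NA_real_
  }, rules$structure, rules$metric)
  pass <- ifelse(
    is.na(observed), NA,
    ifelse(rules$comparator == ">=", observed >= rules$limit, observed < rules$limit)
  )
  out <- cbind(rules, observed = as.numeric(observed), pass = pass)
  attr(out, "overall") <- all(!is.na(pass)) && all(pass)
  out
}
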