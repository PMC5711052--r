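#' Mean and standard deviation of a metric sample
#'
#' Cohort cells are reported as mean plus/minus SD with the n-1 denominator;
#' a single observation gets SD 0 so degenerate cohorts still summarize.
#'
#' @param values numeric vector, at least one value.
#' @return Named list `mean`, `sd`, `n`.
#' @export
summarize_metric <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("cannot summarize an empty sample")
  list(
    mean = mean(values),
    sd = if (length(values) >= 2L) stats::sd(values) else 0,
    n = length(values)
  )
}

check_groups <- function(values, group) {
  group <- as.factor(group)
  stopifnot(length(values) == length(group))
  sizes <- table(group)
  if (length(sizes) < 2L) stop("at least two groups are required")
  if (any(sizes < 2L)) stop("every group needs at least two values")
  group
}

#' Classical one-way fixed-effects ANOVA
#'
#' F and p for equality of group means, with (k - 1, N - k) degrees of
#' freedom. The degenerate case of zero variance everywhere with equal
#' means (groups that are permutations of the same values included) reports
#' F = 0, p = 1 instead of an indeterminate ratio.
#'
#' @param values numeric observations.
#' @param group group membership, same length as `values`.
#' @return Named list `F`, `p`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(values, group) {
  group <- check_groups(values, group)
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  ssb <- tab[["Sum Sq"]][1]
  # no between-group variance (identical or permuted groups, or all-constant
  # data): report F = 0, p = 1 rather than a 0/0 artifact
  if (!is.finite(f) || ssb <= 1e-12 * max(sum(values^2), .Machine$double.xmin)) {
    f <- 0
    p <- 1
  }
  list(F = f, p = p,
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2])
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-adjusted p-values for all group pairs after a one-way
#' layout; unequal group sizes use the Tukey-Kramer variant. When the pooled
#' within-group variance is exactly zero the adjusted p is 1 for pairs with
#' equal means and 0 otherwise.
#'
#' @inheritParams one_way_anova
#' @return Data frame with columns `group1`, `group2`, `diff`, `p_adj`.
#' @export
tukey_hsd <- function(values, group) {
  group <- check_groups(values, group)
  fit <- stats::aov(values ~ group)
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  means <- tapply(values, group, mean)
  levs <- levels(group)
  pairs <- utils::combn(levs, 2)
  if (mse <= 0 || !is.finite(mse)) {
    diffs <- means[pairs[2, ]] - means[pairs[1, ]]
    return(data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      diff = as.numeric(diffs),
      p_adj = ifelse(abs(diffs) < 1e-12, 1, 0),
      stringsAsFactors = FALSE
    ))
  }
  tk <- stats::TukeyHSD(fit)$group
  # TukeyHSD labels rows "B-A" in level order; align to our pair order
  key <- paste(pairs[2, ], pairs[1, ], sep = "-")
  tk <- tk[key, , drop = FALSE]
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = as.numeric(tk[, "diff"]),
    p_adj = as.numeric(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
}

#' Cohort comparison report across modalities
#'
#' Assembles, for every metric of the plan panel, the per-modality mean and
#' SD over patients, the one-way ANOVA F and p across the three modalities,
#' and the Tukey-adjusted p for each modality pair, plus significance flags
#' at p < 0.05. By default pairwise tests are always emitted; with
#' `gate_on_anova = TRUE` they are reported only when the overall ANOVA is
#' significant (the stricter post hoc convention).
#'
#' @param cohort list of [plan_record()] objects covering every patient in
#'   all three modalities, or `NULL` when `panels` is given.
#' @param panels optional precomputed per-plan panels: data frame with
#'   columns `patient_id`, `modality`, `structure`, `metric`, `value`
#'   (as produced by [evaluate_cohort()]); avoids recomputing DVHs.
#' @param gate_on_anova logical; gate pairwise p-values on ANOVA p < 0.05.
#' @param alpha significance threshold (default 0.05).
#' @param ... passed to [metric_panel()] when panels are computed here.
#' @return Data frame (class `comparison_report`) with one row per metric:
#'   per-modality `*_mean`/`*_sd`, `anova_F`, `anova_p`, pairwise
#'   `p_crt_imrt`, `p_crt_vmat`, `p_imrt_vmat` and matching `sig_*` flags.
#' @export
build_report <- function(cohort = NULL, panels = NULL, gate_on_anova = FALSE,
                         alpha = 0.05, ...) {
  if (is.null(panels)) {
    stopifnot(is.list(cohort), length(cohort) > 0)
    panels <- do.call(rbind, lapply(cohort, function(p) {
      cbind(patient_id = p$patient_id, modality = p$modality,
            metric_panel(p, ...))
    }))
  }
  need <- c("patient_id", "modality", "structure", "metric", "value")
  stopifnot(all(need %in% names(panels)))
  modalities <- c("CRT", "IMRT", "VMAT")

  # balance check: every patient must appear under every modality
  pts <- unique(panels$patient_id)
  missing <- list()
  for (pt in pts) {
    for (m in modalities) {
      if (!any(panels$patient_id == pt & panels$modality == m)) {
        missing[[length(missing) + 1L]] <- sprintf("(%s, %s)", pt, m)
      }
    }
  }
  if (length(missing) > 0) {
    stop("unbalanced cohort; missing plans: ", paste(unlist(missing), collapse = ", "))
  }

  keys <- unique(panels[, c("structure", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- keys$structure[i]; m <- keys$metric[i]
    sub <- panels[panels$structure == s & panels$metric == m, ]
    out <- data.frame(structure = s, metric = m, stringsAsFactors = FALSE)
    vals <- list()
    for (mod in modalities) {
      v <- sub$value[sub$modality == mod]
      v <- v[!is.na(v)]
      vals[[mod]] <- v
      sm <- if (length(v) > 0) summarize_metric(v) else list(mean = NA_real_, sd = NA_real_)
      out[[paste0(tolower(mod), "_mean")]] <- sm$mean
      out[[paste0(tolower(mod), "_sd")]] <- sm$sd
    }
    testable <- all(vapply(vals, length, integer(1)) >= 2L)
    if (testable) {
      values <- unlist(vals, use.names = FALSE)
      group <- rep(modalities, times = vapply(vals, length, integer(1)))
      an <- one_way_anova(values, group)
      tk <- tukey_hsd(values, group)
      p_of <- function(a, b) {
        tk$p_adj[(tk$group1 == a & tk$group2 == b) | (tk$group1 == b & tk$group2 == a)]
      }
      gated <- gate_on_anova && an$p >= alpha
      out$anova_F <- an$F
      out$anova_p <- an$p
      out$p_crt_imrt <- if (gated) NA_real_ else p_of("CRT", "IMRT")
      out$p_crt_vmat <- if (gated) NA_real_ else p_of("CRT", "VMAT")
      out$p_imrt_vmat <- if (gated) NA_real_ else p_of("IMRT", "VMAT")
    } else {
      out$anova_F <- NA_real_
      out$anova_p <- NA_real_
      out$p_crt_imrt <- NA_real_
      out$p_crt_vmat <- NA_real_
      out$p_imrt_vmat <- NA_real_
    }
    out
  })
  report <- do.call(rbind, rows)
  report$sig_anova <- !is.na(report$anova_p) & report$anova_p < alpha
  report$sig_crt_imrt <- !is.na(report$p_crt_imrt) & report$p_crt_imrt < alpha
  report$sig_crt_vmat <- !is.na(report$p_crt_vmat) & report$p_crt_vmat < alpha
  report$sig_imrt_vmat <- !is.na(report$p_imrt_vmat) & report$p_imrt_vmat < alpha
  class(report) <- c("comparison_report", "data.frame")
  report
}

#' Format a comparison report as markdown
#'
#' Mirrors the usual published layout: one row per metric, per-modality
#' "mean +/- SD" cells and the three pairwise p-value columns. Doses are
#' printed in cGy (the tabulation convention), volumes in percent.
#'
#' @param report a [build_report()] result.
#' @param panels the per-plan panel table (provides units).
#' @param digits decimals for mean/SD cells (default 1).
#' @return Character vector of markdown lines.
#' @export
format_report_markdown <- function(report, panels = NULL, digits = 1) {
  unit_of <- function(s, m) {
    if (is.null(panels) || !"unit" %in% names(panels)) return("")
    u <- unique(panels$unit[panels$structure == s & panels$metric == m])
    if (length(u) == 1) u else ""
  }
  cell <- function(mean, sd, unit) {
    if (is.na(mean)) return("-")
    scale <- if (identical(unit, "Gy")) 100 else 1  # print doses in cGy
    sprintf(paste0("%.", digits, "f±%.", digits, "f"), mean * scale, sd * scale)
  }
  pfmt <- function(p) {
    if (is.na(p)) "-" else if (p < 0.01) "<0.01" else sprintf("%.2f", p)
  }
  lines <- c(
    "| Structure | Metric | CRT | IMRT | VMAT | p CRT-IMRT | p CRT-VMAT | p IMRT-VMAT |",
    "|---|---|---|---|---|---|---|---|"
  )
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    u <- unit_of(r$structure, r$metric)
    label <- if (identical(u, "Gy")) paste0(r$metric, " (cGy)") else
      if (identical(u, "%")) paste0(r$metric, " (%)") else r$metric
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s |",
      r$structure, label,
      cell(r$crt_mean, r$crt_sd, u),
      cell(r$imrt_mean, r$imrt_sd, u),
      cell(r$vmat_mean, r$vmat_sd, u),
      pfmt(r$p_crt_imrt), pfmt(r$p_crt_vmat), pfmt(r$p_imrt_vmat)
    ))
  }
  lines
}
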