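# Synthetic thorax phantom and analytic beam-model dose generator.
#
# The phantom is an elliptical-cylinder body holding two lateral lung
# ellipsoids, an anterior heart ellipsoid, a posterior midline cord cylinder
# and a centered elongated PTV ellipsoid (an esophageal-type target). The
# dose engine superposes divergent attenuated slab beams shaped to the PTV
# silhouette with a sigmoid penumbra, a scatter bath, optional cord
# shielding and smooth noise. It makes no claim of dosimetric realism: its
# job is to produce plan cohorts with the qualitative structure of the three
# modalities (few-beam CRT with generous fields vs. many-beam IMRT/VMAT with
# tight fields and a larger low-dose bath) so the evaluation pipeline can be
# exercised end to end.

# evaluate code under a temporary RNG state so generators never perturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

coord_arrays <- function(shape, spacing) {
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - (shape[i] + 1) / 2) * spacing[i])
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(
    X = array(rep(ax[[1]], times = ny * nz), shape),
    Y = array(rep(rep(ax[[2]], each = nx), times = nz), shape),
    Z = array(rep(ax[[3]], each = nx * ny), shape)
  )
}

ellipsoid <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 +
    ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

#' Phantom specification
#'
#' Geometry of one synthetic thorax phantom. The PTV is a centered ellipsoid
#' elongated cranio-caudally (semi-axes a, a, 2.5a) whose volume is drawn
#' uniformly from `ptv_volume_range` (default 158.3 to 378.9 cm^3, the span
#' of planning target volumes in middle-thoracic esophageal cohorts) unless
#' `ptv_volume_cc` is given. Organ sizes get a small per-phantom jitter so a
#' cohort has anatomical variability beyond the target volume.
#'
#' @param seed integer seed; the phantom is fully deterministic given it.
#' @param shape voxel counts per axis (default 64 x 64 x 48).
#' @param spacing voxel edge lengths in mm (default 4 mm isotropic).
#' @param ptv_volume_cc fixed PTV volume in cm^3, or `NULL` to draw one.
#' @param ptv_volume_range sampling range for the PTV volume in cm^3.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1, shape = c(64, 64, 48), spacing = c(4, 4, 4),
                         ptv_volume_cc = NULL,
                         ptv_volume_range = c(158.3, 378.9)) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, all(shape > 0),
            length(spacing) == 3, all(spacing > 0))
  with_seed(seed, {
    if (is.null(ptv_volume_cc)) {
      ptv_volume_cc <- stats::runif(1, ptv_volume_range[1], ptv_volume_range[2])
    }
    jit <- stats::runif(4, 0.95, 1.05)    # lung, heart, PTV y-shift, heart z-shift
    spec <- list(
      seed = as.integer(seed), shape = shape, spacing = spacing,
      ptv_volume_cc = ptv_volume_cc,
      body_semi = c(112, 92),
      ptv_center = c(0, 12 + (jit[3] - 1) * 80, 0),
      lung_centers = list(c(-68, 0, 0), c(68, 0, 0)),
      lung_semi = c(36, 58, 82) * jit[1],
      heart_center = c(10, -38, -20 + (jit[4] - 1) * 100),
      heart_semi = c(42, 34, 40) * jit[2],
      cord_center = c(0, 62), cord_radius = 6
    )
    class(spec) <- "phantom_spec"
    spec
  })
}

ptv_semi_axes <- function(volume_cc) {
  # ellipsoid with semi-axes (a, a, 2.5a): V = (4/3) pi a^2 (2.5 a)
  a <- (3 * volume_cc * 1000 / (10 * pi))^(1 / 3)
  c(a, a, 2.5 * a)
}

#' Generate the structure masks of a phantom
#'
#' Voxelizes the phantom geometry at voxel centers. Structures are disjoint
#' (lungs and heart exclude the PTV, the cord excludes everything else) and
#' all lie inside the body. Deterministic for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return Named list of [structure_mask()] objects (`ptv`, `lung`, `heart`,
#'   `cord`, `body`) with the spec and derived PTV geometry attached as
#'   attributes `spec` and `geometry`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  semi <- ptv_semi_axes(spec$ptv_volume_cc)
  half_extent <- spec$shape * spec$spacing / 2
  if (semi[1] + abs(spec$ptv_center[1]) > spec$body_semi[1] - 4 ||
      semi[2] + abs(spec$ptv_center[2]) > spec$body_semi[2] - 4 ||
      semi[3] > half_extent[3] - spec$spacing[3]) {
    stop(sprintf("PTV of %.1f cm^3 does not fit inside the phantom body",
                 spec$ptv_volume_cc))
  }
  co <- coord_arrays(spec$shape, spec$spacing)
  body <- ((co$X / spec$body_semi[1])^2 + (co$Y / spec$body_semi[2])^2) <= 1
  ptv <- ellipsoid(co, spec$ptv_center, semi) & body
  heart <- ellipsoid(co, spec$heart_center, spec$heart_semi) & body & !ptv
  lung <- (ellipsoid(co, spec$lung_centers[[1]], spec$lung_semi) |
             ellipsoid(co, spec$lung_centers[[2]], spec$lung_semi)) &
    body & !ptv & !heart
  cord <- (((co$X - spec$cord_center[1])^2 +
              (co$Y - spec$cord_center[2])^2) <= spec$cord_radius^2) &
    body & !ptv & !heart & !lung
  out <- list(
    ptv = structure_mask(ptv, "ptv"),
    lung = structure_mask(lung, "lung"),
    heart = structure_mask(heart, "heart"),
    cord = structure_mask(cord, "cord"),
    body = structure_mask(body, "body")
  )
  attr(out, "spec") <- spec
  attr(out, "geometry") <- list(ptv_center = spec$ptv_center, ptv_semi = semi,
                                cord_center = spec$cord_center)
  out
}

#' Modality beam profiles
#'
#' Default beam arrangements and field parameters per modality:
#' \itemize{
#'   \item CRT: two phases of open fields — an antero-posterior /
#'     postero-anterior (APPA) opposed pair to 36 Gy, then off-cord
#'     anterior obliques (65 / 295 degrees) to 24 Gy with an explicit cord
#'     block; generous field margin, small scatter bath, no conformal
#'     shaping (each field delivers its full corridor dose along the beam
#'     path).
#'   \item IMRT: five equally spaced beams (0, 72, 144, 216, 288 degrees);
#'     most of the dose is delivered as a conformal target-shaped component
#'     (`conformal_frac`, emulating the optimizer's modulated result) with
#'     the remainder spread over the beam corridors; tight margin, larger
#'     scatter bath (the many-segment low-dose spread).
#'   \item VMAT: a single 181 to 180 degree clockwise arc approximated by 36
#'     evenly spaced directions, same conformal-plus-corridor split as
#'     IMRT; tight margin, intermediate bath.
#' }
#' Cord shielding is applied per corridor beam only when the cord is
#' laterally clear of the target in that beam's eye view (for CRT this
#' models the off-cord block; for IMRT/VMAT it stands in for
#' optimizer-driven cord avoidance, with higher transmission).
#'
#' These defaults are a pinned modelling choice, calibrated once so the
#' characteristic modality contrasts (conformity, low-dose bath, high-dose
#' lung/heart sparing) hold with margin on the default cohort.
#'
#' @param modality `"CRT"`, `"IMRT"` or `"VMAT"`.
#' @return A list of class `modality_profile`.
#' @export
modality_profile <- function(modality) {
  modality <- match.arg(toupper(modality), c("CRT", "IMRT", "VMAT"))
  base <- list(modality = modality, mu = 0.0035, noise_sd = 0.5,
               shield_radius = 6)
  prof <- switch(modality,
    CRT = c(base, list(
      phases = list(
        list(rx_frac = 0.6, gantry = c(0, 180), weights = c(0.5, 0.5)),
        list(rx_frac = 0.4, gantry = c(65, 295), weights = c(0.5, 0.5))
      ),
      conformal_frac = 0, margin = 10, penumbra = 7, bath = 0.01,
      shield_transmission = 0.08
    )),
    IMRT = c(base, list(
      phases = list(
        list(rx_frac = 1, gantry = c(0, 72, 144, 216, 288),
             weights = rep(0.2, 5))
      ),
      conformal_frac = 0.5, margin = 6, penumbra = 5, bath = 0.12,
      shield_transmission = 0.45
    )),
    VMAT = c(base, list(
      phases = list(
        list(rx_frac = 1,
             gantry = (181 + seq(0, 350, length.out = 36)) %% 360,
             weights = rep(1 / 36, 36))
      ),
      conformal_frac = 0.5, margin = 6, penumbra = 5, bath = 0.10,
      shield_transmission = 0.45
    ))
  )
  class(prof) <- "modality_profile"
  prof
}

smooth_field <- function(a, passes = 2) {
  dims <- dim(a)
  for (p in seq_len(passes)) {
    for (ax in 1:3) {
      n <- dims[ax]
      lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n - 1) + 1, n)
      if (ax == 1) a <- (a[lo, , , drop = FALSE] + a + a[hi, , , drop = FALSE]) / 3
      if (ax == 2) a <- (a[, lo, , drop = FALSE] + a + a[, hi, , drop = FALSE]) / 3
      if (ax == 3) a <- (a[, , lo, drop = FALSE] + a + a[, , hi, drop = FALSE]) / 3
    }
  }
  a
}

#' Generate a modality-specific dose distribution on a phantom
#'
#' Per phase, the dose is a mix of (i) a conformal component — a 3-D
#' sigmoid shell around the margin-expanded PTV, standing in for the
#' modulated dose an optimizer shapes to the target (weight
#' `conformal_frac`; zero for open-field CRT) — and (ii) one attenuated
#' slab corridor per gantry angle: cross-profile 1 inside the PTV
#' silhouette expanded by the field margin, sigmoid penumbra falloff,
#' exponential depth attenuation, and a cord block on beams whose eye view
#' separates cord and target. A scatter-bath floor is mixed into every
#' component. Each phase is normalized so the PTV median equals the phase
#' prescription; smooth noise is added and the composite rescaled so the
#' PTV median dose equals the full prescription (within 0.1 Gy). Dose is
#' zero outside the body. A profile with no beams returns zero dose
#' everywhere. Deterministic per seed.
#'
#' @param structures phantom structures from [generate_phantom()].
#' @param profile a [modality_profile()].
#' @param prescription total prescription dose in Gy.
#' @param seed integer seed for the noise field.
#' @return A [dose_grid()].
#' @export
generate_dose <- function(structures, profile, prescription = 60, seed = 1) {
  stopifnot(inherits(profile, "modality_profile"))
  spec <- attr(structures, "spec")
  geom <- attr(structures, "geometry")
  if (is.null(spec) || is.null(geom)) {
    stop("structures must come from generate_phantom()")
  }
  if (!is.finite(prescription) || prescription <= 0) {
    stop("prescription must be > 0")
  }
  shape <- spec$shape
  body <- structures$body$mask
  ptv <- structures$ptv$mask
  n_beams <- sum(vapply(profile$phases, function(ph) length(ph$gantry), integer(1)))
  if (n_beams == 0L) {
    return(dose_grid(array(0, shape), spec$spacing))
  }
  co <- coord_arrays(shape, spec$spacing)
  au <- geom$ptv_semi[1] + profile$margin
  cz <- geom$ptv_semi[3] + profile$margin
  rz2 <- ((co$Z - geom$ptv_center[3]) / cz)^2
  bath <- profile$bath
  cf <- profile$conformal_frac
  conformal <- if (cf > 0) {
    r3 <- sqrt(((co$X - geom$ptv_center[1]) / au)^2 +
                 ((co$Y - geom$ptv_center[2]) / au)^2 + rz2)
    stats::plogis(4 * (1 - r3) * au / profile$penumbra)
  } else {
    NULL
  }

  total <- array(0, shape)
  for (ph in profile$phases) {
    phase_dose <- if (is.null(conformal)) {
      array(0, shape)
    } else {
      cf * (bath + (1 - bath) * conformal)
    }
    for (b in seq_along(ph$gantry)) {
      g <- ph$gantry[b] * pi / 180
      dirx <- sin(g); diry <- cos(g)
      t <- co$X * dirx + co$Y * diry          # along-beam coordinate
      u <- co$X * diry - co$Y * dirx          # cross-beam coordinate
      u0 <- geom$ptv_center[1] * diry - geom$ptv_center[2] * dirx
      ru2 <- ((u - u0) / au)^2
      r <- sqrt(ru2 + rz2)
      field <- stats::plogis(4 * (1 - r) * au / profile$penumbra)
      u_cord <- spec$cord_center[1] * diry - spec$cord_center[2] * dirx
      if (abs(u_cord - u0) > geom$ptv_semi[1]) {
        # cord clear of the target in this beam's eye view: block it
        dc <- abs(u - u_cord)
        tr <- profile$shield_transmission
        field <- field * (tr + (1 - tr) *
          stats::plogis(4 * (dc - profile$shield_radius) / profile$penumbra))
      }
      field <- bath + (1 - bath) * field
      depth <- t - min(t[body])
      phase_dose <- phase_dose +
        (1 - cf) * ph$weights[b] * field * exp(-profile$mu * depth)
    }
    med <- stats::median(phase_dose[ptv])
    if (med > 0) {
      phase_dose <- phase_dose * (ph$rx_frac * prescription / med)
    }
    total <- total + phase_dose
  }
  noise <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  noise <- smooth_field(noise)
  noise <- noise / stats::sd(noise) * profile$noise_sd
  total <- pmax(total + noise, 0)
  total[!body] <- 0
  med <- stats::median(total[ptv])
  if (med > 0) total <- total * (prescription / med)
  dose_grid(total, spec$spacing)
}

#' Generate a balanced synthetic plan cohort
#'
#' `n` phantom patients, each planned under all three modalities at a common
#' prescription. Seeds for each patient and each (patient, modality) dose
#' are derived from the root seed so adding a patient never perturbs
#' existing ones; the whole cohort is deterministic per (n, seed, config).
#'
#' @param n number of patients (default 8).
#' @param seed root integer seed.
#' @param prescription prescription dose in Gy (default 60).
#' @param shape,spacing grid geometry passed to [phantom_spec()].
#' @param modalities modalities to plan (default all three).
#' @return List of [plan_record()] objects, length `n * length(modalities)`.
#' @export
generate_cohort <- function(n = 8, seed = 1, prescription = 60,
                            shape = c(64, 64, 48), spacing = c(4, 4, 4),
                            modalities = c("CRT", "IMRT", "VMAT")) {
  stopifnot(n >= 1)
  base <- abs(as.integer(seed)) %% 1000000L
  plans <- list()
  for (i in seq_len(n)) {
    spec <- phantom_spec(seed = base * 1000L + i * 10L,
                         shape = shape, spacing = spacing)
    structures <- generate_phantom(spec)
    for (k in seq_along(modalities)) {
      m <- modalities[k]
      dose <- generate_dose(structures, modality_profile(m), prescription,
                            seed = base * 1000L + i * 10L + k)
      plans[[length(plans) + 1L]] <- plan_record(
        patient_id = sprintf("P%02d", i), modality = m,
        prescription_dose = prescription, dose = dose,
        structures = structures
      )
    }
  }
  plans
}

#' Synthesize a DVH curve from a parametric cumulative specification
#'
#' Builds a valid [dvh_curve()] directly from a cumulative curve given
#' either as a function of dose (returning percent of volume receiving at
#' least that dose) or as a vector of values at the bin edges. Useful as a
#' grid-free DVH fixture. A specification that is not non-increasing, or
#' does not start at 100 percent at zero dose, is rejected.
#'
#' @param cumulative function of dose (Gy) or numeric vector at `bin_edges`.
#' @param bin_edges strictly increasing dose values in Gy starting at 0.
#' @param total_volume structure volume in cm^3.
#' @param structure label for the curve.
#' @return A [dvh_curve()].
#' @export
synthesize_dvh <- function(cumulative, bin_edges, total_volume = 100,
                           structure = "synthetic") {
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L || bin_edges[1] != 0 || any(diff(bin_edges) <= 0)) {
    stop("bin_edges must be strictly increasing and start at 0")
  }
  cum <- if (is.function(cumulative)) cumulative(bin_edges) else as.numeric(cumulative)
  if (length(cum) != length(bin_edges)) {
    stop("cumulative values must match bin_edges in length")
  }
  if (any(diff(cum) > 1e-9)) stop("cumulative specification must be non-increasing")
  if (abs(cum[1] - 100) > 1e-6) stop("cumulative must be 100% at zero dose")
  if (any(cum < -1e-9) || any(cum > 100 + 1e-9)) stop("cumulative must lie in [0, 100]")
  diffs <- -diff(c(cum, 0)) / 100 * total_volume
  # mass still above the last edge is assigned to a closing bin
  if (diffs[length(diffs)] > 0) {
    w <- bin_edges[length(bin_edges)] - bin_edges[length(bin_edges) - 1L]
    bin_edges <- c(bin_edges, bin_edges[length(bin_edges)] + w)
  } else {
    diffs <- diffs[-length(diffs)]
  }
  dvh_curve(bin_edges, pmax(diffs, 0), structure)
}
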