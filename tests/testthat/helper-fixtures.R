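# Small in-code fixtures shared across test files.

# grid whose voxels take the given doses (filled in array order)
grid_from_values <- function(values, shape = NULL, spacing = c(10, 10, 10)) {
  if (is.null(shape)) shape <- c(length(values), 1, 1)
  dose_grid(array(values, shape), spacing)
}

full_mask <- function(shape, label = "ptv") {
  structure_mask(array(TRUE, shape), label)
}

# a random small plan-like grid + mask for property sweeps
random_grid_case <- function(max_dose = 60) {
  shape <- c(sample(2:10, 1), sample(2:10, 1), sample(2:10, 1))
  g <- dose_grid(array(stats::runif(prod(shape), 0, max_dose), shape),
                 spacing = stats::runif(3, 1, 5))
  m <- array(stats::runif(prod(shape)) < 0.7, shape)
  if (!any(m)) m[1] <- TRUE
  list(dose = g, mask = structure_mask(m, "s"))
}

# uniform-dose plan: d Gy inside the PTV ellipsoid region, bath outside
uniform_plan <- function(d = 60, bath = 0, shape = c(12, 12, 8)) {
  inner <- array(FALSE, shape)
  inner[4:9, 4:9, 3:6] <- TRUE
  vals <- array(bath, shape)
  vals[inner] <- d
  body <- array(TRUE, shape)
  plan_record(
    patient_id = "T1", modality = "CRT", prescription_dose = d,
    dose = dose_grid(vals, c(4, 4, 4)),
    structures = list(ptv = structure_mask(inner, "ptv"),
                      body = structure_mask(body, "body"))
  )
}

tiny_cohort <- function(n = 2, seed = 11) {
  generate_cohort(n = n, seed = seed, shape = c(32, 32, 24), spacing = c(8, 8, 8))
}
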