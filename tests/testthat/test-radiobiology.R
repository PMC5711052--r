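test_that("shipped parameter registry carries the published constants", {
  reg <- default_radiobio_params()
  row <- function(s) reg[reg$structure == s, ]
  expect_equal(row("ptv")[, c("a", "d50", "gamma50", "slope50")],
               data.frame(a = -13, d50 = 49.09, gamma50 = 2.16, slope50 = 4.14),
               ignore_attr = TRUE)
  expect_equal(row("cord")[, c("a", "d50", "gamma50")],
               data.frame(a = 13, d50 = 66.5, gamma50 = 3), ignore_attr = TRUE)
  expect_equal(row("lung")[, c("a", "d50", "gamma50")],
               data.frame(a = 1, d50 = 24.5, gamma50 = 2), ignore_attr = TRUE)
  expect_equal(row("heart")[, c("a", "d50", "gamma50")],
               data.frame(a = 3, d50 = 48, gamma50 = 3), ignore_attr = TRUE)
  expect_equal(row("brainstem")[, c("a", "d50", "gamma50")],
               data.frame(a = 7, d50 = 65, gamma50 = 3), ignore_attr = TRUE)
  # registry round-trips through its JSON serialization
  tmp <- tempfile(fileext = ".json")
  write_radiobio_params(reg, tmp)
  expect_equal(read_radiobio_params(tmp), reg, ignore_attr = TRUE)
})

test_that("EUD reproduces hand-computed power means", {
  expect_equal(eud(rep(60, 10), a = -13), 60)
  expect_equal(eud(rep(60, 10), a = 1), 60)
  expect_equal(eud(c(10, 20, 30), a = 1), 20)
  expect_equal(eud(c(30, 40), a = 2), sqrt((30^2 + 40^2) / 2), tolerance = 1e-12)
  expect_equal(eud(c(30, 40), a = 2), 35.3553, tolerance = 1e-4)
  # volume weighting: duplicating a dose equals doubling its weight
  expect_equal(eud(c(10, 20, 20), a = 3),
               eud(c(10, 20), a = 3, volumes = c(1, 2)), tolerance = 1e-12)
})

test_that("EUD limits, monotonicity in a, and the zero-dose floor behave", {
  set.seed(405)
  for (i in 1:10) {
    doses <- stats::runif(50, 5, 70)
    as <- sort(stats::runif(5, -20, 20))
    as <- as[as != 0]
    euds <- vapply(as, function(a) eud(doses, a), numeric(1))
    expect_true(all(diff(euds) >= -1e-9))           # power-mean inequality
    expect_true(all(euds >= min(doses) - 1e-9 & euds <= max(doses) + 1e-9))
    expect_equal(eud(doses, 50), max(doses), tolerance = 0.1)
    expect_equal(eud(doses, -50), min(doses), tolerance = 0.1)
    expect_equal(eud(doses, 1), mean(doses), tolerance = 1e-12)
  }
  expect_warning(e <- eud(c(0, 60, 60), a = -13, structure = "ptv"), "flooring")
  expect_true(e > 0)
  expect_error(eud(numeric(0), a = 1), "at least one")
})

test_that("TCP/NTCP sigmoid fixed points hold to 1e-12 for every registry entry", {
  reg <- default_radiobio_params()
  for (i in seq_len(nrow(reg))) {
    p <- reg[i, ]
    f <- if (p$kind == "tumor") tcp else ntcp
    expect_equal(f(p$d50, p), 0.5, tolerance = 1e-12)
    expect_equal(f(0, p), 0)
    expect_gt(f(1e4, p), 0.999)
    # strictly increasing in EUD
    e <- seq(5, 90, by = 5)
    expect_true(all(diff(f(e, p)) > 0))
  }
})

test_that("TCP and NTCP match direct scalar evaluation of the sigmoid", {
  reg <- default_radiobio_params()
  esoph <- reg[reg$structure == "ptv", ]
  expect_equal(tcp(60.296, esoph),
               1 / (1 + (49.09 / 60.296)^(4 * 2.16)), tolerance = 1e-12)
  expect_equal(tcp(60.296, esoph), 0.855, tolerance = 5e-4)
  cord <- reg[reg$structure == "cord", ]
  expect_equal(ntcp(36.869, cord), 8.43e-4, tolerance = 2e-3)
  # kind mismatch is an error
  expect_error(tcp(50, cord), "tumor")
  expect_error(ntcp(50, esoph), "normal")
  # slope50 mode substitutes the %/Gy slope for the esophageal entry
  expect_equal(tcp(60, esoph, slope_mode = "slope50"),
               1 / (1 + (49.09 / 60)^(4 * 4.14)), tolerance = 1e-12)
  expect_error(ntcp(30, cord, slope_mode = "slope50"), "slope50")
})

test_that("probabilities are invariant under Gy/cGy round trips of the inputs", {
  reg <- default_radiobio_params()
  lung <- reg[reg$structure == "lung", ]
  doses <- c(3, 11, 24, 40)
  e1 <- eud(doses, a = lung$a)
  e2 <- eud(doses * 100, a = lung$a) / 100   # compute in cGy, convert back
  expect_equal(e1, e2, tolerance = 1e-9)
  expect_equal(ntcp(e1, lung), ntcp(e2, lung), tolerance = 1e-12)
})

test_that("plan-level radiobiology composes per-structure EUD with the right model", {
  plan <- uniform_plan(d = 60, bath = 2)
  rb <- plan_radiobiology(plan)
  ptv_row <- rb[rb$structure == "ptv", ]
  expect_equal(ptv_row$eud_gy, 60, tolerance = 1e-9)  # uniform PTV, any a
  expect_equal(ptv_row$model, "TCP")
  # determinism: same plan, same answer
  expect_identical(rb, plan_radiobiology(plan))

  # lung (a = 1): EUD equals the mean lung dose exactly
  cohort <- tiny_cohort(n = 1)
  p <- cohort[[1]]
  rb <- plan_radiobiology(p)
  lung_mean <- mean(p$dose$values[p$structures$lung$mask])
  expect_equal(rb$eud_gy[rb$structure == "lung"], lung_mean, tolerance = 1e-9)
  expect_true(all(rb$model[rb$structure != "ptv"] == "NTCP", na.rm = TRUE))

  # voxel-path and DVH-path EUD agree within the bin tolerance
  ld <- compute_dvh(p$dose, p$structures$lung, 0.05)
  expect_equal(eud_from_dvh(ld, a = 1), lung_mean, tolerance = 5e-3)

  # missing registry entry: unevaluable, not dropped
  reg <- default_radiobio_params()
  rb2 <- plan_radiobiology(p, reg[reg$structure != "heart", ])
  expect_false(rb2$evaluable[rb2$structure == "heart"])
})
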