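make_targets <- function(fl = c(SVC = 6000, IVC = 5800, LPA = 4400,
                                RPA = 6500),
                         rv = c(IVC = 850, LPA = 120, RPA = 7),
                         pr = NULL) {
  if (is.null(pr)) {
    pr <- rbind(mean = c(1870, 1870, 1790, 1790),
                systolic = c(1960, 2150, 1900, 1890),
                diastolic = c(1780, 1700, 1700, 1700))
    colnames(pr) <- c("SVC", "IVC", "LPA", "RPA")
  }
  calibration_targets(fl, rv, pr)
}

test_that("residuals are relative per item with category maxima", {
  tg <- make_targets()
  sim <- structure(list(
    mean_flows = c(SVC = 6000, IVC = 5800, LPA = 4400, RPA = 6500,
                   FEN = 700, AV = 11800),
    retrograde_volumes = c(SVC = 0, IVC = 850, LPA = 120, RPA = 7),
    pressures = rbind(mean = c(SVC = 1870, IVC = 1870, LPA = 1790,
                               RPA = 1790),
                      systolic = c(1960, 2150, 1900, 1890),
                      diastolic = c(1780, 1700, 1700, 1700),
                      pulse = c(180, 450, 200, 190))),
    class = "metrics_report")
  res <- calibration_residuals(sim, tg)
  expect_true(all(res$per_item == 0))
  expect_equal(unname(res$category_max), c(0, 0, 0))
  # 2% flow error at one face dominates the flow category
  sim2 <- sim
  sim2$mean_flows[["SVC"]] <- 6000 * 1.02
  res2 <- calibration_residuals(sim2, tg)
  expect_equal(res2$per_item[["flow_SVC"]], 2, tolerance = 1e-10)
  expect_equal(res2$category_max[["flow"]], 2, tolerance = 1e-10)
  # zero targets fall back to an absolute scale and are flagged
  tg0 <- make_targets(rv = c(IVC = 850, LPA = 120, RPA = 0))
  res0 <- calibration_residuals(sim, tg0)
  expect_true("backflow_RPA" %in% res0$fallback_items)
  expect_true(is.finite(res0$per_item[["backflow_RPA"]]))
})

test_that("analytic seeding is Ohmic for the pulmonary beds", {
  m <- default_network()
  # spec-style single-bed example: 1e4 mm^3/s at 1600 Pa above distal
  fl <- c(SVC = 6000, IVC = 5800, LPA = 1e4, RPA = 1e4)
  pr <- rbind(mean = c(1900, 1900, 1600, 1600),
              systolic = c(2000, 2100, 1700, 1700),
              diastolic = c(1800, 1750, 1500, 1500))
  colnames(pr) <- c("SVC", "IVC", "LPA", "RPA")
  tg <- make_targets(fl = fl, pr = pr)
  init <- initialize_parameters(tg, m)
  expect_equal(unname(init$R_totals["lpa"]), 0.16, tolerance = 1e-10)
  # symmetric targets give symmetric seeds
  expect_equal(unname(init$R_totals["lpa"]), unname(init$R_totals["rpa"]))
  # doubling the pressure targets doubles the resistance seeds
  pr2 <- pr * 2
  tg2 <- make_targets(fl = fl, pr = pr2)
  init2 <- initialize_parameters(tg2, m)
  expect_equal(init2$R_totals, init$R_totals * 2)
  expect_true(all(init$scales > 0))
  # infeasible target (zero flow) errors
  fl_bad <- fl; fl_bad[["LPA"]] <- 0
  expect_error(initialize_parameters(make_targets(fl = fl_bad, pr = pr), m),
               "infeasible")
})

test_that("seeded resistances reproduce target pressures in the steady net", {
  sc <- cached_scenario()
  init <- initialize_parameters(sc$targets, sc$truth)
  for (bed in c("lpa", "rpa")) {
    f <- toupper(bed)
    p_pred <- init$R_totals[[bed]] * sc$targets$mean_flows[[f]] +
      sc$truth[[bed]]$P_distal
    expect_equal(p_pred, sc$targets$pressures["mean", f],
                 tolerance = 0.2, label = bed)
  }
})

test_that("calibration from the truth is an immediate fixed point", {
  truth <- default_network()
  ds0 <- generate_dataset(truth, default_noise_spec(0, 0), seed = 1,
                          sim = cached_pre_sim())
  tg <- dataset_to_targets(ds0)
  cr <- calibrate(truth, tg, budget = 60)
  expect_true(cr$converged)
  expect_lt(cr$residuals$category_max[["flow"]], 0.5)
  expect_lt(cr$residuals$category_max[["pressure"]], 1)
  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(cr$trace) <= 1e-12))
  # objective at the fitted vector does not exceed the start's
  expect_lte(cr$objective, cr$trace[1])
})

test_that("calibration is deterministic and recovers perturbed resistances", {
  sc <- cached_scenario()
  free <- c("R_lpa", "R_rpa", "C_lpa", "C_rpa")
  start <- c(R_lpa = 0.6, R_rpa = 1.6, C_lpa = 1.4, C_rpa = 0.7)
  cr1 <- calibrate(sc$truth, sc$targets, budget = 120, free = free,
                   start = start)
  cr2 <- calibrate(sc$truth, sc$targets, budget = 120, free = free,
                   start = start)
  expect_identical(cr1$scales, cr2$scales)
  # total pulmonary bed resistances recovered within 10% of the truth
  for (bed in c("lpa", "rpa")) {
    truth_R <- sc$truth[[bed]]$R_p + sc$truth[[bed]]$R_d
    fit_R <- cr1$model[[bed]]$R_p + cr1$model[[bed]]$R_d
    expect_equal(fit_R / truth_R, 1, tolerance = 0.1, label = bed)
  }
})
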