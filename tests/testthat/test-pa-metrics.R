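test_that("dose-response curves carry their baseline and show the PA shape", {
  p <- default_params()
  curve <- dose_response(p, "CA", default_dose_grid(81), mode = "free_drug",
                         s_free = 0)
  expect_s3_class(curve, "dose_response")
  expect_equal(curve$dose[1], 0)
  expect_equal(curve$active[1], attr(curve, "baseline"))
  baseline <- attr(curve, "baseline")
  # rises above baseline, peaks, then decays below it
  expect_gt(max(curve$active), baseline)
  expect_lt(curve$active[nrow(curve)], baseline)
  i_peak <- which.max(curve$active)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(curve))

  # degenerate grid: only the baseline dose
  c0 <- dose_response(p, "CA", 0, mode = "free_drug", s_free = 0)
  expect_equal(nrow(c0), 1L)
  expect_equal(c0$active, attr(c0, "baseline"))

  expect_error(dose_response(p, "CA", c(1, 0.5)), "increasing")
  expect_error(dose_response(p, "CA", -1), "non-negative")
  expect_error(dose_response(p, "CA", 1, mode = "total_drug", s_free = 2),
               "free_drug")
})

test_that("total-drug curves mapped through conservation agree between engines", {
  p <- default_params()
  doses <- default_dose_grid(13)
  a <- dose_response(p, "CAS_DS", doses, mode = "total_drug",
                     engine = "analytic")
  o <- dose_response(p, "CAS_DS", doses, mode = "total_drug",
                     engine = "oracle")
  expect_equal(a$active, o$active, tolerance = 1e-9)
})

test_that("fold change is 1 without autoinhibition and grid-independent with it", {
  p0 <- raf_params(K_A = 0)
  c0 <- dose_response(p0, "CA", default_dose_grid(41), mode = "free_drug",
                      s_free = 0)
  expect_true(all(diff(c0$active) <= 0))
  expect_equal(pa_fold_change(c0), 1)

  p <- default_params()
  fc <- pa_fold_change(dose_response(p, "CA", default_dose_grid(121),
                                     mode = "free_drug", s_free = 0))
  expect_gt(fc, 1)
  # brute-force fine grid scan as reference
  fine <- 10^seq(-4, 2, length.out = 1e5)
  ref <- max(active_fraction(p, "CA", fine)) /
    active_fraction(p, "CA", 0)
  expect_equal(fc, ref, tolerance = 1e-6)
  # a 10x coarser grid reaches the same refined value
  fc2 <- pa_fold_change(dose_response(p, "CA", default_dose_grid(13),
                                      mode = "free_drug", s_free = 0))
  expect_equal(fc2, fc, tolerance = 1e-6)
})

test_that("fold change depends only on the dimensionless groups", {
  p <- default_params()
  q <- raf_params(K_A = p$K_A, K_d = p$K_d, K_dim = 2 * p$K_dim,
                  K_Smon = p$K_Smon, K_Sdim = p$K_Sdim,
                  R_total = 2 * p$R_total, S_total = p$S_total)
  doses <- default_dose_grid(61)
  fc_p <- pa_fold_change(dose_response(p, "CA", doses, mode = "free_drug",
                                       s_free = 0))
  fc_q <- pa_fold_change(dose_response(q, "CA", doses, mode = "free_drug",
                                       s_free = 0))
  expect_equal(fc_p, fc_q, tolerance = 1e-10)
})

test_that("crossover dose is absent without PA and matches a fine grid scan with it", {
  expect_true(is.na(pa_crossover_dose(raf_params(K_A = 1), "CA",
                                      mode = "free_drug", s_free = 0)))
  p <- default_params()
  cross <- pa_crossover_dose(p, "CA", mode = "free_drug", s_free = 0)
  expect_true(is.finite(cross))
  # brute-force: first fine-grid dose beyond the peak that falls below baseline
  fine <- 10^seq(-4, 3, length.out = 1e6)
  act <- active_fraction(p, "CA", fine)
  baseline <- active_fraction(p, "CA", 0)
  below <- which(act < baseline & seq_along(fine) > which.max(act))
  expect_lt(abs(log10(cross) - log10(fine[below[1]])), 7 / 1e6 * 2)
})

test_that("analytic and oracle engines yield the same PA metrics", {
  set.seed(404)
  for (i in 1:12) {
    q <- random_params()
    v <- sample(raf_variants(), 1)
    s <- runif(1, 0, 10)
    doses <- default_dose_grid(41)
    ca <- dose_response(q, v, doses, mode = "free_drug",
                        engine = "analytic", s_free = s)
    co <- dose_response(q, v, doses, mode = "free_drug",
                        engine = "oracle", s_free = s)
    expect_equal(pa_fold_change(ca), pa_fold_change(co), tolerance = 1e-6)
    xa <- pa_crossover_of_curves <- pa_crossover_dose(q, v, doses,
                                                      mode = "free_drug",
                                                      engine = "analytic",
                                                      s_free = s)
    xo <- pa_crossover_dose(q, v, doses, mode = "free_drug",
                            engine = "oracle", s_free = s)
    if (is.na(xa)) expect_true(is.na(xo))
    else expect_equal(xa, xo, tolerance = 1e-6)
  }
})

test_that("sweep grids reduce to the scalar metric and order with 14-3-3 as claimed", {
  p <- default_params()
  g <- sweep_grid(p, "CA",
                  axis1 = list(name = "K_A", values = 10),
                  axis2 = list(name = "R_total", values = 0.04),
                  metric = "fold_change", doses = default_dose_grid(41),
                  mode = "free_drug", s_free = 0)
  expect_equal(nrow(g), 1L)
  expect_equal(g$value,
               pa_fold_change(dose_response(p, "CA", default_dose_grid(41),
                                            mode = "free_drug", s_free = 0)))

  # more 14-3-3 widens the CAS PA range and narrows the DS PA range
  S_vals <- c(0.1, 1, 10)
  for (v in c("CAS", "DS")) {
    g <- sweep_grid(p, v,
                    axis1 = list(name = "S_total", values = S_vals),
                    axis2 = list(name = "K_A", values = 10),
                    metric = "crossover_dose", doses = default_dose_grid(41),
                    mode = "free_drug")
    # an NA crossover means the PA window has closed entirely (range 0)
    range_val <- ifelse(is.na(g$value), 0, g$value)
    if (v == "CAS") expect_true(all(diff(range_val) > 0))
    else expect_true(all(diff(range_val) < 0))
  }
  expect_error(sweep_grid(p, "CA", list(name = "bogus", values = 1),
                          list(name = "K_A", values = 1), "fold_change"),
               "unknown axis")
})

test_that("alpha is a valid sweep axis applied through the meta-parameter", {
  p <- default_params()
  g <- sweep_grid(p, "CAS_DS",
                  axis1 = list(name = "alpha", values = c(0.1, 1, 10)),
                  axis2 = list(name = "S_total", values = 1),
                  metric = "baseline_pct", mode = "free_drug")
  expect_equal(g$value[g$axis1 == 1],
               100 * active_fraction(p, "CAS_DS", 0, p$S_total))
  # small alpha = DS-dominant: baseline above the identity point
  expect_gt(g$value[g$axis1 == 0.1], g$value[g$axis1 == 1])
  expect_lt(g$value[g$axis1 == 10], g$value[g$axis1 == 1])
})
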