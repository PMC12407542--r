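test_that("free-clamped solve reproduces the independent bisection oracle", {
  p <- default_params()
  # frozen: positive root of 20 M^2 + 11 M - 0.04 = 0, active = 2 M^2 / (K_dim R)
  st <- solve_free_clamped(p, "CA", 0, 0)
  expect_equal(active_raf(st), 0.006525563, tolerance = 1e-7)
  expect_equal(active_raf(st), bisect_active(p, "CA", 0, 0),
               tolerance = 1e-10)

  set.seed(101)
  for (i in 1:25) {
    q <- random_params()
    d <- runif(1, 0, 100) * q$K_d
    s <- runif(1, 0, 50)
    v <- sample(raf_variants(), 1)
    expect_equal(active_raf(solve_free_clamped(q, v, d, s)),
                 bisect_active(q, v, d, s), tolerance = 1e-10)
  }
})

test_that("free-clamped states satisfy the equilibrium relations and RAF conservation", {
  p <- default_params()
  st <- solve_free_clamped(p, "CAS_DS", d_free = 0.3, s_free = 0.8)
  expect_equal(st$A, p$K_A * st$M)
  expect_equal(st$AS, st$A * 0.8 / p$K_Smon)
  expect_equal(st$Md, st$M * 0.3 / p$K_d)
  expect_equal(st$D00, st$M^2 / p$K_dim)
  expect_equal(st$D01, 2 * st$M * st$Md / p$K_dim)
  expect_equal(st$D11, st$Md^2 / p$K_dim)
  expect_equal(st$D01S, st$D01 * 0.8 / p$K_Sdim)
  expect_lt(abs(conservation_residuals(st)$r_RAF), 1e-10 * p$R_total)

  # disabled couplings hold no species
  st_cas <- solve_free_clamped(p, "CAS", 0.3, 0.8)
  expect_equal(st_cas$D00S + st_cas$D01S + st_cas$D11S, 0)
  st_ds <- solve_free_clamped(p, "DS", 0.3, 0.8)
  expect_equal(st_ds$AS, 0)
})

test_that("limiting regimes collapse to the expected behavior", {
  p <- default_params()
  # empty system
  st0 <- solve_free_clamped(raf_params(R_total = 1e-12), "CA", 0, 0)
  expect_lt(active_raf(st0), 1e-9)
  # zero 14-3-3 decouples both roles
  a <- active_raf(solve_free_clamped(p, "CAS_DS", 0.2, 0))
  b <- active_raf(solve_free_clamped(p, "CA", 0.2, 0))
  expect_equal(a, b)
  # saturating inhibitor kills all drug-free dimer protomers
  st_sat <- solve_free_clamped(p, "CA", 1e4 * p$K_d, 0)
  expect_lt(active_raf(st_sat), 1e-4)
})

test_that("conservation solve closes all three totals and re-clamps consistently", {
  set.seed(202)
  for (i in 1:20) {
    q <- random_params()
    v <- sample(raf_variants(), 1)
    st <- solve_totals(q, v)
    res <- conservation_residuals(st)
    expect_lt(abs(res$r_RAF), 1e-10 * q$R_total)
    expect_lt(abs(res$r_drug), 1e-10 * max(q$D_total, q$R_total))
    expect_lt(abs(res$r_S), 1e-10 * max(q$S_total, q$R_total))
    # re-clamping the solved free ligands reproduces the same state
    st2 <- solve_free_clamped(q, v, st$d_free, st$s_free)
    expect_equal(unlist(unclass(st2)[1:12]), unlist(unclass(st)[1:12]),
                 tolerance = 1e-9)
  }
})

test_that("conservation solve handles the no-ligand and saturating-drug limits", {
  p <- default_params()
  st <- solve_totals(raf_params(S_total = 0), "CAS_DS")
  st0 <- solve_free_clamped(raf_params(S_total = 0), "CAS_DS", 0, 0)
  expect_equal(unclass(st)[1:12], unclass(st0)[1:12], tolerance = 1e-12)

  # with no drug, some but not all 14-3-3 is taken up by RAF
  st1 <- solve_totals(p, "CAS_DS")
  expect_gt(st1$s_free, 0)
  expect_lt(st1$s_free, p$S_total)

  # overwhelming drug: active fraction collapses
  st2 <- solve_totals(raf_params(D_total = 1e4 * 0.1), "CAS_DS")
  expect_lt(active_raf(st2), 1e-3)
})

test_that("dimer bookkeeping matches the protomer identity", {
  p <- default_params()
  st <- solve_free_clamped(p, "CA", 0, 0)
  expect_equal(dimer_count(st), active_raf(st) / 2)
  # at d_free = K_d the dimer complexes equal the active protomer fraction
  st1 <- solve_free_clamped(p, "CAS_DS", p$K_d, 0.5)
  expect_equal(dimer_count(st1), active_raf(st1), tolerance = 1e-12)
})

test_that("thermodynamic cycle products equal one and perturbations are detected", {
  p <- default_params()
  for (v in raf_variants()) {
    db <- check_detailed_balance(p, v)
    expect_true(all(db$product == 1))
  }
  expect_gt(nrow(check_detailed_balance(p, "CAS_DS")),
            nrow(check_detailed_balance(p, "CA")))
  # negative control: a broken relation must surface as product != 1
  db_bad <- check_detailed_balance(p, "CAS_DS",
                                   perturb = c("D00+d=D01" = 1.1))
  expect_true(any(db_bad$product != 1))
  expect_error(check_detailed_balance(p, "CA", perturb = c(nope = 2)),
               "unknown edge")
})

test_that("variant reductions: extreme constants recover the simpler models", {
  p <- default_params()
  d <- 0.2
  target <- function(v, q) active_raf(solve_free_clamped(q, v, d, 0.8))
  # S_total = 0 handled above; K_Sdim -> infinity turns CAS_DS into CAS
  # (the residual coupling at 1e6 x default is s_rel ~ 4e-5)
  q <- p; q$K_Sdim <- 1e6 * p$K_Sdim
  expect_equal(target("CAS_DS", q), target("CAS", q), tolerance = 1e-4)
  # K_Smon -> infinity turns CAS_DS into DS
  q <- p; q$K_Smon <- 1e6 * p$K_Smon
  expect_equal(target("CAS_DS", q), target("DS", q), tolerance = 1e-4)
})

test_that("solved states flatten to a one-row record", {
  st <- solve_totals(default_params(), "CAS_DS")
  df <- as.data.frame(st)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("M", "D00S", "d_free", "active_raf") %in% names(df)))
})
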