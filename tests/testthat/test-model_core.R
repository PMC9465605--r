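test_that("physiological defaults satisfy their invariants", {
  p <- fix_phys()
  expect_length(unclass(p), 26)
  expect_equal(p[["L_b"]], p[["Q_CSF"]] + p[["Q_ISF"]], tolerance = 1e-12)
  expect_error(phys_params(Q_CSF = 2e-4), "L_b")
  expect_error(phys_params(V_plasma = -1), "positive")
  expect_error(phys_params(sigma_TV = 1.2), "reflection")
  expect_error(phys_params(nonsense = 1), "unknown")
  # consistent override keeps the fluid balance valid
  p2 <- phys_params(Q_CSF = 2e-4, L_b = 2.3e-4)
  expect_equal(p2[["Q_CSF"]], 2e-4)
})

test_that("drug parameter validation rejects out-of-range values", {
  expect_error(drug_params("x", 195000, 1.0, 0.9, 0.9, 1), "strictly in")
  expect_error(drug_params("x", 195000, 0.9, 0.9, 0.9, -1), "k_deg")
  expect_error(drug_params("x", -1, 0.9, 0.9, 0.9, 1), "MW")
  expect_error(drug_params("x", 195000, 0.9, 0.9, 0.9, 1, recovery = 0), "recovery")
  d <- drug_egfrviii_tcb()
  expect_equal(d$sigma_BBB, 0.9853)
  expect_equal(d$k_deg, 82.4)
})

test_that("state layout has 13 states each mapped to a volume", {
  expect_length(state_names(), 13)
  v <- state_volumes(fix_phys())
  expect_named(v, state_names())
  expect_true(all(v > 0))
  # the three endosomal species share one volume
  expect_equal(unname(v["tissue_endo_free"]), unname(v["tissue_endo_FcRn"]))
})

test_that("dose arithmetic reproduces the study doses", {
  expect_equal(dose_from_mgkg(15, BW, 195000), 23.846, tolerance = 1e-4)
  expect_equal(dose_from_mgkg(3, BW, 195000), 4.769, tolerance = 1e-3)
  expect_error(dose_from_mgkg(0, BW, 195000), "positive")
  ev3 <- icv_infusion(3, BW, 195000, 20, 3)
  expect_equal(ev3$amount, 4.769, tolerance = 1e-3)
  expect_equal(ev3$duration * 60, 15.5, tolerance = 1e-9)   # minutes
  ev1 <- icv_infusion(1, BW, 195000, 20, 3)
  expect_equal(ev1$duration * 60, 5.1667, tolerance = 1e-4)
  expect_error(icv_infusion(3, BW, 195000, 20, 0), "flow")
  expect_identical(ev3$target, "csf_LV")
  expect_identical(iv_bolus(15, BW, 195000)$target, "plasma")
})

test_that("rhs matches an independent flux-by-flux implementation", {
  phys <- fix_phys(); drug <- fix_drug()
  set.seed(42)
  for (rep in 1:5) {
    A <- setNames(runif(13, 0, 10), state_names())
    A[["tissue_endo_FcRn"]] <- runif(1, 0, 70)
    d_pkg <- rpbpk_rhs(A, phys, drug)
    d_ref <- ref_rhs(A, phys, drug)
    expect_equal(d_pkg, d_ref, tolerance = 1e-12)
  }
  # with an active ICV infusion
  inf <- c(csf_LV = 18.5)
  A <- setNames(rep(1, 13), state_names())
  expect_equal(rpbpk_rhs(A, phys, drug, inf),
               ref_rhs(A, phys, drug, c(rep(0, 8), 18.5, rep(0, 4))),
               tolerance = 1e-12)
})

test_that("rhs conserves drug when k_deg = 0 and respects full reflection", {
  phys <- fix_phys(); drug <- fix_drug(k_deg = 0)
  A <- setNames(runif(13, 0, 5), state_names())
  d <- rpbpk_rhs(A, phys, drug, infusion_rate = c(csf_LV = 7))
  expect_equal(sum(d[drug_states()]), 7, tolerance = 1e-10)
  # receptor pool: free FcRn + complex derivative sums to zero
  expect_equal(sum(d[c("tissue_endo_FcRn", "tissue_endo_complex")]) -
                 d[["tissue_endo_complex"]] * 0,
               d[["tissue_endo_FcRn"]] + d[["tissue_endo_complex"]],
               tolerance = 1e-12)

  # sigma = 1 at both barriers, empty brain: brain states stay empty
  shut <- fix_drug(sigma_BBB = 1 - 1e-15, sigma_BCSFB = 1 - 1e-15,
                   sigma_CSF_ISF = 1 - 1e-15)
  A0 <- setNames(numeric(13), state_names())
  A0[["plasma"]] <- 10
  d0 <- rpbpk_rhs(A0, phys, shut)
  brain <- c("csf_LV", "csf_TFV", "csf_CM", "csf_SAS", "brain_isf")
  expect_equal(unname(d0[brain]), rep(0, 5), tolerance = 1e-12)
  expect_error(rpbpk_rhs(c(A0[-1], NA), phys, drug), "finite")
  expect_error(rpbpk_rhs(A0, phys, drug, infusion_rate = c(bogus = 1)),
               "unknown compartment")
})

test_that("BBB influx at unit brain-vascular concentration is (1-sigma)*Q_ISF", {
  phys <- fix_phys(); drug <- fix_drug()
  A <- setNames(numeric(13), state_names())
  A[["brain_vasc"]] <- phys[["V_brain_vasc"]] * 1  # C_bv = 1 nM
  d <- rpbpk_rhs(A, phys, drug)
  expect_equal(d[["brain_isf"]], (1 - 0.9853) * 3.0e-5 * 1, tolerance = 1e-10)
  expect_equal(d[["brain_isf"]], 4.41e-7, tolerance = 1e-3)
})

test_that("zero doses give all-zero drug states and constant FcRn", {
  phys <- fix_phys(); drug <- fix_drug()
  sim <- simulate_rpbpk(phys, drug, list(), t_grid = seq(0, 10, 1))
  expect_true(all(sim$amounts[, drug_states()] == 0))
  expect_equal(unname(sim$amounts[, "tissue_endo_FcRn"]),
               rep(phys[["FcRn_SS"]] * phys[["V_tissue_endo"]], 11),
               tolerance = 1e-12)
})

test_that("IV bolus with k_deg = 0 conserves total drug to 1e-6 relative", {
  phys <- fix_phys(); drug <- fix_drug(k_deg = 0)
  dose <- dose_from_mgkg(15, BW, 195000)
  sim <- simulate_rpbpk(phys, drug, iv_bolus(15, BW, 195000),
                        t_grid = default_grid(48))
  expect_lt(max(abs(total_drug(sim) - dose)) / dose, 1e-6)
})

test_that("ICV infusion conserves cumulative administered amount", {
  phys <- fix_phys(); drug <- fix_drug(k_deg = 0)
  ev <- icv_infusion(3, BW, 195000)
  sim <- simulate_rpbpk(phys, drug, ev, t_grid = default_grid(48))
  rate <- ev$amount / ev$duration
  administered <- pmin(sim$t, ev$duration) * rate
  during_after <- sim$t > 0
  expect_lt(max(abs(total_drug(sim)[during_after] -
                    administered[during_after]) / ev$amount), 1e-6)
})

test_that("initial serum concentration equals dose over plasma volume", {
  sim <- simulate_rpbpk(fix_phys(), fix_drug(), iv_bolus(15, BW, 195000),
                        t_grid = c(0, 0.01, 0.1))
  c0 <- unname(sim$conc[1, "plasma"])
  expect_equal(c0, 23.846 / 0.0067, tolerance = 1e-3)
  expect_equal(c0, 3559, tolerance = 1e-3)
})

test_that("FcRn total (free + complex) is conserved through a simulation", {
  phys <- fix_phys()
  sim <- simulate_rpbpk(phys, fix_drug(), iv_bolus(15, BW, 195000),
                        t_grid = default_grid(48))
  tot <- sim$amounts[, "tissue_endo_FcRn"] + sim$amounts[, "tissue_endo_complex"]
  expected <- phys[["FcRn_SS"]] * phys[["V_tissue_endo"]]
  expect_lt(max(abs(tot - expected)) / expected, 1e-6)
})

test_that("all states stay non-negative within solver tolerance", {
  for (ev in list(iv_bolus(15, BW, 195000), icv_infusion(1, BW, 195000))) {
    sim <- simulate_rpbpk(fix_phys(), fix_drug(), ev,
                          t_grid = default_grid(48))
    expect_gt(min(sim$amounts), -1e-9)
  }
})

test_that("integrator matches a matrix-exponential oracle on the linear reduction", {
  skip_if_not_installed("Matrix")
  # with k_on = 0 the system is linear; its matrix is the model Jacobian
  phys <- fix_phys(k_on_FcRn = 0)
  drug <- fix_drug()
  M <- rpbpk:::.jac_cpp(numeric(13), rpbpk:::pack_phys(phys),
                        rpbpk:::pack_drug(drug))
  y0 <- numeric(13); y0[1] <- dose_from_mgkg(15, BW, 195000)
  y0[6] <- phys[["FcRn_SS"]] * phys[["V_tissue_endo"]]
  sim <- simulate_rpbpk(phys, drug, iv_bolus(15, BW, 195000),
                        t_grid = c(0, 0.5, 2, 12, 48),
                        rtol = 1e-10, atol = 1e-12)
  for (i in 2:5) {
    t <- sim$t[i]
    y_exact <- as.numeric(Matrix::expm(M * t) %*% y0)
    # mixed norm: absolute floor at the solver atol scale
    expect_true(all(abs(sim$amounts[i, ] - y_exact) <
                      1e-6 * abs(y_exact) + 1e-9))
  }
})

test_that("dose-normalized ICV CSF and ISF profiles superimpose (linearity)", {
  phys <- fix_phys(); drug <- fix_drug()
  tg <- default_grid(48)
  # proportional inputs (equal infusion duration): superposition is exact
  # up to solver error because endosomal drug stays far below FcRn_SS
  dur <- icv_infusion(3, BW, 195000)$duration
  ev1 <- rpbpk:::new_dose_event("ICV", dose_from_mgkg(1, BW, 195000) , 0, dur,
                                "csf_LV")
  ev3 <- icv_infusion(3, BW, 195000)
  s1 <- simulate_rpbpk(phys, drug, ev1, t_grid = tg)
  s3 <- simulate_rpbpk(phys, drug, ev3, t_grid = tg)
  sel <- tg > dur
  for (comp in c("csf_CM", "brain_isf")) {
    c1 <- s1$conc[sel, comp]; c3 <- s3$conc[sel, comp] / 3
    expect_lt(max(abs(c1 - c3) / pmax(c3, 1e-12)), 0.01)
  }
  # the study schedules (same pump rate, hence different durations) converge
  # to the same dose-normalized curves once the input-timing transient decays
  s1r <- simulate_rpbpk(phys, drug, icv_infusion(1, BW, 195000), t_grid = tg)
  late <- tg >= 12
  for (comp in c("csf_CM", "brain_isf")) {
    c1 <- s1r$conc[late, comp]; c3 <- s3$conc[late, comp] / 3
    expect_lt(max(abs(c1 - c3) / pmax(c3, 1e-12)), 0.01)
  }
})

test_that("brain-vascular concentration tracks plasma after distribution", {
  sim <- simulate_rpbpk(fix_phys(), fix_drug(), iv_bolus(15, BW, 195000),
                        t_grid = default_grid(48))
  sel <- sim$t >= 1
  rel <- abs(sim$conc[sel, "brain_vasc"] - sim$conc[sel, "plasma"]) /
    sim$conc[sel, "plasma"]
  expect_lt(max(rel), 0.015)
})

test_that("simulation errors are informative", {
  phys <- fix_phys(); drug <- fix_drug()
  expect_error(simulate_rpbpk(phys, drug, iv_bolus(15, BW, 195000, t_start = 100),
                              t_grid = seq(0, 48, 1)), "outside")
  expect_error(simulate_rpbpk(phys, drug, iv_bolus(15, BW, 195000),
                              t_grid = c(0, 1, 1)), "increasing")
})

test_that("simulation result is self-consistent (conc = amount / volume)", {
  phys <- fix_phys()
  sim <- simulate_rpbpk(phys, fix_drug(), iv_bolus(15, BW, 195000),
                        t_grid = seq(0, 24, 0.5))
  v <- state_volumes(phys)
  expect_equal(sim$conc, sweep(sim$amounts, 2, v, "/"), tolerance = 1e-12)
  df <- as.data.frame(sim)
  expect_identical(dim(df), c(49L, 14L))
})
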