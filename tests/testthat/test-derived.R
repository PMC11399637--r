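test_that("half-life identity ln2 * Vd / CL", {
  expect_equal(half_life(list(Vd = 2.2, CL = 2.2)), log(2))
  # typical per-kg values (typical-value arithmetic, not the published
  # individual-mean summaries)
  expect_equal(half_life(list(Vd = 3.14, CL = 1.53)), 1.4226, tolerance = 1e-4)
  expect_equal(half_life(list(Vd = 0.62, CL = 0.15)), 2.865, tolerance = 1e-3)
  expect_equal(half_life(list(Vd = 0.51, CL = 0.15)), 2.357, tolerance = 1e-3)
})

test_that("AUC to infinity: route identity and quadrature oracle", {
  p <- structural_params(F = 1, ka = 0.7, Vd = 1.02, CL = 0.3)
  expect_equal(auc_inf(p, 64, "IV"), auc_inf(p, 64, "ORAL"))
  # typical SDZ IV at 32 mg/kg on the per-kg basis
  p_sdz <- structural_params(F = 0.99, ka = 0.71, Vd = 0.51, CL = 0.15)
  expect_equal(auc_inf(p_sdz, 32, "IV"), 213.33, tolerance = 1e-4)
  # quadrature of the actual curves
  q_iv <- integrate(function(t) conc_iv_1cmt(p_sdz, 32, t), 0, Inf,
                    rel.tol = 1e-9)$value
  expect_equal(q_iv, auc_inf(p_sdz, 32, "IV"), tolerance = 1e-4)
  q_or <- integrate(function(t) conc_oral_1cmt(p_sdz, 32, t), 0, 2000,
                    rel.tol = 1e-9)$value
  expect_equal(q_or, auc_inf(p_sdz, 32, "ORAL"), tolerance = 1e-4)
})

test_that("unbound fraction arithmetic is linear", {
  spec <- binding_spec()
  expect_equal(unbound(10, spec, "SDZ"), 2)     # 80% bound
  expect_equal(unbound(1, spec, "TMP"), 0.23)   # 77% bound
  expect_equal(unbound(10, spec, "SMX"), 3.8)   # 62% bound
  free0 <- binding_spec(c(SDZ = 0, SMX = 0, TMP = 0))
  expect_equal(unbound(c(0, 1, 7.5), free0, "SDZ"), c(0, 1, 7.5))
  expect_equal(unbound(4, spec, "SDZ") + unbound(6, spec, "SDZ"),
               unbound(10, spec, "SDZ"))
  expect_error(binding_spec(c(SDZ = 1)), "\\[0, 1\\)")
})

test_that("ratio trajectory, target attainment and duration", {
  tt <- seq(0, 24, by = 0.05)
  spec <- binding_spec()
  # equal free concentrations give ratio one everywhere
  eq <- binding_spec(c(SDZ = 0.5, SMX = 0.5, TMP = 0.5))
  rt <- ratio_trajectory(rep(2, length(tt)), rep(2, length(tt)), tt, eq, "SDZ")
  expect_true(all(rt$ratio == 1))
  expect_true(rt$attained)
  expect_equal(rt$duration_h, 24)
  # hand-computed Bateman oracle at t = 12 h for the registered oral doses
  # (25 mg/kg SDZ + 5 mg/kg TMP, per-kg typical parameters):
  # SDZ: ke = 0.15/0.51, C = .99*25*.71/(0.51*(0.71-ke))*(e^-ke*12 - e^-.71*12)
  # TMP: ke = 1.53/3.14, C = .99*5*.59/(3.14*(0.59-ke))*(e^-ke*12 - e^-.59*12)
  ke_s <- 0.15 / 0.51
  c_s <- 0.99 * 25 * 0.71 / (0.51 * (0.71 - ke_s)) *
    (exp(-ke_s * 12) - exp(-0.71 * 12))
  ke_t <- 1.53 / 3.14
  c_t <- 0.99 * 5 * 0.59 / (3.14 * (0.59 - ke_t)) *
    (exp(-ke_t * 12) - exp(-0.59 * 12))
  hand_ratio <- (c_t * 0.23) / (c_s * 0.20)
  p_s <- structural_params(F = 0.99, ka = 0.71, Vd = 0.51, CL = 0.15)
  p_t <- structural_params(F = 0.99, ka = 0.59, Vd = 3.14, CL = 1.53)
  rt2 <- ratio_trajectory(conc_oral_1cmt(p_t, 5, tt), conc_oral_1cmt(p_s, 25, tt),
                          tt, spec, "SDZ")
  expect_equal(rt2$ratio[tt == 12], hand_ratio, tolerance = 1e-10)
  # typical birds never reach 1:19 at the registered doses
  expect_false(rt2$attained)
  expect_equal(rt2$duration_h, 0)
  # scaling TMP down 100x keeps attainment impossible
  rt3 <- ratio_trajectory(conc_oral_1cmt(p_t, 0.05, tt),
                          conc_oral_1cmt(p_s, 25, tt), tt, spec, "SDZ")
  expect_false(rt3$attained)
  # rescaling both curves by a common factor leaves the ratio unchanged
  rt4 <- ratio_trajectory(3 * conc_oral_1cmt(p_t, 5, tt),
                          3 * conc_oral_1cmt(p_s, 25, tt), tt, spec, "SDZ")
  expect_equal(rt4$ratio, rt2$ratio)
  # zero sulfonamide concentration is masked, not divided
  rt5 <- ratio_trajectory(c(1, 1), c(0, 2), c(0, 1), spec, "SDZ")
  expect_true(is.na(rt5$ratio[1]))
  expect_equal(rt5$n_masked, 1)
})

test_that("duration above target interpolates threshold crossings", {
  # synthetic ratio curve crossing 1/19 between grid points: build
  # concentrations whose free ratio is linear in time
  tt <- 0:4
  target <- 1 / 19
  r <- c(0.02, 0.04, 0.07, 0.05, 0.02) # up-crossing in (1,2), down in (2,3)
  spec0 <- binding_spec(c(SDZ = 0, SMX = 0, TMP = 0))
  rt <- ratio_trajectory(r, rep(1, 5), tt, spec0, "SDZ", target = target)
  up <- 1 + (target - 0.04) / (0.07 - 0.04)
  down <- 2 + (0.07 - target) / (0.07 - 0.05)
  expect_equal(rt$duration_h, down - up, tolerance = 1e-10)
})

test_that("dose from volume and strength reproduces the label doses", {
  expect_equal(dose_from_volume(0.35, 83.35), 29.1725) # ~29.2 mg/kg SDZ
  expect_equal(dose_from_volume(0.35, 16.65), 5.8275)  # ~5.8 mg/kg TMP
  expect_equal(dose_from_volume(1, 1), 1)
  expect_equal(round(dose_from_volume(0.35, 83.35), 1), 29.2)
  expect_equal(round(dose_from_volume(0.35, 16.65), 1), 5.8)
})
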