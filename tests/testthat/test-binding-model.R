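test_that("Ku has its defining midpoint and limiting behaviour", {
  expect_equal(ku_of_T(330, Tm = 330, dH = 100), 1)
  expect_equal(ku_of_T(332, Tm = 332, dH = 80), 1)
  # strictly increasing in T, vanishing at low temperature
  Ts <- seq(280, 380, by = 5)
  ku <- ku_of_T(Ts, Tm = 330, dH = 100)
  expect_true(all(diff(ku) > 0))
  expect_lt(ku_of_T(100, Tm = 330, dH = 100), 1e-30)
  # independent evaluation via the algebraically rearranged closed form
  dH <- 100; Tm <- 330; T <- 335; R <- 0.0019872041
  expect_equal(ku_of_T(T, Tm, dH),
               exp((dH / R) * (T - Tm) / (T * Tm)), tolerance = 1e-12)
})

test_that("native and folded fractions obey the printed formula exactly", {
  f <- native_fraction(Ku = 1, M_conc = 0)
  expect_equal(f$S_n, 0.5)
  expect_equal(f$folded, 0.5)
  f2 <- native_fraction(Ku = 0, M_conc = 5e-6, Kd = 5e-6)
  expect_equal(f2$S_n, 0.5)      # S_n = (1 + [M]/Kd + Ku)^-1
  expect_equal(f2$folded, 1)     # everything folded when Ku = 0
  # with no ligand the two observables coincide at 1/(1+Ku)
  for (ku in c(0, 0.3, 1, 7)) {
    f3 <- native_fraction(ku, 0)
    expect_equal(f3$S_n, 1 / (1 + ku))
    expect_equal(f3$folded, f3$S_n)
  }
})

test_that("folded fraction decreases with T and increases with ligand", {
  Ts <- seq(298, 363, by = 1)
  ku <- ku_of_T(Ts, 332, 80)
  f0 <- native_fraction(ku, 0)$folded
  expect_true(all(diff(f0) < 0))
  f_lig <- native_fraction(ku, M_conc = 4.5e-6, Kd = 5e-6)$folded
  expect_true(all(f_lig > f0))   # rightward-shifted melt
  # more ligand, more stabilization at fixed T
  f_more <- native_fraction(ku, M_conc = 9e-6, Kd = 5e-6)$folded
  expect_true(all(f_more > f_lig))
})

test_that("baseline subtraction recovers known baselines and is idempotent", {
  # sharp transition (dH 120) so both baseline windows are clean
  raw <- simulate_melt_curve(330, 120, noise_sd = 0,
                             pre = c(-20, 0.01), post = c(-2, 0.005),
                             seed = 1)
  norm <- subtract_baselines(raw)
  expect_lt(abs(norm$baselines$pre[2] - 0.01) / 0.01, 0.05)
  expect_lt(abs(norm$baselines$post[2] - 0.005) / 0.005, 0.05)
  # a normalized sigmoid whose tails are exactly 1 and 0 passes unchanged
  f_exact <- c(rep(1, 15), seq(1, 0, length.out = 36), rep(0, 15))
  clean <- melt_curve(seq(298, by = 1, length.out = 66), f_exact)
  renorm <- subtract_baselines(clean)
  expect_lt(max(abs(renorm$signal - f_exact)), 1e-9)
  # degenerate identical baselines are an error
  flatline <- melt_curve(seq(298, 363, 1), rep(1, 66))
  expect_error(subtract_baselines(flatline), "degenerate|transition")
})

test_that("reference melt fitting recovers Tm and dH", {
  raw <- simulate_melt_curve(332, 80, noise_sd = 0.01, seed = 7)
  fit <- fit_reference_melt(subtract_baselines(raw))
  expect_lt(abs(fit$Tm - 332), 0.5)
  expect_lt(abs(fit$dH - 80) / 80, 0.10)
  # noiseless normalized curve is fit essentially exactly (same model class)
  Ts <- seq(298, 363, by = 1)
  clean <- melt_curve(Ts, native_fraction(ku_of_T(Ts, 330.4, 91))$folded,
                      normalized = TRUE)
  cfit <- fit_reference_melt(clean)
  expect_lt(cfit$rss, 1e-10)
  # flat curve: no transition
  flat <- melt_curve(seq(298, 363, 1), rep(1, 66), normalized = TRUE)
  flat$normalized <- TRUE
  expect_error(fit_reference_melt(flat), "transition")
})

test_that("Kd is recovered from a thermal shift within a factor of 1.5", {
  ref <- subtract_baselines(simulate_melt_curve(332, 80, noise_sd = 0.01,
                                                seed = 7))
  cpx <- subtract_baselines(simulate_melt_curve(332, 80, Kd = 5e-6,
                                                M_conc = 4.5e-6,
                                                noise_sd = 0.01, seed = 3))
  est <- estimate_kd(ref, cpx)
  expect_false(est$unidentifiable)
  expect_lt(max(est$Kd / 5e-6, 5e-6 / est$Kd), 1.5)
})

test_that("a complex curve indistinguishable from the reference is flagged", {
  ref <- subtract_baselines(simulate_melt_curve(332, 80, noise_sd = 0.01,
                                                seed = 7))
  same <- subtract_baselines(simulate_melt_curve(332, 80, noise_sd = 0.01,
                                                 seed = 8))
  same$M_conc <- 4.5e-6
  est <- estimate_kd(ref, same)
  expect_true(est$unidentifiable)
  expect_false(is.na(est$Kd_lower_bound))
})

test_that("stronger binders produce monotonically larger stabilization", {
  ref <- subtract_baselines(simulate_melt_curve(332, 80, noise_sd = 0.005,
                                                seed = 17))
  kds <- c(30, 5, 1, 0.2) * 1e-6
  stab <- vapply(seq_along(kds), function(i) {
    cpx <- subtract_baselines(simulate_melt_curve(
      332, 80, Kd = kds[i], M_conc = 4.5e-6, noise_sd = 0.005,
      seed = 300 + i))
    estimate_kd(ref, cpx)$stabilization_at_Tm
  }, numeric(1))
  expect_true(all(diff(stab) > 0))
})

test_that("melt curves round-trip through the CSV interchange format", {
  c0 <- simulate_melt_curve(332, 80, Kd = 5e-6, M_conc = 4.5e-6,
                            noise_sd = 0.01, seed = 4)
  p <- withr::local_tempfile(fileext = ".csv")
  write_melt_csv(c0, p)
  c1 <- read_melt_csv(p)
  expect_equal(c1$T, c0$T)
  expect_equal(c1$signal, c0$signal, tolerance = 1e-12)
  expect_equal(c1$M_conc, 4.5e-6, tolerance = 1e-12)
})
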