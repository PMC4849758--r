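# Two-state thermal-denaturation model with ligand stabilization.
#
# Ku(T) = [denatured]/[native] is closed with a zero-heat-capacity van't
# Hoff form, Ku(T) = exp(-(dH/R) (1/T - 1/Tm)), so Ku(Tm) = 1.  With a
# ligand at free concentration [M] that binds exclusively the folded state
# with dissociation constant Kd, the native fraction is
#   S_n = (1 + [M]/Kd + Ku)^-1
# and the CD-visible folded fraction (native + complex) is
#   f = (1 + [M]/Kd) * S_n,
# which shifts the apparent melt to higher temperatures as [M]/Kd grows.
# Fitting the reference melt ([M] = 0) fixes (Tm, dH); a one-dimensional
# fit of log10(Kd) to the ligand curve then ranks binder affinities.

R_KCAL <- 0.0019872041  # gas constant, kcal / (mol K)

#' Two-state unfolding equilibrium constant Ku(T)
#'
#' Van't Hoff closure with zero heat-capacity change:
#' `Ku(T) = exp(-(dH/R) * (1/T - 1/Tm))`, so `Ku(Tm) = 1` and Ku is
#' strictly increasing in temperature for positive enthalpy.
#'
#' @param T temperature(s) in Kelvin (> 0).
#' @param Tm midpoint temperature in Kelvin (where Ku = 1).
#' @param dH van't Hoff unfolding enthalpy in kcal/mol (> 0).
#' @return the unfolding equilibrium constant `[denatured]/[native]`.
#' @export
ku_of_T <- function(T, Tm, dH) {
  stopifnot(all(T > 0), Tm > 0, dH > 0)
  exp(-(dH / R_KCAL) * (1 / T - 1 / Tm))
}

#' Native and folded fractions under ligand stabilization
#'
#' Implements `S_n = (1 + [M]/Kd + Ku)^-1` (the native, ligand-free
#' fraction) together with the companion folded fraction
#' `(1 + [M]/Kd) * S_n` (native plus complex), which is the observable
#' modelled for melt curves: the ligand binds only the folded state, so the
#' folded total is stabilized.
#'
#' @param Ku unfolding equilibrium constant(s) (>= 0).
#' @param M_conc ligand concentration, molar (>= 0).
#' @param Kd ligand dissociation constant, molar (> 0).
#' @return list with numeric components `S_n` and `folded`.
#' @export
native_fraction <- function(Ku, M_conc = 0, Kd = Inf) {
  stopifnot(all(Ku >= 0), M_conc >= 0)
  ratio <- if (M_conc == 0) 0 else M_conc / Kd
  S_n <- 1 / (1 + ratio + Ku)
  list(S_n = S_n, folded = (1 + ratio) * S_n)
}

#' Melt curve container
#'
#' @param T temperature grid in Kelvin, strictly increasing, length >= 5.
#' @param signal observable at each temperature (raw or normalized).
#' @param M_conc ligand concentration in molar.
#' @param normalized whether `signal` is already a folded fraction in [0,1].
#' @return an object of class `melt_curve`.
#' @export
melt_curve <- function(T, signal, M_conc = 0, normalized = FALSE) {
  stopifnot(length(T) == length(signal), length(T) >= 5,
            all(diff(T) > 0))
  structure(list(T = as.numeric(T), signal = as.numeric(signal),
                 M_conc = M_conc, normalized = normalized,
                 baselines = NULL),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("melt_curve: %d points, %.1f-%.1f K, [M] = %.3g M%s\n",
              length(x$T), min(x$T), max(x$T), x$M_conc,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Simulate a noisy melt curve
#'
#' Generates `signal = pre_line * f + post_line * (1 - f) + noise`, where
#' `f` is the folded fraction of the two-state model with ligand
#' stabilization and the baselines are straight lines in temperature.
#' Seed-deterministic.
#'
#' @param Tm,dH two-state parameters (Kelvin, kcal/mol).
#' @param Kd ligand dissociation constant, molar (`Inf` for no ligand).
#' @param M_conc ligand concentration, molar.
#' @param T_grid temperature grid in Kelvin (default 298-363 K, 1 K steps,
#'   the conventional span of a protein CD melt).
#' @param pre,post baseline `c(intercept, slope)` for the folded and
#'   unfolded states (signal units, units/K).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed integer seed.
#' @return a `melt_curve`.
#' @export
simulate_melt_curve <- function(Tm, dH, Kd = Inf, M_conc = 0,
                                T_grid = seq(298, 363, by = 1),
                                pre = c(-20, 0.01), post = c(-2, 0.005),
                                noise_sd = 0, seed = 1) {
  f <- native_fraction(ku_of_T(T_grid, Tm, dH), M_conc, Kd)$folded
  pre_line <- pre[1] + pre[2] * T_grid
  post_line <- post[1] + post[2] * T_grid
  set.seed(seed)
  sig <- pre_line * f + post_line * (1 - f) +
    stats::rnorm(length(T_grid), sd = noise_sd)
  melt_curve(T_grid, sig, M_conc = M_conc, normalized = FALSE)
}

#' Subtract linear baselines and normalize a melt curve
#'
#' Fits straight lines to the initial and final fractions of the
#' temperature grid and rescales the signal to the folded fraction
#' `f(T) = (signal - post_line) / (pre_line - post_line)`, clipped to
#' `[-0.1, 1.1]`.
#'
#' @param c a `melt_curve`.
#' @param pre_window,post_window fractions of the temperature grid used for
#'   the pre- and post-transition baselines (defaults 0.15).
#' @return a normalized `melt_curve` with the fitted baselines attached.
#' @export
subtract_baselines <- function(c, pre_window = 0.15, post_window = 0.15) {
  stopifnot(inherits(c, "melt_curve"))
  n <- length(c$T)
  n_pre <- max(3, floor(n * pre_window))
  n_post <- max(3, floor(n * post_window))
  if (n_pre + n_post > n)
    stop("baseline windows exceed the curve length")
  idx_pre <- seq_len(n_pre)
  idx_post <- seq(n - n_post + 1, n)
  fit_pre <- stats::lm(signal ~ T, data = data.frame(T = c$T[idx_pre],
                                                     signal = c$signal[idx_pre]))
  fit_post <- stats::lm(signal ~ T, data = data.frame(T = c$T[idx_post],
                                                      signal = c$signal[idx_post]))
  pre_line <- stats::predict(fit_pre, data.frame(T = c$T))
  post_line <- stats::predict(fit_post, data.frame(T = c$T))
  denom <- pre_line - post_line
  if (mean(abs(denom)) < 1e-8 * max(1, mean(abs(c$signal))))
    stop("degenerate baselines: pre- and post-transition lines coincide")
  f <- (c$signal - post_line) / denom
  out <- melt_curve(c$T, pmin(1.1, pmax(-0.1, f)), M_conc = c$M_conc,
                    normalized = TRUE)
  out$baselines <- list(pre = unname(stats::coef(fit_pre)),
                        post = unname(stats::coef(fit_post)))
  out
}

melt_ss <- function(curve, Tm, dH, M_conc = 0, Kd = Inf) {
  f <- native_fraction(ku_of_T(curve$T, Tm, dH), M_conc, Kd)$folded
  sum((curve$signal - f)^2)
}

#' Fit the reference (ligand-free) melt curve
#'
#' Least-squares fit of `f(T) = 1/(1 + Ku(T))` over `(Tm, dH)` to a
#' normalized, ligand-free melt curve.  Deterministic: a fixed multi-start
#' grid (Tm at 1 K steps over the observed range, dH from 20 to 200
#' kcal/mol at 10 kcal/mol steps) followed by local refinement.
#'
#' @param c a normalized `melt_curve` with `M_conc = 0`.
#' @return list with `Tm` (K), `dH` (kcal/mol), and `rss` (residual sum of
#'   squares).
#' @export
fit_reference_melt <- function(c) {
  stopifnot(inherits(c, "melt_curve"))
  if (!c$normalized)
    stop("curve must be normalized first (subtract_baselines)")
  if (c$M_conc != 0)
    stop("reference melt must be ligand-free (M_conc = 0)")
  # a transition must be present: the curve has to fall substantially
  if (diff(range(c$signal)) < 0.5)
    stop("no unfolding transition detected in the reference curve")
  grid <- expand.grid(Tm = seq(ceiling(min(c$T)), floor(max(c$T)), by = 1),
                      dH = seq(20, 200, by = 10))
  ss <- mapply(function(Tm, dH) melt_ss(c, Tm, dH), grid$Tm, grid$dH)
  best <- grid[which.min(ss), ]
  fit <- stats::optim(c(best$Tm, best$dH),
                      function(p) {
                        if (p[1] <= 0 || p[2] <= 0) return(1e10)
                        melt_ss(c, p[1], p[2])
                      },
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(Tm = fit$par[1], dH = fit$par[2], rss = fit$value)
}

#' Estimate a ligand dissociation constant from a thermal shift
#'
#' Fixes the two-state parameters from the ligand-free reference curve,
#' then performs a one-dimensional least-squares fit of `log10(Kd)` on the
#' ligand curve using the folded fraction.  Reports the fitted Kd, the fit
#' residual, and the folded-fraction increase at the reference midpoint
#' (the stabilization readout).  The model provides a relative ranking of
#' binder affinities, not absolute thermodynamics: when the ligand curve is
#' indistinguishable from the reference the Kd is unidentifiable and only a
#' lower bound is reported (`unidentifiable = TRUE`).
#'
#' @param protein_curve normalized ligand-free `melt_curve`.
#' @param complex_curve normalized `melt_curve` with `M_conc > 0` (molar).
#' @param log10_kd_range search interval for `log10(Kd / M)`.
#' @return list with `Kd` (molar), `log10_Kd`, `Tm`, `dH`, `rss`,
#'   `stabilization_at_Tm` (folded-fraction increase at the reference Tm)
#'   and `unidentifiable`.
#' @export
estimate_kd <- function(protein_curve, complex_curve,
                        log10_kd_range = c(-9, -1)) {
  stopifnot(inherits(complex_curve, "melt_curve"))
  if (complex_curve$M_conc <= 0)
    stop("complex curve must have M_conc > 0")
  if (!complex_curve$normalized)
    stop("complex curve must be normalized first (subtract_baselines)")
  ref <- fit_reference_melt(protein_curve)
  M <- complex_curve$M_conc
  obj <- function(lk) melt_ss(complex_curve, ref$Tm, ref$dH, M, 10^lk)
  fit <- stats::optimize(obj, interval = log10_kd_range, tol = 1e-6)
  lk <- fit$minimum
  kd <- 10^lk
  stab <- native_fraction(1, M, kd)$folded - 0.5  # Ku(Tm) = 1 exactly
  # unidentifiable: no meaningful improvement over "no binding", or the
  # optimum pinned at the weak-affinity end of the search interval
  ss_none <- melt_ss(complex_curve, ref$Tm, ref$dH, 0, Inf)
  unident <- (lk > log10_kd_range[2] - 0.05) ||
    (ss_none - fit$objective) < 1e-4 * max(ss_none, 1e-12) ||
    stab < 0.02
  list(Kd = kd, log10_Kd = lk, Tm = ref$Tm, dH = ref$dH,
       rss = fit$objective, stabilization_at_Tm = stab,
       unidentifiable = unident,
       Kd_lower_bound = if (unident) kd else NA_real_)
}

## ---- melt curve file I/O ----------------------------------------------------

#' Read or write a melt curve as two-column CSV
#'
#' The format is `T_K,signal` with `#`-prefixed metadata header lines; the
#' ligand concentration travels as `# M_conc_uM=<value>`.
#'
#' @param path CSV file path.
#' @param c a `melt_curve` (for writing).
#' @return a `melt_curve` (for reading) or the path, invisibly.
#' @export
read_melt_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  m_conc <- 0
  hit <- grep("M_conc_uM\\s*=", meta, value = TRUE)
  if (length(hit) > 0)
    m_conc <- as.numeric(sub(".*M_conc_uM\\s*=\\s*", "", hit[1])) * 1e-6
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  melt_curve(df[[1]], df[[2]], M_conc = m_conc)
}

#' @rdname read_melt_csv
#' @export
write_melt_csv <- function(c, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# M_conc_uM=%g", c$M_conc * 1e6), con)
  utils::write.csv(data.frame(T_K = c$T, signal = c$signal), con,
                   row.names = FALSE)
  invisible(path)
}
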