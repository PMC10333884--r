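#' Bound probe fraction under the 1:1 ligand-depletion (quadratic) model
#'
#' Fraction of total labeled probe in complex, given total protein
#' `p_total`, total probe `l_total` and dissociation constant `kd`
#' (all micromolar):
#' `[PL] = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`.
#'
#' @param p_total,l_total,kd Concentrations in micromolar.
#' @return `[PL] / l_total`, the bound fraction.
#' @export
quadratic_bound_fraction <- function(p_total, l_total, kd) {
  s <- p_total + l_total + kd
  pl <- (s - sqrt(s^2 - 4 * p_total * l_total)) / 2
  pl / l_total
}

new_fp_fit <- function(kind, estimates, data, fit = NULL, no_binding = FALSE,
                       extra = list()) {
  structure(c(list(kind = kind, estimates = estimates, data = data,
                   fit = fit, no_binding = no_binding), extra),
            class = "fp_fit")
}

nls_estimates <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble(term = rownames(sm), estimate = unname(sm[, "Estimate"]),
         std_error = unname(sm[, "Std. Error"]))
}

#' Fit an FP saturation curve (quadratic 1:1 model)
#'
#' Least-squares fit of `signal = s_free + (s_bound - s_free) * f(P)`
#' where `f` is the quadratic bound-probe fraction, accounting for probe
#' depletion at protein concentrations near the probe concentration.
#' Initial guesses: `s_free`/`s_bound` from the signal extremes, `kd`
#' from the concentration at half-maximal signal.
#'
#' @param data Tibble with `concentration` (total protein, micromolar)
#'   and `signal` (mP).
#' @param probe_total Total labeled-probe concentration in micromolar
#'   (e.g. 5 nM = 0.005).
#' @return An `fp_fit` object; `tidy()` gives the parameter table,
#'   `glance()` the one-row summary including `kd`.
#' @export
fit_saturation <- function(data, probe_total) {
  stopifnot(all(c("concentration", "signal") %in% names(data)),
            nrow(data) >= 5, all(data$concentration >= 0))
  half <- min(data$signal) + diff(range(data$signal)) / 2
  kd0 <- data$concentration[which.min(abs(data$signal - half))]
  kd0 <- max(kd0, probe_total, 1e-6)
  fit <- minpack.lm::nlsLM(
    signal ~ s_free + (s_bound - s_free) *
      quadratic_bound_fraction(concentration, probe_total, kd),
    data = data,
    start = list(s_free = min(data$signal), s_bound = max(data$signal),
                 kd = kd0),
    lower = c(-Inf, -Inf, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- nls_estimates(fit)
  kd <- est$estimate[est$term == "kd"]
  at_bound <- kd <= 2e-9
  new_fp_fit("saturation", est, data, fit,
             extra = list(kd = unname(kd), probe_total = probe_total,
                          kd_at_bound = at_bound))
}

#' Fit an FP displacement curve
#'
#' Descending logistic in concentration,
#' `signal = s_bottom + (s_top - s_bottom) / (1 + (x / ic50)^h)`, with
#' either a fixed unit slope (`h = 1`, the default) or a free slope. The
#' IC50 is the total competitor concentration at half-maximal signal
#' change. Curves displacing less than `min_displacement` of the
#' reference amplitude at the highest competitor concentration are
#' flagged "no binding" and no IC50 is reported.
#'
#' @param data Tibble with `concentration` (total unlabeled competitor,
#'   micromolar; zero rows allowed) and `signal` (mP).
#' @param fixed_slope Fit with Hill slope fixed at 1 (default TRUE).
#' @param min_displacement Fraction of the amplitude below which the
#'   curve is called "no binding" (default 0.2).
#' @param signal_free Optional mP of the free probe (full displacement
#'   floor); when absent the observed top signal is the reference and the
#'   displacement fraction is `(top - min) / top`.
#' @return An `fp_fit` object with `ic50` (NA when flagged no binding).
#' @export
fit_displacement <- function(data, fixed_slope = TRUE,
                             min_displacement = 0.2, signal_free = NULL) {
  stopifnot(all(c("concentration", "signal") %in% names(data)),
            nrow(data) >= 5, all(data$concentration >= 0))
  top <- mean(data$signal[data$concentration ==
                            min(data$concentration)])
  floor_sig <- mean(data$signal[data$concentration ==
                                  max(data$concentration)])
  disp_frac <- if (!is.null(signal_free)) {
    (top - floor_sig) / (top - signal_free)
  } else {
    (top - floor_sig) / abs(top)
  }
  if (!is.finite(disp_frac) || disp_frac < min_displacement) {
    return(new_fp_fit("displacement", tibble(), data, no_binding = TRUE,
                      extra = list(ic50 = NA_real_,
                                   displacement_fraction = disp_frac)))
  }
  half <- (top + floor_sig) / 2
  pos <- data[data$concentration > 0, ]
  ic50_0 <- pos$concentration[which.min(abs(pos$signal - half))]
  fit <- if (fixed_slope) {
    minpack.lm::nlsLM(
      signal ~ s_bottom + (s_top - s_bottom) / (1 + concentration / ic50),
      data = data,
      start = list(s_top = top, s_bottom = floor_sig, ic50 = ic50_0),
      lower = c(-Inf, -Inf, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(
      signal ~ s_bottom + (s_top - s_bottom) /
        (1 + (concentration / ic50)^h),
      data = data,
      start = list(s_top = top, s_bottom = floor_sig, ic50 = ic50_0, h = 1),
      lower = c(-Inf, -Inf, 1e-12, 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  est <- nls_estimates(fit)
  new_fp_fit("displacement", est, data, fit,
             extra = list(ic50 = unname(est$estimate[est$term == "ic50"]),
                          displacement_fraction = disp_frac))
}

#' Solve the three-species competitive binding equilibrium
#'
#' Mass-balance solution for protein P binding a labeled probe L
#' (dissociation constant `probe_kd`) and an unlabeled competitor I
#' (dissociation constant `ki`) simultaneously. Free protein is found by
#' monotone root bracketing; all other species follow. Used both as the
#' displacement-curve generator and as the numeric oracle for
#' [ki_from_ic50()].
#'
#' @param protein_total,probe_total,competitor_total Total concentrations
#'   (micromolar); `competitor_total` may be a vector.
#' @param probe_kd,ki Dissociation constants (micromolar).
#' @return A tibble with one row per competitor concentration: free `p`,
#'   `l`, `i`, complexes `pl`, `pi`, and `bound_fraction` (= pl /
#'   probe_total).
#' @export
solve_competitive_equilibrium <- function(protein_total, probe_total,
                                          competitor_total, probe_kd, ki) {
  one <- function(it) {
    f <- function(p) {
      l <- probe_total / (1 + p / probe_kd)
      i <- it / (1 + p / ki)
      p + p * l / probe_kd + p * i / ki - protein_total
    }
    p <- uniroot(f, c(0, protein_total), tol = 1e-12)$root
    l <- probe_total / (1 + p / probe_kd)
    i <- it / (1 + p / ki)
    tibble(p = p, l = l, i = i, pl = p * l / probe_kd, pi = p * i / ki,
           bound_fraction = p * l / probe_kd / probe_total)
  }
  bind_rows(lapply(competitor_total, one)) |>
    mutate(competitor_total = competitor_total, .before = 1)
}

#' Competitor K_i from a displacement IC50 (exact analysis)
#'
#' Exact conversion for competitive FP displacement under ligand and
#' protein depletion. At zero competitor the bound probe `[PL]0` follows
#' the quadratic model; the IC50 is defined as the total competitor
#' concentration at which `[PL] = [PL]0 / 2`. Free-species
#' concentrations at that point follow from the mass balances, and
#' `Ki = [P]50 [I]50 / [PI]50`. This matches the numeric three-species
#' equilibrium solver to within numerical precision.
#'
#' @param ic50 Total competitor concentration at half displacement
#'   (micromolar).
#' @param probe_kd Dissociation constant of the labeled probe
#'   (micromolar).
#' @param probe_total,protein_total Total probe and protein
#'   concentrations in the displacement mixture (micromolar).
#' @return The competitor dissociation constant K_i (micromolar).
#' @export
ki_from_ic50 <- function(ic50, probe_kd, probe_total, protein_total) {
  stopifnot(probe_kd > 0, probe_total > 0, protein_total > 0,
            all(ic50 >= 0))
  s <- protein_total + probe_total + probe_kd
  pl0 <- (s - sqrt(s^2 - 4 * protein_total * probe_total)) / 2
  pl50 <- pl0 / 2
  l50 <- probe_total - pl50
  p50 <- probe_kd * pl50 / l50
  pi50 <- protein_total - p50 - pl50
  i50 <- ic50 - pi50
  if (any(i50 <= 0)) {
    abort("ic50 below the theoretical minimum for this complex concentration")
  }
  p50 * i50 / pi50
}

#' Back-calculate the active protein fraction from a saturation curve
#'
#' With the probe K_D known (from a reference preparation), refits the
#' quadratic saturation model with the protein concentrations scaled by
#' a single multiplicative active-fraction parameter. Used to normalize
#' displacement amplitudes between protein preparations.
#'
#' @param data Tibble with `concentration` (nominal total protein,
#'   micromolar) and `signal` (mP).
#' @param probe_kd Known probe dissociation constant (micromolar).
#' @param probe_total Total probe concentration (micromolar).
#' @return An `fp_fit` object with `active_fraction` (constrained to
#'   (0, 1.5]).
#' @export
back_calculate_active_fraction <- function(data, probe_kd, probe_total) {
  stopifnot(nrow(data) >= 5)
  fit <- minpack.lm::nlsLM(
    signal ~ s_free + (s_bound - s_free) *
      quadratic_bound_fraction(active * concentration, probe_total,
                               probe_kd),
    data = data,
    start = list(s_free = min(data$signal), s_bound = max(data$signal),
                 active = 1),
    lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 1.5),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  est <- nls_estimates(fit)
  new_fp_fit("active_fraction", est, data, fit,
             extra = list(active_fraction =
                            unname(est$estimate[est$term == "active"]),
                          probe_kd = probe_kd, probe_total = probe_total))
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("FP fit (", x$kind, ")\n", sep = "")
  if (isTRUE(x$no_binding)) {
    cat("  no binding (displacement below threshold)\n")
    return(invisible(x))
  }
  print(x$estimates)
  invisible(x)
}
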