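# Nonlinear least squares via Levenberg-Marquardt with a numeric Jacobian.
# Used instead of stats::nls for every kinetic fit because the synthetic
# oracles routinely produce zero-residual data, on which nls aborts.
# Asymptotic CIs come from the Jacobian at the optimum.
lm_nls <- function(fn, par, y, lower = NULL, upper = NULL,
                   maxit = 200L, tol = 1e-12) {
  p <- length(par)
  if (is.null(lower)) lower <- rep(-Inf, p)
  if (is.null(upper)) upper <- rep(Inf, p)
  clamp <- function(th) pmin(pmax(th, lower), upper)
  resid <- function(th) y - fn(th)
  jac <- function(th) {
    J <- matrix(0, length(y), p)
    for (j in seq_len(p)) {
      h <- max(1e-7 * abs(th[j]), 1e-9)
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      J[, j] <- (fn(tp) - fn(tm)) / (2 * h)
    }
    J
  }
  th <- clamp(par)
  r <- resid(th)
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  for (it in seq_len(maxit)) {
    J <- jac(th)
    g <- crossprod(J, r)
    A <- crossprod(J)
    step_ok <- FALSE
    for (tries in seq_len(30L)) {
      H <- A + lambda * diag(pmax(diag(A), 1e-12), p)
      step <- try(solve(H, g), silent = TRUE)
      if (!inherits(step, "try-error")) {
        cand <- clamp(th + as.numeric(step))
        rc <- resid(cand)
        rssc <- sum(rc^2)
        if (is.finite(rssc) && rssc <= rss) {
          improve <- rss - rssc
          th <- cand; r <- rc; rss <- rssc
          lambda <- max(lambda / 4, 1e-12)
          step_ok <- TRUE
          if (improve <= tol * (rss + tol)) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok || converged) {
      converged <- converged || !step_ok && it > 1L
      break
    }
  }
  J <- jac(th)
  dof <- max(length(y) - p, 1L)
  s2 <- rss / dof
  covm <- try(s2 * solve(crossprod(J) +
                           diag(1e-300, p)), silent = TRUE)
  se <- if (inherits(covm, "try-error")) rep(NA_real_, p) else sqrt(pmax(diag(covm), 0))
  tq <- qt(0.975, dof)
  list(par = th, se = se, ci = cbind(lower = th - tq * se,
                                     upper = th + tq * se),
       rss = rss, residual_norm = sqrt(rss), dof = dof,
       converged = converged, fitted = fn(th))
}

new_fit <- function(class, par, fit, extra = list()) {
  out <- c(as.list(par), list(se = stats::setNames(fit$se, names(par)),
                              ci = fit$ci, residual_norm = fit$residual_norm,
                              rss = fit$rss, converged = fit$converged,
                              fitted = fit$fitted), extra)
  rownames(out$ci) <- names(par)
  structure(out, class = c(class, "gatekin_fit"))
}

#' @export
print.gatekin_fit <- function(x, ...) {
  pars <- setdiff(names(x), c("se", "ci", "residual_norm", "rss", "converged",
                              "fitted", "data", "warnings"))
  cat(sprintf("<%s>\n", class(x)[1]))
  for (p in pars)
    if (is.numeric(x[[p]]) && length(x[[p]]) == 1L)
      cat(sprintf("  %-18s %.6g\n", p, x[[p]]))
  cat(sprintf("  residual norm      %.3g\n", x$residual_norm))
  invisible(x)
}

#' Mono-exponential relaxation of a capacitive peak current
#'
#' Detects the peak of a 0 mV trace (first sample after pulse onset
#' exceeding five baseline SDs marks the onset; the extremum after onset is
#' the peak) and fits `I(t) = A exp(-k (t - t_peak)) + C` from the peak
#' onward. The relaxation rate k is the flipping rate: at saturating
#' substrate it reports the binding + occlusion + inward-opening transition,
#' the slowest step of the forward path under zeroed gradients.
#'
#' @param trace current_trace_set (mode `peak_0mV` or compatible)
#' @return object of class `mono_exp_fit` with `K` (1/s), `A`, `C`,
#'   per-parameter 95 percent CIs and the residual norm
#' @export
fit_peak_relaxation <- function(trace) {
  t <- trace$time_s
  i <- trace$current
  if (sd(i) == 0) stopf("constant trace: nothing to fit")
  onset_t <- trace$protocol$pulse_start_s
  base <- i[t < onset_t]
  if (length(base) >= 5L && sd(base) > 0) {
    thr <- 5 * sd(base)
    cand <- which(t >= onset_t & abs(i - mean(base)) > thr)
    if (length(cand)) onset_t <- t[cand[1]]
  }
  after <- which(t >= onset_t)
  pk <- after[which.max(abs(i[after]))]
  tt <- t[pk:length(t)] - t[pk]
  yy <- i[pk:length(i)]
  tail_mean <- mean(utils::tail(yy, max(5L, length(yy) %/% 20L)))
  A0 <- yy[1] - tail_mean
  if (abs(A0) < 10 * max(sd(base %||% 0), 1e-12) && abs(A0) < 1e-12)
    stopf("no decaying peak detected")
  # time to 37 percent decay for the rate guess
  target <- tail_mean + A0 * exp(-1)
  below <- if (A0 > 0) which(yy <= target) else which(yy >= target)
  k0 <- if (length(below)) 1 / max(tt[below[1]], tt[2]) else 1 / max(tt[length(tt)] / 3, 1e-9)
  fit <- lm_nls(function(th) th[1] * exp(-th[2] * tt) + th[3],
                c(A0, k0, tail_mean), yy,
                lower = c(-Inf, 1e-12, -Inf))
  if (!fit$converged || fit$par[2] <= 1e-10)
    stopf("relaxation fit did not converge (non-decaying trace?)")
  # guard against fits that merely chase noise: the fitted amplitude must
  # dominate the residual
  if (abs(fit$par[1]) < 2 * fit$residual_norm / sqrt(length(yy)))
    stopf("no resolvable decay above the noise floor")
  new_fit("mono_exp_fit",
          c(A = fit$par[1], K = fit$par[2], C = fit$par[3]), fit,
          list(t_peak_s = t[pk]))
}

#' Saturating dose dependence of the flipping rate and K_on
#'
#' Fits the observed relaxation rate versus concentration with
#' `Y = Y0 + (Plateau - Y0)(1 - exp(-K c))` and reports the association
#' rate constant as the closed-form derivative of the fitted curve at zero
#' concentration, `K_on = (Plateau - Y0) K` (the y-intercept of the first
#' derivative), not a numerical difference.
#'
#' @param concentrations_uM compound concentrations, uM (>= 4 distinct)
#' @param rates_s observed relaxation rates, 1/s
#' @return object of class `dose_rate_fit`: `Y0`, `Plateau`, `K` (1/uM),
#'   `K_on` (1/(uM s)), CIs, `K_on_reliable` flag (FALSE when the K CI
#'   includes zero, i.e. no saturation is resolved)
#' @export
fit_flipping_dose_curve <- function(concentrations_uM, rates_s) {
  x <- as.numeric(concentrations_uM)
  y <- as.numeric(rates_s)
  if (length(unique(x)) < 4L) stopf("need >= 4 distinct concentrations")
  if (sd(y) == 0) {
    fit <- list(par = c(y[1], y[1], 0), se = rep(0, 3),
                ci = cbind(lower = c(y[1], y[1], 0), upper = c(y[1], y[1], 0)),
                rss = 0, residual_norm = 0, dof = length(y) - 3L,
                converged = TRUE, fitted = y)
    warnf("all rates equal: no saturation, K_on = 0 flagged unreliable")
    out <- new_fit("dose_rate_fit", c(Y0 = y[1], Plateau = y[1], K = 0), fit,
                   list(K_on = 0, K_on_reliable = FALSE))
    return(out)
  }
  k0 <- 1 / max(mean(x), 1e-9)
  fit <- lm_nls(function(th) th[1] + (th[2] - th[1]) * (1 - exp(-th[3] * x)),
                c(min(y), max(y), k0), y, lower = c(-Inf, -Inf, 1e-12))
  if (!fit$converged) stopf("dose-curve fit did not converge")
  K_ci <- fit$ci[3, ]
  reliable <- is.finite(K_ci[1]) && K_ci[1] > 0
  if (!reliable)
    warnf("saturation not resolved (K CI includes 0); K_on flagged unreliable")
  K_on <- (fit$par[2] - fit$par[1]) * fit$par[3]
  new_fit("dose_rate_fit",
          c(Y0 = fit$par[1], Plateau = fit$par[2], K = fit$par[3]), fit,
          list(K_on = K_on, K_on_reliable = reliable))
}

#' Dissociation rate from recovery amplitudes
#'
#' Fits fractional peak (or steady-state) amplitudes against wash time with
#' `Y = Y0 + (Plateau - Y0)(1 - exp(-K t))`; K is the dissociation rate
#' K_off for the peak-recovery protocol or the cumulative K_off (release
#' from outward- and inward-facing states) for the steady-state-recovery
#' protocol.
#'
#' @param wash_times_s wash intervals, s (>= 4 points)
#' @param amplitudes fractional amplitudes, normalized to the reference
#'   pulse; must lie in `[0, 1.2]`
#' @return object of class `mono_exp_fit` with `K` = dissociation rate (1/s)
#' @export
fit_recovery <- function(wash_times_s, amplitudes) {
  t <- as.numeric(wash_times_s)
  y <- as.numeric(amplitudes)
  if (length(t) < 4L) stopf("need >= 4 recovery points")
  if (any(y < 0 | y > 1.2))
    stopf("amplitudes must be fractional (in [0, 1.2])")
  if (diff(range(y)) < 0.05)
    stopf("amplitudes already at plateau: K unidentifiable")
  half <- min(y) + (max(y) - min(y)) / 2
  t_half <- t[which.min(abs(y - half))]
  fit <- lm_nls(function(th) th[1] + (th[2] - th[1]) * (1 - exp(-th[3] * t)),
                c(max(0, min(y)), max(y), log(2) / max(t_half, min(t[t > 0]))),
                y, lower = c(-Inf, -Inf, 1e-12))
  if (!fit$converged || fit$par[3] <= 1e-10)
    stopf("recovery fit did not converge")
  new_fit("mono_exp_fit",
          c(Y0 = fit$par[1], Plateau = fit$par[2], K = fit$par[3]), fit)
}

#' Four-parameter-logistic uptake inhibition (IC50)
#'
#' Fits `Y = Bottom + (Top - Bottom) / (1 + 10^(X - logIC50))` with
#' `X = log10(concentration)` and the Hill slope fixed at 1 (the standard
#' printed form carries no slope parameter); `hill_free = TRUE` frees the
#' slope.
#'
#' @param concentrations_uM inhibitor concentrations, uM; >= 5 values
#'   spanning >= 2 log units
#' @param responses uptake as percent of control
#' @param hill_free free Hill slope variant (default FALSE)
#' @return object of class `dose_response_fit`: `Bottom`, `Top`, `logIC50`,
#'   `IC50` (uM) with 95 percent CIs
#' @export
fit_ic50 <- function(concentrations_uM, responses, hill_free = FALSE) {
  x <- log10(as.numeric(concentrations_uM))
  y <- as.numeric(responses)
  if (length(unique(x)) < 5L) stopf("need >= 5 distinct concentrations")
  if (diff(range(x)) < 2) stopf("concentrations must span >= 2 log units")
  mx <- tapply(y, x, mean)
  if (all(diff(mx[order(as.numeric(names(mx)))]) > 0))
    stopf("responses increase with concentration: not an inhibition curve")
  mid <- min(y) + (max(y) - min(y)) / 2
  l0 <- x[which.min(abs(y - mid))]
  if (hill_free) {
    f <- function(th) th[1] + (th[2] - th[1]) / (1 + 10^(th[4] * (x - th[3])))
    fit <- lm_nls(f, c(min(y), max(y), l0, 1), y)
    pars <- c(Bottom = fit$par[1], Top = fit$par[2], logIC50 = fit$par[3],
              Hill = fit$par[4])
  } else {
    f <- function(th) th[1] + (th[2] - th[1]) / (1 + 10^(x - th[3]))
    fit <- lm_nls(f, c(min(y), max(y), l0), y)
    pars <- c(Bottom = fit$par[1], Top = fit$par[2], logIC50 = fit$par[3])
  }
  if (!fit$converged) stopf("IC50 fit did not converge")
  if (pars["Top"] <= pars["Bottom"]) warnf("fitted Top <= Bottom")
  ic50_ci <- 10^fit$ci[3, ]
  out <- new_fit("dose_response_fit", pars, fit,
                 list(IC50 = unname(10^pars["logIC50"]), IC50_ci = ic50_ci))
  out
}

#' Michaelis-Menten uptake kinetics
#'
#' Direct nonlinear fit of `v = Vmax X / (Km + X)` (no linearization).
#'
#' @param substrate_uM substrate concentrations, uM (>= 5)
#' @param velocity uptake velocities, response units/min
#' @return object of class `mm_fit`: `Km` (uM), `Vmax`, CIs
#' @export
fit_km_vmax <- function(substrate_uM, velocity) {
  x <- as.numeric(substrate_uM)
  y <- as.numeric(velocity)
  if (length(unique(x)) < 5L) stopf("need >= 5 distinct concentrations")
  v0 <- max(y)
  km0 <- x[which.min(abs(y - v0 / 2))]
  fit <- lm_nls(function(th) th[1] * x / (th[2] + x), c(v0, max(km0, 1e-9)),
                y, lower = c(1e-12, 1e-12))
  if (!fit$converged) stopf("Michaelis-Menten fit did not converge")
  if (max(x) < fit$par[2])
    warnf("saturation not approached: max concentration (%.3g) below the Km estimate (%.3g)",
          max(x), fit$par[2])
  new_fit("mm_fit", c(Vmax = fit$par[1], Km = fit$par[2]), fit)
}

#' Classify the mode of uptake inhibition
#'
#' Applies the textbook hallmarks: competitive inhibition raises Km without
#' touching Vmax; non-competitive inhibition lowers Vmax without touching
#' Km; both signatures together give a mixed call. "Raised"/"lowered" means
#' the ratio crosses `alpha_ratio` (default 1.5); "unchanged" means the
#' 95 percent CIs of control and treated overlap.
#'
#' @param control,treated mm_fit objects
#' @param alpha_ratio fold-change threshold (default 1.5)
#' @return object of class `inhibition_call`: `verdict` in
#'   {competitive, non-competitive, mixed, none}, the Km and Vmax ratios and
#'   the thresholds used
#' @export
classify_inhibition <- function(control, treated, alpha_ratio = 1.5) {
  stopifnot(inherits(control, "mm_fit"), inherits(treated, "mm_fit"))
  km_ratio <- treated$Km / control$Km
  vmax_ratio <- treated$Vmax / control$Vmax
  overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  km_same <- overlap(control$ci["Km", ], treated$ci["Km", ])
  vmax_same <- overlap(control$ci["Vmax", ], treated$ci["Vmax", ])
  km_up <- km_ratio >= alpha_ratio
  vmax_down <- vmax_ratio <= 1 / alpha_ratio
  verdict <- if (km_up && vmax_down) "mixed"
  else if (km_up && vmax_same) "competitive"
  else if (vmax_down && km_same) "non-competitive"
  else "none"
  structure(list(verdict = verdict, km_ratio = km_ratio,
                 vmax_ratio = vmax_ratio, alpha_ratio = alpha_ratio,
                 km_ci_overlap = km_same, vmax_ci_overlap = vmax_same),
            class = "inhibition_call")
}

#' @export
print.inhibition_call <- function(x, ...) {
  cat(sprintf("<inhibition_call> %s (Km ratio %.2f, Vmax ratio %.2f, threshold %.2f)\n",
              x$verdict, x$km_ratio, x$vmax_ratio, x$alpha_ratio))
  invisible(x)
}

#' Write a fit report as a YAML block
#'
#' @param fit any gatekin_fit
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fit_report <- function(fit, path) {
  pars <- Filter(function(v) is.numeric(v) && length(v) == 1L,
                 fit[setdiff(names(fit), c("fitted", "ci", "se"))])
  yaml::write_yaml(list(fit = class(fit)[1], parameters = pars,
                        se = as.list(fit$se),
                        ci95 = apply(fit$ci, 1L, as.list),
                        residual_norm = fit$residual_norm), path)
  invisible(path)
}
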