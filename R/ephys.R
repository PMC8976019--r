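#' Step voltage protocol
#'
#' Describes the classic activation/tail protocol: from a holding potential,
#' repetitive depolarising test pulses followed by a fixed tail pulse. The
#' defaults are 7 s pulses from -100 to +60 mV in 20 mV increments with a 3 s
#' tail at -120 mV from a -80 mV holding potential.
#'
#' @param holding holding potential (mV).
#' @param test_potentials test-pulse potentials (mV), non-empty.
#' @param test_duration test-pulse duration (s), > 0.
#' @param tail_potential tail-pulse potential (mV).
#' @param tail_duration tail-pulse duration (s), > 0.
#' @return A list of class `voltage_protocol`.
#' @export
voltage_protocol <- function(holding = -80,
                             test_potentials = seq(-100, 60, by = 20),
                             test_duration = 7,
                             tail_potential = -120,
                             tail_duration = 3) {
  if (!length(test_potentials)) stop("test_potentials must be non-empty")
  if (test_duration <= 0 || tail_duration <= 0)
    stop("pulse durations must be > 0")
  structure(list(holding = holding, test_potentials = test_potentials,
                 test_duration = test_duration,
                 tail_potential = tail_potential,
                 tail_duration = tail_duration),
            class = "voltage_protocol")
}

#' Single current trace
#'
#' @param time time points (s), strictly increasing.
#' @param current current (microamps), same length as `time`.
#' @param test_potential the test potential (mV) the trace was recorded at.
#' @param condition free-text condition label.
#' @return A list of class `current_trace`.
#' @export
current_trace <- function(time, current, test_potential,
                          condition = NA_character_) {
  if (length(time) != length(current))
    stop("time and current lengths differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(list(time = time, current = current,
                 test_potential = test_potential, condition = condition),
            class = "current_trace")
}

#' Percent change in current
#'
#' The drug-effect statistic `100 * (I_drug - I_ctrl) / I_ctrl`, e.g. the
#' percent change in current at the end of a +40 mV pulse after drug
#' application.
#'
#' @param i_drug,i_ctrl currents in the same units; `i_ctrl` must be nonzero.
#' @return Percent change (vectorised).
#' @export
percent_activation <- function(i_drug, i_ctrl) {
  if (any(i_ctrl == 0)) stop("control current is zero; percent change undefined")
  100 * (i_drug - i_ctrl) / i_ctrl
}

#' Gating parameter set for the trace simulator
#'
#' Boltzmann voltage dependence plus voltage-independent biexponential
#' activation/deactivation kinetics. Defaults echo a slowly gating
#' depolarisation-activated potassium channel: half-activation -20 mV, slope
#' 12 mV, fast/slow activation time constants 0.5 and 3 s.
#'
#' @param v_half half-maximal activation voltage (mV).
#' @param slope_k Boltzmann slope factor (mV), > 0 for
#'   depolarisation-activated channels.
#' @param g_max maximal conductance (microsiemens).
#' @param e_rev reversal potential (mV).
#' @param tau_act fast/slow activation time constants (s), fast < slow.
#' @param act_weights fractional amplitudes of the two activation components
#'   (sum to 1).
#' @param tau_deact fast/slow deactivation time constants (s).
#' @param deact_weights fractional amplitudes of the deactivation components.
#' @return A list of class `gating_params`.
#' @export
gating_params <- function(v_half = -20, slope_k = 12, g_max = 1,
                          e_rev = -90,
                          tau_act = c(fast = 0.5, slow = 3.0),
                          act_weights = c(0.7, 0.3),
                          tau_deact = c(fast = 0.15, slow = 1.2),
                          deact_weights = c(0.6, 0.4)) {
  if (any(tau_act <= 0) || any(tau_deact <= 0)) stop("time constants must be > 0")
  if (tau_act[1] >= tau_act[2] || tau_deact[1] >= tau_deact[2])
    stop("fast time constant must be smaller than slow")
  if (abs(sum(act_weights) - 1) > 1e-9 || abs(sum(deact_weights) - 1) > 1e-9)
    stop("component weights must sum to 1")
  if (slope_k == 0) stop("slope_k must be nonzero")
  structure(list(v_half = v_half, slope_k = slope_k, g_max = g_max,
                 e_rev = e_rev, tau_act = tau_act,
                 act_weights = act_weights, tau_deact = tau_deact,
                 deact_weights = deact_weights),
            class = "gating_params")
}

boltzmann_p <- function(v, v_half, slope_k) 1 / (1 + exp((v_half - v) / slope_k))

#' Simulate current traces under a step protocol
#'
#' One trace per test potential: during the test pulse the current rises
#' biexponentially toward a steady state `g_max * p_open(V) * (V - e_rev)`
#' with the Boltzmann open probability `p_open`; on stepping to the tail
#' potential the current decays biexponentially from an initial amplitude
#' proportional to the activation level reached, with the driving force of
#' the tail potential. Additive Gaussian noise is optional and reproducible
#' from `seed`. Kinetics are voltage independent, so normalised tail
#' amplitudes reproduce the Boltzmann open probabilities exactly.
#'
#' @param params a [gating_params()].
#' @param protocol a [voltage_protocol()].
#' @param noise_sd additive Gaussian noise standard deviation (microamps).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @param dt sample interval (s), default 0.005 (200 Hz).
#' @return List of [current_trace()] objects, one per test potential.
#' @export
simulate_traces <- function(params, protocol, noise_sd = 0, seed = 1,
                            dt = 0.005) {
  stopifnot(inherits(params, "gating_params"),
            inherits(protocol, "voltage_protocol"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_test <- seq(0, protocol$test_duration, by = dt)
  t_tail <- seq(dt, protocol$tail_duration, by = dt)
  lapply(protocol$test_potentials, function(v) {
    p <- boltzmann_p(v, params$v_half, params$slope_k)
    act <- params$act_weights[1] * (1 - exp(-t_test / params$tau_act[1])) +
      params$act_weights[2] * (1 - exp(-t_test / params$tau_act[2]))
    i_test <- params$g_max * p * (v - params$e_rev) * act
    a_end <- act[length(act)]
    decay <- params$deact_weights[1] * exp(-t_tail / params$tau_deact[1]) +
      params$deact_weights[2] * exp(-t_tail / params$tau_deact[2])
    i_tail <- params$g_max * p * a_end *
      (protocol$tail_potential - params$e_rev) * decay
    time <- c(t_test, protocol$test_duration + t_tail)
    current <- c(i_test, i_tail)
    if (noise_sd > 0)
      current <- current + stats::rnorm(length(current), 0, noise_sd)
    current_trace(time, current, test_potential = v)
  })
}

#' Normalised conductance-voltage relation from tail currents
#'
#' The activation curve is read from the tail pulse: for each test potential
#' the peak tail-current magnitude (after a capacitive blanking window,
#' estimated on a short boxcar-smoothed stretch to suppress sampling noise)
#' is proportional to the open probability reached during the pulse; values
#' are normalised to the tail peak after the reference pulse (+40 mV by
#' default).
#'
#' @param traces list of [current_trace()] covering the tail window.
#' @param protocol the [voltage_protocol()] used.
#' @param reference_potential potential whose tail defines G = 1 (default
#'   +40 mV).
#' @param blank capacitive blanking window after the tail step (s, default
#'   0.005).
#' @param smooth boxcar smoothing width for peak detection (s, default
#'   0.025; 0 disables).
#' @return data.frame with columns `potential` (mV), `g` (tail amplitude,
#'   microamps) and `g_norm`.
#' @export
gv_from_tails <- function(traces, protocol, reference_potential = 40,
                          blank = 0.005, smooth = 0.025) {
  t0 <- protocol$test_duration
  amp <- vapply(traces, function(tr) {
    sel <- tr$time >= t0 + blank &
      tr$time <= t0 + protocol$tail_duration + 1e-9
    if (!any(sel)) stop("trace at ", tr$test_potential,
                        " mV does not cover the tail window")
    y <- abs(tr$current[sel])
    if (smooth > 0) {
      dt <- stats::median(diff(tr$time[sel]))
      k <- max(1L, round(smooth / dt))
      y <- stats::filter(y, rep(1 / k, k), sides = 2)
      y <- y[!is.na(y)]
    }
    max(y)
  }, numeric(1))
  pots <- vapply(traces, `[[`, numeric(1), "test_potential")
  if (all(amp == 0)) stop("all tail currents are zero; no peak to normalise")
  iref <- which(pots == reference_potential)
  if (!length(iref))
    stop("no trace at the reference potential ", reference_potential, " mV")
  out <- data.frame(potential = pots, g = amp, g_norm = amp / amp[iref[1]])
  out[order(out$potential), , drop = FALSE]
}

#' Boltzmann fit of a normalised activation curve
#'
#' Least-squares fit of `G(V) = G_max / (1 + exp((V_half - V) / k))`. By
#' default the amplitude `G_max` is a free nuisance parameter: tail currents
#' are normalised to a finite reference potential where the open probability
#' is slightly below 1, and fixing the amplitude at 1 would bias `V_half`.
#' With `free_amplitude = FALSE` the classic two-parameter fit is performed.
#' The same routine fits any normalised sigmoid voltage relation, including
#' fluorescence dF/F curves (see [fluorescence_fit()]).
#'
#' @param v test potentials (mV), at least 4, spanning the transition.
#' @param g normalised conductance values.
#' @param free_amplitude fit `G_max` as a free parameter (default `TRUE`).
#' @param positive_k the depolarisation-activated sign convention, `k > 0`
#'   (default `TRUE`); set `FALSE` for hyperpolarisation-activated channels.
#' @return A list of class `boltzmann_fit`: `v_half`, `slope_k`, `g_max`,
#'   `residual` (RMS), `fitted`.
#' @export
boltzmann_fit <- function(v, g, free_amplitude = TRUE, positive_k = TRUE) {
  if (length(v) < 4) stop("need at least 4 points for a Boltzmann fit")
  if (length(v) != length(g)) stop("v and g lengths differ")
  sgn <- if (positive_k) 1 else -1
  v_start <- v[which.min(abs(g - max(g) / 2))]
  start <- list(vh = v_start, k = sgn * diff(range(v)) / 8)
  df <- data.frame(v = v, g = g)
  fit <- if (free_amplitude) {
    minpack.lm::nlsLM(g ~ a / (1 + exp((vh - v) / k)), data = df,
                      start = c(start, a = max(g)),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(g ~ 1 / (1 + exp((vh - v) / k)), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  structure(list(v_half = unname(cf["vh"]), slope_k = unname(cf["k"]),
                 g_max = if (free_amplitude) unname(cf["a"]) else 1,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.2f mV, k = %.2f mV (RMS %.2e)\n",
              x$v_half, x$slope_k, x$residual))
  invisible(x)
}

#' Boltzmann fit of a voltage-clamp fluorometry dF/F curve
#'
#' Normalised fluorescence-voltage relations report voltage-sensor movement
#' and are fitted with the same sigmoid machinery as conductance-voltage
#' curves; this entry point simply forwards to [boltzmann_fit()].
#'
#' @inheritParams boltzmann_fit
#' @param df_norm normalised dF/F values.
#' @return A `boltzmann_fit` object.
#' @export
fluorescence_fit <- function(v, df_norm, free_amplitude = TRUE,
                             positive_k = TRUE) {
  boltzmann_fit(v, df_norm, free_amplitude, positive_k)
}

#' Biexponential fit of activation or deactivation kinetics
#'
#' Fits `A_f (1 - exp(-t/tau_f)) + A_s (1 - exp(-t/tau_s)) + C` to a rising
#' (activation) phase or `A_f exp(-t/tau_f) + A_s exp(-t/tau_s) + C` to a
#' decaying (deactivation/tail) phase, with time measured from the window
#' start. Initial time constants are multi-started on a log-spaced grid over
#' `[window/100, window]` (amplitudes seeded by linear least squares given
#' the taus); the lowest-residual convergent fit wins, ties resolved by grid
#' order, and the fast/slow labels are assigned by sorting the fitted taus.
#'
#' @param trace a [current_trace()].
#' @param phase `"activation"` or `"deactivation"`.
#' @param window numeric `c(start, end)` time window (s) within the trace;
#'   defaults to the full trace.
#' @param n_starts tau grid size per axis (default 5).
#' @return A list of class `biexp_fit`: `tau_fast`, `tau_slow`, `amp_fast`,
#'   `amp_slow`, `offset`, `residual`, `degenerate` (flag for flat input).
#' @export
biexp_fit <- function(trace, phase = c("activation", "deactivation"),
                      window = NULL, n_starts = 5) {
  phase <- match.arg(phase)
  if (is.null(window)) window <- range(trace$time)
  sel <- trace$time >= window[1] - 1e-12 & trace$time <= window[2] + 1e-12
  t <- trace$time[sel] - window[1]
  y <- trace$current[sel]
  if (length(t) < 20) stop("need at least 20 samples in the fit window")
  if (stats::sd(y) == 0)
    return(structure(list(tau_fast = NA_real_, tau_slow = NA_real_,
                          amp_fast = 0, amp_slow = 0, offset = y[1],
                          residual = 0, degenerate = TRUE),
                     class = "biexp_fit"))
  w <- diff(range(t))
  taus <- exp(seq(log(w / 100), log(w), length.out = n_starts))
  basis <- function(tau) if (phase == "activation")
    1 - exp(-t / tau) else exp(-t / tau)
  model <- if (phase == "activation")
    y ~ af * (1 - exp(-t / tf)) + as * (1 - exp(-t / ts)) + c0
  else
    y ~ af * exp(-t / tf) + as * exp(-t / ts) + c0
  candidates <- list(); tried <- character()
  for (i in seq_len(n_starts - 1)) for (j in (i + 1):n_starts) {
    tf0 <- taus[i]; ts0 <- taus[j]
    tried <- c(tried, sprintf("(%.3g, %.3g)", tf0, ts0))
    X <- cbind(basis(tf0), basis(ts0), 1)
    ab <- tryCatch(unname(stats::lm.fit(X, y)$coefficients),
                   error = function(e) NULL)
    if (is.null(ab) || anyNA(ab)) ab <- c(diff(range(y)), 0, y[1])
    fit <- tryCatch(
      minpack.lm::nlsLM(model, data = data.frame(t = t, y = y),
                        start = list(af = ab[1], as = ab[2], c0 = ab[3],
                                     tf = tf0, ts = ts0),
                        lower = c(-Inf, -Inf, -Inf, w * 1e-6, w * 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    candidates[[length(candidates) + 1L]] <-
      list(fit = fit, rss = sum(stats::resid(fit)^2))
  }
  if (!length(candidates))
    stop("biexponential fit failed to converge from any start; tried tau ",
         "pairs: ", paste(tried, collapse = " "))
  # On a single-exponential input the (af, as, tf, ts) surface has a flat
  # ridge: many starts reach the same residual with the amplitude split
  # arbitrarily between two equal taus. Among residual ties, prefer the
  # most parsimonious fit (largest amplitude disparity, i.e. closest to a
  # single exponential); remaining ties fall to grid order.
  rss_all <- vapply(candidates, `[[`, 0, "rss")
  best_rss <- min(rss_all)
  tss <- sum((y - mean(y))^2)
  tied <- which(rss_all <= best_rss * (1 + 1e-6) + 1e-12 * tss)
  disparity <- vapply(tied, function(k) {
    a <- abs(stats::coef(candidates[[k]]$fit)[c("af", "as")])
    if (max(a) == 0) 1 else min(a) / max(a)
  }, numeric(1))
  best <- candidates[[tied[which.min(disparity)]]]
  cf <- stats::coef(best$fit)
  ord <- order(c(cf["tf"], cf["ts"]))
  tau <- unname(c(cf["tf"], cf["ts"]))[ord]
  amp <- unname(c(cf["af"], cf["as"]))[ord]
  structure(list(tau_fast = tau[1], tau_slow = tau[2],
                 amp_fast = amp[1], amp_slow = amp[2],
                 offset = unname(cf["c0"]),
                 residual = sqrt(best$rss / length(y)),
                 degenerate = FALSE),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Biexponential fit: degenerate (flat input)\n")
  } else {
    cat(sprintf(
      "Biexponential fit: tau_f = %.3g s (A %.3g), tau_s = %.3g s (A %.3g), RMS %.2e\n",
      x$tau_fast, x$amp_fast, x$tau_slow, x$amp_slow, x$residual))
  }
  invisible(x)
}

#' Hill dose-response fit
#'
#' Fits `E(c) = E_max * c^h / (EC50^h + c^h)`; the Hill coefficient is fixed
#' at 1 by default (a hyperbolic saturation), matching the convention of
#' reporting only EC50 and maximal effect.
#'
#' @param conc concentrations (micromolar), at least 3 spanning the EC50
#'   region.
#' @param effect effects (e.g. percent activation), same length.
#' @param fix_hill keep the Hill coefficient at 1 (default `TRUE`).
#' @return A list of class `dose_response_fit`: `ec50`, `e_max`, `hill`,
#'   `residual`, `degenerate` (flag when the effect is flat zero and EC50 is
#'   unidentifiable).
#' @export
dose_response_fit <- function(conc, effect, fix_hill = TRUE) {
  if (length(conc) < 3) stop("need at least 3 concentrations")
  if (length(conc) != length(effect)) stop("conc and effect lengths differ")
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (all(abs(effect) < 1e-12))
    return(structure(list(ec50 = NA_real_, e_max = 0, hill = 1,
                          residual = 0, degenerate = TRUE),
                     class = "dose_response_fit"))
  emax0 <- effect[which.max(abs(effect))]
  ec0 <- conc[which.min(abs(effect - emax0 / 2))]
  df <- data.frame(conc = conc, effect = effect)
  fit <- if (fix_hill) {
    minpack.lm::nlsLM(effect ~ emax * conc / (ec50 + conc), data = df,
                      start = list(emax = emax0, ec50 = ec0),
                      lower = c(-Inf, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(effect ~ emax * conc^h / (ec50^h + conc^h), data = df,
                      start = list(emax = emax0, ec50 = ec0, h = 1),
                      lower = c(-Inf, 1e-9, 0.1),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  cf <- stats::coef(fit)
  structure(list(ec50 = unname(cf["ec50"]), e_max = unname(cf["emax"]),
                 hill = if (fix_hill) 1 else unname(cf["h"]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 degenerate = FALSE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Dose-response fit: degenerate (no effect; EC50 unidentifiable)\n")
  } else {
    cat(sprintf("Dose-response fit: EC50 = %.3g uM, Emax = %.3g%% (h = %g)\n",
                x$ec50, x$e_max, x$hill))
  }
  invisible(x)
}

#' Write a current trace as two-column delimited text
#' @param trace a [current_trace()].
#' @param path output path (columns: time s, current microamps; the test
#'   potential is recorded on a `# test_potential_mV:` header line).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# test_potential_mV: %g", trace$test_potential), con)
  utils::write.table(data.frame(time = trace$time, current = trace$current),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a current trace written by [write_trace()]
#' @param path input path.
#' @return A [current_trace()].
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  pot <- NA_real_
  if (grepl("^# test_potential_mV:", first))
    pot <- as.numeric(sub("^# test_potential_mV:", "", first))
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("time", "current") %in% names(tab)))
    stop("not a trace file (need 'time' and 'current' columns): ", path)
  current_trace(tab$time, tab$current, test_potential = pot)
}
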