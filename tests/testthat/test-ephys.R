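test_that("percent activation follows its algebra", {
  expect_equal(percent_activation(2, 1), 100)
  expect_equal(percent_activation(1, 1), 0)
  expect_equal(percent_activation(0.5, 1), -50)
  expect_error(percent_activation(1, 0), "zero")
  # identity pa(a, b) = -100 * (1 - a/b) for arbitrary nonzero b
  set.seed(61)
  a <- rnorm(50); b <- rnorm(50); b[b == 0] <- 1
  expect_equal(percent_activation(a, b), -100 * (1 - a / b),
               tolerance = 1e-12)
})

test_that("the simulator emits one deterministic trace per test potential", {
  prot <- voltage_protocol()
  expect_length(prot$test_potentials, 9)  # -100..+60 in 20 mV steps
  tr <- simulate_traces(gating_params(), prot, noise_sd = 0.01, seed = 7)
  expect_length(tr, 9)
  tr2 <- simulate_traces(gating_params(), prot, noise_sd = 0.01, seed = 7)
  expect_identical(tr[[4]]$current, tr2[[4]]$current)
  tr3 <- simulate_traces(gating_params(), prot, noise_sd = 0.01, seed = 8)
  expect_false(identical(tr[[4]]$current, tr3[[4]]$current))
})

test_that("tail-current normalisation recovers the Boltzmann open probabilities", {
  p <- gating_params()
  prot <- voltage_protocol()
  traces <- simulate_traces(p, prot, noise_sd = 0)
  gv <- gv_from_tails(traces, prot)
  p_open <- 1 / (1 + exp((p$v_half - gv$potential) / p$slope_k))
  expect_equal(gv$g_norm, p_open / p_open[gv$potential == 40],
               tolerance = 1e-6)
  # reference-only input gives the single point 1.0
  gv1 <- gv_from_tails(traces[prot$test_potentials == 40],
                       voltage_protocol(test_potentials = 40))
  expect_equal(gv1$g_norm, 1.0)
  # all-zero tails cannot be normalised
  flat <- current_trace(traces[[1]]$time, rep(0, length(traces[[1]]$time)), 40)
  expect_error(gv_from_tails(list(flat), prot), "no peak")
  expect_error(gv_from_tails(traces[1:3], prot), "reference potential")
})

test_that("Boltzmann fit recovers noiseless parameters and is shift-equivariant", {
  v <- seq(-100, 60, by = 20)
  g <- 1 / (1 + exp((-20 - v) / 12))
  fit <- boltzmann_fit(v, g)
  expect_equal(fit$v_half, -20, tolerance = 1e-6)
  expect_equal(fit$slope_k, 12, tolerance = 1e-6)
  fit_shift <- boltzmann_fit(v + 15, g)
  expect_equal(fit_shift$v_half, fit$v_half + 15, tolerance = 1e-6)
  expect_equal(fit_shift$slope_k, fit$slope_k, tolerance = 1e-6)
  expect_error(boltzmann_fit(v[1:3], g[1:3]), "at least 4")
  # dF/F machinery is the same code path
  ffit <- fluorescence_fit(v, g)
  expect_identical(ffit$v_half, fit$v_half)
  expect_identical(ffit$slope_k, fit$slope_k)
})

test_that("Boltzmann V1/2 stays within 1 mV under 1 percent noise (median)", {
  v <- seq(-100, 60, by = 20)
  g0 <- 1 / (1 + exp((-20 - v) / 12))
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    abs(boltzmann_fit(v, g0 + rnorm(length(v), 0, 0.01))$v_half + 20)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("biexponential fits recover noiseless kinetics within 1 percent", {
  t <- seq(0, 7, by = 0.005)
  y <- 4 * (1 - exp(-t / 0.5)) + 2 * (1 - exp(-t / 3))
  fit <- biexp_fit(current_trace(t, y, 40), "activation")
  expect_equal(fit$tau_fast, 0.5, tolerance = 0.01)
  expect_equal(fit$tau_slow, 3.0, tolerance = 0.01)
  expect_equal(fit$amp_fast, 4, tolerance = 0.01)
  expect_equal(fit$amp_slow, 2, tolerance = 0.01)
  yd <- 4 * exp(-t / 0.5) + 2 * exp(-t / 3)
  fitd <- biexp_fit(current_trace(t, yd, -120), "deactivation")
  expect_equal(fitd$tau_fast, 0.5, tolerance = 0.01)
  expect_equal(fitd$tau_slow, 3.0, tolerance = 0.01)
  expect_lt(fit$tau_fast, fit$tau_slow)  # ordering enforced
})

test_that("single-exponential input collapses one biexponential amplitude", {
  t <- seq(0, 5, by = 0.01)
  fit <- biexp_fit(current_trace(t, 3 * (1 - exp(-t / 1)), 0), "activation")
  amps <- abs(c(fit$amp_fast, fit$amp_slow))
  expect_lt(min(amps) / max(amps), 0.01)
  # a plain single-exponential oracle fit confirms the recovered tau
  single <- minpack.lm::nlsLM(y ~ a * (1 - exp(-t / tau)) + c0,
                              data = data.frame(t = t,
                                                y = 3 * (1 - exp(-t / 1))),
                              start = list(a = 2, tau = 0.5, c0 = 0))
  tau_major <- if (abs(fit$amp_fast) > abs(fit$amp_slow))
    fit$tau_fast else fit$tau_slow
  expect_equal(tau_major, unname(coef(single)["tau"]), tolerance = 1e-3)
})

test_that("flat traces yield a flagged degenerate kinetic fit", {
  t <- seq(0, 5, by = 0.01)
  fit <- biexp_fit(current_trace(t, rep(2, length(t)), 0), "activation")
  expect_true(fit$degenerate)
  expect_equal(fit$amp_fast, 0)
  expect_equal(fit$amp_slow, 0)
  expect_error(biexp_fit(current_trace(t, t, 0), "activation", c(0, 0.05)),
               "at least 20")
})

test_that("dose-response fit recovers noiseless EC50/Emax and scales with units", {
  conc <- c(0.3, 1, 3, 10, 30, 100)
  eff <- 212 * conc / (4.2 + conc)
  fit <- dose_response_fit(conc, eff)
  expect_equal(fit$ec50, 4.2, tolerance = 1e-4)
  expect_equal(fit$e_max, 212, tolerance = 1e-4)
  fit10 <- dose_response_fit(conc * 10, eff)
  expect_equal(fit10$ec50, 42, tolerance = 1e-4)
  expect_equal(fit10$e_max, fit$e_max, tolerance = 1e-6)
  # no effect: Emax ~ 0, EC50 unidentifiable and flagged
  flat <- dose_response_fit(conc, rep(0, 6))
  expect_true(flat$degenerate)
  expect_equal(flat$e_max, 0)
  expect_error(dose_response_fit(c(1, 2), c(5, 10)), "at least 3")
})

test_that("simulate -> fit round trip recovers the generating parameters", {
  p <- gating_params()
  prot <- voltage_protocol()
  traces <- simulate_traces(p, prot, noise_sd = 0)
  gv <- gv_from_tails(traces, prot)
  bf <- boltzmann_fit(gv$potential, gv$g_norm)
  expect_equal(bf$v_half, p$v_half, tolerance = 1e-6)
  expect_equal(bf$slope_k, p$slope_k, tolerance = 1e-6)
  act <- biexp_fit(traces[[which(prot$test_potentials == 40)]],
                   "activation", c(0, prot$test_duration))
  expect_equal(act$tau_fast, unname(p$tau_act[1]), tolerance = 1e-4)
  expect_equal(act$tau_slow, unname(p$tau_act[2]), tolerance = 1e-4)
  deact <- biexp_fit(traces[[which(prot$test_potentials == 40)]],
                     "deactivation",
                     c(prot$test_duration + 0.005,
                       prot$test_duration + prot$tail_duration))
  expect_equal(deact$tau_fast, unname(p$tau_deact[1]), tolerance = 1e-4)
  expect_equal(deact$tau_slow, unname(p$tau_deact[2]), tolerance = 1e-4)
})

test_that("current traces round-trip through delimited text", {
  tr <- simulate_traces(gating_params(), voltage_protocol(), noise_sd = 0)[[5]]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$test_potential, tr$test_potential)
  expect_equal(back$current, tr$current, tolerance = 1e-12)
})
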