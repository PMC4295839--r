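#' Logistic growth curve and its analytic growth rate
#'
#' `A(t) = A0*Kc/(A0 + (Kc - A0)*exp(-r*t))`, with growth rate
#' `mu(t) = d log A/dt = r*(1 - A(t)/Kc)`.
#'
#' @param A0 initial absorbance (OD), `0 < A0 < Kc`.
#' @param r maximum specific growth rate (1/min).
#' @param Kc carrying capacity (OD).
#' @return A list with functions `A(t)` and `mu(t)`.
#' @export
growth_curve <- function(A0, r, Kc) {
  if (A0 <= 0 || Kc <= A0 || r < 0)
    stop("need 0 < A0 < Kc and r >= 0")
  A <- function(t) A0 * Kc / (A0 + (Kc - A0) * exp(-r * t))
  mu <- function(t) r * (1 - A(t) / Kc)
  list(A = A, mu = mu)
}

#' Smooth pulse-shaped promoter activity
#'
#' A non-negative log-normal-shaped bump in time plus a basal level,
#' emulating the transient activity peak of motility promoters during
#' exponential growth followed by stabilisation at a low level:
#' `f(t) = basal + height * exp(-log((t - onset)/peak_delay)^2 / (2*width^2))`
#' for `t > onset`, `basal` otherwise. The peak is at `onset + peak_delay`.
#'
#' @param onset induction start time (minutes).
#' @param peak_delay time from onset to the peak (minutes), > 0.
#' @param width dimensionless log-scale width of the pulse.
#' @param height peak activity above basal (RFU/min), >= 0.
#' @param basal basal activity (RFU/min), >= 0.
#' @return A vectorised function of time (minutes).
#' @export
activity_pulse <- function(onset, peak_delay, width, height, basal = 0) {
  if (peak_delay <= 0 || width <= 0 || height < 0 || basal < 0)
    stop("invalid pulse parameters")
  function(t) {
    u <- t - onset
    bump <- ifelse(u > 0, exp(-log(pmax(u, 1e-12) / peak_delay)^2 / (2 * width^2)), 0)
    basal + height * bump
  }
}

.integrate_fluorescence <- function(f, A, gamma_r, times, r0) {
  deriv <- function(t, y, parms) list(f(t) * A(t) - gamma_r * y)
  sol <- deSolve::lsoda(y = c(I = r0 * A(times[1])), times = times,
                        func = deriv, parms = NULL, rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[, "I"])
}

#' Default measurement noise model
#'
#' @param abs_sd additive absorbance noise SD (OD).
#' @param fluo_rel multiplicative fluorescence noise (fraction of signal).
#' @param fluo_floor additive fluorescence noise floor (RFU).
#' @param bg_abs medium blank absorbance (OD).
#' @param bg_fluo medium blank fluorescence (RFU).
#' @param autofluo_per_od autofluorescence per unit biomass (RFU/OD).
#' @return A named list of noise parameters.
#' @export
noise_model <- function(abs_sd = 0.005, fluo_rel = 0.02, fluo_floor = 1,
                        bg_abs = 0.04, bg_fluo = 30, autofluo_per_od = 20) {
  as.list(environment())
}

#' Simulate reporter-well fluorescence and absorbance time series
#'
#' Forward-generates plate measurements from a promoter activity `f` and a
#' growth curve by integrating `dI/dt = f(t)*A(t) - gamma_r*I` — the unique
#' reporter dynamics for which `r = I/A` obeys
#' `dr/dt = f - (gamma_r + mu)*r` — then adding backgrounds (medium blank
#' plus biomass-proportional autofluorescence) and i.i.d. Gaussian noise
#' per replicate. The initial reporter concentration is the preculture
#' steady state `r0 = f(t0)/gamma_r` unless given.
#'
#' @param f promoter activity function (RFU/min).
#' @param growth list with `A(t)` and `mu(t)` from [growth_curve()].
#' @param gamma_r reporter degradation constant (1/min).
#' @param times sampling times (minutes).
#' @param noise a [noise_model()] list.
#' @param n_replicates number of replicate wells, >= 2.
#' @param condition,reporter labels for the emitted rows.
#' @param r0 initial reporter concentration (RFU); `NULL` for the
#'   preculture steady state.
#' @param well_prefix prefix for generated well ids.
#' @return A data frame in the plate-table dialect of [read_plate_table()]
#'   (reporter wells only; backgrounds are emitted by
#'   [simulate_scenario()]). Noise is drawn from the current RNG state.
#' @export
simulate_reporter_fluorescence <- function(f, growth, gamma_r = 6e-4, times,
                                           noise = noise_model(),
                                           n_replicates = 6,
                                           condition = "cond", reporter = "gene",
                                           r0 = NULL, well_prefix = reporter) {
  if (gamma_r < 0) stop("gamma_r must be non-negative")
  if (is.null(r0)) {
    mu0 <- growth$mu(times[1])
    r0 <- f(times[1]) / (gamma_r + mu0 + (gamma_r + mu0 == 0))
  }
  I_true <- .integrate_fluorescence(f, growth$A, gamma_r, times, r0)
  A_true <- growth$A(times)
  out <- lapply(seq_len(n_replicates), function(k) {
    A_obs <- A_true + noise$bg_abs + stats::rnorm(length(times), 0, noise$abs_sd)
    I_sig <- I_true + noise$bg_fluo + noise$autofluo_per_od * A_true
    I_obs <- I_sig + stats::rnorm(length(times), 0,
                                  noise$fluo_rel * abs(I_true) + noise$fluo_floor)
    data.frame(condition = condition,
               well = sprintf("%s_%02d", well_prefix, k),
               reporter = reporter, replicate = k, role = "reporter",
               time_min = times, absorbance = A_obs, fluorescence = I_obs)
  })
  do.call(rbind, out)
}

.background_wells <- function(times, growth, noise, condition, n_each = 2) {
  out <- list()
  for (k in seq_len(n_each)) {
    out[[length(out) + 1]] <- data.frame(
      condition = condition, well = sprintf("med_%02d", k),
      reporter = NA_character_, replicate = k, role = "background_medium",
      time_min = times,
      absorbance = noise$bg_abs + stats::rnorm(length(times), 0, noise$abs_sd),
      fluorescence = noise$bg_fluo + stats::rnorm(length(times), 0, noise$fluo_floor))
    A_true <- growth$A(times)
    out[[length(out) + 1]] <- data.frame(
      condition = condition, well = sprintf("bgs_%02d", k),
      reporter = NA_character_, replicate = k, role = "background_strain",
      time_min = times,
      absorbance = A_true + noise$bg_abs + stats::rnorm(length(times), 0, noise$abs_sd),
      fluorescence = noise$bg_fluo + noise$autofluo_per_od * A_true +
        stats::rnorm(length(times), 0, noise$fluo_floor))
  }
  do.call(rbind, out)
}

#' Default synthetic scenario emulating the FliA-FlgM module study
#'
#' Five experimental conditions (three M9 deletion mutants, one LB deletion
#' mutant, wild type in LB), each with logistic growth to stationary phase,
#' pulse-shaped fliA and flgM promoter activities with condition-dependent
#' timing (late induction in LB), a growth-linked constitutive promoter,
#' and target amplitudes spanning roughly 10-fold across conditions. The
#' flgM pulse lags fliA and overshoots it, so the target activity first
#' rises with free sigma factor, dips when the anti-sigma pool overtakes
#' (sequestration), and peaks once the less stable FlgM pool collapses.
#' Regulator half-lives sit at the measured values (FliA 30 min, FlgM 18
#' min), the reporter is stable (19 h half-life), about 150 time points
#' per condition, 6 replicates, and signal-dependent measurement noise
#' with autofluorescence background.
#'
#' @param seed integer seed recorded in the scenario; all randomness in
#'   [simulate_scenario()] flows from it.
#' @param alpha strength of global physiological effects used to generate
#'   the target promoter (1 = the plain constitutive-multiplier model).
#' @param tau_A,tau_M regulator half-lives (minutes) shared across
#'   conditions.
#' @param n_replicates replicate wells per reporter and condition.
#' @param noise a [noise_model()] list; use zero SDs for noise-free data.
#' @return A scenario list consumed by [simulate_scenario()].
#' @export
default_scenario <- function(seed = 1, alpha = 1, tau_A = 30, tau_M = 18,
                             n_replicates = 6, noise = noise_model()) {
  # fliA switches on first; for a short while the sigma factor is free and
  # the target rises. flgM follows with a stronger, narrower pulse: the
  # anti-sigma pool overtakes FliA mid-growth, free FliA collapses and the
  # target activity dips while fliA expression is still rising -- the
  # sequestration signature that makes FlgM indispensable for explaining
  # the data. Because FlgM is less stable, its pool then collapses first
  # and the target turns on fully while both regulator activities are
  # already past their peaks, well before growth arrest in M9 and shortly
  # before it in LB.
  m9 <- function(name, h_fliA, h_flgM, h_pRM, onset,
                 dA = 110, wA = 0.5, lagM = 45, dM = 75, wM = 0.38) {
    list(name = name, A0 = 0.05, r = 0.010, Kc = 1.2,
         times = seq(0, 600, length.out = 150),
         fliA = list(onset = onset, peak_delay = dA, width = wA,
                     height = h_fliA, basal = 0.05),
         flgM = list(onset = onset + lagM, peak_delay = dM, width = wM,
                     height = h_flgM, basal = 0.03),
         pRM = list(height = h_pRM, basal = 0.3))
  }
  lb <- function(name, h_fliA, h_flgM, h_pRM, onset,
                 dA = 130, wA = 0.5, lagM = 55, dM = 85, wM = 0.38) {
    list(name = name, A0 = 0.05, r = 0.007, Kc = 1.5,
         times = seq(0, 960, length.out = 150),
         fliA = list(onset = onset, peak_delay = dA, width = wA,
                     height = h_fliA, basal = 0.02),
         flgM = list(onset = onset + lagM, peak_delay = dM, width = wM,
                     height = h_flgM, basal = 0.015),
         pRM = list(height = h_pRM, basal = 0.25))
  }
  conditions <- list(
    m9("rpoS-M9", 12, 30, 2.5, 30),
    m9("cpxR-M9", 9, 22.5, 2.0, 60),
    m9("csgD-M9", 15, 37.5, 3.0, 40),
    lb("csgD-LB", 6, 15, 1.2, 200),
    lb("WT-LB", 1.5, 3.75, 0.45, 280))
  names(conditions) <- vapply(conditions, `[[`, "", "name")
  # tight FliA-FlgM binding (K small relative to the regulator
  # concentrations), as in the real module where the anti-sigma factor
  # sequesters most FliA until it is secreted
  list(seed = seed, alpha = alpha, gamma_r = 6e-4,
       tau_A = tau_A, tau_M = tau_M,
       preculture_halflife = c(fliA = 120, flgM = 180),
       c_true = regulation_params(k0 = 0.2, k1 = 6, n = 2,
                                  theta = 30, K = 10),
       n_replicates = n_replicates, noise = noise,
       conditions = conditions)
}

#' Simulate a full synthetic microplate dataset for the module
#'
#' Composes the generator: pulse activities for fliA, flgM and the
#' constitutive promoter; FliA and FlgM protein profiles by integrating the
#' protein kinetic model at the scenario half-lives (initial conditions
#' from the preculture steady state with stationary-phase half-lives);
#' target (tar) promoter activity from the titration/Hill regulation
#' function with global physiological effects (rescaled by `alpha` around
#' the pooled temporal mean of the constitutive activity when
#' `alpha != 1`); all four reporters rendered to noisy plate wells together
#' with background wells. Ground truth is returned alongside the plate
#' table; no analysis stage reads it.
#'
#' @param scenario a scenario list from [default_scenario()].
#' @return A list with `plate` (data frame in the [read_plate_table()]
#'   dialect), `truth` (per condition: `times`, true activity functions and
#'   vectors for `fliA`, `flgM`, `pRM`, `tar`, protein vectors `pA`, `pM`,
#'   growth functions) and the scenario itself.
#' @export
simulate_scenario <- function(scenario = default_scenario()) {
  set.seed(scenario$seed)
  gamma_r <- scenario$gamma_r
  c_true <- scenario$c_true
  gA <- log(2) / scenario$tau_A
  gM <- log(2) / scenario$tau_M
  truth <- list()
  # first pass: growth, pulses, proteins, constitutive activity
  for (cond in names(scenario$conditions)) {
    cs <- scenario$conditions[[cond]]
    growth <- growth_curve(cs$A0, cs$r, cs$Kc)
    f_fliA <- do.call(activity_pulse, cs$fliA)
    f_flgM <- do.call(activity_pulse, cs$flgM)
    # the constitutive promoter reads out the gene expression machinery,
    # which tracks the growth state: activity proportional to the growth
    # rate plus a basal level, declining into stationary phase
    f_pRM <- local({
      h <- cs$pRM$height; b <- cs$pRM$basal; g <- growth; r <- cs$r
      function(t) b + h * g$mu(t) / r
    })
    times <- cs$times
    p0A <- f_fliA(0) / (log(2) / scenario$preculture_halflife[["fliA"]])
    p0M <- f_flgM(0) / (log(2) / scenario$preculture_halflife[["flgM"]])
    pA <- protein_concentration(f_fliA, growth$mu, scenario$tau_A, p0A,
                                times = times, condition = cond,
                                regulator = "fliA")$p
    pM <- protein_concentration(f_flgM, growth$mu, scenario$tau_M, p0M,
                                times = times, condition = cond,
                                regulator = "flgM")$p
    truth[[cond]] <- list(times = times, growth = growth,
                          f_fliA = f_fliA, f_flgM = f_flgM, f_pRM = f_pRM,
                          fliA = f_fliA(times), flgM = f_flgM(times),
                          pRM = f_pRM(times), pA = pA, pM = pM)
  }
  # pooled temporal mean of the constitutive activity across all conditions
  f_const_mean <- mean(unlist(lapply(truth, `[[`, "pRM")))
  plate <- list()
  for (cond in names(scenario$conditions)) {
    tr <- truth[[cond]]
    pA_free <- free_fliA(tr$pA, tr$pM, c_true[["K"]])
    f_tar_vec <- alpha_activity(tr$pRM, f_const_mean, pA_free, c_true,
                                scenario$alpha)
    f_tar <- stats::approxfun(tr$times, f_tar_vec, rule = 2)
    truth[[cond]]$tar <- f_tar_vec
    truth[[cond]]$pA_free <- pA_free
    truth[[cond]]$f_tar <- f_tar
    for (rep_spec in list(list(f = tr$f_fliA, name = "fliA"),
                          list(f = tr$f_flgM, name = "flgM"),
                          list(f = tr$f_pRM, name = "pRM"),
                          list(f = f_tar, name = "tar"))) {
      plate[[length(plate) + 1]] <- simulate_reporter_fluorescence(
        f = rep_spec$f, growth = tr$growth, gamma_r = gamma_r,
        times = tr$times, noise = scenario$noise,
        n_replicates = scenario$n_replicates,
        condition = cond, reporter = rep_spec$name)
    }
    plate[[length(plate) + 1]] <- .background_wells(tr$times, tr$growth,
                                                    scenario$noise, cond)
  }
  list(plate = do.call(rbind, plate), truth = truth,
       f_const_mean = f_const_mean, scenario = scenario)
}
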