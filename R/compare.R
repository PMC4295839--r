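#' Build a fitting dataset from processed plate profiles
#'
#' Assembles a [fit_dataset] for the target gene from the output of
#' [process_plate()], with regressors taken either directly from the fliA
#' and flgM promoter activities (`"activities"`) or from protein
#' concentrations reconstructed at the given half-lives (`"proteins"`).
#' For protein regressors, below-detection early activities are first
#' back-extrapolated towards zero and initial concentrations follow the
#' preculture steady state with stationary-phase half-lives.
#'
#' @param processed output of [process_plate()].
#' @param regressors `"activities"` or `"proteins"`.
#' @param target name of the target reporter (default `"tar"`).
#' @param tau_A,tau_M regulator half-lives in minutes (protein regressors).
#' @param gamma_r reporter degradation constant (1/min).
#' @param global include the constitutive promoter activity (`"pRM"`) as
#'   the `fconst` trajectory.
#' @param preculture_halflife stationary-phase half-lives (minutes) used
#'   for the initial protein concentrations.
#' @param window `"expression"` (default) restricts every condition to its
#'   [analysis_window()] -- from regulator detection to growth arrest;
#'   `"full"` keeps the whole grid; alternatively a named list of
#'   `c(start, end)` vectors per condition.
#' @return A [fit_dataset] with one condition per element of `processed`.
#' @export
build_fit_dataset <- function(processed, regressors = c("activities", "proteins"),
                              target = "tar", tau_A = 30, tau_M = 18,
                              gamma_r = 6e-4, global = TRUE,
                              preculture_halflife = c(fliA = 120, flgM = 180),
                              window = "expression") {
  regressors <- match.arg(regressors)
  conds <- lapply(names(processed), function(cond) {
    pr <- processed[[cond]]
    tp <- .window_profile(pr$activities[[target]], .resolve_window(window, pr, cond))
    grid <- tp$time
    get_x <- function(gene, tau) {
      prof <- pr$activities[[gene]]
      if (regressors == "activities")
        return(.interp_to(prof$f_mean, prof$time, grid))
      prof <- backextrapolate_activity(prof, pr$detect_time[[gene]])
      # estimated reporter concentrations can dip below 0 at the window
      # start through measurement noise; the preculture relation needs a
      # non-negative concentration
      r0 <- max(pr$r[[gene]]$f_mean[1], 0)
      p0 <- initial_protein(r0, gamma_r,
                            log(2) / preculture_halflife[[gene]])
      pp <- protein_concentration(prof, pr$mu, tau, p0,
                                  condition = cond, regulator = gene)
      .interp_to(pp$p, pp$time, grid)
    }
    cc <- list(name = cond, time = grid, fbar = tp$f_mean, eps = tp$epsilon,
               x1 = get_x("fliA", tau_A), x2 = get_x("flgM", tau_M))
    if (global) {
      fc <- pr$activities[["pRM"]]
      cc$fconst <- .interp_to(fc$f_mean, fc$time, grid)
    }
    cc
  })
  fit_dataset(conds)
}

.resolve_window <- function(window, pr, cond) {
  if (is.list(window)) return(window[[cond]])
  if (identical(window, "full")) return(c(-Inf, Inf))
  if (identical(window, "expression")) return(analysis_window(pr))
  stop("window must be \"expression\", \"full\", or a named list of ranges")
}

.profiles_for_halflife_fit <- function(processed, target = "tar",
                                       gamma_r = 6e-4,
                                       preculture_halflife = c(fliA = 120,
                                                               flgM = 180),
                                       window = "expression") {
  conds <- names(processed)
  # regulator profiles stay on the full grid: protein reconstruction
  # integrates from the start of the experiment; only the target and
  # constitutive profiles, which define the comparison grid, are windowed
  grab <- function(gene, backx = FALSE, windowed = FALSE) {
    out <- lapply(conds, function(cond) {
      prof <- processed[[cond]]$activities[[gene]]
      if (backx)
        prof <- backextrapolate_activity(prof,
                                         processed[[cond]]$detect_time[[gene]])
      if (windowed)
        prof <- .window_profile(prof,
                                .resolve_window(window, processed[[cond]], cond))
      prof
    })
    stats::setNames(out, conds)
  }
  r0s <- function(gene) vapply(conds, function(cond)
    max(processed[[cond]]$r[[gene]]$f_mean[1], 0), 0)
  list(target = grab(target, windowed = TRUE), fliA = grab("fliA", TRUE),
       flgM = grab("flgM", TRUE), fconst = grab("pRM"),
       mu = stats::setNames(lapply(conds, function(cond)
         processed[[cond]]$mu), conds),
       preculture = list(
         fliA = list(gamma_p_pre = log(2) / preculture_halflife[["fliA"]],
                     mu_T = 0, r_T = r0s("fliA")),
         flgM = list(gamma_p_pre = log(2) / preculture_halflife[["flgM"]],
                     mu_T = 0, r_T = r0s("flgM"))))
}

#' Compare the four analysis configurations of the inference pipeline
#'
#' Runs, on the same processed plate data, the four configurations of the
#' target-gene regulation fit: (1) promoter activities as proxies for the
#' regulator concentrations, specific regulation only; (2) activities plus
#' the constitutive-promoter multiplier for global physiological effects;
#' (3) protein concentrations reconstructed at fixed half-lives plus global
#' effects; (4) as (3) but with the half-lives estimated from the data by
#' grid search. Optionally also a proteins-without-global-effects fit.
#' Reconstructing protein concentrations and accounting for the gene
#' expression machinery each remove a modelling bias, so the fitting error
#' Q is expected to decrease along the sequence.
#'
#' @param processed output of [process_plate()].
#' @param target target reporter name.
#' @param tau_A,tau_M fixed regulator half-lives (minutes) for
#'   configuration 3.
#' @param halflives half-life grid for configuration 4; must contain
#'   `tau_A` and `tau_M` for the fixed configuration to be nested in the
#'   search.
#' @param n_starts,seed,gamma_r,loss passed to the fitting routines.
#' @param include_no_global also fit protein regressors without global
#'   effects (a fifth row in the table).
#' @return A list with `table` (data frame of configuration and Q) and
#'   `fits` (the underlying `"regfit"` objects).
#' @export
compare_configurations <- function(processed, target = "tar",
                                   tau_A = 30, tau_M = 18,
                                   halflives = c(7, 18, 30, 60, 120, 240),
                                   n_starts = 10, seed = 1, gamma_r = 6e-4,
                                   loss = "abs", include_no_global = FALSE) {
  fits <- list()
  dat_act <- build_fit_dataset(processed, "activities", target,
                               gamma_r = gamma_r, global = TRUE)
  fits$activities <- fit_regulation(dat_act, model = "hill",
                                    n_starts = n_starts, seed = seed,
                                    loss = loss)
  fits$activities_global <- fit_regulation(dat_act, model = "hill_global",
                                           n_starts = n_starts, seed = seed,
                                           loss = loss)
  dat_prot <- build_fit_dataset(processed, "proteins", target, tau_A, tau_M,
                                gamma_r = gamma_r, global = TRUE)
  fits$proteins_global <- fit_regulation(dat_prot, model = "hill_global",
                                         n_starts = n_starts, seed = seed,
                                         loss = loss)
  parts <- .profiles_for_halflife_fit(processed, target, gamma_r)
  fits$proteins_global_esthl <- fit_with_halflives(
    parts$target, parts$fliA, parts$flgM, parts$fconst, parts$mu,
    halflives = halflives, mode = "shared", preculture = parts$preculture,
    gamma_r = gamma_r, model = "hill_global", loss = loss,
    n_starts = n_starts, seed = seed)
  if (include_no_global)
    fits$proteins_no_global <- fit_regulation(dat_prot, model = "hill",
                                              n_starts = n_starts,
                                              seed = seed, loss = loss)
  list(table = data.frame(configuration = names(fits),
                          Q = vapply(fits, `[[`, 0, "Q"), row.names = NULL),
       fits = fits)
}
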