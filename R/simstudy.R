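#' Rescale regulation parameters to new regressor ranges
#'
#' When simulated regulator concentration profiles change scale (e.g. for
#' different half-lives), the threshold `theta` and dissociation constant
#' `K` are mapped so that their relative positions within the plausible
#' intervals of the search box, which scale with the regressor maxima, are
#' preserved; `k0`, `k1` and `n` are left unchanged.
#'
#' @param c_ref reference [regulation_params].
#' @param ranges_ref,ranges_new lists with positive elements `x1_max`
#'   (FliA regressor maximum) and `x2_max` (FlgM regressor maximum).
#' @return Rescaled [regulation_params].
#' @export
rescale_params <- function(c_ref, ranges_ref, ranges_new) {
  c_ref <- as_regulation_params(c_ref)
  for (r in list(ranges_ref, ranges_new))
    if (r$x1_max <= 0 || r$x2_max <= 0)
      stop("regressor ranges must be positive")
  regulation_params(c_ref[["k0"]], c_ref[["k1"]], c_ref[["n"]],
                    c_ref[["theta"]] * ranges_new$x1_max / ranges_ref$x1_max,
                    c_ref[["K"]] * ranges_new$x2_max / ranges_ref$x2_max)
}

.as_target_profiles <- function(f_list, grid_list, eps_frac) {
  out <- lapply(names(f_list), function(cond) {
    f <- f_list[[cond]]
    structure(list(condition = cond, time = grid_list[[cond]], f_mean = f,
                   epsilon = rep(eps_frac * max(f), length(f)),
                   n_replicates = 2L, epsilon_defined = TRUE),
              class = "activity_profile")
  })
  stats::setNames(out, names(f_list))
}

.heatmap_result <- function(axis, Q, type) {
  structure(list(axis = axis, Q = Q, Q_normalized = Q / max(Q), type = type),
            class = "heatmap_result")
}

#' @export
print.heatmap_result <- function(x, ...) {
  cat(sprintf("<heatmap_result> %s scan, %d cell(s), Q in [%.4g, %.4g]\n",
              x$type, length(x$Q), min(x$Q), max(x$Q)))
  invisible(x)
}

#' @export
plot.heatmap_result <- function(x, ...) {
  if (is.matrix(x$Q)) {
    graphics::image(x$axis$tau_M, x$axis$tau_A, t(x$Q_normalized),
                    xlab = "FlgM half-life (min)",
                    ylab = "FliA half-life (min)", log = "xy",
                    main = "normalised misfit Q", ...)
  } else {
    graphics::plot(x$axis$alpha, x$Q_normalized, type = "b",
                   xlab = expression(alpha), ylab = "normalised misfit Q",
                   ...)
  }
  invisible(x)
}

#' Misfit of the activities-as-proxies fit versus regulator half-lives
#'
#' For every combination of simulated FliA and FlgM half-lives on
#' `sim_grid`, regulator protein profiles are computed from the measured
#' (or synthetic) fliA and flgM promoter activities, a target activity is
#' generated from the titration/Hill model with global effects at
#' parameters rescaled to the cell's concentration ranges, and a model
#' using promoter activities in place of protein concentrations (but
#' keeping global effects) is fitted to the simulated target. The residual
#' Q quantifies the bias of ignoring protein kinetics; it is normalised by
#' its maximum over the grid.
#'
#' @inheritParams fit_with_halflives
#' @param sim_grid half-life grid (minutes) for both regulators; the
#'   default spans 7 min to 16 h in 33 log-spaced values.
#' @param c_ref reference [regulation_params], interpreted at `ref_tau`.
#' @param ref_tau half-lives (FliA, FlgM, minutes) at which `c_ref` was
#'   obtained; parameter rescaling is relative to the concentration ranges
#'   there.
#' @param eps_frac weight band for the simulated target, as a fraction of
#'   its per-condition maximum.
#' @return A `"heatmap_result"` with a Q matrix (rows = FliA half-life,
#'   columns = FlgM half-life).
#' @export
halflife_misfit_scan <- function(fliA, flgM, fconst, mu,
                                 sim_grid = halflife_grid(33, 7, 960),
                                 c_ref, ref_tau = c(30, 18),
                                 preculture = NULL, gamma_r = 6e-4,
                                 eps_frac = 0.05, n_starts = 10, seed = 1,
                                 ...) {
  c_ref <- as_regulation_params(c_ref)
  conds <- names(fliA)
  grids <- lapply(fliA, `[[`, "time")
  # reference protein ranges at the half-lives where c_ref lives
  ref_profs <- precompute_profiles(list(fliA = fliA, flgM = flgM), mu,
                                   ref_tau, gamma_r, preculture)
  ranges_ref <- list(
    x1_max = max(vapply(conds, function(cc) max(ref_profs$fliA[[cc]][[1]]$p), 0)),
    x2_max = max(vapply(conds, function(cc) max(ref_profs$flgM[[cc]][[2]]$p), 0)))
  profs <- precompute_profiles(list(fliA = fliA, flgM = flgM), mu, sim_grid,
                               gamma_r, preculture)
  # the proxy fit always regresses on the promoter activities themselves
  act_data_of <- function(targets) fit_dataset(lapply(conds, function(cc) {
    tp <- targets[[cc]]
    list(name = cc, time = tp$time, fbar = tp$f_mean, eps = tp$epsilon,
         x1 = .interp_to(fliA[[cc]]$f_mean, fliA[[cc]]$time, tp$time),
         x2 = .interp_to(flgM[[cc]]$f_mean, flgM[[cc]]$time, tp$time),
         fconst = .interp_to(fconst[[cc]]$f_mean, fconst[[cc]]$time, tp$time))
  }))
  n <- length(sim_grid)
  Q <- matrix(NA_real_, n, n, dimnames = list(tau_A = signif(sim_grid, 4),
                                              tau_M = signif(sim_grid, 4)))
  for (iA in seq_len(n)) for (iM in seq_len(n)) {
    pA <- lapply(conds, function(cc) profs$fliA[[cc]][[iA]]$p)
    pM <- lapply(conds, function(cc) profs$flgM[[cc]][[iM]]$p)
    names(pA) <- names(pM) <- conds
    c_cell <- rescale_params(c_ref, ranges_ref,
                             list(x1_max = max(unlist(lapply(pA, max))),
                                  x2_max = max(unlist(lapply(pM, max)))))
    f_tar <- lapply(conds, function(cc) {
      fc <- pmax(.interp_to(fconst[[cc]]$f_mean, fconst[[cc]]$time,
                            grids[[cc]]), 0)
      global_activity(fc, free_fliA(pA[[cc]], pM[[cc]], c_cell[["K"]]),
                      c_cell)
    })
    names(f_tar) <- conds
    targets <- .as_target_profiles(f_tar, grids, eps_frac)
    fit <- fit_regulation(act_data_of(targets), model = "hill_global",
                          n_starts = n_starts, seed = seed, ...)
    Q[iA, iM] <- fit$Q
  }
  .heatmap_result(list(tau_A = sim_grid, tau_M = sim_grid), Q, "half-life")
}

#' Misfit of the global-effects-ignoring fit versus effect strength
#'
#' For each strength `alpha`, a target activity is generated from the
#' regulation model in which the constitutive-promoter variation around its
#' pooled temporal mean is rescaled by `alpha`, using protein profiles at
#' the reference half-lives; a model using those protein concentrations but
#' ignoring global effects (titration + Hill only) is then fitted. The
#' residual Q quantifies the bias of ignoring global physiology.
#'
#' Promoter activities are non-negative, so when a measured constitutive
#' profile varies strongly enough that the rescaled prefactor
#' `alpha*(f_const - mean) + mean` turns negative at large `alpha`, the
#' generator floors it at zero instead of failing.
#'
#' @inheritParams halflife_misfit_scan
#' @param alphas strengths in `[0, 1.25]`; the default is 26 equally
#'   spaced values.
#' @param halflives reference half-lives (FliA, FlgM, minutes) for the
#'   protein profiles.
#' @return A `"heatmap_result"` with a Q vector over `alphas`.
#' @export
alpha_misfit_scan <- function(fliA, flgM, fconst, mu,
                              alphas = seq(0, 1.25, length.out = 26),
                              halflives = c(30, 18), c_ref,
                              preculture = NULL, gamma_r = 6e-4,
                              eps_frac = 0.05, n_starts = 10, seed = 1,
                              ...) {
  if (any(alphas < 0 | alphas > 1.25))
    stop("alpha values must lie in [0, 1.25]")
  c_ref <- as_regulation_params(c_ref)
  conds <- names(fliA)
  grids <- lapply(fliA, `[[`, "time")
  profs <- precompute_profiles(list(fliA = fliA, flgM = flgM), mu, halflives,
                               gamma_r, preculture)
  pA <- lapply(conds, function(cc) profs$fliA[[cc]][[1]]$p)
  pM <- lapply(conds, function(cc) profs$flgM[[cc]][[2]]$p)
  names(pA) <- names(pM) <- conds
  fc <- lapply(conds, function(cc)
    pmax(.interp_to(fconst[[cc]]$f_mean, fconst[[cc]]$time, grids[[cc]]), 0))
  names(fc) <- conds
  fc_mean <- mean(unlist(fc))
  prot_data_of <- function(targets) fit_dataset(lapply(conds, function(cc) {
    tp <- targets[[cc]]
    list(name = cc, time = tp$time, fbar = tp$f_mean, eps = tp$epsilon,
         x1 = pA[[cc]], x2 = pM[[cc]])
  }))
  Q <- vapply(alphas, function(a) {
    f_tar <- lapply(conds, function(cc) {
      pre <- pmax(a * (fc[[cc]] - fc_mean) + fc_mean, 0)
      pre * hill_activity(free_fliA(pA[[cc]], pM[[cc]], c_ref[["K"]]), c_ref)
    })
    names(f_tar) <- conds
    targets <- .as_target_profiles(f_tar, grids, eps_frac)
    fit_regulation(prot_data_of(targets), model = "hill",
                   n_starts = n_starts, seed = seed, ...)$Q
  }, numeric(1))
  .heatmap_result(list(alpha = alphas), Q, "alpha")
}
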