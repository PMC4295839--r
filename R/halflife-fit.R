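.interp_to <- function(x, time, target_time) {
  stats::approx(time, x, xout = target_time, rule = 2)$y
}

.build_halflife_data <- function(target, fconst, profs, iA, iM) {
  conds <- lapply(names(target), function(cond) {
    tp <- target[[cond]]
    jA <- if (length(iA) > 1) iA[[cond]] else iA
    jM <- if (length(iM) > 1) iM[[cond]] else iM
    pA <- profs$fliA[[cond]][[jA]]
    pM <- profs$flgM[[cond]][[jM]]
    cc <- list(name = cond, time = tp$time, fbar = tp$f_mean,
               eps = tp$epsilon,
               x1 = .interp_to(pA$p, pA$time, tp$time),
               x2 = .interp_to(pM$p, pM$time, tp$time))
    if (!is.null(fconst))
      cc$fconst <- .interp_to(fconst[[cond]]$f_mean, fconst[[cond]]$time,
                              tp$time)
    cc
  })
  fit_dataset(conds)
}

#' Estimate regulation parameters and regulator half-lives jointly
#'
#' Discretises the candidate half-lives of FliA and FlgM on a grid,
#' precomputes the protein concentration profiles for every grid value in
#' every condition, and searches for the half-life combination whose inner
#' regulation-function fit minimises the objective. In `"shared"` mode a
#' single `(tau_A, tau_M)` pair applies to all conditions and the grid x
#' grid combinations are searched exhaustively. In `"per_condition"` mode
#' each condition gets its own pair, found by greedy coordinate descent
#' (cycling over conditions, updating each pair to the grid argmin of that
#' condition's misfit at the current parameters, then refitting) with
#' random restarts.
#'
#' @param target named list of target `"activity_profile"`s per condition.
#' @param fliA,flgM named lists of regulator `"activity_profile"`s per
#'   condition.
#' @param fconst named list of constitutive-promoter profiles per
#'   condition, or `NULL` for the `"hill"` model.
#' @param mu named list of growth-rate functions per condition.
#' @param halflives candidate half-life grid (minutes), e.g.
#'   [halflife_grid()].
#' @param mode `"shared"` or `"per_condition"`.
#' @param preculture preculture specification, see [precompute_profiles()].
#' @param gamma_r reporter degradation constant (1/min).
#' @param model,loss,n_starts,seed,... passed to [fit_regulation()].
#' @param restarts random restarts for `"per_condition"` mode.
#' @return A `"regfit"` whose `$half_lives` element records the mode, the
#'   chosen `tau_A` and `tau_M` (scalars in shared mode, named per-condition
#'   vectors otherwise) and, in shared mode, the full `Q_grid` matrix
#'   (rows = FliA half-lives, columns = FlgM half-lives).
#' @export
fit_with_halflives <- function(target, fliA, flgM, fconst = NULL, mu,
                               halflives = halflife_grid(),
                               mode = c("shared", "per_condition"),
                               preculture = NULL, gamma_r = 6e-4,
                               model = if (is.null(fconst)) "hill" else "hill_global",
                               loss = "abs", n_starts = 10, seed = 1,
                               restarts = 10, ...) {
  mode <- match.arg(mode)
  if (!length(halflives)) stop("empty half-life grid")
  profs <- precompute_profiles(list(fliA = fliA, flgM = flgM), mu, halflives,
                               gamma_r = gamma_r, preculture = preculture)
  n <- length(halflives)
  if (mode == "shared") {
    Qgrid <- matrix(NA_real_, n, n,
                    dimnames = list(tau_A = signif(halflives, 4),
                                    tau_M = signif(halflives, 4)))
    best <- NULL; best_idx <- c(NA, NA)
    for (iA in seq_len(n)) for (iM in seq_len(n)) {
      dat <- .build_halflife_data(target, fconst, profs, iA, iM)
      fit <- fit_regulation(dat, model = model, loss = loss,
                            n_starts = n_starts, seed = seed, ...)
      Qgrid[iA, iM] <- fit$Q
      if (is.null(best) || fit$Q < best$Q) { best <- fit; best_idx <- c(iA, iM) }
    }
    best$half_lives <- list(mode = "shared",
                            tau_A = halflives[best_idx[1]],
                            tau_M = halflives[best_idx[2]],
                            grid = halflives, Q_grid = Qgrid)
    return(best)
  }
  # per-condition greedy coordinate descent with random restarts
  conds <- names(target)
  cond_Q <- function(p, cond, iA, iM) {
    dat <- .build_halflife_data(target[cond], fconst[cond], profs,
                                stats::setNames(iA, cond),
                                stats::setNames(iM, cond))
    .Q_value(p, dat, model, loss)
  }
  set.seed(seed)
  starts <- lapply(seq_len(restarts), function(k)
    list(iA = stats::setNames(sample.int(n, length(conds), replace = TRUE), conds),
         iM = stats::setNames(sample.int(n, length(conds), replace = TRUE), conds)))
  best <- NULL; best_assign <- NULL
  for (k in seq_len(restarts)) {
    iA <- starts[[k]]$iA; iM <- starts[[k]]$iM
    fit <- fit_regulation(.build_halflife_data(target, fconst, profs, iA, iM),
                          model = model, loss = loss, n_starts = n_starts,
                          seed = seed, ...)
    for (iter in 1:20) {
      changed <- FALSE
      p <- unclass(fit$params)
      for (cond in conds) {
        qvals <- outer(seq_len(n), seq_len(n),
                       Vectorize(function(a, m) cond_Q(p, cond, a, m)))
        idx <- arrayInd(which.min(qvals), dim(qvals))
        if (idx[1] != iA[[cond]] || idx[2] != iM[[cond]]) {
          iA[[cond]] <- idx[1]; iM[[cond]] <- idx[2]; changed <- TRUE
        }
      }
      fit2 <- fit_regulation(.build_halflife_data(target, fconst, profs, iA, iM),
                             model = model, loss = loss, n_starts = n_starts,
                             seed = seed, ...)
      if (fit2$Q <= fit$Q) fit <- fit2
      if (!changed) break
    }
    if (is.null(best) || fit$Q < best$Q) {
      best <- fit; best_assign <- list(iA = iA, iM = iM)
    }
  }
  best$half_lives <- list(mode = "per_condition",
                          tau_A = halflives[best_assign$iA],
                          tau_M = halflives[best_assign$iM],
                          grid = halflives)
  names(best$half_lives$tau_A) <- conds
  names(best$half_lives$tau_M) <- conds
  best
}

#' Bootstrap-like confidence intervals for regulation parameters
#'
#' Resamples the target promoter activities at each time point from a
#' Gaussian with the observed mean and the replicate SEM (`eps/2`), refits
#' the model `B` times, and reports percentile intervals per parameter.
#'
#' @param fit a `"regfit"` from [fit_regulation()].
#' @param B number of bootstrap refits, >= 100 for production use.
#' @param seed integer seed (resampling and refits are reproducible).
#' @param level confidence level (default 0.95: 2.5/97.5 percentiles).
#' @param n_starts multistart count per refit; defaults to the original
#'   fit's.
#' @return A data frame with columns `parameter`, `estimate`, `lower`,
#'   `upper`; the matrix of bootstrap draws is attached as attribute
#'   `"draws"`. Errors if more than 20% of refits fail.
#' @export
bootstrap_cis <- function(fit, B = 200, seed = 1, level = 0.95,
                          n_starts = fit$n_starts) {
  stopifnot(inherits(fit, "regfit"))
  datasets <- stats::simulate(fit, nsim = B, seed = seed)
  draws <- matrix(NA_real_, B, 5,
                  dimnames = list(NULL, names(unclass(fit$params))))
  fails <- 0
  for (b in seq_len(B)) {
    res <- tryCatch(
      fit_regulation(datasets[[b]], model = fit$model, loss = fit$loss,
                     n_starts = n_starts, seed = seed + b,
                     fixed = fit$fixed),
      error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1 else draws[b, ] <- unclass(res$params)
  }
  if (fails > 0.2 * B)
    stop(sprintf("bootstrap refit failure rate too high: %d of %d", fails, B))
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  out <- data.frame(parameter = colnames(draws),
                    estimate = as.numeric(unclass(fit$params)),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  attr(out, "draws") <- draws
  out
}
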