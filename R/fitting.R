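#' Assemble a fitting dataset
#'
#' Bundles, per experimental condition, the target promoter activity
#' profile (mean and 2-SEM band used as objective weights) and the
#' regressor trajectories: the FliA-side regressor `x1` and FlgM-side
#' regressor `x2` (either promoter activities used as proxies, or
#' reconstructed protein concentrations) plus, optionally, the constitutive
#' promoter activity `fconst`. All trajectories must share the condition's
#' evaluation grid. Points with a zero or undefined band (e.g. imputed
#' back-extrapolated segments) are excluded from the objective.
#'
#' @param ... one or more condition lists, each with elements `name`,
#'   `time`, `fbar`, `eps`, `x1`, `x2` and optionally `fconst`.
#' @return An object of class `"fit_dataset"`.
#' @export
fit_dataset <- function(...) {
  conds <- list(...)
  if (length(conds) == 1 && is.null(conds[[1]]$fbar)) conds <- conds[[1]]
  if (!length(conds)) stop("empty dataset")
  conds <- lapply(conds, function(cc) {
    lens <- c(length(cc$time), length(cc$fbar), length(cc$eps),
              length(cc$x1), length(cc$x2),
              if (!is.null(cc$fconst)) length(cc$fconst))
    if (length(unique(lens)) != 1)
      stop("trajectories in condition ", cc$name,
           " do not share the evaluation grid")
    # regressors are concentrations or activities; negative values are
    # estimation noise and are floored at zero
    cc$x1 <- pmax(cc$x1, 0)
    cc$x2 <- pmax(cc$x2, 0)
    if (!is.null(cc$fconst)) cc$fconst <- pmax(cc$fconst, 0)
    cc$use <- is.finite(cc$eps) & cc$eps > 0
    cc
  })
  names(conds) <- vapply(conds, `[[`, "", "name")
  structure(conds, class = "fit_dataset")
}

#' @export
print.fit_dataset <- function(x, ...) {
  cat(sprintf("<fit_dataset> %d condition(s): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

# fast internal model evaluation; p is a plain named numeric vector
.eval_model <- function(p, cond, model) {
  b <- p[["K"]] + cond$x2 - cond$x1
  disc <- sqrt(b^2 + 4 * p[["K"]] * cond$x1)
  paf <- ifelse(b > 0,
                ifelse(b + disc > 0, 2 * p[["K"]] * cond$x1 / (b + disc), 0),
                0.5 * (-b + disc))
  paf <- pmin(pmax(paf, 0), cond$x1)
  h <- ifelse(paf > 0, 1 / (1 + (p[["theta"]] / paf)^p[["n"]]), 0)
  f <- p[["k0"]] + p[["k1"]] * h
  if (model == "hill_global") cond$fconst * f else f
}

#' Weighted misfit objective of the regulation model
#'
#' The fitting error
#' `Q(c) = sum_s sum_t |fbar_s(t) - f(x_s(t), c)| / (2 * eps_s(t))`,
#' a deviation from the observed target activity weighted by the inverse
#' confidence half-width. Points with `eps <= 0` are excluded. The
#' `"squared"` loss replaces the absolute deviation by its square.
#'
#' @param params a [regulation_params] vector (or coercible).
#' @param data a [fit_dataset].
#' @param model `"hill"` (titration + Hill only) or `"hill_global"`
#'   (multiplied by the constitutive activity).
#' @param loss `"abs"` (default, the weighted absolute deviation) or
#'   `"squared"`.
#' @return The scalar objective value, >= 0.
#' @export
objective_Q <- function(params, data, model = c("hill_global", "hill"),
                        loss = c("abs", "squared")) {
  model <- match.arg(model)
  loss <- match.arg(loss)
  if (!inherits(data, "fit_dataset")) data <- fit_dataset(data)
  p <- unclass(as_regulation_params(params))
  .Q_value(p, data, model, loss)
}

.Q_value <- function(p, data, model, loss) {
  tot <- 0
  for (cond in data) {
    pred <- .eval_model(p, cond, model)
    w <- cond$use
    d <- (cond$fbar[w] - pred[w]) / (2 * cond$eps[w])
    tot <- tot + if (loss == "abs") sum(abs(d)) else sum(d * d)
  }
  tot
}

#' Parameter search box from the data
#'
#' The physiologically plausible box constraints:
#' `0 <= k0 <= max(fbar)`, `0 <= k1 <= 10*max(fbar)`, `1 <= n <= 4`,
#' `0 <= theta <= max(x1)` and `0 <= K <= 20*max(x2)`, maxima taken over
#' all conditions and times. With `theta_min_obs = TRUE` the lower bound on
#' `theta` is raised to the smallest observed `x1`, the reading under which
#' the threshold lies within the range of observed FliA concentrations.
#'
#' @param data a [fit_dataset].
#' @param theta_min_obs raise the lower bound of `theta` to `min(x1)`.
#' @return A list with named numeric vectors `lower` and `upper`.
#' @export
search_box <- function(data, theta_min_obs = FALSE) {
  if (!inherits(data, "fit_dataset")) data <- fit_dataset(data)
  max_f <- max(vapply(data, function(cc) max(cc$fbar), 0))
  max_x1 <- max(vapply(data, function(cc) max(cc$x1), 0))
  max_x2 <- max(vapply(data, function(cc) max(cc$x2), 0))
  min_x1 <- min(vapply(data, function(cc) min(cc$x1), 0))
  lower <- c(k0 = 0, k1 = 0, n = 1, theta = if (theta_min_obs) min_x1 else 0,
             K = 0)
  upper <- c(k0 = max_f, k1 = 10 * max_f, n = 4, theta = max_x1,
             K = 20 * max_x2)
  list(lower = lower, upper = upper)
}

# map the unit cube to the box; k1/theta/K live on a log scale to handle
# their wide dynamic range
.log_scaled <- c("k1", "theta", "K")

.u_to_params <- function(u, box, free) {
  p <- box$lower
  for (i in seq_along(free)) {
    nm <- free[i]
    L <- box$lower[[nm]]; U <- box$upper[[nm]]
    if (nm %in% .log_scaled && U > 0) {
      Le <- max(L, U * 1e-6)
      p[[nm]] <- Le * (U / Le)^u[i]
    } else {
      p[[nm]] <- L + (U - L) * u[i]
    }
  }
  p
}

#' Fit the regulation function by multistart optimisation
#'
#' Minimises [objective_Q()] over the [search_box()] by best-of-`n_starts`
#' local minimisation. Start points are a seeded Latin hypercube sample of
#' the box; each local search is a Nelder-Mead minimisation in an
#' unconstrained reparameterisation of the box (logistic transform, with
#' `k1`, `theta`, `K` on a log scale). The result is reproducible given
#' `seed`.
#'
#' @param data a [fit_dataset].
#' @param model `"hill_global"` (default) or `"hill"`.
#' @param n_starts number of multistart points, >= 1.
#' @param seed integer seed for start-point sampling.
#' @param fixed optional named numeric vector of parameters clamped to
#'   given values (e.g. `c(K = 14615)`).
#' @param loss `"abs"` or `"squared"`, see [objective_Q()].
#' @param theta_min_obs see [search_box()].
#' @param maxit maximum Nelder-Mead iterations per start.
#' @return An object of class `"regfit"`: the estimated parameters
#'   (`$params`), objective value (`$Q`), per-start objective values
#'   (`$start_Q`), the dataset, model, box and seed, and per-condition
#'   fitted values.
#' @export
fit_regulation <- function(data, model = c("hill_global", "hill"),
                           n_starts = 20, seed = 1, fixed = NULL,
                           loss = c("abs", "squared"),
                           theta_min_obs = FALSE, maxit = 400) {
  model <- match.arg(model)
  loss <- match.arg(loss)
  if (!inherits(data, "fit_dataset")) data <- fit_dataset(data)
  if (n_starts < 1) stop("n_starts must be >= 1")
  if (model == "hill_global" &&
      any(vapply(data, function(cc) is.null(cc$fconst), TRUE)))
    stop("model 'hill_global' needs an fconst trajectory in every condition")
  box <- search_box(data, theta_min_obs = theta_min_obs)
  if (!is.null(fixed)) {
    for (nm in names(fixed)) box$lower[[nm]] <- box$upper[[nm]] <- fixed[[nm]]
  }
  free <- names(box$lower)[box$upper > box$lower]
  d <- length(free)
  set.seed(seed)
  U0 <- if (d > 0) lhs::randomLHS(n_starts, d) else matrix(0, n_starts, 0)
  obj_z <- function(z) {
    p <- .u_to_params(stats::plogis(z), box, free)
    .Q_value(p, data, model, loss)
  }
  fits <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    z0 <- stats::qlogis(pmin(pmax(U0[k, ], 0.02), 0.98))
    fits[[k]] <- if (d > 0)
      stats::optim(z0, obj_z, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10))
    else list(par = numeric(0), value = obj_z(numeric(0)), convergence = 0)
  }
  vals <- vapply(fits, `[[`, 0, "value")
  if (all(!is.finite(vals)))
    stop("optimisation failed at every start point")
  best <- fits[[which.min(vals)]]
  # restarting Nelder-Mead at the incumbent re-initialises the simplex and
  # regularly escapes premature convergence; iterate until stationary
  if (d > 0) for (round in 1:10) {
    nxt <- stats::optim(best$par, obj_z, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (nxt$value >= best$value * (1 - 1e-8)) break
    best <- nxt
  }
  p_hat <- .u_to_params(stats::plogis(best$par), box, free)
  fitted <- lapply(data, function(cond) .eval_model(p_hat, cond, model))
  structure(list(params = as_regulation_params(p_hat), Q = best$value,
                 start_Q = vals, data = data, model = model, loss = loss,
                 box = box, fixed = fixed, n_starts = n_starts, seed = seed,
                 fitted = fitted, half_lives = NULL,
                 convergence = best$convergence),
            class = "regfit")
}

#' @export
print.regfit <- function(x, digits = 4, ...) {
  cat(sprintf("Regulation function fit (model '%s', %s loss)\n",
              x$model, x$loss))
  cat(sprintf("  conditions: %s\n", paste(names(x$data), collapse = ", ")))
  cat(sprintf("  Q = %.*g  (best of %d starts, seed %d)\n", digits, x$Q,
              x$n_starts, x$seed))
  cat("  parameters:\n")
  print(signif(unclass(x$params), digits))
  if (!is.null(x$half_lives)) {
    cat("  half-lives (min):\n")
    cat("    FliA:", paste(signif(x$half_lives$tau_A, 3), collapse = " "), "\n")
    cat("    FlgM:", paste(signif(x$half_lives$tau_M, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.regfit <- function(object, ...) unclass(object$params)

#' @export
summary.regfit <- function(object, ...) {
  res <- residuals(object)
  data.frame(condition = names(object$data),
             n_points = vapply(object$data, function(cc) sum(cc$use), 0L),
             rmse = vapply(res, function(r) sqrt(mean(r^2)), 0),
             max_obs = vapply(object$data, function(cc) max(cc$fbar), 0),
             row.names = NULL)
}

#' @export
predict.regfit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else {
    if (!inherits(newdata, "fit_dataset")) fit_dataset(newdata) else newdata
  }
  p <- unclass(object$params)
  lapply(data, function(cond) .eval_model(p, cond, object$model))
}

#' @export
residuals.regfit <- function(object, ...) {
  Map(function(cond, fit) cond$fbar - fit, object$data, object$fitted)
}

#' @export
plot.regfit <- function(x, ...) {
  ncond <- length(x$data)
  old <- graphics::par(mfrow = c(ceiling(ncond / 2), min(ncond, 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in names(x$data)) {
    cond <- x$data[[nm]]
    graphics::plot(cond$time, cond$fbar, type = "l", col = "skyblue3",
                   xlab = "time (min)", ylab = "activity (RFU/min)",
                   main = nm, ...)
    graphics::polygon(c(cond$time, rev(cond$time)),
                      c(cond$fbar - cond$eps, rev(cond$fbar + cond$eps)),
                      border = NA,
                      col = grDevices::adjustcolor("skyblue", 0.3))
    graphics::lines(cond$time, x$fitted[[nm]], col = "navy", lwd = 2)
  }
  invisible(x)
}

#' Simulate resampled datasets from a fitted regulation model
#'
#' Draws datasets in which the target activity at each time point is
#' resampled from a Gaussian with the observed mean and standard deviation
#' `eps/2` (the band half-width is 2 SEM, so `eps/2` is the SEM of the
#' replicate mean). Used by [bootstrap_cis()].
#'
#' @param object a `"regfit"`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` [fit_dataset] objects.
#' @export
simulate.regfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    conds <- lapply(object$data, function(cond) {
      sdv <- ifelse(cond$use, cond$eps / 2, 0)
      cond$fbar <- cond$fbar + stats::rnorm(length(cond$fbar), 0, sdv)
      cond
    })
    fit_dataset(conds)
  })
}

#' Fit the flgM-promoter variant of the regulation model
#'
#' For the class-3 flgM promoter the WT-LB condition is unavailable and the
#' dissociation constant `K` is fixed, for biological consistency, to the
#' value inferred from the tar fit. Errors if a condition named `"WT-LB"`
#' is present.
#'
#' @param data a [fit_dataset] without the WT-LB condition.
#' @param K_fixed value at which `K` is clamped (RFU), >= 0.
#' @param ... passed to [fit_regulation()].
#' @return A `"regfit"` with free parameters `(k0, k1, n, theta)` only.
#' @export
fit_flgM_variant <- function(data, K_fixed, ...) {
  if (!inherits(data, "fit_dataset")) data <- fit_dataset(data)
  if (K_fixed < 0) stop("K_fixed must be non-negative")
  if ("WT-LB" %in% names(data))
    stop("condition WT-LB must be excluded from the flgM fit")
  fit_regulation(data, fixed = c(K = K_fixed), ...)
}
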