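#' Steady-state initial protein concentration from preculture
#'
#' Initial concentration of the protein of interest at the start of the
#' experiment, obtained by assuming gene expression in the preculture is at
#' steady state:
#' `p0 = (mu_T + gamma_r)/(mu_T + gamma_p_pre) * r_T`,
#' where `r_T` is the reporter concentration at the end of the preculture,
#' `mu_T` the growth rate there (0 for a stationary-phase preculture) and
#' `gamma_p_pre` the protein degradation constant in the preculture (for
#' FliA and FlgM the stationary-phase apparent half-lives of 2 h and 3 h,
#' not the short exponential-phase ones).
#'
#' @param r_T reporter concentration at the end of the preculture (RFU).
#' @param gamma_r reporter degradation constant (1/min).
#' @param gamma_p_pre protein degradation constant in the preculture (1/min).
#' @param mu_T growth rate at the end of the preculture (1/min), default 0.
#' @return Initial protein concentration `p0` (RFU).
#' @examples
#' initial_protein(100, 6e-4, log(2) / 120)  # FliA, 2 h preculture half-life
#' @export
initial_protein <- function(r_T, gamma_r, gamma_p_pre, mu_T = 0) {
  if (r_T < 0 || gamma_r < 0 || gamma_p_pre < 0 || mu_T < 0)
    stop("all rates and concentrations must be non-negative")
  if (mu_T + gamma_p_pre == 0)
    stop("mu_T and gamma_p_pre cannot both be zero")
  (mu_T + gamma_r) / (mu_T + gamma_p_pre) * r_T
}

.as_time_fun <- function(f, what = "activity") {
  if (is.function(f)) return(f)
  if (inherits(f, "activity_profile"))
    return(stats::approxfun(f$time, f$f_mean, rule = 2))
  if (is.numeric(f) && length(f) == 1) {
    force(f); return(function(t) rep(f, length(t)))
  }
  stop("cannot interpret ", what, " input; give a function, a scalar, ",
       "or an activity_profile")
}

#' Reconstruct a protein concentration profile from a promoter activity
#'
#' Integrates the kinetic model of gene expression
#' `dp/dt = f(t) - (gamma_p + mu(t)) * p(t)`, `p(0) = p0`, with
#' `gamma_p = log(2)/half_life`, using an adaptive stiff-capable solver
#' (relative tolerance 1e-8, absolute 1e-10). Synthesis is driven by the
#' promoter activity `f`, removal by degradation and growth dilution.
#'
#' @param f promoter activity: an `"activity_profile"`, a function of time,
#'   or a scalar (RFU/min).
#' @param mu growth rate: a function of time or a scalar (1/min).
#' @param half_life protein half-life (minutes), > 0.
#' @param p0 initial concentration (RFU).
#' @param times output times (minutes); defaults to the profile's grid when
#'   `f` is an `"activity_profile"`.
#' @param condition,regulator labels stored in the result.
#' @return An object of class `"protein_profile"`: fields `condition`,
#'   `regulator`, `time`, `p` (RFU, non-negative), `half_life` (min) and
#'   `gamma_p` (1/min).
#' @export
protein_concentration <- function(f, mu = 0, half_life, p0 = 0, times = NULL,
                                  condition = NA_character_,
                                  regulator = NA_character_) {
  if (half_life <= 0) stop("half_life must be positive")
  if (is.null(times)) {
    if (!inherits(f, "activity_profile"))
      stop("times must be given unless f is an activity_profile")
    times <- f$time
  }
  if (inherits(f, "activity_profile")) {
    cond <- f$condition
    if (is.na(condition)) condition <- cond
    lo <- min(f$time); hi <- max(f$time)
    if (min(times) < lo - 1e-9 || max(times) > hi + 1e-9)
      stop("integration window extends beyond the activity profile")
  }
  ffun <- .as_time_fun(f, "activity")
  mufun <- .as_time_fun(mu, "growth rate")
  gamma_p <- log(2) / half_life
  deriv <- function(t, y, parms)
    list(ffun(t) - (gamma_p + mufun(t)) * y)
  p0 <- unname(p0)
  sol <- deSolve::lsoda(y = c(p = p0), times = times, func = deriv,
                        parms = NULL, rtol = 1e-8, atol = 1e-10)
  p <- pmax(as.numeric(sol[, "p"]), 0)
  structure(list(condition = condition, regulator = regulator,
                 time = times, p = p, half_life = half_life,
                 gamma_p = gamma_p, p0 = p0),
            class = "protein_profile")
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("<protein_profile> %s in %s: half-life %g min, %d points, peak %.4g RFU\n",
              x$regulator, x$condition, x$half_life, length(x$time), max(x$p)))
  invisible(x)
}

#' @export
plot.protein_profile <- function(x, ...) {
  graphics::plot(x$time, x$p, type = "l", xlab = "time (min)",
                 ylab = "protein concentration (RFU)",
                 main = sprintf("%s (half-life %g min)", x$regulator,
                                x$half_life), ...)
  invisible(x)
}

#' Back-extrapolate below-detection promoter activities towards zero
#'
#' In conditions where a promoter is inactive during the first part of the
#' experiment, its measured fluorescence is indistinguishable from
#' background and its activity is taken to be 0 there: the profile is set
#' to 0 for times before the detection boundary and ramped linearly to the
#' first reliably detected value over one detection interval. The
#' confidence band is kept where measured and set to 0 on imputed points.
#'
#' @param f an `"activity_profile"`.
#' @param detect_time first time (minutes) at which the signal is reliably
#'   above detection; `NA` (already detected at the window start) returns
#'   the profile unchanged.
#' @param ramp width of the linear ramp (minutes); defaults to the median
#'   grid spacing (one detection interval).
#' @return The modified `"activity_profile"`.
#' @export
backextrapolate_activity <- function(f, detect_time, ramp = NULL) {
  stopifnot(inherits(f, "activity_profile"))
  if (is.na(detect_time) || detect_time <= min(f$time)) return(f)
  if (detect_time > max(f$time))
    stop("detect_time lies after the end of the profile window")
  if (is.null(ramp)) ramp <- stats::median(diff(f$time))
  f_det <- stats::approx(f$time, f$f_mean, xout = detect_time, rule = 2)$y
  imputed <- f$time < detect_time
  w <- pmin(pmax((f$time - (detect_time - ramp)) / ramp, 0), 1)
  f$f_mean[imputed] <- (w * f_det)[imputed]
  f$epsilon[imputed] <- 0
  f
}

#' Log-spaced grid of candidate protein half-lives
#'
#' @param n number of grid values (default 27).
#' @param lo,hi range in minutes (defaults 7 min to 4 h).
#' @return Strictly increasing numeric vector of half-lives (minutes).
#' @export
halflife_grid <- function(n = 27, lo = 7, hi = 240) {
  if (lo <= 0 || hi <= lo || n < 1) stop("invalid half-life grid")
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Precompute protein concentration profiles over a half-life grid
#'
#' For each regulator, condition and candidate half-life, integrates the
#' protein kinetic model from the condition's promoter activity profile.
#' The initial condition follows the preculture steady-state relation with
#' the stationary-phase degradation constant, and is therefore shared
#' across the experiment-phase half-life grid.
#'
#' @param activities nested list `activities[[regulator]][[condition]]` of
#'   `"activity_profile"` objects.
#' @param mu named list of growth-rate functions per condition (or scalars).
#' @param halflives numeric vector of candidate half-lives (minutes), e.g.
#'   [halflife_grid()].
#' @param gamma_r reporter degradation constant (1/min).
#' @param preculture named list per regulator with elements `gamma_p_pre`
#'   (1/min), `mu_T` (1/min, default 0) and `r_T` (named vector of reporter
#'   concentrations per condition, RFU). `NULL` uses `p0 = 0`.
#' @return Nested list `res[[regulator]][[condition]][[i]]` of
#'   `"protein_profile"` objects, `i` indexing `halflives`; the half-life
#'   vector is attached as attribute `"halflives"`.
#' @export
precompute_profiles <- function(activities, mu, halflives, gamma_r = 6e-4,
                                preculture = NULL) {
  if (!length(halflives)) stop("empty half-life grid")
  res <- list()
  for (reg in names(activities)) {
    res[[reg]] <- list()
    for (cond in names(activities[[reg]])) {
      prof <- activities[[reg]][[cond]]
      p0 <- 0
      if (!is.null(preculture) && !is.null(preculture[[reg]])) {
        pc <- preculture[[reg]]
        mu_T <- if (is.null(pc$mu_T)) 0 else pc$mu_T
        r_T <- if (length(pc$r_T) > 1) pc$r_T[[cond]] else pc$r_T
        p0 <- initial_protein(r_T, gamma_r, pc$gamma_p_pre, mu_T)
      }
      res[[reg]][[cond]] <- lapply(halflives, function(hl)
        protein_concentration(prof, mu = mu[[cond]], half_life = hl,
                              p0 = p0, condition = cond, regulator = reg))
    }
  }
  attr(res, "halflives") <- halflives
  res
}
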