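#' Read a tidy microplate table
#'
#' Reads a CSV of per-well microplate time series into a list of per-well
#' series. The file must contain the columns `condition`, `well`, `reporter`,
#' `replicate`, `role`, `time_min`, `absorbance`, `fluorescence`, with one
#' row per (well, time). `role` is one of `"reporter"`,
#' `"background_medium"` (medium blank) or `"background_strain"`
#' (non-fluorescent strain, for autofluorescence); `reporter` names the
#' promoter construct and may be `NA` for background wells.
#'
#' @param path path to a CSV file, or a data frame with the same columns.
#' @return An object of class `"plate_data"`: a list of `"plate_series"`
#'   objects (one per well), each with fields `condition`, `well`,
#'   `reporter`, `replicate`, `role`, `time`, `absorbance`, `fluorescence`,
#'   time-sorted.
#' @export
read_plate_table <- function(path) {
  df <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "well", "reporter", "replicate", "role",
                "time_min", "absorbance", "fluorescence")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("plate table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  bad_role <- !df$role %in% c("reporter", "background_medium", "background_strain")
  if (any(bad_role))
    stop("plate table schema error: invalid role at row(s) ",
         paste(utils::head(which(bad_role), 5), collapse = ", "))
  key <- paste(df$condition, df$well, df$time_min)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("plate table data error: duplicated (well, time) at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "))
  }
  wells <- split(df, paste(df$condition, df$well, sep = "\r"))
  out <- lapply(wells, function(w) {
    ord <- order(w$time_min)
    w <- w[ord, ]
    if (any(diff(w$time_min) <= 0))
      stop("plate table data error: non-monotone time in well ", w$well[1])
    structure(list(condition = w$condition[1], well = w$well[1],
                   reporter = w$reporter[1], replicate = w$replicate[1],
                   role = w$role[1], time = w$time_min,
                   absorbance = w$absorbance, fluorescence = w$fluorescence),
              class = "plate_series")
  })
  names(out) <- vapply(out, function(w) paste(w$condition, w$well, sep = ":"),
                       character(1))
  structure(out[order(names(out))], class = "plate_data")
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("<plate_series> well %s (%s), condition %s, role %s, %d readings over [%g, %g] min\n",
              x$well, if (is.na(x$reporter)) "-" else x$reporter,
              x$condition, x$role, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' @export
print.plate_data <- function(x, ...) {
  cat(sprintf("<plate_data> %d wells, %d condition(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "condition")))))
  invisible(x)
}

# interpolate the mean signal of a set of wells onto target times
.mean_signal_at <- function(wells, field, times) {
  if (!length(wells)) return(rep(NA_real_, length(times)))
  mat <- vapply(wells, function(w)
    stats::approx(w$time, w[[field]], xout = times, rule = 2)$y,
    numeric(length(times)))
  rowMeans(matrix(mat, nrow = length(times)))
}

#' Correct plate measurements for background
#'
#' Subtracts the medium blank from absorbance, and from fluorescence both the
#' medium blank and an autofluorescence estimate derived from the
#' non-fluorescent background strain: the background strain's corrected
#' fluorescence is interpolated to the reporter well's times and scaled by
#' the ratio of corrected absorbances (autofluorescence is proportional to
#' biomass). Negative corrected values are floored at 0. Time windows where
#' the corrected fluorescence is statistically indistinguishable from 0
#' (within `detection_z` times the background-strain residual scale) are
#' flagged below detection in the `below_detection` field of each series.
#'
#' @param plate a `"plate_data"` object from [read_plate_table()].
#' @param detection_z z-score threshold on corrected fluorescence for the
#'   below-detection flag (default 2).
#' @return A `"plate_data"` object containing only the reporter wells,
#'   background-corrected, each series gaining a logical `below_detection`
#'   vector.
#' @export
correct_background <- function(plate, detection_z = 2) {
  stopifnot(inherits(plate, "plate_data"))
  conds <- unique(vapply(plate, `[[`, "", "condition"))
  out <- list()
  for (cond in conds) {
    in_cond <- Filter(function(w) w$condition == cond, plate)
    roles <- vapply(in_cond, `[[`, "", "role")
    med <- in_cond[roles == "background_medium"]
    bgs <- in_cond[roles == "background_strain"]
    rep_wells <- in_cond[roles == "reporter"]
    if (!length(med) || !length(bgs))
      stop("no background wells for condition ", cond)
    for (w in rep_wells) {
      med_A <- .mean_signal_at(med, "absorbance", w$time)
      med_I <- .mean_signal_at(med, "fluorescence", w$time)
      bg_A <- pmax(.mean_signal_at(bgs, "absorbance", w$time) - med_A, 0)
      bg_I <- pmax(.mean_signal_at(bgs, "fluorescence", w$time) - med_I, 0)
      A_corr <- w$absorbance - med_A
      ratio <- ifelse(bg_A > 0, pmax(A_corr, 0) / bg_A, 1)
      autofluo <- bg_I * ratio
      I_corr <- w$fluorescence - med_I - autofluo
      # residual scale of the background strain's own corrected fluorescence,
      # used as the detection noise floor
      # measurement noise scale from the high-frequency component of the
      # background-strain fluorescence (first differences, robust to trends)
      bg_resid <- mean(vapply(bgs, function(b)
        stats::sd(diff(b$fluorescence)) / sqrt(2), numeric(1)))
      if (!is.finite(bg_resid) || bg_resid == 0) bg_resid <- 1e-12
      w$below_detection <- I_corr < detection_z * bg_resid
      w$absorbance <- pmax(A_corr, 0)
      w$fluorescence <- pmax(I_corr, 0)
      out[[paste(w$condition, w$well, sep = ":")]] <- w
    }
  }
  structure(out, class = "plate_data")
}

#' Fit smoothing splines to absorbance and fluorescence signals
#'
#' Fits cubic smoothing splines to the absorbance and fluorescence series of
#' one well, giving evaluable estimates of `A(t)`, `I(t)` and their exact
#' spline derivatives. The smoothing parameter `smoothing` in `(0, 1]`
#' weights fidelity against roughness as in the classical cubic smoothing
#' spline criterion (penalty `lambda = (1 - smoothing)/smoothing`);
#' `smoothing = 1` yields the interpolating natural cubic spline, and the
#' default `NULL` selects the penalty by generalized cross-validation.
#'
#' Fluorescence noise grows with the signal (shot noise, gain), so an
#' unweighted spline lets the large residuals of the bright late phase set
#' the penalty and over-smooths the faint early dynamics. When replicate
#' wells are available, per-time-point weights proportional to the inverse
#' empirical variance across replicates restore the balance; these are
#' computed by [process_plate()] and passed through `weights`.
#'
#' @param series a `"plate_series"` (background-corrected) with at least 8
#'   time points.
#' @param smoothing smoothing parameter in `(0, 1]`, or `NULL` for GCV.
#' @param weights optional list with numeric vectors `absorbance` and/or
#'   `fluorescence` (same length as `time`) of spline weights.
#' @return An object of class `"smoothed_signal"`: functions `A`, `I`, `dA`,
#'   `dI` of time (minutes), the analysis `window` (truncated, with a
#'   warning, to the largest interval on which `A > 0`), and the
#'   `smoothing` parameter used.
#' @export
smooth_signals <- function(series, smoothing = NULL, weights = NULL) {
  stopifnot(inherits(series, "plate_series"))
  t <- series$time
  if (length(t) < 8) stop("need at least 8 time points to smooth")
  if (!is.null(smoothing) && (smoothing <= 0 || smoothing > 1))
    stop("smoothing must lie in (0, 1]")
  fit_one <- function(y, w = NULL) {
    if (!is.null(w) && (length(w) != length(t) || any(!is.finite(w)) ||
                        any(w <= 0)))
      stop("weights must be positive, finite and match the time vector")
    if (!is.null(smoothing) && smoothing == 1) {
      f <- stats::splinefun(t, y, method = "natural")
      list(f = function(x) f(x), df = function(x) f(x, deriv = 1))
    } else if (is.null(smoothing)) {
      ss <- stats::smooth.spline(t, y, w = w, all.knots = TRUE,
                                 keep.data = FALSE)
      list(f = function(x) stats::predict(ss, x)$y,
           df = function(x) stats::predict(ss, x, deriv = 1)$y)
    } else {
      ss <- stats::smooth.spline(t, y, w = w, all.knots = TRUE,
                                 keep.data = FALSE,
                                 lambda = (1 - smoothing) / smoothing)
      list(f = function(x) stats::predict(ss, x)$y,
           df = function(x) stats::predict(ss, x, deriv = 1)$y)
    }
  }
  fa <- fit_one(series$absorbance, weights$absorbance)
  fi <- fit_one(series$fluorescence, weights$fluorescence)
  window <- range(t)
  grid <- seq(window[1], window[2], length.out = 512)
  pos <- fa$f(grid) > 0
  if (!all(pos)) {
    runs <- rle(pos)
    ends <- cumsum(runs$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    best <- which.max(ifelse(runs$values, runs$lengths, 0))
    window <- c(grid[starts[best]], grid[ends[best]])
    warning("smoothed absorbance is non-positive on part of the range; ",
            "analysis window truncated to [", signif(window[1], 4), ", ",
            signif(window[2], 4), "] min")
  }
  structure(list(A = fa$f, I = fi$f, dA = fa$df, dI = fi$df,
                 window = window, smoothing = smoothing,
                 condition = series$condition, well = series$well,
                 reporter = series$reporter,
                 below_detection = series$below_detection,
                 time = t),
            class = "smoothed_signal")
}

#' @export
print.smoothed_signal <- function(x, ...) {
  cat(sprintf("<smoothed_signal> well %s, window [%g, %g] min, smoothing %s\n",
              x$well, x$window[1], x$window[2],
              if (is.null(x$smoothing)) "GCV" else format(x$smoothing)))
  invisible(x)
}

.check_window <- function(t, window) {
  if (any(t < window[1] - 1e-9) || any(t > window[2] + 1e-9))
    stop("evaluation outside the fitted window [", window[1], ", ",
         window[2], "] min")
}

#' Growth rate from a smoothed absorbance signal
#'
#' Returns the evaluable growth rate `mu(t) = d log A(t)/dt = A'(t)/A(t)`
#' in 1/min.
#'
#' @param s a `"smoothed_signal"`.
#' @return A function of time (minutes); errors outside the fitted window.
#' @export
growth_rate <- function(s) {
  stopifnot(inherits(s, "smoothed_signal"))
  function(t) {
    .check_window(t, s$window)
    s$dA(t) / s$A(t)
  }
}

#' Reporter concentration from smoothed signals
#'
#' The reporter protein concentration per unit biomass,
#' `r(t) = I(t)/A(t)` (RFU).
#'
#' @param s a `"smoothed_signal"`.
#' @return A function of time (minutes).
#' @export
reporter_concentration <- function(s) {
  stopifnot(inherits(s, "smoothed_signal"))
  function(t) {
    .check_window(t, s$window)
    s$I(t) / s$A(t)
  }
}

#' Promoter activity from smoothed signals
#'
#' The promoter activity (protein synthesis rate per unit biomass) derived
#' from the kinetic model of reporter gene expression:
#' `f(t) = I'(t)/A(t) + gamma_r * I(t)/A(t)`, equivalently
#' `r'(t) + (gamma_r + mu(t)) * r(t)` (RFU/min). `gamma_r` is the reporter
#' degradation constant; the default corresponds to the 19 h half-life of
#' stable GFP variants.
#'
#' @param s a `"smoothed_signal"`.
#' @param gamma_r reporter degradation constant (1/min), non-negative.
#' @return A function of time (minutes).
#' @export
promoter_activity <- function(s, gamma_r = 6e-4) {
  stopifnot(inherits(s, "smoothed_signal"))
  if (gamma_r < 0) stop("gamma_r must be non-negative")
  function(t) {
    .check_window(t, s$window)
    (s$dI(t) + gamma_r * s$I(t)) / s$A(t)
  }
}

#' Uniform evaluation grid across replicate windows
#'
#' A 1-minute grid spanning the intersection of the replicate analysis
#' windows, with the edges trimmed by three sampling intervals to avoid
#' spline boundary artifacts in the derivative estimates.
#'
#' @param signals list of `"smoothed_signal"` objects (replicates).
#' @param step grid step in minutes (default 1).
#' @param trim number of median sampling intervals trimmed at each edge.
#' @return Numeric vector of times (minutes).
#' @export
evaluation_grid <- function(signals, step = 1, trim = 3) {
  lo <- max(vapply(signals, function(s) s$window[1], 0))
  hi <- min(vapply(signals, function(s) s$window[2], 0))
  dt <- stats::median(unlist(lapply(signals, function(s) diff(s$time))))
  lo <- lo + trim * dt
  hi <- hi - trim * dt
  if (hi <= lo) stop("replicate windows do not overlap after trimming")
  seq(lo, hi, by = step)
}

#' Aggregate replicate activity curves into a mean profile with a band
#'
#' Pointwise mean across replicates with half-width confidence band
#' `epsilon(t) = 2 * SEM(t)` (twice the standard error of the replicate
#' mean, sample SD with `n - 1` denominator).
#'
#' @param fs either a numeric matrix (rows = grid points, columns =
#'   replicates) or a list of functions of time evaluated on `grid`.
#' @param grid common evaluation grid (minutes).
#' @param condition condition label stored in the profile.
#' @return An object of class `"activity_profile"` with fields `condition`,
#'   `time`, `f_mean`, `epsilon`, `n_replicates`. With a single replicate
#'   `epsilon` is `NA` and the profile is flagged `epsilon_defined = FALSE`.
#' @export
aggregate_replicates <- function(fs, grid, condition = NA_character_) {
  if (is.list(fs) && !is.data.frame(fs))
    fs <- vapply(fs, function(f) f(grid), numeric(length(grid)))
  fs <- as.matrix(fs)
  if (nrow(fs) != length(grid)) stop("curves and grid lengths differ")
  n <- ncol(fs)
  f_mean <- rowMeans(fs)
  if (n >= 2) {
    sdv <- apply(fs, 1, stats::sd)
    epsilon <- 2 * sdv / sqrt(n)
  } else {
    epsilon <- rep(NA_real_, length(grid))
  }
  structure(list(condition = condition, time = grid, f_mean = f_mean,
                 epsilon = epsilon, n_replicates = n,
                 epsilon_defined = n >= 2),
            class = "activity_profile")
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> %s: %d points on [%g, %g] min, %d replicate(s)\n",
              x$condition, length(x$time), min(x$time), max(x$time),
              x$n_replicates))
  invisible(x)
}

#' @export
plot.activity_profile <- function(x, ...) {
  graphics::plot(x$time, x$f_mean, type = "l", xlab = "time (min)",
                 ylab = "promoter activity (RFU/min)",
                 main = x$condition, ...)
  if (x$epsilon_defined) {
    graphics::polygon(c(x$time, rev(x$time)),
                      c(x$f_mean - x$epsilon, rev(x$f_mean + x$epsilon)),
                      border = NA, col = grDevices::adjustcolor("steelblue", 0.3))
    graphics::lines(x$time, x$f_mean)
  }
  invisible(x)
}

#' Process a plate into per-condition promoter activity profiles
#'
#' Full preprocessing chain: background correction, spline smoothing of
#' every reporter well, evaluation of promoter activities on a common
#' 1-minute grid, and aggregation of replicates per (condition, reporter)
#' with 2-SEM bands. Growth-rate and reporter-concentration estimates are
#' aggregated the same way.
#'
#' @param plate a `"plate_data"` object.
#' @param gamma_r reporter degradation constant (1/min).
#' @param smoothing smoothing parameter passed to [smooth_signals()].
#' @param detection_z detection threshold passed to [correct_background()].
#' @return A list with one element per condition, each containing:
#'   `activities` (named list of `"activity_profile"` per reporter), `mu`
#'   (growth-rate function of time from the replicate-averaged absorbance),
#'   `r` (named list of reporter-concentration profiles), `grid`, and
#'   `detect_time` (named vector: first time each reporter is reliably above
#'   detection, NA when always detected).
#' @export
process_plate <- function(plate, gamma_r = 6e-4, smoothing = NULL,
                          detection_z = 2) {
  corrected <- correct_background(plate, detection_z = detection_z)
  conds <- unique(vapply(corrected, `[[`, "", "condition"))
  out <- list()
  for (cond in conds) {
    wells <- Filter(function(w) w$condition == cond, corrected)
    reporters <- unique(vapply(wells, `[[`, "", "reporter"))
    # replicate wells of one reporter share the true curves, so the spread
    # across them at each time point estimates the measurement variance;
    # inverse-variance weights keep the spline from over-smoothing the dim
    # early signal to accommodate the large absolute noise of the bright
    # late phase
    smooth_group <- function(grp) {
      times <- lapply(grp, `[[`, "time")
      w <- NULL
      if (length(grp) >= 3 &&
          all(vapply(times, identical, NA, times[[1]]))) {
        sd_floor <- function(m) {
          s <- apply(m, 1, stats::sd)
          if (max(s) <= 0) return(NULL)
          pmax(s, 0.05 * max(s))
        }
        sI <- sd_floor(vapply(grp, `[[`, numeric(length(times[[1]])),
                              "fluorescence"))
        sA <- sd_floor(vapply(grp, `[[`, numeric(length(times[[1]])),
                              "absorbance"))
        w <- list(fluorescence = if (!is.null(sI)) 1 / sI^2,
                  absorbance = if (!is.null(sA)) 1 / sA^2)
      }
      lapply(grp, smooth_signals, smoothing = smoothing, weights = w)
    }
    sm_all <- unlist(lapply(reporters, function(rep_name)
      smooth_group(Filter(function(w) w$reporter == rep_name, wells))),
      recursive = FALSE)
    grid <- evaluation_grid(sm_all)
    activities <- list(); rconc <- list(); detect <- c()
    for (rep_name in reporters) {
      sm <- Filter(function(s) s$reporter == rep_name, sm_all)
      fmat <- vapply(sm, function(s) promoter_activity(s, gamma_r)(grid),
                     numeric(length(grid)))
      rmat <- vapply(sm, function(s) reporter_concentration(s)(grid),
                     numeric(length(grid)))
      activities[[rep_name]] <- aggregate_replicates(fmat, grid, cond)
      rconc[[rep_name]] <- aggregate_replicates(rmat, grid, cond)
      # first grid time by which a majority of replicates are above detection
      below <- vapply(sm, function(s) {
        stats::approx(s$time, as.numeric(s$below_detection), xout = grid,
                      rule = 2)$y > 0.5
      }, logical(length(grid)))
      frac_below <- rowMeans(matrix(below, nrow = length(grid)))
      first_det <- which(frac_below < 0.5)[1]
      detect[rep_name] <- if (is.na(first_det) || first_det == 1L)
        NA_real_ else grid[first_det]
    }
    # growth rate from the pooled mean of per-well growth-rate estimates
    mus <- lapply(sm_all, growth_rate)
    mu_mean <- rowMeans(vapply(mus, function(m) m(grid), numeric(length(grid))))
    mu_fun <- stats::approxfun(grid, mu_mean, rule = 2)
    out[[cond]] <- list(activities = activities, r = rconc, mu = mu_fun,
                        grid = grid, detect_time = detect)
  }
  out
}

#' Default analysis window of a processed condition
#'
#' The regulation analysis is restricted to the time frame in which the
#' regulator genes are expressed: the window runs from the first time at
#' which all regulator reporters are reliably above detection to growth
#' arrest,
#' defined as the first time after the growth-rate maximum at which
#' `mu(t) < mu_frac * max(mu)`. The growth-rate curve is despiked with a
#' running median (window of up to 21 grid points) before locating the
#' maximum and the arrest time, so that isolated wiggles of the smoothing
#' splines do not produce a spurious early arrest. Within this frame the
#' regulator
#' half-lives can be taken as constant and promoter activities are well
#' above background.
#'
#' @param pr one element of the [process_plate()] output (a single
#'   condition).
#' @param regulators reporter names whose detection times bound the window
#'   start (default `c("fliA", "flgM")`); a reporter detected from the
#'   start (detection time `NA`) sets the window start to the grid start.
#' @param mu_frac growth-arrest threshold as a fraction of the maximum
#'   growth rate (default 0.1).
#' @return Numeric vector `c(start, end)` in minutes.
#' @export
analysis_window <- function(pr, regulators = c("fliA", "flgM"),
                            mu_frac = 0.1) {
  grid <- pr$grid
  det <- pr$detect_time[intersect(regulators, names(pr$detect_time))]
  det[is.na(det)] <- grid[1]
  start <- if (length(det)) max(det) else grid[1]
  mu <- pr$mu(grid)
  # growth arrest is a sustained state: despike the growth-rate estimate
  # with a running median so that isolated wiggles of the absorbance
  # splines neither set the maximum nor trigger a spurious early arrest
  k <- min(21L, length(mu))
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= 3L) mu <- stats::runmed(mu, k, endrule = "median")
  i_max <- which.max(mu)
  after <- which(seq_along(grid) > i_max & mu < mu_frac * max(mu))
  end <- if (length(after)) grid[after[1]] else grid[length(grid)]
  if (end <= start)
    stop("empty analysis window: growth arrest precedes regulator detection")
  c(start, end)
}

.window_profile <- function(prof, w) {
  keep <- prof$time >= w[1] & prof$time <= w[2]
  prof$time <- prof$time[keep]
  prof$f_mean <- prof$f_mean[keep]
  prof$epsilon <- prof$epsilon[keep]
  prof
}
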