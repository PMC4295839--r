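#' Sign pattern of regulatory interactions
#'
#' A named vector over candidate regulators with entries +1 (activator),
#' -1 (repressor) or 0 (no effect), encoding the hypothesis that the
#' target's activity is monotone nondecreasing in its activators and
#' nonincreasing in its repressors.
#'
#' @param ... named entries in `{-1, 0, +1}`, or a single named vector.
#' @return An object of class `"sign_pattern"`.
#' @examples
#' sign_pattern(fliA = +1, flgM = -1, global = +1)
#' @export
sign_pattern <- function(...) {
  s <- c(...)
  if (is.null(names(s)) || any(names(s) == ""))
    stop("sign pattern entries must be named after regulators")
  if (!all(s %in% c(-1, 0, 1)))
    stop("sign pattern entries must be -1, 0 or +1")
  structure(s, class = "sign_pattern")
}

#' @export
print.sign_pattern <- function(x, ...) {
  lab <- c("-", "0", "+")[unclass(x) + 2]
  cat("<sign_pattern>", paste(names(x), lab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Assemble time-series data for sign-pattern analysis
#'
#' @param ... condition lists, each with `name`, `x` (numeric matrix, rows
#'   = time points, named columns = regulators), `f` (target activity) and
#'   optionally `eps` (confidence half-width of `f`, used for the default
#'   noise tolerance) and `x_eps` (matrix of confidence half-widths of the
#'   regulator series, same shape as `x`).
#' @return An object of class `"regulation_data"`.
#' @export
regulation_data <- function(...) {
  conds <- list(...)
  if (length(conds) == 1 && is.null(conds[[1]]$f)) conds <- conds[[1]]
  regs <- colnames(conds[[1]]$x)
  conds <- lapply(conds, function(cc) {
    cc$x <- as.matrix(cc$x)
    if (!identical(colnames(cc$x), regs))
      stop("conditions disagree on the regulator set")
    if (nrow(cc$x) != length(cc$f))
      stop("regulator and target series lengths differ in condition ", cc$name)
    if (!is.null(cc$x_eps)) {
      cc$x_eps <- as.matrix(cc$x_eps)
      if (!identical(dim(cc$x_eps), dim(cc$x)))
        stop("x_eps must match the shape of x in condition ", cc$name)
    }
    cc
  })
  names(conds) <- vapply(conds, `[[`, "", "name")
  structure(conds, class = "regulation_data")
}

# convert a fit_dataset into regulation_data with regressors
# (fliA, flgM[, global])
#' @export
#' @rdname regulation_data
#' @param data a [fit_dataset] to convert (regulators `fliA`, `flgM` and,
#'   when present, `global` from the constitutive activity).
as_regulation_data <- function(data) {
  if (inherits(data, "regulation_data")) return(data)
  stopifnot(inherits(data, "fit_dataset"))
  regulation_data(lapply(data, function(cc) {
    x <- cbind(fliA = cc$x1, flgM = cc$x2)
    if (!is.null(cc$fconst)) x <- cbind(x, global = cc$fconst)
    list(name = cc$name, x = x, f = cc$fbar, eps = cc$eps)
  }))
}

# per-condition pair matrices: P[[j]][[sgn]][t1, t2] says the move of
# regulator j from t1 to t2 is compatible with sign sgn (it demonstrably
# cannot explain a decrease of the target); Fdec[t1, t2] says the target
# decreases beyond tolerance.  When the condition carries regulator bands
# x_eps, a move only counts as compatible once it exceeds the summed bands
# of the two time points: within the bands the regulator may have moved in
# the explaining direction.
.pair_tables <- function(cond, tol_x, tol_f) {
  L <- length(cond$f)
  if (is.null(tol_f)) {
    e <- if (!is.null(cond$eps)) ifelse(is.finite(cond$eps), cond$eps, 0)
         else rep(0, L)
    tolF <- outer(e, e, `+`)
  } else tolF <- matrix(tol_f, L, L)
  Fdec <- outer(cond$f, cond$f, function(f1, f2) f2 < f1) &
    (outer(cond$f, cond$f, function(f1, f2) f1 - f2) > tolF)
  P <- lapply(seq_len(ncol(cond$x)), function(j) {
    dx <- outer(cond$x[, j], cond$x[, j], function(a, b) b - a)
    B <- if (!is.null(cond$x_eps)) {
      xe <- ifelse(is.finite(cond$x_eps[, j]), cond$x_eps[, j], 0)
      outer(xe, xe, `+`)
    } else 0
    list(pos = dx >= B - tol_x, neg = -dx >= B - tol_x)
  })
  names(P) <- colnames(cond$x)
  list(P = P, Fdec = Fdec)
}

.violations <- function(pattern, tabs) {
  ok <- tabs$Fdec
  for (nm in names(pattern)) {
    s <- pattern[[nm]]
    if (s == 1) ok <- ok & tabs$P[[nm]]$pos
    else if (s == -1) ok <- ok & tabs$P[[nm]]$neg
  }
  which(ok, arr.ind = TRUE)
}

#' Test a sign pattern for consistency with time-series data
#'
#' A pattern is inconsistent if, within any single condition, two time
#' points exist at which every non-zero regulator moves compatibly with its
#' sign (activators non-decreasing, repressors non-increasing, within
#' `tol_x`) while the target activity decreases by more than the noise
#' tolerance. The default target tolerance at a pair `(t1, t2)` is
#' `eps(t1) + eps(t2)`, so measured noise bands cannot by themselves
#' invalidate a pattern. When the data carry regulator bands `x_eps`, a
#' regulator move additionally counts as compatible only once it exceeds
#' `x_eps(t1) + x_eps(t2)`: within its band the regulator may in truth
#' have moved in the direction that explains the target decrease, so the
#' pair proves nothing against the pattern. Time points are never compared
#' across conditions.
#'
#' @param pattern a [sign_pattern] over the data's regulators.
#' @param data a `"regulation_data"` (or a [fit_dataset], converted via
#'   [as_regulation_data()]).
#' @param tol_x tolerance on regulator moves (same units as `x`).
#' @param tol_f tolerance on target decreases; `NULL` (default) uses the
#'   per-pair band sum.
#' @return An object of class `"pattern_verdict"`: `pattern`, `consistent`,
#'   and `violating_pairs` (data frame of condition, t1 index, t2 index).
#' @export
is_consistent <- function(pattern, data, tol_x = 0, tol_f = NULL) {
  data <- as_regulation_data(data)
  regs <- colnames(data[[1]]$x)
  if (!all(names(pattern) %in% regs) || length(pattern) != length(regs))
    stop("pattern regulators do not match the data")
  pattern <- pattern[regs]
  viol <- list()
  for (cond in data) {
    tabs <- .pair_tables(cond, tol_x, tol_f)
    v <- .violations(pattern, tabs)
    if (nrow(v))
      viol[[length(viol) + 1]] <- data.frame(condition = cond$name,
                                             t1 = v[, 1], t2 = v[, 2])
  }
  viol <- if (length(viol)) do.call(rbind, viol)
          else data.frame(condition = character(), t1 = integer(),
                          t2 = integer())
  structure(list(pattern = pattern, consistent = nrow(viol) == 0,
                 violating_pairs = viol),
            class = "pattern_verdict")
}

#' @export
`[.regulation_data` <- function(x, i) {
  structure(unclass(x)[i], class = "regulation_data")
}

#' @export
print.pattern_verdict <- function(x, ...) {
  lab <- c("-", "0", "+")[unclass(x$pattern) + 2]
  cat(sprintf("<pattern_verdict> %s: %s (%d violating pair(s))\n",
              paste(names(x$pattern), lab, sep = ":", collapse = " "),
              if (x$consistent) "consistent" else "inconsistent",
              nrow(x$violating_pairs)))
  invisible(x)
}

#' Enumerate minimal consistent sign patterns
#'
#' Enumerates all `3^m` sign patterns over the candidate regulators,
#' retains the consistent ones, and marks as minimal those for which
#' zeroing any single non-zero entry yields an inconsistent pattern
#' (removing an interaction breaks consistency, while adding one never
#' does).
#'
#' @inheritParams is_consistent
#' @return A data frame with one row per consistent pattern: a column per
#'   regulator plus logical `minimal`; the full enumeration (with a
#'   `consistent` column) is attached as attribute `"all_patterns"`.
#' @export
minimal_sign_patterns <- function(data, tol_x = 0, tol_f = NULL) {
  data <- as_regulation_data(data)
  regs <- colnames(data[[1]]$x)
  m <- length(regs)
  if (m > 8) stop("enumeration supports at most 8 regulators")
  tabs <- lapply(data, .pair_tables, tol_x = tol_x, tol_f = tol_f)
  ok_fun <- function(s) {
    for (tb in tabs) if (nrow(.violations(stats::setNames(s, regs), tb)))
      return(FALSE)
    TRUE
  }
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), m)))
  colnames(grid) <- regs
  # row index of a pattern in the expand.grid enumeration (first column
  # varies fastest)
  row_of <- function(s) 1L + sum((s + 1) * 3^(seq_len(m) - 1))
  consistent <- apply(grid, 1, ok_fun)
  minimal <- logical(nrow(grid))
  for (i in which(consistent)) {
    s <- grid[i, ]
    min_i <- TRUE
    for (j in which(s != 0)) {
      s2 <- s; s2[j] <- 0
      if (consistent[row_of(s2)]) { min_i <- FALSE; break }
    }
    minimal[i] <- min_i
  }
  all_pat <- data.frame(grid, consistent = consistent, minimal = minimal)
  out <- all_pat[consistent, c(regs, "minimal")]
  rownames(out) <- NULL
  attr(out, "all_patterns") <- all_pat
  out
}

#' Classify an expected sign pattern against the data
#'
#' `"green"` if the expected pattern is among the minimal sign patterns,
#' `"yellow"` if it is consistent with the data but not minimal (some
#' interaction could be dropped), `"red"` if it is inconsistent.
#'
#' @inheritParams is_consistent
#' @param expected the expected [sign_pattern].
#' @return One of `"green"`, `"yellow"`, `"red"`.
#' @export
classify_expected <- function(data, expected, tol_x = 0, tol_f = NULL) {
  v <- is_consistent(expected, data, tol_x = tol_x, tol_f = tol_f)
  if (!v$consistent) return("red")
  # minimal iff zeroing each non-zero entry is inconsistent
  for (j in which(unclass(v$pattern) != 0)) {
    s2 <- unclass(v$pattern); s2[j] <- 0
    if (is_consistent(sign_pattern(s2), data, tol_x, tol_f)$consistent)
      return("yellow")
  }
  "green"
}

#' Diagnose fragility of an invalidation
#'
#' An inconsistent pattern dismissed on the strength of a single pair of
#' measurements is fragile; robust invalidations rest on many pairs.
#'
#' @param verdict an inconsistent `"pattern_verdict"`.
#' @return A list with `n_pairs` and logical `fragile` (`n_pairs == 1`).
#' @export
single_pair_robustness <- function(verdict) {
  stopifnot(inherits(verdict, "pattern_verdict"))
  if (verdict$consistent)
    stop("robustness diagnostic applies to inconsistent verdicts only")
  n <- nrow(verdict$violating_pairs)
  list(n_pairs = n, fragile = n == 1L)
}

#' Classify the expected pattern over a grid of regulator half-lives
#'
#' For every combination of candidate FliA and FlgM half-lives, protein
#' concentration profiles are reconstructed in each condition and the
#' expected pattern (over regulators fliA, flgM and, when a constitutive
#' profile is supplied, global) is classified green/yellow/red per
#' condition and, when `pooled = TRUE`, on all conditions analysed at once
#' (reported as `"Intersection"`; pairs are still compared only within a
#' condition, but one pattern must satisfy all conditions simultaneously,
#' which is more constraining).
#'
#' Uncertainty bands are propagated to the regressors: protein profiles
#' are additionally reconstructed from the regulator activities shifted up
#' and down by their confidence half-widths, and half the spread enters
#' the consistency test as `x_eps` (see [is_consistent()]); the
#' constitutive regressor uses its own activity band directly.
#'
#' @inheritParams fit_with_halflives
#' @param expected the expected [sign_pattern].
#' @param tol_x,tol_f tolerances, see [is_consistent()].
#' @param pooled also classify the pooled dataset.
#' @return A data frame with columns `condition`, `tau_A`, `tau_M`,
#'   `verdict`.
#' @export
halflife_pattern_map <- function(target, fliA, flgM, fconst = NULL, mu,
                                 halflives = halflife_grid(), expected,
                                 preculture = NULL, gamma_r = 6e-4,
                                 tol_x = 0, tol_f = NULL, pooled = TRUE) {
  shift <- function(profiles, sgn) lapply(profiles, function(p) {
    e <- ifelse(is.finite(p$epsilon), p$epsilon, 0)
    p$f_mean <- pmax(p$f_mean + sgn * e, 0)
    p
  })
  pc <- function(fA, fM) precompute_profiles(list(fliA = fA, flgM = fM), mu,
                                             halflives, gamma_r = gamma_r,
                                             preculture = preculture)
  profs <- pc(fliA, flgM)
  profs_hi <- pc(shift(fliA, 1), shift(flgM, 1))
  profs_lo <- pc(shift(fliA, -1), shift(flgM, -1))
  n <- length(halflives)
  rows <- list()
  for (iA in seq_len(n)) for (iM in seq_len(n)) {
    dat <- as_regulation_data(.build_halflife_data(target, fconst, profs,
                                                   iA, iM))
    hi <- as_regulation_data(.build_halflife_data(target, fconst, profs_hi,
                                                  iA, iM))
    lo <- as_regulation_data(.build_halflife_data(target, fconst, profs_lo,
                                                  iA, iM))
    for (cond in names(dat)) {
      xe <- abs(hi[[cond]]$x - lo[[cond]]$x) / 2
      if (!is.null(fconst)) {
        fc <- fconst[[cond]]
        e <- ifelse(is.finite(fc$epsilon), fc$epsilon, 0)
        xe[, "global"] <- .interp_to(e, fc$time, target[[cond]]$time)
      }
      dat[[cond]]$x_eps <- xe
    }
    for (cond in names(dat)) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, tau_A = halflives[iA], tau_M = halflives[iM],
        verdict = classify_expected(dat[cond], expected, tol_x, tol_f))
    }
    if (pooled)
      rows[[length(rows) + 1]] <- data.frame(
        condition = "Intersection", tau_A = halflives[iA],
        tau_M = halflives[iM],
        verdict = classify_expected(dat, expected, tol_x, tol_f))
  }
  do.call(rbind, rows)
}
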