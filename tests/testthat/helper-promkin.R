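# shared helpers for the promkin test suite

# a noise-free measurement model (backgrounds kept so correction is exercised)
zero_noise <- function() {
  noise_model(abs_sd = 0, fluo_rel = 0, fluo_floor = 0)
}

# small single-condition plate: logistic growth, pulse-shaped target promoter
tiny_plate <- function(n_replicates = 3, noise = zero_noise(),
                       times = seq(0, 400, by = 5), condition = "c1",
                       reporter = "tar", onset = 30, peak_delay = 90,
                       width = 0.5, height = 8, basal = 0.3) {
  growth <- growth_curve(0.05, 0.01, 1.2)
  f <- activity_pulse(onset, peak_delay, width, height, basal)
  wells <- simulate_reporter_fluorescence(f, growth, 6e-4, times, noise,
                                          n_replicates, condition, reporter)
  bg <- promkin:::.background_wells(times, growth, noise, condition)
  list(plate = rbind(wells, bg), f = f, growth = growth, times = times)
}

# a reduced multi-reporter scenario for the pipeline-level tests: two
# conditions, fewer replicates, shorter series than the default scenario
small_scenario <- function(seed = 11, n_replicates = 4) {
  sc <- default_scenario(seed = seed, n_replicates = n_replicates)
  sc$conditions <- sc$conditions[c("rpoS-M9", "csgD-M9")]
  sc
}

# cache expensive processed fixtures across test files (helpers are sourced
# once per test run, so this is computed at most once)
.fixture_env <- new.env(parent = emptyenv())
small_processed <- function() {
  if (is.null(.fixture_env$proc)) {
    sim <- simulate_scenario(small_scenario())
    .fixture_env$sim <- sim
    .fixture_env$proc <- process_plate(read_plate_table(sim$plate))
  }
  list(sim = .fixture_env$sim, proc = .fixture_env$proc)
}

# full five-condition scenario at realistic noise, processed once and
# shared by the acceptance-level tests
full_processed <- function(seed = 2) {
  key <- paste0("full", seed)
  if (is.null(.fixture_env[[key]])) {
    sim <- simulate_scenario(default_scenario(seed = seed))
    proc <- process_plate(read_plate_table(sim$plate))
    .fixture_env[[key]] <- list(
      sim = sim, proc = proc,
      parts = promkin:::.profiles_for_halflife_fit(proc))
  }
  .fixture_env[[key]]
}

# independent brute-force oracle for sign-pattern consistency, written
# directly from the definition: a pattern is inconsistent iff some
# within-condition ordered pair (t1, t2) has the target falling beyond the
# noise tolerance while every non-zero regulator moves compatibly with its
# sign (activators non-decreasing, repressors non-increasing, within tol_x)
oracle_consistent <- function(pattern, data, tol_x = 0) {
  for (cond in data) {
    L <- length(cond$f)
    eps <- if (!is.null(cond$eps)) cond$eps else rep(0, L)
    for (t1 in seq_len(L)) for (t2 in seq_len(L)) {
      if (!(cond$f[t2] < cond$f[t1] - (eps[t1] + eps[t2]))) next
      compatible <- TRUE
      for (j in seq_along(pattern)) {
        s <- pattern[[j]]
        dx <- cond$x[t2, j] - cond$x[t1, j]
        if (s == 1 && !(dx >= -tol_x)) compatible <- FALSE
        if (s == -1 && !(-dx >= -tol_x)) compatible <- FALSE
      }
      if (compatible) return(FALSE)
    }
  }
  TRUE
}

# random regulation_data instance for property tests
random_instance <- function(m, L, n_cond = 1) {
  regs <- paste0("r", seq_len(m))
  conds <- lapply(seq_len(n_cond), function(k) {
    x <- matrix(round(apply(matrix(stats::rnorm(L * m), L, m), 2, cumsum), 1),
                L, m, dimnames = list(NULL, regs))
    f <- round(cumsum(stats::rnorm(L)), 1)
    eps <- if (stats::runif(1) < 0.5) rep(0, L)
           else round(stats::runif(L, 0, 0.6), 2)
    list(name = paste0("c", k), x = x, f = f, eps = eps)
  })
  do.call(regulation_data, conds)
}
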