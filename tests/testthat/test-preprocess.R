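# plate reading, background correction, smoothing and activity estimation

make_df <- function() {
  data.frame(condition = "c1", well = rep(c("w1", "m1", "b1"), each = 3),
             reporter = c(rep("tar", 3), rep(NA, 6)),
             replicate = 1,
             role = rep(c("reporter", "background_medium",
                          "background_strain"), each = 3),
             time_min = rep(c(0, 10, 20), 3),
             absorbance = runif(9, 0.1, 0.5), fluorescence = runif(9, 10, 50))
}

test_that("read_plate_table enforces the schema", {
  df <- make_df()
  plate <- read_plate_table(df)
  expect_s3_class(plate, "plate_data")
  expect_length(plate, 3)
  expect_s3_class(plate[[1]], "plate_series")
  expect_error(read_plate_table(df[, -3]), "missing column")
  bad <- df; bad$role[1] <- "blankety"
  expect_error(read_plate_table(bad), "invalid role")
  dup <- rbind(df, df[1, ])
  expect_error(read_plate_table(dup), "duplicated")
})

test_that("read_plate_table sorts readings by time per well", {
  df <- make_df()[c(3, 1, 2, 4:9), ]
  plate <- read_plate_table(df)
  w <- plate[["c1:w1"]]
  expect_equal(w$time, c(0, 10, 20))
})

test_that("background correction recovers the noise-free signals", {
  tp <- tiny_plate()
  plate <- read_plate_table(tp$plate)
  corr <- correct_background(plate)
  # only reporter wells survive
  expect_true(all(vapply(corr, `[[`, "", "role") == "reporter"))
  w <- corr[[1]]
  A_true <- tp$growth$A(w$time)
  r_true <- promkin:::.integrate_fluorescence(tp$f, tp$growth$A, 6e-4,
                                              tp$times,
                                              tp$f(0) / (6e-4 + tp$growth$mu(0)))
  expect_equal(w$absorbance, A_true, tolerance = 1e-8)
  expect_equal(w$fluorescence, r_true, tolerance = 1e-6)
  expect_error(correct_background(read_plate_table(make_df()[1:3, ])),
               "no background wells")
})

test_that("below-detection flag marks the pre-induction phase", {
  tp <- tiny_plate(noise = noise_model(abs_sd = 0.003, fluo_rel = 0.02,
                                       fluo_floor = 1),
                   onset = 150, height = 30, basal = 0)
  corr <- correct_background(read_plate_table(tp$plate))
  w <- Filter(function(x) x$role == "reporter", corr)[[1]]
  expect_true(mean(w$below_detection[w$time < 100]) > 0.5)
  expect_true(all(!w$below_detection[w$time > 280 & w$time < 350]))
})

test_that("smooth_signals validates inputs and interpolates at smoothing 1", {
  tp <- tiny_plate()
  w <- correct_background(read_plate_table(tp$plate))[[1]]
  expect_error(smooth_signals(w, smoothing = 0), "smoothing")
  expect_error(smooth_signals(w, smoothing = 1.2), "smoothing")
  short <- w; short$time <- w$time[1:5]
  short$absorbance <- w$absorbance[1:5]; short$fluorescence <- w$fluorescence[1:5]
  expect_error(smooth_signals(short), "at least 8")
  expect_error(smooth_signals(w, weights = list(absorbance = c(1, 2))),
               "weights")
  expect_error(smooth_signals(w, weights = list(fluorescence =
                                                  rep(-1, length(w$time)))),
               "weights")
  s <- smooth_signals(w, smoothing = 1)
  expect_s3_class(s, "smoothed_signal")
  expect_equal(s$A(w$time), w$absorbance, tolerance = 1e-10)
  expect_equal(s$I(w$time), w$fluorescence, tolerance = 1e-10)
})

test_that("growth rate, concentration and activity follow their definitions", {
  # exponential growth with constant reporter concentration: A = A0*e^(mu t),
  # I = r*A, so mu(t) = mu, r(t) = r and f = r*(mu + gamma_r) exactly
  t <- seq(0, 300, by = 4)
  mu0 <- 0.008; r0 <- 40
  w <- structure(list(condition = "c", well = "w", reporter = "g",
                      replicate = 1, role = "reporter", time = t,
                      absorbance = 0.05 * exp(mu0 * t),
                      fluorescence = r0 * 0.05 * exp(mu0 * t)),
                 class = "plate_series")
  s <- smooth_signals(w, smoothing = 1)
  tt <- seq(20, 280, by = 7)
  expect_equal(growth_rate(s)(tt), rep(mu0, length(tt)), tolerance = 1e-3)
  expect_equal(reporter_concentration(s)(tt), rep(r0, length(tt)),
               tolerance = 1e-6)
  gamma_r <- 6e-4
  expect_equal(promoter_activity(s, gamma_r)(tt),
               rep(r0 * (mu0 + gamma_r), length(tt)), tolerance = 1e-2)
  expect_error(promoter_activity(s, -1), "non-negative")
  expect_error(growth_rate(s)(1e4), "outside the fitted window")
})

test_that("evaluation grid trims spline boundaries and needs overlap", {
  mk <- function(w0, w1, dt) structure(list(window = c(w0, w1),
                                            time = seq(w0, w1, by = dt)),
                                       class = "smoothed_signal")
  g <- evaluation_grid(list(mk(0, 100, 5), mk(10, 120, 5)))
  expect_equal(min(g), 10 + 3 * 5)
  expect_equal(max(g), 100 - 3 * 5)
  expect_equal(diff(g)[1], 1)
  expect_error(evaluation_grid(list(mk(0, 20, 5), mk(90, 120, 5))),
               "do not overlap")
})

test_that("replicate aggregation gives the mean and a 2-SEM band", {
  fs <- cbind(c(8, 1), c(10, 1), c(12, 1), c(10, 1))
  prof <- aggregate_replicates(fs, grid = c(0, 1), condition = "c1")
  expect_s3_class(prof, "activity_profile")
  expect_equal(prof$f_mean, c(10, 1))
  expect_equal(prof$epsilon[1], 2 * sd(c(8, 10, 12, 10)) / sqrt(4))
  expect_equal(prof$epsilon[2], 0)
  expect_true(prof$epsilon_defined)
  # single replicate: no band
  p1 <- aggregate_replicates(matrix(1:3, 3, 1), grid = 1:3)
  expect_false(p1$epsilon_defined)
  expect_true(all(is.na(p1$epsilon)))
  # list-of-functions input
  p2 <- aggregate_replicates(list(function(t) t, function(t) 3 * t), 0:2)
  expect_equal(p2$f_mean, c(0, 2, 4))
  expect_error(aggregate_replicates(fs, grid = 1:3), "lengths differ")
})

test_that("analysis window runs from last regulator detection to growth arrest", {
  grid <- 0:400
  mu <- function(t) ifelse(t < 250, 0.01, 0.01 * exp(-(t - 250) / 15))
  pr <- list(grid = grid, mu = mu,
             detect_time = c(fliA = 60, flgM = 110, tar = 150))
  w <- analysis_window(pr)
  expect_equal(w[1], 110)           # max over regulator detect times only
  expect_lt(w[2], 320)              # growth arrest at mu < 0.1 * max
  expect_gt(w[2], 250)
  # NA detection = detected from the start
  pr$detect_time <- c(fliA = NA, flgM = NA)
  expect_equal(analysis_window(pr)[1], 0)
  pr$detect_time <- c(fliA = 390)
  expect_error(analysis_window(pr), "empty analysis window")
})

test_that("process_plate recovers a known activity on clean data", {
  tp <- tiny_plate()
  proc <- process_plate(read_plate_table(tp$plate))
  expect_named(proc, "c1")
  prof <- proc$c1$activities$tar
  keep <- prof$time > 60 & prof$time < 330
  f_true <- tp$f(prof$time[keep])
  rel <- abs(prof$f_mean[keep] - f_true) / max(f_true)
  expect_lt(max(rel), 0.05)
  expect_s3_class(proc$c1$r$tar, "activity_profile")
  expect_true(is.function(proc$c1$mu))
})
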