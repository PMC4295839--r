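# objective, search box and multistart fitting

make_cond <- function(name = "c1", L = 40, seed = 5, with_global = TRUE) {
  set.seed(seed)
  t <- seq(0, 200, length.out = L)
  x1 <- 60 * exp(-((t - 80) / 60)^2)
  x2 <- 90 * exp(-((t - 120) / 50)^2)
  fconst <- 1.5 - 0.004 * t
  cc <- list(name = name, time = t, x1 = x1, x2 = x2)
  if (with_global) cc$fconst <- fconst
  cc
}

truth_dataset <- function(params, eps_frac = 0.04, with_global = TRUE,
                          n_cond = 2) {
  conds <- lapply(seq_len(n_cond), function(k) {
    cc <- make_cond(paste0("c", k), seed = 4 + k, with_global = with_global)
    free <- free_fliA(cc$x1, cc$x2, params[["K"]])
    f <- if (with_global) global_activity(cc$fconst, free, params)
         else hill_activity(free, params)
    cc$fbar <- f
    cc$eps <- rep(eps_frac * max(f), length(f))
    cc
  })
  fit_dataset(conds)
}

test_that("fit_dataset validates grids and floors negative regressors", {
  cc <- make_cond()
  cc$fbar <- rep(1, length(cc$time)); cc$eps <- rep(0.1, length(cc$time))
  cc$x1[3] <- -5
  cc$eps[c(2, 9)] <- 0
  dat <- fit_dataset(cc)
  expect_s3_class(dat, "fit_dataset")
  expect_equal(dat$c1$x1[3], 0)
  expect_false(any(dat$c1$use[c(2, 9)]))
  expect_true(all(dat$c1$use[-c(2, 9)]))
  bad <- cc; bad$fbar <- bad$fbar[-1]
  expect_error(fit_dataset(bad), "evaluation grid")
  expect_error(fit_dataset(), "empty dataset")
})

test_that("objective_Q equals the hand-computed weighted deviation", {
  p <- regulation_params(0.3, 5, 2, 20, 40)
  cc <- list(name = "c1", time = 1:4, fbar = c(1, 2, 3, 4),
             eps = c(0.5, 0.5, 1, 1), x1 = c(0, 10, 50, 80),
             x2 = c(5, 5, 20, 10), fconst = c(1, 1.2, 0.9, 1))
  dat <- fit_dataset(cc)
  pred <- global_activity(cc$fconst, free_fliA(cc$x1, cc$x2, 40), p)
  by_hand <- sum(abs(cc$fbar - pred) / (2 * cc$eps))
  expect_equal(objective_Q(p, dat, "hill_global"), by_hand, tolerance = 1e-12)
  expect_equal(objective_Q(p, dat, "hill_global", loss = "squared"),
               sum(((cc$fbar - pred) / (2 * cc$eps))^2), tolerance = 1e-12)
  pred_h <- hill_activity(free_fliA(cc$x1, cc$x2, 40), p)
  expect_equal(objective_Q(p, dat, "hill"),
               sum(abs(cc$fbar - pred_h) / (2 * cc$eps)), tolerance = 1e-12)
  # excluded points do not contribute
  cc$eps[2] <- 0
  dat2 <- fit_dataset(cc)
  expect_equal(objective_Q(p, dat2, "hill_global"),
               by_hand - abs(cc$fbar[2] - pred[2]) / (2 * 0.5),
               tolerance = 1e-12)
})

test_that("the objective vanishes at the generating parameters", {
  p <- regulation_params(0.2, 6, 2, 30, 10)
  dat <- truth_dataset(p)
  expect_equal(objective_Q(p, dat, "hill_global"), 0, tolerance = 1e-9)
})

test_that("search box follows the data ranges", {
  dat <- truth_dataset(regulation_params(0.2, 6, 2, 30, 10))
  box <- search_box(dat)
  max_f <- max(vapply(dat, function(cc) max(cc$fbar), 0))
  expect_equal(box$lower,
               c(k0 = 0, k1 = 0, n = 1, theta = 0, K = 0))
  expect_equal(box$upper[["k0"]], max_f)
  expect_equal(box$upper[["k1"]], 10 * max_f)
  expect_equal(box$upper[["n"]], 4)
  expect_equal(box$upper[["theta"]],
               max(vapply(dat, function(cc) max(cc$x1), 0)))
  expect_equal(box$upper[["K"]],
               20 * max(vapply(dat, function(cc) max(cc$x2), 0)))
  box2 <- search_box(dat, theta_min_obs = TRUE)
  expect_equal(box2$lower[["theta"]],
               min(vapply(dat, function(cc) min(cc$x1), 0)))
})

test_that("multistart fit recovers generating parameters on clean data", {
  p_true <- regulation_params(0.2, 6, 2, 30, 10)
  dat <- truth_dataset(p_true)
  fit <- fit_regulation(dat, "hill_global", n_starts = 8, seed = 3)
  expect_s3_class(fit, "regfit")
  expect_length(fit$start_Q, 8)
  expect_lte(fit$Q, min(fit$start_Q))
  expect_lt(abs(fit$params[["k1"]] - 6) / 6, 0.1)
  expect_lt(abs(fit$params[["theta"]] - 30) / 30, 0.1)
  expect_lt(abs(fit$params[["n"]] - 2), 0.5)
  # on clean data Q(p_true) is exactly zero, so allow an absolute floor
  # for the optimizer's numerical convergence tolerance
  expect_lte(fit$Q, 1.05 * objective_Q(p_true, dat, "hill_global") + 1e-8)
})

test_that("fitting is reproducible given the seed", {
  dat <- truth_dataset(regulation_params(0.2, 6, 2, 30, 10))
  f1 <- fit_regulation(dat, "hill_global", n_starts = 4, seed = 9)
  f2 <- fit_regulation(dat, "hill_global", n_starts = 4, seed = 9)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$Q, f2$Q)
})

test_that("fixed parameters are clamped exactly", {
  dat <- truth_dataset(regulation_params(0.2, 6, 2, 30, 10))
  fit <- fit_regulation(dat, "hill_global", n_starts = 3, seed = 1,
                        fixed = c(K = 10, n = 2))
  expect_identical(fit$params[["K"]], 10)
  expect_identical(fit$params[["n"]], 2)
})

test_that("the global model demands a constitutive trajectory", {
  dat <- truth_dataset(regulation_params(0.2, 6, 2, 30, 10),
                       with_global = FALSE)
  expect_error(fit_regulation(dat, "hill_global"), "fconst")
  fit <- fit_regulation(dat, "hill", n_starts = 4, seed = 2)
  expect_lt(abs(fit$params[["theta"]] - 30) / 30, 0.15)
})

test_that("regfit methods are coherent", {
  p_true <- regulation_params(0.2, 6, 2, 30, 10)
  dat <- truth_dataset(p_true)
  fit <- fit_regulation(dat, "hill_global", n_starts = 4, seed = 1)
  expect_named(coef(fit), c("k0", "k1", "n", "theta", "K"))
  sm <- summary(fit)
  expect_equal(sm$condition, names(dat))
  expect_true(all(sm$rmse >= 0))
  pr <- predict(fit)
  expect_equal(pr, fit$fitted)
  res <- residuals(fit)
  expect_equal(res$c1, dat$c1$fbar - fit$fitted$c1)
  expect_output(print(fit), "Regulation function fit")
  # predict on new data evaluates the fitted model there
  nd <- truth_dataset(p_true, n_cond = 1)
  expect_equal(predict(fit, nd)$c1,
               promkin:::.eval_model(unclass(fit$params), nd$c1,
                                     "hill_global"))
})

test_that("simulate resamples the target within the band, reproducibly", {
  dat <- truth_dataset(regulation_params(0.2, 6, 2, 30, 10))
  fit <- fit_regulation(dat, "hill_global", n_starts = 2, seed = 1)
  s1 <- simulate(fit, nsim = 2, seed = 7)
  s2 <- simulate(fit, nsim = 2, seed = 7)
  expect_equal(s1, s2)
  expect_s3_class(s1[[1]], "fit_dataset")
  expect_false(identical(s1[[1]]$c1$fbar, dat$c1$fbar))
  expect_identical(s1[[1]]$c1$eps, dat$c1$eps)
  # perturbations are zero-mean and scale with eps/2
  d <- s1[[1]]$c1$fbar - dat$c1$fbar
  expect_lt(max(abs(d)), 6 * max(dat$c1$eps) / 2)
})

test_that("bootstrap intervals bracket a clean-data estimate", {
  p_true <- regulation_params(0.2, 6, 2, 30, 10)
  dat <- truth_dataset(p_true, eps_frac = 0.03, n_cond = 1)
  fit <- fit_regulation(dat, "hill_global", n_starts = 3, seed = 2,
                        fixed = c(n = 2, K = 10))
  cis <- bootstrap_cis(fit, B = 10, seed = 4, n_starts = 2)
  expect_named(cis, c("parameter", "estimate", "lower", "upper"))
  expect_equal(nrow(cis), 5)
  draws <- attr(cis, "draws")
  expect_equal(dim(draws), c(10, 5))
  free <- c("k0", "k1", "theta")
  expect_true(all(cis$lower[cis$parameter %in% free] <=
                    cis$upper[cis$parameter %in% free]))
})

test_that("the flgM variant clamps K and refuses WT-LB", {
  p_true <- regulation_params(0.2, 6, 2, 30, 10)
  dat <- truth_dataset(p_true)
  fit <- fit_flgM_variant(dat, K_fixed = 14615, n_starts = 2, seed = 1)
  expect_identical(fit$params[["K"]], 14615)
  bad <- dat
  names(bad)[1] <- "WT-LB"
  bad[[1]]$name <- "WT-LB"
  expect_error(fit_flgM_variant(bad, 10), "WT-LB")
  expect_error(fit_flgM_variant(dat, -1), "non-negative")
})
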