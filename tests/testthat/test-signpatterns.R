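# qualitative sign-pattern analysis

test_that("sign_pattern validates entries", {
  p <- sign_pattern(fliA = 1, flgM = -1, global = 0)
  expect_s3_class(p, "sign_pattern")
  expect_error(sign_pattern(1, -1), "named")
  expect_error(sign_pattern(a = 2), "-1, 0 or \\+1")
})

test_that("regulation_data validates shapes", {
  x <- cbind(a = 1:3, b = 3:1)
  expect_error(regulation_data(list(name = "c", x = x, f = 1:2)),
               "lengths differ")
  expect_error(regulation_data(list(name = "c", x = x, f = 1:3,
                                    x_eps = x[1:2, ])),
               "x_eps")
  d <- regulation_data(list(name = "c", x = x, f = c(1, 2, 3)))
  expect_s3_class(d, "regulation_data")
})

test_that("a monotone activator is detected and dropping it breaks consistency", {
  # f rises with x1; x2 stays flat
  d <- regulation_data(list(
    name = "c1",
    x = cbind(x1 = c(1, 2, 3, 4, 5), x2 = rep(2, 5)),
    f = c(0.5, 1, 2, 3.5, 5), eps = rep(0, 5)))
  expect_true(is_consistent(sign_pattern(x1 = 1, x2 = 0), d)$consistent)
  v <- is_consistent(sign_pattern(x1 = 0, x2 = 0), d)
  expect_false(v$consistent)
  expect_gt(nrow(v$violating_pairs), 0)
  # violating pairs are ordered so the target falls from t1 to t2
  with(v$violating_pairs, expect_true(all(d$c1$f[t2] < d$c1$f[t1])))
  mins <- minimal_sign_patterns(d)
  expect_equal(nrow(mins), 3)           # x1:+1 with x2 in {-1, 0, +1}
  expect_true(all(mins$x1 == 1))
  expect_equal(sum(mins$minimal), 1)
  expect_equal(mins[mins$minimal, "x2"], 0)
  expect_equal(classify_expected(d, sign_pattern(x1 = 1, x2 = 0)), "green")
  expect_equal(classify_expected(d, sign_pattern(x1 = 1, x2 = -1)), "yellow")
  expect_equal(classify_expected(d, sign_pattern(x1 = 0, x2 = 0)), "red")
})

test_that("noise bands on the target rescue small decreases", {
  d0 <- regulation_data(list(name = "c", x = cbind(a = c(1, 2)),
                             f = c(1, 0.9), eps = c(0, 0)))
  expect_false(is_consistent(sign_pattern(a = 1), d0)$consistent)
  d1 <- regulation_data(list(name = "c", x = cbind(a = c(1, 2)),
                             f = c(1, 0.9), eps = c(0.06, 0.06)))
  expect_true(is_consistent(sign_pattern(a = 1), d1)$consistent)
  # explicit tol_f overrides the band sum
  expect_false(is_consistent(sign_pattern(a = 1), d1, tol_f = 0.05)$consistent)
  expect_true(is_consistent(sign_pattern(a = 1), d0, tol_f = 0.2)$consistent)
})

test_that("regulator bands discard pairs whose move stays within x_eps", {
  # the target falls while the activator nominally rises, but the rise is
  # smaller than the uncertainty band, so the pair proves nothing
  base <- list(name = "c", x = cbind(a = c(1, 1.1)), f = c(1, 0.5),
               eps = c(0, 0))
  expect_false(is_consistent(sign_pattern(a = 1),
                             regulation_data(base))$consistent)
  banded <- base
  banded$x_eps <- cbind(a = c(0.1, 0.1))
  expect_true(is_consistent(sign_pattern(a = 1),
                            regulation_data(banded))$consistent)
  # a move clearly beyond the band still invalidates
  big <- banded
  big$x <- cbind(a = c(1, 2))
  expect_false(is_consistent(sign_pattern(a = 1),
                             regulation_data(big))$consistent)
})

test_that("time points are never compared across conditions", {
  # each condition is monotone; jointly the levels contradict, which must
  # not matter
  d <- regulation_data(
    list(name = "c1", x = cbind(a = c(1, 2)), f = c(10, 11), eps = c(0, 0)),
    list(name = "c2", x = cbind(a = c(5, 6)), f = c(1, 2), eps = c(0, 0)))
  expect_true(is_consistent(sign_pattern(a = 1), d)$consistent)
  # but within-condition violations in any one condition invalidate
  d2 <- regulation_data(
    list(name = "c1", x = cbind(a = c(1, 2)), f = c(10, 11), eps = c(0, 0)),
    list(name = "c2", x = cbind(a = c(5, 6)), f = c(2, 1), eps = c(0, 0)))
  v <- is_consistent(sign_pattern(a = 1), d2)
  expect_false(v$consistent)
  expect_equal(unique(v$violating_pairs$condition), "c2")
})

test_that("enumeration agrees with the brute-force oracle on random data", {
  set.seed(101)
  for (rep in 1:200) {
    m <- sample(1:3, 1)
    L <- sample(4:12, 1)
    d <- random_instance(m, L, n_cond = sample(1:2, 1))
    tol_x <- sample(c(0, 0.05), 1)
    mins <- minimal_sign_patterns(d, tol_x = tol_x)
    all_pat <- attr(mins, "all_patterns")
    regs <- colnames(d[[1]]$x)
    for (i in seq_len(nrow(all_pat))) {
      s <- stats::setNames(unlist(all_pat[i, regs]), regs)
      expect_identical(all_pat$consistent[i], oracle_consistent(s, d, tol_x),
                       label = sprintf("rep %d pattern %s", rep,
                                       paste(s, collapse = ",")))
    }
    # minimality: zeroing any non-zero entry of a minimal pattern breaks it
    for (i in which(all_pat$minimal)) {
      s <- stats::setNames(unlist(all_pat[i, regs]), regs)
      for (j in which(s != 0)) {
        s2 <- s; s2[j] <- 0
        expect_false(oracle_consistent(s2, d, tol_x))
      }
    }
  }
})

test_that("adding an interaction to a consistent pattern never hurts", {
  # monotonicity of the constraint set: a zero entry imposes nothing
  set.seed(55)
  for (rep in 1:30) {
    d <- random_instance(2, 8)
    all_pat <- attr(minimal_sign_patterns(d), "all_patterns")
    regs <- colnames(d[[1]]$x)
    for (i in which(all_pat$consistent)) {
      s <- stats::setNames(unlist(all_pat[i, regs]), regs)
      for (j in which(s == 0)) for (v in c(-1, 1)) {
        s2 <- s; s2[j] <- v
        k <- 1L + sum((s2 + 1) * 3^(seq_along(s2) - 1))
        expect_true(all_pat$consistent[k])
      }
    }
  }
})

test_that("single-pair invalidations are flagged fragile", {
  d <- regulation_data(list(name = "c", x = cbind(a = c(1, 2, 3)),
                            f = c(1, 0.5, 2), eps = rep(0, 3)))
  v <- is_consistent(sign_pattern(a = 1), d)
  expect_false(v$consistent)
  r <- single_pair_robustness(v)
  expect_equal(r$n_pairs, 1)
  expect_true(r$fragile)
  ok <- is_consistent(sign_pattern(a = 0), d)
  expect_false(ok$consistent)
  expect_false(single_pair_robustness(ok)$fragile)
  cons <- is_consistent(sign_pattern(a = 1),
                        regulation_data(list(name = "c",
                                             x = cbind(a = c(1, 2)),
                                             f = c(1, 2), eps = c(0, 0))))
  expect_error(single_pair_robustness(cons), "inconsistent verdicts only")
})

test_that("fit datasets convert to regulation data with a global regressor", {
  cc <- list(name = "c1", time = 1:3, fbar = c(1, 2, 3), eps = rep(0.1, 3),
             x1 = c(1, 2, 3), x2 = c(3, 2, 1), fconst = c(1, 1, 1))
  rd <- as_regulation_data(fit_dataset(cc))
  expect_s3_class(rd, "regulation_data")
  expect_equal(colnames(rd$c1$x), c("fliA", "flgM", "global"))
  expect_equal(rd$c1$f, c(1, 2, 3))
  no_g <- as_regulation_data(fit_dataset(cc[setdiff(names(cc), "fconst")]))
  expect_equal(colnames(no_g$c1$x), c("fliA", "flgM"))
})

test_that("the half-life pattern map classifies every grid cell", {
  prof <- function(cond, f) structure(
    list(condition = cond, time = seq(0, 100, by = 5), f_mean = f,
         epsilon = rep(0.05 * max(f), 21), n_replicates = 3L,
         epsilon_defined = TRUE),
    class = "activity_profile")
  t <- seq(0, 100, by = 5)
  fA <- 5 * exp(-((t - 40) / 30)^2)
  fM <- 8 * exp(-((t - 60) / 25)^2)
  tar <- 2 + 3 * exp(-((t - 75) / 20)^2)
  target <- list(c1 = prof("c1", tar))
  fliA <- list(c1 = prof("c1", fA))
  flgM <- list(c1 = prof("c1", fM))
  fconst <- list(c1 = prof("c1", rep(1.2, 21)))
  mp <- halflife_pattern_map(target, fliA, flgM, fconst, mu = list(c1 = 0.002),
                             halflives = c(15, 60),
                             expected = sign_pattern(fliA = 1, flgM = -1,
                                                     global = 1))
  expect_equal(nrow(mp), 2 * 2 * 2)  # grid cells x (condition + pooled)
  expect_setequal(unique(mp$condition), c("c1", "Intersection"))
  expect_true(all(mp$verdict %in% c("green", "yellow", "red")))
  expect_setequal(unique(mp$tau_A), c(15, 60))
})
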