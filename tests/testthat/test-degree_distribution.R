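test_that("weighted degrees are row sums in subject-major order", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 1; m[1, 3] <- 2; m[2, 3] <- 3
  m <- m + t(m)
  st <- subject_stack(list(m, m * 0))
  dg <- weighted_degrees(st)
  expect_equal(nrow(dg), 6L)               # S x N values, zeros retained
  expect_equal(dg$degree[1:3], c(3, 4, 5))
  expect_equal(dg$degree[4:6], c(0, 0, 0))
  expect_equal(dg$subject[1:3], rep(st$subject_ids[1], 3))
})

test_that("normal MLE is exact on tiny samples and recovers simulated parameters", {
  f <- fit_full(c(0, 2), "normal")
  expect_equal(unname(f$params["mean"]), 1)
  expect_equal(unname(f$params["sd"]), 1)  # population MLE
  expect_equal(f$n_used, 2L)

  set.seed(31)
  x <- rnorm(5000, 50, 10)
  f2 <- fit_full(x, "normal")
  expect_lt(abs(f2$params["mean"] - 50), 0.5)
  expect_lt(abs(f2$params["sd"] - 10), 0.5)
  expect_lt(f2$ks_distance, 0.03)
})

test_that("gamma fit excludes zeros and recovers simulated parameters", {
  set.seed(32)
  x <- c(rgamma(4000, shape = 5, scale = 2), rep(0, 100))
  f <- fit_full(x, "gamma")
  expect_equal(f$n_used, 4000L)
  expect_lt(abs(f$params["shape"] - 5) / 5, 0.1)
  expect_lt(abs(f$params["scale"] - 2) / 2, 0.1)
  expect_error(fit_full(rep(0, 10), "gamma"), "positive")
})

test_that("sample mode finds the dominant histogram bin", {
  expect_equal(sample_mode(rep(3.5, 20)), 3.5)

  set.seed(33)
  x <- rgamma(20000, shape = 9, scale = 1)   # analytic mode (shape-1)*scale = 8
  h <- 2 * IQR(x) / length(x)^(1 / 3)
  expect_lt(abs(sample_mode(x) - 8), h)

  # heavier left peak wins on bimodal data
  y <- c(rnorm(600, 2, 0.05), rnorm(400, 8, 0.05))
  expect_lt(sample_mode(y), 3)
})

test_that("exponential tail fit is the mean-excess MLE", {
  b <- 2
  f <- fit_exponential_tail(c(b + 1, b + 3, rep(b + 2, 8)), b)
  expect_equal(unname(f$params["rate"]), 1 / 2)

  set.seed(34)
  x <- rexp(5000, rate = 0.2)
  f2 <- fit_exponential_tail(x, 0)
  expect_lt(abs(f2$params["rate"] - 0.2) / 0.2, 0.05)

  expect_error(fit_exponential_tail(1:20, 100), "insufficient")
})

test_that("pareto fit: closed-form alpha, forced and scanned x_min agree with brute force", {
  f <- fit_powerlaw(c(1, exp(1)), x_min = 1)
  expect_equal(unname(f$params["alpha"]), 3)   # 1 + 2 / sum(log) = 3

  set.seed(35)
  x <- 1 * (1 - runif(5000))^(-1 / 1.5)        # Pareto alpha = 2.5, x_min = 1
  f2 <- fit_powerlaw(x)
  expect_lt(abs(f2$params["alpha"] - 2.5), 0.1)
  expect_lte(f2$params["x_min"], 1.2)

  # exhaustive brute-force x_min oracle on a smaller sample
  set.seed(36)
  y <- c(runif(300, 0, 2), 2 * (1 - runif(300))^(-1 / 1.2))
  brute <- function(vals) {
    vals <- sort(vals[vals > 0])
    best <- NULL
    for (b in unique(vals)) {
      tail <- vals[vals >= b]
      if (length(tail) < 10) next
      sl <- sum(log(tail / b)); if (sl <= 0) next
      a <- 1 + length(tail) / sl
      d <- ks_distance(tail, function(q) 1 - (b / q)^(a - 1))
      if (is.null(best) || d < best$d) best <- list(b = b, a = a, d = d)
    }
    best
  }
  bf <- brute(y)
  fy <- fit_powerlaw(y)
  expect_equal(unname(fy$params["x_min"]), bf$b)
  expect_equal(unname(fy$params["alpha"]), bf$a, tolerance = 1e-12)
  expect_equal(fy$ks_distance, bf$d, tolerance = 1e-12)

  expect_error(fit_powerlaw(rep(c(1, 2), 50)), "distinct")
})

test_that("compare_fits ranks families by KS and reports support restrictions", {
  set.seed(37)
  x <- abs(rnorm(1260, 50, 10))
  tab <- compare_fits(x)
  expect_setequal(tab$family, c("normal", "gamma", "exponential", "powerlaw"))
  expect_equal(tab$n_used[tab$family == "normal"], 1260L)
  expect_true(all(diff(tab$ks_distance[!is.na(tab$ks_distance)]) >= 0))
  expect_equal(tab$support[tab$family %in% c("normal", "gamma")], c("full", "full"))
  expect_true(all(tab$n_used[tab$support == "tail"] < 1260L, na.rm = TRUE))
})

test_that("model-selection harness ranks the generating family first", {
  set.seed(38)
  wins_normal <- 0L
  wins_pareto <- 0L
  n_runs <- 20L
  for (r in seq_len(n_runs)) {
    xn <- rnorm(1260, 50, 15)               # CV 0.3 regime
    tn <- compare_fits(pmax(xn, 0))
    if (tn$family[1] == "normal") wins_normal <- wins_normal + 1L
    xp <- 1 * (1 - runif(1260))^(-1 / 1.5)  # Pareto alpha 2.5
    tp <- compare_fits(xp)
    if (tp$family[1] == "powerlaw") wins_pareto <- wins_pareto + 1L
  }
  expect_gte(wins_normal / n_runs, 0.9)
  expect_gte(wins_pareto / n_runs, 0.9)
})

test_that("KS distance is invariant under common rescaling for scale families", {
  set.seed(40)
  x <- rgamma(800, shape = 3, scale = 2)
  for (fit_fun in list(function(v) fit_full(v, "normal"),
                       function(v) fit_exponential_tail(v, 0))) {
    expect_equal(fit_fun(x)$ks_distance, fit_fun(x * 7.3)$ks_distance,
                 tolerance = 1e-9)
  }
  expect_equal(fit_powerlaw(x)$ks_distance, fit_powerlaw(x * 7.3)$ks_distance,
               tolerance = 1e-9)
  # gamma MLE is numeric, so equivariance holds only to optimizer precision
  expect_equal(fit_full(x, "gamma")$ks_distance,
               fit_full(x * 7.3, "gamma")$ks_distance, tolerance = 1e-2)
})

test_that("quantile report pairs empirical and fitted-normal quantiles", {
  set.seed(39)
  x <- rnorm(4000, 20, 4)
  f <- fit_full(x, "normal")
  qr <- quantile_report(x, f)
  expect_equal(nrow(qr), 99L)
  expect_equal(qr$fitted[qr$percentile == 50], unname(f$params["mean"]))
  expect_equal(qr$empirical[qr$percentile == 50], unname(median(x)), tolerance = 1e-9)
  expect_true(all(diff(qr$empirical) >= 0))
  expect_true(all(diff(qr$fitted) >= 0))
  expect_lt(max(abs(qr$empirical - qr$fitted)), 1)  # sample from the fitted family
})
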