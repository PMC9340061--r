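test_that("standardize_env z-scores columns and is idempotent", {
  env <- tibble::tibble(site = c("a", "b", "c"), x = c(2, 4, 6))
  out <- standardize_env(env)
  expect_equal(out$x, c(-1, 0, 1))
  out2 <- standardize_env(out)
  expect_lt(max(abs(out2$x - out$x)), 1e-12)

  env9 <- generate_env(sim_config(n_sites = 50), seed = 2)
  std <- standardize_env(env9)
  vals <- as.matrix(std[-1])
  expect_lt(max(abs(colMeans(vals))), 1e-12)
  expect_lt(max(abs(apply(vals, 2, sd) - 1)), 1e-12)

  expect_error(standardize_env(tibble::tibble(x = rep(1, 5))), "constant.*x",
               class = "phylassem_validation_error")
})

test_that("vif_filter keeps orthogonal predictors and resolves exact collinearity", {
  n <- 40
  # columns orthogonal to each other *and* to the intercept, so each VIF is 1
  q <- withr::with_seed(3, qr.Q(qr(cbind(1, matrix(rnorm(n * 4), n, 4))))[, -1])
  env <- tibble::as_tibble(as.data.frame(q))
  names(env) <- paste0("v", 1:4)
  out <- vif_filter(env, threshold = 3)
  expect_setequal(setdiff(names(out), "site"), names(env))
  expect_lt(max(abs(attr(out, "vif") - 1)), 1e-8)

  env$v5 <- env$v1 + env$v2  # exact collinearity
  out2 <- vif_filter(env, threshold = 3)
  expect_equal(nrow(vif_removal_log(out2)), 1)
  expect_identical(vif_removal_log(out2)$variable, "v5")  # later column drops first
  expect_true(all(attr(out2, "vif") <= 3))

  single <- tibble::tibble(x = rnorm(10))
  out3 <- vif_filter(single)
  expect_identical(names(out3), "x")
})

test_that("univariate fits recover exact and noisy linear relations", {
  n <- 60
  dat <- withr::with_seed(5, tibble::tibble(x1 = rnorm(n), x2 = rnorm(n)))
  dat$y <- 2 * dat$x1
  uf <- suppressWarnings(univariate_fits(dat, "y", c("x1", "x2")))
  expect_equal(uf$slope[uf$variable == "x1"], 2, tolerance = 1e-10)
  expect_equal(uf$r_squared[uf$variable == "x1"], 1, tolerance = 1e-10)

  dat2 <- withr::with_seed(6, {
    x <- rnorm(183)
    tibble::tibble(x1 = x, y = x + rnorm(183))
  })
  uf2 <- univariate_fits(dat2, "y", "x1")
  expect_gt(uf2$slope, 0)
  expect_gt(uf2$r_squared, 0.3)
  expect_lt(uf2$r_squared, 0.7)

  flat <- tibble::tibble(y = rep(1, 20), x1 = rnorm(20))
  uf3 <- univariate_fits(flat, "y", "x1")
  expect_equal(uf3$r_squared, 0)
  expect_equal(uf3$p_value, 1)
})

test_that("univariate slope test holds its type-I rate", {
  rej <- vapply(1:500, function(i) {
    dat <- withr::with_seed(7000 + i, tibble::tibble(y = rnorm(60), x = rnorm(60)))
    univariate_fits(dat, "y", "x")$p_value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("forward selection recovers the true predictor among noise", {
  dat <- withr::with_seed(11, {
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(120 * 9), 120, 9)))
    names(d) <- paste0("x", 1:9)
    d$y <- d$x1
    d
  })
  fit <- suppressWarnings(forward_select(dat, "y"))
  expect_identical(fit$selected, "x1")
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(all(suppressWarnings(tidy(fit))$p_value < 0.05))

  empty <- forward_select(tibble::tibble(y = rnorm(30)), "y", predictors = character(0))
  expect_length(empty$selected, 0)
  expect_equal(empty$r_squared, 0)
})

test_that("forward selection holds its false-entry rate under a pure-noise response", {
  hits <- vapply(1:500, function(i) {
    dat <- withr::with_seed(9000 + i, tibble::tibble(y = rnorm(50), x = rnorm(50)))
    length(forward_select(dat, "y", "x")$selected) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.09)
})

test_that("selected models never contain terms above the entry threshold", {
  for (i in 1:10) {
    dat <- withr::with_seed(300 + i, {
      d <- tibble::as_tibble(as.data.frame(matrix(rnorm(80 * 5), 80, 5)))
      names(d) <- paste0("x", 1:5)
      d$y <- 0.6 * d$x1 + 0.4 * d$x2 + rnorm(80)
      d
    })
    fit <- forward_select(dat, "y")
    if (length(fit$selected)) expect_true(all(tidy(fit)$p_value < 0.05))
  }
})

test_that("hierarchical partitioning: trivial, orthogonal and no-noise cases", {
  dat <- withr::with_seed(21, tibble::tibble(x1 = rnorm(50)))
  dat$y <- 0.5 * dat$x1 + withr::with_seed(22, rnorm(50))
  hp1 <- hierarchical_partition(dat, "y", "x1")
  expect_equal(hp1$independent_effect, hp1$univariate_r2, tolerance = 1e-12)
  expect_equal(hp1$joint_effect, 0, tolerance = 1e-12)

  n <- 64
  q <- withr::with_seed(23, qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, -1])
  dat2 <- tibble::tibble(x1 = q[, 1], x2 = q[, 2])
  dat2$y <- dat2$x1 + dat2$x2
  hp2 <- hierarchical_partition(dat2, "y", c("x1", "x2"))
  expect_equal(hp2$independent_effect, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(hp2$joint_effect, c(0, 0), tolerance = 1e-8)
  expect_equal(attr(hp2, "r_squared_full"), 1, tolerance = 1e-10)
})

test_that("hierarchical partitioning matches the ordering-average oracle", {
  for (case in 1:5) {
    dat <- withr::with_seed(500 + case, {
      z <- matrix(rnorm(40 * 4), 40, 4)
      z[, 2] <- z[, 1] * 0.7 + z[, 2] * 0.3   # correlated design
      d <- tibble::as_tibble(as.data.frame(z))
      names(d) <- paste0("x", 1:4)
      d$y <- z[, 1] + 0.5 * z[, 3] + rnorm(40)
      d
    })
    hp <- suppressWarnings(hierarchical_partition(dat, "y", paste0("x", 1:4)))
    oracle <- hp_oracle(dat, "y", paste0("x", 1:4))
    expect_equal(hp$independent_effect, oracle, tolerance = 1e-8)
    expect_equal(sum(hp$independent_effect), attr(hp, "r_squared_full"),
                 tolerance = 1e-8)
  }
  expect_error(hierarchical_partition(tibble::tibble(y = 1), "y", paste0("x", 1:13)),
               "12", class = "phylassem_validation_error")
})

test_that("driver_analysis links SES to its generating environmental variable", {
  cfg <- sim_config(n_sites = 183)
  env <- generate_env(cfg, seed = 41)
  # response built on SM with r^2 ~ 0.3
  sm <- (env$SM - mean(env$SM)) / sd(env$SM)
  dat <- env
  dat$ses <- withr::with_seed(42, sqrt(0.3) * sm + sqrt(0.7) * rnorm(183))
  dr <- suppressMessages(driver_analysis(dat, "ses"))
  expect_true("SM" %in% dr$fit$selected)
  top <- dr$partition$variable[which.max(dr$partition$independent_effect)]
  expect_identical(top, "SM")
  expect_equal(sum(dr$partition$independent_effect), dr$r_squared, tolerance = 1e-8)
  g <- glance(dr)
  expect_identical(g$response, "ses")
  td <- tidy(dr)
  expect_true(all(c("variable", "selected", "independent_effect") %in% names(td)))
})
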