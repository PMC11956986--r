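test_that("lab effects are paired differences with the textbook standard error", {
  e <- lab_effect(c(2, 3, 4), c(1, 1, 1))
  expect_equal(e$y, 2)
  expect_equal(e$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(e$n, 3)
  same <- lab_effect(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$y, 0)
  expect_error(lab_effect(1, 1), "2 paired")
  # median mode with its quantile-based SE
  d <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  em <- lab_effect(d, rep(0, 5), statistic = "median")
  expect_equal(em$y, 0.4)
  iqr <- unname(diff(quantile(d, c(.25, .75))))
  expect_equal(em$se, 1.2533 * (iqr / 1.349) / sqrt(5), tolerance = 1e-12)
})

test_that("lab summary fixture reproduces the printed cross-lab effect ranges", {
  t1 <- read_table1_fixture()
  expect_equal(nrow(t1), 14 * 3 * 4)
  bc <- summary_table_differences(t1, "binary_control")
  expect_equal(attr(bc, "range"), c(-0.012, 0.093), tolerance = 1e-9)
  ba <- summary_table_differences(t1, "binary_active")
  expect_equal(max(attr(ba, "range")), 0.120, tolerance = 1e-9)
  ta <- summary_table_differences(t1, "ternary_active")
  expect_equal(attr(ta, "range"), c(-0.033, 0.089), tolerance = 1e-9)
  # Lab 11's binary_control difference, computable by hand from the fixture
  expect_equal(bc$diff[bc$lab == 11], 0.093, tolerance = 1e-9)
})

test_that("random-effects pooling matches long-hand DerSimonian-Laird formulas", {
  y <- c(0.02, 0.05, -0.01, 0.08, 0.03)
  se <- c(0.02, 0.03, 0.025, 0.04, 0.015)
  m <- re_meta(data.frame(y = y, se = se), method = "DL")
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- max(0, (Q - 4) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  expect_equal(m$Q, Q, tolerance = 1e-10)
  expect_equal(m$tau2, tau2, tolerance = 1e-10)
  expect_equal(m$estimate, sum(ws * y) / sum(ws), tolerance = 1e-10)
  expect_equal(m$I2, max(0, (Q - 4) / Q) * 100, tolerance = 1e-10)
  expect_equal(m$H2, Q / 4, tolerance = 1e-10)
  expect_equal(m$ci_low, m$estimate - qnorm(.975) * sqrt(1 / sum(ws)),
               tolerance = 1e-10)
})

test_that("REML and DL pooling agree with metafor on random problems", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:5) {
    k <- sample(5:15, 1)
    y <- rnorm(k, 0.05, 0.05)
    se <- runif(k, 0.01, 0.06)
    eff <- data.frame(y = y, se = se)
    for (meth in c("REML", "DL")) {
      mine <- re_meta(eff, method = meth)
      ref <- metafor::rma(yi = y, sei = se, method = meth,
                          control = list(threshold = 1e-10))
      expect_equal(mine$estimate, unname(ref$beta[1]), tolerance = 1e-5)
      expect_equal(mine$tau2, ref$tau2, tolerance = 1e-5)
      expect_equal(mine$se, ref$se, tolerance = 1e-5)
      expect_equal(mine$Q, ref$QE, tolerance = 1e-8)
    }
  }
})

test_that("degenerate poolings behave: one study, equal studies, zero heterogeneity", {
  one <- re_meta(data.frame(y = 0.04, se = 0.02))
  expect_equal(one$estimate, 0.04)
  expect_equal(one$ci_low, 0.04 - qnorm(.975) * 0.02, tolerance = 1e-10)
  two <- re_meta(data.frame(y = c(0.02, 0.06), se = c(0.03, 0.03)))
  expect_equal(two$estimate, 0.04, tolerance = 1e-10)
  idn <- re_meta(data.frame(y = rep(0.03, 6), se = rep(0.02, 6)))
  expect_equal(idn$tau2, 0)
  expect_equal(idn$I2, 0)
  expect_error(re_meta(data.frame(y = c(1, 2), se = c(0.1, 0))), "positive")
  # pooled estimate within the range of inputs; tau2=0 equals fixed effect
  set.seed(8)
  y <- rnorm(8, 0, 0.05); se <- runif(8, 0.01, 0.05)
  m <- re_meta(data.frame(y = y, se = se))
  expect_gte(m$estimate, min(y)); expect_lte(m$estimate, max(y))
})

test_that("moderator meta-regression matches metafor and recovers perfect moderators", {
  skip_if_not_installed("metafor")
  set.seed(9)
  k <- 12
  x <- runif(k, 0, 10)
  y <- 0.01 + 0.005 * x + rnorm(k, 0, 0.01)
  se <- runif(k, 0.008, 0.03)
  eff <- data.frame(y = y, se = se, mod = x)
  mine <- meta_regression(eff, "mod")
  ref <- metafor::rma(yi = y, sei = se, mods = ~x, method = "REML",
                      control = list(threshold = 1e-10))
  expect_equal(mine$moderator_coefs$estimate, unname(as.vector(ref$beta)),
               tolerance = 1e-4)
  expect_equal(mine$tau2, ref$tau2, tolerance = 1e-4)
  # perfect moderator: slope = c, residual heterogeneity collapses
  y2 <- 0.004 * x
  eff2 <- data.frame(y = y2, se = se, mod = x)
  m2 <- meta_regression(eff2, "mod")
  expect_equal(m2$moderator_coefs$estimate[2], 0.004, tolerance = 1e-6)
  expect_lt(m2$tau2, 1e-8)
  expect_error(meta_regression(data.frame(y = y, se = se, mod = rep(1, k)),
                               "mod"), "singular|constant")
  # three-diamond prediction rows at mean -1 SD, mean, mean +1 SD
  expect_equal(nrow(mine$predicted), 3)
  expect_equal(mine$predicted[, "x"], c(mean(x) - sd(x), mean(x),
                                        mean(x) + sd(x)), ignore_attr = TRUE)
})

test_that("null moderators show no systematic slope across replicates", {
  set.seed(10)
  slopes <- replicate(300, {
    k <- 13
    x <- runif(k, 0, 10)
    y <- rnorm(k, 0.03, 0.02)
    se <- rep(0.02, k)
    meta_regression(data.frame(y = y, se = se, mod = x),
                    "mod")$moderator_coefs$estimate[2]
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("median pooling converges to mean pooling for symmetric data and handles degenerates", {
  set.seed(11)
  effm <- do.call(rbind, lapply(1:10, function(i) {
    d <- rnorm(4000, 0.03, 0.05)
    cbind(lab_effect(d, rep(0, 4000), statistic = "median",
                     lab_id = paste(i)),
          mean_y = mean(d))
  }))
  mm <- median_meta(effm)
  rm_ <- re_meta(data.frame(y = effm$mean_y, se = 0.05 / sqrt(4000)))
  expect_lt(abs(mm$estimate - rm_$estimate), 0.005)
  single <- median_meta(lab_effect(c(1, 2, 5), c(0, 0, 0),
                                   statistic = "median", lab_id = "a"))
  expect_equal(single$estimate, 2)
  idn <- median_meta(data.frame(y = rep(0.03, 5), se = rep(0.01, 5)))
  expect_equal(idn$tau2, 0); expect_equal(idn$I2, 0)
})

test_that("forest export carries one row per lab plus the pooled diamond", {
  set.seed(12)
  eff <- do.call(rbind, lapply(1:13, function(i)
    lab_effect(rnorm(10, 0.05, 0.05), rnorm(10, 0, 0.05),
               lab_id = sprintf("lab_%02d", i))))
  m <- re_meta(eff)
  fx <- forest_export(m, eff)
  expect_equal(nrow(fx), 14)
  labs <- fx[fx$row == "lab", ]
  expect_equal(sum(labs$weight), 1, tolerance = 1e-12)
  expect_equal(labs$ci_low, labs$y - qnorm(.975) * eff$se, tolerance = 1e-12)
  expect_equal(fx$y[14], m$estimate)
})
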