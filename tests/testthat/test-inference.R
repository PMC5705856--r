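test_that("Cohen's h matches published effect sizes and closed forms", {
  expect_equal(round(cohen_h(385, 2620, 212, 2380), 2), 0.18)
  expect_equal(cohen_h(5, 10, 5, 10), 0)
  # arcsin(sqrt(0.75)) = pi/3, arcsin(sqrt(0.25)) = pi/6
  expect_equal(cohen_h(75, 100, 25, 100), pi / 3, tolerance = 1e-12)
})

test_that("Cohen's h is symmetric in groups and monotone in the proportion gap", {
  tables <- list(c(3, 9, 5, 11), c(0, 7, 7, 7), c(40, 60, 10, 55))
  for (tb in tables) {
    expect_equal(
      cohen_h(tb[1], tb[2], tb[3], tb[4]),
      cohen_h(tb[3], tb[4], tb[1], tb[2])
    )
  }
  hs <- vapply(seq(55, 95, 10), function(x) cohen_h(x, 100, 50, 100), numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("pooled-variance Z reproduces published statistics", {
  expect_equal(round(pooled_z_test(235, 443, 332, 1269)$z, 2), 10.35)
  expect_equal(round(pooled_z_test(443, 5750, 1269, 8810)$z, 2), -12.27)
  expect_equal(round(pooled_z_test(71, 107, 68, 110)$z, 3), 0.696)
  expect_equal(pooled_z_test(6, 12, 12, 24)$z, 0)
  expect_error(pooled_z_test(0, 10, 0, 12), class = "carealert_data_error")
  expect_error(pooled_z_test(10, 10, 12, 12), class = "carealert_data_error")
})

test_that("unpooled Wald interval reproduces published bounds and degenerate cases", {
  expect_equal(round(wald_unpooled_ci(235, 443, 332, 1269), 3), c(0.216, 0.321))
  expect_equal(round(wald_unpooled_ci(443, 5750, 1269, 8810), 3), c(-0.077, -0.057))
  expect_equal(wald_unpooled_ci(0, 10, 0, 15), c(0, 0))
  ci <- wald_unpooled_ci(1, 2, 9, 10)
  expect_gte(ci[1], -1)
  expect_lte(ci[2], 1)
})

test_that("the restricted MLE behind the score statistic maximises the null likelihood", {
  loglik <- function(p2, x1, n1, x2, n2, d) {
    p1 <- p2 + d
    stats::dbinom(x1, n1, p1, log = TRUE) + stats::dbinom(x2, n2, p2, log = TRUE)
  }
  cases <- list(c(5, 10, 2, 10), c(235, 443, 332, 1269), c(0, 8, 3, 12), c(7, 7, 1, 9))
  for (cc in cases) {
    for (d in c(-0.4, -0.05, 0, 0.2, 0.55)) {
      cf <- carealert:::mn_restricted_mle(cc[1], cc[2], cc[3], cc[4], d)
      num <- stats::optimize(
        loglik,
        c(max(0, -d), min(1, 1 - d)),
        x1 = cc[1], n1 = cc[2], x2 = cc[3], n2 = cc[4], d = d,
        maximum = TRUE, tol = 1e-12
      )$maximum
      expect_equal(cf$p2, num, tolerance = 1e-6)
    }
  }
})

test_that("MN score interval is contained, symmetric, and Wald-consistent", {
  ci0 <- mn_score_ci(0, 10, 0, 10)
  expect_gt(ci0[1], -1)
  expect_lt(ci0[2], 1)
  expect_lte(ci0[1], 0)
  expect_gte(ci0[2], 0)

  # large-sample agreement with the unpooled Wald interval
  mn <- mn_score_ci(235, 443, 332, 1269)
  wd <- wald_unpooled_ci(235, 443, 332, 1269)
  expect_lt(max(abs(mn - wd)), 0.003)

  # swapping groups reflects the interval about zero
  a <- mn_score_ci(5, 10, 2, 10)
  b <- mn_score_ci(2, 10, 5, 10)
  expect_equal(a, -rev(b), tolerance = 1e-6)

  # convergence to Wald as n grows at fixed proportions
  gaps <- vapply(c(1e2, 1e3, 1e4, 1e5), function(n) {
    x1 <- round(0.45 * n)
    x2 <- round(0.30 * n)
    max(abs(mn_score_ci(x1, n, x2, n) - wald_unpooled_ci(x1, n, x2, n)))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("MN score interval matches the grid-inversion oracle on a small table", {
  ci <- mn_score_ci(5, 10, 2, 10)
  oracle <- oracle_mn_grid_ci(5, 10, 2, 10)
  expect_lt(max(abs(ci - oracle)), 1e-4)
})

test_that("Chan-Zhang interval behaves exactly at extremes and contains the score interval", {
  cz <- chan_zhang_ci(10, 10, 0, 10)
  expect_equal(cz[2], 1)
  expect_gt(cz[1], 0)

  cz2 <- chan_zhang_ci(5, 10, 2, 10)
  mn2 <- mn_score_ci(5, 10, 2, 10)
  expect_lte(cz2[1], mn2[1]) # exact methods are no shorter at small n
  expect_gte(cz2[2], mn2[2])

  expect_error(chan_zhang_ci(50, 300, 40, 300), class = "carealert_config_error")
})

test_that("two-group McNemar has the documented direction and reductions", {
  tab <- matrix(c(5, 3, 4, 8), 2, 2, byrow = TRUE,
    dimnames = list(
      pretest = c("threshold", "non_threshold"),
      checkin = c("threshold", "non_threshold")
    )
  )
  same <- mcnemar_two_group(tab, tab)
  expect_equal(same$z, 0)

  # ALERT group sheds thresholds one way only: strong positive z
  shed <- matrix(c(0, 15, 0, 5), 2, 2, byrow = TRUE)
  balanced <- matrix(c(5, 5, 5, 5), 2, 2, byrow = TRUE)
  res <- mcnemar_two_group(balanced, shed)
  expect_gt(res$z, 3)
  expect_lt(res$p_value, 0.001)

  # one empty group reduces to the one-sample net-change z
  empty <- matrix(0, 2, 2)
  one <- mcnemar_two_group(empty, shed)
  b <- 15; cc <- 0; N <- 20
  d <- (b - cc) / N
  v <- (b + cc - (b - cc)^2 / N) / N^2
  expect_equal(one$z, d / sqrt(v))

  expect_error(
    mcnemar_two_group(matrix(c(5, 0, 0, 5), 2, 2), matrix(c(2, 0, 0, 9), 2, 2)),
    class = "carealert_data_error"
  )
})

test_that("comparison bundles are internally consistent and sign-symmetric", {
  cmp <- compare_proportions(103, 385, 113, 212, methods = c("wald", "mn"))
  expect_equal(round(cmp$h, 2), 0.55)
  expect_true(all(cmp$ci$low <= cmp$ci$high))

  flip <- compare_proportions(113, 212, 103, 385, methods = c("wald", "mn"))
  expect_equal(flip$diff, -cmp$diff)
  expect_equal(flip$z, -cmp$z)
  expect_equal(flip$h, cmp$h)
  expect_equal(flip$ci$low, -cmp$ci$high, tolerance = 1e-6)
  expect_equal(flip$ci$high, -cmp$ci$low, tolerance = 1e-6)

  sym <- compare_proportions(4, 12, 4, 12, methods = "wald")
  expect_equal(sym$diff, 0)
  expect_equal(sym$z, 0)
  expect_equal(sym$h, 0)
})
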