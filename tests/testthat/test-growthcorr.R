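growth_fixture <- function() {
  rows <- expand.grid(genotype = c("WT", "mutA"), replicate = 1:3,
                      time_h = c(0, 24, 48), stringsAsFactors = FALSE)
  od0 <- 0.1
  rows$od600 <- ifelse(rows$time_h == 0, od0,
                       od0 * ifelse(rows$genotype == "WT", 8, 2) *
                         (rows$time_h / 24) * (1 + 0.01 * rows$replicate))
  rows
}

test_that("fold changes divide by each replicate's inoculation OD", {
  tab <- data.frame(genotype = "g", replicate = 1, time_h = c(0, 24),
                    od600 = c(0.1, 0.8))
  fc <- fold_change(tab)
  expect_equal(fc$fold_change, 8)

  flat <- data.frame(genotype = "g", replicate = 1, time_h = c(0, 24),
                     od600 = c(0.1, 0.1))
  expect_equal(fold_change(flat)$fold_change, 1)

  # replicates {8, 9, 10}: mean 9, sd 1 by the hand formula
  tri <- do.call(rbind, lapply(1:3, function(r)
    data.frame(genotype = "g", replicate = r, time_h = c(0, 24),
               od600 = c(0.1, 0.1 * (7 + r)))))
  fc3 <- fold_change(tri, time = 24)
  expect_equal(fc3$fold_change, 9)
  expect_equal(fc3$sd, 1)
  expect_identical(fc3$n, 3L)

  bad <- data.frame(genotype = "g", replicate = 2, time_h = 24, od600 = 0.5)
  expect_error(fold_change(bad), "replicate 2")
})

test_that("t-test against WT matches the closed-form oracle", {
  same <- c(1, 1.1, 0.9)
  res0 <- ttest_vs_wt(same, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  expect_false(res0$significant)

  a <- c(1.0, 1.1, 0.9); b <- c(5.0, 5.1, 4.9)
  res <- ttest_vs_wt(a, b)
  # independent closed form: pooled-variance t with n1+n2-2 df
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_ref <- 2 * pt(-abs(t_ref), df = length(a) + length(b) - 2)
  expect_equal(res$t, t_ref, tolerance = 1e-8)
  expect_equal(res$p, p_ref, tolerance = 1e-8)
  expect_true(res$significant)

  expect_error(ttest_vs_wt(1, c(1, 2)), ">= 2 replicates")

  # swapping groups leaves p unchanged
  sw <- ttest_vs_wt(b, a)
  expect_equal(sw$p, res$p)
  # Welch variant uses non-integer df
  w <- ttest_vs_wt(a, c(4, 5.5, 5.6, 4.1), welch = TRUE)
  expect_false(isTRUE(all.equal(w$df, round(w$df))))
})

test_that("Pearson correlation matches its closed form and rejects degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, 2 + 3 * x), 1)

  x3 <- c(1, 2, 3); y3 <- c(1, 2, 2)
  r_ref <- sum((x3 - mean(x3)) * (y3 - mean(y3))) /
    sqrt(sum((x3 - mean(x3))^2) * sum((y3 - mean(y3))^2))
  expect_equal(pearson_r(x3, y3), r_ref, tolerance = 1e-12)

  expect_error(pearson_r(x3, c(1, 1, 1)), "variance")
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

test_that("quadrant classification anchors on the WT point", {
  feats <- data.frame(genotype = c("WT", "up", "down"),
                      activity_meas_pA = c(-1, -2, -2))
  growth <- data.frame(genotype = c("WT", "up", "down"),
                       time_h = 48, fold_change = c(4, 8, 2), sd = NA, n = 3)
  cls <- classify_vs_wt(feats, growth, wt = "WT")
  expect_identical(cls$call[cls$genotype == "up"], "concordant")
  expect_identical(cls$call[cls$genotype == "down"], "discordant")
  counts <- attr(cls, "counts")
  expect_identical(unname(counts[c("concordant", "discordant")]), c(1L, 1L))

  # exact tie with WT is excluded with a warning
  feats$activity_meas_pA[3] <- -1
  expect_warning(cls2 <- classify_vs_wt(feats, growth, wt = "WT"), "tie")
  expect_identical(cls2$call[cls2$genotype == "down"], "tie-excluded")

  expect_error(classify_vs_wt(feats, growth, wt = "nope"), "missing")
})

test_that("classification is invariant under monotone feature transforms", {
  set.seed(77)
  feats <- data.frame(genotype = c("WT", letters[1:6]),
                      activity_meas_pA = -c(1, 0.2, 0.5, 1.5, 2, 3, 0.8))
  growth <- data.frame(genotype = feats$genotype, time_h = 48,
                       fold_change = c(4, 2, 3, 6, 5, 9, 3.5), sd = NA, n = 3)
  base <- classify_vs_wt(feats, growth, wt = "WT")
  mono <- feats
  mono$activity_meas_pA <- -(abs(feats$activity_meas_pA)^1.7 + 2)
  trans <- classify_vs_wt(mono, growth, wt = "WT")
  expect_identical(base$call, trans$call)
})

test_that("a fully informative synthetic panel classifies concordantly", {
  pan <- make_panel(preset_panel(), growth = growth_model(noise_sd = 0),
                    seed = 5, render_traces = FALSE)
  feats <- data.frame(genotype = names(pan$activities),
                      activity_meas_pA = unname(pan$activities))
  fc <- fold_change(pan$growth, time = 48)
  cls <- classify_vs_wt(feats, fc, wt = "WT")
  non_tie <- cls$call[cls$call != "tie-excluded"]
  expect_true(all(non_tie == "concordant"))
})

test_that("multilinear growth model matches the normal-equations oracle", {
  set.seed(9)
  i <- rnorm(10); po <- runif(10)
  y_exact <- 2 + 0.5 * i - po
  fit_exact <- multilinear_r2(y_exact, i, po)
  expect_equal(fit_exact$r_squared, 1, tolerance = 1e-12)

  y_const <- rep(3, 10)
  expect_equal(multilinear_r2(y_const, i, po)$r_squared, 0)

  y <- 1 + 0.3 * i - 2 * po + 0.8 * i * po + rnorm(10, 0, 0.1)
  fit <- multilinear_r2(y, i, po)
  X <- cbind(1, i, po, i * po)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2_ref <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_equal(fit$r_squared, r2_ref, tolerance = 1e-8)

  expect_error(multilinear_r2(y[1:4], i[1:4], po[1:4]), ">= 5")
  expect_error(multilinear_r2(y, i, i), "collinear")
})

test_that("the full model's R^2 dominates nested submodels", {
  set.seed(12)
  i <- rnorm(12); po <- runif(12)
  y <- 1 + 0.5 * i - po + rnorm(12, 0, 0.5)
  full <- multilinear_r2(y, i, po)$r_squared
  r2_of <- function(X) {
    fit <- lm(y ~ X)
    1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  }
  expect_gte(full + 1e-12, r2_of(cbind(i)))
  expect_gte(full + 1e-12, r2_of(cbind(po)))
  expect_gte(full + 1e-12, r2_of(cbind(i, po)))
})
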