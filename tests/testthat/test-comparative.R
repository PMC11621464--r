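test_that("tip values reduce to species means in degenerate designs", {
  # one recording per colony: no shrinkage is possible
  met <- make_metrics(colony = list(a = c(2, 4), b = c(6, 10)),
                      individual = list(a = c(1, 3), b = c(5, 7)))
  tips <- species_tip_values(met)
  expect_equal(tips$colony_rhythmicity, c(3, 8), tolerance = 1e-6)
  expect_equal(tips$individual_rhythmicity, c(2, 6), tolerance = 1e-6)
  # single species, single colony, n recordings -> plain mean
  met1 <- make_metrics(colony = list(a = matrix(c(1, 2, 6), ncol = 1)),
                       individual = list(a = 4))
  expect_equal(species_tip_values(met1)$colony_rhythmicity, 3,
               tolerance = 1e-6)
})

test_that("mixed-model tip values agree with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  set.seed(42)
  df <- data.frame(
    species = rep(c("a", "b", "c"), times = c(7, 5, 6)),
    colony_id = c(1, 1, 1, 2, 2, 3, 3, 1, 1, 2, 2, 2, 1, 2, 2, 3, 3, 3),
    individual_id = NA, level = "colony")
  grp <- factor(paste(df$species, df$colony_id))
  df$beta <- 2 + as.numeric(factor(df$species)) +
    rnorm(nlevels(grp), 0, 0.8)[as.integer(grp)] + rnorm(nrow(df), 0, 0.5)
  df$dominant_period_min <- 40
  # colony-level data only: the individual-side tips are flagged missing
  expect_warning(tips <- species_tip_values(df), "missing tip values")
  ref <- lme4::fixef(lme4::lmer(beta ~ 0 + species + (1 | species:colony_id),
                                df, REML = TRUE))
  expect_equal(unname(tips$colony_rhythmicity), unname(ref),
               tolerance = 1e-4)
})

test_that("trait standardization divides by the cross-species mean", {
  tab <- data.frame(species = c("a", "b", "c"),
                    colony_rhythmicity = c(2, 4, 6),
                    individual_rhythmicity = c(5, 5, 5))
  std <- standardize_traits(tab)
  expect_equal(std$colony_rhythmicity, c(0.5, 1, 1.5))
  expect_equal(std$individual_rhythmicity, rep(1, 3))
  expect_equal(standardize_traits(std), std)  # idempotent
  tab$colony_rhythmicity <- c(-1, 0, 1)
  expect_error(standardize_traits(tab), "zero")
})

test_that("BM fit matches the two-tip closed form and scaling laws", {
  star <- star_tree(2, bl = 0.8)
  x <- c(t1 = 1.3, t2 = -0.9)
  f <- fit_bm(star, x)
  expect_equal(f$sigma2, (1.3 - (-0.9))^2 / (4 * 0.8), tolerance = 1e-12)
  expect_equal(f$root_state, mean(x), tolerance = 1e-12)
  # all tips equal -> zero rate
  tr <- simulate_chronogram(8, seed = 3)
  expect_equal(fit_bm(tr, setNames(rep(2, 8), tr$tip.label))$sigma2, 0)
  # branch scaling: sigma2(c * tree) = sigma2 / c, exactly
  y <- simulate_bm_traits(tr, 1.7, seed = 5)
  f1 <- fit_bm(tr, y)
  tr3 <- tr
  tr3$edge.length <- 3 * tr$edge.length
  expect_equal(fit_bm(tr3, y)$sigma2, f1$sigma2 / 3, tolerance = 1e-12)
  # location/scale equivariance
  f2 <- fit_bm(tr, 2.5 * y + 7)
  expect_equal(f2$sigma2, 2.5^2 * f1$sigma2, tolerance = 1e-10)
  expect_equal(f2$root_state, 2.5 * f1$root_state + 7, tolerance = 1e-10)
})

test_that("BM fit agrees with an independent ML implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_chronogram(12, seed = 7)
  x <- simulate_bm_traits(tr, 2, root_state = 1, seed = 11)
  f <- fit_bm(tr, x)
  ref <- phytools::brownie.lite(tr, x)
  expect_equal(f$sigma2, ref$sig2.single, tolerance = 1e-6)
  expect_equal(f$log_likelihood, ref$logL1, tolerance = 1e-6)
})

test_that("PGLS equals OLS on star trees and the whitening oracle elsewhere", {
  star <- star_tree(10)
  set.seed(8)
  x <- setNames(rnorm(10), star$tip.label)
  y <- 1.5 * x + rnorm(10, 0, 0.4)
  f <- pgls(star, x, y)
  ref <- summary(lm(y ~ x))
  expect_equal(f$slope, unname(coef(ref)[2, 1]), tolerance = 1e-8)
  expect_equal(f$t_statistic, unname(coef(ref)[2, 3]), tolerance = 1e-8)
  expect_equal(f$df, 8L)
  # exact linear relation
  fe <- pgls(star, x, setNames(2 * x + 1, names(x)))
  expect_equal(fe$slope, 2, tolerance = 1e-10)
  expect_equal(fe$intercept, 1, tolerance = 1e-10)
  # whitening oracle on a structured 8-tip tree
  tr <- simulate_chronogram(8, seed = 13)
  xb <- simulate_bm_traits(tr, 1, seed = 1)
  yb <- setNames(0.8 * xb + simulate_bm_traits(tr, 0.5, seed = 2),
                 names(xb))
  f8 <- pgls(tr, xb, yb)
  C <- ape::vcv(tr)
  W <- solve(t(chol(C)))
  wy <- drop(W %*% yb[rownames(C)])
  wX <- W %*% cbind(1, xb[rownames(C)])
  o <- summary(lm(wy ~ 0 + wX))
  expect_equal(f8$slope, unname(coef(o)[2, 1]), tolerance = 1e-10)
  expect_equal(f8$t_statistic, unname(coef(o)[2, 3]), tolerance = 1e-10)
  # t is invariant to affine transforms of y
  fa <- pgls(tr, xb, setNames(-3 * yb + 5, names(yb)))
  expect_equal(abs(fa$t_statistic), abs(f8$t_statistic), tolerance = 1e-9)
})

test_that("sensitivity PGLS collapses to plain PGLS at zero spread", {
  tr <- simulate_chronogram(10, seed = 21)
  x <- simulate_bm_traits(tr, 1, seed = 3)
  y <- setNames(0.5 * x + simulate_bm_traits(tr, 0.3, seed = 4), names(x))
  base <- pgls(tr, x, y)
  sens <- sensitivity_pgls(tr, x, y, x_sd = 0, y_sd = 0, n_iter = 50,
                           seed = 1)
  expect_equal(unique(sens$p_values), base$p_value)
  expect_equal(unique(sens$slopes), base$slope)
})

test_that("sensitivity PGLS tracks the strength of the true relation", {
  strong <- vapply(1:8, function(ms) {
    tr <- simulate_chronogram(12, seed = 100 + ms)
    x <- simulate_bm_traits(tr, 1, seed = 200 + ms)
    y <- setNames(x + simulate_bm_traits(tr, 0.05, seed = 300 + ms),
                  names(x))
    sensitivity_pgls(tr, x, y, x_sd = 0.05, y_sd = 0.05, n_iter = 60,
                     seed = ms)$median_p
  }, numeric(1))
  expect_gte(sum(strong < 0.05), 7)
})

test_that("disparity equals the direct sum of variances", {
  set.seed(31)
  a <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  b <- matrix(rnorm(10, 2, 3), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  res <- disparity_comparison(a, b, n_boot = 100, seed = 1)
  # oracle: z-score by hand with explicit loops, then per-axis variance
  pooled <- rbind(a, b)
  oracle <- function(m) {
    tot <- 0
    for (j in 1:2) {
      z <- (m[, j] - mean(pooled[, j])) / sd(pooled[, j])
      tot <- tot + sum((z - mean(z))^2) / (nrow(m) - 1)
    }
    tot
  }
  expect_equal(res$sum_of_variances_colony, oracle(a), tolerance = 1e-12)
  expect_equal(res$sum_of_variances_individual, oracle(b), tolerance = 1e-12)
  # a degenerate cloud has zero disparity
  flat <- matrix(1, 5, 2, dimnames = dimnames(a))
  expect_equal(disparity_comparison(a, flat, n_boot = 100,
                                    seed = 2)$sum_of_variances_individual, 0)
})

test_that("identical metric tables give a rate-comparison p of exactly 1", {
  met <- make_metrics(
    colony = list(a = c(3, 5), b = c(4, 7), c = c(6, 9), d = c(5, 8)),
    individual = list(a = c(3, 5), b = c(4, 7), c = c(6, 9), d = c(5, 8)))
  rc <- bootstrap_rate_comparison(met, tree4(), "rhythmicity",
                                  n_boot = 200, seed = 3)
  expect_true(all(rc$sigma2_colony_draws == rc$sigma2_individual_draws))
  expect_identical(rc$p_value, 1)
  expect_equal(rc$observed_difference, 0)
})

test_that("rate comparison validates its inputs", {
  met <- make_metrics(colony = list(a = c(3, 5), b = c(4, 7), c = c(6, 9)),
                      individual = list(a = 1, b = 2, c = 3))
  tr <- tree4()
  met_missing <- met[met$species != "b" | met$level != "individual", ]
  expect_error(bootstrap_rate_comparison(met_missing, tr, "rhythmicity",
                                         n_boot = 100, seed = 1),
               "individual-level data: b")
  expect_warning(bootstrap_rate_comparison(met, tr, "rhythmicity",
                                           n_boot = 50, seed = 1),
                 "coarse")
})

test_that("bootstrap draws are seed-deterministic", {
  met <- make_metrics(colony = list(a = c(3, 5), b = c(4, 7), c = c(6, 9)),
                      individual = list(a = c(1, 2), b = c(2, 4),
                                        c = c(3, 5)))
  r1 <- bootstrap_rate_comparison(met, tree4(), "rhythmicity",
                                  n_boot = 150, seed = 7)
  r2 <- bootstrap_rate_comparison(met, tree4(), "rhythmicity",
                                  n_boot = 150, seed = 7)
  expect_identical(r1$sigma2_colony_draws, r2$sigma2_colony_draws)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("interspecific-difference tests flag planted species effects", {
  met <- make_metrics(
    colony = list(a = c(2, 2.1), b = c(6, 6.2), c = c(10, 9.9)),
    individual = list(a = c(5, 5.05), b = c(5.1, 4.95), c = c(5, 5.02)))
  eff_col <- species_effect_test(met, "beta", "colony")
  eff_ind <- species_effect_test(met, "beta", "individual")
  expect_lt(eff_col$p_value, 0.01)
  expect_gt(eff_ind$p_value, 0.1)
})
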