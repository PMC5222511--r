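test_that("percent_difference is signed and guards zero references", {
  expect_equal(percent_difference(2, 3), 50)
  expect_equal(percent_difference(4, 2), -50)
  expect_error(percent_difference(0, 1), "zero")
})

test_that("two-level RM-ANOVA has epsilon exactly 1 and flat data F = 0", {
  set.seed(3)
  Y <- matrix(stats::rnorm(12), 6, 2)
  a <- rm_anova_gg(Y)
  expect_equal(a$epsilon_gg, 1)
  flat <- matrix(5, 4, 3)
  af <- rm_anova_gg(flat)
  expect_equal(af$F, 0)
  expect_equal(af$ss_condition, 0)
  expect_error(rm_anova_gg(matrix(1:3, 1)), "2 subjects")
})

test_that("RM-ANOVA matches the loop-based oracle on 50 random matrices", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:9, 1); k <- sample(3:6, 1)
    Y <- matrix(stats::rnorm(n * k), n, k) +
      outer(stats::rnorm(n), stats::rnorm(k, sd = 0.5), `+`)
    a <- rm_anova_gg(Y)
    o <- oracle_rm_anova(Y)
    expect_equal(a$F, o$F, tolerance = 1e-8)
    expect_equal(a$epsilon_gg, max(min(o$eps, 1), 1 / (k - 1)), tolerance = 1e-8)
    expect_gte(a$epsilon_gg, 1 / (k - 1))
    expect_lte(a$epsilon_gg, 1)
    expect_gte(a$p_gg, 0); expect_lte(a$p_gg, 1)
  }
})

test_that("RM-ANOVA agrees with car's Greenhouse-Geisser machinery", {
  set.seed(42)
  Y <- matrix(stats::rnorm(20), 5, 4)
  a <- rm_anova_gg(Y)
  mlm <- stats::lm(Y ~ 1)
  av <- suppressWarnings(
    summary(car::Anova(mlm, idata = data.frame(cond = factor(1:4)),
                       idesign = ~cond), multivariate = FALSE))
  expect_equal(a$epsilon_gg, unname(av$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-10)
  expect_equal(a$p_gg, unname(av$pval.adjustments[1, "Pr(>F[GG])"]),
               tolerance = 1e-10)
  expect_equal(a$F, unname(av$univariate.tests[2, "F value"]),
               tolerance = 1e-10)
})

test_that("sequential post hoc adjusts by the number of pairs and flags degeneracy", {
  set.seed(5)
  Y <- matrix(stats::rnorm(200), 20, 10)
  ph <- sequential_posthoc(Y)
  expect_equal(nrow(ph), 9)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 9))
  expect_true(all(ph$p_adj >= ph$p_raw))

  Z <- cbind(Y[, 1], Y[, 1], Y[, 1] + 1)
  phz <- sequential_posthoc(Z)
  expect_true(phz$degenerate[1]); expect_equal(phz$p_raw[1], 1)
  expect_true(phz$degenerate[2]); expect_equal(phz$p_raw[2], 0)
})

test_that("post hoc detects a shift confined to the first level", {
  set.seed(12)
  hits <- replicate(100, {
    Y <- matrix(stats::rnorm(20 * 10), 20, 10)
    Y[, 1] <- Y[, 1] - 2      # only level 1 differs by 2 SD
    ph <- sequential_posthoc(Y)
    c(first = ph$significant[1], others = any(ph$significant[-1]))
  })
  expect_gte(mean(hits["first", ]), 0.95)
  expect_lte(mean(hits["others", ]), 0.1)
})

test_that("optimal_frames implements the smallest-stable-n rule", {
  fake <- function(p) {
    out <- data.frame(pair = paste0(1:9, "v", 2:10), p_raw = p,
                      p_adj = p, degenerate = FALSE, significant = p < 0.05)
    attr(out, "alpha") <- 0.05
    out
  }
  expect_equal(optimal_frames(fake(rep(0.9, 9))), 1L)
  expect_equal(optimal_frames(fake(c(0.01, rep(0.9, 8)))), 2L)
  expect_equal(optimal_frames(fake(c(rep(0.01, 5), rep(0.9, 4)))), 6L)
  expect_equal(optimal_frames(fake(c(rep(0.9, 8), 0.01))), 10L)
})

test_that("optimal_frames is monotone in alpha on random tables", {
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(9)
    fake <- data.frame(pair = paste0(1:9, "v", 2:10), p_raw = p, p_adj = p,
                       degenerate = FALSE, significant = p < 0.05)
    attr(fake, "alpha") <- 0.05
    n_strict <- optimal_frames(fake, alpha = 0.01)
    n_loose <- optimal_frames(fake, alpha = 0.05)
    expect_lte(n_strict, n_loose)
  }
})

test_that("sequential post hoc controls the familywise type-I rate under the null", {
  set.seed(2024)
  false_pos <- replicate(1000, {
    Y <- matrix(stats::rnorm(22 * 10), 22, 10)
    any(sequential_posthoc(Y)$significant)
  })
  expect_lte(mean(false_pos), 0.07)
})

test_that("area coverage conversion matches arithmetic", {
  expect_equal(area_coverage_from_length_density(25, 9), 22.5)
  expect_equal(area_coverage_from_length_density(0), 0)
  expect_error(area_coverage_from_length_density(-1), ">= 0")
})

test_that("normative comparison flags cases below the control box", {
  set.seed(9)
  ctrl <- list(S = stats::rnorm(22, 25, 2))
  med <- stats::median(ctrl$S)
  out <- normative_comparison(ctrl, c(S = med))
  expect_equal(out$quantile, 0.5, tolerance = 0.05)
  expect_false(out$below_lower_whisker)

  low <- normative_comparison(ctrl, c(S = min(ctrl$S) - 1))
  expect_true(low$below_minimum)
  expect_equal(low$quantile, 0)

  flagged <- replicate(100, {
    cs <- stats::rnorm(22, 25, 2)
    normative_comparison(list(S = cs), c(S = 18))$below_lower_whisker
  })
  expect_gte(mean(flagged), 0.95)

  expect_error(normative_comparison(ctrl, c(T = 20)), "absent")
  expect_error(normative_comparison(list(S = 1:3), c(S = 2)), ">= 5")
})

test_that("metric_matrix pivots tidy metrics and drops incomplete subjects", {
  d <- expand.grid(subject = c("a", "b", "c"), n_frames = 1:3,
                   stringsAsFactors = FALSE)
  d$region <- "T"
  d$snr <- seq_len(nrow(d)) / 10
  d$excluded <- FALSE
  d$excluded[d$subject == "c" & d$n_frames == 2] <- TRUE
  M <- metric_matrix(d, "snr", "T", 1:3)
  expect_equal(rownames(M), c("a", "b"))
  expect_equal(M["a", "2"], d$snr[d$subject == "a" & d$n_frames == 2])
})
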