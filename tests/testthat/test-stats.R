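test_that("a perfect line is fitted exactly", {
  x <- 1:10
  fit <- huber_irls(x, 2 * x + 1)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
  expect_true(fit$converged)
  expect_equal(predict(fit, newdata = c(0, 5)), c(1, 11),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("huber fit resists a gross outlier that breaks least squares", {
  x <- 1:20
  y <- 3 * x
  y[20] <- y[20] + 150                      # ~50 sigma at high leverage
  ols <- stats::lm.fit(cbind(1, x), y)$coefficients   # plain LS oracle
  expect_gt(abs(ols[2] / 3 - 1), 0.05)
  fit <- huber_irls(x, y)
  expect_lt(abs(coef(fit)["slope"] / 3 - 1), 0.01)
  expect_true(any(fit$weights < 0.5))       # the outlier is down-weighted
})

test_that("huber irls agrees with an independent robust fitter", {
  skip_if_not_installed("MASS")
  set.seed(10)
  x <- runif(60, 0, 10)
  y <- 1.5 + 0.8 * x + rnorm(60, 0, 0.5)
  y[c(5, 20)] <- y[c(5, 20)] + 12
  fit <- huber_irls(x, y)
  ref <- MASS::rlm(y ~ x, k = 1.345, maxit = 100)
  expect_equal(unname(coef(fit)["slope"]), unname(coef(ref)[2]),
               tolerance = 0.01)
})

test_that("with no large residuals the fit reduces to least squares", {
  set.seed(2)
  x <- 1:30
  y <- 2 + 0.5 * x + rnorm(30, 0, 0.001)   # residuals all within c * scale
  fit <- huber_irls(x, y)
  ols <- stats::lm(y ~ x)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-4)
})

test_that("regression input contracts are enforced", {
  expect_error(huber_irls(1:2, 1:2), "at least 3")
  expect_error(huber_irls(rep(1, 5), 1:5), "constant")
})

test_that("exact Mann-Whitney matches full enumeration", {
  # frozen oracle: all C(4,2) = 6 labelings of {1,2,3,4} give
  # P(U <= 0) = 1/6, two-tailed 1/3
  out <- mann_whitney_two_tailed(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(round(out$p_value, 4), 0.3333)
  # independent enumeration oracle over random small samples
  enum_p <- function(a, b) {
    pool <- c(a, b); m <- length(a)
    u_obs <- sum(rank(pool)[seq_len(m)]) - m * (m + 1) / 2
    us <- apply(utils::combn(length(pool), m), 2, function(idx) {
      sum(rank(pool)[idx]) - m * (m + 1) / 2
    })
    min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  }
  set.seed(6)
  for (i in 1:5) {
    a <- sample(100, 4); b <- sample(200, 5)  # tie-free
    expect_equal(mann_whitney_two_tailed(a, b, method = "exact")$p_value,
                 enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("identical samples and separated samples behave as expected", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_two_tailed(a, a)$p_value, 1)
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30, 5)
  expect_lt(mann_whitney_two_tailed(x, y)$p_value, 1e-6)
  expect_error(mann_whitney_two_tailed(numeric(0), 1:3), "nonempty")
})

test_that("exact and normal approximations agree at moderate n", {
  set.seed(33)
  for (i in 1:10) {
    a <- sample(1000, 10); b <- sample(2000, 10)
    pe <- mann_whitney_two_tailed(a, b, method = "exact")$p_value
    pn <- mann_whitney_two_tailed(a, b, method = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("mann-whitney p is invariant under monotone transforms", {
  set.seed(5)
  a <- rlnorm(12); b <- rlnorm(15, 0.8)
  p0 <- mann_whitney_two_tailed(a, b)$p_value
  expect_equal(mann_whitney_two_tailed(log(a), log(b))$p_value, p0)
  expect_equal(mann_whitney_two_tailed(a^3, b^3)$p_value, p0)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  g <- list(1:5, 2:6, 3:7)
  vals <- unlist(g)
  grp <- rep(c("a", "b", "c"), each = 5)
  # oracle, computed before implementation: group means 3, 4, 5; grand 4;
  # SSB = 5 * (1 + 0 + 1) = 10 on 2 df; SSW = 3 * 10 = 30 on 12 df;
  # F = (10 / 2) / (30 / 12) = 2.0
  out <- anova_oneway(vals, grp)
  expect_equal(out$F, 2.0, tolerance = 1e-12)
  expect_equal(out$df_between, 2)
  expect_equal(out$df_within, 12)
  expect_equal(out$p_value, stats::pf(2, 2, 12, lower.tail = FALSE))
})

test_that("degenerate and two-group ANOVA behave correctly", {
  expect_equal(anova_oneway(rep(1, 6), rep(c("a", "b"), 3))$F, 0)
  expect_error(anova_oneway(1:3, c("a", "a", "b")), "at least 2 members")
  # F = t^2 identity against the equal-variance t test
  set.seed(8)
  x <- rnorm(10); y <- rnorm(12, 0.7)
  out <- anova_oneway(c(x, y), rep(c("x", "y"), c(10, 12)))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("ANOVA F is invariant under shift and positive rescale", {
  set.seed(9)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  f0 <- anova_oneway(v, g)$F
  expect_equal(anova_oneway(5 + 2.5 * v, g)$F, f0, tolerance = 1e-10)
})

test_that("group summaries use type-7 quartiles", {
  s <- summarize_groups(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(attr(s, "quartile_type"), 7L)
  s1 <- summarize_groups(7)
  expect_equal(unlist(s1[c("median", "q1", "q3")]),
               c(median = 7, q1 = 7, q3 = 7))
})

test_that("simulated phase groups are ordered as in the reference table", {
  ph <- make_phantom_population(400, seed = 17, min_separation_um = 0,
                                border_margin_um = 30)
  sm <- summarize_groups(ph$dry_mass_pg, ph$cycle_phase)
  sc <- summarize_groups(ph$expected_cpm, ph$cycle_phase)
  expect_gt(sm$median[sm$group == "S_G2_M"], sm$median[sm$group == "G1"])
  expect_gt(sc$median[sc$group == "S_G2_M"], sc$median[sc$group == "G1"])
})
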