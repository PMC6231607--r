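# build an attribute_estimate-like object through the public API by
# simulating opinions is heavy; instead tests drive build_design with a
# real estimate and fit_multinomial with constructed design tables.

make_design <- function(outcome, cls, reference = NULL) {
  classes <- sort(unique(cls))
  reference <- reference %||% classes[which.max(tabulate(match(cls, classes)))]
  d <- data.frame(outcome = factor(outcome, levels = c("0", "-1", "1")))
  for (c in setdiff(classes, reference)) d[[paste0("class_", c)]] <- as.integer(cls == c)
  attr(d, "reference_class") <- reference
  d
}

test_that("design construction dummy-codes classes against the reference", {
  sim <- simulate_planted_reports(planted_config(n = 60, m = 60, k = 25, B = 5,
                                                 K_true = 3, seed = 2))
  est <- ascribe_all(sim$reports)
  part <- stats::setNames(sim$communities, names(sim$communities))
  d <- build_design(part, est, "A1", reference_class = 2L)
  expect_setequal(setdiff(names(d), "outcome"), c("class_1", "class_3"))
  expect_equal(attr(d, "reference_class"), 2L)
  expect_equal(levels(d$outcome)[1], "0")
  # default reference is the largest class
  part2 <- part; part2[1:40] <- 1L
  d2 <- build_design(part2, est, "A1")
  expect_equal(attr(d2, "reference_class"), 1L)
  # two classes -> single indicator column
  part3 <- stats::setNames(rep(c(1L, 2L), 30), names(part))
  d3 <- build_design(part3, est, "A1", reference_class = 1L)
  expect_equal(setdiff(names(d3), "outcome"), "class_2")
  # all nodes in the reference class -> degenerate flag
  part4 <- stats::setNames(rep(1L, 60), names(part))
  d4 <- build_design(part4, est, "A1", reference_class = 1L)
  expect_true(attr(d4, "degenerate"))
})

test_that("two-class fits reproduce closed-form log odds ratios from the table", {
  # class 1: 30 of "0", 10 of "1", 5 of "-1"; class 2: 20 / 20 / 10
  outcome <- c(rep("0", 30), rep("1", 10), rep("-1", 5),
               rep("0", 20), rep("1", 20), rep("-1", 10))
  cls <- c(rep(1L, 45), rep(2L, 50))
  fit <- fit_multinomial(make_design(outcome, cls, reference = 1L))
  expect_true(fit$converged)
  # saturated model: coefficients are the log odds from the cell counts
  expect_equal(unname(fit$coefficients["-1", "(Intercept)"]), log(5 / 30),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["1", "(Intercept)"]), log(10 / 30),
               tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["-1", "class_2"]),
               log((10 / 20) / (5 / 30)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["1", "class_2"]),
               log((20 / 20) / (10 / 30)), tolerance = 1e-4)
  # fitted probabilities reproduce the empirical cell proportions
  probs <- fit$fitted[c(1, 46), ]
  expect_equal(unname(probs[1, ]), c(30, 5, 10) / 45, tolerance = 1e-4)
  expect_equal(unname(probs[2, ]), c(20, 10, 20) / 50, tolerance = 1e-4)
})

test_that("changing the reference class changes coefficients but not fit quality", {
  set.seed(14)
  cls <- sample(1:3, 300, replace = TRUE)
  probs <- rbind(c(0.6, 0.2, 0.2), c(0.4, 0.1, 0.5), c(0.7, 0.25, 0.05))
  outcome <- vapply(cls, function(c)
    sample(c("0", "-1", "1"), 1, prob = probs[c, ]), "")
  f1 <- fit_multinomial(make_design(outcome, cls, reference = 1L))
  f2 <- fit_multinomial(make_design(outcome, cls, reference = 3L))
  expect_false(isTRUE(all.equal(f1$coefficients, f2$coefficients)))
  expect_equal(f1$aic, f2$aic, tolerance = 1e-5)
  ord <- order(cls)
  expect_equal(f1$fitted[ord, ], f2$fitted[ord, ], tolerance = 1e-3)
})

test_that("null simulations give coefficients near zero; planted effects are recovered", {
  set.seed(15)
  n <- 2000
  cls <- sample(1:2, n, replace = TRUE)
  # no class effect
  outcome <- sample(c("0", "-1", "1"), n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  f0 <- fit_multinomial(make_design(outcome, cls, reference = 1L))
  z <- f0$coefficients[, "class_2"] / f0$std_errors[, "class_2"]
  expect_true(all(abs(z) < 3))

  # class 2 raises the +1 log-odds by log(2) relative to baseline
  base <- c(0.6, 0.2, 0.2)
  boosted <- c(0.6, 0.2, 0.4); boosted <- boosted / sum(boosted)
  outcome2 <- vapply(cls, function(c)
    sample(c("0", "-1", "1"), 1, prob = if (c == 2) boosted else base), "")
  f1 <- fit_multinomial(make_design(outcome2, cls, reference = 1L))
  est <- f1$coefficients["1", "class_2"]
  se <- f1$std_errors["1", "class_2"]
  expect_lt(abs(est - log(2)), 3 * se)
})

test_that("degenerate outcomes error and quasi-separation is flagged", {
  d <- make_design(rep("0", 40), rep(1:2, 20), reference = 1L)
  expect_error(fit_multinomial(d), "degenerate outcome")

  # class 2 never shows outcome "1": empty cell -> separation flag
  outcome <- c(rep("0", 20), rep("1", 10), rep("0", 25), rep("-1", 10))
  cls <- c(rep(1L, 30), rep(2L, 35))
  fit <- fit_multinomial(make_design(outcome, cls, reference = 1L))
  expect_true(fit$separation)
})
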