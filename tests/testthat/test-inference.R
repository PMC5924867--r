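test_that("equity test handles the degenerate all-zero case", {
  dat <- tibble::tibble(log_r = rep(0, 40),
                        cluster_id = rep(sprintf("c%d", 1:8), each = 5))
  tt <- test_equity(dat, "log_r")
  expect_equal(tt$estimate, 0)
  expect_equal(tt$p.value, 1)
  expect_equal(tt$n, 40)

  expect_error(test_equity(dplyr::mutate(dat, cluster_id = "c1"), "log_r"),
               "2 clusters", class = "hh_model_error")
  expect_error(test_equity(dplyr::mutate(dat, log_r = NA_real_), "log_r"),
               class = "hh_validation_error")
})

test_that("equity test recovers a known mean with sensible intervals", {
  set.seed(61)
  truth <- -0.2
  ests <- replicate(40, {
    cl <- rep(sprintf("c%d", 1:20), each = 8)
    y <- truth + rnorm(20, 0, 0.1)[as.integer(factor(cl))] +
      rnorm(160, 0, 0.3)
    tt <- test_equity(tibble::tibble(y = y, cluster_id = cl), "y")
    c(est = tt$estimate,
      cover = tt$conf.low <= truth && truth <= tt$conf.high)
  })
  expect_lt(abs(mean(ests["est", ]) - truth),
            3 * sd(ests["est", ]) / sqrt(40))
  expect_gte(mean(ests["cover", ]), 0.85)
  # tidy/glance return the advertised columns
  dat <- tibble::tibble(y = rnorm(40), cluster_id = rep(c("a", "b"), 20))
  tt <- test_equity(dat, "y")
  expect_named(tidy(tt), c("outcome", "n", "estimate", "std.error",
                           "conf.low", "conf.high", "p.value"))
  expect_true(tidy(tt)$conf.low <= tidy(tt)$estimate &
                tidy(tt)$estimate <= tidy(tt)$conf.high)
  expect_named(glance(tt), c("n", "n_clusters", "var_cluster",
                             "var_residual"))
})

test_that("VIF matches its closed form", {
  set.seed(71)
  raw <- matrix(rnorm(200 * 3), ncol = 3)
  qq <- qr.Q(qr(cbind(1, raw)))  # columns 2:4 centred and orthonormal
  ortho <- qq[, 2:4]
  colnames(ortho) <- c("u1", "u2", "u3")
  expect_equal(unname(vif(ortho)), rep(1, 3), tolerance = 1e-10)

  # exactly correlated pair, r = 0.6: VIF = 1 / (1 - 0.36) = 1.5625
  x <- cbind(a = qq[, 2], b = 0.6 * qq[, 2] + 0.8 * qq[, 3])
  expect_equal(unname(vif(x)), rep(1.5625, 2), tolerance = 1e-10)

  # independent oracle: car::vif on the same design
  y <- rnorm(200)
  fit <- lm(y ~ x[, 1] + x[, 2])
  expect_equal(unname(vif(x)), unname(car::vif(fit)), tolerance = 1e-8)

  dup <- cbind(a = raw[, 1], b = raw[, 1])
  expect_error(vif(dup), "collinear", class = "hh_model_error")
  expect_error(vif(raw[, 1, drop = FALSE]), "at least 2",
               class = "hh_validation_error")
})

test_that("determinants model recovers injected effects and flags rank problems", {
  s <- simulate_study(sim_config(n_clusters = 10,
                                 households_per_cluster = 8, seed = 81))
  profiles <- intake_profiles(s$portions, s$visits, s$fct)
  ratios <- allocation_ratios(profiles, s$members)
  frame <- determinant_frame(ratios, s$households, profiles, s$members,
                             "pw_hh")
  fit <- fit_determinants(frame, "log_rdear")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high",
                    "p.value", "vif") %in% names(td)))
  # every VIF is >= 1 and the design is near-orthogonal by construction
  expect_true(all(td$vif[!is.na(td$vif)] >= 1))
  earn <- td[td$term == "earnings_parity", ]
  expect_lt(abs(earn$estimate - 0.27), 4 * earn$std.error)

  # duplicated covariate: rank-deficiency error naming the column
  frame$dup <- frame$earnings_parity
  expect_error(
    fit_determinants(frame, "log_rdear",
                     covariates = c(determinant_covariates(), "dup")),
    "collinear|rank deficient", class = "hh_model_error")

  # all covariates constant: dropped with a warning, and the fit
  # degenerates to the equity-test intercept
  frame2 <- dplyr::mutate(frame, earnings_parity = 1)
  expect_warning(
    deg <- fit_determinants(frame2, "log_rdear",
                            covariates = "earnings_parity"),
    "constant")
  et <- test_equity(frame2, "log_rdear")
  expect_equal(deg$terms$estimate[1], et$estimate, tolerance = 1e-8)
})

test_that("quadratic wealth term is added behind its flag", {
  s <- tiny_study()
  profiles <- tiny_profiles()
  ratios <- allocation_ratios(profiles, s$members)
  frame <- determinant_frame(ratios, s$households, profiles, s$members,
                             "pw_hh")
  fit <- fit_determinants(frame, "log_rdear", quadratic_wealth = TRUE)
  expect_true("asset_score_sq" %in% tidy(fit)$term)
})

test_that("log coefficients convert to percent statements", {
  got <- pct_from_log(c(0, 0.27, -0.47))
  expect_equal(got$percent, c(0, 31, 38))
  expect_equal(got$direction, c("higher", "higher", "lower"))
  expect_equal(got$label[2], "31% higher")

  # reciprocal ratios: (1 + p_up/100) * (1 - p_down/100) = 1 pre-rounding
  cc <- runif(50, 0.01, 1)
  up <- pct_from_log(cc)$percent_raw
  down <- pct_from_log(-cc)$percent_raw
  expect_equal((1 + up / 100) * (1 - down / 100), rep(1, 50),
               tolerance = 1e-12)

  # rounding is half-up, not banker's (42.5 -> 43, not 42)
  expect_equal(pct_from_log(log(1.425))$percent, 43)
  expect_error(pct_from_log(Inf), class = "hh_validation_error")
})
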