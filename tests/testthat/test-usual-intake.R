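test_that("Box-Cox lambda lands near the generating transform", {
  set.seed(11)
  # log-normal data: log is the lambda = 0 limit
  x <- rlnorm(500, meanlog = 5, sdlog = 0.5)
  fit <- fit_boxcox(x)
  expect_true(fit$lambda > -0.2 && fit$lambda < 0.2)
  expect_equal(fit$shift, 0)

  # positive normal data: identity transform is already normal
  y <- rnorm(500, mean = 100, sd = 5)
  expect_true(abs(fit_boxcox(y)$lambda - 1) < 0.4)

  # cross-check the profile-likelihood maximiser against MASS::boxcox
  grid <- MASS::boxcox(x ~ 1, lambda = seq(-1, 1, 0.01), plotit = FALSE)
  expect_lt(abs(fit$lambda - grid$x[which.max(grid$y)]), 0.02)
})

test_that("Box-Cox transform and inverse are exact inverses", {
  set.seed(12)
  x <- c(rlnorm(50, 4, 1), 0)  # includes a zero -> shift kicks in
  fit <- fit_boxcox(x)
  expect_true(fit$shift > 0)
  expect_equal(boxcox_inverse(boxcox_transform(x, fit), fit), x,
               tolerance = 1e-10)
  # at lambda = 0 the inverse is the exponential
  f0 <- structure(list(lambda = 0, shift = 0), class = "boxcox_fit")
  expect_equal(boxcox_inverse(2, f0), exp(2))
  f1 <- structure(list(lambda = 1, shift = 0), class = "boxcox_fit")
  expect_equal(boxcox_inverse(5, f1), 6)  # (1*5+1)^1

  expect_error(fit_boxcox(c(1, 2)), "at least 3",
               class = "hh_validation_error")
  expect_error(fit_boxcox(c(0, 0, 0)), "zero",
               class = "hh_validation_error")
})

test_that("degenerate day noise gives near-zero residual variance and exact BLUP recovery", {
  s <- simulate_study(sim_config(n_clusters = 3, households_per_cluster = 4,
                                 seed = 5, sd_day = 0))
  pv <- portions_to_intake(s$portions, s$fct)
  meta <- dplyr::left_join(
    s$members[, c("member_id", "household_id", "role")],
    s$households[, c("household_id", "cluster_id", "stratum")],
    by = "household_id")
  dat <- dplyr::left_join(pv[, c("member_id", "visit_index", "energy_kcal")],
                          meta, by = "member_id") |>
    dplyr::rename(value = energy_kcal) |>
    dplyr::filter(role == "pregnant_woman")
  m <- fit_usual_model(dat, "energy_kcal", "pregnant_woman")
  expect_lt(m$var_residual, 1e-6 * (m$var_individual + m$var_residual + 1e-12))
  pred <- predict_usual(m)
  truth <- dat |>
    dplyr::group_by(member_id) |>
    dplyr::summarise(value = mean(value))
  merged <- dplyr::left_join(pred, truth, by = "member_id")
  expect_equal(merged$usual, merged$value, tolerance = 1e-3)
})

test_that("single-stratum data fits without stratum coefficients", {
  set.seed(21)
  dat <- tidyr::expand_grid(member_id = sprintf("m%02d", 1:20),
                            visit = 1:3) |>
    dplyr::mutate(cluster_id = rep(rep(c("c1", "c2"), each = 10), each = 3),
                  stratum = "only",
                  value = rlnorm(60, 7, 0.3))
  m <- fit_usual_model(dat, "energy", "pregnant_woman")
  expect_false(m$multi_stratum)
  expect_equal(names(m$fixed_effects), "(Intercept)")
  expect_error(
    fit_usual_model(dplyr::mutate(dat, cluster_id = "c1"), "e", "r"),
    "2 clusters", class = "hh_model_error")
})

test_that("individual variance component is recovered across replicates", {
  # transformed-scale oracle: data generated straight from the mixed model
  n_rep <- 100
  truth <- 0.04
  identity_bc <- structure(list(lambda = 1, shift = 0),
                           class = "boxcox_fit")
  set.seed(31)
  est <- replicate(n_rep, {
    members <- tidyr::expand_grid(cluster = sprintf("c%d", 1:8),
                                  m = 1:8) |>
      dplyr::mutate(member_id = paste(cluster, m))
    u <- rnorm(nrow(members), 0, sqrt(truth))
    ck <- stats::setNames(rnorm(8, 0, 0.1), sprintf("c%d", 1:8))
    dat <- tidyr::expand_grid(i = seq_len(nrow(members)), visit = 1:3)
    dat$member_id <- members$member_id[dat$i]
    dat$cluster_id <- members$cluster[dat$i]
    dat$stratum <- "s"
    dat$value <- 8 + ck[dat$cluster_id] + u[dat$i] +
      rnorm(nrow(dat), 0, 0.25)
    fit_usual_model(dat, boxcox = identity_bc)$var_individual
  })
  expect_lt(abs(mean(est) - truth) / truth, 0.30)
})

test_that("usual intakes shrink toward the mean and track the truth", {
  s <- tiny_study()
  pv <- portions_to_intake(s$portions, s$fct)
  meta <- dplyr::left_join(
    s$members[, c("member_id", "household_id", "role")],
    s$households[, c("household_id", "cluster_id", "stratum")],
    by = "household_id")
  long <- dplyr::left_join(pv[, c("member_id", "visit_index",
                                  "energy_kcal")],
                           meta, by = "member_id") |>
    dplyr::rename(value = energy_kcal)
  truth <- tiny_study()$ground_truth$members

  rel_err <- unlist(lapply(hh_roles(), function(r) {
    dat <- long[long$role == r, ]
    m <- fit_usual_model(dat, "energy_kcal", r)
    pred <- predict_usual(m)
    tr <- truth[match(pred$member_id, truth$member_id), ]
    # shrinkage: predicted usual intakes vary less than single days
    expect_lt(var(boxcox_transform(pred$usual, m$boxcox)),
              var(boxcox_transform(dat$value, m$boxcox)))
    abs(pred$usual / tr$true_usual_energy - 1)
  }))
  # BLUPs at the default noise level sit close to the stored truth
  expect_lt(median(rel_err), 0.10)
  expect_lt(mean(rel_err), 0.15)
})

test_that("back-transformed usual intake is increasing in the member BLUP", {
  f <- structure(list(lambda = 0.4, shift = 2), class = "boxcox_fit")
  eta <- seq(-1, 8, length.out = 40)
  vals <- boxcox_inverse(eta, f)
  expect_true(all(diff(vals) >= 0))
})
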