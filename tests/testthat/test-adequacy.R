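test_that("energy EARs follow the coefficient model plus the pregnancy increment", {
  base <- tibble::tibble(
    member_id = c("a", "b"), household_id = "h",
    role = c("pregnant_woman", "mother_in_law"),
    sex = "female", age = c(22, 50), body_weight = 52,
    gestational_age = c(36, NA), activity_level = "moderate",
    illness_any = FALSE, fasting_any = FALSE
  )
  ears <- energy_ear(base)
  # identical except pregnancy: difference is exactly the 390 kcal/d cost
  expect_equal(ears[1] - ears[2], 390)

  # non-increment part is linear in body weight
  heavier <- dplyr::mutate(base, body_weight = 104)
  expect_equal(energy_ear(heavier)[2], 2 * ears[2])

  # coefficients are ordered by activity level for both sexes
  co <- default_energy_coefficients() |>
    tidyr::pivot_wider(names_from = "activity_level",
                       values_from = "kcal_per_kg")
  expect_true(all(co$sedentary < co$moderate & co$moderate < co$heavy))

  expect_error(energy_ear(dplyr::mutate(base, activity_level = NA)),
               class = "hh_validation_error")
})

test_that("normal probability of adequacy is the requirement CDF", {
  expect_identical(pa_normal(40, 40, 4), 0.5)
  expect_equal(pa_normal(40 + 1.96 * 4, 40, 4), 0.975, tolerance = 1e-4)
  # pregnant zinc at usual 11 vs EAR 12 (1.5): direct CDF evaluation
  expect_equal(pa_normal(11, 12, 1.5), pnorm(-2 / 3), tolerance = 1e-12)
  expect_equal(round(pa_normal(11, 12, 1.5), 3), 0.252)

  # tabulated requirement passed in error
  expect_error(pa_normal(10, NA, NA), class = "hh_type_error")

  # lowering the EAR mean never decreases PA
  u <- runif(50, 0, 30)
  expect_true(all(pa_normal(u, 10, 2) >= pa_normal(u, 12, 2)))
})

test_that("tabulated iron PA handles boundaries and is monotone", {
  tab <- default_iron_table()
  f <- tab[tab$sex == "female", ]
  expect_equal(pa_iron_tabulated(0, f), min(f$probability))
  expect_equal(pa_iron_tabulated(1e6, f), max(f$probability))
  u <- sort(runif(200, 0, 90))
  pa <- pa_iron_tabulated(u, f)
  expect_true(all(diff(pa) >= 0))
  expect_true(all(pa >= 0 & pa <= 1))
  expect_error(pa_iron_tabulated(10, f[0, ]), "empty",
               class = "hh_validation_error")
})

test_that("the shipped iron table is frozen output of its builder", {
  built <- dplyr::bind_rows(build_iron_probability_table("female"),
                            build_iron_probability_table("male"))
  expect_equal(as.data.frame(default_iron_table()), as.data.frame(built),
               tolerance = 1e-9)
  expect_true(all(diff(built$probability[built$sex == "female"]) >= 0))
})

test_that("MPA is the mean over exactly the 11 micronutrients", {
  pa <- stats::setNames(rep(1, 11), hh_micronutrients())
  expect_equal(mpa(pa), 1)
  expect_equal(mpa(pa * 0.5), 0.5)

  set.seed(4)
  pa[] <- runif(11)
  expect_equal(mpa(pa), sum(pa) / 11)
  # permutation invariant
  expect_equal(mpa(sample(pa)), mpa(pa))

  expect_error(mpa(pa[-1]), "missing", class = "hh_validation_error")
  expect_error(mpa(c(pa, energy_kcal = 0.5)), "unexpected",
               class = "hh_validation_error")
})

test_that("per-member adequacy table uses roles, sexes and both PA kinds", {
  s <- tiny_study()
  pv <- portions_to_intake(s$portions, s$fct)
  ui <- usual_intakes(pv, s$members, s$households,
                      nutrients = hh_micronutrients())
  ad <- compute_adequacy(ui$usual, s$members)
  expect_equal(nrow(ad), nrow(s$members))
  pa_cols <- paste0("pa_", hh_micronutrients())
  expect_true(all(as.matrix(ad[, pa_cols]) >= 0 &
                    as.matrix(ad[, pa_cols]) <= 1))
  expect_equal(ad$mpa, rowMeans(ad[, pa_cols]))

  # PA is monotone in usual intake: doubling every usual intake can
  # never lower any PA
  doubled <- dplyr::mutate(ui$usual, usual = usual * 2)
  ad2 <- compute_adequacy(doubled, s$members)
  expect_true(all(as.matrix(ad2[, pa_cols]) >=
                    as.matrix(ad[, pa_cols]) - 1e-12))
})

test_that("requirement configuration covers all roles and micronutrients", {
  req <- default_requirements()
  combos <- table(req$role, req$nutrient)
  expect_true(all(combos == 1))
  expect_equal(sort(unique(req$nutrient)), sort(hh_micronutrients()))
  tab <- req[req$kind == "tabulated", ]
  # only non-pregnant iron is tabulated
  expect_setequal(tab$role, c("mother_in_law", "household_head"))
  expect_setequal(tab$nutrient, "iron_mg")
  norm <- req[req$kind == "normal", ]
  expect_true(all(norm$ear_sd > 0))
})
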