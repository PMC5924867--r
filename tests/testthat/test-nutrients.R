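test_that("recipe averaging is the element-wise mean", {
  fct <- generate_fct(1)
  one <- fct[3, hh_nutrients()]
  expect_equal(as.numeric(average_recipes(one, "dish")[, hh_nutrients()]),
               as.numeric(one))

  two <- tibble::as_tibble(lapply(hh_nutrients(), function(x) c(10, 20)) |>
                             stats::setNames(hh_nutrients()))
  expect_equal(average_recipes(two, "dish")$energy_kcal, 15)

  set.seed(9)
  obs <- tibble::as_tibble(matrix(runif(5 * 13, 0, 50), nrow = 5,
                                  dimnames = list(NULL, hh_nutrients())))
  got <- average_recipes(obs, "dish")
  # independent oracle: column means computed directly
  expect_equal(as.numeric(got[, hh_nutrients()]),
               unname(apply(as.matrix(obs), 2, mean)))

  expect_error(average_recipes(obs[0, ], "dish"), "at least one",
               class = "hh_validation_error")
})

test_that("nutrient totalling is linear in grams and permutation invariant", {
  fct <- generate_fct(1)
  mk <- function(code, grams) {
    tibble::tibble(member_id = "m", visit_index = 1L, food_code = code,
                   grams = grams, hour = 12L, location = "home")
  }
  # 100 g returns exactly the per-100 g vector
  one <- portions_to_intake(mk("lentil_dal", 100), fct)
  expect_equal(as.numeric(one[, hh_nutrients()]),
               as.numeric(fct[fct$food_code == "lentil_dal",
                              hh_nutrients()]))

  # 150 g + 50 g of the same food is twice the 100 g total
  two <- portions_to_intake(dplyr::bind_rows(mk("rice", 150),
                                             mk("rice", 50)), fct)
  base <- portions_to_intake(mk("rice", 100), fct)
  expect_equal(as.numeric(two[, hh_nutrients()]),
               2 * as.numeric(base[, hh_nutrients()]))

  # permutation of portions leaves totals unchanged
  s <- tiny_study()
  shuffled <- s$portions[sample(nrow(s$portions)), ]
  expect_equal(
    dplyr::arrange(portions_to_intake(shuffled, s$fct), member_id,
                   visit_index),
    dplyr::arrange(portions_to_intake(s$portions, s$fct), member_id,
                   visit_index)
  )

  # empty portion set gives a zero-row table
  expect_equal(nrow(portions_to_intake(s$portions[0, ], fct)), 0)

  expect_error(portions_to_intake(mk("unobtainium", 10), fct),
               "unobtainium", class = "hh_lookup_error")
})

test_that("MDD-W scoring follows the first-visit, ten-group, >=5 rule", {
  fct <- generate_fct(1)
  # one food from each of the 10 groups plus alcohol
  ten_foods <- c("rice", "lentil_dal", "peanut", "curd", "fish_small",
                 "egg", "spinach_saag", "mango", "okra", "banana")
  mk_visits <- function(member) {
    tidyr::expand_grid(member_id = member, visit_index = 1:3) |>
      dplyr::mutate(proxy_respondent = FALSE)
  }
  mk_portions <- function(member, foods, visit = 1L) {
    tibble::tibble(member_id = member, visit_index = visit,
                   food_code = foods, grams = 50, hour = 12L,
                   location = "home")
  }

  # all 10 groups on visit 1
  p <- intake_profiles(mk_portions("a", ten_foods), mk_visits("a"), fct)
  expect_equal(p$mddw_score, 10L)
  expect_true(p$mddw_adequate)

  # exactly 5 groups: adequate; 4: inadequate
  p5 <- intake_profiles(mk_portions("a", ten_foods[1:5]), mk_visits("a"),
                        fct)
  expect_equal(p5$mddw_score, 5L)
  expect_true(p5$mddw_adequate)
  p4 <- intake_profiles(mk_portions("a", ten_foods[1:4]), mk_visits("a"),
                        fct)
  expect_equal(p4$mddw_score, 4L)
  expect_false(p4$mddw_adequate)

  # alcohol never counts towards the score
  p_alc <- intake_profiles(mk_portions("a", c(ten_foods[1:4], "raksi")),
                           mk_visits("a"), fct)
  expect_equal(p_alc$mddw_score, 4L)
  expect_false(p_alc$mddw_adequate)
  expect_true(p_alc$any_alcohol)

  # groups eaten only on visit 2 are excluded from the score but
  # included in consumed-any
  p_v2 <- intake_profiles(
    dplyr::bind_rows(mk_portions("a", ten_foods[1:4], 1L),
                     mk_portions("a", "egg", 2L)),
    mk_visits("a"), fct)
  expect_equal(p_v2$mddw_score, 4L)
  expect_true(p_v2$any_eggs)

  expect_error(intake_profiles(mk_portions("a", "rice"),
                               mk_visits("a")[0, ], fct),
               "at least one visit", class = "hh_validation_error")
})

test_that("profiles average intakes over available visits, zero days included", {
  fct <- generate_fct(1)
  visits <- tibble::tibble(member_id = "a", visit_index = 1:3,
                           proxy_respondent = FALSE)
  # food only on visit 1: the 3-day mean is one third of the day total
  portions <- tibble::tibble(member_id = "a", visit_index = 1L,
                             food_code = "rice", grams = 300, hour = 12L,
                             location = "home")
  p <- intake_profiles(portions, visits, fct)
  day1 <- as.numeric(portions_to_intake(portions, fct)[, "energy_kcal"])
  expect_equal(p$energy_kcal, day1 / 3)
  expect_equal(p$grams_grains_roots_tubers, 100)
  expect_equal(p$n_visits, 3L)
})

test_that("simulated recall energies match their day targets", {
  s <- tiny_study()
  pv <- portions_to_intake(s$portions, s$fct)
  # reconstruct day targets from the stored truth under the fixed seed:
  # with sd_day > 0 targets vary, but each day's total is scaled exactly,
  # so re-totalling via the nutrient engine must hit the target to <1%.
  # The scaling is exact in this generator, so check a tight tolerance
  # against an independent re-totalling with plain base R.
  manual <- tapply(
    s$portions$grams *
      s$fct$energy_kcal[match(s$portions$food_code, s$fct$food_code)] / 100,
    paste(s$portions$member_id, s$portions$visit_index), sum)
  engine <- stats::setNames(pv$energy_kcal,
                            paste(pv$member_id, pv$visit_index))
  expect_equal(unname(engine[names(manual)]), as.numeric(manual),
               tolerance = 1e-10)

  # energy positive everywhere (staple always present)
  expect_true(all(pv$energy_kcal > 0))
})
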