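#' Simulation configuration
#'
#' Builds the configuration object for the synthetic study generator. The
#' defaults emulate the study design the package targets: 20 sampling
#' clusters of joint households, each household holding exactly one
#' pregnant woman, her mother-in-law and the male household head, with
#' three non-consecutive 24-h recalls per person, log-normal within-person
#' day-to-day intake variation, and covariate-driven allocation effects.
#'
#' Energy is generated on the adequacy (log intake/requirement) scale so
#' that household-level allocation ratios are controlled exactly: the
#' household head's log energy adequacy is `log_adequacy_hh_mean` plus a
#' cluster effect (`sd_cluster`) and an individual effect
#' (`sd_individual`); the pregnant woman's and mother-in-law's adequacies
#' are offset from the same cluster baseline by the configured pair
#' contrasts, so each household's true log relative dietary energy
#' adequacy ratio (log-RDEAR) equals the configured mean plus covariate
#' effects plus individual-effect differences. Covariate effects are
#' centred at their realised sample mean, so the crude (marginal) mean of
#' the true log-RDEARs equals `true_log_rdear_mean` in every generated
#' dataset while a determinants regression still recovers the configured
#' coefficient.
#'
#' @param n_clusters Number of clusters (Village Development Committee
#'   areas). Default 20.
#' @param households_per_cluster Households per cluster. Default 8.
#' @param seed Integer seed; every random draw derives from it.
#' @param true_log_rdear_mean Named vector with elements `pw_hh` and
#'   `pw_mil`: true crude mean log-RDEAR for the pregnant woman vs the
#'   household head and vs the mother-in-law. The `mil_hh` contrast is
#'   implied (`pw_hh - pw_mil`).
#' @param earnings_effect Additive shift on the pregnant woman's log
#'   energy adequacy (hence on her log-RDEARs) when she earns the same or
#'   more than her spouse, centred at the sample prevalence.
#' @param hh_kcal_effect_on_log_mpa_ratio Tilt, per 1000 kcal of
#'   household mean energy intake, applied to the log-odds of the pregnant
#'   woman consuming micronutrient-dense food groups. Raises her
#'   micronutrient density (and so the MPA ratio) with household-level
#'   calorie consumption; the induced coefficient on the log MPA ratio is
#'   monotone in this value but not numerically equal to it, because MPA
#'   is a nonlinear function of intakes. Default 0.
#' @param sd_cluster,sd_individual Between-cluster and between-individual
#'   SDs of log energy adequacy.
#' @param sd_day Within-person day-to-day SD of log intake.
#' @param log_adequacy_hh_mean Mean log energy adequacy (log of intake
#'   over requirement) for household heads; anchors absolute intake
#'   levels.
#' @param covariate_prevalences Named list of covariate generation
#'   parameters: `earnings_parity`, `husband_overseas`, `monsoon`
#'   (Bernoulli probabilities), `gravidity_1plus` (probability of one or
#'   more previous pregnancies) and `empowerment_prob` (success
#'   probability of the Binomial(10) empowerment score).
#' @param food_use_probs Optional tibble (`food_code`, one probability
#'   column per role) giving per-day consumption probabilities; defaults
#'   to the built-in pattern matched to the study population's diet.
#' @param portion_lognormal_params Optional tibble (`food_code`,
#'   `meanlog`, `sdlog`) for raw portion-size draws; defaults built in.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 20,
                       households_per_cluster = 8,
                       seed = 1L,
                       true_log_rdear_mean = c(pw_hh = -0.20, pw_mil = -0.15),
                       earnings_effect = 0.27,
                       hh_kcal_effect_on_log_mpa_ratio = 0,
                       sd_cluster = 0.1,
                       sd_individual = 0.2,
                       sd_day = 0.25,
                       log_adequacy_hh_mean = 0.075,
                       covariate_prevalences = list(),
                       food_use_probs = NULL,
                       portion_lognormal_params = NULL) {
  prev <- utils::modifyList(
    list(earnings_parity = 0.25, gravidity_1plus = 0.676,
         husband_overseas = 0.30, monsoon = 0.5, empowerment_prob = 0.5),
    covariate_prevalences
  )
  cfg <- structure(
    list(
      n_clusters = as.integer(n_clusters),
      households_per_cluster = as.integer(households_per_cluster),
      seed = as.integer(seed),
      true_log_rdear_mean = true_log_rdear_mean,
      earnings_effect = earnings_effect,
      hh_kcal_effect_on_log_mpa_ratio = hh_kcal_effect_on_log_mpa_ratio,
      sd_cluster = sd_cluster,
      sd_individual = sd_individual,
      sd_day = sd_day,
      log_adequacy_hh_mean = log_adequacy_hh_mean,
      covariate_prevalences = prev,
      food_use_probs = food_use_probs,
      portion_lognormal_params = portion_lognormal_params
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_clusters < 1 || cfg$households_per_cluster < 1) {
    abort("n_clusters and households_per_cluster must be >= 1",
          class = "hh_config_error")
  }
  sds <- c(cfg$sd_cluster, cfg$sd_individual, cfg$sd_day)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort("simulation SDs must be finite and >= 0", class = "hh_config_error")
  }
  if (!all(c("pw_hh", "pw_mil") %in% names(cfg$true_log_rdear_mean))) {
    abort("true_log_rdear_mean must name pw_hh and pw_mil",
          class = "hh_config_error")
  }
  probs <- unlist(cfg$covariate_prevalences)
  if (any(probs < 0 | probs > 1)) {
    abort("covariate prevalences must lie in [0, 1]",
          class = "hh_config_error")
  }
  cfg
}

#' Generate a synthetic food composition table
#'
#' Returns a curated table of common Nepali *Terai* foods covering all 10
#' MDD-W food groups plus alcohol and an `other` group (tea, oil), with
#' per-100 g energy, protein and the 11 assessed micronutrients. Every food
#' has strictly positive energy and each micronutrient has at least one
#' rich source (e.g. sesame for iron/zinc/calcium, small fish for vitamin
#' B12, carrot for vitamin A). The seed drives a small (about 5%)
#' multiplicative jitter of the non-energy composition values, so distinct
#' seeds give distinct but equally plausible tables and equal seeds give
#' identical ones.
#'
#' @param seed Integer seed.
#' @return An FCT tibble (see [read_fct()]).
#' @export
generate_fct <- function(seed = 1L) {
  base <- base_fct()
  withr_seed(seed, {
    jitter <- matrix(
      exp(rnorm(nrow(base) * length(hh_micronutrients()), 0, 0.05)),
      nrow = nrow(base)
    )
    base[, hh_micronutrients()] <-
      as.matrix(base[, hh_micronutrients()]) * jitter
  })
  validate_fct(base)
}

# fixed composition backbone (per 100 g, cooked/as-consumed basis)
base_fct <- function() {
  codes <- c("rice", "roti", "beaten_rice", "potato", "lentil_dal",
             "chickpea", "peanut", "sesame", "buffalo_milk", "curd",
             "goat_meat", "fish_small", "egg", "spinach_saag",
             "mustard_greens", "mango", "pumpkin", "carrot", "cauliflower",
             "okra", "pointed_gourd", "banana", "guava", "raksi",
             "sweet_tea", "mustard_oil")
  names_ <- c("Cooked rice", "Wheat flatbread", "Beaten rice",
              "Potato curry", "Lentil dal", "Chickpea curry",
              "Roasted peanut", "Sesame seed", "Buffalo milk",
              "Curd (dahi)", "Goat meat curry", "Small fish", "Hen egg",
              "Spinach saag", "Mustard greens", "Ripe mango",
              "Pumpkin curry", "Carrot", "Cauliflower curry", "Okra curry",
              "Pointed gourd curry", "Banana", "Guava", "Distilled raksi",
              "Tea with milk and sugar", "Mustard oil")
  groups <- c(rep("grains_roots_tubers", 4), rep("pulses", 2),
              rep("nuts_seeds", 2), rep("dairy", 2),
              rep("meat_poultry_fish", 2), "eggs",
              rep("dark_green_leafy_veg", 2), rep("vitamin_a_fruits_veg", 3),
              rep("other_vegetables", 3), rep("other_fruits", 2),
              "alcohol", rep("other", 2))
  # energy, protein, vitC, vitA, thiamin, riboflavin, niacin, B6, folate,
  # B12, iron, zinc, calcium per 100 g
  comp <- matrix(c(
    130, 2.7, 0, 0, 0.02, 0.01, 0.4, 0.09, 4, 0, 0.2, 0.5, 10,
    300, 10, 0, 0, 0.30, 0.10, 3.2, 0.20, 30, 0, 2.5, 1.5, 30,
    350, 7, 0, 0, 0.10, 0.05, 1.5, 0.10, 10, 0, 2.0, 1.0, 12,
    87, 1.9, 13, 0, 0.08, 0.03, 1.1, 0.30, 18, 0, 0.8, 0.3, 9,
    116, 9, 1.5, 1, 0.17, 0.07, 1.1, 0.18, 180, 0, 3.3, 1.3, 25,
    164, 8.9, 1.3, 1, 0.12, 0.06, 0.5, 0.14, 170, 0, 2.9, 1.5, 50,
    567, 26, 0, 0, 0.64, 0.14, 12.0, 0.35, 240, 0, 4.6, 3.3, 92,
    573, 18, 0, 3, 0.79, 0.25, 4.5, 0.80, 97, 0, 14.6, 7.8, 975,
    97, 3.8, 2.3, 53, 0.05, 0.14, 0.09, 0.02, 6, 0.4, 0.1, 0.2, 169,
    98, 4.0, 0.8, 30, 0.03, 0.16, 0.10, 0.03, 7, 0.4, 0.1, 0.4, 149,
    143, 27, 0, 0, 0.10, 0.60, 6.5, 0.40, 5, 1.2, 3.7, 4.5, 13,
    127, 18, 0, 45, 0.05, 0.10, 3.0, 0.20, 15, 2.4, 2.5, 1.2, 400,
    155, 13, 0, 160, 0.07, 0.50, 0.06, 0.12, 47, 1.1, 1.8, 1.1, 50,
    23, 2.9, 28, 470, 0.08, 0.19, 0.7, 0.20, 194, 0, 2.7, 0.5, 99,
    27, 2.9, 70, 525, 0.08, 0.11, 0.8, 0.18, 12, 0, 1.6, 0.25, 115,
    60, 0.8, 36, 54, 0.03, 0.04, 0.7, 0.12, 43, 0, 0.2, 0.1, 11,
    26, 1.0, 9, 430, 0.05, 0.11, 0.6, 0.06, 16, 0, 0.8, 0.3, 21,
    41, 0.9, 6, 835, 0.07, 0.06, 1.0, 0.14, 19, 0, 0.3, 0.2, 33,
    60, 1.9, 46, 0, 0.05, 0.06, 0.5, 0.18, 57, 0, 0.4, 0.3, 22,
    33, 1.9, 23, 36, 0.20, 0.06, 1.0, 0.22, 60, 0, 0.6, 0.6, 82,
    20, 2.0, 29, 25, 0.05, 0.06, 0.5, 0.04, 15, 0, 1.7, 0.5, 30,
    89, 1.1, 8.7, 3, 0.03, 0.07, 0.67, 0.37, 20, 0, 0.3, 0.15, 5,
    68, 2.6, 228, 31, 0.07, 0.04, 1.08, 0.11, 49, 0, 0.3, 0.23, 18,
    220, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
    40, 0.8, 0, 10, 0.01, 0.03, 0.05, 0.01, 1, 0.05, 0.05, 0.05, 30,
    884, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0
  ), ncol = 13, byrow = TRUE)
  colnames(comp) <- hh_nutrients()
  bind_cols(tibble(food_code = codes, name = names_, mddw_group = groups),
            as_tibble(comp))
}

# per-day consumption probabilities per food and role
default_food_use_probs <- function() {
  p <- tibble(
    food_code = base_fct()$food_code,
    pregnant_woman = c(1, .50, .20, .50, .85, .20, .10, .05, .30, .10, .06,
                       .06, .06, .25, .15, .25, .15, .10, .50, .40, .30,
                       .07, .05, 0, .50, .90),
    mother_in_law = c(1, .50, .20, .50, .85, .20, .12, .05, .28, .10, .06,
                      .06, .07, .25, .15, .20, .15, .10, .50, .40, .30,
                      .06, .05, 0, .50, .90),
    household_head = c(1, .50, .30, .50, .85, .20, .12, .05, .40, .15, .10,
                       .10, .12, .22, .13, .20, .15, .10, .50, .40, .30,
                       .08, .05, .08, .70, .90)
  )
  p
}

default_portion_params <- function() {
  typical <- c(rice = 300, roti = 120, beaten_rice = 80, potato = 100,
               lentil_dal = 120, chickpea = 80, peanut = 20, sesame = 10,
               buffalo_milk = 150, curd = 100, goat_meat = 80,
               fish_small = 60, egg = 50, spinach_saag = 60,
               mustard_greens = 60, mango = 150, pumpkin = 80, carrot = 50,
               cauliflower = 100, okra = 80, pointed_gourd = 80,
               banana = 100, guava = 100, raksi = 150, sweet_tea = 150,
               mustard_oil = 15)
  tibble(food_code = names(typical),
         meanlog = log(unname(typical)),
         sdlog = 0.3)
}

#' Generate synthetic households, members and ground truth
#'
#' Draws `n_clusters * households_per_cluster` households, each with the
#' full role triad, covariates at the configured prevalences, and the true
#' usual energy intake of every member built on the adequacy scale (see
#' [sim_config()]). The returned ground truth stores every quantity the
#' downstream estimators are later asked to recover.
#'
#' @param config A [sim_config()] object.
#' @param fct Food composition table used to derive true usual
#'   micronutrient intakes (defaults to `generate_fct(config$seed)`).
#' @return A list with tibbles `households`, `members`, and a
#'   `ground_truth` list holding `members` (true usual intake per nutrient
#'   per member), `households` (true log allocation ratios), and the
#'   `config` echo.
#' @export
generate_households <- function(config, fct = NULL) {
  config <- validate_sim_config(config)
  fct <- fct %||% generate_fct(config$seed)
  prev <- config$covariate_prevalences
  n_hh <- config$n_clusters * config$households_per_cluster

  out <- withr_seed(config$seed, {
    households <- tibble(
      household_id = sprintf("hh%03d", seq_len(n_hh)),
      cluster_id = sprintf("c%02d", rep(seq_len(config$n_clusters),
                                        each = config$households_per_cluster)),
      stratum = ifelse(rep(seq_len(config$n_clusters),
                           each = config$households_per_cluster) %%
                         2 == 0, "stratum_b", "stratum_a"),
      earnings_parity = rbinom(n_hh, 1, prev$earnings_parity),
      gravidity = ifelse(rbinom(n_hh, 1, prev$gravidity_1plus) == 1,
                         "1plus", "0"),
      empowerment = rbinom(n_hh, 10, prev$empowerment_prob),
      asset_score = rnorm(n_hh),
      husband_overseas = rbinom(n_hh, 1, prev$husband_overseas),
      caste_group = sample(caste_levels(), n_hh, replace = TRUE,
                           prob = c(0.362, 0.429, 0.209)),
      season = ifelse(rbinom(n_hh, 1, prev$monsoon) == 1,
                      "monsoon", "pre_monsoon")
    )

    members <- make_members(households)

    # energy requirement per member; truth is built on the adequacy scale
    members$energy_ear <- energy_ear(members)

    cl_eff <- setNames(rnorm(config$n_clusters, 0, config$sd_cluster),
                       unique(households$cluster_id))
    ind_eff <- rnorm(nrow(members), 0, config$sd_individual)

    tl <- config$true_log_rdear_mean
    role_offset <- c(
      household_head = 0,
      pregnant_woman = tl[["pw_hh"]],
      mother_in_law = tl[["pw_hh"]] - tl[["pw_mil"]]
    )

    mm <- members |>
      left_join(households[, c("household_id", "cluster_id",
                               "earnings_parity")], by = "household_id")
    # covariate effect on the pregnant woman's adequacy, centred at the
    # realised sample mean so the crude mean log-RDEAR stays at the target
    parity_centred <- mm$earnings_parity - mean(households$earnings_parity)
    cov_eff <- ifelse(mm$role == "pregnant_woman",
                      config$earnings_effect * parity_centred, 0)

    log_adequacy <- config$log_adequacy_hh_mean +
      role_offset[mm$role] +
      cl_eff[mm$cluster_id] +
      ind_eff +
      cov_eff

    truth_members <- tibble(
      member_id = mm$member_id,
      household_id = mm$household_id,
      cluster_id = mm$cluster_id,
      role = mm$role,
      energy_ear = mm$energy_ear,
      log_adequacy = unname(log_adequacy),
      true_usual_energy = mm$energy_ear * exp(unname(log_adequacy))
    )
    list(households = households, members = members,
         truth_members = truth_members)
  })

  households <- out$households
  members <- out$members
  truth_members <- out$truth_members

  # per-household true log allocation ratios implied by the truth
  wide <- truth_members |>
    mutate(la = .data$log_adequacy) |>
    select("household_id", "role", "la") |>
    pivot_wider(names_from = "role", values_from = "la")
  truth_households <- tibble(
    household_id = wide$household_id,
    true_log_rdear_pw_hh = wide$pregnant_woman - wide$household_head,
    true_log_rdear_pw_mil = wide$pregnant_woman - wide$mother_in_law,
    true_log_rdear_mil_hh = wide$mother_in_law - wide$household_head
  ) |>
    left_join(households[, c("household_id", "earnings_parity")],
              by = "household_id")

  truth_members <- add_true_micronutrients(truth_members, config, fct,
                                           households)

  list(
    households = households,
    members = select(members, -"energy_ear"),
    ground_truth = list(members = truth_members,
                        households = truth_households,
                        config = config)
  )
}

make_members <- function(households) {
  n_hh <- nrow(households)
  role <- rep(hh_roles(), times = n_hh)
  hh <- rep(households$household_id, each = 3)
  n <- length(role)
  age <- numeric(n)
  weight <- numeric(n)
  activity <- character(n)
  is_pw <- role == "pregnant_woman"
  is_mil <- role == "mother_in_law"
  is_hh <- role == "household_head"
  age[is_pw] <- pmin(pmax(round(rnorm(sum(is_pw), 22, 3)), 16), 40)
  age[is_mil] <- pmin(pmax(round(rnorm(sum(is_mil), 50, 7)), 38), 75)
  age[is_hh] <- pmin(pmax(round(rnorm(sum(is_hh), 40, 12)), 22), 75)
  weight[is_pw] <- pmax(rnorm(sum(is_pw), 52, 6), 35)
  weight[is_mil] <- pmax(rnorm(sum(is_mil), 48, 7), 32)
  weight[is_hh] <- pmax(rnorm(sum(is_hh), 58, 8), 40)
  activity[is_pw] <- sample(activity_levels(), sum(is_pw), TRUE,
                            prob = c(0.3, 0.6, 0.1))
  activity[is_mil] <- sample(activity_levels(), sum(is_mil), TRUE,
                             prob = c(0.4, 0.5, 0.1))
  activity[is_hh] <- sample(activity_levels(), sum(is_hh), TRUE,
                            prob = c(0.2, 0.5, 0.3))
  tibble(
    member_id = paste0(hh, "_", c("pw", "mil", "hhh")[match(role, hh_roles())]),
    household_id = hh,
    role = role,
    sex = ifelse(is_hh, "male", "female"),
    age = age,
    body_weight = round(weight, 1),
    gestational_age = ifelse(is_pw, sample(28:40, n, TRUE,
                                           prob = dnorm(28:40, 36, 2.5)), NA_real_),
    activity_level = activity,
    illness_any = rbinom(n, 1, ifelse(is_hh, 0.07, 0.12)) == 1,
    fasting_any = rbinom(n, 1, ifelse(is_pw, 0.10, ifelse(is_mil, 0.13, 0.09))) == 1
  )
}

# expected-basket micronutrient truth: expected grams per food scaled so
# the expected basket's energy equals the member's true usual energy
add_true_micronutrients <- function(truth_members, config, fct, households) {
  probs <- config$food_use_probs %||% default_food_use_probs()
  pp <- config$portion_lognormal_params %||% default_portion_params()
  basket <- probs |>
    pivot_longer(-"food_code", names_to = "role", values_to = "p_use") |>
    left_join(pp, by = "food_code") |>
    mutate(e_grams = .data$p_use * exp(.data$meanlog + .data$sdlog^2 / 2)) |>
    left_join(fct, by = "food_code")

  hh_kcal <- household_kcal_truth(truth_members)
  tilt <- pw_density_tilt(config, hh_kcal)

  per_member <- truth_members |>
    left_join(tilt, by = "household_id")
  per_member$tilt <- replace_na_with(per_member$tilt, 0)

  nut_cols <- hh_nutrients()
  dense <- dense_group_foods(fct)

  # vectorised over members x foods
  res <- lapply(seq_len(nrow(per_member)), function(i) {
    b <- basket[basket$role == per_member$role[i], ]
    p <- b$p_use
    if (per_member$role[i] == "pregnant_woman" && per_member$tilt[i] != 0) {
      odds <- p / (1 - pmin(p, 0.999)) * exp(per_member$tilt[i])
      p <- ifelse(b$food_code %in% dense, odds / (1 + odds), p)
    }
    eg <- p * exp(b$meanlog + b$sdlog^2 / 2)
    raw_energy <- sum(eg * b$energy_kcal / 100)
    scale <- per_member$true_usual_energy[i] / raw_energy
    colSums(eg * scale * as.matrix(b[, nut_cols]) / 100)
  })
  res <- do.call(rbind, res)
  colnames(res) <- paste0("true_usual_", nut_cols)
  res <- as_tibble(res)
  res$true_usual_energy_kcal <- NULL  # energy truth is exact, not basket-based
  bind_cols(truth_members, res)
}

household_kcal_truth <- function(truth_members) {
  truth_members |>
    group_by(.data$household_id) |>
    summarise(hh_mean_kcal = mean(.data$true_usual_energy), .groups = "drop")
}

pw_density_tilt <- function(config, hh_kcal) {
  beta <- config$hh_kcal_effect_on_log_mpa_ratio
  centred <- hh_kcal$hh_mean_kcal / 1000 - mean(hh_kcal$hh_mean_kcal) / 1000
  tibble(household_id = hh_kcal$household_id, tilt = beta * centred)
}

dense_group_foods <- function(fct) {
  fct$food_code[fct$mddw_group %in%
                  c("pulses", "nuts_seeds", "dairy", "meat_poultry_fish",
                    "eggs", "dark_green_leafy_veg", "vitamin_a_fruits_veg",
                    "other_fruits")]
}

#' Generate 3-visit recall data for simulated members
#'
#' Draws, for every member, three recall days: the day's target energy is
#' the member's true usual energy times a log-normal day factor
#' (`sd_day`), foods are included by per-day Bernoulli draws at the
#' configured per-role probabilities (the staple is always present), raw
#' portion sizes are log-normal, and all grams are then rescaled so the
#' day's summed energy matches the target exactly. Micronutrient intakes
#' follow from the realised basket composition.
#'
#' @param config A [sim_config()].
#' @param members Member tibble from [generate_households()].
#' @param fct Food composition table.
#' @param ground_truth Ground-truth list from [generate_households()].
#' @return A list with tibbles `visits` and `portions`.
#' @export
generate_recalls <- function(config, members, fct, ground_truth) {
  config <- validate_sim_config(config)
  probs <- config$food_use_probs %||% default_food_use_probs()
  pp <- config$portion_lognormal_params %||% default_portion_params()
  truth <- ground_truth$members

  hh_kcal <- household_kcal_truth(truth)
  tilt <- pw_density_tilt(config, hh_kcal)
  dense <- dense_group_foods(fct)

  withr_seed(config$seed + 1L, {
    md <- tidyr::expand_grid(
      member_id = members$member_id,
      visit_index = 1:3
    ) |>
      left_join(members[, c("member_id", "household_id", "role")],
                by = "member_id") |>
      left_join(truth[, c("member_id", "true_usual_energy")],
                by = "member_id")
    md$day_target <- md$true_usual_energy *
      exp(rnorm(nrow(md), 0, config$sd_day))

    long_probs <- probs |>
      pivot_longer(-"food_code", names_to = "role", values_to = "p_use")

    grid <- md |>
      left_join(long_probs, by = "role", relationship = "many-to-many") |>
      left_join(tilt, by = "household_id") |>
      left_join(pp, by = "food_code")
    grid$tilt <- replace_na_with(grid$tilt, 0)
    tilted <- grid$role == "pregnant_woman" & grid$tilt != 0 &
      grid$food_code %in% dense
    if (any(tilted)) {
      odds <- grid$p_use[tilted] / (1 - pmin(grid$p_use[tilted], 0.999)) *
        exp(grid$tilt[tilted])
      grid$p_use[tilted] <- odds / (1 + odds)
    }

    grid$include <- rbinom(nrow(grid), 1, grid$p_use) == 1
    # staple always consumed so every day has positive energy
    grid$include[grid$food_code == "rice"] <- TRUE
    grid <- grid[grid$include, ]
    grid$grams_raw <- rlnorm(nrow(grid), grid$meanlog, grid$sdlog)

    energy_lu <- setNames(fct$energy_kcal, fct$food_code)
    grid$raw_energy <- grid$grams_raw * energy_lu[grid$food_code] / 100
    grid <- grid |>
      group_by(.data$member_id, .data$visit_index) |>
      mutate(grams = .data$grams_raw * first(.data$day_target) /
               sum(.data$raw_energy)) |>
      ungroup()

    grid$hour <- sample(c(7L, 9L, 12L, 16L, 19L), nrow(grid), TRUE,
                        prob = c(0.25, 0.1, 0.3, 0.1, 0.25))
    grid$location <- ifelse(
      grid$role == "household_head" & runif(nrow(grid)) < 0.25,
      "outside", "home")

    portions <- grid |>
      select("member_id", "visit_index", "food_code", "grams", "hour",
             "location") |>
      arrange(.data$member_id, .data$visit_index, .data$food_code)

    visits <- md |>
      select("member_id", "visit_index", "role") |>
      mutate(proxy_respondent = .data$visit_index > 1 &
               runif(nrow(md)) < ifelse(.data$role == "household_head", 0.35,
                                        ifelse(.data$role == "mother_in_law",
                                               0.2, 0))) |>
      select("member_id", "visit_index", "proxy_respondent") |>
      arrange(.data$member_id, .data$visit_index)

    list(visits = visits, portions = portions)
  })
}

#' Simulate a complete synthetic study
#'
#' One-call wrapper: generates the food composition table, households,
#' members, ground truth and 3-visit recall data from a single
#' configuration, and validates the result against the package data model.
#'
#' @param config A [sim_config()]; `sim_config()` defaults are the study
#'   conditions the package emulates.
#' @return A named list: `households`, `members`, `visits`, `portions`,
#'   `fct`, `ground_truth`.
#' @examples
#' study <- simulate_study(sim_config(n_clusters = 4,
#'                                    households_per_cluster = 3,
#'                                    seed = 7))
#' nrow(study$households)
#' @export
simulate_study <- function(config = sim_config()) {
  fct <- generate_fct(config$seed)
  hh <- generate_households(config, fct = fct)
  rec <- generate_recalls(config, hh$members, fct, hh$ground_truth)
  tables <- validate_tables(list(households = hh$households,
                                 members = hh$members,
                                 visits = rec$visits,
                                 portions = rec$portions))
  c(tables, list(fct = fct, ground_truth = hh$ground_truth))
}

# --- small local utilities ----------------------------------------------

# evaluate `code` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

replace_na_with <- function(x, value) {
  x[is.na(x)] <- value
  x
}
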