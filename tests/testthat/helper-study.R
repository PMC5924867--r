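# shared small simulated study, built once per test run
.fixtures <- new.env(parent = emptyenv())

tiny_study <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- simulate_study(
      sim_config(n_clusters = 4, households_per_cluster = 3, seed = 42)
    )
  }
  .fixtures$tiny
}

tiny_profiles <- function() {
  if (is.null(.fixtures$tiny_profiles)) {
    s <- tiny_study()
    .fixtures$tiny_profiles <- intake_profiles(s$portions, s$visits, s$fct)
  }
  .fixtures$tiny_profiles
}

# a minimal hand-built study: 1 household, 3 members, identical diets
handmade_study <- function(grams = c(rice = 300, lentil_dal = 100)) {
  households <- tibble::tibble(
    household_id = "h1", cluster_id = "c1", stratum = "s1",
    earnings_parity = 0, gravidity = "0", empowerment = 5,
    asset_score = 0, husband_overseas = 0,
    caste_group = "middle", season = "monsoon"
  )
  members <- tibble::tibble(
    member_id = c("m_pw", "m_mil", "m_hh"),
    household_id = "h1",
    role = hh_roles(),
    sex = c("female", "female", "male"),
    age = c(22, 50, 40),
    body_weight = c(52, 48, 58),
    gestational_age = c(36, NA, NA),
    activity_level = "moderate",
    illness_any = FALSE, fasting_any = FALSE
  )
  visits <- tidyr::expand_grid(member_id = members$member_id,
                               visit_index = 1:3) |>
    dplyr::mutate(proxy_respondent = FALSE)
  portions <- tidyr::expand_grid(member_id = members$member_id,
                                 visit_index = 1:3,
                                 food_code = names(grams)) |>
    dplyr::mutate(grams = unname(grams[food_code]), hour = 12L,
                  location = "home")
  list(households = households, members = members, visits = visits,
       portions = portions, fct = generate_fct(1))
}
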