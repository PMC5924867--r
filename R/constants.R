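#' Nutrient and food-group vocabularies
#'
#' Column vocabularies used throughout the package. `hh_nutrients()` returns
#' the 13 nutrient column names carried on every composition and intake
#' table (energy, protein and 11 micronutrients); `hh_micronutrients()`
#' returns the 11 micronutrients entering the mean probability of adequacy
#' (MPA); `mddw_groups()` returns the 10 food groups of the Minimum Dietary
#' Diversity for Women (MDD-W) indicator; `hh_roles()` the three household
#' member roles; `hh_pairs()` the three within-household comparison pairs.
#'
#' @return A character vector.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
hh_nutrients <- function() {
  c("energy_kcal", "protein_g", hh_micronutrients())
}

#' @rdname vocabularies
#' @export
hh_micronutrients <- function() {
  c("vitamin_c_mg", "vitamin_a_re", "thiamin_mg", "riboflavin_mg",
    "niacin_mg", "vitamin_b6_mg", "folate_ug", "vitamin_b12_ug",
    "iron_mg", "zinc_mg", "calcium_mg")
}

#' @rdname vocabularies
#' @export
mddw_groups <- function() {
  c("grains_roots_tubers", "pulses", "nuts_seeds", "dairy",
    "meat_poultry_fish", "eggs", "dark_green_leafy_veg",
    "vitamin_a_fruits_veg", "other_vegetables", "other_fruits")
}

# groups carried on composition tables but never counted in MDD-W
food_groups_all <- function() c(mddw_groups(), "alcohol", "other")

#' @rdname vocabularies
#' @export
hh_roles <- function() {
  c("pregnant_woman", "mother_in_law", "household_head")
}

#' @rdname vocabularies
#' @export
hh_pairs <- function() {
  c("pw_hh", "pw_mil", "mil_hh")
}

# (numerator, denominator) roles for each comparison pair
pair_members <- function() {
  list(
    pw_hh  = c(a = "pregnant_woman", b = "household_head"),
    pw_mil = c(a = "pregnant_woman", b = "mother_in_law"),
    mil_hh = c(a = "mother_in_law", b = "household_head")
  )
}

caste_levels <- function() {
  c("disadvantaged", "middle", "least_disadvantaged")
}

season_levels <- function() c("pre_monsoon", "monsoon")

activity_levels <- function() c("sedentary", "moderate", "heavy")
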