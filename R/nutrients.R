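#' Average replicate recipe observations into one composition row
#'
#' Mixed dishes are entered in the food composition table as a single row
#' whose per-100 g composition is the element-wise arithmetic mean of the
#' replicate recipe observations collected for that dish.
#'
#' @param observations Tibble with one row per observed recipe and the
#'   nutrient columns of [hh_nutrients()] (per 100 g).
#' @param food_code,name,mddw_group Identity of the resulting dish row.
#' @return A one-row FCT tibble.
#' @export
average_recipes <- function(observations, food_code, name = food_code,
                            mddw_group = "other") {
  observations <- as_tibble(observations)
  require_columns(observations, hh_nutrients(), "recipe observations")
  if (nrow(observations) == 0) {
    abort("average_recipes() needs at least one observation",
          class = "hh_validation_error")
  }
  means <- colMeans(as.matrix(observations[, hh_nutrients()]))
  bind_cols(tibble(food_code = food_code, name = name,
                   mddw_group = mddw_group),
            as_tibble(as.list(means)))
}

#' Total nutrients from portion records
#'
#' Converts portion records (grams of a food code) into nutrient intakes
#' by linear combination with the food composition table: each portion
#' contributes `grams / 100 * per_100g`, and portions are summed within
#' each member-visit.
#'
#' @param portions Portion tibble (`member_id`, `visit_index`,
#'   `food_code`, `grams`, ...).
#' @param fct Food composition table; every `food_code` in `portions` must
#'   be present.
#' @return A tibble with one row per (`member_id`, `visit_index`) present
#'   in `portions` and one column per nutrient in [hh_nutrients()].
#' @export
portions_to_intake <- function(portions, fct) {
  fct <- validate_fct(fct)
  unknown <- setdiff(unique(portions$food_code), fct$food_code)
  if (length(unknown) > 0) {
    abort(sprintf("food code(s) missing from the FCT: %s",
                  paste(unknown, collapse = ", ")),
          class = "hh_lookup_error")
  }
  nut <- hh_nutrients()
  if (nrow(portions) == 0) {
    empty <- c(list(member_id = character(0), visit_index = integer(0)),
               setNames(rep(list(numeric(0)), length(nut)), nut))
    return(as_tibble(empty))
  }
  joined <- portions |>
    left_join(fct[, c("food_code", nut)], by = "food_code")
  joined[nut] <- joined[nut] * joined$grams / 100
  joined |>
    group_by(.data$member_id, .data$visit_index) |>
    summarise(across(all_of(nut), sum), .groups = "drop")
}

#' Per-member intake profiles: mean intakes, food-group grams and MDD-W
#'
#' Builds one profile row per member from their 1-3 recall visits:
#'
#' * mean daily nutrient intakes, the arithmetic mean over the member's
#'   available visits (visits with no recorded portions count as zero
#'   intake days);
#' * mean daily grams per food group over the recall period, and a
#'   consumed-any flag per group (any positive grams on any visit);
#' * the MDD-W dietary diversity score, counted on the first visit only
#'   (the reference period for which the indicator was validated), as the
#'   number of the 10 MDD-W groups consumed; alcohol and `other` never
#'   count towards the score;
#' * `mddw_adequate`: `TRUE` when the score is at least 5 groups.
#'
#' @param portions,visits Tibbles as in [read_tables()].
#' @param fct Food composition table.
#' @return A tibble with one row per member appearing in `visits`.
#' @export
intake_profiles <- function(portions, visits, fct) {
  fct <- validate_fct(fct)
  if (nrow(visits) == 0) {
    abort("intake_profiles() needs at least one visit",
          class = "hh_validation_error")
  }
  nut <- hh_nutrients()

  per_visit <- portions_to_intake(portions, fct)
  # zero-intake visits contribute zero rows to the averages
  per_visit <- visits |>
    select("member_id", "visit_index") |>
    left_join(per_visit, by = c("member_id", "visit_index"))
  per_visit[nut] <- lapply(per_visit[nut], replace_na_with, 0)

  mean_intakes <- per_visit |>
    group_by(.data$member_id) |>
    summarise(n_visits = dplyr::n(), across(all_of(nut), mean),
              .groups = "drop")

  # food-group grams per visit, averaged over the recall period
  grp <- portions |>
    left_join(fct[, c("food_code", "mddw_group")], by = "food_code") |>
    group_by(.data$member_id, .data$visit_index, .data$mddw_group) |>
    summarise(grams = sum(.data$grams), .groups = "drop")

  n_visits_lu <- mean_intakes |> select("member_id", "n_visits")
  group_means <- grp |>
    group_by(.data$member_id, .data$mddw_group) |>
    summarise(total = sum(.data$grams),
              any = any(.data$grams > 0), .groups = "drop") |>
    left_join(n_visits_lu, by = "member_id") |>
    mutate(mean_grams = .data$total / .data$n_visits)

  all_groups <- c(mddw_groups(), "alcohol")
  grams_wide <- group_means |>
    filter(.data$mddw_group %in% all_groups) |>
    select("member_id", "mddw_group", "mean_grams") |>
    pivot_wider(names_from = "mddw_group", values_from = "mean_grams",
                names_prefix = "grams_") |>
    ensure_columns(paste0("grams_", all_groups), 0)
  any_wide <- group_means |>
    filter(.data$mddw_group %in% all_groups) |>
    select("member_id", "mddw_group", "any") |>
    pivot_wider(names_from = "mddw_group", values_from = "any",
                names_prefix = "any_") |>
    ensure_columns(paste0("any_", all_groups), FALSE)

  mddw <- portions |>
    filter(.data$visit_index == 1, .data$grams > 0) |>
    left_join(fct[, c("food_code", "mddw_group")], by = "food_code") |>
    filter(.data$mddw_group %in% mddw_groups()) |>
    distinct(.data$member_id, .data$mddw_group) |>
    dplyr::count(.data$member_id, name = "mddw_score")

  out <- mean_intakes |>
    left_join(grams_wide, by = "member_id") |>
    left_join(any_wide, by = "member_id") |>
    left_join(mddw, by = "member_id")
  for (col in paste0("grams_", all_groups)) {
    out[[col]] <- replace_na_with(out[[col]], 0)
  }
  for (col in paste0("any_", all_groups)) {
    out[[col]] <- replace_na_with(out[[col]], FALSE)
  }
  out$mddw_score <- as.integer(replace_na_with(out$mddw_score, 0L))
  out$mddw_adequate <- out$mddw_score >= 5L
  out
}

ensure_columns <- function(x, cols, fill) {
  for (col in setdiff(cols, names(x))) x[[col]] <- fill
  x[, c(setdiff(names(x), cols), cols)]
}
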