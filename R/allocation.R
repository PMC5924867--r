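#' Pairwise allocation ratio primitives
#'
#' Scalar (vectorised) building blocks for intra-household allocation
#' statistics between two members `a` and `b`:
#'
#' * `food_share()` — ratio of food-group gram intakes, defined only when
#'   both members consumed any of the group (`NA` otherwise);
#' * `fs_es()` — food share to energy share,
#'   `(food_a / kcal_a) / (food_b / kcal_b)`: the relative per-kcal
#'   contribution of the group to each diet;
#' * `rdear()` — relative dietary energy adequacy ratio,
#'   `(intake_a / EAR_a) / (intake_b / EAR_b)`;
#' * `mpa_ratio()` — ratio of mean probabilities of adequacy,
#'   `MPA_a / MPA_b`;
#' * `classify_disparity()` — flags a household pair as starkly disparate
#'   when member `a` consumes less than 90% of their energy requirement
#'   while member `b` consumes more than 110% of theirs.
#'
#' All ratio primitives satisfy `f(a, b) * f(b, a) = 1` where defined.
#'
#' @param grams_a,grams_b Food-group intakes in grams (>= 0).
#' @return Numeric ratio (or `NA` where the statistic is undefined);
#'   `classify_disparity()` returns logical.
#' @name allocation_primitives
NULL

#' @rdname allocation_primitives
#' @export
food_share <- function(grams_a, grams_b) {
  if (any(grams_a < 0, na.rm = TRUE) || any(grams_b < 0, na.rm = TRUE)) {
    abort("food_share(): grams must be >= 0", class = "hh_validation_error")
  }
  if_else(grams_a > 0 & grams_b > 0, grams_a / grams_b, NA_real_)
}

#' @rdname allocation_primitives
#' @param food_a,food_b Food-group intakes (g); `kcal_a,kcal_b` total
#'   energy intakes (kcal, > 0).
#' @export
fs_es <- function(food_a, kcal_a, food_b, kcal_b) {
  if (any(kcal_a <= 0, na.rm = TRUE) || any(kcal_b <= 0, na.rm = TRUE)) {
    abort("fs_es(): kcal intakes must be > 0", class = "hh_validation_error")
  }
  if (any(food_a < 0, na.rm = TRUE) || any(food_b < 0, na.rm = TRUE)) {
    abort("fs_es(): food intakes must be >= 0",
          class = "hh_validation_error")
  }
  if_else(food_a > 0 & food_b > 0,
          (food_a / kcal_a) / (food_b / kcal_b), NA_real_)
}

#' @rdname allocation_primitives
#' @param intake_a,intake_b Energy intakes (kcal/d); `ear_a,ear_b` energy
#'   requirements (kcal/d, > 0).
#' @export
rdear <- function(intake_a, ear_a, intake_b, ear_b) {
  if (any(ear_a <= 0, na.rm = TRUE) || any(ear_b <= 0, na.rm = TRUE)) {
    abort("rdear(): energy EARs must be > 0", class = "hh_validation_error")
  }
  if_else(intake_a > 0 & intake_b > 0,
          (intake_a / ear_a) / (intake_b / ear_b), NA_real_)
}

#' @rdname allocation_primitives
#' @param mpa_a,mpa_b Mean probabilities of adequacy; `mpa_b` must be
#'   positive.
#' @export
mpa_ratio <- function(mpa_a, mpa_b) {
  if (any(mpa_b == 0, na.rm = TRUE)) {
    abort("mpa_ratio(): undefined when the denominator MPA is 0",
          class = "hh_validation_error")
  }
  mpa_a / mpa_b
}

#' @rdname allocation_primitives
#' @param adequacy_a,adequacy_b Energy intakes as fractions of the
#'   members' EARs; `low,high` the disparity thresholds (defaults 0.90
#'   and 1.10).
#' @export
classify_disparity <- function(adequacy_a, adequacy_b,
                               low = 0.90, high = 1.10) {
  if (any(adequacy_a < 0, na.rm = TRUE) || any(adequacy_b < 0, na.rm = TRUE)) {
    abort("energy adequacies must be >= 0", class = "hh_validation_error")
  }
  adequacy_a < low & adequacy_b > high
}

#' Household-pair allocation ratio table
#'
#' Builds the full allocation table: one row per household and comparison
#' pair (pregnant woman : household head, pregnant woman : mother-in-law,
#' mother-in-law : household head), with per-food-group food shares (FS)
#' and food-shares-to-energy-shares (FS:ES), the relative dietary energy
#' adequacy ratio (RDEAR), the MPA ratio, dietary-diversity ratios, their
#' natural logs, and the extreme-outlier exclusion flag
#' (`log_mpa_ratio < -8`).
#'
#' Food-group ratios and RDEAR use mean intakes over the 3-day recall
#' period; MPA ratios use the model-based (BLUP) MPA values. The
#' dietary-diversity columns follow the convention of the equity tables:
#' `log_dd_ratio` is the log ratio of the two MDD-W scores and
#' `log_dd_es` is that log ratio adjusted by (minus) the members' log
#' kcal-intake ratio.
#'
#' @param profiles Intake profiles from [intake_profiles()].
#' @param members Member tibble.
#' @param adequacy Adequacy table from [compute_adequacy()] (for MPA
#'   ratios); optional — MPA columns are `NA` when omitted.
#' @param energy_ears Optional tibble (`member_id`, `energy_ear`);
#'   computed with [energy_ear()] defaults when `NULL`.
#' @param mpa_log_cutoff Exclusion threshold on the log MPA ratio
#'   (default -8, lower tail only).
#' @return Tibble, one row per household x pair.
#' @export
allocation_ratios <- function(profiles, members, adequacy = NULL,
                              energy_ears = NULL, mpa_log_cutoff = -8) {
  if (is.null(energy_ears)) {
    energy_ears <- tibble(member_id = members$member_id,
                          energy_ear = energy_ear(members))
  }
  per_member <- members |>
    select("member_id", "household_id", "role") |>
    left_join(profiles, by = "member_id") |>
    left_join(energy_ears, by = "member_id")
  if (!is.null(adequacy)) {
    per_member <- per_member |>
      left_join(adequacy[, c("member_id", "mpa")], by = "member_id")
  } else {
    per_member$mpa <- NA_real_
  }

  pairs <- pair_members()
  rows <- map(names(pairs), function(pr) {
    a <- per_member[per_member$role == pairs[[pr]][["a"]], ]
    b <- per_member[per_member$role == pairs[[pr]][["b"]], ]
    key <- intersect(a$household_id, b$household_id)
    a <- a[match(key, a$household_id), ]
    b <- b[match(key, b$household_id), ]
    out <- tibble(household_id = key, pair = pr)
    for (g in mddw_groups()) {
      ga <- a[[paste0("grams_", g)]]
      gb <- b[[paste0("grams_", g)]]
      out[[paste0("fs_", g)]] <- food_share(ga, gb)
      out[[paste0("fs_es_", g)]] <- fs_es(ga, a$energy_kcal,
                                          gb, b$energy_kcal)
    }
    out$kcal_ratio <- a$energy_kcal / b$energy_kcal
    out$rdear <- rdear(a$energy_kcal, a$energy_ear,
                       b$energy_kcal, b$energy_ear)
    out$energy_adequacy_a <- a$energy_kcal / a$energy_ear
    out$energy_adequacy_b <- b$energy_kcal / b$energy_ear
    out$disparity_flag <- classify_disparity(out$energy_adequacy_a,
                                             out$energy_adequacy_b)
    out$mpa_ratio <- if_else(!is.na(a$mpa) & !is.na(b$mpa) & b$mpa > 0,
                             a$mpa / b$mpa, NA_real_)
    out$dd_ratio <- if_else(a$mddw_score > 0 & b$mddw_score > 0,
                            a$mddw_score / b$mddw_score, NA_real_)
    out
  }) |> list_rbind()

  for (g in mddw_groups()) {
    rows[[paste0("log_fs_", g)]] <- log(rows[[paste0("fs_", g)]])
    rows[[paste0("log_fs_es_", g)]] <- log(rows[[paste0("fs_es_", g)]])
  }
  rows$log_kcal_ratio <- log(rows$kcal_ratio)
  rows$log_rdear <- log(rows$rdear)
  rows$log_mpa_ratio <- log(rows$mpa_ratio)
  rows$log_dd_ratio <- log(rows$dd_ratio)
  rows$log_dd_es <- rows$log_dd_ratio - rows$log_kcal_ratio
  rows$excluded_mpa_outlier <- !is.na(rows$log_mpa_ratio) &
    rows$log_mpa_ratio < mpa_log_cutoff
  rows
}
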