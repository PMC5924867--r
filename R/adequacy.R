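#' Default micronutrient requirement distributions per member role
#'
#' Ships the estimated average requirements (EAR mean and SD of the
#' normal requirement distribution) used for the probability-of-adequacy
#' calculations, per nutrient and member role: WHO/FAO values for the B
#' vitamins, vitamin C and folate; IOM values for calcium and iron
#' (pregnant iron at 23% absorption); IZiNCG values for zinc (25%
#' absorption for women, 18% for men). Iron for non-pregnant adults is
#' not normally distributed and is marked `kind = "tabulated"`; its PA
#' comes from the interval probability table (see
#' [build_iron_probability_table()]). Bioavailability enters only through
#' these requirement parameters, never by rescaling intakes.
#'
#' @return Tibble with columns `role`, `nutrient`, `kind` (`normal` or
#'   `tabulated`), `ear_mean`, `ear_sd`, `source`.
#' @export
default_requirements <- function() {
  req <- function(role, nutrient, mean, sd, source) {
    tibble(role = role, nutrient = nutrient, kind = "normal",
           ear_mean = mean, ear_sd = sd, source = source)
  }
  pw <- "pregnant_woman"; mil <- "mother_in_law"; hh <- "household_head"
  whofao <- "WHO/FAO"; iom <- "IOM"; izincg <- "IZiNCG"
  out <- bind_rows(
    req(pw, "vitamin_c_mg", 40, 4.0, whofao),
    req(pw, "vitamin_a_re", 370, 74, whofao),
    req(pw, "thiamin_mg", 1.2, 0.1, whofao),
    req(pw, "riboflavin_mg", 1.2, 0.1, whofao),
    req(pw, "niacin_mg", 14, 2.1, whofao),
    req(pw, "vitamin_b6_mg", 1.6, 0.2, whofao),
    req(pw, "folate_ug", 520, 52, whofao),
    req(pw, "vitamin_b12_ug", 2.2, 0.2, whofao),
    req(pw, "iron_mg", 22, 2.1, paste(iom, "23% absorption")),
    req(pw, "zinc_mg", 12, 1.5, paste(izincg, "25% absorption")),
    req(pw, "calcium_mg", 800, 100, iom),

    req(mil, "vitamin_c_mg", 30, 3.0, whofao),
    req(mil, "vitamin_a_re", 270, 54, whofao),
    req(mil, "thiamin_mg", 0.9, 0.1, whofao),
    req(mil, "riboflavin_mg", 0.9, 0.1, whofao),
    req(mil, "niacin_mg", 11, 1.7, whofao),
    req(mil, "vitamin_b6_mg", 1.1, 0.1, whofao),
    req(mil, "folate_ug", 320, 32, whofao),
    req(mil, "vitamin_b12_ug", 2.0, 0.2, whofao),
    tibble(role = mil, nutrient = "iron_mg", kind = "tabulated",
           ear_mean = NA_real_, ear_sd = NA_real_,
           source = paste(iom, "5% bioavailability table")),
    req(mil, "zinc_mg", 7, 0.9, paste(izincg, "25% absorption")),
    req(mil, "calcium_mg", 800, 100, iom),

    req(hh, "vitamin_c_mg", 40, 4.0, whofao),
    req(hh, "vitamin_a_re", 300, 60, whofao),
    req(hh, "thiamin_mg", 1.0, 0.1, whofao),
    req(hh, "riboflavin_mg", 1.0, 0.1, whofao),
    req(hh, "niacin_mg", 12, 1.8, whofao),
    req(hh, "vitamin_b6_mg", 1.1, 0.1, whofao),
    req(hh, "folate_ug", 320, 32, whofao),
    req(hh, "vitamin_b12_ug", 2.0, 0.2, whofao),
    tibble(role = hh, nutrient = "iron_mg", kind = "tabulated",
           ear_mean = NA_real_, ear_sd = NA_real_,
           source = paste(iom, "5% bioavailability table")),
    req(hh, "zinc_mg", 15, 1.9, paste(izincg, "18% absorption")),
    req(hh, "calcium_mg", 800, 100, iom)
  )
  out
}

#' Energy requirement coefficients and the energy EAR
#'
#' Energy requirements are computed per member as the per-kilogram
#' coefficient for the member's sex and self-reported activity level
#' (Indian Council of Medical Research reference-adult values, editable)
#' times body weight, plus a fixed 390 kcal/d increment for pregnancy.
#'
#' @return `default_energy_coefficients()`: a tibble (`sex`,
#'   `activity_level`, `kcal_per_kg`).
#' @export
default_energy_coefficients <- function() {
  tidyr::expand_grid(sex = c("female", "male"),
                     activity_level = activity_levels()) |>
    mutate(kcal_per_kg = c(34.5, 40.5, 51.8, 38.7, 45.5, 58.2))
}

#' @rdname default_energy_coefficients
#' @param members Member tibble (`sex`, `activity_level`, `body_weight`,
#'   `role`).
#' @param coefficients Coefficient tibble, as
#'   [default_energy_coefficients()].
#' @param pregnancy_increment Additional energy cost of pregnancy,
#'   kcal/d.
#' @return `energy_ear()`: numeric vector of kcal/day, one per member
#'   row.
#' @export
energy_ear <- function(members, coefficients = default_energy_coefficients(),
                       pregnancy_increment = 390) {
  require_columns(members, c("sex", "activity_level", "body_weight", "role"),
                  "members")
  if (any(is.na(members$body_weight)) || any(is.na(members$activity_level))) {
    abort("energy_ear(): body_weight and activity_level must be present",
          class = "hh_validation_error")
  }
  if (any(coefficients$kcal_per_kg <= 0)) {
    abort("energy coefficients must be > 0", class = "hh_config_error")
  }
  joined <- members |>
    left_join(coefficients, by = c("sex", "activity_level"))
  if (any(is.na(joined$kcal_per_kg))) {
    abort("no energy coefficient for some sex x activity_level combination",
          class = "hh_config_error")
  }
  joined$kcal_per_kg * joined$body_weight +
    ifelse(joined$role == "pregnant_woman", pregnancy_increment, 0)
}

#' Probability of adequacy against a normal requirement distribution
#'
#' The probability that a usual intake meets the individual's own
#' requirement, when requirements are normal with mean `ear_mean` (the
#' EAR) and SD `ear_sd`: `pnorm((usual - ear_mean) / ear_sd)`. At the EAR
#' the probability is exactly 0.5.
#'
#' @param usual Usual intake (requirement units/day); vectorised.
#' @param ear_mean,ear_sd Requirement distribution parameters
#'   (`ear_sd > 0`).
#' @return Probability in `[0, 1]`.
#' @export
pa_normal <- function(usual, ear_mean, ear_sd) {
  if (any(!is.finite(ear_sd)) || any(ear_sd <= 0)) {
    abort("pa_normal() needs a normal requirement distribution with sd > 0; use pa_iron_tabulated() for tabulated requirements",
          class = "hh_type_error")
  }
  pnorm((usual - ear_mean) / ear_sd)
}

#' Build the tabulated iron probability-of-adequacy table
#'
#' Iron requirements of non-pregnant adults are right-skewed, so their PA
#' is read from a table of probabilities per usual-intake interval rather
#' than a normal curve. The table is constructed by numerical integration
#' of a log-normal absorbed-requirement distribution rescaled to dietary
#' intake units at the assumed bioavailability (default 5%): each
#' interval's probability is the requirement CDF evaluated at the
#' interval midpoint, i.e. the probability that a requirement drawn from
#' the distribution is covered by an intake in that interval. Intervals
#' are kept narrow (0.25 mg) so the piecewise-constant table tracks the
#' continuous CDF to well under 0.02 everywhere. The copy shipped in
#' `inst/extdata/iron_pa_table_5pct.csv` is frozen output of this
#' function.
#'
#' @param sex `"female"` (non-pregnant adult woman) or `"male"`.
#' @param bioavailability Absorbed fraction of ingested iron.
#' @param absorbed_median,absorbed_sdlog Median (mg/d) and log-scale SD of
#'   the absorbed-requirement log-normal distribution; defaults follow
#'   the IOM percentile spread for menstruating women and adult men.
#' @param step,upper Interval width and top bound, mg/d of dietary iron.
#' @return Tibble (`sex`, `lower_bound`, `upper_bound`, `probability`)
#'   with probabilities nondecreasing in intake.
#' @export
build_iron_probability_table <- function(sex = "female",
                                         bioavailability = 0.05,
                                         absorbed_median = NULL,
                                         absorbed_sdlog = NULL,
                                         step = 0.25, upper = 80) {
  sex <- match.arg(sex, c("female", "male"))
  defaults <- list(female = c(median = 1.46, sdlog = 0.39),
                   male = c(median = 1.00, sdlog = 0.20))
  absorbed_median <- absorbed_median %||% defaults[[sex]][["median"]]
  absorbed_sdlog <- absorbed_sdlog %||% defaults[[sex]][["sdlog"]]
  if (bioavailability <= 0 || bioavailability > 1) {
    abort("bioavailability must be in (0, 1]", class = "hh_config_error")
  }
  meanlog <- log(absorbed_median / bioavailability)
  lower <- seq(0, upper - step, by = step)
  mid <- lower + step / 2
  tibble(sex = sex,
         lower_bound = lower,
         upper_bound = lower + step,
         probability = plnorm(mid, meanlog, absorbed_sdlog))
}

#' The iron probability table shipped with the package
#'
#' Reads the frozen 5%-bioavailability table (both sexes) from the
#' package's `extdata`; identical to calling
#' [build_iron_probability_table()] at its defaults.
#'
#' @return Tibble as in [build_iron_probability_table()] with both sexes
#'   stacked.
#' @export
default_iron_table <- function() {
  path <- system.file("extdata", "iron_pa_table_5pct.csv",
                      package = "hhequity", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Probability of adequacy from a tabulated requirement
#'
#' Looks up the probability of the interval containing the usual intake.
#' Intakes below the lowest bound take the lowest interval's probability;
#' intakes above the highest bound take the highest.
#'
#' @param usual Usual iron intake, mg/day; vectorised.
#' @param table Interval table (`upper_bound`, `probability`), ordered by
#'   intake, e.g. one sex's rows of [default_iron_table()].
#' @return Probability in `[0, 1]`.
#' @export
pa_iron_tabulated <- function(usual, table) {
  if (is.null(table) || nrow(table) == 0) {
    abort("empty iron probability table", class = "hh_validation_error")
  }
  table <- table[order(table$upper_bound), ]
  if (is.unsorted(table$probability)) {
    abort("iron table probabilities must be nondecreasing in intake",
          class = "hh_validation_error")
  }
  idx <- findInterval(usual, table$upper_bound, left.open = TRUE) + 1L
  idx <- pmin(pmax(idx, 1L), nrow(table))
  table$probability[idx]
}

#' Mean probability of adequacy over the 11 micronutrients
#'
#' @param pa Named numeric vector of probabilities of adequacy; the names
#'   must be exactly the 11 micronutrients of [hh_micronutrients()]
#'   (energy and protein are never included).
#' @return The arithmetic mean, in `[0, 1]`.
#' @export
mpa <- function(pa) {
  nms <- names(pa)
  missing <- setdiff(hh_micronutrients(), nms)
  extra <- setdiff(nms, hh_micronutrients())
  if (length(missing) > 0 || length(extra) > 0) {
    abort(sprintf(
      "mpa() needs exactly the 11 micronutrient PAs%s%s",
      if (length(missing)) paste0("; missing: ",
                                  paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ",
                                paste(extra, collapse = ", ")) else ""),
      class = "hh_validation_error")
  }
  if (any(pa < 0 | pa > 1)) {
    abort("probabilities of adequacy must lie in [0, 1]",
          class = "hh_validation_error")
  }
  mean(unname(pa[hh_micronutrients()]))
}

#' Per-member probability of adequacy and MPA
#'
#' Combines usual micronutrient intakes with the requirement
#' distributions: normal-kind nutrients through [pa_normal()], tabulated
#' iron (non-pregnant members) through [pa_iron_tabulated()] using the
#' member's sex, then averages the 11 PAs into the MPA.
#'
#' @param usual Long tibble (`member_id`, `nutrient`, `usual`) as from
#'   [usual_intakes()]; micronutrient rows are used.
#' @param members Member tibble (for `role` and `sex`).
#' @param requirements Requirement tibble, default
#'   [default_requirements()].
#' @param iron_table Tabulated iron PA table, default
#'   [default_iron_table()].
#' @return Tibble: `member_id`, `role`, one `pa_<nutrient>` column per
#'   micronutrient, `mpa`.
#' @export
compute_adequacy <- function(usual, members,
                             requirements = default_requirements(),
                             iron_table = default_iron_table()) {
  dat <- usual |>
    filter(.data$nutrient %in% hh_micronutrients()) |>
    left_join(members[, c("member_id", "role", "sex")], by = "member_id") |>
    left_join(requirements, by = c("role", "nutrient"))
  if (any(is.na(dat$kind))) {
    bad <- dat[is.na(dat$kind), ][1, ]
    abort(sprintf("no requirement distribution for %s / %s",
                  bad$nutrient, bad$role),
          class = "hh_config_error")
  }
  normal <- dat$kind == "normal"
  dat$pa <- NA_real_
  dat$pa[normal] <- pa_normal(dat$usual[normal], dat$ear_mean[normal],
                              dat$ear_sd[normal])
  for (sx in unique(dat$sex[!normal])) {
    sel <- !normal & dat$sex == sx
    dat$pa[sel] <- pa_iron_tabulated(dat$usual[sel],
                                     iron_table[iron_table$sex == sx, ])
  }
  counts <- dat |> dplyr::count(.data$member_id)
  if (any(counts$n != 11)) {
    abort(sprintf("member %s has %d micronutrient PAs (expected 11)",
                  counts$member_id[counts$n != 11][1],
                  counts$n[counts$n != 11][1]),
          class = "hh_validation_error")
  }
  wide <- dat |>
    select("member_id", "role", "nutrient", "pa") |>
    pivot_wider(names_from = "nutrient", values_from = "pa",
                names_prefix = "pa_")
  wide$mpa <- rowMeans(wide[, paste0("pa_", hh_micronutrients())])
  wide
}
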