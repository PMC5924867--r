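#' Read and validate the study input tables
#'
#' Reads the four tabular inputs of the analysis — the household roster, the
#' member roster, the recall-visit index and the portion records — from CSV
#' (UTF-8, comma-separated, header row required), validates each against the
#' data model, and checks referential integrity: every portion row must
#' belong to a declared visit, every visit to a declared member, and every
#' member to a declared household.
#'
#' Expected columns:
#' * `households.csv`: `household_id`, `cluster_id`, `stratum`,
#'   `earnings_parity` (0/1, pregnant woman earns same or more than her
#'   spouse), `gravidity` (`"0"` or `"1plus"` previous pregnancies),
#'   `empowerment` (integer 0-10), `asset_score`, `husband_overseas` (0/1),
#'   `caste_group` (`disadvantaged`, `middle`, `least_disadvantaged`),
#'   `season` (`pre_monsoon`, `monsoon`).
#' * `members.csv`: `member_id`, `household_id`, `role` (`pregnant_woman`,
#'   `mother_in_law`, `household_head`), `sex`, `age`, `body_weight` (kg),
#'   `gestational_age` (weeks; present iff pregnant), `activity_level`
#'   (`sedentary`, `moderate`, `heavy`), `illness_any`, `fasting_any`.
#' * `visits.csv`: `member_id`, `visit_index` (1-3), `proxy_respondent`.
#' * `portions.csv`: `member_id`, `visit_index`, `food_code`, `grams`,
#'   `hour` (0-23), `location` (`home`, `outside`).
#'
#' @param paths Either a directory containing `households.csv`,
#'   `members.csv`, `visits.csv` and `portions.csv`, or a named list/vector
#'   with elements `households`, `members`, `visits`, `portions` giving file
#'   paths.
#' @return A named list of validated tibbles: `households`, `members`,
#'   `visits`, `portions`.
#' @seealso [write_tables()], [read_fct()]
#' @export
read_tables <- function(paths) {
  paths <- resolve_table_paths(paths)
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing) > 0) {
    abort(sprintf("input file(s) not found: %s",
                  paste(unlist(missing), collapse = ", ")),
          class = "hh_io_error")
  }
  tables <- list(
    households = readr::read_csv(paths$households, show_col_types = FALSE),
    members    = readr::read_csv(paths$members, show_col_types = FALSE),
    visits     = readr::read_csv(paths$visits, show_col_types = FALSE),
    portions   = readr::read_csv(paths$portions, show_col_types = FALSE)
  )
  validate_tables(tables)
}

resolve_table_paths <- function(paths) {
  wanted <- c("households", "members", "visits", "portions")
  if (is.character(paths) && length(paths) == 1 && is.null(names(paths))) {
    paths <- setNames(file.path(paths, paste0(wanted, ".csv")), wanted)
  }
  paths <- as.list(paths)
  if (!all(wanted %in% names(paths))) {
    abort(sprintf("`paths` must name files for: %s",
                  paste(setdiff(wanted, names(paths)), collapse = ", ")),
          class = "hh_config_error")
  }
  paths[wanted]
}

#' Validate a set of study tables
#'
#' Applies the full data model: field types and ranges, categorical levels,
#' the one-member-per-role-per-household rule, visit-index uniqueness, and
#' referential integrity across tables. Called by [read_tables()]; exported
#' so that programmatically built tables (e.g. from [simulate_study()]) can
#' be checked with the same contract.
#'
#' @param tables Named list with tibbles `households`, `members`, `visits`,
#'   `portions`.
#' @return The validated tables, invisibly unchanged, as a named list.
#' @export
validate_tables <- function(tables) {
  households <- validate_households(tables$households)
  members <- validate_members(tables$members)
  visits <- validate_visits(tables$visits)
  portions <- validate_portions(tables$portions)

  orphan <- anti_join(members, households, by = "household_id")
  if (nrow(orphan) > 0) {
    abort(sprintf("member(s) reference unknown household_id: %s",
                  paste(unique(orphan$household_id), collapse = ", ")),
          class = "hh_validation_error")
  }
  orphan <- anti_join(visits, members, by = "member_id")
  if (nrow(orphan) > 0) {
    abort(sprintf("visit(s) reference unknown member_id: %s",
                  paste(unique(orphan$member_id), collapse = ", ")),
          class = "hh_validation_error")
  }
  orphan <- anti_join(portions, visits, by = c("member_id", "visit_index"))
  if (nrow(orphan) > 0) {
    abort(sprintf("portion row(s) reference undeclared visits: %s",
                  paste(unique(paste0(orphan$member_id, "/visit",
                                      orphan$visit_index)), collapse = ", ")),
          class = "hh_validation_error")
  }
  list(households = households, members = members,
       visits = visits, portions = portions)
}

validate_households <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("household_id", "cluster_id", "stratum",
                       "earnings_parity", "gravidity", "empowerment",
                       "asset_score", "husband_overseas", "caste_group",
                       "season"), "households")
  if (anyDuplicated(x$household_id)) {
    abort(sprintf("duplicate household_id: %s",
                  paste(unique(x$household_id[duplicated(x$household_id)]),
                        collapse = ", ")),
          class = "hh_validation_error")
  }
  check_range(x, "empowerment", 0, 10, "households")
  check_levels(x, "gravidity", c("0", "1plus"), "households")
  check_levels(x, "caste_group", caste_levels(), "households")
  check_levels(x, "season", season_levels(), "households")
  check_flag(x, "earnings_parity", "households")
  check_flag(x, "husband_overseas", "households")
  x
}

validate_members <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("member_id", "household_id", "role", "sex", "age",
                       "body_weight", "gestational_age", "activity_level",
                       "illness_any", "fasting_any"), "members")
  if (anyDuplicated(x$member_id)) {
    abort("duplicate member_id in members table",
          class = "hh_validation_error")
  }
  check_levels(x, "role", hh_roles(), "members")
  check_levels(x, "sex", c("female", "male"), "members")
  check_levels(x, "activity_level", activity_levels(), "members")
  bad <- which(!is.finite(x$body_weight) | x$body_weight <= 0)
  if (length(bad) > 0) {
    abort(sprintf("members row %s: body_weight must be > 0", bad[1]),
          class = "hh_validation_error")
  }
  # the fixed study triad: exactly one member per role per household
  counts <- x |>
    dplyr::count(.data$household_id, .data$role)
  if (any(counts$n > 1)) {
    offender <- counts[counts$n > 1, ][1, ]
    abort(sprintf("household %s has %d members with role %s (expected 1)",
                  offender$household_id, offender$n, offender$role),
          class = "hh_validation_error")
  }
  per_hh <- counts |> dplyr::count(.data$household_id)
  if (any(per_hh$n != 3)) {
    offender <- per_hh$household_id[per_hh$n != 3][1]
    abort(sprintf(
      "household %s does not have the full pregnant_woman/mother_in_law/household_head triad",
      offender), class = "hh_validation_error")
  }
  preg <- x$role == "pregnant_woman"
  if (any(is.na(x$gestational_age[preg]))) {
    abort("gestational_age missing for a pregnant_woman row",
          class = "hh_validation_error")
  }
  if (any(!is.na(x$gestational_age[!preg]))) {
    bad <- x$member_id[!preg & !is.na(x$gestational_age)][1]
    abort(sprintf("member %s: gestational_age present but role is not pregnant_woman",
                  bad), class = "hh_validation_error")
  }
  x
}

validate_visits <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("member_id", "visit_index", "proxy_respondent"),
                  "visits")
  if (!all(x$visit_index %in% 1:3)) {
    bad <- which(!x$visit_index %in% 1:3)[1]
    abort(sprintf("visits row %d: visit_index must be 1, 2 or 3", bad),
          class = "hh_validation_error")
  }
  dup <- duplicated(x[, c("member_id", "visit_index")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("duplicate visit: member %s visit %d",
                  x$member_id[i], x$visit_index[i]),
          class = "hh_validation_error")
  }
  check_flag(x, "proxy_respondent", "visits")
  x
}

validate_portions <- function(x) {
  x <- as_tibble(x)
  require_columns(x, c("member_id", "visit_index", "food_code", "grams",
                       "hour", "location"), "portions")
  bad <- which(!is.finite(x$grams) | x$grams < 0)
  if (length(bad) > 0) {
    abort(sprintf("portions row %d: grams must be >= 0", bad[1]),
          class = "hh_validation_error")
  }
  bad <- which(!x$hour %in% 0:23)
  if (length(bad) > 0) {
    abort(sprintf("portions row %d: hour must be in 0..23", bad[1]),
          class = "hh_validation_error")
  }
  check_levels(x, "location", c("home", "outside"), "portions")
  x
}

#' Write the study tables to CSV
#'
#' Inverse of [read_tables()]: writes `households.csv`, `members.csv`,
#' `visits.csv` and `portions.csv` into `dir`, so that
#' `read_tables(dir)` reproduces the tables field for field.
#'
#' @param tables Named list as returned by [read_tables()] or
#'   [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("households", "members", "visits", "portions")) {
    if (!is.null(tables[[nm]])) {
      readr::write_csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       na = "")
    }
  }
  invisible(dir)
}

#' Read or write a food composition table
#'
#' The food composition table (FCT) holds one row per food code: a display
#' name, the MDD-W food group (one of the ten scored groups, `alcohol`, or
#' `other`), and the per-100 g nutrient vector (energy, protein and the 11
#' micronutrients named by [hh_nutrients()]).
#'
#' @param path CSV file path.
#' @return `read_fct()`: a validated FCT tibble.
#' @export
read_fct <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FCT file not found: %s", path), class = "hh_io_error")
  }
  validate_fct(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_fct
#' @param fct FCT tibble.
#' @export
write_fct <- function(fct, path) {
  readr::write_csv(validate_fct(fct), path, na = "")
  invisible(path)
}

validate_fct <- function(fct) {
  fct <- as_tibble(fct)
  require_columns(fct, c("food_code", "name", "mddw_group", hh_nutrients()),
                  "fct")
  if (anyDuplicated(fct$food_code)) {
    abort("duplicate food_code in FCT", class = "hh_validation_error")
  }
  check_levels(fct, "mddw_group", food_groups_all(), "fct")
  vals <- as.matrix(fct[, hh_nutrients()])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("FCT nutrient values must be finite and >= 0",
          class = "hh_validation_error")
  }
  fct
}

# --- shared checks -------------------------------------------------------

require_columns <- function(x, cols, table) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s table is missing column(s): %s",
                  table, paste(miss, collapse = ", ")),
          class = "hh_validation_error")
  }
  invisible(x)
}

check_levels <- function(x, col, levels, table) {
  bad <- which(!x[[col]] %in% levels)
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: %s = '%s' is not one of {%s}",
                  table, bad[1], col, x[[col]][bad[1]],
                  paste(levels, collapse = ", ")),
          class = "hh_validation_error")
  }
  invisible(x)
}

check_range <- function(x, col, lo, hi, table) {
  bad <- which(!is.finite(x[[col]]) | x[[col]] < lo | x[[col]] > hi)
  if (length(bad) > 0) {
    abort(sprintf("%s row %d: %s = %s outside [%s, %s]",
                  table, bad[1], col, x[[col]][bad[1]], lo, hi),
          class = "hh_validation_error")
  }
  invisible(x)
}

check_flag <- function(x, col, table) {
  v <- x[[col]]
  ok <- is.logical(v) | v %in% c(0, 1)
  if (!all(ok)) {
    abort(sprintf("%s: %s must be logical or 0/1", table, col),
          class = "hh_validation_error")
  }
  invisible(x)
}
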