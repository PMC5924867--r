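#' Plot food-group consumption by household member
#'
#' Bar chart of the percentage of each member role consuming any of each
#' MDD-W food group (plus alcohol) over the recall period.
#'
#' @param profiles Intake profiles from [intake_profiles()].
#' @param members Member table (for roles).
#' @return A ggplot object.
#' @export
plot_food_group_consumption <- function(profiles, members) {
  any_cols <- paste0("any_", c(mddw_groups(), "alcohol"))
  dat <- profiles |>
    left_join(members[, c("member_id", "role")], by = "member_id") |>
    pivot_longer(all_of(any_cols), names_to = "group",
                 values_to = "consumed") |>
    mutate(group = sub("^any_", "", .data$group)) |>
    group_by(.data$role, .data$group) |>
    summarise(pct = 100 * mean(.data$consumed), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$pct,
                                    fill = .data$role)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% consuming any", fill = "Member") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of MPA by household member
#'
#' @param adequacy Adequacy table from [compute_adequacy()].
#' @return A ggplot object.
#' @export
plot_mpa <- function(adequacy) {
  ggplot2::ggplot(adequacy, ggplot2::aes(x = .data$role, y = .data$mpa)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Mean probability of adequacy") +
    ggplot2::theme_minimal()
}

#' Forest plot of equity tests
#'
#' Displays the estimated mean log allocation ratios with their 95%
#' confidence intervals; zero marks perfect equity.
#'
#' @param equity Tidy equity-test table from [equity_tests()].
#' @return A ggplot object.
#' @export
plot_equity <- function(equity) {
  ggplot2::ggplot(equity,
                  ggplot2::aes(x = .data$estimate, y = .data$outcome,
                               colour = .data$pair)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2, position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Mean log ratio (95% CI)", y = NULL,
                  colour = "Pair") +
    ggplot2::theme_minimal()
}

#' @rdname plot_equity
#' @param object An `equity_test`.
#' @param ... Unused.
#' @export
autoplot.equity_test <- function(object, ...) {
  plot_equity(dplyr::mutate(tidy(object), pair = object$label))
}
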