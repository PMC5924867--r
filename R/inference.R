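#' Test intra-household equity of a log allocation ratio
#'
#' Perfectly equitable allocation corresponds to a log ratio of zero, so
#' equity is tested by fitting an intercept-only linear mixed model to the
#' log ratios with a random intercept per sampling cluster and asking
#' whether the intercept differs from zero. Estimation is by maximum
#' likelihood; confidence intervals and P values are Wald-type with a t
#' reference on `n_clusters - 1` degrees of freedom, the standard
#' small-sample correction for cluster-level inference (a plain normal
#' reference is anti-conservative with tens of clusters).
#'
#' @param data Tibble holding the log ratios and a cluster column.
#' @param outcome Name of the log-ratio column (string).
#' @param cluster Name of the cluster column (string, default
#'   `"cluster_id"`).
#' @param label Optional display label for the outcome.
#' @return An object of class `equity_test`; see [tidy.equity_test()].
#' @export
test_equity <- function(data, outcome, cluster = "cluster_id",
                        label = outcome) {
  require_columns(data, c(outcome, cluster), "equity-test input")
  y <- data[[outcome]]
  cl <- data[[cluster]]
  keep <- is.finite(y) & !is.na(cl)
  y <- y[keep]
  cl <- cl[keep]
  if (length(y) == 0) {
    abort(sprintf("no non-missing values of %s", outcome),
          class = "hh_validation_error")
  }
  if (dplyr::n_distinct(cl) < 2) {
    abort("test_equity() needs at least 2 clusters",
          class = "hh_model_error")
  }
  if (var(y) == 0) {
    # degenerate: identical ratios in every household
    est <- y[1]
    res <- list(estimate = est, se = 0,
                conf.low = est, conf.high = est,
                p.value = if (est == 0) 1 else 0,
                var_cluster = 0, var_residual = 0, fit = NULL)
  } else if (dplyr::n_distinct(cl) < length(y)) {
    df <- tibble(y = y, cluster = cl)
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | cluster), data = df, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    ))
    est <- unname(lme4::fixef(fit)[1])
    se <- sqrt(as.numeric(stats::vcov(fit)[1, 1]))
    df <- dplyr::n_distinct(cl) - 1
    tv <- est / se
    vc <- as.data.frame(lme4::VarCorr(fit))
    res <- list(estimate = est, se = se,
                conf.low = est - stats::qt(0.975, df) * se,
                conf.high = est + stats::qt(0.975, df) * se,
                p.value = 2 * stats::pt(-abs(tv), df),
                var_cluster = vc$vcov[vc$grp == "cluster"],
                var_residual = vc$vcov[vc$grp == "Residual"],
                fit = fit)
  } else {
    # every observation sits in its own cluster: the cluster variance is
    # unidentifiable, so the model reduces to the intercept-only fit
    fit <- lm(y ~ 1)
    est <- unname(coef(fit)[1])
    se <- unname(sqrt(diag(stats::vcov(fit)))[1])
    df <- length(y) - 1
    tv <- est / se
    res <- list(estimate = est, se = se,
                conf.low = est - stats::qt(0.975, df) * se,
                conf.high = est + stats::qt(0.975, df) * se,
                p.value = 2 * stats::pt(-abs(tv), df),
                var_cluster = 0,
                var_residual = stats::sigma(fit)^2,
                fit = fit)
  }
  structure(c(list(outcome = outcome, label = label, n = length(y),
                   n_clusters = dplyr::n_distinct(cl)),
              res),
            class = "equity_test")
}

#' @export
print.equity_test <- function(x, ...) {
  cat(sprintf("Equity test: %s (n = %d, %d clusters)\n",
              x$label, x$n, x$n_clusters))
  cat(sprintf("  mean %.3f (95%% CI %.3f, %.3f), P = %.3g\n",
              x$estimate, x$conf.low, x$conf.high, x$p.value))
  invisible(x)
}

#' Tidy an equity test
#'
#' @param x An `equity_test`.
#' @param ... Unused.
#' @return One-row tibble: `outcome`, `n`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.equity_test <- function(x, ...) {
  tibble(outcome = x$label, n = x$n, estimate = x$estimate,
         std.error = x$se, conf.low = x$conf.low, conf.high = x$conf.high,
         p.value = x$p.value)
}

#' @rdname tidy.equity_test
#' @export
glance.equity_test <- function(x, ...) {
  tibble(n = x$n, n_clusters = x$n_clusters,
         var_cluster = x$var_cluster, var_residual = x$var_residual)
}

#' Equity tests over many outcomes and pairs
#'
#' Runs [test_equity()] for each requested log-ratio column of the
#' allocation table, separately per comparison pair, dropping missing
#' values and (for the MPA ratio) the flagged extreme outliers.
#'
#' @param ratios Allocation table from [allocation_ratios()].
#' @param households Household table (for `cluster_id`).
#' @param outcomes Log-ratio column names; defaults to every `log_*`
#'   column present except the kcal ratio.
#' @param pairs Which pairs to test (default all three).
#' @param drop_excluded Drop rows flagged `excluded_mpa_outlier` for the
#'   `log_mpa_ratio` outcome (default `TRUE`).
#' @return Tidy tibble, one row per pair x outcome.
#' @export
equity_tests <- function(ratios, households, outcomes = NULL,
                         pairs = hh_pairs(), drop_excluded = TRUE) {
  outcomes <- outcomes %||%
    setdiff(grep("^log_", names(ratios), value = TRUE), "log_kcal_ratio")
  dat <- ratios |>
    left_join(households[, c("household_id", "cluster_id")],
              by = "household_id")
  out <- list()
  for (pr in pairs) {
    sub <- dat[dat$pair == pr, ]
    for (oc in outcomes) {
      keep <- if (drop_excluded && oc == "log_mpa_ratio") {
        !sub$excluded_mpa_outlier
      } else {
        rep(TRUE, nrow(sub))
      }
      vals <- sub[[oc]][keep]
      ok <- is.finite(vals)
      # untestable outcomes (nobody consumed, or a single cluster) are
      # skipped rather than reported with a meaningless interval
      if (sum(ok) < 3 ||
          dplyr::n_distinct(sub$cluster_id[keep][ok]) < 2) next
      tt <- test_equity(sub[keep, ], oc)
      row <- tidy(tt)
      row$pair <- pr
      out[[length(out) + 1]] <- row
    }
  }
  list_rbind(out) |> select("pair", dplyr::everything())
}

#' Variance inflation factors
#'
#' Collinearity diagnostic for a covariate matrix: each covariate is
#' regressed on all the others and its VIF is `1 / (1 - R^2)`.
#'
#' @param x Numeric data frame or matrix with at least two columns, full
#'   column rank.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) {
    abort("vif() needs at least 2 covariates", class = "hh_validation_error")
  }
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-10) {
      abort(sprintf("covariate %s is collinear with the others (VIF infinite)",
                    colnames(x)[j] %||% j),
            class = "hh_model_error")
    }
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' The hypothesised determinants of allocation
#'
#' @return Character vector of the default covariate set for
#'   [fit_determinants()]: earnings parity, gravidity, empowerment score,
#'   asset score, household mean energy intake per 1000 kcal, husband
#'   working overseas, caste group and season.
#' @export
determinant_covariates <- function() {
  c("earnings_parity", "gravidity", "empowerment", "asset_score",
    "hh_kcal_per_1000", "husband_overseas", "caste_group", "season")
}

#' Assemble the determinants model frame
#'
#' Joins one pair's allocation outcomes to the household covariates, adds
#' the household mean energy intake (average over the three members' 3-day
#' mean intakes) rescaled per 1000 kcal, and applies the reference-level
#' coding used in the equity tables: earning less than the spouse, no
#' previous pregnancy, husband not overseas, the most disadvantaged caste
#' group, and pre-monsoon season are the reference levels.
#'
#' @param ratios Allocation table from [allocation_ratios()].
#' @param households Household table.
#' @param profiles Intake profiles (for household mean kcal).
#' @param members Member table.
#' @param pair Which comparison pair to keep.
#' @return Tibble ready for [fit_determinants()].
#' @export
determinant_frame <- function(ratios, households, profiles, members,
                              pair = "pw_hh") {
  hh_kcal <- members |>
    select("member_id", "household_id") |>
    left_join(profiles[, c("member_id", "energy_kcal")], by = "member_id") |>
    group_by(.data$household_id) |>
    summarise(hh_kcal_per_1000 = mean(.data$energy_kcal) / 1000,
              .groups = "drop")
  ratios[ratios$pair == pair, ] |>
    left_join(households, by = "household_id") |>
    left_join(hh_kcal, by = "household_id") |>
    mutate(
      gravidity = factor(.data$gravidity, levels = c("0", "1plus")),
      caste_group = factor(.data$caste_group, levels = caste_levels()),
      season = factor(.data$season, levels = season_levels())
    )
}

#' Multivariable determinants of allocation
#'
#' Fits the determinants model for one log-ratio outcome: a linear mixed
#' model with a cluster random intercept, adjusting simultaneously for
#' all hypothesised determinants (maximum likelihood; Wald-type
#' inference on a t reference with `n_clusters - 1` degrees of freedom).
#' Optionally adds a quadratic wealth (asset score) term to probe
#' nonlinear wealth effects. Variance inflation factors are computed for
#' the fixed-effect columns. Constant covariates are dropped with a
#' warning (with none left the model degenerates to the [test_equity()]
#' intercept model); genuinely collinear covariates raise an error naming
#' the offending columns.
#'
#' @param data Model frame from [determinant_frame()].
#' @param outcome Log-ratio outcome column (string).
#' @param covariates Covariate names (default
#'   [determinant_covariates()]).
#' @param cluster Cluster column name.
#' @param quadratic_wealth Add `asset_score^2` (default `FALSE`).
#' @param drop_excluded Drop flagged MPA-ratio outliers when modelling
#'   `log_mpa_ratio`.
#' @return Object of class `determinants_fit` with [tidy()] and
#'   [glance()] methods.
#' @export
fit_determinants <- function(data, outcome,
                             covariates = determinant_covariates(),
                             cluster = "cluster_id",
                             quadratic_wealth = FALSE,
                             drop_excluded = TRUE) {
  require_columns(data, c(outcome, cluster, covariates),
                  "determinants input")
  keep <- is.finite(data[[outcome]])
  if (drop_excluded && outcome == "log_mpa_ratio" &&
      "excluded_mpa_outlier" %in% names(data)) {
    keep <- keep & !data$excluded_mpa_outlier
  }
  dat <- data[keep, , drop = FALSE]
  dat <- dat[stats::complete.cases(dat[, c(outcome, cluster, covariates)]), ]
  for (col in covariates) {
    if (is.factor(dat[[col]])) dat[[col]] <- droplevels(dat[[col]])
  }
  if (nrow(dat) == 0) {
    abort("no complete observations for the determinants model",
          class = "hh_validation_error")
  }

  constant <- covariates[vapply(covariates, function(v) {
    dplyr::n_distinct(dat[[v]]) < 2
  }, logical(1))]
  if (length(constant) > 0) {
    warn(sprintf("dropping constant covariate(s): %s",
                 paste(constant, collapse = ", ")))
    covariates <- setdiff(covariates, constant)
  }

  if (quadratic_wealth && "asset_score" %in% covariates) {
    dat$asset_score_sq <- dat$asset_score^2
    covariates <- append(covariates, "asset_score_sq",
                         after = match("asset_score", covariates))
  }

  if (length(covariates) == 0) {
    et <- test_equity(dat, outcome, cluster)
    terms <- tidy(et) |>
      mutate(term = "(Intercept)", vif = NA_real_) |>
      select("term", "estimate", "std.error", "conf.low", "conf.high",
             "p.value", "vif")
    return(structure(list(outcome = outcome, n = et$n,
                          terms = terms, vifs = NULL, fit = et$fit,
                          covariates = character(0)),
                     class = "determinants_fit"))
  }

  rhs <- paste(covariates, collapse = " + ")
  mm <- model.matrix(as.formula(paste("~", rhs)), dat)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    abort(sprintf("determinants design is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")),
          class = "hh_model_error")
  }
  vifs <- if (ncol(mm) > 2) vif(mm[, -1, drop = FALSE]) else NULL

  dat$.cluster <- dat[[cluster]]
  form <- as.formula(paste(outcome, "~", rhs, "+ (1 | .cluster)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  df <- dplyr::n_distinct(dat$.cluster) - 1
  tv <- est / se
  # map each design column to its VIF (factor columns carry their own)
  vif_by_term <- if (is.null(vifs)) {
    setNames(rep(NA_real_, length(est)), names(est))
  } else {
    c("(Intercept)" = NA_real_, vifs)[names(est)]
  }
  terms <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    conf.low = unname(est - stats::qt(0.975, df) * se),
    conf.high = unname(est + stats::qt(0.975, df) * se),
    p.value = unname(2 * stats::pt(-abs(tv), df)),
    vif = unname(vif_by_term)
  )
  structure(list(outcome = outcome, n = nrow(dat), terms = terms,
                 vifs = vifs, fit = fit, covariates = covariates),
            class = "determinants_fit")
}

#' @export
print.determinants_fit <- function(x, ...) {
  cat(sprintf("Determinants model: %s (n = %d)\n", x$outcome, x$n))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' Tidy a determinants fit
#'
#' @param x A `determinants_fit`.
#' @param ... Unused.
#' @return Tibble of per-term estimates, Wald CIs, P values and VIFs.
#' @export
tidy.determinants_fit <- function(x, ...) {
  out <- x$terms
  out$outcome <- x$outcome
  select(out, "outcome", dplyr::everything())
}

#' @rdname tidy.determinants_fit
#' @export
glance.determinants_fit <- function(x, ...) {
  tibble(outcome = x$outcome, n = x$n,
         max_vif = if (is.null(x$vifs)) NA_real_ else max(x$vifs),
         logLik = if (is.null(x$fit)) NA_real_ else
           as.numeric(stats::logLik(x$fit)))
}

#' Convert a log-ratio coefficient to a percent statement
#'
#' A coefficient `c` on a log ratio corresponds to a multiplicative
#' effect `exp(c)`: nonnegative coefficients are reported as
#' `100 * (exp(c) - 1)` percent *higher*, negative ones as
#' `100 * (1 - exp(c))` percent *lower*. Displayed percentages are
#' rounded half-up to the nearest integer.
#'
#' @param coefficient Numeric vector of log-scale coefficients.
#' @return Tibble: `log_coeff`, `percent_raw` (unrounded), `percent`
#'   (half-up integer), `direction` (`higher`/`lower`), `label` (e.g.
#'   `"31% higher"`).
#' @export
pct_from_log <- function(coefficient) {
  if (any(!is.finite(coefficient))) {
    abort("coefficients must be finite", class = "hh_validation_error")
  }
  raw <- ifelse(coefficient >= 0,
                100 * (exp(coefficient) - 1),
                100 * (1 - exp(coefficient)))
  direction <- ifelse(coefficient >= 0, "higher", "lower")
  # display precision: one decimal place first, then integer, both
  # half-up (so e.g. 37.4997 -> 37.5 -> 38)
  pct <- round_half_up(round_half_up(raw * 10) / 10)
  tibble(log_coeff = coefficient, percent_raw = raw, percent = pct,
         direction = direction,
         label = sprintf("%d%% %s", pct, direction))
}

round_half_up <- function(x) floor(x + 0.5)
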