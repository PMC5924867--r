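#' Fit a Box-Cox transformation to positive (or zero-inflated) intakes
#'
#' Chooses the power `lambda` maximising the profile log-likelihood of the
#' transformed values under normality. Zero intakes are handled by a shift
#' constant added before transforming: zero when all values are positive,
#' otherwise half the smallest positive value.
#'
#' @param values Numeric vector of daily intakes (>= 0); at least 3 values,
#'   not all zero.
#' @param lambda_range Search interval for `lambda`.
#' @return An object of class `boxcox_fit` with elements `lambda` and
#'   `shift`.
#' @seealso [boxcox_transform()], [boxcox_inverse()]
#' @export
fit_boxcox <- function(values, lambda_range = c(-2, 2)) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    abort("fit_boxcox() needs at least 3 finite values",
          class = "hh_validation_error")
  }
  if (any(values < 0)) {
    abort("intakes must be >= 0", class = "hh_validation_error")
  }
  if (all(values == 0)) {
    abort("all intakes are zero; Box-Cox transform undefined",
          class = "hh_validation_error")
  }
  shift <- if (min(values) > 0) 0 else min(values[values > 0]) / 2
  x <- values + shift
  logx <- log(x)
  n <- length(x)
  profile_ll <- function(lambda) {
    y <- boxcox_core(x, lambda)
    -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(logx)
  }
  opt <- optimize(profile_ll, lambda_range, maximum = TRUE, tol = 1e-6)
  structure(list(lambda = opt$maximum, shift = shift),
            class = "boxcox_fit")
}

boxcox_core <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Apply or invert a fitted Box-Cox transformation
#'
#' `boxcox_transform()` maps intakes onto the normalised scale;
#' `boxcox_inverse()` maps transformed values back to intake units
#' (clamped at zero, since intakes are nonnegative). The two are exact
#' inverses on the data's support.
#'
#' @param x Intakes (original units) or transformed values.
#' @param fit A `boxcox_fit` from [fit_boxcox()].
#' @return Numeric vector.
#' @export
boxcox_transform <- function(x, fit) {
  boxcox_core(x + fit$shift, fit$lambda)
}

#' @rdname boxcox_transform
#' @export
boxcox_inverse <- function(x, fit) {
  lambda <- fit$lambda
  y <- if (abs(lambda) < 1e-8) {
    exp(x)
  } else {
    base <- lambda * x + 1
    ifelse(base > 0, base^(1 / lambda), 0)
  }
  pmax(y - fit$shift, 0)
}

#' Fit the usual-intake mixed model for one nutrient and member role
#'
#' Implements the usual-intake estimator: daily intakes are Box-Cox
#' transformed, then modelled with a linear mixed model on the transformed
#' scale with fixed stratum effects and random intercepts for cluster and
#' for individual nested in cluster. The best linear unbiased predictors
#' (BLUPs) of the random effects, back-transformed, give each member's
#' usual intake. Fitted separately per member role, mirroring the design
#' in which the three roles have systematically different diets.
#'
#' @param data Tibble with one row per member-visit: columns `member_id`,
#'   `cluster_id`, `stratum` and the intake in `value`.
#' @param nutrient,role Labels carried on the result (used in error
#'   messages and summaries).
#' @param boxcox Optional pre-fitted [fit_boxcox()] object; fitted on
#'   `data$value` when `NULL`.
#' @return An object of class `usual_intake_model`: the Box-Cox fit, the
#'   lme4 fit, fixed effects, variance components (`var_cluster`,
#'   `var_individual`, `var_residual`), and per-cluster and per-member
#'   BLUP tables.
#' @export
fit_usual_model <- function(data, nutrient = "nutrient", role = "role",
                            boxcox = NULL) {
  require_columns(data, c("member_id", "cluster_id", "stratum", "value"),
                  "usual-intake input")
  if (dplyr::n_distinct(data$cluster_id) < 2) {
    abort(sprintf("usual-intake model for %s/%s needs at least 2 clusters",
                  nutrient, role),
          class = "hh_model_error")
  }
  boxcox <- boxcox %||% fit_boxcox(data$value)
  df <- data
  df$t_value <- boxcox_transform(df$value, boxcox)
  multi_stratum <- dplyr::n_distinct(df$stratum) > 1

  # degenerate day-to-day variation: repeated visits are numerically
  # identical, so the residual variance is 0 and the member-level model
  # carries all the structure
  within_var <- df |>
    group_by(.data$member_id) |>
    summarise(v = var(.data$t_value), n = dplyr::n(), .groups = "drop")
  degenerate <- all(is.na(within_var$v) | within_var$v <
                      1e-12 * max(var(df$t_value), 1e-300))
  if (degenerate) {
    return(fit_usual_model_degenerate(df, nutrient, role, boxcox,
                                      multi_stratum))
  }
  form <- if (multi_stratum) {
    t_value ~ stratum + (1 | cluster_id) + (1 | member_id)
  } else {
    t_value ~ 1 + (1 | cluster_id) + (1 | member_id)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore"))
    )),
    error = function(e) {
      abort(sprintf("usual-intake model failed for %s/%s: %s",
                    nutrient, role, conditionMessage(e)),
            class = "hh_model_error")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v) == 0) 0 else v
  }
  re <- lme4::ranef(fit)
  blup_member <- tibble(member_id = rownames(re$member_id),
                        blup = re$member_id[["(Intercept)"]])
  blup_cluster <- tibble(cluster_id = rownames(re$cluster_id),
                         blup = re$cluster_id[["(Intercept)"]])
  # each member's stratum/cluster for prediction
  key <- df |> distinct(.data$member_id, .data$cluster_id, .data$stratum)
  structure(
    list(nutrient = nutrient, role = role, boxcox = boxcox, fit = fit,
         fixed_effects = lme4::fixef(fit),
         var_cluster = getv("cluster_id"),
         var_individual = getv("member_id"),
         var_residual = vc$vcov[vc$grp == "Residual"],
         blup_member = blup_member, blup_cluster = blup_cluster,
         member_key = key, multi_stratum = multi_stratum),
    class = "usual_intake_model"
  )
}

# member-level fit used when day-to-day variance vanishes: the member
# mean is the BLUP target and only cluster vs individual needs splitting
fit_usual_model_degenerate <- function(df, nutrient, role, boxcox,
                                       multi_stratum) {
  means <- df |>
    group_by(.data$member_id, .data$cluster_id, .data$stratum) |>
    summarise(t_value = mean(.data$t_value), .groups = "drop")
  form <- if (multi_stratum) {
    t_value ~ stratum + (1 | cluster_id)
  } else {
    t_value ~ 1 + (1 | cluster_id)
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = means, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)
  blup_cluster <- tibble(cluster_id = rownames(re$cluster_id),
                         blup = re$cluster_id[["(Intercept)"]])
  # individual effect: the member's exact offset from the fitted mean,
  # so back-transformed usual intake equals the constant observed intake
  means$blup <- means$t_value - stats::predict(fit, newdata = means)
  structure(
    list(nutrient = nutrient, role = role, boxcox = boxcox, fit = fit,
         fixed_effects = lme4::fixef(fit),
         var_cluster = vc$vcov[vc$grp == "cluster_id"],
         var_individual = vc$vcov[vc$grp == "Residual"],
         var_residual = 0,
         blup_member = means[, c("member_id", "blup")],
         blup_cluster = blup_cluster,
         member_key = means[, c("member_id", "cluster_id", "stratum")],
         multi_stratum = multi_stratum),
    class = "usual_intake_model"
  )
}

#' @export
print.usual_intake_model <- function(x, ...) {
  cat(sprintf("Usual-intake model: %s (%s)\n", x$nutrient, x$role))
  cat(sprintf("  Box-Cox lambda %.3f, shift %.4g\n",
              x$boxcox$lambda, x$boxcox$shift))
  cat(sprintf("  var(cluster) %.4g, var(individual) %.4g, var(residual) %.4g\n",
              x$var_cluster, x$var_individual, x$var_residual))
  cat(sprintf("  %d members in %d clusters\n",
              nrow(x$blup_member), nrow(x$blup_cluster)))
  invisible(x)
}

#' Predict back-transformed usual intakes from a fitted model
#'
#' The usual intake of a member is the inverse Box-Cox transform of their
#' linear predictor: intercept + stratum effect + cluster BLUP +
#' individual BLUP. No back-transformation bias correction is applied by
#' default (the plain inverse of the predictor); `bias_correct = TRUE`
#' adds the usual second-order (residual + smearing-free) correction
#' `0.5 * sigma^2 * d2(inverse)/dx2` for sensitivity analysis.
#'
#' @param model A `usual_intake_model`.
#' @param member_ids Members to predict for; default all members seen by
#'   the model.
#' @param bias_correct Apply the second-order back-transformation
#'   correction (default `FALSE`).
#' @return Tibble with `member_id`, `usual` (original units).
#' @export
predict_usual <- function(model, member_ids = NULL, bias_correct = FALSE) {
  key <- model$member_key
  if (!is.null(member_ids)) {
    missing <- setdiff(member_ids, key$member_id)
    if (length(missing) > 0) {
      abort(sprintf("member(s) not in model %s/%s: %s", model$nutrient,
                    model$role, paste(missing, collapse = ", ")),
            class = "hh_lookup_error")
    }
    key <- key[match(member_ids, key$member_id), ]
  }
  fe <- model$fixed_effects
  stratum_eff <- rep(0, nrow(key))
  if (model$multi_stratum) {
    terms <- paste0("stratum", key$stratum)
    stratum_eff <- ifelse(terms %in% names(fe), fe[terms], 0)
    stratum_eff[is.na(stratum_eff)] <- 0
  }
  cl <- setNames(model$blup_cluster$blup, model$blup_cluster$cluster_id)
  mb <- setNames(model$blup_member$blup, model$blup_member$member_id)
  eta <- unname(fe["(Intercept)"] + stratum_eff +
                  replace_na_with(cl[key$cluster_id], 0) +
                  replace_na_with(mb[key$member_id], 0))
  usual <- boxcox_inverse(eta, model$boxcox)
  if (bias_correct) {
    lambda <- model$boxcox$lambda
    sigma2 <- model$var_residual
    d2 <- if (abs(lambda) < 1e-8) {
      exp(eta)
    } else {
      base <- pmax(lambda * eta + 1, 1e-12)
      (1 - lambda) * base^(1 / lambda - 2)
    }
    usual <- pmax(usual + 0.5 * sigma2 * d2, 0)
  }
  tibble(member_id = key$member_id, usual = usual)
}

#' Estimate usual intakes for every nutrient and member role
#'
#' Convenience driver over [fit_usual_model()] and [predict_usual()]:
#' reshapes per-visit intakes to long form, fits one model per nutrient
#' and role, and returns the back-transformed usual intakes.
#'
#' @param per_visit Per-visit intake tibble from [portions_to_intake()].
#' @param members,households Study tables (for role, cluster, stratum).
#' @param nutrients Nutrient columns to model (default all 13).
#' @param bias_correct Passed to [predict_usual()].
#' @return A list with `usual` (tibble `member_id` x `nutrient` x
#'   `usual`) and `models` (named list of `usual_intake_model`s, named
#'   `<nutrient>.<role>`).
#' @export
usual_intakes <- function(per_visit, members, households,
                          nutrients = hh_nutrients(),
                          bias_correct = FALSE) {
  meta <- members |>
    select("member_id", "household_id", "role") |>
    left_join(households[, c("household_id", "cluster_id", "stratum")],
              by = "household_id")
  long <- per_visit |>
    pivot_longer(all_of(nutrients), names_to = "nutrient",
                 values_to = "value") |>
    left_join(meta, by = "member_id")
  combos <- tidyr::expand_grid(nutrient = nutrients, role = hh_roles())
  models <- pmap(combos, function(nutrient, role) {
    dat <- long[long$nutrient == nutrient & long$role == role, ]
    fit_usual_model(dat, nutrient = nutrient, role = role)
  })
  names(models) <- paste(combos$nutrient, combos$role, sep = ".")
  usual <- imap(models, function(m, nm) {
    out <- predict_usual(m, bias_correct = bias_correct)
    out$nutrient <- m$nutrient
    out
  }) |> list_rbind()
  list(usual = usual, models = models)
}

#' Summarise usual-intake models as a tidy table
#'
#' @param models Named list of models from [usual_intakes()].
#' @return One row per nutrient x role: Box-Cox lambda, shift, variance
#'   components, intercept.
#' @export
usual_model_summary <- function(models) {
  map(models, function(m) {
    tibble(nutrient = m$nutrient, role = m$role,
           lambda = m$boxcox$lambda, shift = m$boxcox$shift,
           var_cluster = m$var_cluster,
           var_individual = m$var_individual,
           var_residual = m$var_residual,
           intercept = unname(m$fixed_effects["(Intercept)"]))
  }) |> list_rbind()
}
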