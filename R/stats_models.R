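#' Fit a single-outcome model with random-intercept fallback
#'
#' Fits the outcome by maximum likelihood as a mixed model with a random
#' intercept (by default for colony) using a binomial-logit or gaussian
#' family. When the random-intercept variance is estimated at (numerically)
#' zero — below `var_tol` on the variance scale — the random term explains
#' none of the variance, the model is refitted as a plain GLM/LM and
#' `fallback_applied` is set. Wald statistics are reported per coefficient:
#' z for binomial fits, t with residual degrees of freedom `n - p` for
#' gaussian fits.
#'
#' @param data A data frame holding the response and predictors.
#' @param formula Fixed-effects formula, e.g. `flew ~ treatment * its_mm`.
#' @param family `"binomial"` (logit link) or `"gaussian"`.
#' @param random Name of the grouping column for the random intercept, or
#'   `NULL` to fit a fixed-effects-only model directly.
#' @param var_tol Variance threshold (variance scale) below which the random
#'   intercept is deemed to explain none of the variance.
#' @param transform Optional response transform: `"log"` replaces the
#'   response by its natural log before fitting (values must be positive);
#'   `NULL` fits the response as-is.
#' @return An object of class `mill_fit`; see [tidy.mill_fit()] and
#'   [glance.mill_fit()]. Key fields: `coefficients` (tibble of term,
#'   estimate, std.error, statistic, p.value), `fallback_applied`,
#'   `converged`, `flags`, `ranef_variances`, `n`, `residual_df`, `model`.
#' @export
fit_outcome_model <- function(data, formula, family = c("binomial", "gaussian"),
                              random = "colony_id", var_tol = 1e-8,
                              transform = NULL) {
  family <- match.arg(family)
  response <- all.vars(formula)[1]
  data <- dplyr::filter(data, !is.na(.data[[response]]))
  if (!is.null(transform)) {
    if (!identical(transform, "log")) {
      stop("fit_outcome_model: unsupported transform '", transform, "'",
           call. = FALSE)
    }
    if (any(data[[response]] <= 0)) {
      stop("fit_outcome_model: log transform needs a positive response",
           call. = FALSE)
    }
    data[[response]] <- log(data[[response]])
  }
  flags <- character(0)
  fallback_applied <- FALSE
  ranef_var <- numeric(0)

  if (!is.null(random)) {
    if (!random %in% names(data)) {
      stop("fit_outcome_model: random grouping column '", random,
           "' not in data", call. = FALSE)
    }
    if (dplyr::n_distinct(data[[random]]) < 2) {
      stop("fit_outcome_model: random grouping factor needs >= 2 levels",
           call. = FALSE)
    }
    mixed_formula <- stats::update(
      formula, paste(". ~ . + (1 |", random, ")"))
    mixed <- tryCatch(fit_lme4(mixed_formula, data, family),
                      error = function(e) e)
    if (inherits(mixed, "error")) {
      # the mixed fit failed outright (e.g. quasi-separation); report the
      # fixed-effects fit, flagged rather than silent
      fit <- fit_fixed(formula, data, family)
      return(new_mill_fit(fit$model, family, formula, data, response,
                          fallback_applied = FALSE,
                          flags = unique(c("mixed_fit_failed", fit$flags)),
                          ranef_var = numeric(0), transform = transform,
                          converged = fit$converged))
    }
    flags <- c(flags, mixed$flags)
    vc <- as.data.frame(lme4::VarCorr(mixed$model))
    ranef_var <- stats::setNames(
      vc$vcov[vc$grp != "Residual"],
      vc$grp[vc$grp != "Residual"])
    if (all(ranef_var < var_tol)) {
      fallback_applied <- TRUE
    } else {
      return(new_mill_fit(mixed$model, family, formula, data, response,
                          fallback_applied = FALSE, flags = flags,
                          ranef_var = ranef_var, transform = transform,
                          converged = mixed$converged))
    }
  }
  fit <- fit_fixed(formula, data, family)
  new_mill_fit(fit$model, family, formula, data, response,
               fallback_applied = fallback_applied,
               flags = unique(c(flags, fit$flags)),
               ranef_var = ranef_var, transform = transform,
               converged = fit$converged)
}

# lme4 fit (ML) with warning capture and one optimizer restart
fit_lme4 <- function(formula, data, family) {
  flags <- character(0)
  capture <- function(expr) {
    warns <- character(0)
    val <- withCallingHandlers(
      expr,
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # lme4 reports boundary/singular fits as messages; record and muffle
        warns <<- c(warns, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    list(model = val, warns = warns)
  }
  run <- function(ctrl) {
    if (family == "binomial") {
      capture(lme4::glmer(formula, data = data, family = stats::binomial(),
                          control = ctrl))
    } else {
      capture(lme4::lmer(formula, data = data, REML = FALSE,
                         control = ctrl))
    }
  }
  ctrl <- if (family == "binomial") lme4::glmerControl() else lme4::lmerControl()
  res <- run(ctrl)
  conv_bad <- any(grepl("converge", res$warns, ignore.case = TRUE))
  if (conv_bad) {
    ctrl2 <- if (family == "binomial") {
      lme4::glmerControl(optimizer = "bobyqa",
                         optCtrl = list(maxfun = 1e5))
    } else {
      lme4::lmerControl(optimizer = "bobyqa", optCtrl = list(maxfun = 1e5))
    }
    res2 <- run(ctrl2)
    if (!any(grepl("converge", res2$warns, ignore.case = TRUE))) {
      res <- res2
      conv_bad <- FALSE
    } else {
      res <- res2
    }
  }
  if (conv_bad) flags <- c(flags, "non_convergence")
  sing <- any(grepl("singular", res$warns, ignore.case = TRUE)) ||
    lme4::isSingular(res$model)
  if (sing) flags <- c(flags, "singular_fit")
  list(model = res$model, flags = flags, converged = !conv_bad)
}

fit_fixed <- function(formula, data, family) {
  flags <- character(0)
  warns <- character(0)
  model <- withCallingHandlers(
    if (family == "binomial") {
      stats::glm(formula, data = data, family = stats::binomial())
    } else {
      stats::lm(formula, data = data)
    },
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("fitted probabilities numerically 0 or 1", warns))) {
    flags <- c(flags, "possible_separation")
  }
  conv <- TRUE
  if (family == "binomial" && !model$converged) {
    flags <- c(flags, "non_convergence")
    conv <- FALSE
  }
  list(model = model, flags = flags, converged = conv)
}

new_mill_fit <- function(model, family, formula, data, response,
                         fallback_applied, flags, ranef_var, transform,
                         converged) {
  n <- stats::nobs(model)
  if (inherits(model, "merMod")) {
    cf <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
  } else {
    sm <- withCallingHandlers(
      summary(model),
      warning = function(w) {
        # a residual variance of ~0 (degenerate/constructed data) is worth a
        # flag on the result, not a console warning
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          flags <<- c(flags, "near_perfect_fit")
          invokeRestart("muffleWarning")
        }
      })
    cf <- stats::coef(model)
    se <- sm$coefficients[, "Std. Error"]
  }
  p <- length(cf)
  residual_df <- n - p
  stat <- cf / se
  if (family == "binomial") {
    pval <- 2 * stats::pnorm(-abs(stat))
    stat_name <- "z"
  } else {
    pval <- 2 * stats::pt(-abs(stat), df = max(residual_df, 1))
    stat_name <- "t"
  }
  coefficients <- tibble::tibble(
    term = names(cf), estimate = unname(cf), std.error = unname(se),
    statistic = unname(stat), p.value = unname(pval))
  structure(list(model = model, family = family, formula = formula,
                 response = response, transform = transform,
                 coefficients = coefficients, statistic = stat_name,
                 fallback_applied = fallback_applied, converged = converged,
                 flags = flags, ranef_variances = ranef_var,
                 n = n, residual_df = residual_df),
            class = "mill_fit")
}

#' @export
print.mill_fit <- function(x, ...) {
  kind <- if (inherits(x$model, "merMod")) {
    if (x$family == "binomial") "GLMM" else "LMM"
  } else {
    if (x$family == "binomial") "GLM" else "LM"
  }
  cat(sprintf("<mill_fit> %s (%s), n = %d, residual df = %d%s\n", kind,
              x$family, x$n, x$residual_df,
              if (x$fallback_applied) ", random intercept dropped (zero variance)" else ""))
  if (length(x$flags) > 0) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a `mill_fit`
#' @param x A `mill_fit`.
#' @param ... Unused.
#' @return A tibble of term, estimate, std.error, statistic, p.value.
#' @method tidy mill_fit
#' @export
tidy.mill_fit <- function(x, ...) x$coefficients

#' One-row model summary for a `mill_fit`
#' @param x A `mill_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance mill_fit
#' @export
glance.mill_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    mixed = inherits(x$model, "merMod"),
    fallback_applied = x$fallback_applied,
    converged = x$converged,
    n = x$n,
    residual_df = x$residual_df,
    logLik = as.numeric(stats::logLik(x$model)),
    AIC = stats::AIC(x$model)
  )
}

#' Solve a two-parameter logistic through two probability anchors
#'
#' Returns the intercept and slope of the logit-linear curve
#' `p(x) = plogis(b0 + b1 x)` passing exactly through `(x1, p1)` and
#' `(x2, p2)`.
#'
#' @param x1,p1,x2,p2 Anchor points; probabilities strictly inside (0, 1).
#' @return Named numeric vector `c(intercept, slope)`.
#' @examples
#' logistic_through_points(4, 0.49, 6, 0.92)
#' @export
logistic_through_points <- function(x1, p1, x2, p2) {
  if (any(c(p1, p2) <= 0 | c(p1, p2) >= 1)) {
    stop("logistic_through_points: probabilities must be in (0, 1)",
         call. = FALSE)
  }
  if (x1 == x2) stop("logistic_through_points: x1 must differ from x2",
                     call. = FALSE)
  slope <- (stats::qlogis(p2) - stats::qlogis(p1)) / (x2 - x1)
  c(intercept = stats::qlogis(p1) - slope * x1, slope = slope)
}

#' Predicted probability from a binomial fit at a given body size
#'
#' Evaluates the inverse-logit of the linear predictor at an intertegular
#' span, holding every other predictor at its reference level. Accepts either
#' a binomial `mill_fit` whose formula contains an ITS term, or a plain
#' numeric `c(intercept, slope)` pair such as from
#' [logistic_through_points()]. ITS values outside the plausible (2, 8) mm
#' range trigger an extrapolation warning.
#'
#' @param object A binomial `mill_fit` or a numeric length-2 coefficient
#'   vector.
#' @param its_mm Intertegular span in mm (vectorised).
#' @return Predicted probabilities.
#' @examples
#' co <- logistic_through_points(4, 0.49, 6, 0.92)
#' predicted_probability(co, 5)
#' @export
predicted_probability <- function(object, its_mm) {
  if (any(its_mm <= 2 | its_mm >= 8)) {
    warning("predicted_probability: ITS outside (2, 8) mm; extrapolating",
            call. = FALSE)
  }
  if (is.numeric(object)) {
    if (length(object) != 2) {
      stop("predicted_probability: coefficient vector must be length 2",
           call. = FALSE)
    }
    return(stats::plogis(object[[1]] + object[[2]] * its_mm))
  }
  if (!inherits(object, "mill_fit") || object$family != "binomial") {
    stop("predicted_probability: need a binomial mill_fit or c(intercept, slope)",
         call. = FALSE)
  }
  cf <- object$coefficients
  its_term <- grep("its", cf$term, ignore.case = TRUE, value = TRUE)
  its_term <- setdiff(its_term, grep(":", its_term, value = TRUE))
  if (length(its_term) != 1) {
    stop("predicted_probability: could not identify a unique ITS main-effect ",
         "term in the fit", call. = FALSE)
  }
  b0 <- cf$estimate[cf$term == "(Intercept)"]
  b1 <- cf$estimate[cf$term == its_term]
  stats::plogis(b0 + b1 * its_mm)
}

#' Assemble the long binned-velocity table for a cohort
#'
#' Unnests the `binned` list-column of a metrics table and joins treatment
#' and body size, producing the repeated-measures table used by
#' [fit_velocity_trajectory()].
#'
#' @param metrics A metrics tibble with a `binned` list-column
#'   (see [compute_metrics()]).
#' @param bees A bee table supplying `treatment` and `its_mm`.
#' @return A long tibble: `bee_id`, `treatment`, `its_mm`, `bin`,
#'   `circuit_mid`, `mean_velocity_mps`, `n_circuits`.
#' @export
binned_velocity_table <- function(metrics, bees) {
  metrics %>%
    dplyr::select("bee_id", "binned") %>%
    tidyr::unnest("binned") %>%
    dplyr::inner_join(
      dplyr::select(bees, "bee_id", "treatment", "its_mm"),
      by = "bee_id") %>%
    dplyr::relocate("treatment", "its_mm", .after = "bee_id")
}

#' Fit the early-flight velocity-trajectory model
#'
#' Repeated-measures linear mixed model of binned mean velocity over the
#' first `trajectory_window` circuits: fixed effects are treatment, body
#' size (when `its_mm` is present), the standardised circuit-bin position and
#' the treatment-by-circuit interaction; a per-bee random intercept absorbs
#' between-individual velocity differences. The circuit variable is z-scored
#' over the bin midpoints before fitting, which is what lets the model
#' converge comfortably. Bees contributing fewer than two non-missing bins
#' are dropped with a message.
#'
#' @param binned_long A long table from [binned_velocity_table()] (columns
#'   `bee_id`, `treatment`, `bin`, `mean_velocity_mps`, optionally `its_mm`).
#' @param var_tol Zero-variance threshold for the random-intercept fallback.
#' @return A `mill_fit`.
#' @export
fit_velocity_trajectory <- function(binned_long, var_tol = 1e-8) {
  d <- dplyr::filter(binned_long, !is.na(.data$mean_velocity_mps))
  per_bee <- dplyr::count(d, .data$bee_id)
  drop <- per_bee$bee_id[per_bee$n < 2]
  if (length(drop) > 0) {
    message("fit_velocity_trajectory: dropping ", length(drop),
            " bee(s) with < 2 non-missing bins")
    d <- dplyr::filter(d, !.data$bee_id %in% drop)
  }
  d$circuit_z <- as.numeric(scale(d$bin))
  rhs <- "treatment * circuit_z"
  if ("its_mm" %in% names(d)) rhs <- paste(rhs, "+ its_mm")
  f <- stats::as.formula(paste("mean_velocity_mps ~", rhs))
  fit_outcome_model(d, f, family = "gaussian", random = "bee_id",
                    var_tol = var_tol)
}

# response plan for the standard model suite
suite_plan <- function() {
  tibble::tribble(
    ~response,            ~family,     ~stage,
    "fed",                "binomial",  "started",
    "feed_duration_s",    "gaussian",  "fed",
    "flew",               "binomial",  "tag_rating_1",
    "over_100m",          "binomial",  "flew",
    "over_2000s",         "binomial",  "its_trimmed",
    "total_distance_m",   "gaussian",  "its_trimmed",
    "mean_velocity_mps",  "gaussian",  "its_trimmed",
    "max_velocity_mps",   "gaussian",  "its_trimmed"
  )
}

#' Fit the full outcome-model suite on a filtered cohort
#'
#' Fits every standard response of the assay at its appropriate cascade
#' stage: propensity to feed (all bees), feeding time (fed bees), propensity
#' to fly (ideal-tag bees), flying beyond the distance threshold (flyers),
#' and the endurance/velocity outcomes (long flight, total distance, mean
#' and maximum velocity) on the trimmed analysis set. Each model uses
#' `treatment * its_mm` fixed effects with a colony random intercept and the
#' zero-variance fallback. For gaussian responses with `transform = "auto"`,
#' a Shapiro–Wilk check on the response decides whether a log transform is
#' applied (positive responses only). Where the treatment-by-size interaction
#' is significant at `alpha`, per-treatment ITS slopes are refitted and
#' attached.
#'
#' @param cascade A `mill_cascade` from [apply_cascade()].
#' @param alpha Significance level used to flag interactions.
#' @param transform `"auto"`, `"none"` or `"log"` for gaussian responses.
#' @param var_tol Zero-variance threshold for the fallback.
#' @return An object of class `mill_suite`: a tibble with one row per
#'   response (`response`, `family`, `stage`, `n`, `transform`,
#'   `fallback_applied`, `converged`, `error`) and list-columns `fit`
#'   (`mill_fit` or `NULL`) and `per_treatment` (per-treatment slope refits
#'   when the interaction is significant).
#' @export
run_flight_model_suite <- function(cascade, alpha = 0.05,
                                   transform = c("auto", "none", "log"),
                                   var_tol = 1e-8) {
  transform <- match.arg(transform)
  stopifnot(inherits(cascade, "mill_cascade"))
  plan <- suite_plan()
  rows <- purrr::pmap(plan, function(response, family, stage) {
    data <- cascade$stages[[stage]]
    if (response == "over_100m") {
      data$over_100m <- data$total_distance_m >
        attr(cascade, "distance_threshold_m")
    }
    tr <- NULL
    if (family == "gaussian") {
      y <- data[[response]]
      tr <- switch(transform,
        none = NULL,
        log = "log",
        auto = {
          y_ok <- y[!is.na(y)]
          if (length(y_ok) >= 3 && length(y_ok) <= 5000 && all(y_ok > 0) &&
              stats::sd(y_ok) > 0 &&
              stats::shapiro.test(y_ok)$p.value < 0.05) "log" else NULL
        })
    }
    f <- stats::as.formula(paste(response, "~ treatment * its_mm"))
    fit <- tryCatch(
      fit_outcome_model(data, f, family = family, random = "colony_id",
                        var_tol = var_tol, transform = tr),
      error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(response = response, family = family,
                            stage = stage, n = NA_integer_,
                            transform = tr %||% "none",
                            fallback_applied = NA, converged = NA,
                            error = conditionMessage(fit),
                            fit = list(NULL), per_treatment = list(NULL)))
    }
    per_trt <- NULL
    int_p <- fit$coefficients$p.value[grepl(":", fit$coefficients$term)]
    if (length(int_p) == 1 && !is.na(int_p) && int_p < alpha) {
      per_trt <- lapply(split(data, data$treatment), function(sub) {
        tryCatch(
          fit_outcome_model(sub, stats::as.formula(paste(response, "~ its_mm")),
                            family = family, random = "colony_id",
                            var_tol = var_tol, transform = tr),
          error = function(e) NULL)
      })
    }
    tibble::tibble(response = response, family = family, stage = stage,
                   n = fit$n, transform = tr %||% "none",
                   fallback_applied = fit$fallback_applied,
                   converged = fit$converged, error = NA_character_,
                   fit = list(fit), per_treatment = list(per_trt))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mill_suite", class(out))
  out
}

#' Tidy a model suite
#' @param x A `mill_suite`.
#' @param ... Unused.
#' @return Coefficient tibble across all fitted responses.
#' @method tidy mill_suite
#' @export
tidy.mill_suite <- function(x, ...) {
  x %>%
    dplyr::filter(!purrr::map_lgl(.data$fit, is.null)) %>%
    dplyr::mutate(coefs = purrr::map(.data$fit, tidy)) %>%
    dplyr::select("response", "family", "n", "coefs") %>%
    tidyr::unnest("coefs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
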