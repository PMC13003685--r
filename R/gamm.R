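## Penalized-smooth (GAMM) models of dive depth, duration, and hourly
## dive rate, with random-effect structure comparison and conditional
## effect curves. Fitting backs onto mgcv; the contract here is the
## model structure: families and links, cyclic vs thin-plate bases,
## basis dimension k = 5, REML smoothing selection, shrinkage
## (double-penalty) term selection, and the two random structures.

#' Specify a dive-metric model
#'
#' @param response column name of the response ("depth", "duration", or
#'   "n_dives" for the hourly count model)
#' @param family "gamma_log" (Gamma, log link) or "negbin_log"
#'   (negative binomial, log link)
#' @param cyclic named list mapping cyclic covariates to their period
#'   (e.g., list(time_of_day = 24, moon_phase = 2*pi)); fitted with
#'   cyclic cubic regression splines
#' @param smooth character vector of covariates fitted with thin-plate
#'   regression splines
#' @param k basis dimension per smooth, default 5
#' @param random "intercept" (random intercept per animal) or
#'   "factor_smooth" (per-animal smooth deviations in the first cyclic
#'   covariate, shared smoothing parameter, plus what that implies for
#'   intercepts)
#' @param offset optional column used as a log offset (e.g.,
#'   "covered_hours" for the hourly count model)
#' @param select apply shrinkage so null terms can drop to ~0 effective
#'   degrees of freedom: non-cyclic smooths use the shrinkage thin-plate
#'   basis and all terms additionally carry mgcv's double penalty;
#'   default TRUE
#' @return list of class "dive_model_spec"
#' @export
model_spec <- function(response,
                       family = c("gamma_log", "negbin_log"),
                       cyclic = list(time_of_day = 24,
                                     moon_phase = 2 * pi),
                       smooth = character(0), k = 5,
                       random = c("intercept", "factor_smooth"),
                       offset = NULL, select = TRUE) {
  family <- match.arg(family)
  random <- match.arg(random)
  structure(list(response = response, family = family, cyclic = cyclic,
                 smooth = smooth, k = k, random = random,
                 offset = offset, select = select),
            class = "dive_model_spec")
}

spec_formula <- function(spec) {
  terms <- character(0)
  for (nm in names(spec$cyclic)) {
    terms <- c(terms, sprintf("s(%s, bs = 'cc', k = %d)", nm, spec$k))
  }
  for (nm in spec$smooth) {
    ## shrinkage thin-plate basis: the whole term, null space included,
    ## can be penalized to ~0 edf (implicit covariate selection)
    basis <- if (spec$select) "ts" else "tp"
    terms <- c(terms, sprintf("s(%s, bs = '%s', k = %d)", nm, basis, spec$k))
  }
  if (spec$random == "intercept") {
    terms <- c(terms, "s(animal_id, bs = 're')")
  } else {
    fs_var <- names(spec$cyclic)[1] %||% spec$smooth[1]
    terms <- c(terms,
               sprintf("s(%s, animal_id, bs = 'fs', xt = list(bs = 'cc'), k = %d, m = 1)",
                       fs_var, spec$k))
  }
  if (!is.null(spec$offset)) {
    terms <- c(terms, sprintf("offset(log(%s))", spec$offset))
  }
  stats::as.formula(paste(spec$response, "~", paste(terms, collapse = " + ")))
}

#' Fit a dive-metric GAMM
#'
#' Penalized-likelihood fit with REML smoothing-parameter selection.
#' Cyclic covariates get cyclic cubic regression splines with knots
#' pinned to the full period so the fit is continuous (value and first
#' derivative) across the period boundary; other covariates get
#' thin-plate splines. With `select = TRUE` every smooth carries a
#' null-space penalty, so covariates without signal shrink toward zero
#' effective degrees of freedom. The negative binomial dispersion is
#' estimated alongside the smoothing parameters.
#'
#' @param data data.frame with the response, covariates, and animal_id
#' @param spec a [model_spec()]
#' @return object of class "dive_model_fit": the mgcv fit plus the spec,
#'   training covariate means, AIC (conditional, penalized-edf), total
#'   deviance explained (%), and per-term effective degrees of freedom
#' @export
fit_metric_model <- function(data, spec) {
  check_that(all(c(spec$response, names(spec$cyclic), spec$smooth,
                   "animal_id") %in% names(data)),
             "data is missing model columns")
  d <- data
  d$animal_id <- factor(d$animal_id)
  cc <- stats::complete.cases(d[c(spec$response, names(spec$cyclic),
                                  spec$smooth, spec$offset)])
  d <- d[cc, , drop = FALSE]
  check_that(length(unique(d$animal_id)) >= 2,
             "random-effect structures need at least 2 animals")
  knots <- lapply(spec$cyclic, function(per) c(0, per))
  fam <- switch(spec$family,
                gamma_log = stats::Gamma(link = "log"),
                negbin_log = mgcv::nb(link = "log"))
  fm <- spec_formula(spec)
  ## The factor-smooth structure deliberately repeats the population
  ## smooth's variable (deviation smooths); silence mgcv's note about it.
  fit <- withCallingHandlers(
    mgcv::gam(fm, family = fam, data = d, method = "REML",
              knots = knots, select = spec$select),
    warning = function(w) {
      if (grepl("repeated 1-d smooths", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("GAMM did not converge; mgcv optimizer info: ",
         paste(utils::capture.output(fit$outer.info), collapse = " "),
         call. = FALSE)
  }
  sm_edf <- vapply(fit$smooth, function(s) {
    sum(fit$edf[s$first.para:s$last.para])
  }, numeric(1))
  names(sm_edf) <- vapply(fit$smooth, function(s) s$label, character(1))
  dev_expl <- 100 * (1 - fit$deviance / fit$null.deviance)
  cov_means <- lapply(d[c(names(spec$cyclic), spec$smooth)], mean)
  structure(list(gam = fit, spec = spec, data = d,
                 covariate_means = cov_means,
                 aic = stats::AIC(fit), deviance_explained = dev_expl,
                 edf = sm_edf,
                 k_index = tryCatch(
                   mgcv::k.check(fit)[, "k-index"],
                   error = function(e) NULL)),
            class = "dive_model_fit")
}

#' @export
print.dive_model_fit <- function(x, ...) {
  cat("Dive-metric GAMM (", x$spec$family, "): ", x$spec$response,
      ", random = ", x$spec$random, "\n", sep = "")
  cat("  AIC = ", round(x$aic, 1), ", deviance explained = ",
      round(x$deviance_explained, 1), "%\n", sep = "")
  cat("  per-term edf:\n")
  for (nm in names(x$edf)) {
    cat("    ", nm, ": ", round(x$edf[[nm]], 2), "\n", sep = "")
  }
  invisible(x)
}

#' Compare random-intercept and factor-smooth random structures
#'
#' Fits the specification under both random-effect structures and
#' selects the one with lower (conditional) AIC; also reports the
#' difference in percent deviance explained. If one structure fails to
#' fit, the comparison is returned partial with a flag.
#'
#' @param data model data.frame
#' @param spec a [model_spec()] (its `random` field is overridden)
#' @return list: fits (both), chosen ("intercept"/"factor_smooth"),
#'   delta_aic (intercept minus factor-smooth), delta_deviance
#'   (factor-smooth minus intercept, percentage points), partial flag
#' @export
compare_random_structures <- function(data, spec) {
  fit1 <- tryCatch({
    s <- spec; s$random <- "intercept"
    fit_metric_model(data, s)
  }, error = function(e) e)
  fit2 <- tryCatch({
    s <- spec; s$random <- "factor_smooth"
    fit_metric_model(data, s)
  }, error = function(e) e)
  ok1 <- inherits(fit1, "dive_model_fit")
  ok2 <- inherits(fit2, "dive_model_fit")
  if (!ok1 && !ok2) stop("both random-structure fits failed", call. = FALSE)
  if (!ok1 || !ok2) {
    chosen <- if (ok1) "intercept" else "factor_smooth"
    return(list(fits = list(intercept = if (ok1) fit1 else NULL,
                            factor_smooth = if (ok2) fit2 else NULL),
                chosen = chosen, delta_aic = NA_real_,
                delta_deviance = NA_real_, partial = TRUE))
  }
  delta_aic <- fit1$aic - fit2$aic
  list(fits = list(intercept = fit1, factor_smooth = fit2),
       chosen = if (fit2$aic < fit1$aic) "factor_smooth" else "intercept",
       delta_aic = delta_aic,
       delta_deviance = fit2$deviance_explained - fit1$deviance_explained,
       partial = FALSE)
}

#' Conditional effect curve for one covariate
#'
#' Predictions over a grid of one covariate with every other covariate
#' held at its training mean and random effects excluded — the
#' functional relationship for a "typical" individual — with a 95%
#' interval from the coefficient covariance on the link scale.
#'
#' @param fit a [fit_metric_model()] result
#' @param covariate covariate name present in the spec
#' @param grid numeric grid; default 100 points over the observed range
#' @param response_scale back-transform predictions through the inverse
#'   link (default TRUE)
#' @return data.frame: covariate value, estimate, lower, upper,
#'   extrapolated flag
#' @export
predict_effects <- function(fit, covariate, grid = NULL,
                            response_scale = TRUE) {
  spec <- fit$spec
  all_cov <- c(names(spec$cyclic), spec$smooth)
  check_that(covariate %in% all_cov, "covariate is not in the model spec")
  obs <- fit$data[[covariate]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 100)
  nd <- as.data.frame(fit$covariate_means)
  nd <- nd[rep(1, length(grid)), , drop = FALSE]
  nd[[covariate]] <- grid
  nd$animal_id <- factor(levels(fit$data$animal_id)[1],
                         levels = levels(fit$data$animal_id))
  if (!is.null(spec$offset)) nd[[spec$offset]] <- 1
  exclude <- vapply(fit$gam$smooth, function(s) s$label, character(1))
  exclude <- exclude[grepl("animal_id", exclude)]
  pr <- mgcv::predict.gam(fit$gam, newdata = nd, type = "link",
                          se.fit = TRUE, exclude = exclude,
                          newdata.guaranteed = TRUE)
  est <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  lo <- est - 1.96 * se; hi <- est + 1.96 * se
  if (response_scale) {
    inv <- fit$gam$family$linkinv
    est <- inv(est); lo <- inv(lo); hi <- inv(hi)
  }
  out <- data.frame(value = grid, estimate = est, lower = lo, upper = hi,
                    extrapolated = grid < min(obs) | grid > max(obs))
  names(out)[1] <- covariate
  out
}
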