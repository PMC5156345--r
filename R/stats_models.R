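#' Model specification
#'
#' Declarative description of one of the pipeline's regression models:
#' family (negative binomial with log link and exposure offset; Gaussian
#' random-intercept mixed model; variable-dispersion beta regression with
#' logit mean link and log precision link), response, covariates with their
#' polynomial degrees, and how the individual enters (fixed intercepts for
#' the GLM-type families, random intercept for the mixed models).
#'
#' @param family `"negbin"`, `"lmm"` or `"beta"`.
#' @param response response column name.
#' @param covariates named integer vector: polynomial degree per covariate
#'   (all >= 1).
#' @param offset exposure column (negbin only); enters as `log(offset)`
#'   with coefficient fixed at 1.
#' @param individual grouping column; fixed intercepts (negbin, beta) or
#'   random intercept (lmm). `NULL` omits it.
#' @param interaction_factor optional factor column interacting with every
#'   covariate (the phase-duration model crosses phase type with each
#'   covariate).
#' @param precision_covariates beta only: covariates of the log-precision
#'   submodel; defaults to the mean submodel's covariates.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("negbin", "lmm", "beta"), response,
                       covariates, offset = NULL, individual = NULL,
                       interaction_factor = NULL,
                       precision_covariates = NULL) {
  family <- match.arg(family)
  if (is.null(names(covariates)) || any(covariates < 1)) {
    stop("covariates must be a named vector of degrees >= 1")
  }
  if (family == "negbin" && is.null(offset)) {
    stop("negbin models require an exposure offset")
  }
  if (family != "negbin" && !is.null(offset)) {
    stop("offset is only meaningful for the negbin family")
  }
  if (family == "beta" && is.null(precision_covariates)) {
    precision_covariates <- names(covariates)
  }
  structure(list(family = family, response = response,
                 covariates = covariates, offset = offset,
                 individual = individual,
                 interaction_factor = interaction_factor,
                 precision_covariates = precision_covariates),
            class = "model_spec")
}

# One formula term for a covariate at its degree; orthogonal polynomials
# keep the degree escalation numerically stable.
cov_term <- function(name, degree) {
  if (degree == 1) name else sprintf("poly(%s, %d)", name, degree)
}

spec_formula <- function(spec) {
  terms <- vapply(names(spec$covariates),
                  function(nm) cov_term(nm, spec$covariates[[nm]]),
                  character(1))
  if (!is.null(spec$interaction_factor)) {
    terms <- c(spec$interaction_factor,
               paste(spec$interaction_factor, "*", terms))
  }
  if (!length(terms)) terms <- "1"
  rhs <- paste(terms, collapse = " + ")
  if (!is.null(spec$individual)) {
    rhs <- paste(rhs, if (spec$family == "lmm") {
      sprintf("+ (1 | %s)", spec$individual)
    } else {
      sprintf("+ %s", spec$individual)
    })
  }
  if (!is.null(spec$offset)) {
    rhs <- paste(rhs, sprintf("+ offset(log(%s))", spec$offset))
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Standardize covariates
#'
#' Centres each covariate to zero mean and scales it to unit SD so that
#' regression slopes are comparable across covariates; the scaling record
#' (attribute `"scaling"`) allows exact back-transformation. Zero-variance
#' covariates are dropped with a warning.
#'
#' @param table data.frame.
#' @param covariates columns to standardize.
#' @return `table` with standardized columns and attribute `"scaling"`
#'   (data.frame `covariate`, `center`, `scale`).
#' @export
standardize_covariates <- function(table, covariates) {
  keep <- character(0)
  sc <- data.frame(covariate = character(0), center = numeric(0),
                   scale = numeric(0))
  for (nm in covariates) {
    s <- stats::sd(table[[nm]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      warning(sprintf("dropping zero-variance covariate '%s'", nm))
      table[[nm]] <- NULL
      next
    }
    m <- mean(table[[nm]], na.rm = TRUE)
    table[[nm]] <- (table[[nm]] - m) / s
    sc <- rbind(sc, data.frame(covariate = nm, center = m, scale = s))
    keep <- c(keep, nm)
  }
  attr(table, "scaling") <- sc
  table
}

#' Thin a table to one row in k
#'
#' Keeps rows 1, k+1, 2k+1, ... within each individual (table assumed
#' time-ordered within individual); the standard device against temporal
#' autocorrelation of consecutive dives.
#'
#' @param table data.frame.
#' @param k thinning factor, default 10.
#' @param individual grouping column name.
#' @return thinned data.frame.
#' @export
thin_every_k <- function(table, k = 10L, individual = "individual") {
  if (k <= 1) return(table)
  idx <- unlist(lapply(split(seq_len(nrow(table)), table[[individual]]),
                       function(i) i[seq(1, length(i), by = k)]))
  table[sort(idx), , drop = FALSE]
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing covariate j on the others;
#' values at or above `warn_at` (5) trigger a warning, perfect colinearity
#' reports `Inf`.
#'
#' @param table data.frame.
#' @param covariates covariate column names (>= 2).
#' @param warn_at warning threshold, default 5.
#' @return named numeric vector of VIFs.
#' @export
vif_screen <- function(table, covariates, warn_at = 5) {
  if (length(covariates) < 2) stop("VIF needs at least 2 covariates")
  out <- vapply(covariates, function(nm) {
    f <- stats::as.formula(paste(nm, "~",
                                 paste(setdiff(covariates, nm),
                                       collapse = " + ")))
    r2 <- suppressWarnings(summary(stats::lm(f, data = table)))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(out >= warn_at)) {
    warning(sprintf("VIF >= %g for: %s", warn_at,
                    paste(covariates[out >= warn_at], collapse = ", ")))
  }
  out
}

new_ses_fit <- function(spec, fit, table) {
  ll <- stats::logLik(fit)
  cf <- tryCatch({
    s <- summary(fit)
    co <- if (inherits(fit, "glmmTMB")) s$coefficients$cond else
      stats::coef(s)
    data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
               row.names = NULL)
  }, error = function(e) NULL)
  structure(list(spec = spec, fit = fit, family = spec$family,
                 coefficients = cf, logLik = as.numeric(ll),
                 df = attr(ll, "df"), aic = stats::AIC(fit),
                 n = nrow(table), table = table),
            class = "ses_fit")
}

#' @export
print.ses_fit <- function(x, ...) {
  cat(sprintf("<ses_fit> %s model: %s\n", x$family,
              deparse(spec_formula(x$spec))))
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f\n", x$n, x$logLik, x$aic))
  invisible(x)
}

#' Fit a negative-binomial count model
#'
#' Log link, exposure entering as `log(offset)` with coefficient fixed at
#' one, dispersion theta estimated by maximum likelihood
#' (via [MASS::glm.nb()]); the variance is `mu + mu^2 / theta`.
#'
#' @param spec a `model_spec` with `family = "negbin"`.
#' @param table data.frame with integer counts in the response column.
#' @return a `ses_fit` with extra fields `theta`, `deviance`,
#'   `null_deviance` (null = intercept + offset).
#' @export
fit_negbin <- function(spec, table) {
  y <- table[[spec$response]]
  if (any(y < 0) || any(y != round(y))) {
    stop("negbin response must be non-negative integers")
  }
  fit <- MASS::glm.nb(spec_formula(spec), data = table)
  out <- new_ses_fit(spec, fit, table)
  out$theta <- fit$theta
  out$deviance <- fit$deviance
  out$null_deviance <- fit$null.deviance
  out
}

#' Fit a Gaussian random-intercept mixed model
#'
#' Via [lme4::lmer()]; maximum likelihood during model selection, REML for
#' final fits. A singular fit is retained with the random-intercept
#' variance at zero (lme4 signals it).
#'
#' @param spec a `model_spec` with `family = "lmm"`.
#' @param table data.frame.
#' @param REML use REML (final fits) or ML (selection).
#' @return a `ses_fit` with extra fields `sigma2_random`, `sigma2_residual`.
#' @export
fit_lmm <- function(spec, table, REML = FALSE) {
  fit <- lme4::lmer(spec_formula(spec), data = table, REML = REML)
  out <- new_ses_fit(spec, fit, table)
  vc <- lme4::VarCorr(fit)
  out$sigma2_random <- as.numeric(vc[[spec$individual]])
  out$sigma2_residual <- stats::sigma(fit)^2
  out
}

#' Fit a variable-dispersion beta regression
#'
#' Beta likelihood parameterized as Beta(mu*phi, (1-mu)*phi) with a logit
#' link for the mean submodel and a log link for the precision submodel
#' (fitted with [glmmTMB::glmmTMB()] using its dispersion formula). The
#' precision covariates default to the mean submodel's covariates.
#'
#' @param spec a `model_spec` with `family = "beta"`.
#' @param table data.frame; response strictly inside (0, 1).
#' @return a `ses_fit` with extra field `precision_coefficients`.
#' @export
fit_beta <- function(spec, table) {
  y <- table[[spec$response]]
  if (any(y <= 0 | y >= 1)) {
    stop("beta response must lie strictly in (0,1); check dive_efficiency flags")
  }
  disp <- stats::as.formula(paste(
    "~", paste(c("1", spec$precision_covariates), collapse = " + ")))
  fit <- glmmTMB::glmmTMB(spec_formula(spec), dispformula = disp,
                          data = table, family = glmmTMB::beta_family())
  out <- new_ses_fit(spec, fit, table)
  dc <- summary(fit)$coefficients$disp
  out$precision_coefficients <- data.frame(term = rownames(dc),
                                           estimate = dc[, 1], se = dc[, 2],
                                           row.names = NULL)
  out
}

#' Fit any model spec
#'
#' @param spec a `model_spec`.
#' @param table data.frame.
#' @param REML passed to [fit_lmm()].
#' @return a `ses_fit`.
#' @export
fit_model <- function(spec, table, REML = FALSE) {
  switch(spec$family,
         negbin = fit_negbin(spec, table),
         lmm = fit_lmm(spec, table, REML),
         beta = fit_beta(spec, table))
}

#' Percentage of null deviance explained
#'
#' `D2 = 1 - residual_deviance / null_deviance`, in percent. By default the
#' null model is intercept + offset only (individual intercepts belong to
#' the model); `null = "individual"` includes the individual intercepts in
#' the null instead.
#'
#' @param fit a negbin `ses_fit`.
#' @param null `"offset_only"` (default) or `"individual"`.
#' @return percentage.
#' @export
deviance_explained <- function(fit, null = c("offset_only", "individual")) {
  null <- match.arg(null)
  stopifnot(fit$family == "negbin")
  nd <- if (null == "offset_only") fit$null_deviance else {
    spec0 <- fit$spec
    spec0$covariates <- stats::setNames(integer(0), character(0))
    nf <- MASS::glm.nb(spec_formula(spec0), data = fit$table)
    nf$deviance
  }
  if (nd <= 0) {
    warning("null deviance is zero; D2 undefined")
    return(NA_real_)
  }
  100 * (1 - fit$deviance / nd)
}

#' Null-deviance explained per covariate
#'
#' Single-term deletion: for each covariate of the fitted model, the drop
#' in D2 when that covariate (with all its polynomial terms) is removed and
#' the model refitted. Values are non-negative and need not sum to the
#' model's D2.
#'
#' @param fit a negbin `ses_fit`.
#' @return named numeric vector of percentages.
#' @export
per_covariate_nde <- function(fit) {
  stopifnot(fit$family == "negbin")
  d2_full <- deviance_explained(fit)
  out <- vapply(names(fit$spec$covariates), function(nm) {
    spec_j <- fit$spec
    spec_j$covariates <- spec_j$covariates[names(spec_j$covariates) != nm]
    d2_full - deviance_explained(fit_negbin(spec_j, fit$table))
  }, numeric(1))
  out
}

#' Nakagawa marginal and conditional R-squared
#'
#' For a Gaussian random-intercept LMM:
#' `R2m = var_fixed / (var_fixed + var_random + var_residual)` and
#' `R2c = (var_fixed + var_random) / (same denominator)`, where `var_fixed`
#' is the variance of the fixed-effect linear predictor over the data.
#'
#' @param fit an lmm `ses_fit`.
#' @return named numeric vector `c(R2m, R2c)`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(fit$family == "lmm")
  xb <- as.numeric(stats::model.matrix(fit$fit) %*% lme4::fixef(fit$fit))
  vf <- stats::var(xb)
  denom <- vf + fit$sigma2_random + fit$sigma2_residual
  c(R2m = vf / denom, R2c = (vf + fit$sigma2_random) / denom)
}

#' Squared Pearson correlation pseudo R-squared
#'
#' Square of the Pearson correlation between the link-transformed observed
#' response and the fitted linear predictor. For counts the observed rate
#' is log-transformed after a half-count continuity adjustment of zeros
#' (adjustment logged via message); for the LMM the identity link and the
#' full (fixed + random) fitted values are used; for the beta model the
#' logit of the response against the mean-submodel linear predictor.
#'
#' @param fit a `ses_fit`.
#' @return scalar in \[0, 1\], `NA` (with warning) if either vector is
#'   degenerate.
#' @export
pearson2 <- function(fit) {
  tab <- fit$table
  y <- tab[[fit$spec$response]]
  if (fit$family == "negbin") {
    nz <- sum(y == 0)
    if (nz) message(sprintf("pearson2: %d zero counts adjusted by +0.5", nz))
    obs <- log(y + 0.5 * (y == 0))
    eta <- as.numeric(stats::predict(fit$fit, type = "link"))
  } else if (fit$family == "lmm") {
    obs <- y
    eta <- as.numeric(stats::fitted(fit$fit))
  } else {
    obs <- stats::qlogis(y)
    eta <- as.numeric(stats::predict(fit$fit, type = "link"))
  }
  if (stats::sd(obs) == 0 || stats::sd(eta) == 0) {
    warning("pearson2 undefined: zero variance")
    return(NA_real_)
  }
  stats::cor(obs, eta)^2
}

#' Backward stepwise selection by AIC
#'
#' Starting from the full model, repeatedly drops the single covariate
#' whose removal lowers AIC most, until no removal lowers it. Ties are
#' broken by dropping the later-listed covariate; candidates whose fit
#' fails are skipped with a message. The offset, individual term and
#' interaction factor are never dropped.
#'
#' @param spec full `model_spec`.
#' @param table data.frame.
#' @return the selected `model_spec` with attribute `"trace"` (data.frame
#'   of steps).
#' @export
stepwise_aic <- function(spec, table) {
  cur <- spec
  cur_fit <- fit_model(cur, table)
  trace <- data.frame(step = 0L, dropped = "", aic = cur_fit$aic)
  repeat {
    nms <- names(cur$covariates)
    if (!length(nms)) break
    aics <- rep(NA_real_, length(nms))
    for (j in seq_along(nms)) {
      cand <- cur
      cand$covariates <- cand$covariates[-j]
      aics[j] <- tryCatch(fit_model(cand, table)$aic, error = function(e) {
        message(sprintf("dropping '%s' failed to fit: %s", nms[j],
                        conditionMessage(e)))
        NA_real_
      })
    }
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= cur_fit$aic) break
    j <- max(which(aics == min(aics, na.rm = TRUE))) # tie: later-listed
    cur$covariates <- cur$covariates[-j]
    cur_fit <- fit_model(cur, table)
    trace <- rbind(trace, data.frame(step = nrow(trace), dropped = nms[j],
                                     aic = cur_fit$aic))
  }
  attr(cur, "trace") <- trace
  cur
}

#' Polynomial degree escalation
#'
#' For each covariate retained by [stepwise_aic()], in turn, raises its
#' polynomial degree 1 -> 2 -> 3 ... while the model AIC decreases,
#' stopping at the first non-improvement (degree capped at `max_degree`).
#'
#' @param spec selected `model_spec`.
#' @param table data.frame.
#' @param max_degree guard cap, default 4.
#' @return `model_spec` with updated degrees.
#' @export
polynomial_escalation <- function(spec, table, max_degree = 4L) {
  cur <- spec
  cur_aic <- fit_model(cur, table)$aic
  for (nm in names(cur$covariates)) {
    repeat {
      d <- cur$covariates[[nm]]
      if (d >= max_degree) break
      cand <- cur
      cand$covariates[[nm]] <- d + 1L
      cand_aic <- tryCatch(fit_model(cand, table)$aic,
                           error = function(e) NA_real_)
      if (is.na(cand_aic) || cand_aic >= cur_aic) break
      cur <- cand
      cur_aic <- cand_aic
    }
  }
  cur
}

#' Full selection procedure for one model
#'
#' VIF screen (warning only), backward AIC, polynomial escalation, and a
#' final refit (REML for mixed models, as selection runs under ML).
#'
#' @param spec full `model_spec`.
#' @param table data.frame (already standardized/thinned as desired).
#' @return final `ses_fit`, with the selection trace in
#'   `attr(fit$spec, "trace")`.
#' @export
select_model <- function(spec, table) {
  if (length(spec$covariates) >= 2) {
    try(vif_screen(table, names(spec$covariates)), silent = TRUE)
  }
  sel <- stepwise_aic(spec, table)
  sel2 <- polynomial_escalation(sel, table)
  attr(sel2, "trace") <- attr(sel, "trace")
  fit_model(sel2, table, REML = TRUE)
}

#' Per-individual residual autocorrelation report
#'
#' Residual autocorrelation at lags 0-`lag_max` for each individual, with
#' the usual +/- 2/sqrt(n) white-noise reference bounds. Report only; no
#' automated rejection.
#'
#' @param fit a `ses_fit` (residuals in table order, time-ordered within
#'   individual).
#' @param lag_max maximum lag, default 20.
#' @return data.frame with `individual`, `lag`, `acf`, `bound`.
#' @export
residual_acf_report <- function(fit, lag_max = 20L) {
  res <- stats::residuals(fit$fit)
  ind <- fit$table[[fit$spec$individual %||% "individual"]]
  if (is.null(ind)) ind <- rep("all", length(res))
  out <- lapply(split(res, ind), function(r) {
    lm <- min(lag_max, length(r) - 1)
    a <- stats::acf(r, lag.max = lm, plot = FALSE)$acf[, 1, 1]
    data.frame(lag = 0:lm, acf = a, bound = 2 / sqrt(length(r)))
  })
  cbind(individual = rep(names(out), vapply(out, nrow, integer(1))),
        do.call(rbind, out), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
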