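#' z-standardize a covariate
#'
#' Centres to mean 0 and scales to sample standard deviation 1, the
#' transformation applied to numeric covariates (throw number, interest
#' period number) before model fitting so that estimates are per standard
#' deviation and the intercept refers to an average event.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return The standardized vector.
#' @export
z_standardize <- function(values) {
  if (length(stats::na.omit(unique(values))) < 2L)
    stop("degenerate covariate: fewer than 2 distinct values", call. = FALSE)
  (values - mean(values, na.rm = TRUE)) / stats::sd(values, na.rm = TRUE)
}

# Build the lmer formula with per-subject random slopes for every fixed
# term, omitting all random-effect correlations: a (1|subject) intercept
# plus one (0 + column | subject) term per non-intercept design column.
# Factor terms contribute their dummy columns. Returns the augmented data
# and the formula.
build_lmm_formula <- function(data, response, fixed, subject) {
  fixed_rhs <- if (length(fixed) == 0L) "1" else paste(fixed, collapse = " + ")
  mm <- stats::model.matrix(stats::reformulate(fixed, intercept = TRUE), data)
  slope_cols <- setdiff(colnames(mm), "(Intercept)")
  rs_names <- character(0)
  for (col in slope_cols) {
    nm <- paste0(".rs_", gsub("[^[:alnum:]_]", "_", col))
    data[[nm]] <- mm[, col]
    rs_names <- c(rs_names, nm)
  }
  rand <- c(sprintf("(1 | %s)", subject),
            sprintf("(0 + %s | %s)", rs_names, subject))
  fml <- stats::as.formula(
    paste(response, "~", fixed_rhs, "+", paste(rand, collapse = " + ")))
  list(data = data, formula = fml, slope_cols = slope_cols)
}

fit_lmer_quiet <- function(formula, data, reml) {
  notes <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  list(fit = fit, notes = notes,
       converged = !any(grepl("failed to converge", notes)))
}

#' Fit a linear mixed model with uncorrelated random slopes
#'
#' Fits the latency model used throughout the anticipation analysis:
#' fixed effects as given, a per-subject random intercept, and a
#' per-subject random slope for every fixed-effect design column, with all
#' correlations among random terms omitted. Estimates, standard errors and
#' Wald confidence intervals come from the REML fit; every reported test is
#' a likelihood-ratio test between maximum-likelihood refits — each fixed
#' term against the model without it (random structure unchanged), and the
#' full model against the intercept-only null.
#'
#' Non-convergence and singular variance estimates are flagged on the
#' result, never silently dropped.
#'
#' @param data Data frame of observations (one row per event).
#' @param response Name of the response column (a latency in ms).
#' @param fixed Character vector of fixed-effect term names. Numeric
#'   covariates should already be z-standardized ([z_standardize()]);
#'   factors should have their reference level set.
#' @param subject Name of the subject identifier column.
#' @return An object of class `lmm_result`: list with `terms` (per-term
#'   estimate/SE/CI/chisq/df/p), `full_null` (chisq/df/p), `n_obs`,
#'   `n_subjects`, `converged`, `singular`, `notes`, plus the fitted
#'   `reml_fit` and the spec needed for refits.
#' @export
fit_lmm <- function(data, response, fixed, subject = "subject_id") {
  data <- stats::na.omit(data[c(response, fixed, subject)])
  data[[subject]] <- factor(data[[subject]])
  n_subj <- nlevels(data[[subject]])
  if (n_subj < 2L)
    stop("random effect unidentifiable: need at least 2 subjects",
         call. = FALSE)
  for (f in fixed) {
    if (length(unique(data[[f]])) < 2L)
      stop(sprintf("fixed term '%s' does not vary in the data", f),
           call. = FALSE)
  }
  built <- build_lmm_formula(data, response, fixed, subject)
  reml <- fit_lmer_quiet(built$formula, built$data, reml = TRUE)
  ml <- fit_lmer_quiet(built$formula, built$data, reml = FALSE)

  co <- summary(reml$fit)$coefficients
  z975 <- stats::qnorm(0.975)
  terms_tab <- data.frame(
    term = rownames(co), estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lower = co[, "Estimate"] - z975 * co[, "Std. Error"],
    ci_upper = co[, "Estimate"] + z975 * co[, "Std. Error"],
    chisq = NA_real_, df = NA_real_, p = NA_real_,
    stability_min = NA_real_, stability_max = NA_real_,
    stringsAsFactors = FALSE)
  rownames(terms_tab) <- NULL

  ll_full <- as.numeric(stats::logLik(ml$fit))
  n_fixed_par <- length(lme4::fixef(ml$fit))
  notes <- c(reml$notes, ml$notes)

  # per-term LRT: drop one fixed term at a time, keep the random structure
  mm <- stats::model.matrix(stats::reformulate(fixed, intercept = TRUE), data)
  assign_map <- attr(mm, "assign")[match(terms_tab$term, colnames(mm))]
  for (j in seq_along(fixed)) {
    red <- build_lmm_formula_reduced(built, data, response, fixed, subject,
                                     drop = fixed[j])
    fit_red <- fit_lmer_quiet(red$formula, red$data, reml = FALSE)
    notes <- c(notes, fit_red$notes)
    chisq <- 2 * (ll_full - as.numeric(stats::logLik(fit_red$fit)))
    df <- n_fixed_par - length(lme4::fixef(fit_red$fit))
    rows <- which(assign_map == j)
    terms_tab$chisq[rows] <- chisq
    terms_tab$df[rows] <- df
    terms_tab$p[rows] <- stats::pchisq(max(chisq, 0), df = df,
                                       lower.tail = FALSE)
  }

  # full-null comparison: all fixed terms dropped, random structure kept
  null <- build_lmm_formula_reduced(built, data, response, fixed, subject,
                                    drop = fixed)
  fit_null <- fit_lmer_quiet(null$formula, null$data, reml = FALSE)
  notes <- c(notes, fit_null$notes)
  chisq0 <- 2 * (ll_full - as.numeric(stats::logLik(fit_null$fit)))
  df0 <- n_fixed_par - length(lme4::fixef(fit_null$fit))
  full_null <- list(chisq = chisq0, df = df0,
                    p = stats::pchisq(max(chisq0, 0), df = df0,
                                      lower.tail = FALSE))

  structure(
    list(terms = terms_tab, full_null = full_null,
         n_obs = nrow(data), n_subjects = n_subj,
         converged = reml$converged && ml$converged,
         singular = lme4::isSingular(reml$fit),
         notes = unique(notes),
         reml_fit = reml$fit, ml_fit = ml$fit,
         spec = list(data = data, response = response, fixed = fixed,
                     subject = subject)),
    class = "lmm_result")
}

# reduced-model formula sharing the full model's random structure
build_lmm_formula_reduced <- function(built, data, response, fixed, subject,
                                      drop) {
  keep <- setdiff(fixed, drop)
  fixed_rhs <- if (length(keep) == 0L) "1" else paste(keep, collapse = " + ")
  rs_names <- grep("^\\.rs_", names(built$data), value = TRUE)
  rand <- c(sprintf("(1 | %s)", subject),
            sprintf("(0 + %s | %s)", rs_names, subject))
  fml <- stats::as.formula(
    paste(response, "~", fixed_rhs, "+", paste(rand, collapse = " + ")))
  list(data = built$data, formula = fml)
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s ~ %s | %d obs, %d subjects%s%s\n",
              x$spec$response, paste(x$spec$fixed, collapse = " + "),
              x$n_obs, x$n_subjects,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular fit]" else ""))
  print(x$terms, digits = 4)
  cat(sprintf("Full-null comparison: chisq = %.2f, df = %d, p = %.3f\n",
              x$full_null$chisq, x$full_null$df, x$full_null$p))
  invisible(x)
}

#' Likelihood-ratio test between two nested mixed models
#'
#' Twice the maximum-likelihood log-likelihood difference, referred to a
#' chi-squared distribution with as many degrees of freedom as the models
#' differ in fixed-effect parameters. The reduced model's fixed terms must
#' be a subset of the full model's.
#'
#' @param full,reduced Two [fit_lmm()] results on the same data and
#'   response.
#' @return A list `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  if (!all(reduced$spec$fixed %in% full$spec$fixed) ||
      reduced$spec$response != full$spec$response)
    stop("models are not nested", call. = FALSE)
  ll_f <- as.numeric(stats::logLik(full$ml_fit))
  ll_r <- as.numeric(stats::logLik(reduced$ml_fit))
  df <- length(lme4::fixef(full$ml_fit)) -
    length(lme4::fixef(reduced$ml_fit))
  if (df < 0) stop("models are not nested", call. = FALSE)
  chisq <- 2 * (ll_f - ll_r)
  p <- if (df == 0) 1 else
    stats::pchisq(max(chisq, 0), df = df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Leave-one-subject-out stability of the fixed estimates
#'
#' Refits the model once per subject with that subject's data removed and
#' reports the minimum and maximum of each fixed-effect estimate across the
#' refits — the model-stability check reported alongside each estimate.
#' Non-convergent refits are excluded from the range and counted.
#'
#' @param fit An [fit_lmm()] result.
#' @return The input with `stability_min`/`stability_max` filled in on
#'   `$terms`, plus `$loso` holding the per-refit estimates and
#'   `$loso_failures` the number of excluded refits.
#' @export
stability_loso <- function(fit) {
  sp <- fit$spec
  subjects <- levels(sp$data[[sp$subject]])
  if (length(subjects) < 3L)
    stop("leave-one-out stability needs at least 3 subjects", call. = FALSE)
  est <- list()
  failures <- 0L
  for (s in subjects) {
    dat <- sp$data[sp$data[[sp$subject]] != s, , drop = FALSE]
    built <- build_lmm_formula(dat, sp$response, sp$fixed, sp$subject)
    ref <- fit_lmer_quiet(built$formula, built$data, reml = TRUE)
    if (!ref$converged) {
      failures <- failures + 1L
      next
    }
    est[[s]] <- lme4::fixef(ref$fit)
  }
  if (length(est) == 0L)
    stop("all leave-one-out refits failed to converge", call. = FALSE)
  mat <- do.call(rbind, est)
  idx <- match(fit$terms$term, colnames(mat))
  fit$terms$stability_min <- apply(mat, 2, min)[idx]
  fit$terms$stability_max <- apply(mat, 2, max)[idx]
  fit$loso <- mat
  fit$loso_failures <- failures
  fit
}

#' Variance inflation factors of the fixed-effects design
#'
#' Collinearity diagnostic computed on the fixed-effects-only design
#' (random effects excluded, as is standard): each design column is
#' regressed on all others and its VIF is `1 / (1 - R^2)`.
#'
#' @param data Data frame of observations.
#' @param fixed Character vector of fixed-effect term names.
#' @return Named numeric vector of VIFs, one per design column.
#' @export
vif_fixed <- function(data, fixed) {
  if (length(fixed) < 2L)
    stop("VIF needs at least two fixed terms", call. = FALSE)
  mm <- stats::model.matrix(stats::reformulate(fixed, intercept = TRUE),
                            stats::na.omit(data[fixed]))
  X <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("rank-deficient fixed-effects design", call. = FALSE)
  out <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}

#' Write a mixed-model report table
#'
#' One row per fixed term with Estimate, SE, CI bounds, chi-squared, df, p
#' and the leave-one-out stability range, followed by a full-null
#' comparison line.
#'
#' @param fit An [fit_lmm()] (optionally [stability_loso()]-augmented)
#'   result.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_lmm_report <- function(fit, path) {
  tab <- fit$terms
  num <- function(v, d = 3) ifelse(is.na(v), "",
                                   formatC(v, digits = d, format = "f"))
  out <- data.frame(
    Term = tab$term, Estimate = num(tab$estimate, 2), SE = num(tab$se, 2),
    LowerCI = num(tab$ci_lower, 2), UpperCI = num(tab$ci_upper, 2),
    Chisq = num(tab$chisq, 2), df = ifelse(is.na(tab$df), "", tab$df),
    p = num(tab$p, 3), Min = num(tab$stability_min, 2),
    Max = num(tab$stability_max, 2), stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(sprintf(
    "# Full-null model comparison: chisq = %.2f, df = %d, p = %.3f; n_obs = %d, n_subjects = %d%s%s",
    fit$full_null$chisq, fit$full_null$df, fit$full_null$p, fit$n_obs,
    fit$n_subjects, if (!fit$converged) "; NOT CONVERGED" else "",
    if (fit$singular) "; singular fit" else ""), con)
  invisible(path)
}
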