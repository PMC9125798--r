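#' Small-sample-corrected AIC
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts all
#' estimated parameters: fixed effects, variance/covariance components, and
#' the residual variance.
#'
#' @param logLik log-likelihood of the fitted model.
#' @param k_params parameter count as above.
#' @param n_obs number of observations; must exceed `k_params + 1`.
#' @return the AICc value.
#' @export
aicc <- function(logLik, k_params, n_obs) {
  if (n_obs <= k_params + 1) {
    stop("AICc undefined: n (", n_obs, ") must exceed k + 1 (",
         k_params + 1, ")", call. = FALSE)
  }
  -2 * logLik + 2 * k_params + 2 * k_params * (k_params + 1) /
    (n_obs - k_params - 1)
}

.lmm_k <- c(null = 3, random_intercept = 4, random_intercept_slope = 6)

#' Fit one candidate mixed model of a per-cycle response against age
#'
#' Gaussian linear mixed-effects models (via `nlme::lme`) of a per-cycle
#' response (peak T concentration, or cycle period) on whale age, with whale
#' identity as the grouping factor:
#' \describe{
#'   \item{null}{`response ~ 1`, random `~1 | whale`}
#'   \item{random_intercept}{`response ~ age`, random `~1 | whale`}
#'   \item{random_intercept_slope}{`response ~ age`, random
#'     `~1 + age | whale` with unstructured covariance}
#' }
#' Fixed-effect t statistics use the within-group denominator df
#' `N_obs - N_groups - q` (q = fixed covariates varying within whale), the
#' convention `nlme` applies to this design.
#'
#' @param observations data frame with columns `whale_id`, `age_yr`,
#'   `response`.
#' @param variant one of `"null"`, `"random_intercept"`,
#'   `"random_intercept_slope"`.
#' @param estimation `"ML"` or `"REML"`.
#' @return object of class `lmm_result`: the variant and estimation method,
#'   `logLik`, `k`, `n`, `n_groups`, `aicc`, `fixed_effects` (estimate, SE,
#'   t, df, p per term), `variance_components`, `coefficients` (per-whale
#'   fixed + empirical-Bayes estimates), `boundary` flag, and the underlying
#'   `nlme` fit.
#' @export
fit_lmm <- function(observations,
                    variant = c("null", "random_intercept",
                                "random_intercept_slope"),
                    estimation = c("ML", "REML")) {
  variant <- match.arg(variant)
  estimation <- match.arg(estimation)
  obs <- as.data.frame(observations)
  need <- c("whale_id", "age_yr", "response")
  if (!all(need %in% names(obs))) {
    stop("observations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(obs$age_yr)) || any(!is.finite(obs$response))) {
    stop("non-finite values in observations", call. = FALSE)
  }
  obs$whale_id <- factor(obs$whale_id)
  if (nlevels(obs$whale_id) < 2L) stop("need at least 2 whales", call. = FALSE)
  fixed <- if (variant == "null") response ~ 1 else response ~ age_yr
  random <- if (variant == "random_intercept_slope") {
    ~ 1 + age_yr | whale_id
  } else ~ 1 | whale_id
  fit_with <- function(optimizer) {
    ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, opt = optimizer,
                             returnObject = FALSE)
    nlme::lme(fixed = fixed, random = random, data = obs,
              method = estimation, control = ctrl)
  }
  fit <- tryCatch(fit_with("nlminb"), error = function(e1) {
    tryCatch(fit_with("optim"), error = function(e2) {
      stop("LMM (", variant, ", ", estimation, ") failed to converge: ",
           conditionMessage(e1), " / ", conditionMessage(e2), call. = FALSE)
    })
  })
  st <- summary(fit)$tTable
  fe <- data.frame(term = rownames(st), estimate = st[, "Value"],
                   se = st[, "Std.Error"], t = st[, "t-value"],
                   df = st[, "DF"], p = st[, "p-value"],
                   row.names = NULL)
  vc <- nlme::VarCorr(fit)
  variances <- suppressWarnings(as.numeric(vc[, "Variance"]))
  names(variances) <- rownames(vc)
  variances <- variances[is.finite(variances)]
  ll <- as.numeric(stats::logLik(fit))
  k <- .lmm_k[[variant]]
  n <- nrow(obs)
  coefs <- stats::coef(fit)
  if (!"age_yr" %in% names(coefs)) coefs$age_yr <- NA_real_
  res <- list(variant = variant, estimation = estimation,
              logLik = ll, k = k, n = n,
              n_groups = nlevels(obs$whale_id),
              aicc = aicc(ll, k, n),
              fixed_effects = fe,
              variance_components = variances,
              coefficients = data.frame(whale_id = rownames(coefs),
                                        intercept = coefs[["(Intercept)"]],
                                        age_slope = coefs[["age_yr"]],
                                        row.names = NULL),
              boundary = any(variances < 1e-8),
              fit = fit)
  class(res) <- "lmm_result"
  res
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("Linear mixed model (", x$variant, ", ", x$estimation, ")\n", sep = "")
  cat("  n = ", x$n, " observations, ", x$n_groups, " whales; logLik = ",
      round(x$logLik, 1), ", AICc = ", round(x$aicc, 1),
      if (x$boundary) "  [variance at boundary]", "\n", sep = "")
  fe <- x$fixed_effects
  for (i in seq_len(nrow(fe))) {
    cat(sprintf("  %-12s %8.4g (SE %.4g), t = %.3g, df = %d, p = %.3g\n",
                fe$term[i], fe$estimate[i], fe$se[i], fe$t[i],
                as.integer(fe$df[i]), fe$p[i]))
  }
  invisible(x)
}

#' Fit, rank and refit the candidate trend models
#'
#' The three candidate models are fit by maximum likelihood, ranked by AICc
#' (ties broken toward the simpler variant), and the winner is refit by REML
#' for reported estimates. Residual diagnostics (Shapiro-Wilk statistic on
#' standardised residuals and the slope of a scale-location regression) are
#' attached as summaries, not gates.
#'
#' @param observations data frame with `whale_id`, `age_yr`, `response`.
#' @return object of class `lmm_selection`: `comparison` table (variant,
#'   logLik, k, AICc, converged), `best_variant`, `best_fit` (an
#'   [fit_lmm()] result refit by REML), `ml_fits`, `diagnostics`.
#' @export
select_model <- function(observations) {
  variants <- c("null", "random_intercept", "random_intercept_slope")
  ml <- lapply(variants, function(v) {
    tryCatch(fit_lmm(observations, v, "ML"), error = function(e) e)
  })
  names(ml) <- variants
  ok <- !vapply(ml, inherits, logical(1), "error")
  if (!any(ok)) stop("all candidate mixed models failed", call. = FALSE)
  comparison <- data.frame(
    variant = variants,
    logLik = vapply(ml, function(f) if (inherits(f, "error")) NA_real_
                    else f$logLik, numeric(1)),
    k = .lmm_k[variants],
    aicc = vapply(ml, function(f) if (inherits(f, "error")) NA_real_
                  else f$aicc, numeric(1)),
    converged = ok, row.names = NULL)
  # order preserves simplicity ranking; which.min takes the first minimum
  best_variant <- variants[ok][which.min(comparison$aicc[ok])]
  best <- fit_lmm(observations, best_variant, "REML")
  r <- stats::residuals(best$fit, type = "pearson")
  f <- stats::fitted(best$fit)
  sw <- if (length(r) >= 3 && length(r) <= 5000 && stats::sd(r) > 0) {
    stats::shapiro.test(r)$statistic
  } else NA_real_
  sl <- if (stats::sd(f) > 0) {
    unname(stats::coef(stats::lm(sqrt(abs(r)) ~ f))[2L])
  } else NA_real_
  structure(list(comparison = comparison, best_variant = best_variant,
                 best_fit = best, ml_fits = ml,
                 diagnostics = list(shapiro_w = unname(sw),
                                    scale_location_slope = sl)),
            class = "lmm_selection")
}

#' @export
print.lmm_selection <- function(x, ...) {
  cat("Candidate mixed models (ML, ranked by AICc):\n")
  cmp <- x$comparison
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf("  %s %-24s logLik %8.1f  k %d  AICc %8.1f%s\n",
                if (cmp$variant[i] == x$best_variant) "*" else " ",
                cmp$variant[i], cmp$logLik[i], cmp$k[i], cmp$aicc[i],
                if (!cmp$converged[i]) "  [failed]" else ""))
  }
  cat("Selected model refit by REML:\n")
  print(x$best_fit)
  invisible(x)
}

#' Pearson correlation with a two-tailed t test
#'
#' Used to relate per-whale plate summaries (mean, median, maximum, minimum,
#' baseline T; %CV of T peaks) to estimated terminal age across whales.
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `corr_result`: `n`, `r`, `r_squared`,
#'   `p_two_tailed`, `significant`, `t`, `df`.
#' @export
pearson_corr_test <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  structure(list(n = length(x), r = r, r_squared = r^2,
                 p_two_tailed = ct$p.value,
                 significant = ct$p.value < alpha,
                 t = unname(ct$statistic), df = unname(ct$parameter)),
            class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f, r^2 = %.4f, t(%d) = %.3f, ",
              x$r, x$r_squared, x$df, x$t))
  cat(sprintf("p = %.4g%s (n = %d)\n", x$p_two_tailed,
              if (x$significant) " *" else "", x$n))
  invisible(x)
}
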