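#' REML fit of the crossed random-effects model
#'
#' Gaussian mixed model with the overall log2-richness slope as the only
#' fixed effect (besides the intercept) and up to five random batches:
#' site, block in site, species composition (global codes, partially
#' crossed with site), per-site slope deviations and site-by-composition.
#' Fitting is by REML (or ML for deviance comparisons).  Super-population
#' variance components are reported on the variance and SD scales with
#' percent shares on the variance scale over all random terms including
#' the residual.
#'
#' @param records complete-case \code{plot_data} with composition codes.
#' @param terms model terms (subset of
#'   \code{\link{default_term_order}()}; \code{"richness"} = fixed slope).
#' @param REML fit by REML (default) or ML.
#' @return object of class \code{reml_fit}: list with \code{fixed}
#'   (data.frame term/estimate/se), \code{varcomps} (data.frame
#'   source/variance/sd/percent), \code{blups} (named list of per-level
#'   predictions), \code{reml_loglik}, \code{converged}, \code{n},
#'   and the underlying \code{lme4} fit in \code{engine}.
#' @export
reml_fit <- function(records, terms = default_term_order(), REML = TRUE) {
  if (any(is.na(records$anpp)))
    stop("missing anpp; run complete_cases() first", call. = FALSE)
  if (any(!is.finite(records$anpp)))
    stop("non-finite response", call. = FALSE)

  df <- data.frame(
    anpp = records$anpp,
    xc = centered_log2_richness(records),
    site = factor(records$site),
    block_id = factor(records$block_id),
    comp = factor(records$composition_code),
    site_comp = factor(paste(records$site, records$composition_code,
                             sep = ":"))
  )
  parts <- c(
    if ("richness" %in% terms) "xc",
    if ("experiment" %in% terms) "(1 | site)",
    if ("block" %in% terms) "(1 | block_id)",
    if ("exp_richness" %in% terms) "(0 + xc | site)",
    if ("composition" %in% terms) "(1 | comp)",
    if ("exp_composition" %in% terms) "(1 | site_comp)"
  )
  if (!any(grepl("\\|", parts)))
    stop("at least one random batch is required", call. = FALSE)
  form <- stats::as.formula(paste("anpp ~", paste(parts, collapse = " + ")))

  fit <- lme4::lmer(form, data = df, REML = REML,
                    control = lme4::lmerControl(
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore",
                      calc.derivs = FALSE))
  # boundary (singular) fits are converged optima; only true optimizer
  # failures clear the flag
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv <- fit@optinfo$conv$opt == 0L &&
    !any(grepl("failed to converge", msgs, fixed = TRUE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  src_of <- c(site = "experiment", block_id = "block", comp = "composition",
              site_comp = "exp_composition", Residual = "residual")
  # lme4 suffixes repeated grouping factors ("site", "site.1")
  grp <- sub("\\.[0-9]+$", "", vc$grp)
  source <- ifelse(!is.na(vc$var1) & vc$var1 == "xc", "exp_richness",
                   src_of[grp])
  varcomps <- data.frame(source = source, variance = vc$vcov,
                         sd = vc$sdcor, stringsAsFactors = FALSE)
  ord <- c(default_term_order(), "residual")
  varcomps <- varcomps[order(match(varcomps$source, ord)), ]
  varcomps$percent <- 100 * varcomps$variance / sum(varcomps$variance)
  rownames(varcomps) <- NULL

  cf <- summary(fit)$coefficients
  fixed <- data.frame(
    term = ifelse(rownames(cf) == "(Intercept)", "grand_mean", "slope"),
    estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
    stringsAsFactors = FALSE)
  rownames(fixed) <- NULL

  re <- lme4::ranef(fit)
  blups <- list()
  if ("site" %in% names(re)) {
    if ("(Intercept)" %in% names(re$site))
      blups$experiment <- stats::setNames(re$site[["(Intercept)"]],
                                          rownames(re$site))
    if ("xc" %in% names(re$site))
      blups$exp_richness <- stats::setNames(re$site[["xc"]],
                                            rownames(re$site))
  }
  if ("block_id" %in% names(re))
    blups$block <- stats::setNames(re$block_id[[1L]], rownames(re$block_id))
  if ("comp" %in% names(re))
    blups$composition <- stats::setNames(re$comp[[1L]], rownames(re$comp))
  if ("site_comp" %in% names(re))
    blups$exp_composition <- stats::setNames(re$site_comp[[1L]],
                                             rownames(re$site_comp))

  structure(list(fixed = fixed, varcomps = varcomps, blups = blups,
                 reml_loglik = as.numeric(stats::logLik(fit)),
                 converged = conv, n = nrow(df), REML = REML,
                 terms = terms, engine = fit),
            class = "reml_fit")
}

#' Wald-type fixed-effect ANOVA for the richness slope
#'
#' F = (slope/SE)^2 with 1 numerator degree of freedom; the SS and MS are
#' reported on the response scale as F times the residual variance (the
#' convention that makes the row comparable with a least-squares ANOVA
#' table).  No P value is emitted: denominator degrees of freedom are not
#' well defined for crossed designs.
#'
#' @param fit a converged \code{\link{reml_fit}} including the slope.
#' @return data.frame: term, df, ss, ms, f.
#' @export
fixed_effect_anova <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged)
    stop("fit did not converge; refusing to report tests", call. = FALSE)
  row <- fit$fixed[fit$fixed$term == "slope", ]
  if (nrow(row) == 0L)
    stop("model has no richness slope", call. = FALSE)
  f <- (row$estimate / row$se)^2
  s2 <- fit$varcomps$variance[which(fit$varcomps$source == "residual")]
  data.frame(term = "richness", df = 1L, ss = f * s2, ms = f * s2, f = f)
}

#' Likelihood-ratio test for one random batch
#'
#' Both models are refitted by maximum likelihood (not REML) so deviances
#' are comparable; the change in deviance on dropping the batch is
#' reported with two P values: the naive upper-tail chi-squared(1), and
#' the 50:50 mixture of chi-squared(0) and chi-squared(1) appropriate for
#' a variance tested on the boundary of its parameter space.
#'
#' @param records complete-case \code{plot_data}.
#' @param full_terms terms of the full model.
#' @param dropped the random term to remove.
#' @return data.frame: dropped, delta_deviance, p_naive, p_halfmix.
#' @export
lrt_random_term <- function(records, full_terms = default_term_order(),
                            dropped) {
  if (!dropped %in% full_terms)
    stop("dropped term '", dropped, "' not in the full model", call. = FALSE)
  if (dropped == "richness")
    stop("richness is the fixed slope; drop a random batch", call. = FALSE)
  full <- reml_fit(records, full_terms, REML = FALSE)
  red <- reml_fit(records, setdiff(full_terms, dropped), REML = FALSE)
  dd <- 2 * (full$reml_loglik - red$reml_loglik)
  dd <- max(dd, 0)
  p1 <- stats::pchisq(dd, df = 1L, lower.tail = FALSE)
  pmix <- if (dd <= 0) 1 else 0.5 * p1
  data.frame(dropped = dropped, delta_deviance = dd,
             p_naive = p1, p_halfmix = pmix, stringsAsFactors = FALSE)
}

#' BLUP per-site richness slopes
#'
#' Site slope = overall fixed slope + the site's predicted slope
#' deviation (best linear unbiased prediction at the REML estimates);
#' exhibits shrinkage toward the overall slope.
#'
#' @param fit a \code{\link{reml_fit}} including the
#'   \code{exp_richness} batch.
#' @return data.frame: site, slope.
#' @export
blup_slopes <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (is.null(fit$blups$exp_richness))
    stop("fit has no per-site slope deviations", call. = FALSE)
  overall <- fit$fixed$estimate[fit$fixed$term == "slope"]
  dev <- fit$blups$exp_richness
  data.frame(site = names(dev), slope = overall + unname(dev),
             stringsAsFactors = FALSE)
}
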