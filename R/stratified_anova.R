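#' Model terms of the multi-site analysis
#'
#' The six explanatory terms, in the canonical fitting order: experimental
#' site, block within site, sown species richness (continuous, log2
#' scale), species composition (global codes), site-by-richness
#' (separate slope per site) and site-by-composition.
#'
#' @param records a complete-case \code{plot_data} data frame.
#' @param term one of \code{"experiment"}, \code{"block"},
#'   \code{"richness"}, \code{"composition"}, \code{"exp_richness"},
#'   \code{"exp_composition"}.
#' @param categorical_richness treat richness as a factor rather than a
#'   continuous log2-scale covariate (off by default).
#' @return numeric design matrix (no intercept) for the term.
#' @keywords internal
term_matrix <- function(records, term, categorical_richness = FALSE) {
  site_f  <- factor(records$site)
  x <- centered_log2_richness(records)
  switch(term,
    experiment = stats::model.matrix(~ 0 + site_f),
    block = stats::model.matrix(~ 0 + factor(records$block_id)),
    richness = if (categorical_richness)
      stats::model.matrix(~ 0 + factor(records$richness))
      else matrix(x, ncol = 1L, dimnames = list(NULL, "log2_richness")),
    composition = stats::model.matrix(~ 0 + factor(records$composition_code)),
    exp_richness = stats::model.matrix(~ 0 + site_f) * x,
    exp_composition = stats::model.matrix(
      ~ 0 + factor(paste(records$site, records$composition_code, sep = ":"))),
    stop("unknown term: ", term, call. = FALSE)
  )
}

#' Default term order of the stratified ANOVA
#' @export
default_term_order <- function() {
  c("experiment", "block", "richness", "composition",
    "exp_richness", "exp_composition")
}

#' Type-I sequential sums of squares
#'
#' Decomposes the total corrected SS over the given term order.  Each
#' term's SS is the squared norm of the response projection onto the
#' incremental column space of its design columns after sweeping out all
#' earlier terms (and the intercept); its DF is the incremental rank,
#' detected by singular values of the residualized block (relative
#' tolerance \code{tol}).  Aliasing — e.g. composition columns partially
#' absorbed by the site, block and richness margins — is therefore
#' handled purely by rank.
#'
#' @param records complete-case \code{plot_data} (no missing ANPP) with
#'   composition codes assigned.
#' @param term_order character vector of term names
#'   (default \code{\link{default_term_order}}).
#' @param categorical_richness see \code{\link{term_matrix}}.
#' @param tol relative singular-value tolerance for incremental rank.
#' @return list with \code{terms} (data.frame source/df/ss),
#'   \code{residual} (df, ss), \code{total} (df = n-1, ss = corrected SS).
#' @export
sequential_ss <- function(records, term_order = default_term_order(),
                          categorical_richness = FALSE, tol = 1e-8) {
  if (any(is.na(records$anpp)))
    stop("missing anpp; run complete_cases() first", call. = FALSE)
  y <- records$anpp
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("need at least 2 distinct responses", call. = FALSE)

  Q <- matrix(1 / sqrt(n), n, 1L)          # intercept basis
  fitted_ss <- sum((crossprod(Q, y))^2)    # intercept SS (uncorrected)
  rows <- vector("list", length(term_order))

  for (k in seq_along(term_order)) {
    X <- term_matrix(records, term_order[k], categorical_richness)
    scale0 <- max(sqrt(colSums(X^2)), 1)
    # residualize against the accumulated basis (twice, for stability)
    R <- X - Q %*% crossprod(Q, X)
    R <- R - Q %*% crossprod(Q, R)
    sv <- svd(R)
    keep <- sv$d > tol * scale0
    df <- sum(keep)
    if (df > 0L) {
      U <- sv$u[, keep, drop = FALSE]
      ss <- sum((crossprod(U, y))^2)
      Q <- cbind(Q, U)
      fitted_ss <- fitted_ss + ss
    } else ss <- 0
    rows[[k]] <- data.frame(source = term_order[k], df = df, ss = ss,
                            stringsAsFactors = FALSE)
  }

  terms_df <- do.call(rbind, rows)
  total_ss <- sum((y - mean(y))^2)
  resid_df <- n - ncol(Q)
  resid_ss <- sum(y^2) - fitted_ss
  if (resid_df == 0L)
    warning("saturated design: zero residual degrees of freedom")
  list(terms = terms_df,
       residual = list(df = resid_df, ss = max(resid_ss, 0)),
       total = list(df = n - 1L, ss = total_ss))
}

#' Error-term maps for the two mixed-model testing schools
#'
#' The unconstrained school (the default, and the convention of modern
#' mixed-effects software) tests random main effects against their
#' interaction with the other factor; the constrained school tests them
#' against the overall plot-level residual.  Both schools test the fixed
#' richness slope against composition and the site-by-richness interaction
#' against site-by-composition.
#'
#' @param school \code{"unconstrained"} (default) or \code{"constrained"}.
#' @return named character vector: source -> error term
#'   (\code{"residual"} = between-plot error).
#' @export
anova_error_map <- function(school = c("unconstrained", "constrained")) {
  school <- match.arg(school)
  m <- c(experiment = "block", block = "residual",
         richness = "composition", composition = "exp_composition",
         exp_richness = "exp_composition", exp_composition = "residual")
  if (school == "constrained") {
    m[["composition"]] <- "residual"
    m[["experiment"]] <- "residual"
  }
  m
}

#' Assemble a multi-stratum ANOVA table
#'
#' Adds mean squares, F ratios against the mapped error terms, upper-tail
#' F P-values and the percent of the total corrected SS explained by each
#' row.
#'
#' @param ss_result output of \code{\link{sequential_ss}}.
#' @param error_map named character vector mapping each source to the term
#'   whose mean square serves as its denominator
#'   (default \code{\link{anova_error_map}()}).
#' @return data.frame of class \code{anova_vc} with columns source, df,
#'   ss, ms, f, p, error_term, r2_percent; residual and total rows
#'   appended.
#' @export
assemble_anova <- function(ss_result, error_map = anova_error_map()) {
  terms <- ss_result$terms
  known <- c(terms$source, "residual")
  bad <- setdiff(c(names(error_map), unname(error_map)), known)
  if (length(bad) > 0L)
    stop("error map names unknown term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ms_of <- c(stats::setNames(terms$ss / terms$df, terms$source),
             residual = ss_result$residual$ss / ss_result$residual$df)
  df_of <- c(stats::setNames(terms$df, terms$source),
             residual = ss_result$residual$df)

  tab <- terms
  tab$ms <- tab$ss / tab$df
  tab$error_term <- unname(error_map[tab$source])
  usable <- !is.na(tab$error_term) & df_of[tab$error_term] > 0
  tab$f <- ifelse(usable, tab$ms / ms_of[tab$error_term], NA_real_)
  tab$p <- ifelse(usable,
                  stats::pf(tab$f, tab$df, df_of[tab$error_term],
                            lower.tail = FALSE), NA_real_)
  total_ss <- ss_result$total$ss
  tab$r2_percent <- 100 * tab$ss / total_ss

  resid_row <- data.frame(source = "residual", df = ss_result$residual$df,
                          ss = ss_result$residual$ss,
                          ms = ms_of[["residual"]], error_term = NA,
                          f = NA_real_, p = NA_real_,
                          r2_percent = 100 * ss_result$residual$ss / total_ss,
                          stringsAsFactors = FALSE)
  total_row <- data.frame(source = "total", df = ss_result$total$df,
                          ss = total_ss, ms = NA_real_, error_term = NA,
                          f = NA_real_, p = NA_real_,
                          r2_percent = 100, stringsAsFactors = FALSE)
  out <- rbind(tab, resid_row, total_row)[
    , c("source", "df", "ss", "ms", "f", "p", "error_term", "r2_percent")]
  rownames(out) <- NULL
  class(out) <- c("anova_vc", "data.frame")
  out
}

#' @method print anova_vc
#' @export
print.anova_vc <- function(x, ...) {
  d <- as.data.frame(x)
  d$ss <- round(d$ss)
  d$ms <- round(d$ms)
  d$f <- round(d$f, 1)
  d$p <- signif(d$p, 3)
  d$r2_percent <- round(d$r2_percent)
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Per-site OLS richness regressions
#'
#' Ordinary least squares of ANPP on log2 richness within each site, with
#' t-based 95\% confidence intervals for the slope.  Sites with a single
#' richness level get \code{NA} (slope not estimable); two-level sites are
#' estimable.
#'
#' @param records complete-case \code{plot_data}.
#' @param conf confidence level (default 0.95).
#' @return data.frame: site, n, intercept, slope, se, ci_lo, ci_hi, df.
#' @export
per_site_regression <- function(records, conf = 0.95) {
  out <- lapply(split(seq_len(nrow(records)), records$site), function(idx) {
    r <- records[idx, ]
    if (length(unique(r$richness)) < 2L)
      return(data.frame(site = r$site[1L], n = nrow(r),
                        intercept = NA_real_, slope = NA_real_,
                        se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        df = NA_integer_, stringsAsFactors = FALSE))
    x <- log2(r$richness)
    fit <- stats::lm(r$anpp ~ x)
    cf <- summary(fit)$coefficients
    se <- cf["x", "Std. Error"]
    df <- fit$df.residual
    tq <- stats::qt(1 - (1 - conf) / 2, df)
    data.frame(site = r$site[1L], n = nrow(r),
               intercept = cf[1L, 1L], slope = cf["x", 1L], se = se,
               ci_lo = cf["x", 1L] - tq * se, ci_hi = cf["x", 1L] + tq * se,
               df = df, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(unique(records$site), res$site), , drop = FALSE]
}
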