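#' MCMC settings
#'
#' @param n_chains number of independent chains (>= 2).
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every \code{thin}-th post-burn-in iteration.
#' @param seed integer seed controlling all chains.
#' @return validated \code{mcmc_settings} list; its \code{retained} field
#'   is \code{floor((n_iter - burn_in)/thin)} and must be >= 50.
#' @export
mcmc_settings <- function(n_chains = 3L, n_iter = 100000L, burn_in = 5000L,
                          thin = 200L, seed = 1L) {
  stopifnot(n_chains >= 2L, thin >= 1L, burn_in >= 0L, burn_in < n_iter)
  retained <- floor((n_iter - burn_in) / thin)
  if (retained < 50L)
    stop("settings retain only ", retained,
         " draws per chain; need at least 50", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), retained = as.integer(retained)),
            class = "mcmc_settings")
}

#' Vague prior specification
#'
#' Conventional vague priors: uniform(0, \code{sd_upper}) on every batch
#' SD and on the residual SD (default upper bound: 10 times the sample SD
#' of the response) and zero-mean normal with SD \code{loc_scale} on the
#' grand mean and the overall richness slope.  An inverse-gamma(a, b)
#' prior on the variances is available for sensitivity analysis.
#'
#' @param sd_upper upper bound of the uniform SD priors (NULL = derive
#'   from the data at sampling time).
#' @param loc_scale SD of the diffuse normal priors on location parameters.
#' @param family \code{"uniform"} (on SDs) or \code{"invgamma"} (on
#'   variances, shape = rate = \code{ig_par}).
#' @param ig_par inverse-gamma hyperparameter (default 0.001).
#' @return \code{prior_spec} list.
#' @export
prior_spec <- function(sd_upper = NULL, loc_scale = 1e6,
                       family = c("uniform", "invgamma"), ig_par = 0.001) {
  family <- match.arg(family)
  stopifnot(is.null(sd_upper) || sd_upper > 0, loc_scale > 0, ig_par > 0)
  structure(list(sd_upper = sd_upper, loc_scale = loc_scale,
                 family = family, ig_par = ig_par), class = "prior_spec")
}

# draw a batch variance from its full conditional given sum of squares S
# over J effects; uniform prior on the SD truncates the conjugate
# scaled-inverse-chi^2 to (0, sd_upper^2); returns the SD
.draw_sd <- function(J, S, prior, sd_upper) {
  if (prior$family == "invgamma") {
    lam <- stats::rgamma(1L, shape = prior$ig_par + J / 2,
                         rate = prior$ig_par + S / 2)
    return(1 / sqrt(lam))
  }
  shape <- (J - 1) / 2
  rate <- S / 2
  lam_min <- 1 / sd_upper^2          # precision lower bound <=> sd <= upper
  plo <- stats::pgamma(lam_min, shape, rate = rate)
  u <- plo + (1 - plo) * stats::runif(1L)
  lam <- stats::qgamma(min(u, 1 - 1e-15), shape, rate = rate)
  if (!is.finite(lam) || lam <= 0) lam <- lam_min
  1 / sqrt(lam)
}

#' Gibbs sampler for the multilevel variance-components model
#'
#' Fits the hierarchical Gaussian model of plot-level ANPP: grand mean,
#' overall log2-richness slope, and zero-mean normal effect batches for
#' site, block-in-site, species composition (global codes), per-site
#' slope deviations and site-by-composition, plus i.i.d. residuals.  All
#' full conditionals are Gaussian (effects, locations) or truncated
#' scaled-inverse-chi-squared (variances under the uniform-on-SD prior),
#' so the scheme is pure Gibbs.  Per retained draw the finite-population
#' SD of every source is computed and stored: categorical batches as the
#' SD over their level effects, the two richness sources as the SD over
#' plot-level contributions (slope times centered log2 richness), and the
#' residual as the SD of the current plot residuals.
#'
#' @param records complete-case \code{plot_data} with composition codes.
#' @param settings an \code{\link{mcmc_settings}} object.
#' @param priors a \code{\link{prior_spec}} (default vague).
#' @param terms model terms to include (default all six); \code{"richness"}
#'   governs the overall slope.
#' @param fix_residual_sd if non-NULL, hold the residual SD fixed at this
#'   value instead of sampling it (testing hook for conjugate oracles).
#' @param store_effects keep the per-draw effect vectors (default TRUE).
#' @return object of class \code{posterior_draws}: list with
#'   \code{settings}, \code{sources}, and per-chain lists of matrices
#'   \code{location} (beta0, slope), \code{sigma} (super-population SDs),
#'   \code{finite_sd} (finite-population SDs) and \code{effects}.
#' @export
gibbs_sample <- function(records, settings, priors = prior_spec(),
                         terms = default_term_order(),
                         fix_residual_sd = NULL, store_effects = TRUE) {
  stopifnot(inherits(settings, "mcmc_settings"), inherits(priors, "prior_spec"))
  if (any(is.na(records$anpp)))
    stop("missing anpp; run complete_cases() first", call. = FALSE)
  y <- records$anpp
  if (any(!is.finite(y))) stop("non-finite response", call. = FALSE)
  n <- length(y)
  x <- centered_log2_richness(records)
  sdy <- stats::sd(y)
  sd_upper <- if (is.null(priors$sd_upper)) 10 * sdy else priors$sd_upper
  tau2 <- priors$loc_scale^2

  cat_terms <- intersect(terms,
                         c("experiment", "block", "composition",
                           "exp_composition"))
  use_slope <- "richness" %in% terms
  use_gdev <- "exp_richness" %in% terms

  idx <- list(
    experiment = as.integer(factor(records$site)),
    block = as.integer(factor(records$block_id)),
    composition = as.integer(factor(records$composition_code)),
    exp_composition = as.integer(factor(paste(records$site,
                                              records$composition_code,
                                              sep = ":")))
  )
  site_ix <- idx$experiment
  J <- vapply(idx, max, integer(1L))
  nj <- lapply(idx, tabulate)
  w2_site <- as.numeric(rowsum(x^2, site_ix))    # per-site sum of x^2
  nE <- max(site_ix)

  sources <- c(intersect(default_term_order(), terms), "residual")
  n_keep <- settings$retained
  mult <- rep(c(0.5, 1, 2), length.out = settings$n_chains)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))

  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + 1000L * (ch - 1L))
    beta0 <- mean(y); gam <- 0
    eff <- lapply(J, function(j) numeric(j))
    g <- numeric(nE)
    sig <- c(experiment = sdy, block = sdy, richness = NA, composition = sdy,
             exp_richness = sdy / max(stats::sd(x), 0.1),
             exp_composition = sdy, residual = sdy) * mult[ch]
    if (!is.null(fix_residual_sd)) sig[["residual"]] <- fix_residual_sd

    r <- y - beta0
    for (b in cat_terms) r <- r - eff[[b]][idx[[b]]]
    if (use_slope) r <- r - gam * x
    if (use_gdev) r <- r - g[site_ix] * x

    loc_keep <- matrix(NA_real_, n_keep, 2L,
                       dimnames = list(NULL, c("grand_mean", "slope")))
    sig_keep <- matrix(NA_real_, n_keep, length(sources),
                       dimnames = list(NULL, sources))
    fsd_keep <- sig_keep
    eff_keep <- if (store_effects)
      stats::setNames(lapply(c(cat_terms, if (use_gdev) "exp_richness"),
                             function(b) matrix(NA_real_, n_keep,
                               if (b == "exp_richness") nE else J[[b]])),
                      c(cat_terms, if (use_gdev) "exp_richness"))

    kept <- 0L
    for (it in seq_len(settings$n_iter)) {
      s2 <- sig[["residual"]]^2

      # grand mean
      radd <- r + beta0
      prec <- n / s2 + 1 / tau2
      beta0 <- stats::rnorm(1L, (sum(radd) / s2) / prec, sqrt(1 / prec))
      r <- radd - beta0

      # overall slope
      if (use_slope) {
        radd <- r + gam * x
        prec <- sum(x^2) / s2 + 1 / tau2
        gam <- stats::rnorm(1L, (sum(x * radd) / s2) / prec, sqrt(1 / prec))
        r <- radd - gam * x
      }

      # categorical batches
      for (b in cat_terms) {
        u <- eff[[b]]; ix <- idx[[b]]
        radd <- r + u[ix]
        prec <- nj[[b]] / s2 + 1 / sig[[b]]^2
        mean_j <- (as.numeric(rowsum(radd, ix)) / s2) / prec
        u <- stats::rnorm(J[[b]], mean_j, sqrt(1 / prec))
        eff[[b]] <- u
        r <- radd - u[ix]
        sig[[b]] <- .draw_sd(J[[b]], sum(u^2), priors, sd_upper)
      }

      # per-site slope deviations
      if (use_gdev) {
        radd <- r + g[site_ix] * x
        prec <- w2_site / s2 + 1 / sig[["exp_richness"]]^2
        mean_j <- (as.numeric(rowsum(x * radd, site_ix)) / s2) / prec
        g <- stats::rnorm(nE, mean_j, sqrt(1 / prec))
        r <- radd - g[site_ix] * x
        sig[["exp_richness"]] <- .draw_sd(nE, sum(g^2), priors,
                                          sd_upper / max(stats::sd(x), 0.1))
      }

      # residual SD
      if (is.null(fix_residual_sd))
        sig[["residual"]] <- .draw_sd(n, sum(r^2), priors, sd_upper)

      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L &&
          kept < n_keep) {
        kept <- kept + 1L
        if (!all(is.finite(r)))
          stop("numerical overflow at iteration ", it, call. = FALSE)
        loc_keep[kept, ] <- c(beta0, gam)
        for (src in sources) {
          sig_keep[kept, src] <- switch(src,
            richness = NA_real_, residual = sig[["residual"]],
            sig[[src]])
          fsd_keep[kept, src] <- switch(src,
            experiment = stats::sd(eff$experiment),
            block = stats::sd(eff$block),
            composition = stats::sd(eff$composition),
            exp_composition = stats::sd(eff$exp_composition),
            richness = stats::sd(gam * x),
            exp_richness = stats::sd(g[site_ix] * x),
            residual = stats::sd(r))
        }
        if (store_effects)
          for (b in names(eff_keep))
            eff_keep[[b]][kept, ] <-
              if (b == "exp_richness") g else eff[[b]]
      }
    }
    chains[[ch]] <- list(location = loc_keep, sigma = sig_keep,
                         finite_sd = fsd_keep, effects = eff_keep)
  }

  structure(list(settings = settings, priors = priors, sources = sources,
                 chains = chains, n_plots = n, sd_upper = sd_upper),
            class = "posterior_draws")
}

#' Finite-population standard deviation of one source
#'
#' Categorical sources: SD over the batch's level effects, centered at the
#' batch mean, denominator (J - 1).  Continuous sources (richness and its
#' site interaction): SD over the finite population of plot-level centered
#' contributions — slope times centered log2 richness — denominator
#' (n - 1).  Both reduce to \code{sd()} of the supplied vector.
#'
#' @param effects level effects (categorical) or plot-level contributions
#'   (continuous); length >= 2.
#' @param kind \code{"categorical"} or \code{"continuous"} (documents the
#'   convention; the arithmetic is identical).
#' @return nonnegative scalar.
#' @export
finite_pop_sd <- function(effects, kind = c("categorical", "continuous")) {
  match.arg(kind)
  if (length(effects) < 2L)
    stop("finite-population SD undefined for fewer than 2 values",
         call. = FALSE)
  stats::sd(effects)
}

#' Potential scale reduction factor (R-hat)
#'
#' Brooks-Gelman-Rubin statistic
#' \eqn{\sqrt{((n-1)/n \, W + B/n)/W}} from the between-chain variance of
#' the chain means (\eqn{B/n}) and the mean within-chain variance
#' \eqn{W}.
#'
#' @param chains matrix (iterations x chains) or list of equal-length
#'   numeric vectors, >= 2 chains of length >= 10.
#' @return scalar R-hat; \code{NA} (with a warning) if all chains have
#'   zero within-chain variance.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2L || n < 10L)
    stop("need >= 2 chains of length >= 10", call. = FALSE)
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) {
    warning("zero within-chain variance; R-hat undefined")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior finite-population variance components
#'
#' Pools chains and reports, per source, the posterior median of the
#' finite-population SD (the point estimate), its posterior SD (reported
#' as SE), the 2.5/16/84/97.5\% empirical quantiles, and the percent
#' share of the summed SD-scale medians.  Chains are checked for
#' convergence (R-hat of grand mean, slope and every finite-population
#' SD); failure sets a flag rather than raising.
#'
#' @param draws a \code{posterior_draws} object.
#' @param rhat_threshold convergence threshold (default 1.1).
#' @return list with \code{varcomp} (data.frame: source, sd_point, sd_se,
#'   q2_5, q16, q84, q97_5, percent_share), \code{convergence}
#'   (data.frame: parameter, rhat, pass) and \code{converged} flag.
#' @export
summarize_posterior <- function(draws, rhat_threshold = 1.1) {
  stopifnot(inherits(draws, "posterior_draws"))
  srcs <- draws$sources
  fsd <- lapply(draws$chains, `[[`, "finite_sd")
  pooled <- do.call(rbind, fsd)

  rows <- lapply(srcs, function(s) {
    v <- pooled[, s]
    q <- stats::quantile(v, c(0.025, 0.16, 0.84, 0.975), names = FALSE)
    data.frame(source = s, sd_point = stats::median(v), sd_se = stats::sd(v),
               q2_5 = q[1L], q16 = q[2L], q84 = q[3L], q97_5 = q[4L],
               stringsAsFactors = FALSE)
  })
  vc <- do.call(rbind, rows)
  vc$percent_share <- sd_percent_share(vc$sd_point)

  mon <- c("grand_mean", "slope")
  rh <- c(
    vapply(mon, function(p) rhat(lapply(draws$chains,
      function(ch) ch$location[, p])), numeric(1L)),
    vapply(srcs, function(s) suppressWarnings(rhat(lapply(draws$chains,
      function(ch) ch$finite_sd[, s]))), numeric(1L))
  )
  conv <- data.frame(parameter = c(mon, srcs), rhat = unname(rh),
                     pass = !is.na(rh) & rh < rhat_threshold,
                     stringsAsFactors = FALSE)
  list(varcomp = vc, convergence = conv, converged = all(conv$pass))
}
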