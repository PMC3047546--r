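#' Default 12-site grassland design configuration
#'
#' The design skeleton of the combined grassland biodiversity analysis:
#' twelve experimental sites, each with its blocks, sown richness gradient
#' (log2-spaced levels), number of distinct species compositions and plot
#' count.  Totals: 359 site-local compositions, 29 blocks, 778 plots.
#'
#' @return list of per-site configs, each a list with \code{site},
#'   \code{blocks}, \code{richness} (integer vector of levels),
#'   \code{n_comps}, \code{n_plots}.
#' @export
default_design <- function() {
  spec <- list(
    list(site = "Wageningen",  blocks = 6L, richness = c(1L, 8L),
         n_comps = 9L,  n_plots = 54L),
    list(site = "Portugal",    blocks = 1L, richness = c(1L, 2L, 4L, 8L, 14L),
         n_comps = 27L, n_plots = 56L),
    list(site = "BioCON",      blocks = 3L, richness = c(1L, 4L, 16L),
         n_comps = 21L, n_plots = 56L),
    list(site = "Greece",      blocks = 2L, richness = c(1L, 2L, 4L, 8L, 18L),
         n_comps = 26L, n_plots = 52L),
    list(site = "Sweden",      blocks = 2L, richness = c(1L, 2L, 4L, 8L, 12L),
         n_comps = 28L, n_plots = 58L),
    list(site = "Jena",        blocks = 4L, richness = c(1L, 2L, 4L, 8L, 16L),
         n_comps = 78L, n_plots = 156L),
    list(site = "Switzerland", blocks = 2L, richness = c(1L, 2L, 4L, 8L, 32L),
         n_comps = 32L, n_plots = 64L),
    list(site = "Sheffield",   blocks = 2L, richness = c(1L, 2L, 4L, 8L, 12L),
         n_comps = 26L, n_plots = 54L),
    list(site = "Silwood",     blocks = 2L, richness = c(1L, 2L, 4L, 8L, 11L),
         n_comps = 33L, n_plots = 66L),
    list(site = "BioGEN",      blocks = 1L, richness = c(1L, 4L),
         n_comps = 16L, n_plots = 32L),
    list(site = "Ireland",     blocks = 2L, richness = c(1L, 2L, 3L, 4L, 8L),
         n_comps = 33L, n_plots = 70L),
    list(site = "Bayreuth",    blocks = 2L, richness = c(1L, 2L, 4L, 8L, 16L),
         n_comps = 30L, n_plots = 60L)
  )
  spec
}

# split n as evenly as possible into k parts, remainder to the first parts
even_split <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}

#' Build a multi-site design skeleton
#'
#' Lays out plots, blocks and species compositions for each configured
#' site: compositions are split as evenly as possible over the site's
#' richness levels, replicate plots as evenly as possible over
#' compositions, and plots assigned to blocks round-robin.  A fraction of
#' each site's compositions (at richness levels already seen at earlier
#' sites) reuse a species set introduced by an earlier site, producing the
#' partially crossed site-by-composition structure: identical species sets
#' share one global \code{composition_code}.
#'
#' @param design per-site configuration list, see \code{\link{default_design}}.
#' @param sharing_fraction fraction in [0,1] of each site's shareable
#'   compositions that reuse a species set from an earlier site.
#' @param seed integer seed; the skeleton is deterministic given it.
#' @param species_pool character vector of species names sets are drawn
#'   from (must be at least as long as the largest richness level).
#' @return a \code{plot_data} data frame with \code{anpp = NA}, carrying
#'   attributes \code{membership} (site, composition, species long table)
#'   and \code{sharing_fraction}.
#' @export
build_skeleton <- function(design, sharing_fraction = 0, seed = 1L,
                           species_pool = sprintf("sp%03d", 1:120)) {
  stopifnot(sharing_fraction >= 0, sharing_fraction <= 1)
  if (max(unlist(lapply(design, `[[`, "richness"))) > length(species_pool))
    stop("species pool smaller than the largest richness level", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  registry <- list()   # per richness level: list of species-set vectors
  set_keys <- character(0)
  rows <- list(); memb <- list()
  n_shareable_total <- 0L

  for (cfg in design) {
    lv <- sort(cfg$richness)
    per_level <- even_split(cfg$n_comps, length(lv))
    comp_rich <- rep(lv, per_level)              # richness of each comp
    # shareable = comps whose level already has registered sets
    shareable <- vapply(comp_rich, function(r)
      length(registry[[as.character(r)]]) > 0L, logical(1L))
    n_shareable_total <- n_shareable_total + sum(shareable)
    n_reuse <- floor(sharing_fraction * sum(shareable) + 1e-9)
    # spread reuse over the whole richness gradient (comp_rich is sorted),
    # as in the real multi-site designs where mixtures as well as
    # monocultures recur across sites; this also keeps the site-by-richness
    # stratum estimable after the composition margin
    slots <- which(shareable)
    reuse_slots <- if (n_reuse > 0L)
      slots[unique(round(seq(1L, length(slots), length.out = n_reuse)))]
    else integer(0)

    used_here <- character(0)
    comp_sets <- vector("list", cfg$n_comps)
    for (j in seq_len(cfg$n_comps)) {
      r <- comp_rich[j]
      if (j %in% reuse_slots) {
        cand <- registry[[as.character(r)]]
        keys <- vapply(cand, paste, character(1L), collapse = "|")
        cand <- cand[!keys %in% used_here]
        if (length(cand) == 0L) {      # all same-level sets already used here
          comp_sets[[j]] <- .new_species_set(r, species_pool, set_keys)
        } else {
          comp_sets[[j]] <- cand[[sample.int(length(cand), 1L)]]
        }
      } else {
        comp_sets[[j]] <- .new_species_set(r, species_pool, set_keys)
      }
      key <- paste(comp_sets[[j]], collapse = "|")
      if (!key %in% set_keys) {
        set_keys <- c(set_keys, key)
        registry[[as.character(r)]] <-
          c(registry[[as.character(r)]], list(comp_sets[[j]]))
      }
      used_here <- c(used_here, key)
    }

    reps <- even_split(cfg$n_plots, cfg$n_comps)
    comp_lab <- sprintf("c%03d", seq_len(cfg$n_comps))
    plot_comp <- rep(seq_len(cfg$n_comps), reps)
    nb <- cfg$blocks
    rows[[cfg$site]] <- data.frame(
      site = cfg$site,
      block = as.character(((seq_along(plot_comp) - 1L) %% nb) + 1L),
      plot = paste0(cfg$site, "_p", sprintf("%03d", seq_along(plot_comp))),
      richness = comp_rich[plot_comp],
      composition = comp_lab[plot_comp],
      anpp = NA_real_,
      stringsAsFactors = FALSE
    )
    memb[[cfg$site]] <- data.frame(
      site = cfg$site,
      composition = rep(comp_lab, lengths(comp_sets)),
      species = unlist(comp_sets),
      stringsAsFactors = FALSE
    )
  }

  if (sharing_fraction > 0 && n_shareable_total == 0L)
    stop("sharing requested but no richness level is shared between sites",
         call. = FALSE)

  records <- plot_data(do.call(rbind, rows))
  membership <- do.call(rbind, memb)
  rownames(membership) <- NULL
  records <- deduplicate_compositions(records, membership)
  attr(records, "membership") <- membership
  attr(records, "sharing_fraction") <- sharing_fraction
  records
}

.new_species_set <- function(r, pool, taken_keys) {
  for (i in 1:1000) {
    s <- sort(sample(pool, r))
    if (!paste(s, collapse = "|") %in% taken_keys) return(s)
  }
  stop("could not draw a fresh species set; enlarge the species pool",
       call. = FALSE)
}

#' Tune the cross-site sharing fraction to a target global composition count
#'
#' Searches the smallest \code{sharing_fraction} whose deterministic reuse
#' allocation yields the requested number of distinct global composition
#' codes (the combined design has 359 site-local compositions collapsing
#' to 308 global codes).
#'
#' @param design per-site configuration list.
#' @param target_global desired number of distinct composition codes.
#' @param seed seed forwarded to \code{\link{build_skeleton}}.
#' @param grid candidate fractions searched in order.
#' @return the tuned fraction (scalar).
#' @export
tune_sharing_fraction <- function(design, target_global = 308L, seed = 1L,
                                  grid = seq(0, 1, by = 0.002)) {
  for (f in grid) {
    sk <- build_skeleton(design, sharing_fraction = f, seed = seed)
    if (length(unique(sk$composition_code)) <= target_global) {
      if (length(unique(sk$composition_code)) == target_global) return(f)
      break
    }
  }
  stop("no grid fraction attains exactly ", target_global, " global codes",
       call. = FALSE)
}

#' Ground-truth parameters of the hierarchical generative model
#'
#' The plot response is
#' \deqn{y_i = \beta_0 + e_{site(i)} + b_{block(i)} +
#'   (\gamma + g_{site(i)}) \tilde x_i + c_{comp(i)} + d_{site:comp(i)}
#'   + \varepsilon_i}
#' with \eqn{\tilde x_i} the centered log2 sown richness and every effect
#' batch drawn from its own zero-mean normal distribution.  All SDs in
#' g m\eqn{^{-2}} yr\eqn{^{-1}}; the two slope-scale parameters
#' (\code{mean_slope}, \code{sd_richness_site}) are per log2-richness unit.
#'
#' @param grand_mean overall expected ANPP (\eqn{\beta_0}).
#' @param mean_slope expected richness slope \eqn{\gamma}.
#' @param sd_experiment,sd_block,sd_composition,sd_exp_composition SDs of
#'   the site, block, composition and site-by-composition effect batches.
#' @param sd_richness_site SD of per-site slope deviations \eqn{g}.
#' @param sd_residual plot-level residual SD (> 0).
#' @return object of class \code{truth_params}.
#' @export
truth_params <- function(grand_mean, mean_slope, sd_experiment, sd_block,
                         sd_richness_site, sd_composition,
                         sd_exp_composition, sd_residual) {
  p <- list(grand_mean = grand_mean, mean_slope = mean_slope,
            sd_experiment = sd_experiment, sd_block = sd_block,
            sd_richness_site = sd_richness_site,
            sd_composition = sd_composition,
            sd_exp_composition = sd_exp_composition,
            sd_residual = sd_residual)
  sds <- unlist(p[grep("^sd_", names(p))])
  if (any(sds < 0) || p$sd_residual <= 0)
    stop("SDs must be nonnegative and sd_residual > 0", call. = FALSE)
  structure(p, class = "truth_params")
}

#' Default truth calibrated to the published variance-component magnitudes
#'
#' SD-scale defaults (96.5, 26.0, 114.2, 101.1, 116.5 for site, block,
#' composition, site-by-composition, residual) are the finite-population
#' point estimates reported for the combined grassland analysis; the
#' richness (111.2) and site-by-richness (80.3) values are converted to
#' the slope scale by dividing by the SD of centered log2 richness over
#' the skeleton's plots.  Grand mean 420 g m\eqn{^{-2}} yr\eqn{^{-1}}
#' (the design-weighted magnitude of the sites' mean ANPP).  This is a
#' calibration, not gospel.
#'
#' @param skeleton a design skeleton (used only for the richness spread).
#' @return a \code{\link{truth_params}} object.
#' @export
default_truth <- function(skeleton) {
  sx <- stats::sd(centered_log2_richness(skeleton))
  truth_params(
    grand_mean = 420, mean_slope = 111.2 / sx,
    sd_experiment = 96.5, sd_block = 26.0,
    sd_richness_site = 80.3 / sx,
    sd_composition = 114.2, sd_exp_composition = 101.1,
    sd_residual = 116.5
  )
}

#' Centered log2 richness covariate
#'
#' @param records a \code{plot_data} data frame.
#' @param center optional fixed centering constant (defaults to the mean
#'   of log2 richness over the given records).
#' @return numeric vector \eqn{\tilde x}.
#' @export
centered_log2_richness <- function(records, center = NULL) {
  x <- log2(records$richness)
  if (is.null(center)) center <- mean(x)
  x - center
}

#' Simulate plot responses from the hierarchical model
#'
#' Draws one effect per level of each batch from its zero-mean normal,
#' forms the plot means additively and adds i.i.d. residual noise.
#' The realized (finite-population) SD of every source is recorded in the
#' \code{realized_sd} attribute for parameter-recovery testing:
#' categorical batches use the SD over their levels, the two
#' richness-related sources use the SD over plot-level contributions
#' (slope times centered log2 richness), and the residual uses the SD of
#' the realized residuals.
#'
#' @param skeleton a design skeleton from \code{\link{build_skeleton}}.
#' @param truth a \code{\link{truth_params}} object.
#' @param seed integer seed.
#' @param missing_frac fraction of plots whose ANPP is set missing
#'   completely at random (default 0).
#' @return a \code{plot_data} data frame with simulated \code{anpp} and
#'   attributes \code{realized_sd} (named vector over the seven sources)
#'   and \code{truth}.
#' @export
simulate_responses <- function(skeleton, truth, seed = 1L,
                               missing_frac = 0) {
  stopifnot(inherits(truth, "truth_params"),
            missing_frac >= 0, missing_frac < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  rec <- skeleton
  x <- centered_log2_richness(rec)
  site_f  <- factor(rec$site, levels = unique(rec$site))
  block_f <- factor(rec$block_id, levels = unique(rec$block_id))
  comp_f  <- factor(rec$composition_code,
                    levels = sort(unique(rec$composition_code)))
  sc_f    <- factor(paste(rec$site, rec$composition_code, sep = ":"),
                    levels = unique(paste(rec$site, rec$composition_code,
                                          sep = ":")))

  e  <- stats::rnorm(nlevels(site_f),  0, truth$sd_experiment)
  b  <- stats::rnorm(nlevels(block_f), 0, truth$sd_block)
  g  <- stats::rnorm(nlevels(site_f),  0, truth$sd_richness_site)
  cc <- stats::rnorm(nlevels(comp_f),  0, truth$sd_composition)
  d  <- stats::rnorm(nlevels(sc_f),    0, truth$sd_exp_composition)
  eps <- stats::rnorm(nrow(rec), 0, truth$sd_residual)

  mu <- truth$grand_mean + e[site_f] + b[block_f] +
    (truth$mean_slope + g[site_f]) * x + cc[comp_f] + d[sc_f]
  rec$anpp <- mu + eps
  if (missing_frac > 0) {
    nmiss <- round(missing_frac * nrow(rec))
    rec$anpp[sample.int(nrow(rec), nmiss)] <- NA_real_
  }

  realized <- c(
    experiment      = stats::sd(e),
    block           = stats::sd(b),
    richness        = stats::sd(truth$mean_slope * x),
    composition     = stats::sd(cc),
    exp_richness    = stats::sd(g[site_f] * x),
    exp_composition = stats::sd(d),
    residual        = stats::sd(eps)
  )
  attr(rec, "realized_sd") <- realized
  attr(rec, "truth") <- truth
  attr(rec, "membership") <- attr(skeleton, "membership")
  validate_plot_data(rec, nonneg_anpp = FALSE)
  rec
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
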