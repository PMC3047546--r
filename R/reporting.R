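#' Graphical ANOVA of finite-population variance components
#'
#' One row per source in model order: the SD-scale point estimate with a
#' wide 95\% interval and a narrow (thicker) 68\% interval nested inside
#' it — the estimation-based replacement for an F-table.
#'
#' @param varcomp data.frame with columns source, sd_point, q2_5, q16,
#'   q84, q97_5 (as produced by \code{\link{summarize_posterior}}).
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return \code{path}, invisibly.
#' @export
graphical_anova_plot <- function(varcomp, path, width = 800, height = 500) {
  if (nrow(varcomp) < 1L) stop("no source rows to plot", call. = FALSE)
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write figure to ", path, call. = FALSE)
  on.exit(grDevices::dev.off())
  n <- nrow(varcomp)
  ypos <- rev(seq_len(n))
  old <- graphics::par(mar = c(4.5, 10, 2, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  xlim <- c(0, max(varcomp$q97_5) * 1.05)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = expression("Finite-population SD (g" ~ m^-2 ~ yr^-1 * ")"),
                 ylab = "", main = "Graphical ANOVA")
  graphics::axis(2, at = ypos, labels = varcomp$source, las = 1)
  graphics::segments(varcomp$q2_5, ypos, varcomp$q97_5, ypos, lwd = 1)
  graphics::segments(varcomp$q16, ypos, varcomp$q84, ypos, lwd = 3)
  graphics::points(varcomp$sd_point, ypos, pch = 16, cex = 1.2)
  invisible(path)
}

#' Per-composition mean ANPP with standard errors
#'
#' SEM = within-composition sample SD / sqrt(replicates); omitted
#' (\code{NA}) for single-replicate compositions.
#'
#' @param records complete-case \code{plot_data}.
#' @return data.frame: site, composition_code, richness, n, mean, sem.
#' @export
composition_means <- function(records) {
  key <- paste(records$site, records$composition_code, sep = ":")
  out <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    r <- records[idx, ]
    data.frame(site = r$site[1L], composition_code = r$composition_code[1L],
               richness = r$richness[1L], n = nrow(r),
               mean = mean(r$anpp),
               sem = if (nrow(r) > 1L) stats::sd(r$anpp) / sqrt(nrow(r))
                     else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-site richness-response panels
#'
#' \code{mode = "ols"}: plot-level points with the within-site OLS line
#' and its 95\% confidence band.  \code{mode = "blup"}: per-composition
#' means with SEM bars, the overall average slope (red) and the
#' shrunken per-site predicted slope (black) from the mixed model.
#' Sites without an estimable slope are drawn without a line.
#'
#' @param records complete-case \code{plot_data}.
#' @param path output PNG path.
#' @param mode \code{"ols"} or \code{"blup"}.
#' @param fit a \code{\link{reml_fit}} (required for \code{mode="blup"}).
#' @param width,height device size in pixels.
#' @return \code{path}, invisibly.
#' @export
slope_panels <- function(records, path, mode = c("ols", "blup"),
                         fit = NULL, width = 1000, height = 750) {
  mode <- match.arg(mode)
  sites <- unique(records$site)
  if (mode == "blup") {
    if (is.null(fit)) stop("mode='blup' needs a reml_fit", call. = FALSE)
    bl <- blup_slopes(fit)
    overall <- fit$fixed$estimate[fit$fixed$term == "slope"]
    beta0 <- fit$fixed$estimate[fit$fixed$term == "grand_mean"]
    site_int <- fit$blups$experiment
    cm <- composition_means(records)
  } else {
    ols <- per_site_regression(records)
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  nc <- ceiling(sqrt(length(sites)))
  nr <- ceiling(length(sites) / nc)
  old <- graphics::par(mfrow = c(nr, nc), mar = c(3.5, 3.5, 2, 0.5),
                       mgp = c(2, 0.7, 0))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  xoff <- mean(log2(records$richness))    # centering constant

  for (s in sites) {
    r <- records[records$site == s, ]
    lx <- log2(r$richness)
    if (mode == "ols") {
      graphics::plot(lx, r$anpp, main = s, xlab = "log2 richness",
                     ylab = "ANPP", pch = 1, col = "grey40")
      row <- ols[ols$site == s, ]
      if (!is.na(row$slope)) {
        xs <- seq(min(lx), max(lx), length.out = 50)
        fit_s <- stats::lm(r$anpp ~ lx)
        pr <- stats::predict(fit_s, newdata = data.frame(lx = xs),
                             interval = "confidence")
        graphics::lines(xs, pr[, "fit"], lwd = 2)
        graphics::lines(xs, pr[, "lwr"], lty = 2)
        graphics::lines(xs, pr[, "upr"], lty = 2)
      } else warning("site ", s, ": slope not estimable; panel has no line")
    } else {
      m <- cm[cm$site == s, ]
      graphics::plot(log2(m$richness), m$mean, main = s,
                     xlab = "log2 richness", ylab = "ANPP", pch = 16)
      has_sem <- !is.na(m$sem)
      graphics::arrows(log2(m$richness)[has_sem], (m$mean - m$sem)[has_sem],
                       log2(m$richness)[has_sem], (m$mean + m$sem)[has_sem],
                       angle = 90, code = 3, length = 0.02)
      xs <- range(log2(m$richness))
      a0 <- beta0 + unname(site_int[s])
      graphics::lines(xs, beta0 + overall * (xs - xoff), col = "red", lwd = 2)
      graphics::lines(xs, a0 + bl$slope[bl$site == s] * (xs - xoff),
                      col = "black", lwd = 2)
    }
  }
  invisible(path)
}

# write a CSV whose first line records the input dataset's checksum
write_bundle_table <- function(df, path, checksum) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dataset_md5: ", checksum), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a pipeline bundle table
#' @param path CSV written by \code{\link{run_pipeline}}.
#' @return data.frame (checksum comment line skipped).
#' @export
read_bundle_table <- function(path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)

#' Default pipeline configuration
#'
#' @return nested list understood by \code{\link{run_pipeline}}: input
#'   (NULL = simulate), stages, seed, and per-stage settings.
#' @export
default_config <- function() {
  list(
    input = NULL,
    stages = c("simulate", "anova", "reml", "bayes", "figures"),
    seed = 1L,
    simulate = list(sharing_fraction = 0.192, missing_frac = 0,
                    grand_mean = 420),
    anova = list(school = "unconstrained"),
    bayes = list(chains = 3L, iter = 5000L, burnin = 500L, thin = 10L,
                 sd_upper = NULL, store_draws = FALSE)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages — simulate (or load a CSV), stratified
#' ANOVA, REML mixed model, Bayesian multilevel model, figures — writing
#' every table as CSV (stamped with the input dataset's MD5 checksum),
#' figures as PNG, and run metadata as JSON into \code{out_dir}.
#' Deterministic given the seed.  A stage failure aborts with the stage
#' name; outputs of completed stages are preserved.
#'
#' @param config config list (see \code{\link{default_config}}) or path
#'   to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return list of written artifact paths plus key in-memory tables.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  for (k in names(base))
    if (is.null(config[[k]])) config[[k]] <- base[[k]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  seed <- as.integer(config$seed)
  artifacts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  data_path <- file.path(out_dir, "dataset.csv")
  if (is.null(config$input)) {
    records <- stage("simulate", {
      sim <- config$simulate
      sk <- build_skeleton(default_design(),
                           sharing_fraction = sim$sharing_fraction %||% 0.192,
                           seed = seed)
      tr <- default_truth(sk)
      if (!is.null(sim$grand_mean)) tr$grand_mean <- sim$grand_mean
      simulate_responses(sk, tr, seed = seed,
                         missing_frac = sim$missing_frac %||% 0)
    })
    write_plot_data(records, data_path)
  } else {
    records <- stage("load", read_plot_data(config$input,
                                            nonneg_anpp = FALSE))
    file.copy(config$input, data_path, overwrite = TRUE)
    if (all(is.na(records$composition_code)))
      records$composition_code <-
        as.integer(factor(paste(records$site, records$composition)))
  }
  checksum <- unname(tools::md5sum(data_path))
  artifacts$dataset <- data_path
  records <- complete_cases(records)

  if ("anova" %in% stages) {
    stage("anova", {
      tab <- assemble_anova(sequential_ss(records),
                            anova_error_map(config$anova$school %||%
                                              "unconstrained"))
      write_bundle_table(as.data.frame(tab),
                         file.path(out_dir, "anova.csv"), checksum)
      writeLines(utils::capture.output(print(tab)),
                 file.path(out_dir, "anova.txt"))
      ols <- per_site_regression(records)
      write_bundle_table(ols, file.path(out_dir, "slopes_ols.csv"), checksum)
      artifacts$anova <- file.path(out_dir, "anova.csv")
      artifacts$anova_table <- tab
      artifacts$ols <- ols
    })
  }

  if ("reml" %in% stages) {
    stage("reml", {
      fit <- reml_fit(records)
      write_bundle_table(fit$fixed, file.path(out_dir, "reml_fixed.csv"),
                         checksum)
      write_bundle_table(fit$varcomps,
                         file.path(out_dir, "reml_varcomp.csv"), checksum)
      write_bundle_table(fixed_effect_anova(fit),
                         file.path(out_dir, "reml_fixed_anova.csv"), checksum)
      lrt <- do.call(rbind, lapply(
        setdiff(default_term_order(), "richness"),
        function(tm) lrt_random_term(records, dropped = tm)))
      write_bundle_table(lrt, file.path(out_dir, "reml_lrt.csv"), checksum)
      write_bundle_table(blup_slopes(fit),
                         file.path(out_dir, "slopes_blup.csv"), checksum)
      artifacts$reml_fit <- fit
    })
  }

  if ("bayes" %in% stages) {
    stage("bayes", {
      bcf <- config$bayes
      st <- mcmc_settings(n_chains = bcf$chains %||% 3L,
                          n_iter = bcf$iter %||% 5000L,
                          burn_in = bcf$burnin %||% 500L,
                          thin = bcf$thin %||% 10L, seed = seed)
      pr <- prior_spec(sd_upper = bcf$sd_upper)
      draws <- gibbs_sample(records, st, pr)
      summ <- summarize_posterior(draws)
      write_bundle_table(summ$varcomp,
                         file.path(out_dir, "varcomp_summary.csv"), checksum)
      write_bundle_table(summ$convergence,
                         file.path(out_dir, "convergence.csv"), checksum)
      if (isTRUE(bcf$store_draws)) {
        pooled <- do.call(rbind, lapply(draws$chains, function(ch)
          cbind(ch$location, ch$finite_sd)))
        write_bundle_table(as.data.frame(pooled),
                           file.path(out_dir, "draws.csv"), checksum)
      }
      artifacts$posterior <- summ
    })
  }

  if ("figures" %in% stages) {
    stage("figures", {
      if (!is.null(artifacts$posterior))
        artifacts$fig_varcomp <- graphical_anova_plot(
          artifacts$posterior$varcomp,
          file.path(out_dir, "graphical_anova.png"))
      artifacts$fig_ols <- slope_panels(
        records, file.path(out_dir, "slopes_ols.png"), mode = "ols")
      if (!is.null(artifacts$reml_fit))
        artifacts$fig_blup <- slope_panels(
          records, file.path(out_dir, "slopes_blup.png"), mode = "blup",
          fit = artifacts$reml_fit)
    })
  }

  meta <- list(seed = seed, stages = stages, dataset_md5 = checksum,
               n_records = nrow(records),
               package_version = as.character(utils::packageVersion("vcanova")),
               r_version = R.version.string)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  artifacts$metadata <- file.path(out_dir, "run_metadata.json")
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands \code{simulate}, \code{anova}, \code{reml}, \code{bayes},
#' \code{report} (figures) and \code{all}, each running the corresponding
#' pipeline stage(s).  Options: \code{--config FILE} (YAML),
#' \code{--seed N}, \code{--out DIR}.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
vcanova_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: vcanova <simulate|anova|reml|bayes|report|all> [--config FILE] [--seed N] [--out DIR] [--input CSV]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[i + 1L] else default
  }
  stage_sets <- list(
    simulate = "simulate",
    anova = c("simulate", "anova"),
    reml = c("simulate", "reml"),
    bayes = c("simulate", "bayes"),
    report = c("simulate", "anova", "reml", "bayes", "figures"),
    all = c("simulate", "anova", "reml", "bayes", "figures")
  )
  if (!cmd %in% names(stage_sets)) { message(usage); return(invisible(1L)) }
  cfg_path <- opt("--config")
  config <- if (is.null(cfg_path)) default_config()
            else yaml::read_yaml(cfg_path)
  seed <- opt("--seed"); if (!is.null(seed)) config$seed <- as.integer(seed)
  input <- opt("--input"); if (!is.null(input)) config$input <- input
  config$stages <- if (!is.null(config$input))
    setdiff(stage_sets[[cmd]], "simulate") else stage_sets[[cmd]]
  out_dir <- opt("--out", "vcanova_out")
  run_pipeline(config, out_dir)
  message("wrote results to ", out_dir)
  invisible(0L)
}
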