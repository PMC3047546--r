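#' Plot-level data for multi-site biodiversity experiments
#'
#' The canonical container used throughout the package is a data frame of
#' class \code{plot_data} with one row per experimental plot and columns
#' \describe{
#'   \item{site}{experimental site label (factor)}
#'   \item{block}{block label, unique within site (input files may reuse
#'     "1", "2" across sites; blocks are disambiguated internally via
#'     \code{block_id})}
#'   \item{block_id}{globally unique block label, \code{site:block}}
#'   \item{plot}{unique plot label}
#'   \item{richness}{sown species richness, integer >= 1}
#'   \item{composition}{site-local species-composition label}
#'   \item{composition_code}{global integer code, shared across sites by
#'     plots sowing the identical species set (see
#'     \code{\link{deduplicate_compositions}}); \code{NA} until assigned}
#'   \item{anpp}{aboveground annual net primary production
#'     (g m\eqn{^{-2}} yr\eqn{^{-1}}), nonnegative, \code{NA} if missing}
#' }
#'
#' @param df data frame with at least columns \code{site}, \code{block},
#'   \code{plot}, \code{richness}, \code{composition}, \code{anpp}
#'   (\code{composition_code} optional).
#' @return a validated \code{plot_data} data frame.
#' @export
plot_data <- function(df, nonneg_anpp = TRUE) {
  req <- c("site", "block", "plot", "richness", "composition", "anpp")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    site        = as.character(df$site),
    block       = as.character(df$block),
    plot        = as.character(df$plot),
    richness    = as.integer(df$richness),
    composition = as.character(df$composition),
    anpp        = as.numeric(df$anpp),
    stringsAsFactors = FALSE
  )
  out$block_id <- paste(out$site, out$block, sep = ":")
  out$composition_code <-
    if ("composition_code" %in% names(df)) as.integer(df$composition_code)
    else NA_integer_
  out <- out[, c("site", "block", "block_id", "plot", "richness",
                 "composition", "composition_code", "anpp")]
  class(out) <- c("plot_data", "data.frame")
  validate_plot_data(out, nonneg_anpp = nonneg_anpp)
  out
}

#' Validate a plot_data table
#'
#' Checks the structural invariants of the design: richness at least 1,
#' ANPP missing or nonnegative, every (site, block) pair belonging to one
#' site, and (when composition codes are assigned) equal richness within
#' each code.
#'
#' @param records a \code{plot_data} data frame.
#' @param nonneg_anpp enforce nonnegative ANPP (TRUE for measured field
#'   data; simulated responses from the unbounded Gaussian model may dip
#'   below zero in the tails and are validated with FALSE).
#' @return \code{records}, invisibly, if valid; otherwise an error naming
#'   the offending row.
#' @export
validate_plot_data <- function(records, nonneg_anpp = TRUE) {
  bad <- which(is.na(records$richness) | records$richness < 1L)
  if (length(bad) > 0L)
    stop("richness < 1 or missing at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.na(records$anpp) & records$anpp < 0)
  if (nonneg_anpp && length(bad) > 0L)
    stop("negative anpp at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  # block_id encodes the site, so each maps to exactly one site by
  # construction; still guard against hand-edited tables
  tab <- unique(records[, c("site", "block_id")])
  if (anyDuplicated(tab$block_id))
    stop("block_id bound to more than one site", call. = FALSE)
  if (!all(is.na(records$composition_code))) {
    rng <- tapply(records$richness, records$composition_code,
                  function(r) length(unique(r)))
    if (any(rng > 1L))
      stop("plots sharing a composition_code differ in richness (code ",
           names(rng)[which(rng > 1L)[1L]], ")", call. = FALSE)
  }
  invisible(records)
}

#' Read a plot-level dataset from delimited text
#'
#' Reads the canonical six-column schema (\code{site}, \code{block},
#' \code{plot}, \code{richness}, \code{composition}, \code{anpp}).
#' Empty ANPP cells are parsed as missing, never as zero; row order is
#' preserved.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field delimiter; \code{","} (default) or \code{"\t"}.
#' @param col_map optional named character vector remapping file column
#'   names to the canonical ones, e.g.
#'   \code{c(site = "experiment", anpp = "biomass")}.
#' @param nonneg_anpp reject negative ANPP values (default TRUE; set
#'   FALSE when re-reading simulated datasets).
#' @return a \code{\link{plot_data}} data frame.
#' @export
read_plot_data <- function(path, sep = ",", col_map = NULL,
                           nonneg_anpp = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "",
                          quote = "\"", check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df))
        stop("column '", col_map[[canon]], "' (mapped to '", canon,
             "') not in file", call. = FALSE)
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  plot_data(df, nonneg_anpp = nonneg_anpp)
}

#' Write a plot-level dataset to delimited text
#'
#' @param records a \code{plot_data} data frame.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_plot_data <- function(records, path, sep = ",") {
  cols <- c("site", "block", "plot", "richness", "composition",
            "composition_code", "anpp")
  utils::write.table(as.data.frame(records)[, cols], path, sep = sep,
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assign global composition codes by species-set identity
#'
#' Plots at different sites that sow the identical set of species receive
#' the same integer code; codes are dense (1..S) in order of first
#' appearance.  Identity is exact set equality of case-normalized species
#' names.  Re-applying the operation is idempotent.
#'
#' @param records a \code{plot_data} data frame.
#' @param membership long-format data frame with columns \code{site},
#'   \code{composition}, \code{species}: one row per species sown in each
#'   site-local composition.
#' @return \code{records} with \code{composition_code} filled in.
#' @export
deduplicate_compositions <- function(records, membership) {
  req <- c("site", "composition", "species")
  if (!all(req %in% names(membership)))
    stop("membership table needs columns site, composition, species",
         call. = FALSE)
  membership$species <- tolower(trimws(as.character(membership$species)))
  key <- paste(membership$site, membership$composition, sep = "\r")
  sets <- vapply(split(membership$species, key), function(sp)
    paste(sort(unique(sp)), collapse = "|"), character(1L))
  sizes <- vapply(split(membership$species, key), function(sp)
    length(unique(sp)), integer(1L))
  rec_key <- paste(records$site, records$composition, sep = "\r")
  # a label whose species set disagrees in size with the sown richness of
  # its plots has been bound to the wrong set
  clash <- !is.na(records$richness) & records$richness != sizes[rec_key]
  if (any(clash, na.rm = TRUE))
    stop("composition label bound to a species set inconsistent with plot ",
         "richness: ", sub("\r", "/", rec_key[which(clash)[1L]]),
         call. = FALSE)
  unknown <- setdiff(rec_key, names(sets))
  if (length(unknown) > 0L)
    stop("composition(s) absent from membership table: ",
         paste(utils::head(sub("\r", "/", unknown), 3L), collapse = ", "),
         call. = FALSE)
  set_of_rec <- sets[rec_key]
  records$composition_code <-
    as.integer(factor(set_of_rec, levels = unique(set_of_rec)))
  validate_plot_data(records)
  records
}

#' Summarize a multi-site design
#'
#' Per-site counts of distinct compositions, blocks and plots plus the
#' sorted richness levels, with a totals row.  Totals distinguish the raw
#' composition count (summing site-local labels over sites) from the
#' crossed count (distinct global codes after deduplication).
#'
#' @param records a \code{plot_data} data frame.
#' @return list with elements \code{sites} (one row per site) and
#'   \code{totals} (named list: \code{n_blocks}, \code{n_plots},
#'   \code{n_compositions_raw}, \code{n_compositions_crossed}).
#' @export
summarize_design <- function(records) {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  sites <- unique(records$site)
  rows <- lapply(sites, function(s) {
    r <- records[records$site == s, ]
    data.frame(
      site            = s,
      n_compositions  = length(unique(r$composition)),
      n_blocks        = length(unique(r$block_id)),
      n_plots         = nrow(r),
      richness_levels = paste(sort(unique(r$richness)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  sites_df <- do.call(rbind, rows)
  crossed <- if (all(is.na(records$composition_code)))
    NA_integer_ else length(unique(records$composition_code))
  totals <- list(
    n_blocks = sum(sites_df$n_blocks),
    n_plots = sum(sites_df$n_plots),
    n_compositions_raw = sum(sites_df$n_compositions),
    n_compositions_crossed = crossed
  )
  list(sites = sites_df, totals = totals)
}

#' Drop plots with missing response
#'
#' All model fits in this package operate on complete cases; the count of
#' removed rows is reported via \code{message()}.
#'
#' @param records a \code{plot_data} data frame.
#' @return the complete-case subset.
#' @export
complete_cases <- function(records) {
  drop <- is.na(records$anpp)
  if (all(drop)) stop("all rows have missing anpp", call. = FALSE)
  if (any(drop))
    message("complete_cases: dropped ", sum(drop), " of ", nrow(records),
            " rows with missing anpp")
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
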