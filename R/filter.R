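## Column layout shared by the variant-table functions.
VT_DEPTH_COLS <- c("ref_depth_low", "alt_depth_low",
                   "ref_depth_high", "alt_depth_high")

validate_variant_table <- function(table) {
  stop_if_not_cols(table, c("chrom", "pos", "ref", "alt", VT_DEPTH_COLS),
                   "variant table")
  table <- table[order(table$chrom, table$pos), , drop = FALSE]
  rownames(table) <- NULL
  table
}

## Per-site pooled alternate-allele read fraction across both bulks,
## computed over the non-missing bulks.
pooled_alt_freq <- function(table) {
  alt <- rowSums(cbind(table$alt_depth_low, table$alt_depth_high), na.rm = TRUE)
  tot <- rowSums(cbind(table$alt_depth_low, table$alt_depth_high,
                       table$ref_depth_low, table$ref_depth_high), na.rm = TRUE)
  ifelse(tot > 0, alt / tot, NA_real_)
}

## Per-site total depth summed over the non-missing bulks.
total_depth <- function(table) {
  rowSums(cbind(table$ref_depth_low, table$alt_depth_low,
                table$ref_depth_high, table$alt_depth_high), na.rm = TRUE)
}

is_missing_bulk <- function(table) {
  cbind(low = is.na(table$ref_depth_low) | is.na(table$alt_depth_low),
        high = is.na(table$ref_depth_high) | is.na(table$alt_depth_high))
}

#' Polarize a variant table by the low-phenotype parent allele
#'
#' Re-orients every site so that the reference allele is the allele carried by
#' the low-rhizosheath parent (the cross's reference line) and the alternate
#' allele is the high-parent allele. Sites whose recorded alleles are already
#' oriented are unchanged; sites where the parent carries the recorded
#' alternate allele have ref/alt and their depths swapped in both bulks;
#' sites where neither allele matches the declared parent allele are dropped
#' and counted.
#'
#' @param table a variant table (see [simulate_bulk_reads()] for the layout).
#' @param low_parent_alleles data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele}: the low-parent allele at each site. Sites absent from
#'   this table are dropped and counted.
#' @return The polarized table, with attributes \code{n_swapped} and
#'   \code{n_dropped}.
#' @export
polarize <- function(table, low_parent_alleles) {
  table <- validate_variant_table(table)
  stop_if_not_cols(low_parent_alleles, c("chrom", "pos", "allele"),
                   "low_parent_alleles")
  key <- paste(table$chrom, table$pos)
  pkey <- paste(chrom_id(low_parent_alleles$chrom), low_parent_alleles$pos)
  parent <- low_parent_alleles$allele[match(key, pkey)]
  first_alt <- sub(",.*$", "", table$alt)
  keep_as_is <- !is.na(parent) & parent == table$ref
  swap <- !is.na(parent) & parent == first_alt
  drop <- !(keep_as_is | swap)
  out <- table[!drop, , drop = FALSE]
  sw <- swap[!drop]
  if (any(sw)) {
    tmp_allele <- out$ref[sw]
    out$ref[sw] <- sub(",.*$", "", out$alt[sw])
    out$alt[sw] <- sub("^[^,]*", tmp_allele, out$alt[sw])
    for (side in c("low", "high")) {
      rc <- paste0("ref_depth_", side); ac <- paste0("alt_depth_", side)
      tmp <- out[[rc]][sw]
      out[[rc]][sw] <- out[[ac]][sw]
      out[[ac]][sw] <- tmp
    }
  }
  rownames(out) <- NULL
  attr(out, "n_swapped") <- sum(sw)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' SNP quality filter cascade for two-bulk allele-depth tables
#'
#' Applies, in order: (1) drop multiallelic sites; (2) drop sites whose
#' pooled alternate-allele read fraction across both bulks is below
#' \code{freq_min} (optionally symmetric, also dropping above
#' \code{1 - freq_min}); (3) drop sites whose total depth (summed over bulks)
#' falls below the lower or above the upper depth percentile, computed on the
#' sites surviving step 2 with the linear-interpolation percentile
#' definition and boundary values retained; (4) drop sites missing in too
#' many bulks (with two bulks the operative rule is: missing in at least one
#' bulk); (5) drop sites with pooled minor allele frequency below
#' \code{maf_min}, computed on pooled read counts. Every removed site is
#' attributed to the first filter that rejects it.
#'
#' @param table a polarized variant table.
#' @param freq_min pooled alternate-allele frequency floor (default 0.25).
#' @param freq_symmetric also drop sites with pooled alternate frequency
#'   above \code{1 - freq_min} (default \code{FALSE}: the literal one-sided
#'   rule).
#' @param depth_quantiles lower/upper depth percentiles (default
#'   \code{c(0.25, 0.95)}).
#' @param depth_bounds optional frozen numeric bounds \code{c(lo, hi)}
#'   overriding the percentile estimation (used to make re-runs strictly
#'   idempotent).
#' @param missing_max maximum tolerated fraction of missing bulks per site;
#'   sites with a missing fraction \code{>= missing_max} are dropped
#'   (default 0.5, i.e. one of two bulks).
#' @param maf_min pooled minor-allele-frequency floor (default 0.05).
#' @return List of class \code{"filter_result"} with \code{table} (surviving
#'   sites) and \code{report}, a data.frame of class \code{"filter_report"}
#'   listing per filter the sites removed and remaining; the applied depth
#'   bounds are attached to the report as attribute \code{depth_bounds}.
#' @examples
#' sim <- simulate_bsa_dataset(sim_config(n_chromosomes = 1,
#'   n_markers_per_chrom = 300, n_f2 = 80, mean_depth = 80, seed = 7))
#' filter_cascade(sim$variants)$report
#' @export
filter_cascade <- function(table,
                           freq_min = 0.25,
                           freq_symmetric = FALSE,
                           depth_quantiles = c(0.25, 0.95),
                           depth_bounds = NULL,
                           missing_max = 0.5,
                           maf_min = 0.05) {
  table <- validate_variant_table(table)
  steps <- c("multiallelic", "allele_frequency", "depth_percentile",
             "missing", "maf")
  removed <- stats::setNames(integer(5), steps)
  n0 <- nrow(table)

  ## 1. multiallelic
  multi <- grepl(",", table$alt) | grepl(",", table$ref)
  removed["multiallelic"] <- sum(multi)
  table <- table[!multi, , drop = FALSE]

  ## 2. pooled alternate-allele frequency
  f <- pooled_alt_freq(table)
  lowf <- !is.na(f) & (f < freq_min |
                         (freq_symmetric & f > 1 - freq_min))
  removed["allele_frequency"] <- sum(lowf)
  table <- table[!lowf, , drop = FALSE]

  ## 3. total-depth percentiles (estimated on the post-frequency table)
  dep <- total_depth(table)
  if (is.null(depth_bounds)) {
    depth_bounds <- if (nrow(table) > 0)
      unname(stats::quantile(dep, depth_quantiles, type = 7)) else c(0, Inf)
  }
  baddep <- dep < depth_bounds[1] | dep > depth_bounds[2]
  removed["depth_percentile"] <- sum(baddep)
  table <- table[!baddep, , drop = FALSE]

  ## 4. missing bulks
  missfrac <- rowMeans(is_missing_bulk(table))
  gone <- missfrac >= missing_max & missfrac > 0
  removed["missing"] <- sum(gone)
  table <- table[!gone, , drop = FALSE]

  ## 5. pooled minor allele frequency
  f <- pooled_alt_freq(table)
  maf <- pmin(f, 1 - f)
  rare <- !is.na(maf) & maf < maf_min
  removed["maf"] <- sum(rare)
  table <- table[!rare, , drop = FALSE]
  rownames(table) <- NULL

  remaining <- n0 - cumsum(removed)
  report <- data.frame(filter = steps, removed = unname(removed),
                       remaining = unname(remaining),
                       stringsAsFactors = FALSE)
  attr(report, "n_input") <- n0
  attr(report, "depth_bounds") <- depth_bounds
  class(report) <- c("filter_report", "data.frame")
  structure(list(table = table, report = report), class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("SNP filter cascade: %d sites in, %d retained\n",
              attr(x, "n_input"), x$remaining[nrow(x)]))
  db <- attr(x, "depth_bounds")
  cat(sprintf("  depth bounds applied: [%.1f, %.1f]\n", db[1], db[2]))
  print.data.frame(x)
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
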