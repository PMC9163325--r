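#' Per-bulk allele frequencies from read depths
#'
#' Estimates the alternate- and reference-allele frequency in each bulk as
#' the read fraction \code{alt / (alt + ref)}. Sites with zero usable depth
#' in a bulk come out as \code{NA} (they are removed upstream by the filter
#' cascade).
#'
#' @param table a filtered variant table.
#' @return data.frame with columns \code{f_aL}, \code{f_AL}, \code{f_aH},
#'   \code{f_AH}: alternate (a) and reference (A) allele frequency in the
#'   low (L) and high (H) bulk.
#' @export
bulk_frequencies <- function(table) {
  stop_if_not_cols(table, VT_DEPTH_COLS, "variant table")
  dl <- table$alt_depth_low + table$ref_depth_low
  dh <- table$alt_depth_high + table$ref_depth_high
  f_aL <- ifelse(!is.na(dl) & dl > 0, table$alt_depth_low / dl, NA_real_)
  f_aH <- ifelse(!is.na(dh) & dh > 0, table$alt_depth_high / dh, NA_real_)
  data.frame(f_aL = f_aL, f_AL = 1 - f_aL, f_aH = f_aH, f_AH = 1 - f_aH)
}

#' Euclidean distance between bulk allele frequencies at a marker
#'
#' The per-marker signal of a bulked segregant scan. The default
#' \code{"between"} variant contrasts the two bulks allele by allele,
#' \deqn{ED_m = \sqrt{(f_{aL} - f_{aH})^2 + (f_{AL} - f_{AH})^2}
#'            = \sqrt{2}\,|f_{aL} - f_{aH}|,}
#' which is zero when the bulks agree and \eqn{\sqrt 2} at opposite
#' fixation. The \code{"within"} variant contrasts the two alleles within
#' each bulk, \eqn{\sqrt{(f_{aL} - f_{AL})^2 + (f_{aH} - f_{AH})^2}}; it is
#' blind to the direction of divergence and is provided for comparison only.
#'
#' @param freqs a [bulk_frequencies()] data.frame (or any data.frame with
#'   columns \code{f_aL}, \code{f_AL}, \code{f_aH}, \code{f_AH}).
#' @param variant \code{"between"} (default) or \code{"within"}.
#' @return Numeric vector of per-marker distances in \[0, sqrt(2)\].
#' @examples
#' ed_statistic(data.frame(f_aL = 0.2, f_AL = 0.8, f_aH = 0.8, f_AH = 0.2))
#' @export
ed_statistic <- function(freqs, variant = c("between", "within")) {
  variant <- match.arg(variant)
  stop_if_not_cols(freqs, c("f_aL", "f_AL", "f_aH", "f_AH"), "freqs")
  vals <- c(freqs$f_aL, freqs$f_AL, freqs$f_aH, freqs$f_AH)
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  if (variant == "between") {
    sqrt((freqs$f_aL - freqs$f_aH)^2 + (freqs$f_AL - freqs$f_AH)^2)
  } else {
    sqrt((freqs$f_aL - freqs$f_AL)^2 + (freqs$f_aH - freqs$f_AH)^2)
  }
}

## Rolling window sum over the rows of a matrix (or vector), full windows
## only; returns a (m - w + 1) x ncol matrix.
roll_sum <- function(x, w) {
  x <- as.matrix(x)
  m <- nrow(x)
  cs <- apply(x, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = m)
  if (w == 1L) return(cs - rbind(0, cs[-m, , drop = FALSE]))
  cs[w:m, , drop = FALSE] -
    rbind(rep(0, ncol(x)), cs[seq_len(m - w), , drop = FALSE])
}

## Centre-marker index offset for a window of w markers starting at j:
## the centre is marker j + ceiling(w/2) - 1 (the 50th of 100).
window_centre_offset <- function(w) as.integer(ceiling(w / 2) - 1)

#' Windowed fourth-power ED statistic
#'
#' Aggregates the per-marker Euclidean distance over sliding windows of
#' \code{window_size} consecutive markers (step 1, never spanning a
#' chromosome boundary) and raises the window sum to the fourth power
#' (\code{stat = "sum4"}, the cumulative-then-power reading; default). The
#' alternative \code{"pow4sum"} sums per-marker fourth powers instead. The
#' window value is assigned to the centre marker; markers without a full
#' window get \code{NA}. Chromosomes with fewer markers than the window are
#' skipped with a warning.
#'
#' @param ed per-marker ED values, sorted by (chrom, pos).
#' @param chrom chromosome label per marker, same length as \code{ed}.
#' @param window_size number of consecutive markers per window (default 100).
#' @param stat \code{"sum4"} or \code{"pow4sum"}.
#' @return Numeric vector of windowed values aligned with the input markers.
#' @export
window_statistic <- function(ed, chrom, window_size = 100,
                             stat = c("sum4", "pow4sum")) {
  stat <- match.arg(stat)
  stopifnot(length(ed) == length(chrom), window_size >= 1)
  window_size <- as.integer(window_size)
  out <- rep(NA_real_, length(ed))
  off <- window_centre_offset(window_size)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    if (m < window_size) {
      warning(sprintf(
        "chromosome %s has %d markers (< window of %d): no windowed values",
        ch, m, window_size))
      next
    }
    x <- if (stat == "sum4") ed[idx] else ed[idx]^4
    ws <- drop(roll_sum(x, window_size))
    if (stat == "sum4") ws <- ws^4
    out[idx[seq_along(ws) + off]] <- ws
  }
  out
}

#' Simulated genome-wide significance threshold for the windowed ED statistic
#'
#' Reconstructs a null distribution for the scan under no-QTL Mendelian
#' segregation: at every marker, each bulk's true allele frequency is drawn
#' by pooling \code{bulk_size} F2 genotypes from the 1:2:1 distribution
#' (total alternate alleles ~ Binomial(2 bulk_size, 1/2)), read counts are
#' Binomial(site depth, bulk frequency) with the observed per-site depths,
#' and the windowed statistic is computed on each simulated genome. The
#' default threshold is the \code{1 - alpha} quantile of the per-genome
#' maximum (family-wise control over all markers); \code{method =
#' "per_marker"} uses the pooled per-window \code{1 - alpha} quantile
#' instead (less conservative). \code{alpha >= 1} degenerates to a zero
#' threshold (every marker significant).
#'
#' @param depth_low,depth_high per-site read depths of the two bulks (the
#'   filtered table's depths).
#' @param chrom chromosome label per site.
#' @param bulk_size number of F2 individuals per bulk (e.g. 55).
#' @param window_size,variant,stat as in [window_statistic()] /
#'   [ed_statistic()].
#' @param alpha family-wise significance level (default 0.05).
#' @param n_sims number of simulated null genomes (>= 20; default 200).
#' @param method \code{"genome_max"} (default) or \code{"per_marker"}.
#' @param seed optional seed; recorded in the result.
#' @return Object of class \code{"ed_threshold"}: list with
#'   \code{threshold}, \code{maxima} (per-genome maxima), \code{method},
#'   \code{alpha}, \code{n_sims}, \code{seed}.
#' @export
significance_threshold <- function(depth_low, depth_high, chrom, bulk_size,
                                   window_size = 100,
                                   variant = c("between", "within"),
                                   stat = c("sum4", "pow4sum"),
                                   alpha = 0.05, n_sims = 200,
                                   method = c("genome_max", "per_marker"),
                                   seed = NULL) {
  variant <- match.arg(variant); stat <- match.arg(stat)
  method <- match.arg(method)
  if (n_sims < 20) stop("n_sims < 20: the threshold quantile would be unstable")
  m <- length(depth_low)
  stopifnot(length(depth_high) == m, length(chrom) == m, bulk_size >= 1)
  if (any(is.na(depth_low) | is.na(depth_high)))
    stop("null simulation needs complete depths: filter the table first")
  with_seed(seed, {
    nall <- 2L * as.integer(bulk_size)
    sim_freq <- function(depth) {
      p <- matrix(stats::rbinom(m * n_sims, nall, 0.5), m) / nall
      alt <- matrix(stats::rbinom(m * n_sims, rep(depth, n_sims),
                                  as.vector(p)), m)
      alt / depth                     # depth recycles down columns
    }
    fL <- sim_freq(depth_low)
    fH <- sim_freq(depth_high)
    ed <- if (variant == "between") {
      sqrt(2) * abs(fL - fH)
    } else {
      sqrt((2 * fL - 1)^2 + (2 * fH - 1)^2)
    }
    win <- vector("list", 0L)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      if (length(idx) < window_size) next
      x <- ed[idx, , drop = FALSE]
      if (stat == "pow4sum") x <- x^4
      ws <- roll_sum(x, as.integer(window_size))
      if (stat == "sum4") ws <- ws^4
      win[[length(win) + 1L]] <- ws
    }
    if (length(win) == 0L)
      stop("no chromosome holds a full window: cannot calibrate a threshold")
    allw <- do.call(rbind, win)
    maxima <- apply(allw, 2L, max)
    threshold <- if (alpha >= 1) 0 else if (method == "genome_max") {
      unname(stats::quantile(maxima, 1 - alpha, type = 7))
    } else {
      unname(stats::quantile(allw, 1 - alpha, type = 7))
    }
    structure(list(threshold = threshold, maxima = maxima, method = method,
                   alpha = alpha, n_sims = n_sims, bulk_size = bulk_size,
                   window_size = window_size, variant = variant, stat = stat,
                   seed = seed),
              class = "ed_threshold")
  })
}

#' @export
print.ed_threshold <- function(x, ...) {
  cat(sprintf(
    "ED^4 null threshold: %.4g (%s, alpha = %.3g, %d simulated genomes, bulks of %d)\n",
    x$threshold, x$method, x$alpha, x$n_sims, x$bulk_size))
  invisible(x)
}

#' Bulked segregant ED scan
#'
#' The central fitting function: from a filtered two-bulk variant table it
#' estimates per-bulk allele frequencies, computes the per-marker Euclidean
#' distance, aggregates it over sliding 100-marker windows as the
#' fourth-power statistic, calibrates a genome-wide significance threshold by
#' null simulation (unless a precomputed threshold is supplied) and flags
#' significant markers.
#'
#' @param table a filtered, polarized variant table (see [filter_cascade()]).
#' @param bulk_size number of F2 individuals per bulk, used by the null
#'   simulation (e.g. 55).
#' @param window_size markers per window (default 100).
#' @param formula ED variant, \code{"between"} (default) or \code{"within"};
#'   see [ed_statistic()].
#' @param window_stat \code{"sum4"} (default) or \code{"pow4sum"}; see
#'   [window_statistic()].
#' @param alpha family-wise significance level (default 0.05).
#' @param n_sims null genomes for the threshold (default 200).
#' @param threshold optional: a precomputed \code{"ed_threshold"} object or a
#'   bare number, skipping the null simulation.
#' @param method threshold calibration, \code{"genome_max"} or
#'   \code{"per_marker"}.
#' @param seed seed for the null simulation.
#' @return Object of class \code{"bsa_scan"}: list with \code{profile} (a
#'   data.frame \code{chrom}, \code{pos}, \code{f_aL}, \code{f_aH}, \code{ed},
#'   \code{ed4}, \code{significant}), \code{threshold} (the
#'   \code{"ed_threshold"} object or the supplied value) and the scan
#'   parameters.
#' @seealso [call_regions()] to turn significant markers into QTL regions,
#'   [plot.bsa_scan()] for the genome-wide profile.
#' @export
bsa_scan <- function(table, bulk_size, window_size = 100,
                     formula = c("between", "within"),
                     window_stat = c("sum4", "pow4sum"),
                     alpha = 0.05, n_sims = 200, threshold = NULL,
                     method = c("genome_max", "per_marker"), seed = NULL) {
  formula <- match.arg(formula); window_stat <- match.arg(window_stat)
  method <- match.arg(method)
  table <- validate_variant_table(table)
  if (nrow(table) == 0L) stop("empty variant table: nothing to scan")
  freqs <- bulk_frequencies(table)
  ed <- ed_statistic(freqs, variant = formula)
  if (anyNA(ed))
    stop("NA allele frequencies in the scan input: filter the table first")
  ed4 <- window_statistic(ed, table$chrom, window_size = window_size,
                          stat = window_stat)
  thr_obj <- threshold
  if (is.null(thr_obj)) {
    thr_obj <- significance_threshold(
      depth_low = table$ref_depth_low + table$alt_depth_low,
      depth_high = table$ref_depth_high + table$alt_depth_high,
      chrom = table$chrom, bulk_size = bulk_size,
      window_size = window_size, variant = formula, stat = window_stat,
      alpha = alpha, n_sims = n_sims, method = method, seed = seed)
  }
  thr <- if (inherits(thr_obj, "ed_threshold")) thr_obj$threshold else
    as.numeric(thr_obj)
  profile <- data.frame(chrom = table$chrom, pos = table$pos,
                        f_aL = freqs$f_aL, f_aH = freqs$f_aH,
                        ed = ed, ed4 = ed4,
                        significant = !is.na(ed4) & ed4 >= thr,
                        stringsAsFactors = FALSE)
  structure(list(profile = profile, threshold = thr_obj,
                 threshold_value = thr,
                 window_size = as.integer(window_size), formula = formula,
                 window_stat = window_stat, alpha = alpha,
                 bulk_size = bulk_size, seed = seed),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  p <- x$profile
  cat("Bulked segregant ED scan\n")
  cat(sprintf("  %d markers on %d chromosome(s); ED variant '%s', window %d (%s)\n",
              nrow(p), length(unique(p$chrom)), x$formula, x$window_size,
              x$window_stat))
  cat(sprintf("  threshold %.4g (alpha = %.3g): %d significant marker(s)\n",
              x$threshold_value, x$alpha, sum(p$significant)))
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  p <- object$profile
  bychr <- do.call(rbind, lapply(split(p, p$chrom), function(d) {
    data.frame(chrom = d$chrom[1], n_markers = nrow(d),
               n_significant = sum(d$significant),
               max_ed4 = if (all(is.na(d$ed4))) NA_real_ else
                 max(d$ed4, na.rm = TRUE),
               peak_pos = if (all(is.na(d$ed4))) NA_real_ else
                 d$pos[which.max(d$ed4)],
               stringsAsFactors = FALSE)
  }))
  rownames(bychr) <- NULL
  out <- list(by_chrom = bychr, threshold = object$threshold_value,
              alpha = object$alpha)
  class(out) <- "summary.bsa_scan"
  out
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf("Per-chromosome ED^4 summary (threshold %.4g, alpha %.3g)\n",
              x$threshold, x$alpha))
  print.data.frame(x$by_chrom)
  invisible(x)
}

#' Genome-wide windowed ED profile plot
#'
#' Manhattan-style plot of the windowed ED^4 statistic against cumulative
#' genome position, chromosomes in alternating shades, with the significance
#' threshold as a dashed line.
#'
#' @param x a [bsa_scan()] object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.bsa_scan <- function(x, ...) {
  p <- x$profile[!is.na(x$profile$ed4), , drop = FALSE]
  if (nrow(p) == 0L) stop("no windowed values to plot")
  chr <- unique(p$chrom)
  offs <- c(0, cumsum(vapply(chr, function(ch) max(p$pos[p$chrom == ch]),
                             numeric(1))))
  xpos <- p$pos + offs[match(p$chrom, chr)]
  cols <- c("grey25", "steelblue")[(match(p$chrom, chr) %% 2) + 1]
  graphics::plot(xpos / 1e6, p$ed4, col = cols, pch = 16, cex = 0.4,
                 xlab = "cumulative position (Mbp)",
                 ylab = expression(ED^4 ~ "(100-marker window)"), ...)
  graphics::abline(h = x$threshold_value, lty = 2, col = "firebrick")
  invisible(x)
}
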