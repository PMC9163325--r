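## Merge closed 1-based intervals per chromosome with IRanges; abutting
## intervals (gap 0) are merged.
merge_intervals <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(end >= start))
  out <- lapply(unique(chrom), function(ch) {
    on <- chrom == ch
    ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(start[on]),
                                           end = as.integer(end[on])),
                          min.gapwidth = 1L)
    data.frame(chrom = ch, start = IRanges::start(ir), end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Call significant QTL regions from a scan profile
#'
#' Each significant marker contributes the physical span of its 100-marker
#' window (the resolution of the windowed statistic); overlapping or abutting
#' spans on a chromosome are merged into one region. The region peak is the
#' position of the marker with the maximal windowed statistic inside the
#' region, the SNP count is the number of significant markers inside, and
#' regions are auto-named \code{RAS<chrom>.<k>} in positional order.
#'
#' @param scan a [bsa_scan()] object (or its profile data.frame together
#'   with \code{window_size}).
#' @param window_size markers per window; taken from the scan object when
#'   omitted.
#' @return A data.frame of class \code{"qtl_regions"} with columns
#'   \code{name}, \code{chrom}, \code{peak_bp}, \code{start_bp},
#'   \code{end_bp}, \code{length_bp}, \code{n_sig_snps}. Zero rows when no
#'   marker is significant.
#' @export
call_regions <- function(scan, window_size = NULL) {
  if (inherits(scan, "bsa_scan")) {
    profile <- scan$profile
    window_size <- window_size %||% scan$window_size
  } else {
    profile <- scan
    if (is.null(window_size)) stop("window_size needed with a bare profile")
  }
  stop_if_not_cols(profile, c("chrom", "pos", "ed4", "significant"),
                   "scan profile")
  window_size <- as.integer(window_size)
  off_lo <- window_centre_offset(window_size)          # markers before centre
  off_hi <- window_size - off_lo - 1L                  # markers after centre
  empty <- data.frame(name = character(), chrom = character(),
                      peak_bp = numeric(), start_bp = numeric(),
                      end_bp = numeric(), length_bp = numeric(),
                      n_sig_snps = integer(), stringsAsFactors = FALSE)
  sig_all <- which(profile$significant)
  if (length(sig_all) == 0L) {
    class(empty) <- c("qtl_regions", "data.frame")
    return(empty)
  }
  rows <- list()
  for (ch in unique(profile$chrom[sig_all])) {
    idx <- which(profile$chrom == ch)
    sig <- intersect(sig_all, idx)
    loc <- match(sig, idx)                             # index within chrom
    span_start <- profile$pos[idx[pmax(1L, loc - off_lo)]]
    span_end <- profile$pos[idx[pmin(length(idx), loc + off_hi)]]
    merged <- merge_intervals(rep(ch, length(sig)), span_start, span_end)
    for (r in seq_len(nrow(merged))) {
      inside <- idx[profile$pos[idx] >= merged$start[r] &
                      profile$pos[idx] <= merged$end[r]]
      n_sig <- sum(profile$significant[inside])
      scored <- inside[!is.na(profile$ed4[inside])]
      peak <- scored[which.max(profile$ed4[scored])]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, peak_bp = profile$pos[peak],
        start_bp = merged$start[r], end_bp = merged$end[r],
        length_bp = merged$end[r] - merged$start[r],
        n_sig_snps = n_sig, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  idx_in_chr <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  out <- cbind(name = sprintf("RAS%s.%d", chrom_num(out$chrom), idx_in_chr),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("qtl_regions", "data.frame")
  out
}

#' Validate (or build) a QTL region table
#'
#' Checks the internal consistency of a region table -- coordinates ordered,
#' peak inside the region -- and (re)computes \code{length_bp} as
#' \code{end_bp - start_bp}. Useful for constructing region tables from
#' published coordinates and checking their printed lengths.
#'
#' @param df data.frame with at least \code{name}, \code{chrom},
#'   \code{start_bp}, \code{end_bp}; optional \code{peak_bp},
#'   \code{n_sig_snps}.
#' @return The validated data.frame of class \code{"qtl_regions"}.
#' @export
as_qtl_regions <- function(df) {
  stop_if_not_cols(df, c("name", "chrom", "start_bp", "end_bp"),
                   "region table")
  if (any(df$end_bp < df$start_bp)) stop("region end before start")
  if (!"peak_bp" %in% names(df)) df$peak_bp <- (df$start_bp + df$end_bp) / 2
  if (any(df$peak_bp < df$start_bp | df$peak_bp > df$end_bp))
    stop("region peak outside [start, end]")
  df$length_bp <- df$end_bp - df$start_bp
  df$chrom <- chrom_id(df$chrom)
  class(df) <- unique(c("qtl_regions", class(df)))
  df
}

#' @export
print.qtl_regions <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No significant QTL regions\n")
    return(invisible(x))
  }
  disp <- data.frame(name = x$name, chrom = x$chrom,
                     peak_Mbp = round(x$peak_bp / 1e6, 2),
                     range_Mbp = sprintf("%.2f-%.2f", x$start_bp / 1e6,
                                         x$end_bp / 1e6),
                     length_Mbp = round(x$length_bp / 1e6, 2),
                     n_sig_snps = if ("n_sig_snps" %in% names(x))
                       x$n_sig_snps else NA_integer_)
  cat("Significant BSA regions\n")
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' GWAS significance windows
#'
#' Builds the +/- \code{flank} window around each significant GWAS SNP
#' (clipped at the chromosome start) and merges overlapping or abutting
#' windows per chromosome, so a cluster of hits yields a single region.
#'
#' @param hits data.frame with columns \code{chrom}, \code{pos} and
#'   optionally \code{p_value}.
#' @param flank half-window in bp (default 50 kb).
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{n_hits}; zero rows for empty input.
#' @examples
#' gwas_windows(data.frame(chrom = "chr5", pos = 3282686))
#' @export
gwas_windows <- function(hits, flank = 5e4) {
  if (is.null(hits) || nrow(hits) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_hits = integer()))
  stop_if_not_cols(hits, c("chrom", "pos"), "GWAS hits")
  hits$chrom <- chrom_id(hits$chrom)
  hits <- hits[order(hits$chrom, hits$pos), , drop = FALSE]
  merged <- merge_intervals(hits$chrom, pmax(1, hits$pos - flank),
                            hits$pos + flank)
  merged$n_hits <- vapply(seq_len(nrow(merged)), function(i) {
    sum(hits$chrom == merged$chrom[i] & hits$pos >= merged$start[i] &
          hits$pos <= merged$end[i])
  }, integer(1))
  merged
}

#' Overlap report between BSA regions and GWAS hits
#'
#' For every (region, hit) pair on a shared chromosome, reports the overlap
#' length between the region and the hit's +/- \code{flank} window (0 when
#' disjoint), the gap between region and window when disjoint, and the
#' distance from the region peak to the hit position. The summary counts how
#' many regions are overlapped by at least one window.
#'
#' @param regions a \code{"qtl_regions"} table.
#' @param hits GWAS hits (\code{chrom}, \code{pos}, optional \code{p_value}).
#' @param flank half-window in bp (default 50 kb).
#' @return data.frame of class \code{"overlap_report"} with one row per
#'   pair; attribute \code{n_regions_overlapped} carries the summary count.
#'   Raises an error when the two inputs share no chromosome name.
#' @export
overlap_report <- function(regions, hits, flank = 5e4) {
  stop_if_not_cols(regions, c("name", "chrom", "peak_bp", "start_bp",
                              "end_bp"), "regions")
  stop_if_not_cols(hits, c("chrom", "pos"), "GWAS hits")
  hits$chrom <- chrom_id(hits$chrom)
  regions$chrom <- chrom_id(regions$chrom)
  if (nrow(regions) > 0L && nrow(hits) > 0L &&
      length(intersect(regions$chrom, hits$chrom)) == 0L)
    stop("no shared chromosome names between regions (",
         paste(unique(regions$chrom), collapse = ", "), ") and hits (",
         paste(unique(hits$chrom), collapse = ", "), ")")
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    on <- which(hits$chrom == regions$chrom[i])
    for (j in on) {
      ws <- max(1, hits$pos[j] - flank); we <- hits$pos[j] + flank
      ov <- max(0, min(regions$end_bp[i], we) - max(regions$start_bp[i], ws))
      gap <- if (ov > 0) 0 else max(ws - regions$end_bp[i],
                                    regions$start_bp[i] - we)
      rows[[length(rows) + 1L]] <- data.frame(
        region = regions$name[i], chrom = regions$chrom[i],
        hit_pos = hits$pos[j], window_start = ws, window_end = we,
        overlap_bp = ov, gap_bp = gap,
        peak_to_hit_bp = abs(regions$peak_bp[i] - hits$pos[j]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(), chrom = character(),
               hit_pos = numeric(), window_start = numeric(),
               window_end = numeric(), overlap_bp = numeric(),
               gap_bp = numeric(), peak_to_hit_bp = numeric())
  overlapped <- unique(out$region[out$overlap_bp > 0])
  attr(out, "n_regions_overlapped") <- length(overlapped)
  attr(out, "n_regions") <- nrow(regions)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("BSA x GWAS overlap: %d of %d region(s) overlapped by >= 1 window\n",
              attr(x, "n_regions_overlapped"), attr(x, "n_regions")))
  print.data.frame(x)
  invisible(x)
}
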