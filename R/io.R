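#' Write a two-bulk variant table as VCF
#'
#' Minimal VCF 4.2 writer with two samples (low and high bulk) carrying
#' per-allele read depths in the AD FORMAT field; positions are 1-based.
#' Missing bulk calls are written as \code{.}.
#'
#' @param table a variant table (see [simulate_bulk_reads()]).
#' @param path output file path.
#' @param low_name,high_name sample names (defaults LOW / HIGH).
#' @return Invisibly, \code{path}.
#' @export
write_variant_vcf <- function(table, path, low_name = "LOW",
                              high_name = "HIGH") {
  table <- validate_variant_table(table)
  ad_field <- function(ref, alt, alt2, multi) {
    out <- ifelse(is.na(ref) | is.na(alt), ".",
                  ifelse(multi, paste(ref, alt, alt2, sep = ","),
                         paste(ref, alt, sep = ",")))
    out
  }
  multi <- grepl(",", table$alt)
  a2l <- if ("alt2_depth_low" %in% names(table)) table$alt2_depth_low else 0L
  a2h <- if ("alt2_depth_high" %in% names(table)) table$alt2_depth_high else 0L
  header <- c("##fileformat=VCFv4.2",
              "##source=rhizobsa",
              paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                     "Description=\"Allelic depths for the ref and alt alleles\">"),
              vapply(unique(table$chrom), function(ch)
                sprintf("##contig=<ID=%s,length=%d>", ch,
                        as.integer(max(table$pos[table$chrom == ch]))),
                character(1)),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", low_name, high_name, sep = "\t"))
  body <- paste(table$chrom, format(table$pos, scientific = FALSE,
                                    trim = TRUE),
                ".", table$ref, table$alt, ".", "PASS", ".", "AD",
                ad_field(table$ref_depth_low, table$alt_depth_low, a2l, multi),
                ad_field(table$ref_depth_high, table$alt_depth_high, a2h, multi),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-bulk allele-depth VCF
#'
#' Parses a VCF with two pooled samples and an AD (allelic depth) FORMAT
#' field into the package's variant-table layout. Missing calls
#' (\code{.}) become \code{NA} depths; additional AD entries beyond
#' ref/alt1 are kept as \code{alt2_depth_*}.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param low_name,high_name the sample names of the low and high bulk.
#' @return A variant table data.frame sorted by (chrom, pos).
#' @export
read_variant_vcf <- function(path, low_name = "LOW", high_name = "HIGH") {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-variant file
  gt <- v@gt
  if (is.null(dim(gt))) gt <- t(as.matrix(gt))
  samples <- colnames(gt)[-1L]
  for (s in c(low_name, high_name)) {
    if (!s %in% samples)
      stop("sample '", s, "' not present in ", path)
  }
  fmt_has_ad <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                       function(f) "AD" %in% f, logical(1))
  if (!all(fmt_has_ad)) {
    i <- which(!fmt_has_ad)[1L]
    stop(sprintf(
      "allele-depth (AD) field absent at %s:%s for samples %s / %s",
      fix[i, "CHROM"], fix[i, "POS"], low_name, high_name))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x) | x == ".", "NA,NA", x), ",",
                      fixed = TRUE)
    ref <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, character(1))))
    alt2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else "0", character(1))))
    alt2[is.na(ref)] <- NA_integer_
    list(ref = ref, alt = alt, alt2 = alt2)
  }
  lo <- parse_ad(ad[, low_name])
  hi <- parse_ad(ad[, high_name])
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    ref_depth_low = lo$ref, alt_depth_low = lo$alt,
                    alt2_depth_low = lo$alt2,
                    ref_depth_high = hi$ref, alt_depth_high = hi$alt,
                    alt2_depth_high = hi$alt2,
                    stringsAsFactors = FALSE)
  validate_variant_table(out)
}

#' @rdname read_variant_vcf
#' @param table a variant table (for the TSV writer).
#' @export
write_variant_tsv <- function(table, path) {
  utils::write.table(validate_variant_table(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_variant_vcf
#' @export
read_variant_tsv <- function(path) {
  validate_variant_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read / write per-plant phenotype tables
#'
#' Tab-separated tables with columns \code{id}, \code{block}, \code{ras_g},
#' \code{rt_g} (grams).
#'
#' @param table a phenotype data.frame.
#' @param path file path.
#' @return The table (reader) or the path, invisibly (writer).
#' @export
write_phenotype_tsv <- function(table, path) {
  stop_if_not_cols(table, c("id", "block", "ras_g", "rt_g"),
                   "phenotype table")
  utils::write.table(table[, c("id", "block", "ras_g", "rt_g")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_cols(tab, c("id", "block", "ras_g", "rt_g"), path)
  tab$ratio <- ras_rt_ratio(tab$ras_g, tab$rt_g)
  tab
}

#' Read a GWAS hit list
#'
#' TSV with columns \code{chrom}, \code{pos} and optionally \code{p_value}.
#'
#' @param path file path.
#' @return data.frame sorted by (chrom, pos).
#' @export
read_gwas_hits <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not_cols(tab, c("chrom", "pos"), path)
  if ("p_value" %in% names(tab) &&
      any(tab$p_value <= 0 | tab$p_value > 1, na.rm = TRUE))
    stop("GWAS p-values must lie in (0, 1]")
  tab$chrom <- chrom_id(tab$chrom)
  tab[order(tab$chrom, tab$pos), , drop = FALSE]
}

#' Export QTL regions
#'
#' \code{write_regions_bed()} writes 0-based half-open BED (conversion from
#' the package's 1-based closed coordinates happens here, at the boundary);
#' \code{write_regions_tsv()} writes a publication-style table with Mbp
#' coordinates to two decimals.
#'
#' @param regions a \code{"qtl_regions"} table.
#' @param path file path.
#' @return Invisibly, \code{path}.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start_bp - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(regions$end_bp, scientific = FALSE,
                                 trim = TRUE),
                    name = regions$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
write_regions_tsv <- function(regions, path) {
  tab <- data.frame(name = regions$name, chrom = regions$chrom,
                    peak_Mbp = round(regions$peak_bp / 1e6, 2),
                    start_Mbp = round(regions$start_bp / 1e6, 2),
                    end_Mbp = round(regions$end_bp / 1e6, 2),
                    length_Mbp = round(regions$length_bp / 1e6, 2),
                    n_sig_snps = if ("n_sig_snps" %in% names(regions))
                      regions$n_sig_snps else NA_integer_)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All stage parameters of the end-to-end analysis in one serializable list;
#' every threshold carries the standard defaults of the analysis (10% tails,
#' frequency floor 0.25, depth percentiles 25/95, 50% missing, 5% MAF,
#' 100-marker windows, alpha 0.05).
#'
#' @param variant_file input VCF or TSV of bulk allele depths.
#' @param gwas_file optional GWAS hit TSV.
#' @param phenotype_file optional phenotype TSV (not used by the scan stages;
#'   carried for provenance).
#' @param out_dir output directory.
#' @param bulk_size F2 individuals per bulk.
#' @param low_name,high_name VCF sample names.
#' @param tail_fraction,freq_min,freq_symmetric,depth_quantiles,missing_max,maf_min
#'   filter-stage parameters (see [filter_cascade()] / [select_bulks()]).
#' @param window_size,formula,window_stat,alpha,n_sims,threshold_method
#'   scan-stage parameters (see [bsa_scan()]).
#' @param gwas_flank GWAS window half-width in bp.
#' @param seed master seed for the null simulation.
#' @return Object of class \code{"pipeline_config"} (a list).
#' @export
pipeline_config <- function(variant_file = NULL, gwas_file = NULL,
                            phenotype_file = NULL, out_dir = "rhizobsa_out",
                            bulk_size = 55, low_name = "LOW",
                            high_name = "HIGH", tail_fraction = 0.10,
                            freq_min = 0.25, freq_symmetric = FALSE,
                            depth_quantiles = c(0.25, 0.95),
                            missing_max = 0.5, maf_min = 0.05,
                            window_size = 100, formula = "between",
                            window_stat = "sum4", alpha = 0.05,
                            n_sims = 200, threshold_method = "genome_max",
                            gwas_flank = 5e4, seed = 1L) {
  cfg <- list(variant_file = variant_file, gwas_file = gwas_file,
              phenotype_file = phenotype_file, out_dir = out_dir,
              bulk_size = bulk_size, low_name = low_name,
              high_name = high_name, tail_fraction = tail_fraction,
              freq_min = freq_min, freq_symmetric = freq_symmetric,
              depth_quantiles = depth_quantiles, missing_max = missing_max,
              maf_min = maf_min, window_size = window_size,
              formula = formula, window_stat = window_stat, alpha = alpha,
              n_sims = n_sims, threshold_method = threshold_method,
              gwas_flank = gwas_flank, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a \code{"pipeline_config"} object.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end BSA pipeline
#'
#' Executes filter, scan, threshold, region calling and (when a GWAS hit
#' list is configured) the overlap comparison, writing every artifact plus a
#' manifest and a parameter log to the output directory. With a fixed seed
#' the outputs are byte-identical across reruns.
#'
#' @param config a [pipeline_config()] object.
#' @return Invisibly, a list of class \code{"bsa_pipeline"} with elements
#'   \code{filter}, \code{scan}, \code{regions}, \code{overlap} (or
#'   \code{NULL}), \code{manifest} and \code{log}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$variant_file)) stop("stage filter [E_INPUT]: no variant_file configured")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logline <- character()
  note <- function(...) logline <<- c(logline, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s [E_%s]: %s", name, toupper(name),
                   conditionMessage(e)), call. = FALSE))
  }
  table <- stage("read", {
    if (grepl("\\.vcf(\\.gz)?$", config$variant_file))
      read_variant_vcf(config$variant_file, config$low_name,
                       config$high_name)
    else read_variant_tsv(config$variant_file)
  })
  note("input: %s (%d sites)", config$variant_file, nrow(table))
  fc <- stage("filter", filter_cascade(
    table, freq_min = config$freq_min,
    freq_symmetric = config$freq_symmetric,
    depth_quantiles = config$depth_quantiles,
    missing_max = config$missing_max, maf_min = config$maf_min))
  note("filter: %d sites retained of %d", nrow(fc$table), nrow(table))
  scan <- stage("scan", bsa_scan(
    fc$table, bulk_size = config$bulk_size,
    window_size = config$window_size, formula = config$formula,
    window_stat = config$window_stat, alpha = config$alpha,
    n_sims = config$n_sims, method = config$threshold_method,
    seed = config$seed))
  note("scan: ED variant '%s', window stat '%s', window %d, threshold %.6g (alpha %.3g, %d sims, seed %s)",
       config$formula, config$window_stat, config$window_size,
       scan$threshold_value, config$alpha, config$n_sims,
       as.character(config$seed))
  regions <- stage("regions", call_regions(scan))
  note("regions: %d significant region(s), %d significant marker(s)",
       nrow(regions), sum(scan$profile$significant))
  overlap <- NULL
  if (!is.null(config$gwas_file)) {
    hits <- stage("compare", read_gwas_hits(config$gwas_file))
    overlap <- stage("compare",
                     overlap_report(regions, hits, flank = config$gwas_flank))
    note("compare: %d of %d region(s) overlap a GWAS window",
         attr(overlap, "n_regions_overlapped"), nrow(regions))
  }
  out <- function(f) file.path(config$out_dir, f)
  utils::write.table(fc$report, out("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_variant_tsv(fc$table, out("filtered_variants.tsv"))
  prof <- scan$profile
  prof$ed <- signif(prof$ed, 10); prof$ed4 <- signif(prof$ed4, 10)
  utils::write.table(prof, out("ed_profile.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_regions_tsv(regions, out("regions.tsv"))
  write_regions_bed(regions, out("regions.bed"))
  if (!is.null(overlap))
    utils::write.table(overlap, out("gwas_overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(logline, out("pipeline_log.txt"))
  files <- c("filter_report.tsv", "filtered_variants.tsv", "ed_profile.tsv",
             "regions.tsv", "regions.bed",
             if (!is.null(overlap)) "gwas_overlap.tsv", "pipeline_log.txt")
  manifest <- data.frame(file = files,
                         bytes = file.size(file.path(config$out_dir, files)))
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(structure(list(filter = fc, scan = scan, regions = regions,
                           overlap = overlap, manifest = manifest,
                           log = logline, config = config),
                      class = "bsa_pipeline"))
}

#' @export
print.bsa_pipeline <- function(x, ...) {
  cat("BSA pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
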