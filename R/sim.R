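#' Configuration for the synthetic F2 / pooled-sequencing generator
#'
#' Collects every parameter of the simulator in one validated object: the
#' genome (chromosome number, physical and genetic lengths, marker density),
#' the F2 design (population size, QTL effects, phenotype scale, blocks) and
#' the pooled-sequencing read model (mean depth, overdispersion, missingness,
#' multiallelic contamination).
#'
#' Phenotypes are generated on the natural-log RAS/RT scale:
#' \code{log-ratio = mean + block + sum over QTLs [a (g - 1) + d 1(g = 1)] + residual}
#' with genotype code \code{g} counting copies of the high-rhizosheath parent
#' allele. The residual variance is set from \code{heritability_target} so that
#' the genetic fraction of the (block-free) phenotypic variance equals the
#' target.
#'
#' @param n_chromosomes number of chromosomes (default 7, the pearl millet
#'   karyotype).
#' @param chrom_lengths_bp physical chromosome lengths in bp (recycled to
#'   \code{n_chromosomes}); default 150 Mbp.
#' @param map_lengths_morgans genetic lengths in Morgans (recycled); default
#'   1.5 M, i.e. about 1 cM/Mbp.
#' @param n_markers_per_chrom markers per chromosome (recycled).
#' @param n_f2 number of F2 individuals (default 547).
#' @param qtls \code{NULL} or a data.frame with columns \code{chrom},
#'   \code{pos_bp}, \code{a} (additive effect, log-ratio units) and \code{d}
#'   (dominance effect). Each QTL is snapped to the nearest marker.
#' @param heritability_target fraction of non-block phenotypic variance that is
#'   genetic, in \[0, 1\].
#' @param phenotype_mean grand mean of the log RAS/RT ratio (default
#'   \code{log(22.3)}, the F2 mean ratio scale).
#' @param resid_sd residual standard deviation (log units) used only when no
#'   QTLs are present (then \code{heritability_target} must be 0).
#' @param n_blocks number of phenotyping blocks (default 5).
#' @param block_effect_sd standard deviation of the block effects (log units).
#' @param block_sizes optional explicit block sizes summing to \code{n_f2}
#'   (e.g. the five-block design 119, 112, 131, 130, 61 for 553 plants);
#'   default round-robin assignment.
#' @param mean_depth mean pooled sequencing depth per site per bulk
#'   (default 875, the high-coverage regime of target-capture bulks).
#' @param depth_dispersion gamma-Poisson overdispersion of site depth
#'   (variance of the gamma depth multiplier; 0 gives pure Poisson).
#' @param missing_rate per-site, per-bulk probability of a missing call.
#' @param multiallelic_rate per-site probability of multiallelic contamination.
#' @param seed integer seed making the whole generated dataset reproducible.
#'
#' @return An object of class \code{"sim_config"} (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 2, n_markers_per_chrom = 500, n_f2 = 100,
#'                   qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.3, d = 0),
#'                   heritability_target = 0.3, seed = 1)
#' @export
sim_config <- function(n_chromosomes = 7,
                       chrom_lengths_bp = 1.5e8,
                       map_lengths_morgans = 1.5,
                       n_markers_per_chrom = 3300,
                       n_f2 = 547,
                       qtls = NULL,
                       heritability_target = if (is.null(qtls)) 0 else 0.3,
                       phenotype_mean = log(22.3),
                       resid_sd = 0.35,
                       n_blocks = 5,
                       block_effect_sd = 0.1,
                       block_sizes = NULL,
                       mean_depth = 875,
                       depth_dispersion = 0.2,
                       missing_rate = 0.01,
                       multiallelic_rate = 0.01,
                       seed = NULL) {
  n_chromosomes <- as.integer(n_chromosomes)
  stopifnot(n_chromosomes >= 1L, n_f2 >= 1L, n_blocks >= 1L,
            mean_depth > 0, depth_dispersion >= 0, resid_sd >= 0,
            block_effect_sd >= 0)
  chrom_lengths_bp <- rep_len(as.numeric(chrom_lengths_bp), n_chromosomes)
  map_lengths_morgans <- rep_len(as.numeric(map_lengths_morgans), n_chromosomes)
  n_markers_per_chrom <- rep_len(as.integer(n_markers_per_chrom), n_chromosomes)
  if (any(chrom_lengths_bp <= 0)) stop("chromosome lengths must be > 0")
  if (any(map_lengths_morgans < 0)) stop("map lengths must be >= 0")
  if (any(n_markers_per_chrom < 1L)) stop("need >= 1 marker per chromosome")
  if (heritability_target < 0 || heritability_target > 1)
    stop("heritability_target must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1 ||
      multiallelic_rate < 0 || multiallelic_rate > 1)
    stop("rates must be fractions in [0, 1]")
  if (!is.null(qtls)) {
    stop_if_not_cols(qtls, c("chrom", "pos_bp", "a", "d"), "qtls")
    qtls$chrom <- chrom_id(qtls$chrom)
    idx <- match(qtls$chrom, chrom_id(seq_len(n_chromosomes)))
    if (anyNA(idx)) stop("QTL on unknown chromosome")
    if (any(qtls$pos_bp < 1 | qtls$pos_bp > chrom_lengths_bp[idx]))
      stop("QTL position outside its chromosome")
  }
  if (!is.null(block_sizes)) {
    block_sizes <- as.integer(block_sizes)
    if (sum(block_sizes) != n_f2)
      stop("block_sizes must sum to n_f2")
    n_blocks <- length(block_sizes)
  }
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_lengths_bp = chrom_lengths_bp,
                 map_lengths_morgans = map_lengths_morgans,
                 n_markers_per_chrom = n_markers_per_chrom,
                 n_f2 = as.integer(n_f2),
                 qtls = qtls,
                 heritability_target = heritability_target,
                 phenotype_mean = phenotype_mean,
                 resid_sd = resid_sd,
                 n_blocks = as.integer(n_blocks),
                 block_effect_sd = block_effect_sd,
                 block_sizes = block_sizes,
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 missing_rate = missing_rate,
                 multiallelic_rate = multiallelic_rate,
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic F2 pooled-sequencing configuration\n")
  cat(sprintf("  genome : %d chromosomes, %s markers, %.0f Mbp / %.2f M each\n",
              x$n_chromosomes, paste(unique(x$n_markers_per_chrom),
                                     collapse = "/"),
              mean(x$chrom_lengths_bp) / 1e6, mean(x$map_lengths_morgans)))
  cat(sprintf("  F2     : n = %d, %d blocks, %d QTL(s), target H2 = %.2f\n",
              x$n_f2, x$n_blocks, if (is.null(x$qtls)) 0L else nrow(x$qtls),
              x$heritability_target))
  cat(sprintf("  reads  : mean depth %.0fX, dispersion %.2f, missing %.1f%%, multiallelic %.1f%%\n",
              x$mean_depth, x$depth_dispersion, 100 * x$missing_rate,
              100 * x$multiallelic_rate))
  invisible(x)
}

## Marker map implied by a sim_config: equally spaced physical positions and
## a uniform recombination rate per chromosome.
marker_map <- function(config) {
  maps <- lapply(seq_len(config$n_chromosomes), function(ci) {
    m <- config$n_markers_per_chrom[ci]
    len <- config$chrom_lengths_bp[ci]
    pos <- if (m == 1L) round(len / 2) else round(seq(1, len, length.out = m))
    pos <- as.numeric(pos)
    if (any(diff(pos) <= 0))
      stop("more markers than distinct bp positions on chromosome ", ci)
    morgan <- if (m == 1L) 0 else
      (pos - pos[1L]) / (pos[m] - pos[1L]) * config$map_lengths_morgans[ci]
    data.frame(chrom = chrom_id(ci), pos = pos, morgan = morgan,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

## Snap each configured QTL to its nearest marker; returns a data.frame with
## marker index and snapped position.
snap_qtls <- function(map, qtls) {
  if (is.null(qtls) || nrow(qtls) == 0L) return(NULL)
  out <- lapply(seq_len(nrow(qtls)), function(i) {
    on_chr <- which(map$chrom == qtls$chrom[i])
    j <- on_chr[which.min(abs(map$pos[on_chr] - qtls$pos_bp[i]))]
    data.frame(chrom = qtls$chrom[i], pos_bp = map$pos[j], marker = j,
               a = qtls$a[i], d = qtls$d[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate F2 genotypes by Haldane meiosis
#'
#' Each individual's chromosome is the sum of two independent gametes. A
#' gamete is a mosaic of the two parental haplotypes produced by a crossover
#' process with no interference: along the marker map, the haplotype switches
#' between adjacent markers with probability equal to the Haldane
#' recombination fraction \code{r = (1 - exp(-2 d)) / 2} for map distance
#' \code{d} Morgans. This marker-to-marker chain is distributionally identical
#' (at the markers) to dropping a Poisson number of uniformly placed
#' crossovers per chromosome. Genotype codes count copies of the
#' high-rhizosheath parent allele, so marginal frequencies converge to the
#' Mendelian 1:2:1.
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed (defaults to \code{config$seed}).
#' @return An object of class \code{"f2_genotypes"}: a list with \code{geno}
#'   (integer matrix, individuals x markers, values 0/1/2), \code{map}
#'   (data.frame \code{chrom}, \code{pos}, \code{morgan}) and \code{qtls}
#'   (configured QTLs snapped to their nearest marker, or \code{NULL}).
#' @examples
#' g <- simulate_f2(sim_config(n_chromosomes = 1, n_markers_per_chrom = 50,
#'                             n_f2 = 20, seed = 1))
#' table(g$geno)
#' @export
simulate_f2 <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  map <- marker_map(config)
  n <- config$n_f2
  with_seed(seed %||% config$seed, {
    geno_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
      on_chr <- map$chrom == chrom_id(ci)
      m <- sum(on_chr)
      if (config$map_lengths_morgans[ci] == 0 && m > 1L)
        warning(sprintf(
          "chromosome %d has zero map length with %d markers: all markers fully linked",
          ci, m))
      r <- 0.5 * (1 - exp(-2 * diff(map$morgan[on_chr])))
      gamete <- function() {
        first <- rbinom(n, 1L, 0.5)
        if (m == 1L) return(matrix(first, nrow = 1L))
        sw <- matrix(rbinom((m - 1L) * n, 1L, r), nrow = m - 1L)
        apply(rbind(first, sw), 2L, cumsum) %% 2L
      }
      t(gamete() + gamete())          # n x m
    })
    geno <- do.call(cbind, geno_chrom)
    storage.mode(geno) <- "integer"
    rownames(geno) <- sprintf("F2_%04d", seq_len(n))
    structure(list(geno = geno, map = map, qtls = snap_qtls(map, config$qtls)),
              class = "f2_genotypes")
  })
}

#' @export
print.f2_genotypes <- function(x, ...) {
  cat(sprintf("F2 genotypes: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  frq <- table(factor(x$geno, levels = 0:2)) / length(x$geno)
  cat(sprintf("  genotype frequencies (0/1/2): %.3f / %.3f / %.3f\n",
              frq[1], frq[2], frq[3]))
  if (!is.null(x$qtls))
    cat(sprintf("  %d QTL(s) at: %s\n", nrow(x$qtls),
                paste(sprintf("%s:%.0f (a=%.2f, d=%.2f)", x$qtls$chrom,
                              x$qtls$pos_bp, x$qtls$a, x$qtls$d),
                      collapse = ", ")))
  invisible(x)
}

#' Simulate F2 phenotypes (RAS/RT) with block and QTL effects
#'
#' Builds the log RAS/RT phenotype as grand mean + block effect + genetic
#' value + Gaussian residual, where the genetic value at each QTL is
#' \code{a (g - 1) + d 1(g = 1)} for genotype code \code{g}. The residual
#' variance is chosen so that the genetic fraction of the non-block
#' phenotypic variance equals \code{config$heritability_target}. Root tissue
#' mass is drawn around 1 g and the root-adhering soil mass derived from the
#' ratio, so the table carries the raw masses the ratio is computed from.
#'
#' @param genotypes an [simulate_f2()] result.
#' @param config the [sim_config()] used (block design, QTLs, heritability).
#' @param seed optional seed (defaults to \code{config$seed}).
#' @return A \code{data.frame} of class \code{"phenotype_table"} with columns
#'   \code{id}, \code{block}, \code{ras_g}, \code{rt_g}, \code{ratio},
#'   \code{log_ratio}; the true genetic values are attached as attribute
#'   \code{"genetic_value"}.
#' @export
simulate_phenotypes <- function(genotypes, config, seed = NULL) {
  stopifnot(inherits(genotypes, "f2_genotypes"), inherits(config, "sim_config"))
  n <- nrow(genotypes$geno)
  q <- genotypes$qtls
  gval <- numeric(n)
  if (!is.null(q)) {
    for (i in seq_len(nrow(q))) {
      g <- genotypes$geno[, q$marker[i]]
      gval <- gval + q$a[i] * (g - 1) + q$d[i] * (g == 1)
    }
  }
  vg <- stats::var(gval)
  h2 <- config$heritability_target
  if (vg > 0) {
    if (h2 == 0)
      stop("heritability_target = 0 contradicts the configured QTL effects")
    resid_var <- vg * (1 - h2) / h2
  } else {
    if (h2 > 0)
      stop("heritability_target > 0 but the configuration has no genetic variance")
    if (h2 == 1 && config$resid_sd > 0)
      stop("heritability_target = 1 with nonzero resid_sd is contradictory")
    resid_var <- config$resid_sd^2
  }
  with_seed(seed %||% config$seed, {
    block <- if (!is.null(config$block_sizes)) {
      rep(seq_along(config$block_sizes), times = config$block_sizes)
    } else {
      rep_len(seq_len(config$n_blocks), n)
    }
    block_eff <- stats::rnorm(config$n_blocks, 0, config$block_effect_sd)
    log_ratio <- config$phenotype_mean + block_eff[block] + gval +
      stats::rnorm(n, 0, sqrt(resid_var))
    rt_g <- exp(stats::rnorm(n, 0, 0.1))           # root tissue mass ~ 1 g
    ras_g <- exp(log_ratio) * rt_g
    out <- data.frame(id = rownames(genotypes$geno),
                      block = factor(block),
                      ras_g = ras_g, rt_g = rt_g,
                      ratio = ras_g / rt_g,
                      log_ratio = log_ratio,
                      stringsAsFactors = FALSE)
    attr(out, "genetic_value") <- gval
    attr(out, "resid_var") <- resid_var
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}

#' Simulate pooled bulk sequencing of two DNA pools
#'
#' For each marker and bulk the true pooled alternate-allele (high-parent
#' allele) frequency is the mean genotype code over the bulk divided by 2.
#' Site depth is gamma-Poisson (mean \code{mean_depth}, overdispersion
#' \code{depth_dispersion}) per bulk; the alternate read count is binomial in
#' that depth. Missing calls (per bulk) and multiallelic contamination (a
#' third allele stealing reads from the reference) are injected at the
#' configured rates, so the filter cascade has realistic work to do.
#'
#' @param genotypes an [simulate_f2()] result.
#' @param low_ids,high_ids disjoint, non-empty character vectors of individual
#'   ids forming the low- and high-phenotype bulks.
#' @param config the [sim_config()] in use (depth model, rates).
#' @param seed optional seed (defaults to \code{config$seed}).
#' @return A \code{data.frame} variant table with columns \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{ref_depth_low},
#'   \code{alt_depth_low}, \code{alt2_depth_low} and the same for the high
#'   bulk. Missing bulk calls are \code{NA} depths; multiallelic sites carry a
#'   comma in \code{alt}. Reference allele = low-parent allele; alternate =
#'   high-parent allele (the table is born polarized).
#' @export
simulate_bulk_reads <- function(genotypes, low_ids, high_ids, config,
                                seed = NULL) {
  stopifnot(inherits(genotypes, "f2_genotypes"), inherits(config, "sim_config"))
  if (length(low_ids) == 0L || length(high_ids) == 0L)
    stop("bulks must be non-empty")
  if (length(intersect(low_ids, high_ids)) > 0L)
    stop("bulks must be disjoint")
  if (!all(c(low_ids, high_ids) %in% rownames(genotypes$geno)))
    stop("unknown individual id in bulk")
  m <- ncol(genotypes$geno)
  p_low <- colSums(genotypes$geno[low_ids, , drop = FALSE]) /
    (2 * length(low_ids))
  p_high <- colSums(genotypes$geno[high_ids, , drop = FALSE]) /
    (2 * length(high_ids))
  with_seed(seed %||% config$seed, {
    draw_depth <- function() {
      mult <- if (config$depth_dispersion > 0) {
        stats::rgamma(m, shape = 1 / config$depth_dispersion,
                      rate = 1 / config$depth_dispersion)
      } else rep(1, m)
      stats::rpois(m, config$mean_depth * mult)
    }
    one_bulk <- function(p) {
      depth <- draw_depth()
      alt <- stats::rbinom(m, depth, p)
      miss <- stats::runif(m) < config$missing_rate | depth == 0L
      list(ref = ifelse(miss, NA_integer_, depth - alt),
           alt = ifelse(miss, NA_integer_, alt))
    }
    low <- one_bulk(p_low)
    high <- one_bulk(p_high)
    multi <- stats::runif(m) < config$multiallelic_rate
    steal <- function(ref) {
      a2 <- integer(m)
      ok <- multi & !is.na(ref)
      a2[ok] <- stats::rbinom(sum(ok), ref[ok], 0.15)
      a2[is.na(ref)] <- NA_integer_
      a2
    }
    a2_low <- steal(low$ref)
    a2_high <- steal(high$ref)
    out <- data.frame(chrom = genotypes$map$chrom,
                      pos = genotypes$map$pos,
                      ref = "A",
                      alt = ifelse(multi, "T,G", "T"),
                      ref_depth_low = low$ref - ifelse(is.na(a2_low), 0L, a2_low),
                      alt_depth_low = low$alt,
                      alt2_depth_low = a2_low,
                      ref_depth_high = high$ref - ifelse(is.na(a2_high), 0L, a2_high),
                      alt_depth_high = high$alt,
                      alt2_depth_high = a2_high,
                      stringsAsFactors = FALSE)
    out
  })
}

#' Simulate per-line phenotypes under the one-way random-effects model
#'
#' Direct generator for the inbred-panel design used to estimate broad-sense
#' heritability: line effects N(0, \code{var_line}), residuals
#' N(0, \code{var_res}), plants distributed as evenly as possible over lines.
#'
#' @param n_lines number of lines (e.g. 181).
#' @param n_plants total number of plants (e.g. 1408).
#' @param var_line,var_res between-line and residual variance components.
#' @param mean grand mean.
#' @param seed optional seed.
#' @return data.frame with columns \code{line} (factor) and \code{y}.
#' @export
simulate_line_phenotypes <- function(n_lines, n_plants, var_line, var_res,
                                     mean = 0, seed = NULL) {
  stopifnot(n_lines >= 2L, n_plants >= n_lines, var_line >= 0, var_res >= 0)
  base <- n_plants %/% n_lines
  extra <- n_plants %% n_lines
  ni <- rep(base, n_lines) + rep(c(1L, 0L), c(extra, n_lines - extra))
  with_seed(seed, {
    line_eff <- stats::rnorm(n_lines, 0, sqrt(var_line))
    line <- rep(seq_len(n_lines), times = ni)
    data.frame(line = factor(sprintf("L%03d", line)),
               y = mean + line_eff[line] + stats::rnorm(n_plants, 0, sqrt(var_res)))
  })
}

#' Generate a complete synthetic BSA dataset
#'
#' One-call wrapper chaining the generator stages: F2 genotypes, phenotypes,
#' block-model residuals, 10%-tail bulk selection and pooled bulk sequencing.
#' With a fixed \code{config$seed} the whole dataset is bit-reproducible.
#'
#' @param config a [sim_config()] object.
#' @param tail_fraction bulk tail fraction passed to [select_bulks()].
#' @return A list of class \code{"bsa_sim"} with elements \code{genotypes},
#'   \code{phenotypes} (with residuals), \code{bulks}, \code{variants} and
#'   \code{qtls} (true snapped QTL positions, or \code{NULL}).
#' @examples
#' sim <- simulate_bsa_dataset(sim_config(n_chromosomes = 1,
#'   n_markers_per_chrom = 200, n_f2 = 100, mean_depth = 60,
#'   qtls = data.frame(chrom = 1, pos_bp = 7.5e7, a = 0.4, d = 0),
#'   heritability_target = 0.4, seed = 42))
#' head(sim$variants)
#' @export
simulate_bsa_dataset <- function(config, tail_fraction = 0.10) {
  seeds <- derive_seeds(config$seed, 3L)
  genotypes <- simulate_f2(config, seed = seeds[1])
  phen <- simulate_phenotypes(genotypes, config, seed = seeds[2])
  phen <- fit_block_model(phen)
  bulks <- select_bulks(phen, tail_fraction = tail_fraction)
  variants <- simulate_bulk_reads(genotypes, bulks$low_ids, bulks$high_ids,
                                  config, seed = seeds[3])
  structure(list(genotypes = genotypes, phenotypes = phen, bulks = bulks,
                 variants = variants, qtls = genotypes$qtls,
                 config = config),
            class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic BSA dataset: %d F2, bulks of %d/%d, %d markers on %d chromosome(s)\n",
    nrow(x$genotypes$geno), length(x$bulks$low_ids), length(x$bulks$high_ids),
    nrow(x$variants), length(unique(x$variants$chrom))))
  invisible(x)
}
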