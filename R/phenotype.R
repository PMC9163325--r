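#' Rhizosheath size ratio (RAS/RT)
#'
#' The rhizosheath phenotype: dry mass of root-adhering soil divided by dry
#' mass of root tissue. Dimensionless; larger values mean more soil bound per
#' unit of root.
#'
#' @param ras_g root-adhering soil dry mass (g), non-negative.
#' @param rt_g root tissue dry mass (g), strictly positive.
#' @return Numeric vector \code{ras_g / rt_g}.
#' @examples
#' ras_rt_ratio(15, 2)   # 7.5
#' @export
ras_rt_ratio <- function(ras_g, rt_g) {
  if (any(!is.finite(rt_g) | rt_g <= 0))
    stop("invalid sample: root tissue mass must be > 0")
  if (any(!is.finite(ras_g) | ras_g < 0))
    stop("invalid sample: root-adhering soil mass must be >= 0")
  ras_g / rt_g
}

#' Block ANOVA of the log RAS/RT ratio
#'
#' Fits the one-way fixed-effect ANOVA \code{log(ratio) ~ block} and attaches
#' per-plant residuals (log ratio minus fitted block mean). Bulks are chosen
#' on these residuals so that block-to-block environmental shifts do not leak
#' into the tails. Rows with non-positive ratio cannot be log-transformed and
#' are excluded with a recorded count.
#'
#' @param table a data.frame with columns \code{block} and either
#'   \code{ratio} or both \code{ras_g} and \code{rt_g}.
#' @return The table (excluded rows dropped) with a \code{residual} column,
#'   of class \code{"phenotype_fit"}; attributes \code{block_means} (fitted
#'   block means of the log ratio), \code{f_statistic}, \code{p_value}
#'   (block effect test; \code{NA} when the residual variance is zero) and
#'   \code{n_excluded}.
#' @export
fit_block_model <- function(table) {
  stop_if_not_cols(table, "block", "phenotype table")
  if (!"ratio" %in% names(table)) {
    stop_if_not_cols(table, c("ras_g", "rt_g"), "phenotype table")
    table$ratio <- ras_rt_ratio(table$ras_g, table$rt_g)
  }
  bad <- !is.finite(table$ratio) | table$ratio <= 0
  if (any(bad)) {
    message(sum(bad), " row(s) with non-positive ratio excluded from the block model")
    table <- table[!bad, , drop = FALSE]
  }
  table$block <- factor(table$block)
  if (nlevels(droplevels(table$block)) < 2L)
    stop("need at least two non-empty blocks")
  table$block <- droplevels(table$block)
  y <- log(table$ratio)
  fit <- stats::lm(y ~ block, data = data.frame(y = y, block = table$block))
  table$residual <- unname(stats::residuals(fit))
  an <- suppressWarnings(stats::anova(fit))
  blk <- tapply(y, table$block, mean)
  attr(table, "block_means") <- stats::setNames(as.vector(blk), names(blk))
  ## a (near-)zero residual mean square makes the F test meaningless
  rss <- an[["Sum Sq"]][2L]
  tss <- sum(an[["Sum Sq"]])
  fstat <- an[["F value"]][1L]
  degenerate <- tss <= 1e-20 * (1 + mean(y)^2) * length(y) ||
    rss <= 1e-12 * tss || !is.finite(fstat)
  attr(table, "f_statistic") <- if (degenerate) NA_real_ else fstat
  attr(table, "p_value") <- if (degenerate) NA_real_ else an[["Pr(>F)"]][1L]
  attr(table, "n_excluded") <- sum(bad)
  class(table) <- unique(c("phenotype_fit", class(table)))
  table
}

#' Select phenotypic tail bulks on block-model residuals
#'
#' Picks the \code{round(tail_fraction * n)} individuals with the smallest and
#' largest residuals as the low and high bulk (547 F2 at the default 10% tail
#' gives bulks of 55). Ties are broken by id order so the selection is
#' deterministic.
#'
#' @param table a [fit_block_model()] result (or any data.frame with columns
#'   \code{id} and \code{residual}).
#' @param tail_fraction fraction per tail, in (0, 0.5).
#' @return List with \code{low_ids}, \code{high_ids} (character) and \code{k}.
#' @examples
#' tab <- data.frame(id = sprintf("i%02d", 1:20), residual = rnorm(20))
#' select_bulks(tab)$k   # 2
#' @export
select_bulks <- function(table, tail_fraction = 0.10) {
  stop_if_not_cols(table, c("id", "residual"), "phenotype table")
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must be in (0, 0.5)")
  n <- nrow(table)
  k <- round(tail_fraction * n)
  if (k < 1L) stop("tail_fraction * n rounds to zero individuals per bulk")
  if (2L * k > n) stop("bulks would overlap: 2 * k exceeds n")
  id <- as.character(table$id)
  low <- id[order(table$residual, id)][seq_len(k)]
  high <- id[order(-table$residual, id)][seq_len(k)]
  list(low_ids = low, high_ids = high, k = k)
}

#' Broad-sense heritability from the one-way random-effects model
#'
#' Estimates the variance components of \code{y = mu + line + residual}
#' (line effects random) and computes
#' \deqn{H^2 = Var(line) / (Var(line) + Var(res) / n_{plant/line})}
#' with \code{n_plant/line} the average number of plants per line. The
#' default estimator is the ANOVA method of moments: \code{Var(res)} is the
#' within-line mean square and \code{Var(line) = (MS_between - MS_within) /
#' n0}, truncated at zero, where \code{n0} is the standard effective
#' replicate number for unbalanced designs,
#' \code{n0 = (N - sum(ni^2)/N) / (k - 1)}. \code{method = "reml"} refits the
#' components by restricted maximum likelihood via \pkg{lme4} if installed.
#'
#' @param y numeric phenotype vector.
#' @param line line labels (coerced to factor), at least two levels.
#' @param method \code{"anova"} (method of moments, default) or \code{"reml"}.
#' @return Object of class \code{"heritability_fit"}: list with
#'   \code{var_line}, \code{var_res}, \code{n_plant_per_line}, \code{h2},
#'   \code{method}.
#' @examples
#' d <- simulate_line_phenotypes(50, 400, var_line = 1, var_res = 3, seed = 1)
#' heritability(d$y, d$line)
#' @export
heritability <- function(y, line, method = c("anova", "reml")) {
  method <- match.arg(method)
  line <- factor(line)
  keep <- is.finite(y) & !is.na(line)
  y <- y[keep]; line <- droplevels(line[keep])
  k <- nlevels(line)
  if (k < 2L) stop("variance between lines is inestimable from a single line")
  N <- length(y)
  ni <- as.numeric(table(line))
  if (N - k < 1L)
    stop("no residual degrees of freedom: need replicate plants within lines")
  if (method == "anova") {
    an <- suppressWarnings(stats::anova(stats::lm(y ~ line)))
    msb <- an[["Mean Sq"]][1L]
    msw <- an[["Mean Sq"]][2L]
    n0 <- (N - sum(ni^2) / N) / (k - 1)
    var_line <- max(0, (msb - msw) / n0)
    var_res <- msw
  } else {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = 'reml' requires the lme4 package")
    fit <- lme4::lmer(y ~ (1 | line),
                      data = data.frame(y = y, line = line))
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_line <- vc$vcov[vc$grp == "line"]
    var_res <- vc$vcov[vc$grp == "Residual"]
  }
  nbar <- mean(ni)
  h2 <- if (var_line == 0 && var_res == 0) NA_real_ else
    var_line / (var_line + var_res / nbar)
  structure(list(var_line = var_line, var_res = var_res,
                 n_plant_per_line = nbar, h2 = h2, method = method,
                 n_lines = k, n_plants = N),
            class = "heritability_fit")
}

#' @export
print.heritability_fit <- function(x, digits = 3, ...) {
  cat("Broad-sense heritability (one-way random-effects model)\n")
  cat(sprintf("  %d lines, %d plants (%.2f plants/line), %s estimator\n",
              x$n_lines, x$n_plants, x$n_plant_per_line,
              toupper(x$method)))
  cat(sprintf("  Var(line) = %.*f, Var(res) = %.*f\n",
              digits, x$var_line, digits, x$var_res))
  cat(sprintf("  H2 = %.*f\n", digits, x$h2))
  invisible(x)
}

#' Pairwise trait correlation matrix with p-values and r-squared
#'
#' Computes the pairwise correlation coefficient, test p-value and squared
#' coefficient for every pair of traits, on pairwise-complete observations.
#' Spearman (rank) correlation is the default, matching a rank-based
#' treatment of per-line trait means; Pearson is available for adjusted
#' least-square means. Constant traits yield \code{NA} with a warning-free
#' missing entry.
#'
#' @param traits a numeric data.frame or matrix, one row per line, one column
#'   per trait (e.g. RAS/RT, root length, surface area, diameter, root-hair
#'   length/density, mycorrhization F% and I%).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return Object of class \code{"trait_cor"}: list of matrices \code{r},
#'   \code{p}, \code{r2} plus \code{n} (pairwise complete counts) and
#'   \code{method}.
#' @export
trait_correlations <- function(traits, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  traits <- as.data.frame(traits)
  nt <- ncol(traits)
  if (nt < 2L) stop("need at least two traits")
  nm <- names(traits)
  r <- p <- nmat <- matrix(NA_real_, nt, nt, dimnames = list(nm, nm))
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      ok <- stats::complete.cases(traits[[i]], traits[[j]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      xi <- traits[[i]][ok]; xj <- traits[[j]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next  # undefined
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        ct <- suppressWarnings(stats::cor.test(xi, xj, method = method,
                                               exact = FALSE))
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, r2 = r^2, n = nmat, method = method),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, digits = 3, ...) {
  cat(sprintf("Trait correlation matrix (%s)\n", x$method))
  cat("\n$r\n"); print(round(x$r, digits))
  cat("\n$p\n"); print(signif(x$p, 2))
  invisible(x)
}

#' Squared correlation coefficient
#'
#' The proportion-of-variance effect size reported alongside a correlation:
#' simply the square of the coefficient (so a coefficient of -0.239 has
#' r-squared 0.057 to three decimals).
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return \code{r^2}.
#' @export
correlation_r2 <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  r^2
}

#' Mycorrhizal colonization scores (F% and I%)
#'
#' Root fragments are scored 0-5 for the proportion of cortex colonized by
#' arbuscular mycorrhizal fungi. Colonization frequency is
#' \code{F = n / N * 100} where \code{n} is the number of fragments showing
#' mycorrhizae out of \code{N} observed; colonization intensity is
#' \code{I = (95 n5 + 70 n4 + 30 n3 + 5 n2 + n1) / N}, both in percent.
#'
#' @param n1,n2,n3,n4,n5 counts of fragments scored 1..5.
#' @param n_total number of fragments observed (N), > 0.
#' @param n_mycorrhizal number of fragments showing mycorrhizae; defaults to
#'   \code{n1 + ... + n5}.
#' @return Named numeric vector \code{c(F_percent, I_percent)}.
#' @examples
#' mycorrhiza_scores(n1 = 1, n3 = 1, n5 = 2, n_total = 10)  # F 40, I 22.1
#' @export
mycorrhiza_scores <- function(n1 = 0, n2 = 0, n3 = 0, n4 = 0, n5 = 0,
                              n_total, n_mycorrhizal = NULL) {
  counts <- c(n1, n2, n3, n4, n5)
  if (any(counts < 0) || n_total < 0)
    stop("counts must be non-negative")
  if (n_total == 0) stop("no fragments observed (N = 0)")
  n_mycorrhizal <- n_mycorrhizal %||% sum(counts)
  if (sum(counts) > n_total || n_mycorrhizal > n_total ||
      n_mycorrhizal < sum(counts))
    stop("inconsistent fragment counts: need n1+...+n5 <= n_mycorrhizal <= N")
  c(F_percent = n_mycorrhizal / n_total * 100,
    I_percent = (95 * n5 + 70 * n4 + 30 * n3 + 5 * n2 + n1) / n_total)
}
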