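test_that("RAS/RT ratio is a guarded division", {
  expect_equal(ras_rt_ratio(0, 5), 0)
  expect_equal(ras_rt_ratio(15, 2), 7.5)
  expect_equal(ras_rt_ratio(32.7 * 1.0, 1.0), 32.7)
  expect_equal(ras_rt_ratio(c(1, 2), c(2, 2)), c(0.5, 1))
  expect_error(ras_rt_ratio(1, 0), "invalid sample")
  expect_error(ras_rt_ratio(-1, 1), "invalid sample")
})

test_that("block model removes exact block shifts and handles degenerate input", {
  ## two blocks with ratio means e^1 and e^2, no noise: residuals all zero,
  ## block effect exactly 1 on the log scale
  tab <- data.frame(id = sprintf("p%02d", 1:10),
                    block = rep(c("b1", "b2"), each = 5),
                    ratio = rep(c(exp(1), exp(2)), each = 5))
  fit <- fit_block_model(tab)
  expect_equal(fit$residual, rep(0, 10), tolerance = 1e-12)
  bm <- attr(fit, "block_means")
  expect_equal(unname(bm["b2"] - bm["b1"]), 1, tolerance = 1e-12)

  ## all observations equal: residuals zero, F flagged as NA
  tab2 <- data.frame(id = 1:6, block = rep(c("A", "B"), 3), ratio = 2)
  fit2 <- fit_block_model(tab2)
  expect_equal(fit2$residual, rep(0, 6), tolerance = 1e-12)
  expect_true(is.na(attr(fit2, "f_statistic")))

  ## non-positive ratios are excluded with a count
  tab3 <- data.frame(id = 1:6, block = rep(c("A", "B"), 3),
                     ratio = c(1, 2, 0, 3, 4, 5))
  expect_message(fit3 <- fit_block_model(tab3), "excluded")
  expect_equal(nrow(fit3), 5)
  expect_equal(attr(fit3, "n_excluded"), 1)

  expect_error(fit_block_model(data.frame(id = 1, block = "A", ratio = 2)),
               "two non-empty blocks")
})

test_that("block effects are recovered from noisy data", {
  set.seed(21)
  shifts <- c(0, 0.5, -0.3)
  n_per <- 200
  block <- rep(c("B1", "B2", "B3"), each = n_per)
  log_ratio <- 3 + shifts[as.integer(factor(block))] +
    stats::rnorm(3 * n_per, 0, 0.2)
  tab <- data.frame(id = seq_along(block), block = block,
                    ratio = exp(log_ratio))
  fit <- fit_block_model(tab)
  bm <- attr(fit, "block_means")
  est <- bm - bm["B1"]
  expect_equal(unname(est), shifts - shifts[1], tolerance = 0.08)
  ## residuals sum to zero within each block (one-way ANOVA identity)
  expect_true(all(abs(tapply(fit$residual, fit$block, sum)) < 1e-9))
  ## and agree with the by-block centring oracle
  oracle <- log(tab$ratio) - stats::ave(log(tab$ratio), tab$block)
  expect_equal(fit$residual, oracle, tolerance = 1e-10)
})

test_that("bulk selection takes deterministic 10% tails of the residuals", {
  tab547 <- data.frame(id = sprintf("x%03d", 1:547), residual = sin(1:547))
  b <- select_bulks(tab547, 0.10)
  expect_equal(b$k, 55)               # round(0.10 * 547)
  expect_length(b$low_ids, 55)
  expect_length(intersect(b$low_ids, b$high_ids), 0)

  expect_equal(select_bulks(data.frame(id = 1:20, residual = rnorm(20)))$k, 2)

  tab100 <- data.frame(id = sprintf("id%03d", 1:100), residual = 1:100)
  b100 <- select_bulks(tab100, 0.1)
  expect_setequal(b100$low_ids, sprintf("id%03d", 1:10))
  expect_setequal(b100$high_ids, sprintf("id%03d", 91:100))

  ## invariant under monotone transforms of the residual
  tabm <- tab547
  tabm$residual <- exp(3 * tabm$residual)
  bm <- select_bulks(tabm, 0.10)
  expect_setequal(bm$low_ids, b$low_ids)
  expect_setequal(bm$high_ids, b$high_ids)

  ## ties broken by id order
  tabt <- data.frame(id = c("b", "a", "c", "d"), residual = c(0, 0, 1, 1))
  bt <- select_bulks(tabt, 0.26)
  expect_equal(bt$low_ids, "a")
  expect_equal(bt$high_ids, "c")

  expect_error(select_bulks(data.frame(id = 1:4, residual = 1:4), 0.05),
               "zero individuals")
})

test_that("heritability: limiting cases, invariance and the unbalanced formula", {
  ## zero within-line variance: H2 = 1
  d1 <- data.frame(line = rep(c("a", "b", "c"), each = 4),
                   y = rep(c(1, 2, 3), each = 4))
  expect_equal(heritability(d1$y, d1$line)$h2, 1)

  ## between-line mean square not above within: Var(line) truncates, H2 = 0
  d0 <- data.frame(line = rep(c("a", "b"), each = 2), y = c(0, 2, 1, 1))
  h0 <- heritability(d0$y, d0$line)
  expect_equal(h0$var_line, 0)
  expect_equal(h0$h2, 0)

  ## location and scale invariance
  d <- simulate_line_phenotypes(40, 300, var_line = 1, var_res = 2, seed = 31)
  h <- heritability(d$y, d$line)
  expect_equal(heritability(d$y + 100, d$line)$h2, h$h2, tolerance = 1e-12)
  expect_equal(heritability(d$y * -3.7, d$line)$h2, h$h2, tolerance = 1e-12)

  ## unbalanced effective replicate number matches the hand formula
  du <- simulate_line_phenotypes(3, 10, var_line = 2, var_res = 1, seed = 32)
  hu <- heritability(du$y, du$line)
  an <- stats::anova(stats::lm(y ~ line, du))
  ni <- as.numeric(table(du$line))
  n0 <- (10 - sum(ni^2) / 10) / 2
  expect_equal(hu$var_line,
               max(0, (an[["Mean Sq"]][1] - an[["Mean Sq"]][2]) / n0))
  expect_equal(hu$n_plant_per_line, mean(ni))

  ## REML route agrees closely on a well-behaved design
  hr <- heritability(d$y, d$line, method = "reml")
  expect_lt(abs(hr$h2 - h$h2), 0.05)

  expect_error(heritability(1:5, rep("one", 5)), "single line")
  expect_error(heritability(c(1, 2), c("a", "b")), "degrees of freedom")
})

test_that("one run at the panel design scale lands near the generating H2", {
  d <- simulate_line_phenotypes(181, 1408, var_line = 1,
                                var_res = 7.779006 * (1 / 0.72 - 1),
                                seed = 33)
  h <- heritability(d$y, d$line)
  expect_lt(abs(h$h2 - 0.72), 0.1)
})

test_that("trait correlations: structure, invariance and degenerate traits", {
  set.seed(41)
  tr <- data.frame(ras_rt = rnorm(30))
  tr$avg_diam <- -0.5 * tr$ras_rt + rnorm(30, 0, 0.8)
  tr$lrh <- 0.4 * tr$ras_rt + rnorm(30, 0, 0.9)
  tc <- trait_correlations(tr)
  expect_equal(diag(tc$r), c(ras_rt = 1, avg_diam = 1, lrh = 1))
  expect_equal(tc$r, t(tc$r))
  expect_equal(tc$r2, tc$r^2)
  expect_true(all(tc$p >= 0 & tc$p <= 1))

  ## Spearman is invariant under monotone transforms of a trait
  tr2 <- tr
  tr2$avg_diam <- exp(tr2$avg_diam)
  tc2 <- trait_correlations(tr2, method = "spearman")
  expect_equal(tc2$r, tc$r, tolerance = 1e-12)

  ## Pearson option matches the base oracle
  tp <- trait_correlations(tr, method = "pearson")
  expect_equal(tp$r["ras_rt", "lrh"], stats::cor(tr$ras_rt, tr$lrh),
               tolerance = 1e-12)

  ## constant trait: undefined, reported missing
  tr$flat <- 1
  tcf <- trait_correlations(tr)
  expect_true(is.na(tcf$r["flat", "ras_rt"]))

  expect_error(correlation_r2(1.3), "\\[-1, 1\\]")
})

test_that("mycorrhization scores implement the weighted fragment formula", {
  expect_equal(mycorrhiza_scores(n5 = 10, n_total = 10),
               c(F_percent = 100, I_percent = 95))
  expect_equal(mycorrhiza_scores(n_total = 10),
               c(F_percent = 0, I_percent = 0))
  expect_equal(mycorrhiza_scores(n1 = 1, n3 = 1, n5 = 2, n_total = 10),
               c(F_percent = 40, I_percent = 22.1))
  expect_error(mycorrhiza_scores(n1 = 1, n_total = 0), "N = 0")
  expect_error(mycorrhiza_scores(n5 = 11, n_total = 10), "inconsistent")
})
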