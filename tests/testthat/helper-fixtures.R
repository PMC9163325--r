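# Fixtures built in code, shared across test files.

## Hand-designed 10-site table with exactly one violation per filter rule:
## sites 1-2 multiallelic, 3 low pooled alternate frequency, 4 low depth,
## 5 high depth, 6 missing in one bulk, 7 rare minor allele, 8-10 clean.
## Depth percentiles are estimated on the 7 sites surviving the frequency
## step (totals 10, 400, 400, 400, 401, 402, 10000): the 25th percentile is
## 400 (boundary kept) and the 95th is 7120.6, so exactly sites 4 and 5 fall
## outside.
make_toy_filter_table <- function() {
  data.frame(
    chrom = "chr1",
    pos = (1:10) * 1000,
    ref = "A",
    alt = c("T,G", "T,G", "T", "T", "T", "T", "T", "T", "T", "T"),
    ref_depth_low  = c(100L, 100L, 180L,    3L, 2500L,  200L,   6L, 100L, 100L, 100L),
    alt_depth_low  = c(100L, 100L,  20L,    2L, 2500L,  201L, 195L, 100L, 100L, 100L),
    ref_depth_high = c(100L, 100L, 180L,    3L, 2500L,    NA,   6L, 100L, 100L, 100L),
    alt_depth_high = c(100L, 100L,  20L,    2L, 2500L,    NA, 195L, 100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

## Minimal f2_genotypes object with a prescribed genotype matrix, one
## chromosome, equally spaced markers.
make_geno <- function(geno_matrix, chrom_len = 1.5e8) {
  m <- ncol(geno_matrix)
  rownames(geno_matrix) <- sprintf("F2_%04d", seq_len(nrow(geno_matrix)))
  storage.mode(geno_matrix) <- "integer"
  map <- data.frame(chrom = "chr1",
                    pos = round(seq(1, chrom_len, length.out = m)),
                    morgan = seq(0, 1.5, length.out = m))
  structure(list(geno = geno_matrix, map = map, qtls = NULL),
            class = "f2_genotypes")
}

## A bare scan profile for region-calling tests: everything insignificant
## except the markers listed in `sig`, whose ed4 values are given.
make_profile <- function(n = 200, sig = integer(), ed4_sig = 5,
                         spacing = 1e6, chrom = "chr1") {
  ed4 <- rep(0, n)
  ed4[sig] <- ed4_sig
  off <- 49L  # centre offset for the default 100-marker window
  ed4[seq_len(min(off, n))] <- NA
  if (n > off + 1) ed4[seq(n - 50L + 1L, n)] <- NA
  thr <- if (length(sig)) min(ed4_sig) else Inf
  data.frame(chrom = chrom, pos = spacing * seq_len(n),
             ed = sqrt(sqrt(pmax(ed4, 0))) / 100,
             ed4 = ed4,
             significant = !is.na(ed4) & ed4 >= thr,
             stringsAsFactors = FALSE)
}
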