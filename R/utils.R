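# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## random stream (same contract as stats::simulate).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

## Draw stage seeds below 2^31 from a master seed (or at random if NULL).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

chrom_id <- function(x) {
  ## normalise chromosome labels: 5 -> "chr5", "chr5" -> "chr5"
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

chrom_num <- function(x) sub("^chr", "", as.character(x))

stop_if_not_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}
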