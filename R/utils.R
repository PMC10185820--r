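#' @importFrom methods new validObject is slot
#' @importFrom stats pnorm qnorm pchisq pf qf lm coef cooks.distance rnorm runif
#'   setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic 31-bit hash of a string, for rsid-keyed RNG streams.
# Polynomial rolling hash mod (2^31 - 1); intermediate values stay < 2^53.
hashString <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (v in utf8ToInt(s)) h <- (h * 127 + v) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Combine a master seed with an rsid into a per-SNP stream seed.
snpStreamSeed <- function(seed, rsid) {
  as.integer((as.numeric(seed) * 69069 + hashString(rsid)) %% 2147483647)
}

# Formatting used by the report writers: effect sizes to 3 dp, p-values to
# 3 significant figures.
fmt3 <- function(x) formatC(round(x, 3), format = "f", digits = 3)
fmtP <- function(p) signif(p, 3)

isCount <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x > 0

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
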