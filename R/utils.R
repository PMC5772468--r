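# Internal helpers shared across modules.

# Population z-score (divides by sqrt(mean squared deviation), not n-1).
zpop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s < .Machine$double.eps^0.5)
    stop("cannot z-score a constant vector (zero variance)")
  (x - mu) / s
}

# Derive a reproducible child seed from a parent seed and a string key.
# Simple 32-bit FNV-1a over the key, folded with the parent; keeps every
# stream below 2^31 so it is a valid R seed.
childSeed <- function(seed, key) {
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(paste0(key))) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Linear-interpolation percentile (type 7); the package-wide convention.
pctl <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

stageLevels <- c("W", "N1", "N2", "N3", "N4", "R")

stageCode <- function(stage) match(stage, stageLevels)

isNremCode <- function(code) code >= 2L & code <= 5L
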