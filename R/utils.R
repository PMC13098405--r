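#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate approx ar chisq.test coef cor fft filter glm
#'   mad median pchisq pnorm predict pt quantile rbinom rlnorm rnorm runif sd
#'   setNames var p.adjust binomial cor.test mcnemar.test pwilcox qnorm
#' @importFrom utils head read.csv write.csv tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a child seed from a parent seed
#'
#' Stages of the pipeline consume independent seeds fanned out from a single
#' experiment seed through a counter scheme, so each stage is independently
#' reproducible. Results stay within the 32-bit signed integer range.
#'
#' @param seed Parent integer seed.
#' @param counter Non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(counter))
  m <- 2147483647
  s <- (abs(seed) %% m)
  for (i in seq_len(3)) {
    s <- (s * 48271 + counter * 2654435761 + 12345) %% m
  }
  as.integer(max(1, s %% (m - 1)))
}

## round-half-up on a 1e-9-tolerant value, so e.g. 0.15 * 30 -> 4.5 -> 5
## despite binary floating point placing 0.15*30 fractionally below 4.5.
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

## FNV-1a over a serialized object; stable identifier for configs/artifacts.
object_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

## sample variance helpers used across modules
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

## Pearson (non-excess) kurtosis m4 / m2^2
kurtosis_pearson <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2
}

assert_cols <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  }
}
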