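# Fixed epoch geometry shared by the whole pipeline: epochs are sampled at
# 250 Hz, span [-1000, +1000) ms around the (virtual) perturbation onset, and
# the onset falls on 1-based sample index 251, i.e. sample k (0-based)
# corresponds to time (k - 250) * 4 ms.
EPOCH_FS <- 250
EPOCH_N <- 500L
EPOCH_ONSET_IDX <- 251L
EPOCH_STEP_MS <- 4

#' Epoch time axis
#'
#' Times in milliseconds, relative to perturbation onset, of the 500 samples
#' of a standard epoch (250 Hz, half-open span \[-1000, +1000) ms).
#'
#' @return Numeric vector of length 500; `epochTimes()[251]` is 0.
#' @export
epochTimes <- function() (seq_len(EPOCH_N) - EPOCH_ONSET_IDX) * EPOCH_STEP_MS

# Map a time in ms (multiple of 4) to the 1-based epoch sample index.
msToEpochIdx <- function(ms) {
  idx <- ms / EPOCH_STEP_MS + EPOCH_ONSET_IDX
  if (any(abs(idx - round(idx)) > 1e-9))
    stop("time ", paste(ms, collapse = ", "),
         " ms does not fall on the 4 ms epoch sample grid")
  as.integer(round(idx))
}

# Deterministic child seeds: one master integer seed fans out to every
# stochastic stage. Plain 32-bit-safe arithmetic so results are identical
# across platforms.
deriveSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (tag in tags) {
    t <- if (is.character(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) else as.numeric(tag)
    s <- (s * 48271 + t * 31 + 1) %% 2147483647
  }
  as.integer(s)
}

# All package RNG goes through here so that the generator kind is pinned.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Truncated-normal draws by rejection; bounds are hard.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- rnorm(length(todo), mean, sd)
    ok <- x >= lower & x <= upper
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

rmsOf <- function(x) sqrt(mean(x^2))

standardError <- function(x) sd(x) / sqrt(length(x))
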