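# Internal helpers shared across modules.

# The common TSS-anchored coordinate frame: offsets -3000..+999 (4000 bp),
# offset 0 = the TSS base itself (downstream side of the anchor).
PROMOTER_UPSTREAM <- -3000L
PROMOTER_DOWNSTREAM <- 1000L
PROMOTER_WIDTH <- 4000L

#' Promoter offset vector
#'
#' The ordered vector of promoter-relative offsets used throughout the
#' package: `-3000, ..., +999`, with offset 0 at the transcription start
#' site. All per-base-pair profiles are indexed by this frame.
#'
#' @return Integer vector of length 4000.
#' @export
promoter_offsets <- function() {
  seq.int(PROMOTER_UPSTREAM, PROMOTER_DOWNSTREAM - 1L)
}

# Run body with a temporary RNG state seeded at `seed`; restores the caller's
# RNG stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small integer hash of a string, for deriving per-gene /
# per-condition RNG streams from one master seed. Kept below 2^31.
str_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (ch in v) h <- (h * 131 + ch) %% 1048573
  as.integer(h)
}

derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 1048573
  for (part in list(...)) {
    h <- (h * 31 + str_hash(as.character(part))) %% 2147483560
  }
  as.integer(h) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
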