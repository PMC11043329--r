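# Independent reference implementations used as oracles. These are written
# as plain, slow loops on purpose: they mirror the definitions, not the
# package's vectorised code paths.

# Region scanner: walk significant offsets of one sign left to right,
# closing a cluster when the gap to the next same-sign significant offset
# exceeds max_gap or an opposite-sign significant offset intervenes.
oracle_scan_regions <- function(mask, mean_delta, offsets,
                                max_gap = 25, min_width = 10) {
  out <- list()
  for (s in c(1, -1)) {
    cur <- NULL
    last <- NULL
    flush <- function(cur) {
      if (!is.null(cur) && cur[2] - cur[1] + 1 >= min_width)
        out[[length(out) + 1]] <<- data.frame(
          start_offset = cur[1], end_offset = cur[2],
          direction = if (s > 0) "gain" else "loss")
    }
    for (i in seq_along(offsets)) {
      if (!mask[i]) next
      if (sign(mean_delta[i]) == -s) {
        # opposite-sign significant offset: never bridge across it
        flush(cur); cur <- NULL; last <- NULL
        next
      }
      if (sign(mean_delta[i]) != s) next
      if (is.null(cur)) {
        cur <- c(offsets[i], offsets[i])
      } else if (offsets[i] - last - 1 <= max_gap) {
        cur[2] <- offsets[i]
      } else {
        flush(cur)
        cur <- c(offsets[i], offsets[i])
      }
      last <- offsets[i]
    }
    flush(cur)
  }
  if (!length(out))
    return(data.frame(start_offset = numeric(0), end_offset = numeric(0),
                      direction = character(0)))
  res <- do.call(rbind, out)
  res[order(res$start_offset), , drop = FALSE]
}

# Brute-force per-base track expansion over [lo, hi).
oracle_expand <- function(track, chrom, lo, hi) {
  v <- numeric(hi - lo)
  for (i in seq_len(nrow(track))) {
    if (track$chrom[i] != chrom) next
    for (p in track$start[i]:(track$end[i] - 1)) {
      if (p >= lo && p < hi) v[p - lo + 1] <- track$value[i]
    }
  }
  v
}

# Brute-force fragment-center coverage: per-fragment midpoint enumeration.
oracle_center_coverage <- function(frags, chrom, lo, hi) {
  v <- numeric(hi - lo)
  for (i in seq_len(nrow(frags))) {
    if (frags$chrom[i] != chrom) next
    c0 <- floor((frags$start[i] + frags$end[i] - 1) / 2)
    for (p in (c0 - 1):(c0 + 1)) {
      if (p >= lo && p < hi) v[p - lo + 1] <- v[p - lo + 1] + 1
    }
  }
  v
}

# Random run-length coverage track on one chromosome.
random_track <- function(chrom = "chr1", n_runs = 20, max_pos = 500) {
  bounds <- sort(sample(0:max_pos, n_runs + 1))
  bounds <- bounds[!duplicated(bounds)]
  df <- data.frame(chrom = chrom, start = bounds[-length(bounds)],
                   end = bounds[-1],
                   value = round(stats::runif(length(bounds) - 1, 0, 50), 3))
  mnasequant:::coverage_track(df)
}

# Small normalized two-condition matrices with a given per-gene difference
# planted at one offset (everything else uniform).
planted_pair <- function(diffs, at = 2000) {
  n <- length(diffs)
  ctrl <- matrix(1 / 4000, n, 4000)
  myo <- ctrl
  myo[, at] <- myo[, at] + diffs
  myo[, -at] <- myo[, -at] - diffs / 3999
  rownames(ctrl) <- rownames(myo) <- sprintf("g%d", seq_len(n))
  list(ctrl = ctrl, myo = myo)
}

small_spec <- function(seed, ...) {
  synthetic_spec(n_genes = c(skeletal = 4L, nonmuscle = 4L),
                 depth = 1500L, chip_depth = 1500L, seed = seed, ...)
}
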