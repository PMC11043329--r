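# Per-promoter coverage profiles in the TSS-anchored frame.

#' Extract a promoter coverage profile
#'
#' Pulls the per-base coverage over a gene's promoter window from a
#' coverage track and maps it into the TSS-relative frame (offsets
#' -3000..+999, strand-corrected).
#'
#' @param track A `coverage_track`.
#' @param chrom,tss,strand Gene coordinates (0-based TSS).
#' @return Named numeric vector of length 4000.
#' @export
promoter_profile <- function(track, chrom, tss, strand) {
  win <- promoter_window(tss, strand)
  vals <- track_values(track, chrom, win$start, win$end)
  to_relative_frame(vals, strand)
}

#' Promoter profile matrix for a set of genes
#'
#' One row per gene, 4000 columns indexed by promoter offset.
#'
#' @param track A `coverage_track`.
#' @param ann Validated annotation `data.frame`.
#' @return Numeric matrix, `rownames` = gene ids, `colnames` = offsets.
#' @export
profile_matrix <- function(track, ann) {
  m <- t(vapply(seq_len(nrow(ann)), function(i)
    promoter_profile(track, ann$chrom[i], ann$tss[i], ann$strand[i]),
    numeric(PROMOTER_WIDTH)))
  rownames(m) <- ann$gene_id
  colnames(m) <- promoter_offsets()
  m
}

#' Sum-normalise promoter profiles
#'
#' Divides each per-base read count by the summed read count over the
#' whole 4000-bp promoter, so every promoter carries equal weight
#' regardless of its absolute coverage:
#' `normalized count[p] = count[p] / sum(count)`. A profile with zero
#' total is degenerate: it is returned as all zeros and flagged.
#'
#' @param x Numeric vector of length 4000, or a gene-by-offset matrix.
#' @return Same shape as `x`, rows summing to 1; attribute `degenerate`
#'   marks zero-sum rows.
#' @export
normalize_profile <- function(x) {
  if (is.matrix(x)) {
    s <- rowSums(x)
    degen <- s == 0
    if (any(degen))
      warnf("%d profile(s) have zero total signal; left as zeros",
            sum(degen))
    s[degen] <- 1
    out <- x / s
    attr(out, "degenerate") <- degen
    return(out)
  }
  s <- sum(x)
  if (s == 0) {
    warnf("profile has zero total signal; left as zeros")
    return(structure(x, degenerate = TRUE))
  }
  structure(x / s, degenerate = FALSE)
}

is_normalized <- function(x, tol = 1e-6) {
  if (is.matrix(x)) {
    s <- rowSums(x)
    all(abs(s - 1) < tol | s == 0)
  } else {
    s <- sum(x)
    abs(s - 1) < tol || s == 0
  }
}

#' Difference of normalised profiles
#'
#' The repositioning statistic for one gene: the element-wise difference
#' `myotube - control` of sum-normalised promoter profiles. Because both
#' inputs sum to 1, the difference profile sums to 0 (mass moved, not
#' gained).
#'
#' @param ctrl,myo Normalised 4000-vectors (or matrices with matching
#'   rows) for the two cell states.
#' @return Numeric vector/matrix of differences.
#' @export
delta_profile <- function(ctrl, myo) {
  if (!is_normalized(ctrl) || !is_normalized(myo))
    stopf("delta_profile requires sum-normalized profiles for both conditions")
  myo - ctrl
}

#' Promoter read sum
#'
#' Total signal over the 4-kb window (one number per promoter).
#'
#' @param x 4000-vector or gene-by-offset matrix.
#' @return Scalar or per-gene vector.
#' @export
read_sum <- function(x) {
  if (is.matrix(x)) rowSums(x) else sum(x)
}
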