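# Fragment-level coverage: size selection, fragment-center counting,
# depth normalisation, bedgraph I/O and track merging at 1-bp resolution.

#' Read aligned fragments from a 3-column BED file
#'
#' One line per sequenced fragment, `chrom  start  end` in 0-based
#' half-open coordinates, with the fragment ends defined by the two mate
#' reads of a proper pair. No header.
#'
#' @param path Path to the BED3 file.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_fragments <- function(path) {
  fr <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end"))
  validate_fragments(fr)
}

validate_fragments <- function(frags) {
  stopifnot(all(c("chrom", "start", "end") %in% names(frags)))
  if (nrow(frags) && any(frags$end <= frags$start))
    stopf("fragment with end <= start at row %d",
          which(frags$end <= frags$start)[1L])
  frags
}

#' Size-select fragments
#'
#' Retains fragments whose length (`end - start`) lies in
#' `[min_len, max_len]`, both bounds inclusive. The defaults select the
#' mononucleosome-protected size range used for nucleosome-footprint
#' coverage.
#'
#' @param frags Fragment `data.frame` (`chrom`, `start`, `end`).
#' @param min_len,max_len Inclusive length bounds in bp (defaults 130, 200).
#' @return The retained rows of `frags`.
#' @export
size_filter <- function(frags, min_len = 130L, max_len = 200L) {
  if (min_len > max_len)
    stopf("size filter misconfigured: min_len (%d) > max_len (%d)",
          min_len, max_len)
  len <- frags$end - frags$start
  out <- frags[len >= min_len & len <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment length histogram
#'
#' Exact integer counts per fragment length, as produced by a paired-end
#' insert-size histogram. With a mono/di-nucleosome MNase digest the
#' histogram is bimodal (~150 bp and ~300 bp modes).
#'
#' @param frags Fragment `data.frame`.
#' @return `data.frame` with columns `length` and `count`.
#' @export
fragment_size_histogram <- function(frags) {
  len <- frags$end - frags$start
  if (!length(len))
    return(data.frame(length = integer(0), count = integer(0)))
  tab <- table(len)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

# Internal: coverage_track constructor. A track is a sorted, non-overlapping
# run-length data.frame (chrom, start, end, value) at 1-bp resolution,
# 0-based half-open -- the bedgraph dialect.
coverage_track <- function(df, normalized = FALSE) {
  df <- df[df$value != 0, , drop = FALSE]
  ord <- order(df$chrom, df$start)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("coverage_track", "data.frame"),
            normalized = normalized)
}

#' Fragment-center coverage at 1-bp resolution
#'
#' For each fragment only the 3 nucleotides at its center are counted:
#' coverage is incremented by 1 at positions `c - 1`, `c`, `c + 1` where
#' `c = floor((start + end - 1) / 2)` (the left-of-middle base for
#' even-length fragments). Contributions falling below coordinate 0 are
#' truncated with a warning. Total signal mass is therefore
#' `3 * nrow(frags)` minus any edge truncation.
#'
#' @param frags Size-filtered fragment `data.frame`.
#' @return A `coverage_track`: run-length `data.frame` with columns
#'   `chrom`, `start`, `end`, `value` (0-based half-open, sorted,
#'   non-overlapping).
#' @export
center_coverage <- function(frags) {
  if (!nrow(frags))
    return(coverage_track(data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), value = numeric(0))))
  centers <- (frags$start + frags$end - 1L) %/% 2L
  pos <- c(centers - 1L, centers, centers + 1L)
  chrom <- rep(frags$chrom, 3L)
  keep <- pos >= 0L
  if (!all(keep)) {
    warnf("%d fragment-center base(s) truncated at coordinate 0",
          sum(!keep))
    pos <- pos[keep]
    chrom <- chrom[keep]
  }
  pieces <- lapply(split(pos, chrom), function(p) {
    tab <- table(p)
    at <- as.integer(names(tab))
    val <- as.numeric(tab)
    # collapse adjacent equal-valued bases into runs
    brk <- c(TRUE, diff(at) != 1L | diff(val) != 0)
    grp <- cumsum(brk)
    data.frame(start = at[brk],
               end = at[c(brk[-1], TRUE)] + 1L,
               value = val[brk])
  })
  df <- do.call(rbind, Map(function(ch, d) cbind(chrom = ch, d),
                           names(pieces), pieces))
  coverage_track(df)
}

track_mass <- function(track) {
  sum((track$end - track$start) * track$value)
}

#' Normalise a coverage track to 1x genome depth
#'
#' Multiplies every value by `effective_genome_size / M`, where `M` is the
#' track's total signal mass, so average genome-wide coverage is 1. This is
#' a pure rescaling: per-promoter profile shapes (and anything downstream
#' of per-promoter sum normalisation) are unchanged. Retained for
#' between-track comparability.
#'
#' @param track A `coverage_track`.
#' @param effective_genome_size Mappable genome size in bp. The default is
#'   the conventional mm10 effective size for 50-bp reads.
#' @return Rescaled `coverage_track`.
#' @export
genome_normalize <- function(track, effective_genome_size = 2652783500) {
  m <- track_mass(track)
  if (m <= 0) stopf("cannot normalize a track with zero total signal")
  track$value <- track$value * (effective_genome_size / m)
  attr(track, "normalized") <- TRUE
  track
}

#' Bedgraph input and output
#'
#' Tracks are written as 4-column bedgraph (`chrom start end value`,
#' 0-based half-open) with adjacent equal-valued bases run-length collapsed;
#' values are printed with the `%.17g` format so that a write/read
#' round-trip is bit-faithful. Reading validates that intervals are sorted
#' and non-overlapping per chromosome.
#'
#' @param track A `coverage_track` (or bare `data.frame` with the four
#'   columns).
#' @param path File path.
#' @return `read_bedgraph()` returns a `coverage_track`;
#'   `write_bedgraph()` returns `path` invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%.17g", track$chrom,
                   as.integer(track$start), as.integer(track$end),
                   track$value)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$start, strictly = TRUE))
      stopf("bedgraph intervals unsorted on %s", ch)
    if (any(sub$start[-1] < sub$end[-nrow(sub)]))
      stopf("bedgraph intervals overlap on %s", ch)
    if (any(sub$end <= sub$start))
      stopf("empty or inverted bedgraph interval on %s", ch)
  }
  coverage_track(df)
}

#' Per-base values of a track over an interval
#'
#' Expands the run-length track to a dense per-base vector over
#' `[start, end)` on `chrom`; bases without coverage are 0.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  out <- numeric(end - start)
  sub <- track[track$chrom == chrom & track$end > start & track$start < end, ,
               drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    a <- max(sub$start[i], start) - start + 1L
    b <- min(sub$end[i], end) - start
    out[a:b] <- sub$value[i]
  }
  out
}

#' Merge coverage tracks into a per-base sample matrix
#'
#' Restores the 1-bp window size from run-length bedgraph tracks and
#' aligns samples: the result has one row per base in the union of covered
#' bases and one value column per input track, with 0 where a sample has
#' no coverage (the `bedtools unionbedg` dialect).
#'
#' @param tracks Named list of `coverage_track`s.
#' @return `data.frame` with columns `chrom`, `start`, `end` (= start + 1)
#'   and one numeric column per sample.
#' @export
merge_tracks <- function(tracks) {
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    names(tracks) <- paste0("sample", seq_along(tracks))
  chroms <- sort(unique(unlist(lapply(tracks, function(t) unique(t$chrom)))))
  blocks <- lapply(chroms, function(ch) {
    lo <- min(unlist(lapply(tracks, function(t)
      if (any(t$chrom == ch)) min(t$start[t$chrom == ch]) else Inf)))
    hi <- max(unlist(lapply(tracks, function(t)
      if (any(t$chrom == ch)) max(t$end[t$chrom == ch]) else -Inf)))
    vals <- lapply(tracks, track_values, chrom = ch, start = lo, end = hi)
    covered <- Reduce(`|`, lapply(vals, function(v) v != 0))
    pos <- (lo:(hi - 1L))[covered]
    out <- data.frame(chrom = rep(ch, length(pos)), start = pos,
                      end = pos + 1L)
    for (nm in names(tracks)) out[[nm]] <- vals[[nm]][covered]
    out
  })
  do.call(rbind, blocks)
}
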