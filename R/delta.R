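# Per-base-pair differential occupancy testing across a gene group,
# region calling/classification, nucleosome counting, and group ANOVA.

#' Per-base-pair paired t-test across a gene group
#'
#' At every promoter offset, performs a two-sided paired t-test across
#' genes on the per-gene differences of normalised read counts
#' (`myotube - control`). This is the group-level repositioning test: a
#' significant offset is a base where the gene group consistently gained
#' or lost nucleosome signal upon differentiation.
#'
#' Zero-variance offsets are handled explicitly: if all paired
#' differences are exactly 0 the offset is null (`p = 1`); if the
#' differences are identical but non-zero the t statistic is infinite and
#' the offset is flagged `degenerate` (significant by construction)
#' rather than assigned `p = 0`.
#'
#' @param ctrl,myo Normalised gene-by-offset matrices with identical row
#'   order (one row per gene in the group).
#' @param alpha Per-offset significance level (default 0.05, uncorrected,
#'   one test per 1-bp window).
#' @param p_adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the 4000 per-offset p-values before masking.
#' @param group Optional group label carried into the result.
#' @return An object of class `nucdelta` with elements `mean`, `se`,
#'   `statistic`, `p.value`, `mask`, `degenerate` (all length-4000,
#'   offset-indexed), `n`, `alpha`, `group`, `offsets`.
#' @seealso [call_regions()], [plot.nucdelta()]
#' @export
per_bp_paired_test <- function(ctrl, myo, alpha = 0.05,
                               p_adjust = c("none", "BH"), group = NA_character_) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.matrix(ctrl), is.matrix(myo),
            all(dim(ctrl) == dim(myo)))
  if (!is.null(rownames(ctrl)) && !is.null(rownames(myo)) &&
      !identical(rownames(ctrl), rownames(myo)))
    stopf("control and myotube matrices must pair the same genes in the same order")
  if (!is_normalized(ctrl) || !is_normalized(myo))
    stopf("per_bp_paired_test requires sum-normalized profiles")
  n <- nrow(ctrl)
  if (n < 2L) stopf("paired test needs at least 2 genes (got %d)", n)
  d <- myo - ctrl
  m <- colMeans(d)
  dc <- d - rep(m, each = n)
  v <- colSums(dc * dc) / (n - 1)
  se <- sqrt(v / n)
  tstat <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = n - 1),
              NA_real_)
  degen <- se == 0 & m != 0
  p[se == 0 & m == 0] <- 1
  p_eff <- if (p_adjust == "BH") stats::p.adjust(p, method = "BH") else p
  mask <- (!is.na(p_eff) & p_eff < alpha) | degen
  structure(
    list(mean = m, se = se, statistic = tstat, p.value = p, mask = mask,
         degenerate = degen, n = n, alpha = alpha, p_adjust = p_adjust,
         group = group,
         offsets = if (ncol(ctrl) == PROMOTER_WIDTH) promoter_offsets()
                   else seq_len(ncol(ctrl))),
    class = "nucdelta")
}

#' @export
print.nucdelta <- function(x, ...) {
  cat("Per-bp paired differential occupancy test\n")
  if (!is.na(x$group)) cat("  group:        ", x$group, "\n")
  cat("  genes (n):    ", x$n, "\n")
  cat("  offsets:      ", length(x$offsets), " (",
      min(x$offsets), "..", max(x$offsets), ")\n", sep = "")
  cat("  alpha:        ", x$alpha,
      if (x$p_adjust != "none") paste0(" (", x$p_adjust, "-adjusted)"), "\n")
  cat("  significant:  ", sum(x$mask), " offsets\n", sep = "")
  invisible(x)
}

#' @export
summary.nucdelta <- function(object, ...) {
  reg <- call_regions(object)
  cat("Significant offsets:", sum(object$mask), "of",
      length(object$offsets), "\n")
  if (nrow(reg)) {
    cat("Called regions:\n")
    print(reg)
  } else cat("No regions called at the default merge parameters.\n")
  invisible(reg)
}

#' Plot a differential occupancy profile
#'
#' Mean difference profile with a standard-error ribbon and called
#' regions shaded.
#'
#' @param x A `nucdelta` object.
#' @param regions Optional `data.frame` from [call_regions()]; computed
#'   with defaults when `NULL`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nucdelta <- function(x, regions = NULL, ...) {
  if (is.null(regions)) regions <- call_regions(x)
  off <- x$offsets
  graphics::plot(off, x$mean, type = "n",
                 xlab = "offset from TSS (bp)",
                 ylab = expression(Delta * " normalized read count"), ...)
  if (nrow(regions))
    graphics::rect(regions$start_offset, graphics::par("usr")[3],
                   regions$end_offset + 1, graphics::par("usr")[4],
                   col = "grey90", border = NA)
  graphics::polygon(c(off, rev(off)),
                    c(x$mean + x$se, rev(x$mean - x$se)),
                    col = "grey75", border = NA)
  graphics::lines(off, x$mean, lwd = 0.5)
  graphics::abline(h = 0, lty = 3)
  if (nrow(regions))
    graphics::text((regions$start_offset + regions$end_offset) / 2,
                   graphics::par("usr")[4], regions$label, pos = 1)
  invisible(x)
}

#' Call repositioning regions from a differential test
#'
#' Merges runs of significant offsets that share the sign of the mean
#' difference, bridging internal gaps of up to `max_gap` non-significant
#' bases (a gap is never bridged across an opposite-sign significant
#' offset). Regions narrower than `min_width` are discarded, and the
#' survivors are labelled `A`, `B`, ... in genomic order. Defaults are
#' chosen so that a narrow (~16 bp) TSS-proximal loss region survives.
#'
#' @param d A `nucdelta` object, or a list with elements `mask`, `mean`
#'   and `offsets`.
#' @param max_gap Maximum bridged gap (bp, default 25).
#' @param min_width Minimum region width (bp, default 10).
#' @return `data.frame` with columns `label`, `start_offset`,
#'   `end_offset` (inclusive), `width`, `direction` (`gain`/`loss`),
#'   `mean_delta`.
#' @export
call_regions <- function(d, max_gap = 25L, min_width = 10L) {
  mask <- d$mask
  sgn <- sign(d$mean)
  offsets <- d$offsets
  regs <- list()
  for (s in c(1, -1)) {
    idx <- which(mask & sgn == s)
    if (!length(idx)) next
    opp <- mask & sgn == -s
    opp_cum <- cumsum(opp)
    brk <- c(TRUE, diff(idx) > max_gap + 1L |
               opp_cum[idx[-1L]] - opp_cum[idx[-length(idx)]] > 0L)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      start <- offsets[ii[1L]]
      end <- offsets[ii[length(ii)]]
      if (end - start + 1L < min_width) next
      regs[[length(regs) + 1L]] <- data.frame(
        start_offset = start, end_offset = end,
        width = end - start + 1L,
        direction = if (s > 0) "gain" else "loss",
        mean_delta = mean(d$mean[ii[1L]:ii[length(ii)]]))
    }
  }
  if (!length(regs))
    return(data.frame(label = character(0), start_offset = integer(0),
                      end_offset = integer(0), width = integer(0),
                      direction = character(0), mean_delta = numeric(0)))
  out <- do.call(rbind, regs)
  out <- out[order(out$start_offset), , drop = FALSE]
  out <- cbind(label = LETTERS[seq_len(nrow(out))], out)
  rownames(out) <- NULL
  out
}

#' Classify called regions as shift, build-up, or loss
#'
#' A paired loss-then-gain couple (loss lobe upstream of a gain lobe,
#' separated by at most `pair_distance` bp) is a nucleosome moving toward
#' the 3' end of the gene (`downstream_shift`); gain-then-loss is an
#' `upstream_shift`. Isolated gains are nucleosome `buildup`, isolated
#' losses are `loss`. Pairing is greedy in genomic order — each region
#' looks ahead to the nearest unpaired opposite-direction region within
#' `pair_distance`, skipping same-direction regions in between — and
#' each region joins at most one couple; paired lobes share a `unit` id
#' so a shift counts as one repositioning event.
#'
#' Because a genuine shift relocates (conserves) signal mass, two lobes
#' only pair when their integrated differences are comparable: the
#' smaller `|mean_delta * width|` must be at least `balance_frac` of the
#' larger. This stops an isolated build-up or loss from being misread as
#' a shift because a marginal opposite blip sits nearby.
#'
#' @param regions `data.frame` from [call_regions()].
#' @param pair_distance Maximum gap between paired lobes (bp, default 300).
#' @param balance_frac Minimum lobe-mass ratio for pairing (default 0.25).
#' @return `regions` with added columns `classification` and `unit`.
#' @export
classify_regions <- function(regions, pair_distance = 300L,
                             balance_frac = 0.25) {
  n <- nrow(regions)
  cls <- rep(NA_character_, n)
  unit <- seq_len(n)
  mass <- abs(regions$mean_delta * regions$width)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      if (!is.na(cls[i])) next
      for (j in (i + 1L):n) {
        gap <- regions$start_offset[j] - regions$end_offset[i] - 1L
        if (gap > pair_distance) break
        if (!is.na(cls[j]) || regions$direction[j] == regions$direction[i])
          next
        if (min(mass[i], mass[j]) < balance_frac * max(mass[i], mass[j]))
          next
        if (regions$direction[i] == "loss") {
          cls[c(i, j)] <- "downstream_shift"
        } else {
          cls[c(i, j)] <- "upstream_shift"
        }
        unit[j] <- unit[i]
        break
      }
    }
  }
  iso <- is.na(cls)
  cls[iso & regions$direction == "gain"] <- "buildup"
  cls[iso & regions$direction == "loss"] <- "loss"
  regions$classification <- cls
  regions$unit <- match(unit, unique(unit))
  regions
}

#' Count nucleosomes in a promoter profile
#'
#' Counts local coverage maxima after averaging the profile in `bin`-bp
#' bins, requiring peaks to be separated by at least `min_sep` bp and to
#' reach at least `min_height_frac` of the profile maximum. The counting
#' rule is deliberately separate from the difference pipeline, which uses
#' the raw unsmoothed 1-bp signal.
#'
#' @param p 4000-vector (raw or normalised).
#' @param bin Bin width in bp (default 10).
#' @param min_sep Minimum peak separation in bp (default 120).
#' @param min_height_frac Minimum peak height as a fraction of the
#'   profile maximum (default 0.1).
#' @return Integer count (0 for a flat profile).
#' @export
count_nucleosomes <- function(p, bin = 10L, min_sep = 120L,
                              min_height_frac = 0.1) {
  if (all(p == p[1L])) return(0L)
  nb <- floor(length(p) / bin)
  binned <- colMeans(matrix(p[seq_len(nb * bin)], nrow = bin))
  pk <- pracma::findpeaks(binned,
                          minpeakheight = min_height_frac * max(binned),
                          minpeakdistance = max(1L, round(min_sep / bin)))
  if (is.null(pk)) 0L else nrow(pk)
}

#' Average nucleosome spacing
#'
#' Promoter length (4 kb) divided by the nucleosome count; `NA` when the
#' count is 0.
#'
#' @param count Integer nucleosome count(s).
#' @return Spacing in bp.
#' @export
avg_spacing <- function(count) {
  ifelse(count > 0, PROMOTER_WIDTH / count, NA_real_)
}

#' Per-promoter summaries and their differentiation deltas
#'
#' `promoter_summary()` tabulates, per gene and condition, the summed
#' read count over the window, the nucleosome count, and the average
#' spacing. `delta_summary()` subtracts the control value from the
#' myotube value per gene (change in read sum and in average spacing
#' upon differentiation).
#'
#' @param profiles Named list of raw gene-by-offset matrices, one per
#'   condition (e.g. `list(control = ..., myotube = ...)`).
#' @param ... Passed to [count_nucleosomes()].
#' @return `promoter_summary()`: `data.frame` with `gene_id`,
#'   `condition`, `read_sum`, `nucleosome_count`, `avg_spacing`.
#'   `delta_summary()`: `data.frame` with per-gene `delta_read_sum` and
#'   `delta_spacing`.
#' @export
promoter_summary <- function(profiles, ...) {
  out <- lapply(names(profiles), function(cond) {
    m <- profiles[[cond]]
    cnt <- vapply(seq_len(nrow(m)), function(i)
      count_nucleosomes(m[i, ], ...), integer(1))
    data.frame(gene_id = rownames(m), condition = cond,
               read_sum = rowSums(m), nucleosome_count = cnt,
               avg_spacing = avg_spacing(cnt))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname promoter_summary
#' @param summary_df Output of `promoter_summary()` containing both
#'   conditions.
#' @param control,myotube Condition labels.
#' @export
delta_summary <- function(summary_df, control = "control",
                          myotube = "myotube") {
  a <- summary_df[summary_df$condition == control, ]
  b <- summary_df[summary_df$condition == myotube, ]
  b <- b[match(a$gene_id, b$gene_id), ]
  data.frame(gene_id = a$gene_id,
             delta_read_sum = b$read_sum - a$read_sum,
             delta_spacing = b$avg_spacing - a$avg_spacing)
}

#' One-way ANOVA across gene groups with Bonferroni post-hoc tests
#'
#' Standard one-way ANOVA of a per-gene scalar (e.g. promoter read sum or
#' spacing change) across groups, followed by pairwise t-tests with
#' Bonferroni-multiplied p-values (capped at 1).
#'
#' @param values Numeric vector of per-gene scalars.
#' @param group Factor/character vector of group labels, same length.
#' @return List of class `group_anova` with `F`, `p.value`, `table`
#'   (the ANOVA table), `pairwise` (Bonferroni-adjusted p matrix) and
#'   `degenerate` (TRUE when the within-group variance is zero).
#' @export
group_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  if (any(table(group) < 2L)) stopf("need at least 2 genes per group")
  dat <- data.frame(y = values, g = group)
  fit <- stats::aov(y ~ g, data = dat)
  # a perfect fit (zero residual variance) is reported via the degenerate
  # flag; silence the corresponding lm warning
  tab <- suppressWarnings(stats::anova(fit))
  degen <- !is.finite(tab[["F value"]][1L]) ||
    tab[["Mean Sq"]][2L] <= .Machine$double.eps * (1 + mean(values)^2)
  pw <- tryCatch(
    stats::pairwise.t.test(values, group,
                           p.adjust.method = "bonferroni")$p.value,
    error = function(e) NULL)
  structure(list(F = tab[["F value"]][1L], p.value = tab[["Pr(>F)"]][1L],
                 table = tab, pairwise = pw, degenerate = degen),
            class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat("One-way ANOVA across gene groups\n")
  if (x$degenerate) cat("  (degenerate: zero within-group variance)\n")
  cat(sprintf("  F = %.4g, p = %.4g\n", x$F, x$p.value))
  if (!is.null(x$pairwise)) {
    cat("  Bonferroni pairwise p-values:\n")
    print(round(x$pairwise, 4))
  }
  invisible(x)
}
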