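# Input-subtracted ChIP-seq binding values and the mean + 4-sigma broad
# peak rule, with site censuses, retention, and region overlap reports.

#' Input-subtracted binding value profile
#'
#' Per-offset binding value: normalised IP coverage minus normalised
#' input coverage over the same promoter window. Subtracting the input
#' removes the underlying chromatin signal so that residual peaks
#' reflect antibody pulldown. Because both inputs sum to 1 the binding
#' values sum to 0.
#'
#' @param ip,input Sum-normalised 4000-vectors (or matrices with
#'   matching rows).
#' @return Signed difference profile, same shape.
#' @export
binding_value <- function(ip, input) {
  if (!is_normalized(ip) || !is_normalized(input))
    stopf("binding_value requires sum-normalized IP and input profiles")
  ip - input
}

#' Gaussian confidence of a k-sigma threshold
#'
#' One-sided Gaussian confidence (in percent) of exceeding
#' `mean + k * SD`: `100 * pnorm(k)`. For `k = 4` this is 99.997%.
#'
#' @param k Sigma multiple.
#' @return Percent confidence.
#' @export
sigma_confidence <- function(k = 4) {
  100 * stats::pnorm(k)
}

#' Call binding sites with the mean + 4-sigma rule
#'
#' Computes the mean and standard deviation of the per-offset binding
#' values across the full promoter window, seeds sites at offsets whose
#' value exceeds `mean + sigma * SD`, and extends each seed to the
#' maximal run of offsets exceeding `mean + extend_sigma * SD`
#' (`extend_sigma = NULL` keeps seed offsets only). The rule is affine
#' invariant: adding a constant to, or positively rescaling, the profile
#' leaves the calls unchanged.
#'
#' @param b Binding-value vector (one promoter window).
#' @param sigma Seed threshold in SD units (default 4).
#' @param extend_sigma Extension threshold in SD units (default 1), or
#'   `NULL` for seed-only sites.
#' @param offsets Offset labels; defaults to the promoter frame when `b`
#'   has length 4000, otherwise 0-based indices.
#' @return `data.frame` with columns `start_offset`, `end_offset`
#'   (inclusive), `peak_value`, `sigma_multiple` (peak height in SD
#'   units), sorted by start; attribute `n_seeds` holds the seed count.
#' @export
call_4sigma <- function(b, sigma = 4, extend_sigma = 1, offsets = NULL) {
  if (is.null(offsets))
    offsets <- if (length(b) == PROMOTER_WIDTH) promoter_offsets()
               else seq_along(b) - 1L
  empty <- data.frame(start_offset = integer(0), end_offset = integer(0),
                      peak_value = numeric(0), sigma_multiple = numeric(0))
  mu <- mean(b)
  s <- stats::sd(b)
  if (!is.finite(s) || s == 0) {
    warnf("binding profile has zero variance; no sites called")
    return(structure(empty, n_seeds = 0L))
  }
  seeds <- b > mu + sigma * s
  if (!any(seeds)) return(structure(empty, n_seeds = 0L))
  ext <- if (is.null(extend_sigma)) seeds else b > mu + extend_sigma * s
  r <- rle(ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(i)
    r$values[i] && any(seeds[starts[i]:ends[i]]), logical(1))
  idx <- which(keep)
  out <- data.frame(
    start_offset = offsets[starts[idx]],
    end_offset = offsets[ends[idx]],
    peak_value = vapply(idx, function(i) max(b[starts[i]:ends[i]]),
                        numeric(1)))
  out$sigma_multiple <- (out$peak_value - mu) / s
  out <- out[order(out$start_offset), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_seeds = sum(seeds))
}

#' Census of genes with at least one binding site
#'
#' Counts, per gene group and condition, the genes carrying one or more
#' called binding sites; a gene counts once regardless of how many sites
#' it has.
#'
#' @param sites `data.frame` with at least `gene_id` and `condition`
#'   columns (one row per site).
#' @param ann Annotation `data.frame` giving each gene's group.
#' @return `data.frame` with `group`, `condition`, `genes_with_site`,
#'   `genes_total`; every group x condition combination is present.
#' @export
site_census <- function(sites, ann) {
  conds <- unique(sites$condition)
  if (!length(conds)) conds <- c("control", "myotube")
  grid <- expand.grid(group = unique(ann$group), condition = conds,
                      stringsAsFactors = FALSE)
  grid$genes_with_site <- vapply(seq_len(nrow(grid)), function(i) {
    genes <- ann$gene_id[ann$group == grid$group[i]]
    hit <- unique(sites$gene_id[sites$condition == grid$condition[i]])
    sum(genes %in% hit)
  }, integer(1))
  grid$genes_total <- vapply(grid$group, function(g)
    sum(ann$group == g), integer(1))
  grid
}

#' Validate sites across replicate libraries
#'
#' A site is validated when it is called in both replicates: each site
#' from the first replicate is kept iff it intersects (>= 1 bp) a site
#' called in the second replicate on the same gene. Because spurious
#' 4-sigma exceedances are narrow and positionally random they rarely
#' replicate, while genuine broad binding sites do.
#'
#' @param sites1,sites2 Site `data.frame`s from the two replicates
#'   (columns `gene_id`, `start_offset`, `end_offset`, ...).
#' @return The validated subset of `sites1`.
#' @export
validate_sites <- function(sites1, sites2) {
  if (!nrow(sites1)) return(sites1)
  keep <- vapply(seq_len(nrow(sites1)), function(i) {
    bb <- sites2[sites2$gene_id == sites1$gene_id[i], , drop = FALSE]
    any(intervals_overlap(sites1$start_offset[i], sites1$end_offset[i],
                          bb$start_offset, bb$end_offset))
  }, logical(1))
  out <- sites1[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

intervals_overlap <- function(s1, e1, s2, e2) {
  # inclusive promoter-offset intervals; >= 1 bp shared
  s1 <= e2 & s2 <= e1
}

#' Binding-site retention between conditions
#'
#' A control site is retained if it intersects (by at least 1 bp) a
#' myotube site on the same gene. Reports per-site retention plus
#' counts of retained, lost, and gained sites.
#'
#' @param sites_control,sites_myotube Site `data.frame`s with `gene_id`,
#'   `start_offset`, `end_offset`.
#' @return List with `control` (sites + `retained` flag), `myotube`
#'   (sites + `gained` flag), and `summary` counts.
#' @export
site_retention <- function(sites_control, sites_myotube) {
  hit <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      bb <- b[b$gene_id == a$gene_id[i], , drop = FALSE]
      any(intervals_overlap(a$start_offset[i], a$end_offset[i],
                            bb$start_offset, bb$end_offset))
    }, logical(1))
  }
  ret <- if (nrow(sites_control)) hit(sites_control, sites_myotube)
         else logical(0)
  gain <- if (nrow(sites_myotube)) !hit(sites_myotube, sites_control)
          else logical(0)
  sites_control$retained <- ret
  sites_myotube$gained <- gain
  list(control = sites_control, myotube = sites_myotube,
       summary = c(retained = sum(ret), lost = sum(!ret),
                   gained = sum(gain)))
}

#' Nucleosome-content change at binding sites
#'
#' For each binding site, sums the per-gene MNase difference profile
#' (myotube - control normalised occupancy) over the site interval: a
#' negative value means the site lost nucleosome content upon
#' differentiation.
#'
#' @param sites Site `data.frame` with `gene_id`, `start_offset`,
#'   `end_offset` (and optionally `condition`).
#' @param delta_mat Gene-by-offset matrix of difference profiles
#'   (rownames = gene ids, 4000 offset columns).
#' @return `sites` with an added `delta_content` column.
#' @export
nucleosome_change_at_sites <- function(sites, delta_mat) {
  off0 <- promoter_offsets()[1L]
  sites$delta_content <- vapply(seq_len(nrow(sites)), function(i) {
    g <- sites$gene_id[i]
    if (!g %in% rownames(delta_mat)) return(NA_real_)
    a <- sites$start_offset[i] - off0 + 1L
    b <- sites$end_offset[i] - off0 + 1L
    sum(delta_mat[g, a:b])
  }, numeric(1))
  sites
}

#' Export binding sites as BED6 in genomic coordinates
#'
#' Maps promoter-offset site intervals back onto the genome through each
#' gene's TSS and strand and writes one BED6 record per site (the score
#' column carries the sigma multiple).
#'
#' @param sites Site `data.frame` with `gene_id`, `start_offset`,
#'   `end_offset` and optionally `sigma_multiple`.
#' @param ann Validated annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, ann, path) {
  i <- match(sites$gene_id, ann$gene_id)
  tss <- ann$tss[i]; strand <- ann$strand[i]
  plus <- strand == "+"
  g1 <- ifelse(plus, tss + sites$start_offset, tss - sites$end_offset)
  g2 <- ifelse(plus, tss + sites$end_offset, tss - sites$start_offset)
  bed <- data.frame(
    chrom = ann$chrom[i], start = g1, end = g2 + 1L,
    name = paste0(sites$gene_id, "_",
                  if (!is.null(sites$condition)) sites$condition else "site"),
    score = if (!is.null(sites$sigma_multiple))
      round(sites$sigma_multiple, 2) else 0,
    strand = strand)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Binding-site positions relative to the TSS and called regions
#'
#' Per site: midpoint offset, whether it overlaps any called
#' repositioning region, and the signed distance to the nearest region
#' (0 on overlap; negative when the site lies upstream of the region).
#' Also returns the histogram of site midpoints in 500-bp bins over the
#' promoter window.
#'
#' @param sites Site `data.frame` (`start_offset`, `end_offset`).
#' @param regions Region `data.frame` from [call_regions()].
#' @param bin Histogram bin width in bp.
#' @return List with `sites` (added `midpoint`, `overlaps_region`,
#'   `nearest_distance`) and `histogram` (`data.frame` of bin edges and
#'   counts).
#' @export
site_region_overlap <- function(sites, regions, bin = 500L) {
  mid <- floor((sites$start_offset + sites$end_offset) / 2)
  ov <- rep(FALSE, nrow(sites))
  dist <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!nrow(regions)) break
    hit <- intervals_overlap(sites$start_offset[i], sites$end_offset[i],
                             regions$start_offset, regions$end_offset)
    if (any(hit)) {
      ov[i] <- TRUE
      dist[i] <- 0
    } else {
      d_up <- sites$start_offset[i] - regions$end_offset   # site downstream: > 0
      d_dn <- sites$end_offset[i] - regions$start_offset   # site upstream:  < 0
      cand <- ifelse(regions$end_offset < sites$start_offset[i], d_up, d_dn)
      dist[i] <- cand[which.min(abs(cand))]
    }
  }
  sites$midpoint <- mid
  sites$overlaps_region <- ov
  sites$nearest_distance <- dist
  edges <- seq(PROMOTER_UPSTREAM, PROMOTER_DOWNSTREAM, by = bin)
  cnt <- if (nrow(sites))
    table(cut(mid, breaks = edges, right = FALSE))
  else table(cut(integer(0), breaks = edges, right = FALSE))
  hist <- data.frame(bin_start = edges[-length(edges)],
                     bin_end = edges[-1L], count = as.integer(cnt))
  list(sites = sites, histogram = hist)
}
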