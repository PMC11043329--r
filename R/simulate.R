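# Seeded synthetic MNase-seq / ChIP-seq generator with planted ground
# truth: phased nucleosome arrays per promoter, a mono/di-nucleosome
# fragment-length mixture, condition-specific repositioning
# perturbations, and boxed ChIP enrichment over input.

#' Synthetic dataset specification
#'
#' Collects every generator parameter with documented defaults chosen to
#' emulate the statistical structure of a deeply sequenced MNase digest
#' of promoter chromatin:
#' nucleosome arrays phased on the TSS with ~190-bp spacing, bell-shaped
#' per-nucleosome occupancy, a fragment-length mixture of ~95%
#' mononucleosomes (N(165, 10^2)) and ~5% dinucleosomes (N(330, 20^2))
#' (a digest in which dinucleosomes are almost fully digested), and
#' multinomial fragment sampling as the counting-noise model.
#'
#' @param n_genes Named integer vector of genes per group.
#' @param spacing_mean,spacing_jitter_sd Nucleosome spacing mean and
#'   per-center positional jitter SD (bp).
#' @param phase Offset of the first nucleosome dyad from the upstream
#'   window edge (bp). The default (160) phases the array so one dyad
#'   sits just downstream of the TSS (at +10), emulating a +1
#'   nucleosome.
#' @param peak_width_sd SD of the per-nucleosome occupancy bell (bp).
#' @param frag_mono_mean,frag_mono_sd,frag_di_mean,frag_di_sd,mono_fraction
#'   Fragment-length mixture parameters.
#' @param background_fraction Fraction of fragment mass from a uniform
#'   background (non-positioned digestion).
#' @param depth Fragments sampled per promoter and condition.
#' @param chip_depth Fragments per ChIP library (IP or input).
#' @param perturbations List of planted repositioning events, each
#'   `list(region = c(start, end), type = "shift"|"loss"|"buildup",
#'   delta = bp | factor = x, group = label)`, applied to the myotube
#'   condition of genes in `group`. A shift relocates all fragment mass
#'   in `region` by `delta` bp downstream (negative `delta` shifts
#'   upstream); loss/build-up multiply the sampling intensity in
#'   `region` by `factor`.
#' @param chip_replicates Number of independent ChIP replicate library
#'   pairs per gene and condition (default 2, enabling cross-replicate
#'   site validation).
#' @param chip_boxes List of planted binding sites, each
#'   `list(region = c(start, end), fold = x, group = label,
#'   condition = "control"|"myotube")`: IP sampling intensity is
#'   multiplied by `fold` inside the box.
#' @param pad Chromosome padding upstream of the first window base.
#' @param seed Mandatory integer master seed; all per-gene streams are
#'   derived from it deterministically.
#' @return Validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = c(skeletal = 12L, common = 9L,
                                       heart = 6L, nonmuscle = 26L),
                           spacing_mean = 190, spacing_jitter_sd = 20,
                           phase = 160, peak_width_sd = 30,
                           frag_mono_mean = 165, frag_mono_sd = 10,
                           frag_di_mean = 330, frag_di_sd = 20,
                           mono_fraction = 0.95,
                           background_fraction = 0.05,
                           depth = 5000L, chip_depth = 5000L,
                           chip_replicates = 2L,
                           perturbations = list(), chip_boxes = list(),
                           pad = 5000L, seed) {
  if (missing(seed)) stopf("synthetic_spec requires an explicit seed")
  stopifnot(spacing_jitter_sd > 0, peak_width_sd > 0, frag_mono_sd > 0,
            frag_di_sd > 0, mono_fraction >= 0, mono_fraction <= 1,
            background_fraction >= 0, background_fraction < 1,
            depth >= 0, spacing_mean > 0, pad >= 3000)
  for (p in perturbations)
    stopifnot(p$type %in% c("shift", "loss", "buildup"),
              length(p$region) == 2L)
  structure(
    list(n_genes = n_genes, spacing_mean = spacing_mean,
         spacing_jitter_sd = spacing_jitter_sd, phase = phase,
         peak_width_sd = peak_width_sd,
         frag_mono_mean = frag_mono_mean, frag_mono_sd = frag_mono_sd,
         frag_di_mean = frag_di_mean, frag_di_sd = frag_di_sd,
         mono_fraction = mono_fraction,
         background_fraction = background_fraction,
         depth = as.integer(depth), chip_depth = as.integer(chip_depth),
         chip_replicates = as.integer(chip_replicates),
         perturbations = perturbations, chip_boxes = chip_boxes,
         pad = as.integer(pad), seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Packaged demonstration spec
#'
#' The default end-to-end demonstration: four gene groups at the default
#' sizes, with five repositioning events planted in the skeletal-group
#' myotube promoters — three downstream shifts (around -2.5 kb, -0.6 kb
#' and +0.6 kb), one build-up (around -2 kb) and one narrow TSS-proximal
#' loss — plus Sp3-like ChIP enrichment boxes 2-3 kb upstream whose
#' control-cell sites are absent from myotubes.
#'
#' @param seed Master seed.
#' @return A `synthetic_spec`.
#' @export
demo_spec <- function(seed = 1L) {
  synthetic_spec(
    perturbations = list(
      list(region = c(-2500L, -2400L), type = "shift", delta = 120L,
           group = "skeletal"),
      list(region = c(-2100L, -2000L), type = "buildup", factor = 2.5,
           group = "skeletal"),
      list(region = c(-650L, -525L), type = "shift", delta = 130L,
           group = "skeletal"),
      list(region = c(5L, 20L), type = "loss", factor = 0.1,
           group = "skeletal"),
      list(region = c(530L, 630L), type = "shift", delta = 120L,
           group = "skeletal")),
    chip_boxes = list(
      list(region = c(-2600L, -2450L), fold = 8, group = "skeletal",
           condition = "control"),
      list(region = c(-690L, -540L), fold = 8, group = "skeletal",
           condition = "myotube"),
      list(region = c(-2500L, -2350L), fold = 6, group = "nonmuscle",
           condition = "control")),
    seed = seed)
}

# extended offset grid on which sampling intensities are built; margin
# lets fragment-center smear and shifted mass stay representable.
SIM_MARGIN <- 300L

sim_grid <- function() {
  seq.int(PROMOTER_UPSTREAM - SIM_MARGIN,
          PROMOTER_DOWNSTREAM - 1L + SIM_MARGIN)
}

# True nucleosome centers for one gene (promoter offsets). Drawn from the
# per-gene stream so both conditions share one architecture.
gene_centers <- function(spec, gene_id) {
  base <- seq(PROMOTER_UPSTREAM + spec$phase,
              PROMOTER_DOWNSTREAM - 1L,
              by = spec$spacing_mean)
  with_seed(derive_seed(spec$seed, gene_id, "arch"),
            base + stats::rnorm(length(base), 0, spec$spacing_jitter_sd))
}

# Per-offset fragment-center sampling intensity over the extended grid.
gene_intensity <- function(spec, centers) {
  x <- sim_grid()
  lam <- rowSums(vapply(centers, function(c0)
    stats::dnorm(x, c0, spec$peak_width_sd), numeric(length(x))))
  bg <- spec$background_fraction
  lam / sum(lam) * (1 - bg) + bg / length(x)
}

in_region <- function(x, region) x >= region[1] & x <= region[2]

apply_perturbations <- function(lam, spec, group) {
  x <- sim_grid()
  for (p in spec$perturbations) {
    if (!is.null(p$group) && !identical(p$group, group)) next
    if (p$type == "shift") {
      moved <- lam * in_region(x, p$region)
      d <- as.integer(p$delta)
      shifted <- if (d >= 0)
        c(rep(0, d), moved[seq_len(length(moved) - d)])
      else
        c(moved[(1 - d):length(moved)], rep(0, -d))
      lam <- lam - moved + shifted
    } else {
      f <- if (p$type == "loss") p$factor else p$factor
      lam <- ifelse(in_region(x, p$region), lam * f, lam)
    }
  }
  lam
}

sample_fragment_lengths <- function(spec, n) {
  mono <- stats::runif(n) < spec$mono_fraction
  len <- ifelse(mono,
                stats::rnorm(n, spec$frag_mono_mean, spec$frag_mono_sd),
                stats::rnorm(n, spec$frag_di_mean, spec$frag_di_sd))
  pmax(50L, as.integer(round(len)))
}

# Sample `n` fragments whose centers follow intensity `lam` (offset grid),
# mapped to genomic coordinates for (tss, strand).
sample_fragments <- function(spec, lam, n, tss, strand) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  x <- sim_grid()
  centers_off <- sample(x, n, replace = TRUE, prob = lam)
  len <- sample_fragment_lengths(spec, n)
  gc <- if (strand == "+") tss + centers_off else tss - centers_off
  start <- gc - (len - 1L) %/% 2L
  data.frame(start = pmax(0L, start), end = pmax(0L, start) + len)
}

#' Simulate MNase fragments for one promoter
#'
#' Places a phased, jittered nucleosome array across the promoter
#' window (the architecture is drawn once per gene and shared between
#' conditions, making the two-condition design genuinely paired),
#' applies any myotube perturbations for the gene's group, and samples
#' `depth` fragments with the spec's length mixture. Deterministic given
#' the spec seed, gene id and condition.
#'
#' @param spec A `synthetic_spec`.
#' @param gene_id Gene identifier.
#' @param condition `"control"` or `"myotube"`.
#' @param group Gene group label (determines which perturbations apply).
#' @param chrom,tss,strand Genomic placement of the gene.
#' @return List with `fragments` (`chrom`, `start`, `end`) and `truth`
#'   (`centers`, applied `perturbations`).
#' @export
simulate_promoter_fragments <- function(spec, gene_id,
                                        condition = c("control", "myotube"),
                                        group = "skeletal",
                                        chrom = paste0("chr_", gene_id),
                                        tss = spec$pad, strand = "+") {
  condition <- match.arg(condition)
  centers <- gene_centers(spec, gene_id)
  lam <- gene_intensity(spec, centers)
  applied <- list()
  if (condition == "myotube") {
    applied <- Filter(function(p) is.null(p$group) ||
                        identical(p$group, group), spec$perturbations)
    lam <- apply_perturbations(lam, spec, group)
  }
  frags <- with_seed(derive_seed(spec$seed, gene_id, condition, "frags"),
                     sample_fragments(spec, lam, spec$depth, tss, strand))
  frags <- cbind(chrom = rep(chrom, nrow(frags)), frags)
  list(fragments = frags,
       truth = list(centers = centers, perturbations = applied))
}

#' Simulate paired ChIP (IP and input) fragments for one promoter
#'
#' The input library follows the gene's MNase architecture; the IP
#' library samples from the same intensity multiplied by `fold` inside
#' each enrichment box that applies to this gene's group and the
#' requested condition.
#'
#' @inheritParams simulate_promoter_fragments
#' @param replicate Replicate index (independent sampling stream per
#'   replicate; the architecture stays the gene's own).
#' @return List with `ip`, `input` (fragment data frames) and `sites`
#'   (the true planted intervals for this gene and condition).
#' @export
simulate_chip <- function(spec, gene_id, condition = c("control", "myotube"),
                          group = "skeletal",
                          chrom = paste0("chr_", gene_id),
                          tss = spec$pad, strand = "+", replicate = 1L) {
  condition <- match.arg(condition)
  centers <- gene_centers(spec, gene_id)
  lam <- gene_intensity(spec, centers)
  boxes <- gene_boxes(spec, group, condition)
  lam_ip <- lam
  x <- sim_grid()
  for (b in boxes)
    lam_ip <- ifelse(in_region(x, b$region), lam_ip * b$fold, lam_ip)
  ip <- with_seed(derive_seed(spec$seed, gene_id, condition, replicate, "ip"),
                  sample_fragments(spec, lam_ip, spec$chip_depth, tss, strand))
  input <- with_seed(derive_seed(spec$seed, gene_id, condition, replicate,
                                 "input"),
                     sample_fragments(spec, lam, spec$chip_depth, tss, strand))
  list(ip = cbind(chrom = rep(chrom, nrow(ip)), ip),
       input = cbind(chrom = rep(chrom, nrow(input)), input),
       sites = true_chip_sites(spec, gene_id, condition, group))
}

gene_boxes <- function(spec, group, condition) {
  Filter(function(b)
    (is.null(b$group) || identical(b$group, group)) &&
      (is.null(b$condition) || identical(b$condition, condition)),
    spec$chip_boxes)
}

#' Planted binding sites for one gene
#'
#' The generator's ground-truth site table for a gene, group and
#' condition (no sampling involved).
#'
#' @inheritParams simulate_chip
#' @return `data.frame` with `gene_id`, `condition`, `start_offset`,
#'   `end_offset`, `fold`.
#' @export
true_chip_sites <- function(spec, gene_id, condition, group) {
  boxes <- gene_boxes(spec, group, condition)
  if (!length(boxes))
    return(data.frame(gene_id = character(0), condition = character(0),
                      start_offset = numeric(0), end_offset = numeric(0),
                      fold = numeric(0)))
  data.frame(gene_id = gene_id, condition = condition,
             start_offset = vapply(boxes, function(b) b$region[1],
                                   numeric(1)),
             end_offset = vapply(boxes, function(b) b$region[2], numeric(1)),
             fold = vapply(boxes, `[[`, numeric(1), "fold"))
}

#' Synthetic annotation and groups for a spec
#'
#' One padded chromosome per gene (so no promoter window underflows),
#' alternating strands. Gene ids reuse the packaged default group lists
#' where the requested sizes allow, extending with numbered ids beyond
#' them.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `annotation` (data.frame) and `groups` (named list).
#' @export
simulate_annotation <- function(spec) {
  defaults <- default_gene_groups()
  groups <- list()
  for (g in names(spec$n_genes)) {
    n <- spec$n_genes[[g]]
    pool <- if (g %in% names(defaults)) defaults[[g]] else character(0)
    ids <- if (n <= length(pool)) pool[seq_len(n)]
           else c(pool, sprintf("%s_%02d", g, seq_len(n - length(pool))))
    groups[[g]] <- ids
  }
  ann <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    data.frame(gene_id = ids, chrom = paste0("chr_", ids),
               tss = spec$pad,
               strand = rep(c("+", "-"), length.out = length(ids)),
               group = g)
  }))
  rownames(ann) <- NULL
  list(annotation = validate_annotation(ann, names(groups)), groups = groups)
}

#' Simulate a complete two-condition dataset
#'
#' Fragments for every gene and condition, plus ChIP libraries when the
#' spec plants enrichment boxes, with full ground truth. Deterministic
#' given the spec (same seed, byte-identical output).
#'
#' @param spec A `synthetic_spec`.
#' @param chip Also simulate IP/input libraries (default: TRUE when the
#'   spec has chip boxes).
#' @return List with `spec`, `annotation`, `groups`, `fragments`
#'   (`fragments[[gene]][[condition]]`), `chip`
#'   (`chip[[gene]][[condition]]$ip/$input`), `truth` (per-gene centers
#'   and perturbations, plus `chip_sites`).
#' @export
simulate_dataset <- function(spec, chip = length(spec$chip_boxes) > 0) {
  sa <- simulate_annotation(spec)
  ann <- sa$annotation
  fragments <- list()
  chip_out <- list()
  truth <- list(genes = list(), chip_sites = list())
  for (i in seq_len(nrow(ann))) {
    g <- ann$gene_id[i]
    fragments[[g]] <- list()
    for (cond in c("control", "myotube")) {
      sim <- simulate_promoter_fragments(spec, g, cond, ann$group[i],
                                         ann$chrom[i], ann$tss[i],
                                         ann$strand[i])
      fragments[[g]][[cond]] <- sim$fragments
      if (cond == "myotube")
        truth$genes[[g]] <- sim$truth
    }
    if (chip) {
      chip_out[[g]] <- list()
      for (cond in c("control", "myotube")) {
        reps <- lapply(seq_len(spec$chip_replicates), function(r)
          simulate_chip(spec, g, cond, ann$group[i], ann$chrom[i],
                        ann$tss[i], ann$strand[i],
                        replicate = r)[c("ip", "input")])
        names(reps) <- paste0("rep", seq_along(reps))
        chip_out[[g]][[cond]] <- reps
        sites <- true_chip_sites(spec, g, cond, ann$group[i])
        if (nrow(sites))
          truth$chip_sites[[length(truth$chip_sites) + 1L]] <- sites
      }
    }
  }
  truth$chip_sites <- if (length(truth$chip_sites))
    do.call(rbind, truth$chip_sites)
  else NULL
  list(spec = spec, annotation = ann, groups = sa$groups,
       fragments = fragments, chip = if (chip) chip_out else NULL,
       truth = truth)
}

#' Null two-condition profile matrices
#'
#' The calibration null for the per-bp paired test: each gene gets one
#' fixed promoter architecture (phased occupancy plus a baseline), and
#' the two conditions are independent noisy observations of it —
#' identical means, i.i.d. Gaussian noise, no planted effect. Profiles
#' are sum-normalised as in the real pipeline.
#'
#' @param n_genes Number of genes (default 12).
#' @param noise_sd Gaussian noise SD, in units of the occupancy baseline
#'   (architecture bumps have amplitude 1 over a 0.5 baseline).
#' @param spacing_mean,spacing_jitter_sd,phase,peak_width_sd Architecture
#'   parameters as in [synthetic_spec()].
#' @param seed Integer seed.
#' @return List with matrices `control` and `myotube`
#'   (`n_genes` x 4000, rows normalised) and `architecture`.
#' @export
simulate_null_groups <- function(n_genes = 12L, noise_sd = 0.1,
                                 spacing_mean = 190, spacing_jitter_sd = 20,
                                 phase = 160, peak_width_sd = 30, seed) {
  if (missing(seed)) stopf("simulate_null_groups requires a seed")
  x <- promoter_offsets()
  with_seed(seed, {
    arch <- t(vapply(seq_len(n_genes), function(i) {
      base <- seq(PROMOTER_UPSTREAM + phase, PROMOTER_DOWNSTREAM - 1L,
                  by = spacing_mean)
      cen <- base + stats::rnorm(length(base), 0, spacing_jitter_sd)
      bump <- rowSums(vapply(cen, function(c0)
        exp(-(x - c0)^2 / (2 * peak_width_sd^2)), numeric(length(x))))
      0.5 + bump
    }, numeric(length(x))))
    noise <- function() matrix(stats::rnorm(n_genes * length(x), 0, noise_sd),
                               n_genes, length(x))
    ctrl <- arch + noise()
    myo <- arch + noise()
    rn <- sprintf("gene_%02d", seq_len(n_genes))
    dimnames(ctrl) <- dimnames(myo) <- list(rn, x)
    list(control = normalize_profile(ctrl),
         myotube = normalize_profile(myo),
         architecture = arch)
  })
}
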