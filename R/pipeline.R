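# End-to-end orchestration: fragments -> coverage -> profiles -> per-group
# differential tests -> regions -> model fits -> inter-group correlation ->
# ChIP site calling -> report tables, under one seeded config.

#' Pipeline run configuration
#'
#' Every stage parameter with its documented default: fragment size
#' bounds 130/200 bp, 1-bp windows over the \[-3000, +1000) promoter
#' frame, per-offset significance level 0.05, region merge gap 25 bp and
#' minimum width 10 bp, lobe pairing distance 300 bp, seed threshold 4
#' sigma with 1-sigma extension, and the skeletal group as the reference
#' whose called regions anchor the cross-group correlations.
#'
#' @param spec A `synthetic_spec` (for simulated runs), or `NULL` when
#'   `input_dir` points at a written dataset.
#' @param input_dir Directory holding `annotation.tsv`, `groups.yaml`
#'   and per-gene fragment BED files (as written by [write_dataset()]).
#' @param out_dir Output directory for the report tables.
#' @param alpha,p_adjust Per-offset test level and adjustment.
#' @param max_gap,min_width,pair_distance Region calling parameters (bp).
#' @param sigma,extend_sigma ChIP peak thresholds (SD units).
#' @param min_len,max_len Fragment size filter (bp).
#' @param effective_genome_size 1x-depth normalisation scalar.
#' @param reference_group Group whose regions are used for fits and
#'   correlations.
#' @param seed Integer seed for any stage randomness.
#' @return List of class `run_config`.
#' @export
run_config <- function(spec = NULL, input_dir = NULL, out_dir = tempfile("mnq_run_"),
                       alpha = 0.05, p_adjust = "none",
                       max_gap = 25L, min_width = 10L, pair_distance = 300L,
                       sigma = 4, extend_sigma = 1,
                       min_len = 130L, max_len = 200L,
                       effective_genome_size = 2652783500,
                       reference_group = "skeletal", seed = 1L) {
  if (is.null(spec) && is.null(input_dir))
    stopf("run_config needs either a synthetic spec or an input directory")
  structure(list(spec = spec, input_dir = input_dir, out_dir = out_dir,
                 alpha = alpha, p_adjust = p_adjust, max_gap = max_gap,
                 min_width = min_width, pair_distance = pair_distance,
                 sigma = sigma, extend_sigma = extend_sigma,
                 min_len = min_len, max_len = max_len,
                 effective_genome_size = effective_genome_size,
                 reference_group = reference_group, seed = as.integer(seed)),
            class = "run_config")
}

#' Correlate gene groups over called regions
#'
#' Pearson correlation between the group-mean difference profiles of
#' every pair of groups, restricted to each called region's offsets and
#' over the whole 4000-bp promoter. Pairs with `|R| > strong` are
#' flagged as strongly correlated. A zero-variance vector within a
#' region yields `NA` (reported as missing).
#'
#' @param deltas Named list of `nucdelta` objects (or of mean-difference
#'   vectors), one per group.
#' @param regions Region `data.frame` (typically the reference group's
#'   calls).
#' @param strong Strong-correlation threshold (default 0.7).
#' @return Object of class `correlation_report`: list of symmetric
#'   unit-diagonal R matrices, one per region label plus `"promoter"`.
#' @export
correlate_groups <- function(deltas, regions, strong = 0.7) {
  if (length(deltas) < 2L) stopf("need at least 2 groups to correlate")
  means <- lapply(deltas, function(d) if (inherits(d, "nucdelta")) d$mean
                  else as.numeric(d))
  off0 <- promoter_offsets()[1L]
  spans <- c(stats::setNames(
    lapply(seq_len(nrow(regions)), function(i)
      (regions$start_offset[i] - off0 + 1L):(regions$end_offset[i] - off0 + 1L)),
    regions$label),
    list(promoter = seq_len(PROMOTER_WIDTH)))
  mats <- lapply(spans, function(idx) {
    m <- diag(1, length(means))
    dimnames(m) <- list(names(means), names(means))
    for (i in seq_along(means)) for (j in seq_along(means)) {
      if (i >= j) next
      a <- means[[i]][idx]; b <- means[[j]][idx]
      r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
           else stats::cor(a, b)
      m[i, j] <- m[j, i] <- r
    }
    m
  })
  structure(list(matrices = mats, strong = strong),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Inter-group Pearson correlations of difference profiles\n")
  for (nm in names(x$matrices)) {
    cat("  [", nm, "]\n", sep = "")
    print(round(x$matrices[[nm]], 3))
  }
  cat(sprintf("  |R| > %.2f is flagged strong\n", x$strong))
  invisible(x)
}

correlation_table <- function(rep) {
  rows <- list()
  for (nm in names(rep$matrices)) {
    m <- rep$matrices[[nm]]
    gs <- rownames(m)
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (i >= j) next
      rows[[length(rows) + 1L]] <- data.frame(
        region = nm, group1 = gs[i], group2 = gs[j], r = m[i, j],
        strong = !is.na(m[i, j]) && abs(m[i, j]) > rep$strong)
    }
  }
  do.call(rbind, rows)
}

#' Write / load a simulated dataset as plain-text files
#'
#' `write_dataset()` emits `annotation.tsv`, `groups.yaml`, a
#' `truth.tsv` sidecar of planted perturbations, and one fragment BED
#' per gene and condition under `fragments/` (plus `chip/` when ChIP
#' libraries were simulated). `load_dataset()` reads them back into the
#' structure [run_pipeline()] consumes.
#'
#' @param ds Dataset from [simulate_dataset()].
#' @param dir Target directory.
#' @return `write_dataset()` returns `dir` invisibly; `load_dataset()`
#'   returns a dataset list.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.table(ds$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_group_config(ds$groups, file.path(dir, "groups.yaml"))
  for (g in names(ds$fragments)) for (cond in names(ds$fragments[[g]]))
    utils::write.table(ds$fragments[[g]][[cond]],
                       file.path(dir, "fragments",
                                 sprintf("%s_%s.bed", g, cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  if (!is.null(ds$chip)) {
    dir.create(file.path(dir, "chip"), showWarnings = FALSE)
    for (g in names(ds$chip)) for (cond in names(ds$chip[[g]]))
      for (rep in names(ds$chip[[g]][[cond]]))
        for (lib in c("ip", "input"))
          utils::write.table(ds$chip[[g]][[cond]][[rep]][[lib]],
                             file.path(dir, "chip",
                                       sprintf("%s_%s_%s_%s.bed", g, cond,
                                               rep, lib)),
                             sep = "\t", quote = FALSE, row.names = FALSE,
                             col.names = FALSE)
  }
  pert <- lapply(ds$truth$genes, function(t) t$perturbations)
  rows <- list()
  for (g in names(pert)) for (p in pert[[g]])
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, type = p$type, start = p$region[1], end = p$region[2],
      value = if (p$type == "shift") p$delta else p$factor)
  if (length(rows))
    utils::write.table(do.call(rbind, rows), file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
load_dataset <- function(dir) {
  ann <- load_annotation(file.path(dir, "annotation.tsv"),
                         valid_groups = NULL)
  groups <- read_group_config(file.path(dir, "groups.yaml"))
  fragments <- list()
  for (g in ann$gene_id) {
    fragments[[g]] <- list()
    for (cond in c("control", "myotube")) {
      f <- file.path(dir, "fragments", sprintf("%s_%s.bed", g, cond))
      if (file.exists(f)) fragments[[g]][[cond]] <- read_fragments(f)
    }
  }
  chip <- NULL
  if (dir.exists(file.path(dir, "chip"))) {
    chip <- list()
    for (g in ann$gene_id) {
      chip[[g]] <- list()
      for (cond in c("control", "myotube")) {
        reps <- list()
        r <- 1L
        repeat {
          pair <- list()
          for (lib in c("ip", "input")) {
            f <- file.path(dir, "chip",
                           sprintf("%s_%s_rep%d_%s.bed", g, cond, r, lib))
            if (file.exists(f)) pair[[lib]] <- read_fragments(f)
          }
          if (!length(pair)) break
          reps[[paste0("rep", r)]] <- pair
          r <- r + 1L
        }
        if (length(reps)) chip[[g]][[cond]] <- reps
      }
    }
  }
  list(annotation = ann, groups = groups, fragments = fragments,
       chip = chip, truth = NULL)
}

# fragments for one gene/condition -> raw TSS-frame profile
fragments_to_profile <- function(frags, cfg, chrom, tss, strand) {
  frags <- size_filter(frags, cfg$min_len, cfg$max_len)
  track <- center_coverage(frags)
  promoter_profile(track, chrom, tss, strand)
}

raw_profiles <- function(ds, cfg) {
  ann <- ds$annotation
  out <- list()
  for (cond in c("control", "myotube")) {
    m <- t(vapply(seq_len(nrow(ann)), function(i)
      fragments_to_profile(ds$fragments[[ann$gene_id[i]]][[cond]], cfg,
                           ann$chrom[i], ann$tss[i], ann$strand[i]),
      numeric(PROMOTER_WIDTH)))
    rownames(m) <- ann$gene_id
    colnames(m) <- promoter_offsets()
    out[[cond]] <- m
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or loaded dataset: size-filtered
#' fragment-center coverage, TSS-frame profiles, sum normalisation,
#' per-group per-bp paired tests, region calling and classification for
#' the reference group, per-unit two-Lorentzian fits and whole-promoter
#' constrained-spline fits, inter-group correlations over the reference
#' regions, promoter summaries with group ANOVAs, and (when ChIP
#' libraries are present) 4-sigma site calling with census, retention,
#' nucleosome-change and region-overlap reports. All tables are written
#' to `cfg$out_dir` together with a manifest recording the package
#' version, seed, parameters and output checksums; rerunning the same
#' config reproduces identical tables.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory results (`profiles`,
#'   `deltas`, `regions`, `fits`, `correlations`, `summaries`, `anova`,
#'   `chip`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stage <- function(name, code)
    tryCatch(code, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  ds <- stage("input", {
    if (!is.null(cfg$input_dir)) load_dataset(cfg$input_dir)
    else simulate_dataset(cfg$spec)
  })
  ann <- ds$annotation

  prof <- stage("coverage", raw_profiles(ds, cfg))
  norm <- stage("normalize", lapply(prof, normalize_profile))

  deltas <- stage("diff", {
    out <- list()
    for (g in names(ds$groups)) {
      ids <- intersect(ds$groups[[g]], rownames(norm$control))
      out[[g]] <- per_bp_paired_test(norm$control[ids, , drop = FALSE],
                                     norm$myotube[ids, , drop = FALSE],
                                     alpha = cfg$alpha,
                                     p_adjust = cfg$p_adjust, group = g)
    }
    out
  })

  regions <- stage("regions", {
    r <- call_regions(deltas[[cfg$reference_group]], cfg$max_gap,
                      cfg$min_width)
    classify_regions(r, cfg$pair_distance)
  })

  fits <- stage("fit", {
    rows <- list()
    d <- deltas[[cfg$reference_group]]
    off0 <- promoter_offsets()[1L]
    if (nrow(regions)) for (u in unique(regions$unit)) {
      sub <- regions[regions$unit == u, , drop = FALSE]
      lo <- min(sub$start_offset) - 100L
      hi <- max(sub$end_offset) + 100L
      idx <- max(1L, lo - off0 + 1L):min(PROMOTER_WIDTH, hi - off0 + 1L)
      x <- d$offsets[idx]; y <- d$mean[idx]
      if (coarse_peak_count(x, y) <= 2L) {
        f <- fit_two_lorentzians(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          group = cfg$reference_group, model = "two_lorentzian",
          start = min(x), end = max(x), rss = f$rss,
          params = paste(sprintf("%s=%.6g", names(coef(f)), coef(f)),
                         collapse = ";"))
      } else {
        f <- fit_constrained_spline(x, y)
        rows[[length(rows) + 1L]] <- data.frame(
          group = cfg$reference_group, model = "constrained_spline",
          start = min(x), end = max(x), rss = f$rss,
          params = sprintf("lambda=%.6g", f$lambda))
      }
    }
    for (g in names(deltas)) {
      f <- fit_constrained_spline(deltas[[g]]$offsets, deltas[[g]]$mean)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, model = "constrained_spline",
        start = PROMOTER_UPSTREAM, end = PROMOTER_DOWNSTREAM - 1L,
        rss = f$rss, params = sprintf("lambda=%.6g", f$lambda))
    }
    do.call(rbind, rows)
  })

  correlations <- if (length(deltas) >= 2L)
    stage("correlate", correlate_groups(deltas, regions))

  summaries <- stage("summary", promoter_summary(prof))
  anova_tab <- stage("anova", {
    ds_sum <- delta_summary(summaries)
    grp <- ann$group[match(ds_sum$gene_id, ann$gene_id)]
    ctrl <- summaries[summaries$condition == "control", ]
    grp_c <- ann$group[match(ctrl$gene_id, ann$gene_id)]
    metrics <- list(
      read_sum_control = list(v = ctrl$read_sum, g = grp_c),
      avg_spacing_control = list(v = ctrl$avg_spacing, g = grp_c),
      delta_read_sum = list(v = ds_sum$delta_read_sum, g = grp),
      delta_spacing = list(v = ds_sum$delta_spacing, g = grp))
    do.call(rbind, lapply(names(metrics), function(nm) {
      a <- tryCatch(group_anova(metrics[[nm]]$v, metrics[[nm]]$g),
                    error = function(e) NULL)
      if (is.null(a))   # single-group runs have no between-group test
        data.frame(metric = nm, F = NA_real_, p.value = NA_real_,
                   degenerate = NA)
      else
        data.frame(metric = nm, F = a$F, p.value = a$p.value,
                   degenerate = a$degenerate)
    }))
  })

  chip_res <- NULL
  if (!is.null(ds$chip)) chip_res <- stage("chip-call", {
    sites <- list()
    for (g in names(ds$chip)) for (cond in names(ds$chip[[g]])) {
      i <- match(g, ann$gene_id)
      reps <- ds$chip[[g]][[cond]]
      per_rep <- lapply(reps, function(pair) {
        ipp <- normalize_profile(fragments_to_profile(pair$ip, cfg,
                 ann$chrom[i], ann$tss[i], ann$strand[i]))
        inp <- normalize_profile(fragments_to_profile(pair$input, cfg,
                 ann$chrom[i], ann$tss[i], ann$strand[i]))
        s <- call_4sigma(binding_value(ipp, inp), cfg$sigma,
                         cfg$extend_sigma)
        cbind(gene_id = rep(g, nrow(s)), s)
      })
      # validated sites: called in the first replicate and reproduced in
      # every other replicate
      s <- per_rep[[1L]]
      if (length(per_rep) > 1L)
        for (r in 2L:length(per_rep)) s <- validate_sites(s, per_rep[[r]])
      if (nrow(s))
        sites[[length(sites) + 1L]] <- cbind(condition = cond, s)
    }
    sites <- if (length(sites)) do.call(rbind, sites)
      else data.frame(gene_id = character(0), condition = character(0),
                      start_offset = integer(0), end_offset = integer(0),
                      peak_value = numeric(0), sigma_multiple = numeric(0))
    census <- site_census(sites, ann)
    ret <- site_retention(sites[sites$condition == "control", , drop = FALSE],
                          sites[sites$condition == "myotube", , drop = FALSE])
    dmat <- delta_profile(norm$control, norm$myotube)
    sites <- nucleosome_change_at_sites(sites, dmat)
    ov <- site_region_overlap(sites, regions)
    list(sites = sites, census = census, retention = ret, overlap = ov)
  })

  files <- c(
    delta_profile.tsv = write_tsv(do.call(rbind, lapply(names(deltas),
      function(g) data.frame(group = g, offset = deltas[[g]]$offsets,
                             mean = deltas[[g]]$mean, se = deltas[[g]]$se,
                             p.value = deltas[[g]]$p.value,
                             significant = deltas[[g]]$mask))),
      file.path(cfg$out_dir, "delta_profile.tsv")),
    regions.tsv = write_tsv(regions, file.path(cfg$out_dir, "regions.tsv")),
    promoter_summary.tsv = write_tsv(summaries,
      file.path(cfg$out_dir, "promoter_summary.tsv")),
    anova.tsv = write_tsv(anova_tab, file.path(cfg$out_dir, "anova.tsv")),
    fits.tsv = write_tsv(fits, file.path(cfg$out_dir, "fits.tsv")))
  if (!is.null(correlations))
    files["correlations.tsv"] <- write_tsv(correlation_table(correlations),
      file.path(cfg$out_dir, "correlations.tsv"))

  # group-mean difference profile of the reference group, and its
  # best-fit overlay curve, as bedgraphs on an arbitrary re-annotated
  # chromosome (position = offset + 3000)
  rel_bedgraph <- function(v, path) {
    brk <- c(TRUE, diff(v) != 0)
    bg <- data.frame(chrom = "chrRel", start = which(brk) - 1L,
                     end = c(which(brk)[-1] - 1L, length(v)), value = v[brk])
    write_bedgraph(coverage_track(bg), path)
  }
  dref <- deltas[[cfg$reference_group]]
  files["delta_mean.bedgraph"] <- rel_bedgraph(
    dref$mean, file.path(cfg$out_dir, "delta_mean.bedgraph"))
  files["best_fit.bedgraph"] <- rel_bedgraph(
    fitted(fit_constrained_spline(dref$offsets, dref$mean)),
    file.path(cfg$out_dir, "best_fit.bedgraph"))

  if (!is.null(chip_res)) {
    files["sites.tsv"] <- write_tsv(chip_res$overlap$sites,
                                    file.path(cfg$out_dir, "sites.tsv"))
    if (nrow(chip_res$sites))
      files["sites.bed"] <- write_sites_bed(
        chip_res$sites, ann, file.path(cfg$out_dir, "sites.bed"))
    files["census.tsv"] <- write_tsv(chip_res$census,
                                     file.path(cfg$out_dir, "census.tsv"))
    files["site_overlap.tsv"] <- write_tsv(chip_res$overlap$histogram,
      file.path(cfg$out_dir, "site_overlap.tsv"))
  }

  manifest <- list(
    package = "mnasequant",
    version = as.character(utils::packageVersion("mnasequant")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("spec", "out_dir", "input_dir"))],
    outputs = as.list(tools::md5sum(unlist(files))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(dataset = ds, profiles = norm, deltas = deltas,
                 regions = regions, fits = fits,
                 correlations = correlations, summaries = summaries,
                 anova = anova_tab, chip = chip_res, manifest = manifest,
                 files = files))
}
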