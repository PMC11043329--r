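# The generator is first-class code: these tests pin its determinism,
# its distributional guarantees, and recovery of its planted ground truth
# by the analysis pipeline.

frag_profile <- function(spec, gene, cond, group = "skeletal",
                         strand = "+") {
  sim <- simulate_promoter_fragments(spec, gene, cond, group,
                                     strand = strand)
  promoter_profile(center_coverage(size_filter(sim$fragments)),
                   paste0("chr_", gene), spec$pad, strand)
}

test_that("the generator is deterministic and honours depth", {
  spec <- small_spec(seed = 7)
  a <- simulate_promoter_fragments(spec, "Neb", "control")
  b <- simulate_promoter_fragments(spec, "Neb", "control")
  expect_identical(a, b)
  # different genes and conditions draw different streams
  c1 <- simulate_promoter_fragments(spec, "Ttn", "control")
  expect_false(identical(a$fragments, c1$fragments))
  z <- synthetic_spec(n_genes = c(skeletal = 1L), depth = 0L, seed = 1)
  expect_equal(nrow(simulate_promoter_fragments(z, "Neb",
                                                "control")$fragments), 0)
})

test_that("conditions share one architecture per gene (paired design)", {
  spec <- small_spec(seed = 7)
  tc <- simulate_promoter_fragments(spec, "Neb", "control")$truth$centers
  tm <- simulate_promoter_fragments(spec, "Neb", "myotube")$truth$centers
  expect_identical(tc, tm)
})

test_that("the planted array has ~21 centers and is recovered by counting", {
  spec <- synthetic_spec(n_genes = c(skeletal = 1L), depth = 60000L,
                         seed = 11)
  sim <- simulate_promoter_fragments(spec, "Neb", "control")
  expect_equal(length(sim$truth$centers), 21)
  p <- promoter_profile(center_coverage(size_filter(sim$fragments)),
                        "chr_Neb", spec$pad, "+")
  expect_equal(count_nucleosomes(p), 21)
})

test_that("fragment lengths reproduce the mono/di mixture", {
  spec <- synthetic_spec(n_genes = c(skeletal = 1L), depth = 20000L,
                         seed = 13)
  sim <- simulate_promoter_fragments(spec, "Neb", "control")
  h <- fragment_size_histogram(sim$fragments)
  lens <- rep(h$length, h$count)
  expect_equal(length(lens), 20000)
  # chi-square goodness of fit against the generating mixture on coarse bins
  edges <- c(-Inf, seq(130, 220, by = 10), 280, seq(300, 360, by = 20), Inf)
  # +0.5 continuity correction: emitted lengths are rounded to integers
  pm <- diff(pnorm(edges + 0.5, 165, 10))
  pd <- diff(pnorm(edges + 0.5, 330, 20))
  probs <- 0.95 * pm + 0.05 * pd
  obs <- table(cut(lens, edges))
  keep <- probs > 1e-6
  gof <- suppressWarnings(
    chisq.test(as.integer(obs)[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(gof$p.value, 0.01)
  # bimodality: both planted modes are populated
  expect_gt(sum(lens > 140 & lens < 190), 0.85 * length(lens))
  expect_gt(sum(lens > 290 & lens < 370), 0.02 * length(lens))
})

test_that("strand handling is symmetric: minus-strand genes give the same
           TSS-frame architecture", {
  spec <- synthetic_spec(n_genes = c(skeletal = 1L), depth = 50000L,
                         seed = 19)
  pp <- frag_profile(spec, "Neb", "control", strand = "+")
  pm <- frag_profile(spec, "Neb", "control", strand = "-")
  # same intensity landscape sampled through mirrored coordinates:
  # peak positions agree within a few bp
  expect_gt(cor(pp, pm), 0.95)
})

test_that("null profiles have no condition effect and calibrate the test", {
  ng <- simulate_null_groups(n_genes = 12, seed = 101)
  expect_equal(rowSums(ng$control), rep(1, 12), ignore_attr = TRUE)
  d <- per_bp_paired_test(ng$control, ng$myotube)
  expect_lt(abs(mean(d$mean)), 1e-6)
  # rejection near alpha (single replicate, loose band)
  expect_gt(mean(d$mask), 0.03)
  expect_lt(mean(d$mask), 0.07)
  # halving the noise halves the per-offset standard error
  lo <- simulate_null_groups(n_genes = 12, noise_sd = 0.05, seed = 101)
  dlo <- per_bp_paired_test(lo$control, lo$myotube)
  expect_equal(mean(dlo$se) / mean(d$se), 0.5, tolerance = 0.05)
})

test_that("ChIP with no enrichment rarely yields validated sites", {
  spec <- synthetic_spec(n_genes = c(skeletal = 2L), chip_depth = 3000L,
                         seed = 23)
  hits <- 0
  for (g in c("gA", "gB", "gC", "gD")) {
    prof <- function(fr)
      normalize_profile(promoter_profile(center_coverage(size_filter(fr)),
                                         paste0("chr_", g), spec$pad, "+"))
    calls <- lapply(1:2, function(r) {
      cs <- simulate_chip(spec, g, "control", replicate = r)
      cbind(gene_id = g,
            call_4sigma(binding_value(prof(cs$ip), prof(cs$input))))
    })
    hits <- hits + nrow(validate_sites(calls[[1]], calls[[2]]))
  }
  expect_lte(hits, 2)
})

test_that("planted repositioning is recovered with correct classification", {
  pert <- list(
    list(region = c(-2100L, -2000L), type = "buildup", factor = 2.5,
         group = "skeletal"),
    list(region = c(-650L, -525L), type = "shift", delta = 130L,
         group = "skeletal"),
    list(region = c(-1560L, -1460L), type = "loss", factor = 0.1,
         group = "skeletal"))
  n_seeds <- 15
  ok_build <- ok_shift <- ok_loss <- 0
  bound_err <- c()
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(n_genes = c(skeletal = 12L),
                           perturbations = pert, seed = 3000 + s)
    ctrl <- t(vapply(default_gene_groups()$skeletal, function(g)
      frag_profile(spec, g, "control"), numeric(4000)))
    myo <- t(vapply(default_gene_groups()$skeletal, function(g)
      frag_profile(spec, g, "myotube"), numeric(4000)))
    d <- per_bp_paired_test(normalize_profile(ctrl),
                            normalize_profile(myo), p_adjust = "BH")
    r <- classify_regions(call_regions(d))
    hit <- function(cls, lo, hi)
      r[r$classification == cls & r$start_offset <= hi &
          r$end_offset >= lo, , drop = FALSE]
    hb <- hit("buildup", -2100, -2000)
    if (nrow(hb)) {
      ok_build <- ok_build + 1
      bound_err <- c(bound_err, abs(hb$start_offset[1] + 2100))
    }
    hl <- hit("loss", -1560, -1460)
    if (nrow(hl)) {
      ok_loss <- ok_loss + 1
      bound_err <- c(bound_err, abs(hl$start_offset[1] + 1560),
                     abs(hl$end_offset[1] + 1460))
    }
    hs <- hit("downstream_shift", -650, -525)   # source lobe
    if (nrow(hs)) ok_shift <- ok_shift + 1
  }
  expect_equal(ok_build, n_seeds)
  expect_equal(ok_loss, n_seeds)
  expect_equal(ok_shift, n_seeds)
  # boundaries of uniformly scaled regions land within the merge gap
  expect_lte(stats::quantile(bound_err, 0.9), 25)
})
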