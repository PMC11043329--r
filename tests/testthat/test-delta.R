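test_that("sum normalization divides by the promoter total", {
  p <- c(1, 2, 3, 4, numeric(3996))
  np <- normalize_profile(p)
  expect_equal(np[1:4], c(0.1, 0.2, 0.3, 0.4))
  expect_equal(sum(np), 1)
  # idempotence
  expect_equal(normalize_profile(np), np, ignore_attr = TRUE)
  # any positive profile sums to 1
  q <- normalize_profile(runif(4000))
  expect_equal(sum(q), 1, tolerance = 1e-12)
  expect_warning(z <- normalize_profile(numeric(4000)), "zero total")
  expect_true(attr(z, "degenerate"))
})

test_that("difference profiles conserve mass and require normalized input", {
  a <- normalize_profile(runif(4000))
  expect_equal(delta_profile(a, a), numeric(4000), ignore_attr = TRUE)
  b <- normalize_profile(runif(4000))
  d <- delta_profile(a, b)
  expect_lt(abs(sum(d)), 1e-9)
  # moving mass: negative lobe at source, positive at sink
  shifted <- a
  shifted[1500] <- shifted[1500] - 0.01
  shifted[1700] <- shifted[1700] + 0.01
  d2 <- delta_profile(a, shifted)
  expect_lt(d2[1500], 0); expect_gt(d2[1700], 0)
  expect_lt(abs(sum(d2)), 1e-9)
  expect_error(delta_profile(runif(4000), b), "normalized")
})

test_that("per-bp paired t matches the closed form on a hand fixture", {
  px <- planted_pair(c(0.01, 0.02, 0.03), at = 2000)
  res <- per_bp_paired_test(px$ctrl, px$myo)
  d <- c(0.01, 0.02, 0.03)
  t_exp <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$statistic[2000], t_exp)
  expect_equal(res$p.value[2000], 2 * pt(-abs(t_exp), df = 2))
  expect_equal(res$n, 3)
})

test_that("per-bp paired t agrees with stats::t.test at random offsets", {
  withr::local_seed(123)
  n <- 6
  ctrl <- normalize_profile(matrix(runif(n * 4000, 0.5, 2), n, 4000))
  myo <- normalize_profile(matrix(runif(n * 4000, 0.5, 2), n, 4000))
  rownames(ctrl) <- rownames(myo) <- sprintf("g%d", 1:n)
  res <- per_bp_paired_test(ctrl, myo)
  for (k in sample(4000, 25)) {
    tt <- t.test(myo[, k], ctrl[, k], paired = TRUE)
    expect_equal(res$statistic[k], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p.value[k], tt$p.value, tolerance = 1e-12)
    expect_equal(res$se[k], unname(tt$stderr), tolerance = 1e-12)
  }
})

test_that("zero-variance offsets follow the documented rules", {
  a <- normalize_profile(matrix(rep(runif(4000, 0.5, 2), each = 3), 3,
                                4000, byrow = FALSE))
  # identical conditions: all diffs exactly 0 -> p = 1 everywhere
  res <- per_bp_paired_test(a, a)
  expect_true(all(res$p.value == 1))
  expect_false(any(res$mask))
  # identical non-zero diffs -> degenerate, masked, p NA not 0
  px <- planted_pair(c(0.01, 0.01, 0.01), at = 1000)
  res2 <- per_bp_paired_test(px$ctrl, px$myo)
  expect_true(res2$degenerate[1000])
  expect_true(res2$mask[1000])
  expect_true(is.na(res2$p.value[1000]))
  # fewer than two genes is an error
  expect_error(per_bp_paired_test(px$ctrl[1, , drop = FALSE],
                                  px$myo[1, , drop = FALSE]), "at least 2")
})

test_that("region calling matches the naive scanner on random masks", {
  withr::local_seed(99)
  offs <- promoter_offsets()
  for (case in 1:200) {
    mask <- runif(4000) < 0.04
    mu <- rnorm(4000, 0, 1)
    d <- list(mask = mask, mean = mu, offsets = offs)
    got <- call_regions(d)
    want <- oracle_scan_regions(mask, mu, offs)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_offset, want$start_offset)
      expect_equal(got$end_offset, want$end_offset)
      expect_equal(got$direction, want$direction)
      expect_identical(got$label, LETTERS[seq_len(nrow(got))])
    }
  }
})

test_that("a narrow 16-bp loss region survives the default parameters", {
  offs <- promoter_offsets()
  mask <- offs >= 5 & offs <= 20
  mu <- ifelse(mask, -1, 0)
  got <- call_regions(list(mask = mask, mean = mu, offsets = offs))
  expect_equal(nrow(got), 1)
  expect_equal(got$start_offset, 5)
  expect_equal(got$end_offset, 20)
  expect_equal(got$width, 16)
  expect_equal(got$direction, "loss")
  # empty mask -> no regions
  none <- call_regions(list(mask = rep(FALSE, 4000), mean = mu,
                            offsets = offs))
  expect_equal(nrow(none), 0)
})

test_that("region classification pairs lobes into shifts", {
  reg <- data.frame(label = c("A", "B"),
                    start_offset = c(-650, -500), end_offset = c(-550, -400),
                    width = c(101, 101), direction = c("loss", "gain"),
                    mean_delta = c(-1, 1))
  cl <- classify_regions(reg)
  expect_equal(cl$classification, rep("downstream_shift", 2))
  expect_equal(cl$unit, c(1, 1))

  reg$direction <- c("gain", "loss")
  cl <- classify_regions(reg)
  expect_equal(cl$classification, rep("upstream_shift", 2))

  iso <- data.frame(label = "A", start_offset = -2100, end_offset = -2000,
                    width = 101, direction = "gain", mean_delta = 1)
  expect_equal(classify_regions(iso)$classification, "buildup")
  iso$direction <- "loss"
  expect_equal(classify_regions(iso)$classification, "loss")

  # lobes further apart than the pairing distance stay isolated
  far <- data.frame(label = c("A", "B"),
                    start_offset = c(-2000, -1000), end_offset = c(-1900, -900),
                    width = 101, direction = c("loss", "gain"),
                    mean_delta = c(-1, 1))
  expect_equal(classify_regions(far)$classification, c("loss", "buildup"))

  # an intervening same-direction region does not block pairing
  trio <- data.frame(label = c("A", "B", "C"),
                     start_offset = c(-650, -540, -480),
                     end_offset = c(-550, -510, -380),
                     width = c(101, 31, 101),
                     direction = c("loss", "loss", "gain"),
                     mean_delta = c(-1, -0.5, 1))
  cl <- classify_regions(trio)
  expect_equal(cl$classification[1], "downstream_shift")
  expect_equal(cl$classification[3], "downstream_shift")
  expect_equal(cl$classification[2], "loss")
  expect_equal(cl$unit[c(1, 3)], c(1, 1))
})

test_that("nucleosome counting recovers planted peaks", {
  x <- seq(-3000, 999)
  centers <- seq(-2900, 900, by = 200)   # 19 well-separated peaks
  p <- rowSums(vapply(centers, function(c0) exp(-(x - c0)^2 / (2 * 30^2)),
                      numeric(4000)))
  expect_equal(count_nucleosomes(p), length(centers))
  single <- exp(-(x + 1000)^2 / (2 * 30^2))
  expect_equal(count_nucleosomes(single), 1)
  expect_equal(count_nucleosomes(numeric(4000)), 0)
})

test_that("spacing and summary arithmetic", {
  expect_equal(avg_spacing(20), 200)
  expect_true(is.na(avg_spacing(0)))
  expect_equal(read_sum(c(1, 2, 3)), 6)
  x <- seq(-3000, 999)
  peaks <- rowSums(vapply(seq(-2900, 900, by = 200), function(c0)
    exp(-(x - c0)^2 / (2 * 30^2)), numeric(4000)))
  m <- rbind(a = peaks, b = peaks)
  profs <- list(control = m, myotube = m * 2)
  s <- promoter_summary(profs)
  expect_equal(nrow(s), 4)
  expect_equal(s$read_sum[s$condition == "myotube"],
               unname(rowSums(m * 2)))
  d <- delta_summary(s)
  expect_equal(d$delta_read_sum, unname(rowSums(m)))
  # identical conditions give zero deltas
  d0 <- delta_summary(promoter_summary(list(control = m, myotube = m)))
  expect_equal(d0$delta_read_sum, c(0, 0))
  expect_equal(d0$delta_spacing, c(0, 0))
})

test_that("group ANOVA matches the textbook decomposition", {
  vals <- c(2, 3, 4, 6, 7, 8, 1, 2, 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  a <- group_anova(vals, grp)
  # hand-computed between/within mean squares
  gm <- mean(vals)
  mb <- vapply(split(vals, grp), mean, numeric(1))
  ssb <- sum(3 * (mb - gm)^2)
  ssw <- sum((vals - rep(mb, each = 3))^2)
  f_exp <- (ssb / 2) / (ssw / 6)
  expect_equal(a$F, f_exp)
  expect_equal(a$p.value, pf(f_exp, 2, 6, lower.tail = FALSE))
  expect_false(a$degenerate)
  expect_true(all(a$pairwise <= 1, na.rm = TRUE))
  # identical values: degenerate flagged
  dg <- suppressWarnings(group_anova(rep(5, 9), grp))
  expect_true(dg$degenerate)
  expect_error(group_anova(vals, rep("a", 9)), "2 groups")
})

test_that("null group ANOVA is calibrated in expectation", {
  withr::local_seed(5)
  fs <- replicate(200, {
    v <- rnorm(30)
    group_anova(v, rep(c("a", "b", "c"), each = 10))$p.value
  })
  # p-values roughly uniform under the null
  expect_gt(ks.test(fs, "punif")$p.value, 0.01)
})
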