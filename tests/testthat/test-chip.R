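test_that("binding values subtract input from IP and antisymmetrize", {
  ip <- normalize_profile(runif(4000, 0.5, 2))
  input <- normalize_profile(runif(4000, 0.5, 2))
  expect_equal(binding_value(ip, ip), numeric(4000), ignore_attr = TRUE)
  bv <- binding_value(ip, input)
  expect_equal(binding_value(input, ip), -bv, ignore_attr = TRUE)
  expect_lt(abs(sum(bv)), 1e-9)
  expect_error(binding_value(runif(4000), input), "normalized")
})

test_that("binding values are invariant to sequencing-depth rescaling", {
  withr::local_seed(3)
  ip_raw <- runif(4000, 0.5, 2)
  input_raw <- runif(4000, 0.5, 2)
  bv1 <- binding_value(normalize_profile(ip_raw),
                       normalize_profile(input_raw))
  bv2 <- binding_value(normalize_profile(ip_raw * 17),
                       normalize_profile(input_raw * 0.3))
  expect_equal(bv1, bv2, ignore_attr = TRUE)
})

test_that("the 4-sigma rule matches direct arithmetic on a unit spike", {
  b <- c(numeric(3999), 1)
  s <- call_4sigma(b)
  expect_equal(nrow(s), 1)
  expect_equal(s$start_offset, 999)
  expect_equal(s$end_offset, 999)
  mu <- 1 / 4000
  sdv <- sqrt((sum((b - mu)^2)) / 3999)
  expect_equal(s$sigma_multiple, (1 - mu) / sdv)
  expect_equal(round(s$sigma_multiple, 1), 63.2)
})

test_that("4-sigma calls are affine invariant and handle flat input", {
  withr::local_seed(29)
  b <- rnorm(4000)
  b[1200:1215] <- b[1200:1215] + 8
  s0 <- call_4sigma(b)
  expect_gt(nrow(s0), 0)
  for (tr in list(b + 5, b * 3.7, b * 2 + 100)) {
    s1 <- call_4sigma(tr)
    expect_equal(s1$start_offset, s0$start_offset)
    expect_equal(s1$end_offset, s0$end_offset)
    expect_equal(s1$sigma_multiple, s0$sigma_multiple, tolerance = 1e-9)
  }
  expect_warning(s <- call_4sigma(rep(2, 4000)), "zero variance")
  expect_equal(nrow(s), 0)
})

test_that("sites extend to the 1-sigma envelope around each seed", {
  b <- numeric(4000)
  b[2000:2060] <- 2          # above 1 sigma, below 4
  b[2020:2030] <- 20         # seed
  s <- call_4sigma(b)
  expect_equal(nrow(s), 1)
  off <- promoter_offsets()
  expect_equal(s$start_offset, off[2000])
  expect_equal(s$end_offset, off[2060])
  expect_equal(s$peak_value, 20)
  # seed-only mode confines the site to the exceedances
  s2 <- call_4sigma(b, extend_sigma = NULL)
  expect_equal(s2$start_offset, off[2020])
  expect_equal(s2$end_offset, off[2030])
  # a 1-sigma run without any seed is not a site
  b2 <- numeric(4000); b2[100:160] <- 0.5; b2[3000] <- 20
  mu2 <- mean(b2); sd2 <- sd(b2)
  expect_true(all(b2[100:160] > mu2 + sd2) && all(b2[100:160] < mu2 + 4 * sd2))
  s3 <- call_4sigma(b2)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$start_offset, off[3000])
})

test_that("gaussian 4-sigma confidence exceeds the conventional quote", {
  expect_equal(sigma_confidence(4), 100 * pnorm(4))
  expect_gt(sigma_confidence(4), 99.8)
  expect_equal(round(sigma_confidence(4), 3), 99.997)
})

test_that("site census counts genes once regardless of multiplicity", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chrom = "x", tss = 5000, strand = "+",
                    group = c("skeletal", "skeletal", "nonmuscle",
                              "nonmuscle"))
  sites <- data.frame(gene_id = c("a", "a", "a", "c"),
                      condition = c("control", "control", "control",
                                    "myotube"),
                      start_offset = c(-100, -50, 0, -2500),
                      end_offset = c(-90, -40, 10, -2400))
  cen <- site_census(sites, ann)
  expect_equal(cen$genes_with_site[cen$group == "skeletal" &
                                     cen$condition == "control"], 1)
  expect_equal(cen$genes_with_site[cen$group == "nonmuscle" &
                                     cen$condition == "myotube"], 1)
  expect_equal(cen$genes_with_site[cen$group == "nonmuscle" &
                                     cen$condition == "control"], 0)
  # empty site list gives an all-zero census
  cen0 <- site_census(sites[0, ], ann)
  expect_true(all(cen0$genes_with_site == 0))
})

test_that("site retention is interval intersection per gene", {
  a <- data.frame(gene_id = c("g1", "g2"), start_offset = c(-2600, -500),
                  end_offset = c(-2450, -400))
  # identical lists: all retained
  r <- site_retention(a, a)
  expect_equal(unname(r$summary["retained"]), 2)
  expect_equal(unname(r$summary["gained"]), 0)
  # disjoint: none retained
  b <- data.frame(gene_id = c("g1", "g2"), start_offset = c(-100, 600),
                  end_offset = c(-50, 700))
  r2 <- site_retention(a, b)
  expect_equal(unname(r2$summary["retained"]), 0)
  expect_equal(unname(r2$summary["gained"]), 2)
  # partial overlap and gene identity both matter
  c1 <- data.frame(gene_id = c("g1", "g1"), start_offset = c(-2500, -100),
                   end_offset = c(-2400, -80))
  c2 <- data.frame(gene_id = c("g1", "g2"), start_offset = c(-2450, -100),
                   end_offset = c(-2300, -80))
  r3 <- site_retention(c1, c2)
  expect_equal(r3$control$retained, c(TRUE, FALSE))
})

test_that("replicate validation keeps reproduced sites only", {
  r1 <- data.frame(gene_id = c("g1", "g1", "g2"),
                   start_offset = c(-2600, -100, 500),
                   end_offset = c(-2450, -90, 600))
  r2 <- data.frame(gene_id = c("g1", "g2"),
                   start_offset = c(-2500, 900),
                   end_offset = c(-2350, 950))
  v <- validate_sites(r1, r2)
  expect_equal(nrow(v), 1)
  expect_equal(v$start_offset, -2600)
})

test_that("nucleosome change at sites sums the difference profile", {
  dmat <- matrix(0, 2, 4000, dimnames = list(c("g1", "g2"), NULL))
  off <- promoter_offsets()
  dmat["g1", off >= -650 & off <= -601] <- -0.001
  sites <- data.frame(gene_id = c("g1", "g2"),
                      start_offset = c(-650, -650),
                      end_offset = c(-601, -601))
  got <- nucleosome_change_at_sites(sites, dmat)
  expect_equal(got$delta_content, c(-0.05, 0))
})

test_that("site-region overlap reports distances and the TSS histogram", {
  regions <- data.frame(label = "A", start_offset = -2500,
                        end_offset = -2400)
  sites <- data.frame(gene_id = c("g1", "g2", "g3"),
                      start_offset = c(-2600, 800, -2380),
                      end_offset = c(-2450, 850, -2300))
  ov <- site_region_overlap(sites, regions)
  expect_equal(ov$sites$overlaps_region, c(TRUE, FALSE, FALSE))
  expect_equal(ov$sites$nearest_distance[1], 0)
  # downstream site: positive distance from region end
  expect_equal(ov$sites$nearest_distance[2], 800 - (-2400))
  expect_equal(ov$sites$nearest_distance[3], -2380 - (-2400))
  expect_equal(sum(ov$histogram$count), 3)
  # upstream concentration lands in the far-upstream bins
  expect_equal(ov$histogram$count[ov$histogram$bin_start == -3000], 1)
  expect_equal(ov$histogram$count[ov$histogram$bin_start == 500], 1)
})

test_that("sites export to BED6 in genomic coordinates", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = c("c1", "c2"),
                    tss = c(10000L, 20000L), strand = c("+", "-"),
                    group = c("skeletal", "heart"))
  sites <- data.frame(gene_id = c("gp", "gm"), condition = "control",
                      start_offset = c(-2600, -2600),
                      end_offset = c(-2450, -2450),
                      sigma_multiple = c(8.1, 9.2))
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, ann, tmp)
  bed <- read.table(tmp, sep = "\t")
  # plus strand: upstream offsets map below the TSS
  expect_equal(bed$V2[bed$V1 == "c1"], 10000 - 2600)
  expect_equal(bed$V3[bed$V1 == "c1"], 10000 - 2450 + 1)
  # minus strand: upstream offsets map above the TSS
  expect_equal(bed$V2[bed$V1 == "c2"], 20000 + 2450)
  expect_equal(bed$V3[bed$V1 == "c2"], 20000 + 2600 + 1)
  expect_identical(bed$V6, c("+", "-"))
})

test_that("planted ChIP enrichment is recovered as a single boxed site", {
  # near-uniform input makes the planted box edges the detectable truth
  spec <- synthetic_spec(n_genes = c(skeletal = 1L),
                         background_fraction = 0.8,
                         chip_depth = 20000L,
                         chip_boxes = list(list(region = c(-2600L, -2450L),
                                                fold = 8)),
                         seed = 41)
  cs <- simulate_chip(spec, "Neb", "control")
  prof <- function(fr)
    normalize_profile(promoter_profile(center_coverage(size_filter(fr)),
                                       "chr_Neb", spec$pad, "+"))
  bv <- binding_value(prof(cs$ip), prof(cs$input))
  s <- call_4sigma(bv)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$start_offset - (-2600)), 25)
  expect_lt(abs(s$end_offset - (-2450)), 25)
  # identical seed reproduces identical fragments
  cs2 <- simulate_chip(spec, "Neb", "control")
  expect_identical(cs$ip, cs2$ip)
})
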