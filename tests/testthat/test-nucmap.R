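test_that("fragments are classified by the stated length bounds", {
  fr <- data.frame(contig = "c1", start = c(0L, 0L, 0L, 0L),
                   end = c(60L, 150L, 1200L, 100L))
  cls <- classify_fragments(fr)
  expect_identical(cls$class, c("subnucleosomal", "nucleosomal",
                                "nucleosomal"))
  expect_identical(nrow(cls), 3L)  # the 1200 bp fragment is discarded
  expect_identical(cls$class[cls$end == 100L], "nucleosomal")  # boundary

  set.seed(1)
  lens <- sample(20:1200, 500L, TRUE)
  fr2 <- data.frame(contig = "c1", start = 0L, end = lens)
  cls2 <- classify_fragments(fr2)
  expect_identical(sum(cls2$class == "subnucleosomal"), sum(lens < 100))
  expect_identical(sum(cls2$class == "nucleosomal"),
                   sum(lens >= 100 & lens <= 1000))

  expect_error(classify_fragments(data.frame(contig = "c1", start = 5L,
                                             end = 5L)), "length")
})

test_that("midpoint coverage places mass at the fragment center", {
  fr <- data.frame(contig = "c1", start = 100L, end = 250L)
  tr <- midpoint_coverage(fr, c(c1 = 1000L))
  expect_identical(which(tr$c1 > 0), 151:200)  # 0-based [150, 200)
  expect_true(all(tr$c1[151:200] == 1))

  # additivity: shared midpoints stack
  fr2 <- rbind(fr, data.frame(contig = "c1", start = 150L, end = 200L))
  tr2 <- midpoint_coverage(fr2, c(c1 = 1000L))
  expect_true(all(tr2$c1[151:200] == 2))

  # mass conservation: 50 x n for interior fragments
  set.seed(2)
  fr3 <- data.frame(contig = "c1", start = sample(100:800, 200L, TRUE))
  fr3$end <- fr3$start + sample(100:180, 200L, TRUE)
  expect_equal(sum(midpoint_coverage(fr3, c(c1 = 2000L))$c1), 50 * 200)
})

test_that("percentile normalization pins the 90th window percentile at 1", {
  flat <- list(c1 = rep(3.7, 2000))
  norm <- normalize_track(flat)
  expect_equal(norm$c1, rep(1, 2000))

  set.seed(3)
  tr <- list(c1 = rexp(20000, 0.2))
  n1 <- normalize_track(tr)
  wm <- luxseq:::window_mean_coverage(n1$c1, 150L, 50L)$mean
  expect_equal(stats::quantile(wm[wm > 0], 0.9, names = FALSE), 1,
               tolerance = 1e-9)
  # scale invariance and idempotence
  n2 <- normalize_track(list(c1 = tr$c1 * 17))
  expect_equal(n1$c1, n2$c1, tolerance = 1e-12)
  expect_equal(normalize_track(n1)$c1, n1$c1, tolerance = 1e-12)
  expect_error(normalize_track(list(c1 = rep(0, 500))), "all-zero")
})

test_that("kernel smoothing preserves constants and unit mass", {
  flat <- list(c1 = rep(2.5, 1000))
  expect_equal(smooth_track(flat, 30)$c1, rep(2.5, 1000),
               tolerance = 1e-12)
  # unit impulse spreads into a kernel of mass ~1
  imp <- list(c1 = c(rep(0, 500), 1, rep(0, 500)))
  sm <- smooth_track(imp, 30)$c1
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  expect_equal(which.max(sm), 501L)
  # no overshoot beyond the local input range
  set.seed(4)
  v <- runif(3000)
  out <- smooth_track(list(c1 = v), 10)$c1
  expect_true(all(out <= max(v) + 1e-12 & out >= min(v) - 1e-12))
})

test_that("+1 nucleosome location honors maxima and tie rules", {
  v <- rep(0, 2000)
  v[1031] <- 5  # 0-based position 1030 = TSS + 30
  tr <- list(c1 = v)
  gene <- data.frame(gene_id = "g", contig = "c1", strand = "+",
                     start = 1000L, end = 1800L, tss = 1000L)
  expect_identical(locate_plus_one(tr, gene), 1030L)

  # symmetric maxima: nearer the TSS wins
  v2 <- rep(0, 2000); v2[1000 - 60 + 1] <- 3; v2[1000 + 20 + 1] <- 3
  expect_identical(locate_plus_one(list(c1 = v2), gene), 1020L)
  # equidistant maxima: downstream wins (strand-aware)
  v3 <- rep(0, 2000); v3[1000 - 40 + 1] <- 3; v3[1000 + 40 + 1] <- 3
  expect_identical(locate_plus_one(list(c1 = v3), gene), 1040L)
  gm <- transform(gene, strand = "-")
  expect_identical(locate_plus_one(list(c1 = v3), gm), 960L)
  # flat nonzero window: everything ties, the TSS itself wins
  expect_identical(locate_plus_one(list(c1 = rep(1, 2000)), gene), 1000L)
  # zero coverage: NA
  expect_true(is.na(locate_plus_one(list(c1 = rep(0, 2000)), gene)))
})

test_that("metagene profiles average strand-aware anchor slices", {
  set.seed(5)
  v <- runif(4000)
  tr <- list(c1 = v)
  a1 <- data.frame(contig = "c1", position = 2000L, strand = "+")
  prof <- metagene_profile(tr, a1, flank = 100L)
  expect_equal(prof$occupancy, v[(2000 - 100 + 1):(2000 + 100 + 1)])
  # minus-strand anchor mirrors the slice
  a2 <- data.frame(contig = "c1", position = 2000L, strand = "-")
  prof2 <- metagene_profile(tr, a2, flank = 100L)
  expect_equal(prof2$occupancy, rev(prof$occupancy))
  # translation-invariant track gives a flat profile within MC error
  anchors <- data.frame(contig = "c1",
                        position = sample(500:3500, 300L, TRUE),
                        strand = "+")
  pf <- metagene_profile(tr, anchors, flank = 200L)
  expect_true(all(abs(pf$occupancy - 0.5) < 0.1))
  expect_error(metagene_profile(tr, a1[0, ]), "anchors")
})

test_that("occupancy is the area under the curve over 176 bp", {
  flat <- list(c1 = rep(1, 1000))
  expect_equal(nucleosome_occupancy(flat, "c1", 500L), 176)
  expect_equal(nucleosome_occupancy(list(c1 = rep(0, 1000)), "c1", 500L), 0)
  set.seed(6)
  v <- runif(1000)
  got <- nucleosome_occupancy(list(c1 = v), "c1", 300L, 176L)
  expect_equal(got, sum(v[(300 - 88 + 1):(300 + 88)]))
})

test_that("repeat-length estimation recovers planted spacing", {
  # noiseless phased cosine: period 176
  x <- 1 + cos(2 * pi * (0:2000) / 176)
  sp <- estimate_spacing(x, method = "autocorrelation")
  expect_true(abs(sp$repeat_length - 176) <= 2)
  x2 <- 1 + cos(2 * pi * (0:2000) / 200)
  expect_true(abs(estimate_spacing(x2, method = "autocorrelation")$
                    repeat_length - 200) <= 2)
  # white noise is aperiodic
  set.seed(7)
  expect_true(is.na(estimate_spacing(rnorm(2000),
                                     method = "autocorrelation")$
                      repeat_length))
  # dyad route with bootstrap CI
  dy <- seq(0, 176 * 20, by = 176) + sample(-2:2, 21, TRUE)
  est <- estimate_spacing(dy)
  expect_true(abs(est$repeat_length - 176) <= 2)
  expect_identical(length(est$ci), 2L)
})

test_that("site occupancy ratio is calibrated on unstructured tracks", {
  g <- make_genome(1L, 2e5, 0.5, seed = 71)
  genes <- make_annotation(g, 40L, seed = 72)
  sim <- simulate_mnase(g, data.frame(contig = character(0),
                                      anchor = integer(0),
                                      n_nucs = integer(0),
                                      repeat_length = integer(0),
                                      occupancy = numeric(0)),
                        background_rate = 0.2, seed = 73)
  nuc <- classify_fragments(sim$fragments)
  nuc <- nuc[nuc$class == "nucleosomal", ]
  tr <- smooth_track(normalize_track(midpoint_coverage(nuc, g)), 30)
  set.seed(74)
  sites <- data.frame(contig = "ctg1", summit = sample(2000:198000, 150L))
  r <- sapply(1:5, function(s)
    site_occupancy_ratio(tr, sites, genes, seed = s)$ratio)
  expect_true(all(r > 0.9 & r < 1.1))
  expect_identical(site_occupancy_ratio(tr, sites, genes, seed = 9)$ratio,
                   site_occupancy_ratio(tr, sites, genes, seed = 9)$ratio)
  expect_error(site_occupancy_ratio(tr, sites[1:3, ], genes), ">= 10")
})

test_that("footprint profiles detect planted sub-nucleosomal protection", {
  g <- make_genome(1L, 1e5, 0.5, seed = 81)
  fp_pos <- seq(5000L, 95000L, by = 2000L)
  fp <- data.frame(contig = "ctg1", position = fp_pos, width = 60L)
  sim <- simulate_mnase(g, data.frame(contig = character(0),
                                      anchor = integer(0),
                                      n_nucs = integer(0),
                                      repeat_length = integer(0),
                                      occupancy = numeric(0)),
                        footprints = fp, frag_per_footprint = 40,
                        background_rate = 0.05, seed = 82)
  sub <- classify_fragments(sim$fragments)
  sub <- sub[sub$class == "subnucleosomal", ]
  prof <- footprint_profile(sub, g,
                            data.frame(contig = "ctg1", summit = fp_pos),
                            flank = 400L)
  center <- mean(prof$occupancy[abs(prof$offset) <= 30])
  flank <- mean(prof$occupancy[abs(prof$offset) >= 300])
  expect_gt(center, 2 * flank)
  # single site: profile is the local slice over the genome mean
  one <- footprint_profile(sub, g, data.frame(contig = "ctg1",
                                              summit = fp_pos[1]),
                           flank = 100L)
  cov <- fragment_coverage(sub, g)
  slice <- cov$ctg1[(fp_pos[1] - 100 + 1):(fp_pos[1] + 100 + 1)]
  expect_equal(one$occupancy, slice / mean(cov$ctg1))
  expect_error(footprint_profile(sub[0, ], g,
                                 data.frame(contig = "ctg1",
                                            summit = 1000L)), "fragments")
})
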