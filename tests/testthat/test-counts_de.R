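test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(5L, 9L, 5L, 9L), 2, 2,
              dimnames = list(c("g1", "g2"), c("wt_DD", "wt_30")))
  expect_equal(unname(estimate_size_factors(count_table(m))), c(1, 1))

  m2 <- matrix(c(2L, 8L, 8L, 32L), 2, 2,
               dimnames = list(c("g1", "g2"), c("wt_DD", "wt_30")))
  expect_equal(unname(estimate_size_factors(count_table(m2))), c(0.5, 2))

  # scaling one sample's counts by c multiplies its factor by c relative
  # to the others (the common geometric-mean shift cancels in ratios)
  set.seed(1)
  base <- matrix(rpois(300, 50) + 1L, 100, 3,
                 dimnames = list(sprintf("g%d", 1:100),
                                 c("a_DD", "b_DD", "c_DD")))
  sf1 <- estimate_size_factors(count_table(base))
  scaled <- base; scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- estimate_size_factors(count_table(scaled))
  expect_equal(sf2[["b_DD"]] / sf2[["a_DD"]],
               3 * sf1[["b_DD"]] / sf1[["a_DD"]], tolerance = 1e-12)

  zeroy <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                  dimnames = list(c("g1", "g2"), c("a_DD", "b_DD")))
  expect_error(estimate_size_factors(count_table(zeroy)),
               "pseudo-reference")
})

test_that("low-expression filter removes the stated lower quantile", {
  m <- matrix(as.integer(outer(c(1, 2, 5, 8, 11, 14, 17, 20, 23, 26),
                               c(1, 1))), 10, 2,
              dimnames = list(sprintf("g%02d", 1:10), c("a_DD", "b_DD")))
  tab <- count_table(m)
  kept <- filter_low_expression(tab, 0.20)
  expect_identical(nrow(kept$counts), 8L)
  expect_identical(nrow(filter_low_expression(tab, 0)$counts), 10L)

  # oracle: retained set equals sort-and-cut on normalized means
  set.seed(2)
  mm <- matrix(rpois(600, rlnorm(200, 3, 1)) + 1L, 200, 3,
               dimnames = list(sprintf("g%03d", 1:200),
                               c("a_DD", "b_DD", "c_DD")))
  tab2 <- count_table(mm)
  sf <- estimate_size_factors(tab2)
  means <- rowMeans(sweep(mm, 2, sf, "/"))
  thr <- sort(means)[ceiling(0.2 * 200)]  # type-7 quantile at distinct n
  keep_oracle <- names(means)[means >= stats::quantile(means, 0.2)]
  got <- rownames(filter_low_expression(tab2, 0.2, sf)$counts)
  expect_setequal(got, keep_oracle)
})

test_that("mean-variance fit recovers planted dispersion trends", {
  # planted v(mu) = mu + 0.1 mu^2
  m <- count_model(frac_induced = 0, phi0 = 0.1, phi1 = 0)
  sim <- simulate_counts(m, 10000L, c("a_DD", "a_30", "a_60", "a_120"),
                         seed = 51)
  sf <- estimate_size_factors(sim$table)
  fit <- fit_mean_variance(sim$table, sf)
  qs <- stats::quantile(sim$truth$mu, c(0.1, 0.9))
  mus <- exp(seq(log(qs[1]), log(qs[2]), length.out = 25))
  ratio <- predict_variance(fit, mus) / (mus + 0.1 * mus^2)
  expect_true(all(ratio >= 0.8 & ratio <= 1.25))

  # Poisson counts: fit collapses to the floor sigma^2 = mu
  mp <- count_model(frac_induced = 0, phi0 = 0, phi1 = 0)
  simp <- simulate_counts(mp, 10000L, c("a_DD", "a_30", "a_60", "a_120"),
                          seed = 52)
  fitp <- fit_mean_variance(simp$table, estimate_size_factors(simp$table))
  rp <- predict_variance(fitp, mus) / mus
  expect_true(all(rp >= 1 & rp <= 1.15))

  # enforced properties: floor and monotonicity
  grid <- exp(seq(log(0.5), log(5000), length.out = 200))
  v <- predict_variance(fit, grid)
  expect_true(all(v >= grid))
  expect_true(all(diff(v) >= -1e-9))

  small <- count_table(matrix(1L, 10, 2,
                              dimnames = list(sprintf("g%d", 1:10),
                                              c("a_DD", "b_DD"))))
  expect_error(fit_mean_variance(small, c(a_DD = 1, b_DD = 1)),
               "fewer than 50")
})

test_that("exact test handles degenerate and symmetric inputs", {
  fit <- const_phi_fit(0.1)
  expect_equal(exact_test(0, 0, 1, 1, fit)$p, 1)
  expect_equal(exact_test(10, 10, 1, 1, fit)$p, 1)
  # symmetry: swapping treatment and control leaves p unchanged
  for (case in list(c(18, 2, 1, 1), c(30, 7, 2, 0.5), c(0, 9, 1.3, 0.8))) {
    p1 <- exact_test(case[1], case[2], case[3], case[4], fit)$p
    p2 <- exact_test(case[2], case[1], case[4], case[3], fit)$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("exact test equals brute-force enumeration", {
  # the spec's worked case: k=18 vs 2, mu0=10, sigma^2 = 15 (phi = 0.05)
  p <- exact_test(18, 2, 1, 1, const_phi_fit(0.05))$p
  expect_equal(p, oracle_exact_p(18, 2, 1, 1, 0.05), tolerance = 1e-12)

  set.seed(61)
  for (i in 1:40) {
    s_t <- runif(1, 0.5, 2); s_c <- runif(1, 0.5, 2)
    phi <- runif(1, 0, 0.3)
    n <- sample(1:400, 1)
    k_t <- sample(0:n, 1); k_c <- n - k_t
    p_impl <- exact_test(k_t, k_c, s_t, s_c, const_phi_fit(phi))$p
    p_orc <- oracle_exact_p(k_t, k_c, s_t, s_c, phi)
    expect_equal(p_impl, p_orc, tolerance = 1e-12)
  }
})

test_that("exact test p is monotone in the deviation from expectation", {
  fit <- const_phi_fit(0.08)
  n <- 60
  ps <- sapply(30:60, function(k) exact_test(k, n - k, 1, 1, fit)$p)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("light-induction calling applies both gates and classifies", {
  res <- list(
    "30" = data.frame(gene_id = c("a", "b", "c", "d"),
                      fold = c(8, 1.9, 1.2, 1.0),
                      p = c(1e-6, 1e-9, 0.5, 0.9)),
    "60" = data.frame(gene_id = c("a", "b", "c", "d"),
                      fold = c(4, 1.5, 3.0, 1.0),
                      p = c(1e-4, 0.2, 0.01, 0.9)),
    "120" = data.frame(gene_id = c("a", "b", "c", "d"),
                       fold = c(2, 1.2, 6.0, 1.0),
                       p = c(0.03, 0.6, 1e-5, 0.9)))
  calls <- call_light_induced(res, alpha = 0.05, min_fold = 2)
  expect_identical(calls$called, c(TRUE, FALSE, TRUE, FALSE))
  # a: >= 2-fold at 30 min -> immediate-early; c: rising profile -> late
  expect_identical(calls$class[1], "immediate-early")
  expect_identical(calls$class[3], "late")
  expect_true(is.na(calls$class[2]))  # fold 1.9 never called despite p
  expect_error(call_light_induced(list(df = res[["30"]])), "timepoint")
})

test_that("planted induced genes are recovered and classified", {
  m <- count_model(frac_induced = 0.1)
  sim <- simulate_counts(m, 3000L, c("wt_DD", "wt_30", "wt_60", "wt_120"),
                         seed = 71)
  out <- light_induction_analysis(sim$table)
  tr <- sim$truth[match(out$calls$gene_id, sim$truth$gene_id), ]
  # reduced scale (3000 genes): looser bound than the full-scale check
  sens <- sum(out$calls$called[tr$class != "null"]) /
    sum(sim$truth$class != "null")
  expect_gt(sens, 0.7)
  expect_lt(mean(out$calls$called[tr$class == "null"]), 0.05)
  # early-archetype genes (8x at 30 min) land in immediate-early
  ie <- out$calls$class[tr$class == "early" & out$calls$called]
  expect_gt(mean(ie == "immediate-early"), 0.9)
})

test_that("genotype comparison flags planted dependence, not nulls", {
  m <- count_model(frac_induced = 0.15, dep_frac = 1,
                   dep_genotype = "ko", dep_mult = 0.25)
  # one joint world so both genotypes share the planted truth
  sim <- simulate_counts(m, 2000L,
                         c("wt_DD", "wt_30", "wt_60", "wt_120",
                           "ko_DD", "ko_30", "ko_60", "ko_120"),
                         seed = 81)
  tab_wt <- count_table(sim$table$counts[, 1:4])
  tab_ko <- count_table(sim$table$counts[, 5:8])
  induced <- sim$truth$gene_id[sim$truth$class != "null" &
                                 sim$truth$fold_30 >= 4]
  cmp <- compare_genotypes(tab_wt, tab_ko, induced, "down")
  expect_gt(mean(cmp$flagged), 0.7)

  # an identical table under other labels: equal counts give p = 1
  ko_copy <- tab_wt$counts
  colnames(ko_copy) <- sub("^wt", "ko", colnames(ko_copy))
  cmp0 <- compare_genotypes(tab_wt, count_table(ko_copy),
                            sim$truth$gene_id[1:500], "down")
  expect_lt(mean(cmp0$flagged), 0.06)

  expect_error(compare_genotypes(tab_wt, tab_ko, "no_such", "down"),
               "absent")
  bad <- count_table(tab_ko$counts[, 1:2])
  expect_error(compare_genotypes(tab_wt, bad, induced[1], "down"),
               "timepoints")
})
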