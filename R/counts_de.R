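# Replicate-free differential expression for count tables: median-of-ratios
# size factors, low-expression filtering, a blind mean-variance fit across
# samples, and a conditional negative-binomial exact test. Raw p-values are
# used throughout (p < 0.05 plus a 2-fold gate); no multiple-testing
# correction is applied.

#' Median-of-ratios size factors
#'
#' For every gene with strictly positive counts in all samples, the
#' per-sample ratio of its count to its across-sample geometric mean is
#' formed; the size factor of a sample is the median of these ratios.
#'
#' @param table A [count_table()].
#' @return Named numeric vector of positive per-sample scale factors.
#' @export
estimate_size_factors <- function(table) {
  stopifnot(inherits(table, "count_table"))
  k <- table$counts
  if (ncol(k) < 2L) stop("need >= 2 samples to estimate size factors")
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos))
    stop("no gene has positive counts in every sample; ",
         "size factors undefined (consider a pseudo-reference)")
  logk <- log(k[pos, , drop = FALSE])
  loggeo <- rowMeans(logk)
  sf <- apply(exp(sweep(logk, 1, loggeo)), 2, stats::median)
  stats::setNames(sf, colnames(k))
}

#' Remove lowly expressed genes
#'
#' Drops genes whose mean size-factor-normalized count lies below the
#' stated quantile (default: the lower 20 percent of all genes).
#'
#' @param table A [count_table()].
#' @param quantile Quantile cutoff in \[0, 1\] (default 0.20).
#' @param size_factors Optional pre-computed size factors.
#' @return Filtered [count_table()].
#' @export
filter_low_expression <- function(table, quantile = 0.20,
                                  size_factors = NULL) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table$counts) == 0L) stop("empty count table")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(table)
  norm <- sweep(table$counts, 2, size_factors, "/")
  means <- rowMeans(norm)
  thr <- stats::quantile(means, quantile, names = FALSE)
  count_table(table$counts[means >= thr, , drop = FALSE])
}

#' Blind mean-variance fit across samples
#'
#' Treats all samples as pseudo-replicates (the design has none): per-gene
#' mean and variance of normalized counts are computed across samples, and
#' the variance trend is estimated robustly: genes are binned by quantiles
#' of log mean, the per-bin median variance is corrected by the analytic
#' median bias of a scaled chi-square at the known degrees of freedom
#' (sample variances at few samples are strongly skewed, so a raw median
#' underestimates and a raw mean is wrecked by genes with real condition
#' effects), and a local (loess) regression is drawn through the corrected
#' bin medians. The
#' returned mapping mu -> sigma^2(mu) is floored at sigma^2 = mu (the
#' Poisson minimum), made nondecreasing, and extrapolated flat beyond the
#' fitted range. Over-dispersion contributed by real condition effects
#' inflates the fit and makes the downstream test conservative.
#'
#' @param table A [count_table()].
#' @param size_factors Per-sample size factors.
#' @param span Loess span on the log-mean axis (default 0.3).
#' @return An object of class `dispersion_fit`: call it as a function of
#'   mu, or via [predict_variance()].
#' @export
fit_mean_variance <- function(table, size_factors = NULL, span = 0.3) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$counts) < 2L) stop("need >= 2 samples")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(table)
  norm <- sweep(table$counts, 2, size_factors, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  use <- mu > 0 & is.finite(v)
  if (sum(use) < 50L)
    stop("fewer than 50 genes with positive mean; ",
         "mean-variance fit would be unstable")
  lmu <- log(mu[use]); vv <- v[use]
  nu <- ncol(table$counts) - 1L
  bias <- nu / stats::qchisq(0.5, nu)  # median of S^2 is sigma^2 / bias
  nbin <- max(10L, min(60L, floor(sum(use) / 25L)))
  qs <- unique(stats::quantile(lmu, probs = seq(0, 1, length.out = nbin + 1L),
                               names = FALSE))
  bin <- cut(lmu, qs, include.lowest = TRUE)
  bl <- as.numeric(tapply(lmu, bin, stats::median))
  bv <- as.numeric(tapply(vv, bin, stats::median)) * bias
  ok <- is.finite(bl) & is.finite(bv)
  bl <- bl[ok]; bv <- bv[ok]
  fit <- stats::loess(bv ~ bl, span = max(span, 3 / length(bl)), degree = 1,
                      control = stats::loess.control(surface = "direct"))
  grid_l <- seq(min(lmu), max(lmu), length.out = 256L)
  sig2 <- stats::predict(fit, data.frame(bl = grid_l))
  grid_mu <- exp(grid_l)
  sig2 <- cummax(pmax(sig2, grid_mu))  # floor at Poisson, enforce monotone
  interp <- stats::approxfun(grid_l, sig2, rule = 2)
  structure(list(interp = interp, span = span, n = sum(use),
                 mu_range = range(grid_mu)),
            class = "dispersion_fit")
}

#' Evaluate a fitted mean-variance mapping
#'
#' @param fit A `dispersion_fit` from [fit_mean_variance()].
#' @param mu Positive means to evaluate at.
#' @return sigma^2(mu), always >= mu.
#' @export
predict_variance <- function(fit, mu) {
  stopifnot(inherits(fit, "dispersion_fit"), all(mu > 0))
  pmax(fit$interp(log(mu)), mu)
}

#' Conditional NB exact test for two counts without replicates
#'
#' Tests a treatment count against a control count conditional on their
#' sum. The common normalized mean is mu0 = (k_t/s_t + k_c/s_c)/2; the
#' dispersion phi = (sigma^2(mu0) - mu0)/mu0^2 from the mean-variance fit
#' is taken scale-invariant, so each condition has mean mu0 * s and
#' variance mu * (1 + phi * mu). The joint probability f(a, b) of a split
#' (a, b) with a + b = k_t + k_c is the product of the two NB point masses
#' (Poisson when sigma^2 <= mu); the two-sided p-value sums f(a, b) over
#' all splits no more probable than the observed one, normalized by the
#' total over all splits.
#'
#' @param k_t,k_c Observed treatment and control counts (>= 0).
#' @param s_t,s_c Size factors of the two samples.
#' @param fit A `dispersion_fit` (or `NULL` for the Poisson limit).
#' @param pseudo_count Pseudo-count added to both normalized means for the
#'   reported fold change (default 0.5).
#' @return data.frame with `mean_treat`, `mean_control` (normalized),
#'   `fold` (treat/control) and `p` (two-sided, in (0, 1\]).
#' @export
exact_test <- function(k_t, k_c, s_t = 1, s_c = 1, fit = NULL,
                       pseudo_count = 0.5) {
  stopifnot(k_t >= 0, k_c >= 0, s_t > 0, s_c > 0)
  nt <- k_t / s_t; nc <- k_c / s_c
  fold <- (nt + pseudo_count) / (nc + pseudo_count)
  n <- k_t + k_c
  if (n == 0L)
    return(data.frame(mean_treat = 0, mean_control = 0, fold = fold, p = 1))
  mu0 <- (nt + nc) / 2
  mu_t <- mu0 * s_t; mu_c <- mu0 * s_c
  sig2 <- if (is.null(fit)) mu0 else predict_variance(fit, mu0)
  a <- 0:n
  if (sig2 <= mu0 * (1 + 1e-8)) {
    f <- stats::dpois(a, mu_t) * stats::dpois(n - a, mu_c)
  } else {
    size <- mu0^2 / (sig2 - mu0)  # shared dispersion phi = 1/size
    f <- stats::dnbinom(a, mu = mu_t, size = size) *
      stats::dnbinom(n - a, mu = mu_c, size = size)
  }
  tot <- sum(f)
  if (!is.finite(tot) || tot <= 0) stop("degenerate exact-test distribution")
  f_obs <- f[k_t + 1L]
  p <- sum(f[f <= f_obs * (1 + 1e-12)]) / tot
  data.frame(mean_treat = nt, mean_control = nc, fold = fold,
             p = min(p, 1))
}

# exact test applied gene-wise between two samples of a count table
exact_test_samples <- function(table, treat, control, size_factors, fit,
                               pseudo_count = 0.5) {
  k <- table$counts
  stopifnot(treat %in% colnames(k), control %in% colnames(k))
  res <- lapply(seq_len(nrow(k)), function(i)
    exact_test(k[i, treat], k[i, control],
               size_factors[[treat]], size_factors[[control]], fit,
               pseudo_count))
  out <- do.call(rbind, res)
  out <- cbind(gene_id = rownames(k), out)
  rownames(out) <- NULL
  out
}

#' Call and classify light-inducible genes
#'
#' A gene is light-inducible if, at any of 30/60/120 min, its expression is
#' significantly higher than in darkness (p < alpha) with at least
#' `min_fold` normalized fold change. Called genes are classified:
#' immediate-early (>= 2-fold already at 30 min), early (fold profile
#' maximal at 30 min and non-increasing after), late (the rest).
#'
#' @param results_by_timepoint Named list (names among "30", "60", "120")
#'   of per-gene exact-test tables as from [exact_test_samples()]; each
#'   compares a light timepoint against DD.
#' @param alpha Significance level (default 0.05).
#' @param min_fold Fold-change gate (default 2).
#' @return data.frame with `gene_id`, folds and p per timepoint, `called`
#'   and `class` (immediate-early/early/late, NA for uncalled genes).
#' @export
call_light_induced <- function(results_by_timepoint, alpha = 0.05,
                               min_fold = 2) {
  tps <- names(results_by_timepoint)
  if (is.null(tps) || !all(tps %in% c("30", "60", "120")) || length(tps) == 0)
    stop("results must be named by light timepoint (30/60/120), ",
         "each tested against DD")
  genes <- results_by_timepoint[[1]]$gene_id
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (tp in tps) {
    r <- results_by_timepoint[[tp]]
    stopifnot(identical(r$gene_id, genes))
    out[[paste0("fold_", tp)]] <- r$fold
    out[[paste0("p_", tp)]] <- r$p
  }
  hit <- rep(FALSE, length(genes))
  for (tp in tps)
    hit <- hit | (out[[paste0("p_", tp)]] < alpha &
                    out[[paste0("fold_", tp)]] >= min_fold)
  out$called <- hit
  f30 <- if ("30" %in% tps) out$fold_30 else rep(NA_real_, length(genes))
  f60 <- if ("60" %in% tps) out$fold_60 else rep(NA_real_, length(genes))
  f120 <- if ("120" %in% tps) out$fold_120 else rep(NA_real_, length(genes))
  cls <- rep(NA_character_, length(genes))
  peak30 <- !is.na(f30) &
    (is.na(f60) | f30 >= f60) & (is.na(f120) | f30 >= f120) &
    (is.na(f60) | is.na(f120) | f60 >= f120)
  cls[hit] <- "late"
  cls[hit & peak30] <- "early"
  cls[hit & !is.na(f30) & f30 >= min_fold] <- "immediate-early"
  out$class <- cls
  out
}

#' Run the light-induction analysis on a count table
#'
#' Convenience wrapper: size factors on the full table, low-expression
#' filter, blind mean-variance fit, exact test of every light timepoint of
#' one genotype against its DD sample, and light-induction calling.
#'
#' @param table A [count_table()] containing a DD sample and >= 1 light
#'   timepoint for `genotype`.
#' @param genotype Genotype to analyze (default `"wt"`).
#' @param cfg Configuration list (see [default_config()]).
#' @return List with `calls` (from [call_light_induced()]), `results`
#'   (per-timepoint exact-test tables), `size_factors` and `fit`.
#' @export
light_induction_analysis <- function(table, genotype = "wt",
                                     cfg = default_config()) {
  smp <- table$samples
  dd <- smp$label[smp$genotype == genotype & smp$timepoint == "DD"]
  if (length(dd) != 1L) stop("need exactly one DD sample for ", genotype)
  light <- smp$label[smp$genotype == genotype & smp$timepoint != "DD"]
  if (length(light) == 0L) stop("no light timepoints for ", genotype)
  sf <- estimate_size_factors(table)
  table <- filter_low_expression(table, cfg$de_low_quantile, sf)
  fit <- fit_mean_variance(table, sf[colnames(table$counts)],
                           span = cfg$de_loess_span)
  results <- list()
  for (lab in light) {
    tp <- smp$timepoint[smp$label == lab]
    results[[tp]] <- exact_test_samples(table, lab, dd, sf, fit,
                                        cfg$de_pseudo_count)
  }
  calls <- call_light_induced(results, cfg$de_alpha, cfg$de_min_fold)
  list(calls = calls, results = results, size_factors = sf, fit = fit)
}

#' Flag genotype-dependent expression of light-inducible genes
#'
#' For each given gene and each shared light timepoint, the exact test
#' compares the two genotypes' counts at that timepoint; a gene is flagged
#' if any timepoint differs at p < alpha in the stated direction (`"down"`:
#' lower in the second table, as for a knock-out; `"up"`: higher, as for an
#' over-expressor). Size factors and the mean-variance trend are estimated
#' on the two tables combined.
#'
#' @param table_a,table_b [count_table()]s of the two genotypes (e.g. wt
#'   and knock-out), one sample per timepoint each.
#' @param genes Gene ids to assess (typically the light-inducible set);
#'   every gene must be present in both tables.
#' @param direction `"down"` or `"up"`: expected direction in `table_b`.
#' @param alpha Significance level.
#' @param cfg Configuration list.
#' @return data.frame with `gene_id`, per-timepoint p and direction flags,
#'   and `flagged`.
#' @export
compare_genotypes <- function(table_a, table_b, genes,
                              direction = c("down", "up"), alpha = 0.05,
                              cfg = default_config()) {
  direction <- match.arg(direction)
  tp_a <- sort(table_a$samples$timepoint[table_a$samples$timepoint != "DD"])
  tp_b <- sort(table_b$samples$timepoint[table_b$samples$timepoint != "DD"])
  if (!identical(tp_a, tp_b))
    stop("light timepoints of the two genotypes do not match")
  missing_b <- setdiff(genes, rownames(table_b$counts))
  if (length(missing_b))
    stop("gene(s) absent from the second table: ",
         paste(utils::head(missing_b, 3), collapse = ", "))
  missing_a <- setdiff(genes, rownames(table_a$counts))
  if (length(missing_a))
    stop("gene(s) absent from the first table: ",
         paste(utils::head(missing_a, 3), collapse = ", "))
  common <- intersect(rownames(table_a$counts), rownames(table_b$counts))
  comb <- count_table(cbind(table_a$counts[common, , drop = FALSE],
                            table_b$counts[common, , drop = FALSE]))
  sf <- estimate_size_factors(comb)
  fit <- fit_mean_variance(comb, sf, span = cfg$de_loess_span)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  flagged <- rep(FALSE, length(genes))
  for (tp in tp_a) {
    lab_a <- table_a$samples$label[table_a$samples$timepoint == tp][1]
    lab_b <- table_b$samples$label[table_b$samples$timepoint == tp][1]
    res <- vapply(genes, function(g) {
      r <- exact_test(comb$counts[g, lab_a], comb$counts[g, lab_b],
                      sf[[lab_a]], sf[[lab_b]], fit, cfg$de_pseudo_count)
      c(r$p, r$mean_treat, r$mean_control)
    }, numeric(3))
    p <- res[1, ]; ma <- res[2, ]; mb <- res[3, ]
    dirok <- if (direction == "down") mb < ma else mb > ma
    out[[paste0("p_", tp)]] <- p
    out[[paste0("hit_", tp)]] <- p < alpha & dirok
    flagged <- flagged | (p < alpha & dirok)
  }
  out$flagged <- flagged
  out
}
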