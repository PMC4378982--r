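# Sliding-window Poisson peak calling against a control library, coverage
# enrichment filtering, peak merging, strand-aware peak-to-gene annotation,
# and prediction-interval classification of light-regulated binding sites.

#' Sliding-window fragment counts
#'
#' Scans each contig with windows of `width` bp advancing by `step` bp and
#' counts the fragments whose 5' position (interval start) falls inside
#' each window.
#'
#' @param fragments data.frame with `contig`, `start`, `end`.
#' @param genome Genome (named character vector) or named contig lengths.
#' @param width Window width in bp (default 150).
#' @param step Window step in bp (default 50).
#' @return data.frame with `contig`, `start` (0-based window start) and
#'   `count`.
#' @export
window_scan <- function(fragments, genome, width = 150L, step = 50L) {
  lens <- contig_lengths(genome)
  out <- lapply(names(lens), function(ctg) {
    pos <- fragments$start[fragments$contig == ctg]
    pos <- pos[pos >= 0 & pos < lens[[ctg]]]
    w <- window_position_counts(pos, lens[[ctg]], width, step)
    if (nrow(w)) cbind(contig = ctg, w) else NULL
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Upper-tail Poisson window test
#'
#' The expected treatment count of a window is lambda = max(k_control,
#' lambda_floor) * scale, where `scale` is the treatment/control ratio of
#' total mapped fragments; the p-value is P(X >= k_treat) under
#' Poisson(lambda), inclusive of the observed count. The floor guards
#' against zero-lambda pathologies in empty control windows.
#'
#' @param k_treat,k_control Window counts (vectors of equal length).
#' @param scale Positive library-size ratio total_treat / total_control.
#' @param lambda_floor Minimum control count used for lambda (default 0.5).
#' @return Vector of upper-tail p-values.
#' @export
poisson_window_test <- function(k_treat, k_control, scale,
                                lambda_floor = 0.5) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  lambda <- pmax(k_control, lambda_floor) * scale
  stats::ppois(k_treat - 1, lambda, lower.tail = FALSE)
}

#' Call peaks from significant window runs
#'
#' Maximal runs of at least `min_consecutive` consecutive (step-adjacent)
#' windows with p below `p_thresh` become one peak spanning the first
#' window start to the last window start + width. The summit is the
#' position of maximal per-base treatment coverage inside the peak
#' (leftmost on ties); fold enrichment compares mean per-base peak
#' coverage to the genome-wide mean coverage.
#'
#' @param stats Window table from [window_scan()] with a `p` column added
#'   (see [poisson_window_test()]).
#' @param track Treatment per-base coverage (see [fragment_coverage()]).
#' @param p_thresh Window significance threshold (default 1e-5).
#' @param min_consecutive Minimum run length (default 4).
#' @param width,step Window geometry used for the scan.
#' @return data.frame with `name`, `contig`, `start`, `end`, `summit`,
#'   `coverage` (mean per-base over the peak), `fold` and `min_p`.
#' @export
call_peaks <- function(stats, track, p_thresh = 1e-5, min_consecutive = 4L,
                       width = 150L, step = 50L) {
  stopifnot("p" %in% names(stats))
  genome_mean <- mean(unlist(track, use.names = FALSE))
  peaks <- list()
  for (ctg in sort(unique(stats$contig))) {
    s <- stats[stats$contig == ctg, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    sig <- s$p < p_thresh
    r <- rle(sig)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_consecutive)
    v <- track[[ctg]]
    for (ri in runs) {
      i0 <- starts_i[ri]; i1 <- ends_i[ri]
      pk_start <- s$start[i0]
      pk_end <- s$start[i1] + width
      seg <- v[(pk_start + 1L):min(pk_end, length(v))]
      summit <- pk_start + which.max(seg) - 1L
      cov <- mean(seg)
      peaks[[length(peaks) + 1L]] <- data.frame(
        contig = ctg, start = pk_start, end = pk_end, summit = summit,
        coverage = cov,
        fold = if (genome_mean > 0) cov / genome_mean else Inf,
        min_p = min(s$p[i0:i1]), stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0L)
    return(data.frame(name = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), coverage = numeric(0),
                      fold = numeric(0), min_p = numeric(0)))
  df <- do.call(rbind, peaks)
  df <- cbind(name = sprintf("peak_%d", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  df
}

#' Filter peaks by coverage enrichment
#'
#' Excludes low-enrichment peaks: a peak is kept only if its mean per-base
#' coverage is at least `min_fold` times the genome-wide mean window
#' coverage and at least the stated percentile of the window coverage
#' distribution.
#'
#' @param peaks Peak table from [call_peaks()].
#' @param track Treatment per-base coverage.
#' @param min_fold Fold cutoff vs mean window coverage (default 1.5).
#' @param percentile Window-coverage percentile cutoff (default 90).
#' @param width,step Window geometry for the coverage distribution.
#' @return Filtered peak table.
#' @export
filter_enrichment <- function(peaks, track, min_fold = 1.5, percentile = 90,
                              width = 150L, step = 50L) {
  wm <- unlist(lapply(track, function(v)
    window_mean_coverage(v, width, step)$mean), use.names = FALSE)
  gen_mean <- mean(wm)
  q <- stats::quantile(wm, percentile / 100, names = FALSE)
  keep <- peaks$coverage >= min_fold * gen_mean & peaks$coverage >= q
  peaks[keep, , drop = FALSE]
}

#' Merge two peak sets by coordinate overlap
#'
#' Intervals overlapping by >= 1 bp are unioned; the provenance column
#' records which input sets contributed to each merged site.
#'
#' @param a,b Peak/site tables with `contig`, `start`, `end`.
#' @return data.frame with `name`, `contig`, `start`, `end`, `summit`
#'   (coverage-weighted pick from the contributing peaks where available)
#'   and `sources` (`"a"`, `"b"` or `"a,b"`).
#' @export
merge_peak_sets <- function(a, b) {
  a$.src <- if (nrow(a)) "a" else character(0)
  b$.src <- if (nrow(b)) "b" else character(0)
  cols <- c("contig", "start", "end", ".src")
  both <- rbind(a[, c(cols, intersect("summit", names(a))), drop = FALSE],
                b[, c(cols, intersect("summit", names(b))), drop = FALSE])
  if (nrow(both) == 0L)
    return(data.frame(name = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), sources = character(0)))
  out <- list()
  for (ctg in sort(unique(both$contig))) {
    x <- both[both$contig == ctg, , drop = FALSE]
    ir <- IRanges::IRanges(start = x$start + 1L, end = x$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    for (j in seq_along(red)) {
      members <- x[S4Vectors_from(ov) [S4Vectors_to(ov) == j], , drop = FALSE]
      summit <- if ("summit" %in% names(members) &&
                    !all(is.na(members$summit)))
        as.integer(stats::median(members$summit, na.rm = TRUE))
      else as.integer((IRanges::start(red)[j] - 1L + IRanges::end(red)[j]) %/% 2L)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(red)[j] - 1L,
        end = IRanges::end(red)[j], summit = summit,
        sources = paste(sort(unique(members$.src)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- cbind(name = sprintf("site_%d", seq_len(nrow(df))), df)
  rownames(df) <- NULL
  df
}

S4Vectors_from <- function(hits) S4Vectors::queryHits(hits)
S4Vectors_to <- function(hits) S4Vectors::subjectHits(hits)

#' Mean per-base coverage of a track over sites
#'
#' @param track Per-base coverage track.
#' @param sites data.frame with `contig`, `start`, `end`.
#' @return Numeric vector, one mean per site.
#' @export
site_intensity <- function(track, sites) {
  vapply(seq_len(nrow(sites)), function(i) {
    v <- track[[sites$contig[i]]]
    lo <- max(1L, sites$start[i] + 1L)
    hi <- min(length(v), sites$end[i])
    if (hi < lo) return(0)
    mean(v[lo:hi])
  }, numeric(1))
}

#' Annotate peaks to genes
#'
#' Three-rule procedure anchored at the peak summit:
#' \enumerate{
#'   \item annotate to every gene whose strand-aware promoter window
#'     (`upstream` bp upstream of the TSS to `downstream` bp downstream,
#'     both boundaries inclusive) contains the summit;
#'   \item otherwise annotate to the single nearest gene for which the
#'     summit lies upstream of the TSS (strand-aware), with no distance
#'     limit;
#'   \item otherwise the peak stays unannotated.
#' }
#'
#' @param peaks Peak table with `name`, `contig`, `summit`.
#' @param genes Gene-model table (see [read_gene_models()]).
#' @param upstream,downstream Promoter window half-widths in bp
#'   (defaults 1000 and 500).
#' @return data.frame with `peak`, `gene_id` (NA if unannotated), `rule`
#'   (1, 2 or NA) and `distance` (|summit - TSS|).
#' @export
annotate_peaks <- function(peaks, genes, upstream = 1000L,
                           downstream = 500L) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    smt <- peaks$summit[i]
    g <- genes[genes$contig == peaks$contig[i], , drop = FALSE]
    rel <- ifelse(g$strand == "+", smt - g$tss, g$tss - smt)
    in_prom <- rel >= -upstream & rel <= downstream
    if (any(in_prom)) {
      hit <- g[in_prom, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        peak = peaks$name[i], gene_id = hit$gene_id, rule = 1L,
        distance = abs(smt - hit$tss), stringsAsFactors = FALSE)
      next
    }
    upstream_of <- rel < 0
    if (any(upstream_of)) {
      cand <- g[upstream_of, , drop = FALSE]
      d <- abs(smt - cand$tss)
      best <- order(d, cand$gene_id)[1]
      out[[length(out) + 1L]] <- data.frame(
        peak = peaks$name[i], gene_id = cand$gene_id[best], rule = 2L,
        distance = d[best], stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        peak = peaks$name[i], gene_id = NA_character_, rule = NA_integer_,
        distance = NA_real_, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(peak = character(0), gene_id = character(0),
                     rule = integer(0), distance = numeric(0))
  rownames(df) <- NULL
  df
}

#' Classify light-regulated binding sites by prediction interval
#'
#' Ordinary least squares of log2(light + 1) on log2(dark + 1) intensities
#' over all sites; each site is classified against its own
#' `band`-level prediction interval (residual variance with leverage
#' term): above the upper bound = light-induced, below the lower bound =
#' light-reduced, otherwise unchanged.
#'
#' @param sites Site table (needs a `name` column) or a character vector
#'   of site ids.
#' @param dark_intensity,light_intensity Per-site read intensities.
#' @param band Prediction-interval level (default 0.80).
#' @return data.frame with `name`, `dark`, `light`, `predicted` (on the
#'   log2 light scale), `lower`, `upper` and `class`.
#' @export
classify_light_regulated <- function(sites, dark_intensity, light_intensity,
                                     band = 0.80) {
  ids <- if (is.data.frame(sites)) sites$name else as.character(sites)
  if (length(ids) < 10L) stop("need >= 10 sites for a stable regression")
  stopifnot(length(dark_intensity) == length(ids),
            length(light_intensity) == length(ids))
  x <- log2(dark_intensity + 1)
  y <- log2(light_intensity + 1)
  if (stats::var(x) == 0)
    stop("degenerate regression: dark intensities have zero variance")
  fit <- stats::lm(y ~ x)
  pr <- stats::predict(fit, newdata = data.frame(x = x),
                       interval = "prediction", level = band)
  cls <- rep("unchanged", length(ids))
  eps <- 1e-8 * (1 + abs(y))  # ties on a collapsed band stay inside
  cls[y > pr[, "upr"] + eps] <- "light-induced"
  cls[y < pr[, "lwr"] - eps] <- "light-reduced"
  data.frame(name = ids, dark = dark_intensity, light = light_intensity,
             predicted = pr[, "fit"], lower = pr[, "lwr"],
             upper = pr[, "upr"], class = cls, stringsAsFactors = FALSE)
}
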