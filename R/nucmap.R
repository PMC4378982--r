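# MNase-seq nucleosome mapping: paired-end fragment classification,
# midpoint coverage, percentile normalization, Gaussian kernel smoothing,
# +1 nucleosome location, TSS/dyad-aligned metagene profiles, repeat-length
# estimation, binding-site occupancy against an NB-distance randomized
# background, and sub-nucleosomal footprint profiles.

#' Classify MNase fragments by length
#'
#' Fragments shorter than `min_len` bp are sub-nucleosomal (candidate TF
#' footprints); fragments of `min_len` to `max_len` bp are nucleosomal;
#' longer fragments are discarded. The boundary length (exactly `min_len`)
#' is nucleosomal.
#'
#' @param pairs data.frame with `contig`, `start`, `end`.
#' @param min_len,max_len Class bounds in bp (defaults 100 and 1000).
#' @return The input with a `class` column, long fragments removed.
#' @export
classify_fragments <- function(pairs, min_len = 100L, max_len = 1000L) {
  len <- pairs$end - pairs$start
  if (any(len <= 0)) stop("fragment with nonpositive length")
  pairs$class <- ifelse(len < min_len, "subnucleosomal", "nucleosomal")
  pairs[len <= max_len, , drop = FALSE]
}

#' Fragment-midpoint coverage
#'
#' Each fragment contributes +1 over the `span` bp centered on its midpoint
#' (midpoint = floor((start + end)/2), interval
#' \[mid - span/2, mid - span/2 + span)), clipped at contig ends.
#'
#' @param fragments data.frame with `contig`, `start`, `end`.
#' @param genome Genome or named contig lengths.
#' @param span Width of the midpoint interval in bp (default 50).
#' @return Per-base coverage track.
#' @export
midpoint_coverage <- function(fragments, genome, span = 50L) {
  half <- span %/% 2L
  mids <- (fragments$start + fragments$end) %/% 2L
  mid_frag <- data.frame(contig = fragments$contig,
                         start = mids - half, end = mids - half + span,
                         stringsAsFactors = FALSE)
  fragment_coverage(mid_frag, genome)
}

#' Normalize a coverage track by a window-coverage percentile
#'
#' Divides the whole track by the stated percentile (default 90th) of mean
#' coverage over sliding windows with nonzero coverage, so the bulk of
#' occupied windows sits at 1. The operation is idempotent and invariant
#' to rescaling of the input.
#'
#' @param track Per-base coverage track.
#' @param percentile Percentile of nonzero window coverage set to 1.
#' @param window,step Window geometry for the normalization statistic.
#' @return Normalized track with attribute `normalized = TRUE`.
#' @export
normalize_track <- function(track, percentile = 90, window = 150L,
                            step = 50L) {
  wm <- unlist(lapply(track, function(v)
    window_mean_coverage(v, window, step)$mean), use.names = FALSE)
  wm <- wm[wm > 0]
  if (length(wm) == 0L) stop("cannot normalize an all-zero track")
  q <- stats::quantile(wm, percentile / 100, names = FALSE)
  out <- lapply(track, function(v) v / q)
  attr(out, "normalized") <- TRUE
  out
}

#' Gaussian kernel smoothing of a coverage track
#'
#' Local Gaussian-weighted average with standard deviation `bandwidth_bp`,
#' kernel truncated at 4 bandwidths; edge weights are renormalized so
#' constants pass through unchanged and interior mass is preserved.
#'
#' @param track Per-base coverage track.
#' @param bandwidth_bp Kernel standard deviation in bp (>= 1, default 30).
#' @return Smoothed track (normalization attribute preserved).
#' @export
smooth_track <- function(track, bandwidth_bp = 30) {
  if (bandwidth_bp < 1) stop("bandwidth must be >= 1 bp")
  h <- as.integer(ceiling(4 * bandwidth_bp))
  w <- stats::dnorm(-h:h, sd = bandwidth_bp)
  w <- w / sum(w)
  out <- lapply(track, function(v) {
    L <- length(v)
    pad <- numeric(h)
    num <- stats::filter(c(pad, v, pad), w, sides = 2)[(h + 1L):(h + L)]
    den <- stats::filter(c(pad, rep(1, L), pad), w, sides = 2)[(h + 1L):(h + L)]
    as.numeric(num / den)
  })
  attr(out, "normalized") <- attr(track, "normalized")
  out
}

#' Locate the +1 nucleosome of a gene
#'
#' The +1 dyad is the position of maximal coverage within a `window`-bp
#' interval centered on the annotated TSS. Ties are broken toward the TSS,
#' then toward the downstream (strand-aware) side.
#'
#' @param track Normalized, smoothed coverage track.
#' @param gene One row of a gene-model table (`contig`, `tss`, `strand`).
#' @param window Search window width in bp (default 200).
#' @return 0-based dyad position, or `NA` if coverage in the window is
#'   zero everywhere.
#' @export
locate_plus_one <- function(track, gene, window = 200L) {
  v <- track[[gene$contig]]
  half <- window %/% 2L
  pos <- max(0L, gene$tss - half):min(length(v) - 1L, gene$tss + half - 1L)
  cov <- v[pos + 1L]
  if (all(cov == 0)) return(NA_integer_)
  cand <- pos[cov == max(cov)]
  d <- cand - gene$tss
  dd <- if (gene$strand == "-") -d else d   # positive = downstream
  cand[order(abs(d), -dd)][1]
}

#' Anchor-aligned metagene profile
#'
#' Averages a track over a set of anchors (e.g. TSSs or +1 dyads) as a
#' function of the signed offset; minus-strand anchors contribute their
#' mirror image. Anchors near contig edges contribute only their defined
#' offsets.
#'
#' @param track Per-base coverage track.
#' @param anchors data.frame with `contig`, `position` and `strand`
#'   (`+`/`-`; anything else is treated as `+`).
#' @param flank Half-width of the profile in bp (default 1500).
#' @return data.frame with `offset` (-flank..flank), `occupancy` (mean
#'   over anchors) and `n` (anchors contributing per offset).
#' @export
metagene_profile <- function(track, anchors, flank = 1500L) {
  if (nrow(anchors) == 0L) stop("no usable anchors")
  offsets <- (-flank):flank
  acc <- numeric(length(offsets))
  cnt <- integer(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    v <- track[[anchors$contig[i]]]
    if (is.null(v)) stop("anchor on unknown contig ", anchors$contig[i])
    sgn <- if (identical(anchors$strand[i], "-")) -1L else 1L
    pos <- anchors$position[i] + sgn * offsets
    ok <- pos >= 0L & pos < length(v)
    acc[ok] <- acc[ok] + v[pos[ok] + 1L]
    cnt[ok] <- cnt[ok] + 1L
  }
  if (all(cnt == 0L)) stop("no anchor contributes any defined offset")
  data.frame(offset = offsets,
             occupancy = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
             n = cnt)
}

#' Nucleosome occupancy as area under the coverage curve
#'
#' Sums normalized coverage over the `width`-bp interval centered on a
#' dyad (\[dyad - width/2, dyad + width/2)).
#'
#' @param track Normalized coverage track.
#' @param contig Contig name.
#' @param dyad 0-based dyad position.
#' @param width Nucleosome footprint in bp (default 176).
#' @return Occupancy (area under the curve).
#' @export
nucleosome_occupancy <- function(track, contig, dyad, width = 176L) {
  v <- track[[contig]]
  half <- width %/% 2L
  pos <- (dyad - half):(dyad + half - 1L)
  pos <- pos[pos >= 0L & pos < length(v)]
  sum(v[pos + 1L])
}

#' Estimate the nucleosome repeat length
#'
#' From ordered dyad positions: the median successive-dyad distance, with
#' a bootstrap percentile confidence interval. From a metagene profile
#' (or plain numeric vector): the lag of the first autocorrelation maximum
#' after the first local minimum, searched within \[min_lag, max_lag\];
#' aperiodic input (peak autocorrelation < 0.1) is reported as undefined.
#'
#' @param x Sorted numeric dyad positions, or a profile data.frame from
#'   [metagene_profile()] (or a numeric coverage vector).
#' @param method `"auto"` (dyads for short sorted position vectors,
#'   autocorrelation otherwise), `"autocorrelation"` or `"dyads"`.
#' @param min_lag,max_lag Search range in bp for the profile route.
#' @param n_boot Bootstrap replicates for the dyad route.
#' @param seed Seed for the bootstrap.
#' @return List with `repeat_length` (NA if undefined), `ci` (length-2
#'   vector or NA) and `method`.
#' @export
estimate_spacing <- function(x, method = c("auto", "autocorrelation",
                                           "dyads"),
                             min_lag = 100L, max_lag = 400L,
                             n_boot = 200L, seed = 1L) {
  method <- match.arg(method)
  if (is.data.frame(x)) x_vec <- x$occupancy
  else x_vec <- as.numeric(x)
  if (method == "auto")
    method <- if (!is.data.frame(x) && is_dyad_vector(x_vec))
      "dyads" else "autocorrelation"
  if (method == "autocorrelation") {
    # profile route: autocorrelation
    z <- x_vec - mean(x_vec)
    n <- length(z)
    denom <- sum(z^2)
    if (denom == 0) return(list(repeat_length = NA_real_, ci = NA,
                                method = "autocorrelation"))
    lags <- seq_len(min(max_lag, n - 2L))
    ac <- vapply(lags, function(l)
      sum(z[seq_len(n - l)] * z[(l + 1L):n]) / denom, numeric(1))
    # first local minimum, then the maximum beyond it
    dmin <- which(diff(ac) > 0)
    if (length(dmin) == 0L)
      return(list(repeat_length = NA_real_, ci = NA,
                  method = "autocorrelation"))
    l0 <- dmin[1]
    search <- lags[lags > l0 & lags >= min_lag]
    if (length(search) == 0L)
      return(list(repeat_length = NA_real_, ci = NA,
                  method = "autocorrelation"))
    peak <- search[which.max(ac[search])]
    if (ac[peak] < 0.1)
      return(list(repeat_length = NA_real_, ci = NA,
                  method = "autocorrelation"))
    return(list(repeat_length = as.numeric(peak), ci = NA,
                method = "autocorrelation"))
  }
  # dyad route: median successive distance
  d <- diff(sort(x_vec))
  if (length(d) < 4L) stop("need >= 5 dyads to estimate spacing")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b)
    stats::median(sample(d, length(d), replace = TRUE)), numeric(1))
  list(repeat_length = stats::median(d),
       ci = stats::quantile(boots, c(0.025, 0.975), names = FALSE),
       method = "median-spacing")
}

is_dyad_vector <- function(x) is.numeric(x) && length(x) <= 10000L &&
  !is.unsorted(x) && all(diff(x) > 50)

#' Nucleosome occupancy at binding sites vs an NB-distance background
#'
#' Observed signal is the mean normalized coverage at site summits. Because
#' binding-site-to-TSS distances follow a negative binomial, the background
#' redraws equally many distances from an NB fitted to the observed
#' |summit - nearest TSS| distances by method of moments, places them
#' relative to randomly chosen TSSs on the side (strand-aware) resampled
#' from the observed sides, and averages coverage there. The ratio removes
#' promoter-proximity bias.
#'
#' @param track Normalized coverage track.
#' @param sites data.frame with `contig` and `summit`.
#' @param genes Gene-model table with `contig`, `tss`, `strand`.
#' @param seed Seed for the background draw.
#' @param n_background Number of background positions (default: number of
#'   sites).
#' @return List with `observed`, `background`, `ratio` and `nb_fit`
#'   (`size`/`mu`, or `NULL` when the empirical fallback was used).
#' @export
site_occupancy_ratio <- function(track, sites, genes, seed = 1L,
                                 n_background = NULL) {
  if (nrow(sites) < 10L) stop("need >= 10 sites")
  set.seed(seed)
  lens <- vapply(track, length, integer(1))
  observed_vals <- vapply(seq_len(nrow(sites)), function(i)
    track[[sites$contig[i]]][sites$summit[i] + 1L], numeric(1))
  observed <- mean(observed_vals)
  # strand-aware signed offset of each summit from its nearest TSS
  rel <- vapply(seq_len(nrow(sites)), function(i) {
    g <- genes[genes$contig == sites$contig[i], , drop = FALSE]
    if (nrow(g) == 0L) return(NA_real_)
    j <- which.min(abs(sites$summit[i] - g$tss))
    if (g$strand[j] == "+") sites$summit[i] - g$tss[j]
    else g$tss[j] - sites$summit[i]
  }, numeric(1))
  rel <- rel[!is.na(rel)]
  if (length(rel) == 0L) stop("no site has a gene on its contig")
  d <- abs(rel)
  m <- mean(d); v <- stats::var(d)
  n_bg <- if (is.null(n_background)) length(rel) else n_background
  if (v > m && m > 0) {
    size <- m^2 / (v - m)
    nb_fit <- list(size = size, mu = m)
    bg_d <- stats::rnbinom(n_bg, size = size, mu = m)
  } else {
    message("NB moment fit infeasible (variance <= mean); ",
            "resampling observed distances instead")
    nb_fit <- NULL
    bg_d <- sample(d, n_bg, replace = TRUE)
  }
  bg_sign <- sample(sign(rel + 0.5), n_bg, replace = TRUE)  # 0 -> downstream
  bg_vals <- numeric(n_bg)
  for (i in seq_len(n_bg)) {
    repeat {
      g <- genes[sample.int(nrow(genes), 1L), , drop = FALSE]
      pos <- if (g$strand == "+") g$tss + bg_sign[i] * bg_d[i]
      else g$tss - bg_sign[i] * bg_d[i]
      if (pos >= 0L && pos < lens[[g$contig]]) break
      bg_d[i] <- if (is.null(nb_fit)) sample(d, 1L)
      else stats::rnbinom(1L, size = nb_fit$size, mu = nb_fit$mu)
    }
    bg_vals[i] <- track[[g$contig]][pos + 1L]
  }
  background <- mean(bg_vals)
  list(observed = observed, background = background,
       ratio = observed / background, nb_fit = nb_fit)
}

#' Sub-nucleosomal footprint profile at binding sites
#'
#' Coverage of sub-nucleosomal (< 100 bp) fragments over their full
#' extent, averaged over site summits and normalized to the genome-wide
#' mean sub-nucleosomal coverage, so 1 means background level.
#'
#' @param subnuc_fragments Sub-nucleosomal fragments (`contig`, `start`,
#'   `end`).
#' @param genome Genome or named contig lengths.
#' @param sites data.frame with `contig` and `summit`.
#' @param flank Profile half-width in bp (default 500).
#' @return Profile data.frame as from [metagene_profile()], occupancy in
#'   units of the genome-wide mean.
#' @export
footprint_profile <- function(subnuc_fragments, genome, sites,
                              flank = 500L) {
  if (nrow(subnuc_fragments) == 0L)
    stop("no sub-nucleosomal fragments")
  cov <- fragment_coverage(subnuc_fragments, genome)
  gmean <- mean(unlist(cov, use.names = FALSE))
  if (gmean == 0) stop("sub-nucleosomal coverage is empty")
  anchors <- data.frame(contig = sites$contig, position = sites$summit,
                        strand = "+", stringsAsFactors = FALSE)
  prof <- metagene_profile(cov, anchors, flank)
  prof$occupancy <- prof$occupancy / gmean
  prof
}
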