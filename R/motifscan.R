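# IUPAC motif scanning, tandem-motif spacing distributions in
# summit-centered regions versus random regions, and motif positional
# density around binding-site summits.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")

#' Scan a genome for a degenerate (IUPAC) motif
#'
#' Reports every exact degenerate match. With `both_strands = TRUE` the
#' reverse complement of the pattern is scanned as well; palindromic
#' patterns (their own reverse complement, such as GATC) are reported once
#' per site.
#'
#' @param genome Named character vector of sequences.
#' @param pattern IUPAC motif string.
#' @param both_strands Scan the minus strand too (default TRUE).
#' @return data.frame with `contig`, `start` (0-based, on the plus
#'   strand), `strand`, `pattern` and `match` (the matched plus-strand
#'   sequence).
#' @export
scan_iupac <- function(genome, pattern, both_strands = TRUE) {
  pattern <- toupper(pattern)
  letters_in <- strsplit(pattern, "")[[1]]
  if (any(!letters_in %in% IUPAC_LETTERS))
    stop("illegal IUPAC letter in pattern: ",
         paste(unique(setdiff(letters_in, IUPAC_LETTERS)), collapse = ""))
  validate_genome(genome)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  palindromic <- identical(rc, pattern)
  out <- list()
  for (ctg in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ctg]])
    fwd <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (length(fwd))
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = IRanges::start(fwd) - 1L, strand = "+",
        pattern = pattern, match = as.character(fwd),
        stringsAsFactors = FALSE)
    if (both_strands && !palindromic) {
      rev <- Biostrings::matchPattern(rc, subj, fixed = "subject")
      if (length(rev))
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = IRanges::start(rev) - 1L, strand = "-",
          pattern = pattern, match = as.character(rev),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), pattern = character(0),
                      match = character(0), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# tally pairwise center-to-center distances of motif starts within one
# region; for a fixed-width pattern the center offset cancels
tally_pairs <- function(starts, max_spacing) {
  counts <- integer(max_spacing)
  if (length(starts) >= 2L) {
    d <- as.integer(unlist(lapply(seq_along(starts)[-1], function(j)
      starts[j] - starts[seq_len(j - 1L)])))
    d <- abs(d)
    d <- d[d >= 1L & d <= max_spacing]
    if (length(d)) {
      t <- tabulate(d, nbins = max_spacing)
      counts <- counts + t
    }
  }
  counts
}

#' Tandem motif spacing distribution in summit-centered regions
#'
#' Within each `region`-bp window centered on a summit, all pairs of motif
#' hits are tallied by center-to-center distance (for a fixed-width motif,
#' the difference of start positions); distances above `max_spacing` are
#' dropped.
#'
#' @param summits data.frame with `contig` and `summit` (0-based).
#' @param genome Named character vector of sequences.
#' @param pattern IUPAC motif (default `GATC`).
#' @param region Region width in bp centered on each summit (default 300).
#' @param max_spacing Largest tallied distance in bp (default 150).
#' @param both_strands Passed to [scan_iupac()].
#' @return data.frame with `distance` (1..max_spacing) and `count`;
#'   attributes `n_regions` and `mean_hits` (mean motif count per region).
#' @export
tandem_spacing <- function(summits, genome, pattern = "GATC",
                           region = 300L, max_spacing = 150L,
                           both_strands = TRUE) {
  lens <- contig_lengths(genome)
  half <- region %/% 2L
  counts <- integer(max_spacing)
  nhits <- 0L
  for (i in seq_len(nrow(summits))) {
    ctg <- summits$contig[i]
    lo <- max(0L, summits$summit[i] - half)
    hi <- min(lens[[ctg]], lo + region)
    seq_i <- substr(genome[[ctg]], lo + 1L, hi)
    sub <- stats::setNames(seq_i, "region")
    hits <- scan_iupac(sub, pattern, both_strands)
    nhits <- nhits + nrow(hits)
    counts <- counts + tally_pairs(sort(unique(hits$start)), max_spacing)
  }
  structure(data.frame(distance = seq_len(max_spacing), count = counts),
            n_regions = nrow(summits),
            mean_hits = if (nrow(summits)) nhits / nrow(summits) else NA_real_)
}

#' Motif spacing distribution in random regions
#'
#' Background for [tandem_spacing()]: the same tally over uniformly placed
#' regions of the same width.
#'
#' @param genome Named character vector of sequences.
#' @param n_regions Number of random regions.
#' @param region Region width in bp (default 300).
#' @param seed Integer seed for region placement.
#' @param pattern IUPAC motif (default `GATC`).
#' @param max_spacing Largest tallied distance in bp (default 150).
#' @param both_strands Passed to [scan_iupac()].
#' @return As [tandem_spacing()], with attribute `mean_hits` giving the
#'   mean motif count per region.
#' @export
random_region_background <- function(genome, n_regions, region = 300L,
                                     seed = 1L, pattern = "GATC",
                                     max_spacing = 150L,
                                     both_strands = TRUE) {
  lens <- contig_lengths(genome)
  if (all(lens < region)) stop("genome smaller than the region width")
  set.seed(seed)
  ok <- names(lens)[lens >= region]
  ctg <- sample(ok, n_regions, replace = TRUE,
                prob = lens[ok] / sum(lens[ok]))
  starts <- vapply(ctg, function(cc)
    sample.int(lens[[cc]] - region + 1L, 1L) - 1L, integer(1))
  summits <- data.frame(contig = ctg,
                        summit = starts + region %/% 2L,
                        stringsAsFactors = FALSE)
  tandem_spacing(summits, genome, pattern, region, max_spacing,
                 both_strands)
}

#' Positional density of motif hits around summits
#'
#' Histogram of signed distances from hit centers to the nearest given
#' summit (strand-agnostic), smoothed with the package's Gaussian kernel
#' smoother.
#'
#' @param hits Motif hits from [scan_iupac()].
#' @param summits data.frame with `contig` and `summit`.
#' @param flank Half-width of the density axis in bp.
#' @param bandwidth_bp Smoother bandwidth (default 10; 0 disables
#'   smoothing).
#' @return data.frame with `offset` (-flank..flank), `count` (raw) and
#'   `density` (smoothed counts).
#' @export
positional_density <- function(hits, summits, flank = 500L,
                               bandwidth_bp = 10) {
  if (nrow(summits) == 0L) stop("need >= 1 summit")
  offsets <- (-flank):flank
  counts <- numeric(length(offsets))
  for (i in seq_len(nrow(hits))) {
    s <- summits[summits$contig == hits$contig[i], , drop = FALSE]
    if (nrow(s) == 0L) next
    w <- nchar(hits$match[i])
    center <- hits$start[i] + (w %/% 2L)
    d <- center - s$summit
    dd <- d[which.min(abs(d))]
    if (abs(dd) <= flank) counts[dd + flank + 1L] <- counts[dd + flank + 1L] + 1
  }
  density <- if (bandwidth_bp > 0)
    smooth_track(list(x = counts), bandwidth_bp)$x else counts
  data.frame(offset = offsets, count = counts, density = density)
}
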