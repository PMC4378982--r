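# Per-base coverage tracks: named lists of numeric vectors, one per contig.
# Pileup is delegated to IRanges::coverage.

#' Per-base fragment pileup
#'
#' Computes per-base coverage of a set of fragment intervals on each contig
#' of a genome. Fragments are clipped at contig ends.
#'
#' @param fragments data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param genome Named character vector of sequences, or a named integer
#'   vector of contig lengths.
#' @return Named list of per-base numeric vectors (a coverage track).
#' @export
fragment_coverage <- function(fragments, genome) {
  lens <- contig_lengths(genome)
  track <- lapply(names(lens), function(ctg) {
    f <- fragments[fragments$contig == ctg, , drop = FALSE]
    L <- lens[[ctg]]
    if (nrow(f) == 0L) return(numeric(L))
    s <- pmax(f$start, 0L)
    e <- pmin(f$end, L)
    keep <- e > s
    if (!any(keep)) return(numeric(L))
    ir <- IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
    as.numeric(IRanges::coverage(ir, width = L))
  })
  names(track) <- names(lens)
  track
}

contig_lengths <- function(genome) {
  if (is.character(genome)) {
    lens <- nchar(genome)
    names(lens) <- names(genome)
  } else if (is.numeric(genome)) {
    lens <- as.integer(genome)
    names(lens) <- names(genome)
  } else if (is.list(genome)) {
    lens <- vapply(genome, length, integer(1))
  } else stop("cannot derive contig lengths")
  if (is.null(names(lens))) stop("contigs must be named")
  lens
}

# Mean per-base coverage over sliding windows of `width` advancing by
# `step`; returns a data.frame of window starts (0-based) and means.
window_mean_coverage <- function(v, width, step) {
  L <- length(v)
  if (L < width) return(data.frame(start = integer(0), mean = numeric(0)))
  cs <- c(0, cumsum(v))
  starts <- seq.int(0L, L - width, by = step)
  data.frame(start = starts,
             mean = (cs[starts + width + 1L] - cs[starts + 1L]) / width)
}

# Counts of positions (e.g. fragment 5' ends) falling in sliding windows
# [start, start + width) advancing by `step` over a contig of length L.
window_position_counts <- function(pos, L, width, step) {
  if (L < width) return(data.frame(start = integer(0), count = integer(0)))
  perbase <- tabulate(pos + 1L, nbins = L)
  cs <- c(0, cumsum(perbase))
  starts <- seq.int(0L, L - width, by = step)
  data.frame(start = starts,
             count = as.integer(cs[starts + width + 1L] - cs[starts + 1L]))
}
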