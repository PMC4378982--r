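# Synthetic data with planted, recorded ground truth: genomes, gene models,
# NB count tables with light-induction profiles, ChIP fragments with
# enriched sites, MNase paired-end fragments from phased nucleosome arrays,
# and planted sequence motifs. Every generator is a pure function of its
# parameters and an explicit seed.

#' Generate a random genome
#'
#' Bases are drawn i.i.d. with the stated GC fraction (G and C equally
#' likely, likewise A and T).
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param gc_fraction GC content, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return Named character vector (`ctg1`, `ctg2`, ...).
#' @export
make_genome <- function(n_contigs = 1L, contig_length = 1e6, gc_fraction = 0.5,
                        seed = 1L) {
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly inside (0, 1)")
  if (any(contig_length < 1)) stop("contig_length must be >= 1")
  set.seed(seed)
  contig_length <- rep_len(as.integer(contig_length), n_contigs)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  genome <- vapply(seq_len(n_contigs), function(i)
    paste(sample(names(p), contig_length[i], replace = TRUE, prob = p),
          collapse = ""), character(1))
  names(genome) <- paste0("ctg", seq_len(n_contigs))
  genome
}

#' Generate non-overlapping gene models on a genome
#'
#' Genes are packed left to right on each contig with random lengths and
#' intergenic gaps; strands are drawn independently.
#'
#' @param genome Named character vector of sequences.
#' @param n_genes Total number of genes.
#' @param min_gene_length,max_gene_length Gene length range in bp.
#' @param min_intergenic Minimum gap between adjacent genes in bp.
#' @param strand_prob Probability of the `+` strand.
#' @param seed Integer seed.
#' @return Gene-model data.frame (see [read_gene_models()]).
#' @export
make_annotation <- function(genome, n_genes, min_gene_length = 1000L,
                            max_gene_length = 3000L, min_intergenic = 200L,
                            strand_prob = 0.5, seed = 1L) {
  set.seed(seed)
  lens <- contig_lengths(genome)
  per_ctg <- table(factor(sample(names(lens), n_genes, replace = TRUE,
                                 prob = lens / sum(lens)),
                          levels = names(lens)))
  rows <- list()
  k <- 0L
  for (ctg in names(lens)) {
    n <- per_ctg[[ctg]]
    if (n == 0L) next
    L <- lens[[ctg]]
    glens <- sample(seq(min_gene_length, max_gene_length), n, replace = TRUE)
    need <- sum(glens) + (n + 1L) * min_intergenic
    if (need > L)
      stop("cannot pack ", n, " genes into contig ", ctg,
           " (", L, " bp) with the requested lengths and gaps")
    # distribute the slack uniformly over the n+1 gaps
    slack <- L - need
    cuts <- sort(sample.int(slack + 1L, n + 1L, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts))
    pos <- min_intergenic + extra[1]
    for (i in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene_id = sprintf("g%04d", k), contig = ctg,
        strand = if (stats::runif(1) < strand_prob) "+" else "-",
        start = pos, end = pos + glens[i], stringsAsFactors = FALSE)
      pos <- pos + glens[i] + min_intergenic + extra[i + 1L]
    }
  }
  gm <- do.call(rbind, rows)
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end - 1L)
  rownames(gm) <- NULL
  gm
}

#' Count model for synthetic RNA-seq tables
#'
#' Baseline means are log-normal with expectation `mean_depth`; the
#' mean-variance relationship is v(mu) = mu + phi(mu) * mu^2 with
#' phi(mu) = phi0 + phi1 / mu, a smooth trend decreasing in mu. Induced
#' genes follow one of two verbal induction archetypes: early genes peak at
#' 30 min then decay, late genes rise monotonically through 120 min.
#'
#' @param mean_depth Expected baseline count per gene (default 50).
#' @param sdlog Log-scale SD of the baseline mean (default 1).
#' @param phi0,phi1 Dispersion trend coefficients (defaults 0.02 and 1).
#' @param frac_induced Fraction of genes planted as light-induced (0.10).
#' @param frac_early Fraction of induced genes of the early archetype.
#' @param profile_early,profile_late Fold over DD at timepoints DD/30/60/120.
#' @param dep_frac Fraction of induced genes whose induction depends on the
#'   genotype named in `dep_genotype`.
#' @param dep_genotype Genotype whose induction folds are scaled.
#' @param dep_mult Multiplier applied to light-timepoint folds of dependent
#'   genes in `dep_genotype` (0.5 = induction halved).
#' @param size_factors Optional named per-sample scale factors (default 1).
#' @return Named list of model parameters.
#' @export
count_model <- function(mean_depth = 50, sdlog = 1, phi0 = 0.02, phi1 = 1,
                        frac_induced = 0.10, frac_early = 0.5,
                        profile_early = c(DD = 1, "30" = 8, "60" = 4, "120" = 2),
                        profile_late = c(DD = 1, "30" = 2, "60" = 4, "120" = 8),
                        dep_frac = 0, dep_genotype = NULL, dep_mult = 0.5,
                        size_factors = NULL) {
  stopifnot(mean_depth > 0, phi0 >= 0, phi1 >= 0,
            frac_induced >= 0, frac_induced <= 1)
  list(mean_depth = mean_depth, sdlog = sdlog, phi0 = phi0, phi1 = phi1,
       frac_induced = frac_induced, frac_early = frac_early,
       profile_early = profile_early, profile_late = profile_late,
       dep_frac = dep_frac, dep_genotype = dep_genotype,
       dep_mult = dep_mult, size_factors = size_factors)
}

#' Simulate an NB count table with planted light-induced genes
#'
#' Counts are drawn NB with mean s_j * mu_i * fold_i(t, genotype) and
#' variance from the model's mean-variance trend evaluated at that mean
#' (Poisson when phi = 0).
#'
#' @param model A [count_model()].
#' @param genes Character vector of gene ids, or a single integer (number
#'   of genes, ids auto-generated).
#' @param samples data.frame with `genotype` and `timepoint` (DD/30/60/120)
#'   columns, or a character vector of `genotype_timepoint` labels.
#' @param seed Integer seed.
#' @return List with `table` (a [count_table()]) and `truth` (data.frame:
#'   `gene_id`, `class` in null/early/late, `fold_30`, `fold_60`,
#'   `fold_120`, `dependent`, plus `mu`), and `seed`.
#' @export
simulate_counts <- function(model, genes, samples, seed = 1L) {
  set.seed(seed)
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- sprintf("gene%05d", seq_len(genes))
  if (is.character(samples))
    samples <- data.frame(genotype = sub("_[^_]*$", "", samples),
                          timepoint = sub(".*_", "", samples),
                          stringsAsFactors = FALSE)
  stopifnot(all(samples$timepoint %in% c("DD", "30", "60", "120")))
  n <- length(genes)
  m <- nrow(samples)
  labels <- paste(samples$genotype, samples$timepoint, sep = "_")
  sf <- model$size_factors
  if (is.null(sf)) sf <- stats::setNames(rep(1, m), labels)
  sf <- sf[labels]

  mu <- stats::rlnorm(n, meanlog = log(model$mean_depth) - model$sdlog^2 / 2,
                      sdlog = model$sdlog)
  n_ind <- round(model$frac_induced * n)
  induced <- sample(n, n_ind)
  early <- induced[seq_len(round(model$frac_early * n_ind))]
  late <- setdiff(induced, early)
  cls <- rep("null", n)
  cls[early] <- "early"; cls[late] <- "late"
  dependent <- rep(FALSE, n)
  if (model$dep_frac > 0 && length(induced))
    dependent[sample(induced, round(model$dep_frac * n_ind))] <- TRUE

  fold_at <- function(i, tp) {
    if (cls[i] == "null") return(1)
    prof <- if (cls[i] == "early") model$profile_early else model$profile_late
    prof[[tp]]
  }
  counts <- matrix(0L, n, m, dimnames = list(genes, labels))
  for (j in seq_len(m)) {
    tp <- samples$timepoint[j]
    folds <- vapply(seq_len(n), fold_at, numeric(1), tp = tp)
    if (!is.null(model$dep_genotype) &&
        samples$genotype[j] == model$dep_genotype && tp != "DD")
      folds[dependent] <- pmax(1, folds[dependent] * model$dep_mult)
    mj <- sf[j] * mu * folds
    phi <- model$phi0 + model$phi1 / mu
    counts[, j] <- ifelse(phi <= 0,
                          stats::rpois(n, mj),
                          stats::rnbinom(n, mu = mj, size = 1 / phi))
  }
  truth <- data.frame(
    gene_id = genes, class = cls, mu = mu,
    fold_30 = vapply(seq_len(n), fold_at, numeric(1), tp = "30"),
    fold_60 = vapply(seq_len(n), fold_at, numeric(1), tp = "60"),
    fold_120 = vapply(seq_len(n), fold_at, numeric(1), tp = "120"),
    dependent = dependent, stringsAsFactors = FALSE)
  list(table = count_table(counts), truth = truth, seed = seed)
}

# draw n values from N(mean, sd), rounded, truncated to [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(integer(0))
  x <- round(stats::rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- which(x < lo | x > hi)
  }
  as.integer(x)
}

#' Simulate single-end ChIP fragments with planted enriched sites
#'
#' Control fragment centers are uniform on the genome; treatment fragment
#' centers are drawn with relative rate `fold` within +/- fragment_mean/2
#' of each planted summit and 1 elsewhere. Fragment lengths are
#' N(fragment_mean, fragment_mean/5) truncated at >= 50 bp.
#'
#' @param genome Named character vector of sequences.
#' @param sites data.frame with `contig`, `position` (summit, 0-based) and
#'   `fold` (>= 1); may have zero rows.
#' @param depth Mean per-base fragment coverage of each library.
#' @param fragment_mean Mean fragment length in bp.
#' @param seed Integer seed.
#' @return List with `treatment` and `control` fragment data.frames and
#'   `truth` (the site table).
#' @export
simulate_chip <- function(genome, sites, depth = 30, fragment_mean = 150L,
                          seed = 1L) {
  set.seed(seed)
  lens <- contig_lengths(genome)
  if (nrow(sites) > 0) {
    if (any(sites$fold < 1)) stop("site folds must be >= 1")
    if (any(!sites$contig %in% names(lens)) ||
        any(sites$position < 0 |
            sites$position >= lens[sites$contig]))
      stop("planted site outside the genome")
  }
  half <- fragment_mean %/% 2L
  draw_lib <- function(enriched) {
    out <- list()
    for (ctg in names(lens)) {
      L <- lens[[ctg]]
      n <- round(depth * L / fragment_mean)
      if (enriched && nrow(sites) > 0) {
        w <- rep(1, L)
        sc <- sites[sites$contig == ctg, , drop = FALSE]
        for (i in seq_len(nrow(sc))) {
          lo <- max(1L, sc$position[i] - half + 1L)
          hi <- min(L, sc$position[i] + half + 1L)
          w[lo:hi] <- sc$fold[i]
        }
        centers <- sample.int(L, n, replace = TRUE, prob = w) - 1L
      } else {
        centers <- sample.int(L, n, replace = TRUE) - 1L
      }
      len <- rnorm_trunc(n, fragment_mean, fragment_mean / 5, 50L, 10L * fragment_mean)
      start <- pmax(0L, centers - len %/% 2L)
      end <- pmin(L, start + len)
      out[[ctg]] <- data.frame(contig = ctg, start = start, end = end,
                               stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  }
  treatment <- draw_lib(TRUE)
  control <- draw_lib(FALSE)
  list(treatment = treatment, control = control, truth = sites, seed = seed)
}

#' Simulate MNase paired-end fragments from phased nucleosome arrays
#'
#' Each array plants `n_nucs` dyads spaced `repeat_length` bp from its
#' anchor. Nucleosomal fragments are centered on dyads with N(0, 10) jitter
#' and lengths N(150, 10) truncated to \[100, 1000\]; per-dyad fragment
#' numbers are Poisson with mean `frag_per_nuc * occupancy`. Planted
#' footprints (< 100 bp) yield short fragments (length N(60, 10) truncated
#' below 100). A uniform background contributes fragments of both classes.
#'
#' @param genome Named character vector of sequences.
#' @param arrays data.frame with `contig`, `anchor` (first dyad, 0-based),
#'   `n_nucs`, `repeat_length` (>= 147) and `occupancy` (>= 0).
#' @param footprints data.frame with `contig`, `position`, `width` (< 100
#'   bp); may have zero rows.
#' @param frag_per_nuc Expected fragments per dyad at occupancy 1.
#' @param frag_per_footprint Expected fragments per footprint.
#' @param background_rate Expected background fragments per bp.
#' @param background_subnuc_frac Fraction of background fragments that are
#'   sub-nucleosomal.
#' @param seed Integer seed.
#' @return List with `fragments` (data.frame `contig`, `start`, `end`) and
#'   `truth` (list with `dyads` and `footprints` tables), and `seed`.
#' @export
simulate_mnase <- function(genome, arrays,
                           footprints = data.frame(contig = character(0),
                                                   position = integer(0),
                                                   width = integer(0)),
                           frag_per_nuc = 50, frag_per_footprint = 50,
                           background_rate = 0.01,
                           background_subnuc_frac = 0.2, seed = 1L) {
  set.seed(seed)
  lens <- contig_lengths(genome)
  if (any(arrays$repeat_length < 147))
    stop("repeat_length must be >= 147 bp")
  if (nrow(footprints) > 0 && any(footprints$width >= 100))
    stop("footprint width must be < 100 bp")
  # arrays must not overlap (pairwise per contig, including the 147 bp core)
  span_lo <- arrays$anchor - 74L
  span_hi <- arrays$anchor + (arrays$n_nucs - 1L) * arrays$repeat_length + 74L
  for (ctg in unique(arrays$contig)) {
    i <- which(arrays$contig == ctg)
    if (length(i) > 1L) {
      o <- order(span_lo[i])
      lo <- span_lo[i][o]; hi <- span_hi[i][o]
      if (any(lo[-1] <= hi[-length(hi)]))
        stop("overlapping nucleosome arrays on contig ", ctg)
    }
  }
  dyads <- do.call(rbind, lapply(seq_len(nrow(arrays)), function(i)
    data.frame(contig = arrays$contig[i], array = i,
               dyad = arrays$anchor[i] +
                 (seq_len(arrays$n_nucs[i]) - 1L) * arrays$repeat_length[i],
               repeat_length = arrays$repeat_length[i],
               occupancy = arrays$occupancy[i], stringsAsFactors = FALSE)))

  frag <- list()
  add <- function(contig, centers, lens_frag) {
    L <- lens[[contig[1]]]
    start <- pmax(0L, centers - lens_frag %/% 2L)
    end <- pmin(L, start + lens_frag)
    keep <- end > start
    data.frame(contig = contig[1], start = start[keep], end = end[keep],
               stringsAsFactors = FALSE)
  }
  if (!is.null(dyads) && nrow(dyads) > 0) {
    for (i in seq_len(nrow(dyads))) {
      n <- stats::rpois(1, frag_per_nuc * dyads$occupancy[i])
      if (n == 0L) next
      centers <- dyads$dyad[i] + round(stats::rnorm(n, 0, 10))
      frag[[length(frag) + 1L]] <-
        add(dyads$contig[i], centers, rnorm_trunc(n, 150, 10, 100L, 1000L))
    }
  }
  if (nrow(footprints) > 0) {
    for (i in seq_len(nrow(footprints))) {
      n <- stats::rpois(1, frag_per_footprint)
      if (n == 0L) next
      centers <- footprints$position[i] + round(stats::rnorm(n, 0, 5))
      frag[[length(frag) + 1L]] <-
        add(footprints$contig[i], centers, rnorm_trunc(n, 60, 10, 20L, 99L))
    }
  }
  for (ctg in names(lens)) {
    L <- lens[[ctg]]
    n <- stats::rpois(1, background_rate * L)
    if (n == 0L) next
    centers <- sample.int(L, n, replace = TRUE) - 1L
    sub <- stats::runif(n) < background_subnuc_frac
    lenv <- integer(n)
    lenv[sub] <- rnorm_trunc(sum(sub), 60, 10, 20L, 99L)
    lenv[!sub] <- rnorm_trunc(sum(!sub), 150, 10, 100L, 1000L)
    frag[[length(frag) + 1L]] <- add(rep(ctg, n), centers, lenv)
  }
  fragments <- if (length(frag)) do.call(rbind, frag) else
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  rownames(fragments) <- NULL
  list(fragments = fragments,
       truth = list(dyads = dyads, footprints = footprints), seed = seed)
}

#' Plant exact motif sequences into a genome
#'
#' Substitutes each pattern at its stated position. Placements must be
#' non-overlapping and in range. To plant a tandem pair at center-to-center
#' spacing d, place the same pattern at p and p + d.
#'
#' @param genome Named character vector of sequences.
#' @param placements data.frame with `contig`, `position` (0-based) and
#'   `pattern` (ACGT string); may have zero rows.
#' @return List with `genome` (modified) and `truth` (the placements).
#' @export
plant_motifs <- function(genome, placements) {
  validate_genome(genome)
  if (nrow(placements) == 0L)
    return(list(genome = genome, truth = placements))
  lens <- contig_lengths(genome)
  placements$pattern <- toupper(placements$pattern)
  w <- nchar(placements$pattern)
  if (any(!placements$contig %in% names(lens)) ||
      any(placements$position < 0) ||
      any(placements$position + w > lens[placements$contig]))
    stop("motif placement outside the genome")
  for (ctg in unique(placements$contig)) {
    p <- placements[placements$contig == ctg, , drop = FALSE]
    o <- order(p$position)
    s <- p$position[o]; e <- s + nchar(p$pattern)[o]
    if (length(s) > 1L && any(s[-1] < e[-length(e)]))
      stop("overlapping motif placements on contig ", ctg)
    for (i in seq_len(nrow(p)))
      substr(genome[[ctg]], p$position[i] + 1L,
             p$position[i] + nchar(p$pattern[i])) <- p$pattern[i]
  }
  list(genome = genome, truth = placements)
}

#' Placements for tandem motif pairs
#'
#' Convenience builder: for each position p, one pattern copy at p and one
#' at p + spacing, giving a center-to-center spacing of `spacing` bp.
#'
#' @param contig Contig name (recycled).
#' @param positions 0-based start positions of the first copy of each pair.
#' @param spacing Center-to-center spacing in bp (>= pattern width for
#'   non-overlapping copies).
#' @param pattern Motif string (default `GATC`).
#' @return Placement data.frame for [plant_motifs()].
#' @export
tandem_placements <- function(contig, positions, spacing, pattern = "GATC") {
  if (spacing < nchar(pattern))
    stop("spacing smaller than the pattern width would overlap the copies")
  data.frame(contig = contig,
             position = as.integer(c(rbind(positions, positions + spacing))),
             pattern = pattern, stringsAsFactors = FALSE)
}
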