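# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately plain (loops, direct formulas) so they stay independent of
# the vectorized implementation paths they check.

# dispersion mapping with constant phi: sigma^2(mu) = mu + phi * mu^2
const_phi_fit <- function(phi) {
  structure(list(interp = function(l) {
    mu <- exp(l)
    mu + phi * mu^2
  }, span = NA, n = NA, mu_range = c(0, Inf)), class = "dispersion_fit")
}

# NB pmf from first principles (lgamma), parameterized by mean/variance
nb_pmf <- function(k, mu, sig2) {
  if (sig2 <= mu * (1 + 1e-8)) return(exp(-mu + k * log(mu) - lgamma(k + 1)))
  r <- mu^2 / (sig2 - mu)
  p <- r / (r + mu)
  exp(lgamma(k + r) - lgamma(r) - lgamma(k + 1) + r * log(p) +
        k * log(1 - p))
}

# brute-force enumeration of the conditional two-sided exact test
oracle_exact_p <- function(k_t, k_c, s_t, s_c, phi) {
  n <- k_t + k_c
  if (n == 0) return(1)
  mu0 <- (k_t / s_t + k_c / s_c) / 2
  mu_t <- mu0 * s_t; mu_c <- mu0 * s_c
  f <- numeric(n + 1)
  for (a in 0:n) {
    f[a + 1] <- nb_pmf(a, mu_t, mu_t + phi * mu_t^2) *
      nb_pmf(n - a, mu_c, mu_c + phi * mu_c^2)
  }
  f_obs <- f[k_t + 1]
  sum(f[f <= f_obs * (1 + 1e-12)]) / sum(f)
}

# two-sided conditional binomial exact test (Poisson-limit closed form)
oracle_binom_p <- function(k_t, k_c, s_t, s_c) {
  n <- k_t + k_c
  if (n == 0) return(1)
  pr <- s_t / (s_t + s_c)
  d <- dbinom(0:n, n, pr)
  sum(d[d <= d[k_t + 1] * (1 + 1e-12)])
}

# IUPAC letter -> regex character class
iupac_class <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
                 B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
                 N = "[ACGT]")

iupac_regex <- function(pattern) {
  paste(iupac_class[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# sliding regex comparison: all 0-based match starts of an IUPAC pattern
brute_iupac_scan <- function(seq, pattern, both_strands = TRUE) {
  find <- function(pat) {
    rx <- iupac_regex(pat)
    w <- nchar(pat)
    starts <- integer(0)
    for (i in seq_len(nchar(seq) - w + 1)) {
      if (grepl(paste0("^", rx, "$"), substr(seq, i, i + w - 1)))
        starts <- c(starts, i - 1L)
    }
    starts
  }
  fwd <- find(pattern)
  rc <- revcomp_chr(toupper(pattern))
  if (!both_strands || identical(rc, toupper(pattern)))
    return(list(fwd = fwd, rev = integer(0)))
  list(fwd = fwd, rev = find(rc))
}

# independent three-rule peak annotation (loops over every peak x gene)
brute_annotate <- function(peaks, genes, up = 1000, down = 500) {
  res <- list()
  for (i in seq_len(nrow(peaks))) {
    smt <- peaks$summit[i]
    prom_genes <- character(0)
    best_gene <- NA_character_; best_d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$contig[j] != peaks$contig[i]) next
      tss <- genes$tss[j]
      if (genes$strand[j] == "+") {
        in_prom <- smt >= tss - up && smt <= tss + down
        upstream <- smt < tss
      } else {
        in_prom <- smt <= tss + up && smt >= tss - down
        upstream <- smt > tss
      }
      if (in_prom) prom_genes <- c(prom_genes, genes$gene_id[j])
      if (upstream) {
        d <- abs(smt - tss)
        if (d < best_d ||
            (d == best_d && genes$gene_id[j] < best_gene)) {
          best_d <- d; best_gene <- genes$gene_id[j]
        }
      }
    }
    if (length(prom_genes)) {
      res[[i]] <- data.frame(peak = peaks$name[i],
                             gene_id = sort(prom_genes), rule = 1L)
    } else if (!is.na(best_gene)) {
      res[[i]] <- data.frame(peak = peaks$name[i], gene_id = best_gene,
                             rule = 2L)
    } else {
      res[[i]] <- data.frame(peak = peaks$name[i],
                             gene_id = NA_character_, rule = NA_integer_)
    }
  }
  do.call(rbind, res)
}

# canonical small gene table builder
make_genes <- function(tss, strand, contig = "c1", len = 1000L) {
  start <- ifelse(strand == "+", tss, tss - len + 1L)
  data.frame(gene_id = sprintf("g%02d", seq_along(tss)), contig = contig,
             strand = strand, start = start, end = start + len,
             tss = tss, stringsAsFactors = FALSE)
}
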