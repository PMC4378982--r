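#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters of every pipeline stage as a
#' named list. Defaults are the published values of the original analysis
#' wherever one is stated; parameters the original analysis left open carry
#' the package's documented choices (see the methods vignette).
#'
#' @return Named list of parameters. Key groups:
#' \describe{
#'   \item{de_*}{differential expression: low-expression quantile (0.20),
#'     significance level (0.05), fold cutoff (2), loess span (0.3),
#'     fold-change pseudo-count (0.5).}
#'   \item{peak_*}{peak calling: window width 150 bp, step 50 bp, Poisson
#'     p-value threshold 1e-5, 4 consecutive windows, 1.5-fold / 90th
#'     percentile enrichment filter, lambda floor 0.5.}
#'   \item{annot_*}{annotation: promoter window 1000 bp upstream to 500 bp
#'     downstream of the TSS.}
#'   \item{nuc_*}{nucleosome mapping: fragment class bounds 100/1000 bp,
#'     midpoint span 50 bp, normalization percentile 90 over 150 bp windows,
#'     smoother bandwidth 30 bp, +1 search window 200 bp, flank 1500 bp,
#'     nucleosome width 176 bp.}
#'   \item{motif_*}{motif analysis: summit region 300 bp, default maximum
#'     tandem spacing 150 bp.}
#'   \item{diffbind_*}{binding-site classification: 80 percent prediction
#'     band.}
#' }
#' @export
default_config <- function() {
  list(
    # differential expression
    de_low_quantile   = 0.20,
    de_alpha          = 0.05,
    de_min_fold       = 2,
    de_loess_span     = 0.3,
    de_pseudo_count   = 0.5,
    # peak calling
    peak_window       = 150L,
    peak_step         = 50L,
    peak_p_thresh     = 1e-5,
    peak_min_consec   = 4L,
    peak_min_fold     = 1.5,
    peak_percentile   = 90,
    peak_lambda_floor = 0.5,
    # annotation
    annot_upstream    = 1000L,
    annot_downstream  = 500L,
    # nucleosome mapping
    nuc_min_len       = 100L,
    nuc_max_len       = 1000L,
    nuc_span          = 50L,
    nuc_norm_pct      = 90,
    nuc_norm_window   = 150L,
    nuc_bandwidth     = 30,
    nuc_plus1_window  = 200L,
    nuc_flank         = 1500L,
    nuc_width         = 176L,
    # motif analysis
    motif_region      = 300L,
    motif_max_spacing = 150L,
    # differential binding
    diffbind_band     = 0.80
  )
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values are coerced to numeric where possible. Keys must be
#' known configuration parameters (see [default_config()]); the result is
#' the default configuration with the file's values overriding.
#'
#' @param path Path to the configuration file.
#' @return Named list as from [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (is.na(num)) val else num
  }
  cfg
}

#' Write a configuration list as a flat key-value file
#'
#' @param cfg Named list of parameters.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(is.list(cfg), length(names(cfg)) == length(cfg))
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", format(cfg[[k]], scientific = FALSE)), character(1))
  writeLines(lines, path)
  invisible(path)
}
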