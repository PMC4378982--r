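# Readers and writers for the pipeline's external formats.
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based conventions of GFF3 and wiggle happens only in this file.

#' Read a genome from a FASTA file
#'
#' Loads every record, upper-cases the sequence, and validates the alphabet
#' (A/C/G/T/N only).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one upper-case sequence per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      # the parser silently drops invalid letters; that is a format error
      if (grepl("invalid one-letter sequence", conditionMessage(w)))
        stop("illegal character in FASTA ", path, ": ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  genome <- toupper(as.character(seqs))
  names(genome) <- sub("\\s.*$", "", names(genome))
  validate_genome(genome, path)
  genome
}

validate_genome <- function(genome, what = "genome") {
  if (length(genome) == 0L) stop("no sequences in ", what)
  if (anyDuplicated(names(genome)))
    stop("duplicate contig names in ", what)
  if (any(nchar(genome) < 1L)) stop("empty sequence in ", what)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("illegal character in contig '", names(genome)[bad][1],
         "' of ", what, " (alphabet is ACGTN)")
  invisible(genome)
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  validate_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 subset
#'
#' Parses `gene` feature lines of a GFF3 file into a gene-model table.
#' GFF3 1-based closed coordinates are converted to 0-based half-open;
#' the TSS is the 5' end of the gene (start for `+`, end - 1 for `-`).
#'
#' @param path Path to a GFF3 file whose gene lines carry `ID=` attributes.
#' @return A data.frame with columns `gene_id`, `contig`, `strand`
#'   (`+`/`-`), `start`, `end` (0-based half-open) and `tss` (0-based).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], ": expected 9 tab-separated fields")
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no gene features in ", path)
  ids <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  noid <- !grepl("ID=", m[, 9])
  if (any(noid)) stop("gene feature without ID attribute in ", path)
  strand <- m[, 7]
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand '", strand[!strand %in% c("+", "-")][1],
         "' in ", path)
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  if (any(is.na(start1)) || any(is.na(end1)) || any(end1 < start1))
    stop("invalid coordinates in ", path)
  gm <- data.frame(
    gene_id = ids, contig = m[, 1], strand = strand,
    start = start1 - 1L, end = end1, stringsAsFactors = FALSE)
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end - 1L)
  if (anyDuplicated(gm$gene_id))
    stop("duplicate gene IDs in ", path)
  rownames(gm) <- NULL
  gm
}

#' Write gene models as a GFF3 subset
#'
#' @param genes Gene-model data.frame as from [read_gene_models()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(all(c("gene_id", "contig", "strand", "start", "end")
                %in% names(genes)))
  lines <- sprintf("%s\tluxseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$contig, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct a count table
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns. Column names are sample labels of the form
#'   `genotype_timepoint` (timepoint in DD/30/60/120).
#' @return A `count_table`: list with `counts` (matrix) and `samples`
#'   (data.frame with `label`, `genotype`, `timepoint`).
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(colnames(counts))) stop("sample labels must be unique")
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  storage.mode(counts) <- "integer"
  lab <- colnames(counts)
  tp <- sub(".*_", "", lab)
  geno <- sub("_[^_]*$", "", lab)
  structure(list(
    counts = counts,
    samples = data.frame(label = lab, genotype = geno, timepoint = tp,
                         stringsAsFactors = FALSE)),
    class = "count_table")
}

#' Read a count table from TSV
#'
#' First column `gene_id`, one column per sample; the header carries sample
#' labels `genotype_timepoint`.
#'
#' @param path Path to the TSV file.
#' @return A [count_table()].
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs gene_id plus >= 1 sample column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_table(m)
}

#' Write a count table as TSV
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(gene_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned fragments from a BED-like TSV
#'
#' Canonical fragment input: tab-separated, no header, columns contig,
#' start, end (0-based half-open). Extra columns (BED6 and BEDPE-style
#' files) are ignored.
#'
#' @param path Path to the fragment file.
#' @return data.frame with `contig`, `start`, `end`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("fragment file needs >= 3 columns: ", path)
  out <- data.frame(contig = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start))
    stop("fragment with end <= start in ", path)
  out
}

#' Write fragments as a 3-column BED-like TSV
#'
#' @param fragments data.frame with `contig`, `start`, `end`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[, c("contig", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#'
#' The score column carries fold enrichment x 100, rounded to integer
#' (0 where no fold is available); the strand column is `.`.
#'
#' @param x data.frame with `contig`, `start`, `end`, optionally `name` and
#'   `fold`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  name <- if ("name" %in% names(x)) x$name else
    sprintf("region_%d", seq_len(nrow(x)))
  score <- if ("fold" %in% names(x)) as.integer(round(x$fold * 100)) else 0L
  df <- data.frame(x$contig, x$start, x$end, name, score, ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first six columns)
#'
#' @param path Path to a BED file.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs >= 3 columns: ", path)
  data.frame(contig = as.character(df[[1]]),
             start = as.integer(df[[2]]),
             end = as.integer(df[[3]]),
             name = if (ncol(df) >= 4) as.character(df[[4]]) else
               sprintf("region_%d", seq_len(nrow(df))),
             score = if (ncol(df) >= 5) as.numeric(df[[5]]) else 0,
             strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
             stringsAsFactors = FALSE)
}

#' Write a coverage track in fixedStep wiggle format
#'
#' Each contig gets one `fixedStep` declaration (1-based start, per UCSC
#' convention) and one value per `step`-bp span, the mean coverage over the
#' span. A trailing partial span is dropped.
#'
#' @param track Named list of per-base numeric vectors (a coverage track).
#' @param path Output path.
#' @param step Span/step size in bp (>= 1).
#' @return Invisibly, `path`.
#' @export
write_wiggle <- function(track, path, step = 10L) {
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (length(track) == 0L || all(lengths(track) == 0L))
    stop("empty coverage track")
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track)) {
    v <- track[[ctg]]
    nspan <- length(v) %/% step
    if (nspan == 0L) next
    idx <- rep(seq_len(nspan), each = step)
    means <- as.numeric(tapply(v[seq_len(nspan * step)], idx, mean))
    writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                       ctg, step, step), con)
    writeLines(as.character(signif(means, 10)), con)
  }
  invisible(path)
}

#' Read a fixedStep wiggle file into a coverage track
#'
#' Each value is expanded over its span, so the result has per-base
#' resolution equal to the file's step resolution.
#'
#' @param path Path to a fixedStep wiggle file.
#' @return Named list of per-base numeric vectors.
#' @export
read_wiggle <- function(path) {
  if (!file.exists(path)) stop("wiggle file not found: ", path)
  lines <- readLines(path)
  heads <- grep("^fixedStep", lines)
  if (length(heads) == 0L) stop("no fixedStep declaration in ", path)
  track <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    h <- lines[heads[i]]
    ctg <- sub(".*chrom=([^ ]+).*", "\\1", h)
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", h))
    span <- if (grepl("span=", h))
      as.integer(sub(".*span=([0-9]+).*", "\\1", h)) else 1L
    vals <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
    if (step != span)
      stop("only step == span fixedStep blocks are supported")
    track[[ctg]] <- rep(vals, each = span)
  }
  track
}
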