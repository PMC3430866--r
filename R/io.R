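## Readers/writers for the plain-text formats the pipeline touches.
## Convention used throughout the package: all genomic coordinates are
## 0-based half-open ([start, end)), as in BED. The TSS of a +-strand gene
## is `start`; of a --strand gene it is `end - 1`.

#' Read a BED file of genomic intervals
#'
#' Parses a BED6 (or BED6 plus declared extra columns) file into a data
#' frame of 0-based half-open intervals. Malformed lines are reported with
#' their line number.
#'
#' @param path Path to a tab-separated BED file without header.
#' @param extra_cols Named character vector declaring columns beyond the
#'   first six, in file order; values are `"integer"`, `"numeric"` or
#'   `"character"`.
#' @param n_cols Minimum number of columns required (default 3; gene and
#'   peak readers require 6).
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`, plus any declared extra columns.
#' @seealso [write_bed()], [read_genes_bed()], [read_peaks_bed()]
#' @export
read_bed <- function(path, extra_cols = NULL, n_cols = 3L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  want <- n_cols + length(extra_cols)
  nf <- lengths(fields)
  bad <- which(nf < want)
  if (length(bad) > 0L)
    stop(sprintf("line %d: expected >= %d columns, found %d",
                 bad[1], want, nf[bad[1]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- data.frame(chrom = get(1),
                    start = suppressWarnings(as.integer(get(2))),
                    end = suppressWarnings(as.integer(get(3))),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    stop(sprintf("line %d: non-integer start/end", bad))
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0L)
    stop(sprintf("line %d: start >= end (%d >= %d)",
                 bad[1], out$start[bad[1]], out$end[bad[1]]))
  if (max(nf) >= 4L && n_cols >= 4L) out$name <- get(4)
  if (max(nf) >= 5L && n_cols >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (max(nf) >= 6L && n_cols >= 6L) {
    out$strand <- get(6)
    bad <- which(!out$strand %in% c("+", "-", "."))
    if (length(bad) > 0L)
      stop(sprintf("line %d: unknown strand symbol '%s'", bad[1], out$strand[bad[1]]))
  }
  if (length(extra_cols) > 0L) {
    for (j in seq_along(extra_cols)) {
      col <- get(n_cols + j)
      nm <- names(extra_cols)[j]
      out[[nm]] <- switch(extra_cols[[j]],
        integer = {
          v <- suppressWarnings(as.integer(col))
          if (anyNA(v)) stop(sprintf("line %d: non-integer value in column %s",
                                     which(is.na(v))[1], nm))
          v
        },
        numeric = {
          v <- suppressWarnings(as.numeric(col))
          if (anyNA(v)) stop(sprintf("line %d: non-numeric value in column %s",
                                     which(is.na(v))[1], nm))
          v
        },
        character = col,
        stop("unknown column type: ", extra_cols[[j]]))
    }
  }
  out
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()] on valid records: writes tab-separated lines with
#' no header, 0-based half-open coordinates.
#'
#' @param x Data frame with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand` and any further columns are appended in the
#'   order given by `extra_cols`.
#' @param path Output path.
#' @param extra_cols Character vector of additional column names to write
#'   after the first six.
#' @export
write_bed <- function(x, path, extra_cols = character()) {
  cols <- list(x$chrom, x$start, x$end)
  if (!is.null(x$name)) {
    cols <- c(cols, list(x$name,
                         if (is.null(x$score)) rep(0, nrow(x)) else x$score,
                         if (is.null(x$strand)) rep(".", nrow(x)) else x$strand))
  }
  for (nm in extra_cols) cols <- c(cols, list(x[[nm]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model BED6 file
#'
#' @param path Path to a BED6 file whose name column carries gene ids.
#' @return Data frame with `gene_id`, `chrom`, `start`, `end`, `strand` and
#'   the derived `tss` (`start` on `+`, `end - 1` on `-`).
#' @export
read_genes_bed <- function(path) {
  x <- read_bed(path, n_cols = 6L)
  if (nrow(x) == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      stringsAsFactors = FALSE))
  bad <- which(!x$strand %in% c("+", "-"))
  if (length(bad) > 0L)
    stop(sprintf("line %d: gene strand must be + or -", bad[1]))
  if (anyDuplicated(x$name))
    stop("duplicated gene id: ", x$name[duplicated(x$name)][1])
  data.frame(gene_id = x$name, chrom = x$chrom, start = x$start, end = x$end,
             strand = x$strand,
             tss = ifelse(x$strand == "+", x$start, x$end - 1L),
             stringsAsFactors = FALSE)
}

#' Write a gene-model table as BED6
#' @param genes Gene table as returned by [read_genes_bed()].
#' @param path Output path.
#' @export
write_genes_bed <- function(genes, path) {
  write_bed(data.frame(chrom = genes$chrom, start = genes$start,
                       end = genes$end, name = genes$gene_id, score = 0,
                       strand = genes$strand, stringsAsFactors = FALSE),
            path)
}

## Peak BED dialect: BED6 (name = peak id, strand "."), then
## col 7 = summit offset from start, cols 8-10 = heights in populations
## 2/3/4, cols 11-13 = 0/1 called flags for populations 2/3/4.

#' Read a peak BED6+7 file
#'
#' @param path Path to a peak BED file in the package dialect (summit offset
#'   and per-population heights/calls as columns 7-13).
#' @return Data frame with `peak_id`, `chrom`, `start`, `end`, `summit`
#'   (absolute coordinate), heights `h2`,`h3`,`h4` and logical calls
#'   `called2`,`called3`,`called4`.
#' @export
read_peaks_bed <- function(path) {
  x <- read_bed(path, n_cols = 6L,
                extra_cols = c(summit_offset = "integer",
                               h2 = "numeric", h3 = "numeric", h4 = "numeric",
                               c2 = "integer", c3 = "integer", c4 = "integer"))
  if (nrow(x) == 0L) return(empty_peaks())
  if (anyDuplicated(x$name))
    stop("duplicated peak id: ", x$name[duplicated(x$name)][1])
  summit <- x$start + x$summit_offset
  bad <- which(summit < x$start | summit >= x$end)
  if (length(bad) > 0L)
    stop(sprintf("peak %s: summit outside [start, end)", x$name[bad[1]]))
  data.frame(peak_id = x$name, chrom = x$chrom, start = x$start, end = x$end,
             summit = summit, h2 = x$h2, h3 = x$h3, h4 = x$h4,
             called2 = x$c2 == 1L, called3 = x$c3 == 1L, called4 = x$c4 == 1L,
             stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(peak_id = character(), chrom = character(), start = integer(),
             end = integer(), summit = integer(), h2 = numeric(),
             h3 = numeric(), h4 = numeric(), called2 = logical(),
             called3 = logical(), called4 = logical(), stringsAsFactors = FALSE)
}

#' Write a peak table in the package BED dialect
#' @param peaks Peak table as returned by [read_peaks_bed()].
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  x <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                  name = peaks$peak_id, score = 0, strand = ".",
                  summit_offset = peaks$summit - peaks$start,
                  h2 = sprintf("%.3f", peaks$h2),
                  h3 = sprintf("%.3f", peaks$h3),
                  h4 = sprintf("%.3f", peaks$h4),
                  c2 = as.integer(peaks$called2),
                  c3 = as.integer(peaks$called3),
                  c4 = as.integer(peaks$called4),
                  stringsAsFactors = FALSE)
  write_bed(x, path, extra_cols = c("summit_offset", "h2", "h3", "h4",
                                    "c2", "c3", "c4"))
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased; letters outside A/C/G/T/N are rejected, as are
#' duplicate record ids.
#'
#' @param path Path to an uncompressed FASTA file.
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(stats::setNames(character(), character()))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record ", ids[bad][1], ": letters outside {A,C,G,T,N}")
  stats::setNames(seqs, ids)
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of A/C/G/T/N sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' Expects a header row naming a gene-id column followed by exactly four
#' population columns; values must be numeric and complete, gene ids unique.
#'
#' @param path Path to the TSV.
#' @param platform Platform label attached to the returned matrix.
#' @return Numeric matrix (genes x 4) with gene ids as rownames and a
#'   `platform` attribute.
#' @export
read_expression_tsv <- function(path, platform = NA_character_) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (ncol(x) != 5L)
    stop("expected 5 columns (gene id + 4 populations), found ", ncol(x))
  ids <- x[[1]]
  if (anyDuplicated(ids))
    stop("duplicated gene id: ", ids[duplicated(ids)][1])
  m <- matrix(NA_real_, nrow = nrow(x), ncol = 4L,
              dimnames = list(ids, colnames(x)[2:5]))
  for (j in 2:5) {
    v <- suppressWarnings(as.numeric(x[[j]]))
    if (anyNA(v))
      stop(sprintf("non-numeric value at row %d, column %s",
                   which(is.na(v))[1], colnames(x)[j]))
    m[, j - 1L] <- v
  }
  attr(m, "platform") <- platform
  m
}

#' Write an expression matrix as TSV
#' @param m Genes x 4 numeric matrix with rownames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(is.matrix(m), ncol(m) == 4L, !is.null(rownames(m)))
  hdr <- paste(c("gene_id", colnames(m)), collapse = "\t")
  lines <- paste(rownames(m),
                 sprintf("%.4f", m[, 1]), sprintf("%.4f", m[, 2]),
                 sprintf("%.4f", m[, 3]), sprintf("%.4f", m[, 4]),
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a knockout replicate expression table
#'
#' Column names encode genotype and replicate structure as
#' `<genotype>_b<i>_t<j>` (e.g. `het_b1_t2`, `null_b2_t1`).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix (genes x replicates) with gene rownames; the
#'   genotype of each column is recoverable from its name.
#' @export
read_ko_tsv <- function(path) {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- x[[1]]
  if (anyDuplicated(ids)) stop("duplicated gene id: ", ids[duplicated(ids)][1])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in KO table")
  rownames(m) <- ids
  if (!all(grepl("^[A-Za-z0-9]+_b[0-9]+_t[0-9]+$", colnames(m))))
    stop("KO column names must follow <genotype>_b<i>_t<j>")
  m
}

#' Write a knockout replicate expression table
#' @param m Genes x replicates numeric matrix, columns named
#'   `<genotype>_b<i>_t<j>`.
#' @param path Output path.
#' @export
write_ko_tsv <- function(m, path) {
  hdr <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- apply(m, 1, function(v) paste(sprintf("%.4f", v), collapse = "\t"))
  writeLines(c(hdr, paste(rownames(m), body, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Accepts four-column bedGraph only (no fixed-step variants). Intervals on
#' each chromosome must be sorted and non-overlapping with non-negative
#' values.
#'
#' @param path Path to the bedGraph file.
#' @return Data frame with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- read_bed(path, extra_cols = c(value = "numeric"), n_cols = 3L)
  if (nrow(x) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  if (any(x$value < 0)) stop("negative coverage value")
  for (ch in unique(x$chrom)) {
    y <- x[x$chrom == ch, ]
    y <- y[order(y$start), ]
    if (nrow(y) > 1L && any(y$start[-1] < y$end[-nrow(y)]))
      stop("overlapping coverage intervals on ", ch)
  }
  x[order(x$chrom, x$start), c("chrom", "start", "end", "value")]
}

#' Write a coverage track as bedGraph
#' @param cov Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, path) {
  writeLines(paste(cov$chrom, cov$start, cov$end,
                   sprintf("%.4f", cov$value), sep = "\t"), path)
  invisible(path)
}

#' Read a simulation truth file
#' @param path Path to `truth.json` written by [simulate_dataset()].
#' @return The truth list (see [generate_expression()] and friends).
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
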