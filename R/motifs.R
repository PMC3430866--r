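## Consensus-motif analysis on peak cores: central-200-bp extraction with
## repeat masking, degenerate (IUPAC) scanning on both strands, extended
## GATA-consensus counting against the uniform 1-in-4 expectation, and
## clustering of the binary peak-annotation table.

iupac_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

## per-letter logical match table: pattern letter x subject letter.
## Subject N never matches any pattern code.
iupac_match_table <- function() {
  sets <- iupac_sets()
  subj <- c("A", "C", "G", "T", "N")
  tab <- matrix(FALSE, length(sets), length(subj),
                dimnames = list(names(sets), subj))
  for (p in names(sets)) tab[p, sets[[p]]] <- TRUE
  tab
}

#' Extract peak cores for motif scanning
#'
#' Takes the centred `core_bp` (default 200 bp) substring of each peak's
#' sequence (the whole sequence if shorter) and excludes cores whose
#' masked-base fraction exceeds `repeat_fraction`. Masked bases are
#' determined from the repeat mask projected onto the peak's coordinates;
#' when no mask is given, lower-case or `N` letters in the input sequence
#' count as masked.
#'
#' @param peaks Peak table.
#' @param sequences Named character vector of peak sequences; each must
#'   have exactly the peak's width.
#' @param repeat_mask Optional repeat-mask intervals (`chrom`, `start`,
#'   `end`), or `NULL`.
#' @param cfg A [pipeline_config()].
#' @return List with `cores` (named character vector, upper-case) and
#'   `excluded` (data frame `peak_id`, `masked_fraction`).
#' @export
extract_cores <- function(peaks, sequences, repeat_mask = NULL,
                          cfg = pipeline_config()) {
  if (nrow(peaks) == 0L)
    return(list(cores = character(),
                excluded = data.frame(peak_id = character(),
                                      masked_fraction = numeric(),
                                      stringsAsFactors = FALSE)))
  cores <- character(0)
  excl <- list()
  have_mask <- !is.null(repeat_mask) && nrow(repeat_mask) > 0
  mk <- if (have_mask) mask_granges(repeat_mask) else NULL
  for (i in seq_len(nrow(peaks))) {
    pid <- peaks$peak_id[i]
    seq <- sequences[[pid]]
    if (is.null(seq) || is.na(seq))
      stop("no sequence for peak ", pid)
    w <- peaks$end[i] - peaks$start[i]
    if (nchar(seq) != w)
      stop(sprintf("peak %s: sequence length %d != peak width %d",
                   pid, nchar(seq), w))
    core_len <- min(cfg$core_bp, w)
    off <- (w - core_len) %/% 2L               # 0-based offset into the peak
    core <- substr(seq, off + 1L, off + core_len)
    if (have_mask) {
      core_gr <- GenomicRanges::GRanges(
        peaks$chrom[i],
        IRanges::IRanges(start = peaks$start[i] + off + 1L,
                         width = core_len))
      ov <- GenomicRanges::findOverlaps(core_gr, mk)
      masked <- if (length(ov) == 0L) 0L else
        sum(IRanges::width(IRanges::pintersect(
          rep(core_gr, length(ov)), mk[S4Vectors::subjectHits(ov)])))
    } else {
      masked <- sum(strsplit(core, NULL)[[1]] %in%
                      c("a", "c", "g", "t", "n", "N"))
    }
    frac <- masked / core_len
    if (frac > cfg$repeat_fraction) {
      excl[[length(excl) + 1L]] <-
        data.frame(peak_id = pid, masked_fraction = frac,
                   stringsAsFactors = FALSE)
    } else {
      cores[pid] <- toupper(core)
    }
  }
  list(cores = cores,
       excluded = if (length(excl) > 0) do.call(rbind, excl) else
         data.frame(peak_id = character(), masked_fraction = numeric(),
                    stringsAsFactors = FALSE))
}

#' Scan a sequence for an IUPAC consensus motif on both strands
#'
#' Reports every offset (0-based) where the motif matches the forward
#' strand, plus every offset where its reverse complement matches (a
#' `-`-strand hit). Overlapping matches are all reported; `N` in the
#' subject sequence matches no code.
#'
#' @param seq A/C/G/T/N character scalar.
#' @param motif IUPAC consensus (A/C/G/T plus R,Y,S,W,K,M,B,D,H,V,N).
#' @return Data frame with `offset` (0-based) and `strand` (`+`/`-`),
#'   ordered by offset.
#' @export
scan_consensus <- function(seq, motif) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(motif), length(motif) == 1L, nchar(motif) > 0L)
  motif <- toupper(motif)
  if (grepl("[^ACGTRYSWKMBDHVN]", motif))
    stop("invalid IUPAC letter in motif: ", motif)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    stop("sequence letters outside {A,C,G,T,N}")
  fwd <- scan_one_strand(seq, motif)
  rev <- scan_one_strand(seq, revcomp(motif))
  out <- rbind(
    if (length(fwd) > 0) data.frame(offset = fwd, strand = "+",
                                    stringsAsFactors = FALSE),
    if (length(rev) > 0) data.frame(offset = rev, strand = "-",
                                    stringsAsFactors = FALSE))
  if (is.null(out))
    return(data.frame(offset = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## vectorized single-strand scan: one logical vector per motif position
scan_one_strand <- function(seq, motif) {
  L <- nchar(seq)
  m <- nchar(motif)
  if (L < m) return(integer(0))
  tab <- iupac_match_table()
  sletters <- strsplit(seq, NULL)[[1]]
  mletters <- strsplit(motif, NULL)[[1]]
  n_off <- L - m + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(m)) {
    ok <- ok & tab[mletters[j], sletters[j:(j + n_off - 1L)]]
  }
  which(ok) - 1L
}

#' Count core-motif matches sitting in an extended consensus
#'
#' Scans every core for `core_motif` on both strands and counts how many
#' matches are immediately followed (3' of the match, strand-aware) by
#' `extension_base`. The expected count under a uniform background is
#' `n_total / 4`, rounded half-up, exactly the back-of-envelope expectation
#' used when judging whether the extension is overrepresented. Matches at
#' a sequence edge with no 3' base count towards `n_total` but are not
#' eligible for extension; the binomial test is computed on the eligible
#' matches against p = 1/4.
#'
#' @param cores Named character vector of core sequences.
#' @param core_motif IUPAC core motif (e.g. `WGATA`).
#' @param extension_base Single extension base (e.g. `A`).
#' @return List with `n_total`, `n_extended`, `n_expected`, `n_eligible`
#'   and `p_binomial`.
#' @export
extended_consensus_counts <- function(cores, core_motif = "WGATA",
                                      extension_base = "A") {
  stopifnot(nchar(extension_base) == 1L)
  extension_base <- toupper(extension_base)
  m <- nchar(core_motif)
  n_total <- 0L
  n_ext <- 0L
  n_elig <- 0L
  for (seq in cores) {
    seq <- toupper(seq)
    hits <- scan_consensus(seq, core_motif)
    n_total <- n_total + nrow(hits)
    if (nrow(hits) == 0L) next
    L <- nchar(seq)
    for (k in seq_len(nrow(hits))) {
      off <- hits$offset[k]
      if (hits$strand[k] == "+") {
        pos <- off + m          # 0-based position just 3' of the match
        if (pos >= L) next
        nb <- substr(seq, pos + 1L, pos + 1L)
      } else {
        if (off == 0L) next
        nb <- revcomp(substr(seq, off, off))
      }
      n_elig <- n_elig + 1L
      if (nb == extension_base) n_ext <- n_ext + 1L
    }
  }
  p <- if (n_elig > 0)
    stats::binom.test(n_ext, n_elig, p = 0.25)$p.value else NA_real_
  list(n_total = n_total, n_extended = n_ext,
       n_expected = as.integer(round_half_up(n_total / 4)),
       n_eligible = n_elig, p_binomial = p)
}

#' Build the binary peak-annotation matrix
#'
#' One row per retained peak; binary columns: membership of the `"2,3,4"`
#' partition, promoter location (highest-priority category), and presence
#' of the novel, regulator (Runx) and Gata consensus motifs in the peak
#' core.
#'
#' @param peaks Retained peak table.
#' @param partition Data frame from [partition_peaks()].
#' @param links Data frame from [assign_peaks()].
#' @param motif_hits Named list of character vectors of peak ids with at
#'   least one hit, with names `new`, `runx`, `gata`.
#' @return Binary integer matrix with peak-id rownames and columns
#'   `in_234`, `promoter`, `has_new_motif`, `has_runx_motif`,
#'   `has_gata_motif`.
#' @export
build_annotation_matrix <- function(peaks, partition, links, motif_hits) {
  ids <- peaks$peak_id
  part <- stats::setNames(partition$partition, partition$peak_id)[ids]
  prom_peaks <- unique(links$peak_id[links$category == "promoter"])
  m <- cbind(in_234 = as.integer(part == "2,3,4"),
             promoter = as.integer(ids %in% prom_peaks),
             has_new_motif = as.integer(ids %in% motif_hits$new),
             has_runx_motif = as.integer(ids %in% motif_hits$runx),
             has_gata_motif = as.integer(ids %in% motif_hits$gata))
  rownames(m) <- ids
  m
}

## Jaccard distance on binary rows; two all-zero rows are identical
## (distance 0) by convention.
jaccard_dist <- function(m) {
  inter <- m %*% t(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  stats::as.dist(d)
}

#' Cluster the binary annotation matrix
#'
#' Agglomerative clustering of peaks with Jaccard distance and average
#' linkage; rows are pre-sorted by peak id so the result is deterministic
#' regardless of input order.
#'
#' @param m Binary matrix from [build_annotation_matrix()].
#' @return List with `order` (peak ids in dendrogram leaf order) and
#'   `hclust` (the tree; `NULL` for a single row).
#' @export
cluster_annotation <- function(m) {
  if (nrow(m) < 1L) stop("annotation matrix has no rows")
  m <- m[order(rownames(m)), , drop = FALSE]
  if (nrow(m) == 1L) return(list(order = rownames(m), hclust = NULL))
  hc <- stats::hclust(jaccard_dist(m), method = "average")
  list(order = rownames(m)[hc$order], hclust = hc)
}

#' Association between promoter location and the novel motif
#'
#' Two-sided Fisher exact test on the 2x2 contingency of promoter status
#' versus novel-motif presence across peaks.
#'
#' @param m Binary matrix from [build_annotation_matrix()].
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
motif_promoter_association <- function(m) {
  stopifnot(all(c("promoter", "has_new_motif") %in% colnames(m)))
  tab <- matrix(c(sum(m[, "promoter"] == 1 & m[, "has_new_motif"] == 1),
                  sum(m[, "promoter"] == 1 & m[, "has_new_motif"] == 0),
                  sum(m[, "promoter"] == 0 & m[, "has_new_motif"] == 1),
                  sum(m[, "promoter"] == 0 & m[, "has_new_motif"] == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(promoter = c("yes", "no"),
                                new_motif = c("yes", "no")))
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p)
}
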