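## Peak-to-gene annotation: summit-anchored assignment with priority
## promoter > intragenic > intergenic, a symmetric promoter window around
## the TSS, and intergenic linking to the nearest gene on each side of the
## summit within the linking window.

#' Assign peaks to genes
#'
#' Category is decided by the summit position with priority
#' promoter > intragenic > intergenic: (1) promoter if the summit lies
#' within `promoter_window_bp` of some gene's TSS (all qualifying genes
#' linked, distance = |summit - TSS|); (2) otherwise intragenic if the
#' summit lies inside a gene body `[start, end)` (all containing genes
#' linked, distance 0); (3) otherwise intergenic: the nearest gene to the
#' left and the nearest gene to the right of the summit (in chromosome
#' coordinates) are each linked if their nearest boundary is within
#' `intergenic_window_bp`, as `intergenic_5prime` (left) and
#' `intergenic_3prime` (right). Peaks with no qualifying gene yield no
#' links. Chromosomes present in only one of the two inputs trigger a
#' warning listing the orphans.
#'
#' @param peaks Peak table.
#' @param genes Gene table.
#' @param cfg A [pipeline_config()].
#' @return Data frame with `peak_id`, `gene_id`, `category`, `distance`
#'   (bp; 0 for intragenic). Each (peak, gene) pair appears at most once.
#' @export
assign_peaks <- function(peaks, genes, cfg = pipeline_config()) {
  empty <- data.frame(peak_id = character(), gene_id = character(),
                      category = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(empty)
  orphan <- union(setdiff(unique(peaks$chrom), unique(genes$chrom)),
                  setdiff(unique(genes$chrom), unique(peaks$chrom)))
  if (length(orphan) > 0)
    warning("chromosomes present in only one input: ",
            paste(sort(orphan), collapse = ", "))
  out <- vector("list", nrow(peaks))
  genes_by_chrom <- split(genes, genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    g <- genes_by_chrom[[peaks$chrom[i]]]
    if (is.null(g) || nrow(g) == 0L) next
    s <- peaks$summit[i]
    links <- NULL
    prom <- which(abs(s - g$tss) <= cfg$promoter_window_bp)
    if (length(prom) > 0) {
      links <- data.frame(gene_id = g$gene_id[prom], category = "promoter",
                          distance = abs(s - g$tss[prom]),
                          stringsAsFactors = FALSE)
    } else {
      intra <- which(s >= g$start & s < g$end)
      if (length(intra) > 0) {
        links <- data.frame(gene_id = g$gene_id[intra], category = "intragenic",
                            distance = 0L, stringsAsFactors = FALSE)
      } else {
        ## nearest gene on each side of the summit; a gene is "left" if its
        ## whole body is left of the summit (we already know s is outside
        ## every gene body)
        left <- g[g$end <= s, , drop = FALSE]
        right <- g[g$start > s, , drop = FALSE]
        rows <- list()
        if (nrow(left) > 0) {
          dl <- s - (left$end - 1L)
          keep <- which(dl == min(dl) & dl <= cfg$intergenic_window_bp)
          if (length(keep) > 0)
            rows <- c(rows, list(data.frame(gene_id = left$gene_id[keep],
                                            category = "intergenic_5prime",
                                            distance = dl[keep],
                                            stringsAsFactors = FALSE)))
        }
        if (nrow(right) > 0) {
          dr <- right$start - s
          keep <- which(dr == min(dr) & dr <= cfg$intergenic_window_bp)
          if (length(keep) > 0)
            rows <- c(rows, list(data.frame(gene_id = right$gene_id[keep],
                                            category = "intergenic_3prime",
                                            distance = dr[keep],
                                            stringsAsFactors = FALSE)))
        }
        if (length(rows) > 0) links <- do.call(rbind, rows)
      }
    }
    if (!is.null(links)) {
      links$peak_id <- peaks$peak_id[i]
      out[[i]] <- links[, c("peak_id", "gene_id", "category", "distance")]
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Candidate target genes from peak-gene links
#' @param links Data frame from [assign_peaks()] (links from any number of
#'   peak sets may be concatenated first).
#' @return Sorted character vector of distinct linked gene ids.
#' @export
candidate_targets <- function(links) {
  sort(unique(links$gene_id))
}

#' Peak-location breakdown per partition
#'
#' Counts each peak once in its highest-priority category (promoter >
#' intragenic > intergenic); unlinked peaks are reported separately, so
#' category counts plus the unlinked count sum to the partition size.
#'
#' @param links Data frame from [assign_peaks()].
#' @param partition Data frame `peak_id`, `partition` from
#'   [partition_peaks()].
#' @return Data frame with `partition`, `promoter`, `intragenic`,
#'   `intergenic`, `unlinked`, `total`.
#' @export
location_breakdown <- function(links, partition) {
  prio <- c(promoter = 1L, intragenic = 2L,
            intergenic_5prime = 3L, intergenic_3prime = 3L)
  cat3 <- c(promoter = "promoter", intragenic = "intragenic",
            intergenic_5prime = "intergenic", intergenic_3prime = "intergenic")
  best <- rep(NA_character_, nrow(partition))
  names(best) <- partition$peak_id
  if (nrow(links) > 0) {
    sp <- split(links$category, links$peak_id)
    top <- vapply(sp, function(cats) cat3[[cats[which.min(prio[cats])]]],
                  character(1))
    best[names(top)] <- top
  }
  out <- lapply(unique(partition$partition), function(p) {
    b <- best[partition$partition == p]
    data.frame(partition = p,
               promoter = sum(b == "promoter", na.rm = TRUE),
               intragenic = sum(b == "intragenic", na.rm = TRUE),
               intergenic = sum(b == "intergenic", na.rm = TRUE),
               unlinked = sum(is.na(b)),
               total = length(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
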