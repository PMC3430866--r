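## Expression-dynamics stage: select dynamically expressed genes, correlate
## each with the regulator over the four populations, classify with
## inclusive cutoffs, require two-platform consensus, and provide a
## permutation control for the correlation structure.

#' Filter dynamically expressed genes
#'
#' A gene is kept iff the sample standard deviation of its four
#' log2(value + 1) expression values exceeds `sd_threshold` and its maximum
#' linear value exceeds `min_expression`. The variability criterion works
#' on the log scale (the array convention under which an SD threshold of 1
#' is meaningful) while the intensity floor applies to linear values.
#'
#' @param expr Genes x 4 linear expression matrix with gene-id rownames.
#' @param cfg A [pipeline_config()].
#' @return Character vector of retained gene ids (possibly empty).
#' @export
filter_dynamic <- function(expr, cfg = pipeline_config()) {
  stopifnot(is.matrix(expr), ncol(expr) == 4L, !is.null(rownames(expr)))
  lg <- log2(expr + 1)
  sds <- apply(lg, 1, stats::sd)
  mx <- apply(expr, 1, max)
  rownames(expr)[sds > cfg$sd_threshold & mx > cfg$min_expression]
}

#' Pearson correlation of each dynamic gene with the regulator
#'
#' Computes the four-point Pearson correlation between every gene in
#' `dynamic_set` and the regulator's expression profile. Profiles are
#' correlated on the log2(value + 1) scale, the scale on which array
#' intensities are conventionally analysed (and on which the dynamic
#' filter's SD threshold operates). Genes with zero variance across the
#' populations get `NA` and are destined for the unclassified label.
#'
#' @param expr Genes x 4 linear expression matrix.
#' @param regulator_gene Gene id of the regulator (must be a rowname).
#' @param dynamic_set Character vector of gene ids to correlate (default:
#'   all rows).
#' @return Data frame with `gene_id` and `pcc`.
#' @export
correlate_with_regulator <- function(expr, regulator_gene,
                                     dynamic_set = rownames(expr)) {
  if (!regulator_gene %in% rownames(expr))
    stop("regulator gene ", regulator_gene, " absent from expression matrix")
  dynamic_set <- intersect(dynamic_set, rownames(expr))
  lg <- log2(expr + 1)
  reg <- lg[regulator_gene, ]
  pcc <- vapply(dynamic_set, function(g) {
    v <- lg[g, ]
    if (stats::sd(v) == 0 || stats::sd(reg) == 0) return(NA_real_)
    stats::cor(v, reg)
  }, numeric(1))
  data.frame(gene_id = dynamic_set, pcc = unname(pcc),
             stringsAsFactors = FALSE)
}

#' Classify correlation records
#'
#' Labels are `positive` iff `pcc >= pos_cut`, `negative` iff
#' `pcc <= neg_cut`, otherwise `unclassified` (including genes without a
#' correlation). Both boundaries are inclusive.
#'
#' @param records Data frame from [correlate_with_regulator()].
#' @param cfg A [pipeline_config()].
#' @return The records with a `label` column added.
#' @export
classify_correlations <- function(records, cfg = pipeline_config()) {
  lab <- rep("unclassified", nrow(records))
  lab[!is.na(records$pcc) & records$pcc >= cfg$pos_cut] <- "positive"
  lab[!is.na(records$pcc) & records$pcc <= cfg$neg_cut] <- "negative"
  records$label <- lab
  records
}

#' Two-platform consensus labels
#'
#' A gene is labelled `positive` (or `negative`) only if both platforms
#' assign it that same label; any disagreement, or absence from either
#' platform, yields `unclassified`.
#'
#' @param labelsA,labelsB Classified record data frames (with `gene_id`
#'   and `label`) from the two platforms.
#' @return Data frame with `gene_id` (union of both platforms) and
#'   `label`.
#' @export
platform_consensus <- function(labelsA, labelsB) {
  ids <- union(labelsA$gene_id, labelsB$gene_id)
  la <- stats::setNames(labelsA$label, labelsA$gene_id)[ids]
  lb <- stats::setNames(labelsB$label, labelsB$gene_id)[ids]
  lab <- ifelse(!is.na(la) & !is.na(lb) & la == lb &
                  la %in% c("positive", "negative"),
                la, "unclassified")
  data.frame(gene_id = ids, label = unname(lab), stringsAsFactors = FALSE)
}

#' Permutation null distribution of regulator correlations
#'
#' For each permutation, the four population values of every gene are
#' independently shuffled (preserving each gene's value multiset) and the
#' Pearson correlation with the unshuffled regulator recomputed on the
#' log2(value + 1) scale, as in [correlate_with_regulator()]; the pooled
#' correlations form an empirical null for the observed correlation
#' structure.
#'
#' @param expr Genes x 4 linear expression matrix.
#' @param regulator_gene Gene id of the regulator.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param gene_set Genes to permute (default: all except the regulator).
#' @return Numeric vector of pooled null correlations (`NA`s from
#'   zero-variance genes dropped).
#' @export
randomized_control <- function(expr, regulator_gene, n_permutations = 100L,
                               seed = 1L,
                               gene_set = setdiff(rownames(expr), regulator_gene)) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (!regulator_gene %in% rownames(expr))
    stop("regulator gene absent from expression matrix")
  set.seed(stage_seed(seed, "null"))
  lg <- log2(expr + 1)
  reg <- lg[regulator_gene, ]
  sub <- lg[intersect(gene_set, rownames(expr)), , drop = FALSE]
  out <- numeric(0)
  for (p in seq_len(n_permutations)) {
    shuffled <- t(apply(sub, 1, sample))
    cc <- suppressWarnings(stats::cor(t(shuffled), reg))
    out <- c(out, cc[!is.na(cc)])
  }
  as.numeric(out)
}
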