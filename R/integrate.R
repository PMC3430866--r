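## Target-set integration: knockout differential calls, hypergeometric
## gene-set overlap, and the triple intersection of correlation, binding
## and loss-of-function evidence into positively- and
## negatively-controlled target sets.

#' Call differential genes from the knockout replicate table
#'
#' Technical replicates are averaged (linear scale) into biological
#' replicates per genotype. Per gene, the fold change is
#' `mean(het) / mean(null)` on the linear scale. The p-value comes either
#' from limma's moderated t statistic on the log2 biological-replicate
#' values (default; the standard small-sample array statistic, which
#' borrows variance information across genes) or from a per-gene two-sided
#' unequal-variance t-test (`method = "ttest"`). A gene is `down_in_null`
#' iff fold >= `ko_fold` and p < `ko_alpha`; `up_in_null` iff
#' fold <= 1/`ko_fold` and p < `ko_alpha`; otherwise `unchanged`.
#'
#' @param ko Genes x replicates linear matrix with columns named
#'   `<genotype>_b<i>_t<j>`; genotypes must be `het` and `null` with at
#'   least 2 biological replicates each.
#' @param cfg A [pipeline_config()].
#' @param method `"limma"` (moderated t) or `"ttest"` (per-gene Welch).
#' @return Data frame with `gene_id`, `log2fc` (het minus null), `fold`
#'   (linear), `p_value`, `direction`.
#' @export
ko_differential <- function(ko, cfg = pipeline_config(),
                            method = c("limma", "ttest")) {
  method <- match.arg(method)
  cn <- colnames(ko)
  parts <- regmatches(cn, regexec("^([A-Za-z0-9]+)_b([0-9]+)_t[0-9]+$", cn))
  geno <- vapply(parts, `[`, character(1), 2)
  bio <- paste(geno, vapply(parts, `[`, character(1), 3), sep = "_b")
  if (!setequal(unique(geno), c("het", "null")))
    stop("KO table must contain genotypes 'het' and 'null'")
  ## average technical replicates into biological replicates (linear scale)
  bios <- unique(bio)
  bm <- vapply(bios, function(b)
    rowMeans(ko[, bio == b, drop = FALSE]), numeric(nrow(ko)))
  bgeno <- sub("_b[0-9]+$", "", bios)
  if (sum(bgeno == "het") < 2L || sum(bgeno == "null") < 2L)
    stop("need at least 2 biological replicates per genotype")
  het <- bm[, bgeno == "het", drop = FALSE]
  nul <- bm[, bgeno == "null", drop = FALSE]
  fold <- rowMeans(het) / rowMeans(nul)
  lhet <- log2(het)
  lnul <- log2(nul)
  if (method == "limma") {
    mat <- cbind(lnul, lhet)
    design <- cbind(intercept = 1,
                    het = c(rep(0, ncol(lnul)), rep(1, ncol(lhet))))
    fit <- limma::eBayes(limma::lmFit(mat, design))
    p <- fit$p.value[, "het"]
  } else {
    p <- vapply(seq_len(nrow(ko)), function(i) {
      if (stats::sd(lhet[i, ]) == 0 && stats::sd(lnul[i, ]) == 0) {
        if (mean(lhet[i, ]) == mean(lnul[i, ])) return(1)
        return(0)
      }
      stats::t.test(lhet[i, ], lnul[i, ])$p.value
    }, numeric(1))
  }
  direction <- rep("unchanged", nrow(ko))
  direction[fold >= cfg$ko_fold & p < cfg$ko_alpha] <- "down_in_null"
  direction[fold <= 1 / cfg$ko_fold & p < cfg$ko_alpha] <- "up_in_null"
  data.frame(gene_id = rownames(ko),
             log2fc = rowMeans(lhet) - rowMeans(lnul),
             fold = fold, p_value = as.numeric(p), direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability of observing at least the seen overlap when
#' `|set_b|` genes are drawn without replacement from a universe
#' containing `|set_a|` successes.
#'
#' @param set_a,set_b Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector defining the sampling frame.
#' @return List with `set_a_size`, `set_b_size`, `universe_size`,
#'   `overlap`, `p_hyper`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) + length(out_b) > 0)
    stop("elements outside universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a),
                     length(universe) - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(set_a_size = length(set_a), set_b_size = length(set_b),
       universe_size = length(universe), overlap = k, p_hyper = p)
}

#' Intersect correlation, knockout and binding evidence
#'
#' The positively-controlled set is the intersection of the
#' positive-consensus genes, the genes down in the null genotype, and the
#' bound genes; the negatively-controlled set intersects the
#' negative-consensus genes, the genes up in the null, and the bound
#' genes. All single, pairwise and triple intersection sizes are reported
#' for Venn rendering.
#'
#' @param consensus_labels Data frame `gene_id`, `label` from
#'   [platform_consensus()].
#' @param ko_records Data frame from [ko_differential()].
#' @param bound_genes Character vector of genes with at least one peak
#'   link.
#' @return List with `positively_controlled`, `negatively_controlled`
#'   (sorted gene ids) and `venn` (named list of intersection counts for
#'   both directions).
#' @export
controlled_target_sets <- function(consensus_labels, ko_records, bound_genes) {
  pos <- consensus_labels$gene_id[consensus_labels$label == "positive"]
  neg <- consensus_labels$gene_id[consensus_labels$label == "negative"]
  down <- ko_records$gene_id[ko_records$direction == "down_in_null"]
  up <- ko_records$gene_id[ko_records$direction == "up_in_null"]
  bound <- unique(bound_genes)
  venn3 <- function(a, b, c) {
    list(n_a = length(a), n_b = length(b), n_c = length(c),
         ab = length(intersect(a, b)), ac = length(intersect(a, c)),
         bc = length(intersect(b, c)),
         abc = length(intersect(intersect(a, b), c)),
         union = length(union(union(a, b), c)))
  }
  list(positively_controlled = sort(intersect(intersect(pos, down), bound)),
       negatively_controlled = sort(intersect(intersect(neg, up), bound)),
       venn = list(positive = venn3(pos, down, bound),
                   negative = venn3(neg, up, bound)))
}

#' Overlap of target sets with reference binding sets
#'
#' For each input gene set, the count and fraction of genes bound by all
#' reference factors and by at least one reference factor.
#'
#' @param target_sets Named list of character vectors of gene ids.
#' @param reference_bound_sets Named list (factor -> character vector of
#'   bound gene ids).
#' @return Data frame with `set`, `size`, `bound_all`, `frac_all`,
#'   `bound_any`, `frac_any`.
#' @export
reference_cobinding <- function(target_sets, reference_bound_sets) {
  if (length(reference_bound_sets) == 0) {
    all_set <- character(0); any_set <- character(0)
  } else {
    all_set <- Reduce(intersect, reference_bound_sets)
    any_set <- Reduce(union, reference_bound_sets)
  }
  out <- lapply(names(target_sets), function(nm) {
    s <- unique(target_sets[[nm]])
    n <- length(s)
    ba <- length(intersect(s, all_set))
    bo <- length(intersect(s, any_set))
    data.frame(set = nm, size = n,
               bound_all = ba, frac_all = if (n > 0) ba / n else 0,
               bound_any = bo, frac_any = if (n > 0) bo / n else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of bound genes per correlation class
#'
#' `|bound ∩ class| / |class|` for the positive, negative and unclassified
#' classes; an empty class yields `NA` (undefined), not 0.
#'
#' @param consensus_labels Data frame `gene_id`, `label`.
#' @param bound_genes Character vector of bound gene ids.
#' @return Named numeric vector with entries `positive`, `negative`,
#'   `unclassified`.
#' @export
bound_fraction_by_class <- function(consensus_labels, bound_genes) {
  bound <- unique(bound_genes)
  vapply(c(positive = "positive", negative = "negative",
           unclassified = "unclassified"), function(cl) {
    members <- consensus_labels$gene_id[consensus_labels$label == cl]
    if (length(members) == 0L) return(NA_real_)
    length(intersect(members, bound)) / length(members)
  }, numeric(1))
}
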