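## Synthetic study generator. Emulates the inputs of a four-population
## developmental timecourse around one regulator: gene models on a small
## genome, two-platform expression with planted correlated and
## anti-correlated targets, ChIP peak sets split into an early-shared and a
## late-only class with planted consensus motifs and a repeat mask, and a
## knockout replicate table with planted fold effects. Every random draw is
## tied to the config seed, so the same config reproduces byte-identical
## files, and all planted truth is recorded for downstream validation.

#' Generate non-nested gene models on the synthetic genome
#'
#' Genes are placed left to right per chromosome with random strands,
#' lengths of 3-10 kb and alternating short (1-10 kb) and long (55-80 kb)
#' intergenic gaps, so both linkable (<50 kb) and unlinkable intergenic
#' space exists. Gene ids are `g0001`, `g0002`, ... in placement order; the
#' configured regulator must be one of them.
#'
#' @param cfg A [sim_config()].
#' @return Gene table with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss` (0-based half-open; TSS is `start` on `+`, `end - 1` on `-`).
#' @export
generate_gene_models <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1: nothing to place")
  if (length(cfg$chrom_lengths) == 0L) stop("chrom_lengths is empty")
  set.seed(stage_seed(cfg$seed, "genes"))
  chroms <- names(cfg$chrom_lengths)
  ## apportion genes across chromosomes proportional to length
  share <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  n_per <- floor(share * cfg$n_genes)
  rem <- cfg$n_genes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  rows <- list()
  idx <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    len <- cfg$chrom_lengths[[ci]]
    pos <- 1000L
    for (k in seq_len(n_per[ci])) {
      gap <- if (stats::runif(1) < 0.8)
        as.integer(stats::runif(1, 1000, 10000))
      else
        as.integer(stats::runif(1, 55000, 80000))
      glen <- as.integer(stats::runif(1, 3000, 10000))
      start <- pos + gap
      end <- start + glen
      if (end >= len - 1000L)
        stop(sprintf("chromosome %s too short to place %d genes", ch, n_per[ci]))
      idx <- idx + 1L
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      rows[[idx]] <- data.frame(gene_id = sprintf("g%04d", idx), chrom = ch,
                                start = start, end = end, strand = strand,
                                stringsAsFactors = FALSE)
      pos <- end
    }
  }
  genes <- do.call(rbind, rows)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (!cfg$regulator_gene %in% genes$gene_id)
    stop("regulator_gene ", cfg$regulator_gene, " not among generated genes")
  genes
}

## log2 profile of the regulator across populations 1-4 (strictly rising)
regulator_profile <- function() c(3, 6, 8, 10)

#' Generate two-platform expression matrices with planted targets
#'
#' The regulator follows a fixed strictly increasing log2 profile across
#' populations 1-4. Planted positive targets carry the same profile plus
#' Gaussian log2 noise; planted negatives carry the affine mirror of the
#' profile (monotone decreasing, noiseless log2 correlation exactly -1)
#' plus noise; all remaining genes are flat profiles (random per-gene baseline)
#' plus noise, so they fail the dynamic-gene filter except by chance. Both
#' platforms share the planted truth but have independent noise. Values are
#' returned on the linear scale (2^log2, rounded to 4 decimals) so the
#' minimum-intensity filter is meaningful.
#'
#' @param genes Gene table from [generate_gene_models()].
#' @param cfg A [sim_config()].
#' @return List with `exprA`, `exprB` (genes x 4 linear matrices, platform
#'   attributes "A"/"B") and `truth` (list with `planted_positive_targets`,
#'   `planted_negative_targets`, `regulator_gene`).
#' @export
generate_expression <- function(genes, cfg) {
  if (cfg$fraction_positive + cfg$fraction_negative > 1)
    stop("fraction_positive + fraction_negative must be <= 1")
  if (!cfg$regulator_gene %in% genes$gene_id)
    stop("regulator gene absent from gene table")
  set.seed(stage_seed(cfg$seed, "expression"))
  ids <- genes$gene_id
  n <- length(ids)
  others <- setdiff(ids, cfg$regulator_gene)
  n_pos <- round_half_up(cfg$fraction_positive * n)
  n_neg <- round_half_up(cfg$fraction_negative * n)
  picked <- sample(others, n_pos + n_neg)
  pos <- sort(picked[seq_len(n_pos)])
  neg <- sort(picked[n_pos + seq_len(n_neg)])
  prof <- regulator_profile()
  base_flat <- stats::runif(n, 2, 9)   # per-gene flat baseline, shared by platforms
  make_platform <- function(label) {
    m <- matrix(base_flat, nrow = n, ncol = 4L)  # each row: that gene's flat baseline
    rownames(m) <- ids
    ## negatives get the affine mirror of the regulator profile, so their
    ## noiseless log2 correlation with the regulator is exactly -1
    mirror <- max(prof) + min(prof) - prof
    m[pos, ] <- matrix(prof, nrow = length(pos), ncol = 4L, byrow = TRUE)
    m[neg, ] <- matrix(mirror, nrow = length(neg), ncol = 4L, byrow = TRUE)
    noise <- matrix(stats::rnorm(n * 4L, 0, cfg$expression_noise_sd), n, 4L)
    m <- m + noise
    m[cfg$regulator_gene, ] <- prof  # regulator is exact: strictly increasing
    lin <- round(2^m, 4)
    colnames(lin) <- paste0("pop", 1:4)
    rownames(lin) <- ids
    attr(lin, "platform") <- label
    lin
  }
  exprA <- make_platform("A")
  exprB <- make_platform("B")
  truth <- list(regulator_gene = cfg$regulator_gene,
                planted_positive_targets = pos,
                planted_negative_targets = neg)
  list(exprA = exprA, exprB = exprB, truth = truth)
}

revcomp <- function(seq) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         vapply(strsplit(seq, NULL), function(ch) paste(rev(ch), collapse = ""),
                character(1)))
}

## draw one concrete instantiation of an IUPAC consensus
instantiate_iupac <- function(motif) {
  sets <- iupac_sets()
  letters <- strsplit(motif, NULL)[[1]]
  paste(vapply(letters, function(l) {
    opts <- sets[[l]]
    if (is.null(opts)) stop("invalid IUPAC letter: ", l)
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate ChIP peaks, their sequences and a repeat mask
#'
#' Peaks come in two classes with recorded truth labels: "shared" peaks are
#' called in populations 2, 3 and 4 with tightly correlated heights;
#' "late_only" peaks are called exclusively in population 4 with a height
#' at least five-fold above populations 2/3. Peak locations follow the
#' configured promoter / intragenic / near-intergenic / far-intergenic
#' fractions; promoter and intragenic peaks preferentially sit on planted
#' target genes (recorded as `peak_host_gene`), near-intergenic peaks avoid
#' planted genes so that binding truth stays unambiguous, and far
#' intergenic peaks sit beyond the linking window of any gene. Sequences
#' are uniform-random ACGT of the peak width with consensus motif
#' instances planted at recorded offsets and strands (the novel motif,
#' together with its upstream TGGGA box, is planted preferentially in
#' promoter peaks). A configurable fraction of peaks is constructed to
#' overlap the emitted repeat mask by 70% of their length.
#'
#' @param genes Gene table from [generate_gene_models()].
#' @param cfg A [sim_config()].
#' @return List with `peaks` (peak table), `sequences` (named character
#'   vector), `repeats` (data frame `chrom`,`start`,`end`) and `truth`
#'   (list with `peak_class_truth`, `peak_host_gene`, `repeat_peaks`,
#'   `planted_motif_positions`).
#' @export
generate_peaks_and_sequences <- function(genes, cfg) {
  set.seed(stage_seed(cfg$seed, "peaks"))
  w <- cfg$peak_width
  if (max(nchar(cfg$motifs)) + 12L > min(w, 200L))
    stop("planted motif longer than peak core")
  n_total <- cfg$n_peaks_shared + cfg$n_peaks_late
  if (n_total == 0L)
    return(list(peaks = empty_peaks(), sequences = character(),
                repeats = data.frame(chrom = character(), start = integer(),
                                     end = integer(), stringsAsFactors = FALSE),
                truth = list(peak_class_truth = list(), peak_host_gene = list(),
                             repeat_peaks = character(),
                             planted_motif_positions = list())))
  class_lab <- c(rep("shared", cfg$n_peaks_shared),
                 rep("late_only", cfg$n_peaks_late))
  loc <- sample(c("promoter", "intragenic", "intergenic_near", "intergenic_far"),
                n_total, replace = TRUE, prob = cfg$loc_fractions)
  ## planted target ids arrive via attribute when run inside simulate_dataset()
  planted_genes <- attr(cfg, "planted_targets")
  if (is.null(planted_genes)) planted_genes <- character(0)
  pl_set <- genes[genes$gene_id %in% planted_genes, , drop = FALSE]

  tails <- lapply(names(cfg$chrom_lengths), function(ch) {
    g <- genes[genes$chrom == ch, ]
    list(chrom = ch, from = max(g$end) + cfg$peak_width + 51000L,
         to = cfg$chrom_lengths[[ch]] - cfg$peak_width - 1000L)
  })
  far_slot <- 0L
  place_far <- function() {
    far_slot <<- far_slot + 1L
    tl <- tails[[(far_slot %% length(tails)) + 1L]]
    if (tl$to <= tl$from) stop("no far-intergenic space on ", tl$chrom)
    summit <- as.integer(stats::runif(1, tl$from, tl$to))
    list(chrom = tl$chrom, summit = summit)
  }
  near_planted <- function(chrom, summit) {
    if (nrow(pl_set) == 0L) return(FALSE)
    g <- pl_set[pl_set$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L) return(FALSE)
    any(summit >= g$start - cfg$peak_width - 51000L &
        summit <= g$end + cfg$peak_width + 51000L)
  }
  in_any_gene <- function(chrom, summit, pad = 600L) {
    g <- genes[genes$chrom == chrom, ]
    any(summit >= g$start - pad & summit < g$end + pad)
  }
  pick_host <- function() {
    use_target <- length(planted_genes) > 0 &&
      stats::runif(1) < cfg$target_host_fraction
    pool <- if (use_target) planted_genes else setdiff(genes$gene_id, planted_genes)
    genes[genes$gene_id == sample(pool, 1L), , drop = FALSE]
  }

  rows <- vector("list", n_total)
  host <- rep(NA_character_, n_total)
  for (i in seq_len(n_total)) {
    if (loc[i] == "promoter") {
      g <- pick_host()
      summit <- g$tss + as.integer(stats::runif(1, -200, 200))
      chrom <- g$chrom
      host[i] <- g$gene_id
    } else if (loc[i] == "intragenic") {
      repeat {
        g <- pick_host()
        lo <- g$start + 600L; hi <- g$end - 600L
        if (hi > lo) break
      }
      summit <- as.integer(stats::runif(1, lo, hi))
      chrom <- g$chrom
      host[i] <- g$gene_id
    } else if (loc[i] == "intergenic_near") {
      ok <- FALSE
      for (try in 1:50) {
        pool <- setdiff(genes$gene_id, planted_genes)
        g <- genes[genes$gene_id == sample(pool, 1L), , drop = FALSE]
        summit <- g$end - 1L + as.integer(stats::runif(1, 2000, 30000))
        chrom <- g$chrom
        if (summit + w < cfg$chrom_lengths[[chrom]] &&
            !in_any_gene(chrom, summit) &&
            !near_planted(chrom, summit)) { ok <- TRUE; break }
      }
      if (!ok) { p <- place_far(); chrom <- p$chrom; summit <- p$summit }
    } else {
      p <- place_far(); chrom <- p$chrom; summit <- p$summit
    }
    start <- summit - w %/% 2L
    if (start < 0L) start <- 0L
    end <- start + w
    rows[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                            summit = summit, stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, rows)
  peaks$peak_id <- sprintf("peak%04d", seq_len(n_total))

  ## heights and presence calls by class
  h2 <- h3 <- h4 <- numeric(n_total)
  shared <- class_lab == "shared"
  nh <- sum(shared)
  base <- stats::rlnorm(nh, log(20), 0.5)
  h2[shared] <- round(base * (1 + stats::rnorm(nh, 0, 0.05)), 3)
  h3[shared] <- round(base * (1 + stats::rnorm(nh, 0, 0.05)), 3)
  h4[shared] <- round(base * (1 + stats::rnorm(nh, 0, 0.05)), 3)
  nl <- sum(!shared)
  b4 <- stats::rlnorm(nl, log(30), 0.5)
  h4[!shared] <- round(b4, 3)
  h2[!shared] <- round(b4 / stats::runif(nl, 8, 15), 3)
  h3[!shared] <- round(b4 / stats::runif(nl, 6, 12), 3)
  peaks$h2 <- h2; peaks$h3 <- h3; peaks$h4 <- h4
  peaks$called2 <- shared
  peaks$called3 <- shared
  peaks$called4 <- TRUE
  peaks <- peaks[, c("peak_id", "chrom", "start", "end", "summit",
                     "h2", "h3", "h4", "called2", "called3", "called4")]

  ## repeat mask: designated peaks overlapped by 70% of their length, plus
  ## decoy intervals clear of all peaks
  n_rep <- round_half_up(cfg$repeat_peak_fraction * n_total)
  rep_idx <- if (n_rep > 0) sample(n_total, n_rep) else integer(0)
  rep_rows <- lapply(rep_idx, function(i) {
    data.frame(chrom = peaks$chrom[i],
               start = peaks$start[i] + as.integer(0.3 * w),
               end = peaks$end[i], stringsAsFactors = FALSE)
  })
  decoys <- list()
  for (k in seq_len(20)) {
    ch <- sample(names(cfg$chrom_lengths), 1L)
    s <- as.integer(stats::runif(1, 0, cfg$chrom_lengths[[ch]] - 2000L))
    e <- s + as.integer(stats::runif(1, 300, 1500))
    pk <- peaks[peaks$chrom == ch, ]
    if (!any(s < pk$end & e > pk$start))
      decoys[[length(decoys) + 1L]] <-
        data.frame(chrom = ch, start = s, end = e, stringsAsFactors = FALSE)
  }
  repeats <- do.call(rbind, c(rep_rows, decoys))
  repeats <- repeats[order(repeats$chrom, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  ## sequences with planted motif instances inside the central core
  core_off <- (w - min(200L, w)) %/% 2L
  core_len <- min(200L, w)
  seqs <- character(n_total)
  motif_truth <- list()
  is_promoter_peak <- loc == "promoter"
  for (i in seq_len(n_total)) {
    letters <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
    used <- matrix(numeric(0), ncol = 2)  # occupied [lo, hi] 0-based intervals
    recs <- list()
    plant <- function(concrete, strand) {
      len <- nchar(concrete)
      written <- if (strand == "+") concrete else revcomp(concrete)
      for (try in 1:100) {
        off <- core_off + sample.int(core_len - len + 1L, 1L) - 1L  # 0-based
        lo <- off; hi <- off + len - 1L
        clash <- nrow(used) > 0 && any(lo <= used[, 2] & hi >= used[, 1])
        if (!clash) {
          letters[(off + 1L):(off + len)] <<- strsplit(written, NULL)[[1]]
          used <<- rbind(used, c(lo, hi))
          recs[[length(recs) + 1L]] <<-
            data.frame(offset = off, motif = concrete, strand = strand,
                       stringsAsFactors = FALSE)
          return(invisible(TRUE))
        }
      }
      invisible(FALSE)
    }
    for (mn in names(cfg$motifs)) {
      p <- if (mn == "new") {
        if (is_promoter_peak[i]) cfg$new_motif_promoter_prob
        else cfg$motif_probs[["new"]]
      } else cfg$motif_probs[[mn]]
      if (is.na(p) || stats::runif(1) >= p) next
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      if (mn == "new") {
        ## TGGGA box, a 0-5 bp spacer, then the TGTAGT box (one cassette)
        gap <- sample.int(6L, 1L) - 1L
        spacer <- paste(sample(c("A", "C", "T"), gap, replace = TRUE),
                        collapse = "")
        cassette <- paste0("TGGGA", spacer, "TGTAGT")
        len <- nchar(cassette)
        written <- if (strand == "+") cassette else revcomp(cassette)
        for (try in 1:100) {
          off <- core_off + sample.int(core_len - len + 1L, 1L) - 1L
          lo <- off; hi <- off + len - 1L
          clash <- nrow(used) > 0 && any(lo <= used[, 2] & hi >= used[, 1])
          if (!clash) {
            letters[(off + 1L):(off + len)] <- strsplit(written, NULL)[[1]]
            used <- rbind(used, c(lo, hi))
            tg_off <- if (strand == "+") off + 5L + gap else off
            recs[[length(recs) + 1L]] <-
              data.frame(offset = tg_off, motif = "TGTAGT", strand = strand,
                         stringsAsFactors = FALSE)
            break
          }
        }
      } else {
        plant(instantiate_iupac(cfg$motifs[[mn]]), strand)
      }
    }
    seqs[i] <- paste(letters, collapse = "")
    if (length(recs) > 0)
      motif_truth[[peaks$peak_id[i]]] <- do.call(rbind, recs)
  }
  names(seqs) <- peaks$peak_id

  truth <- list(peak_class_truth = stats::setNames(as.list(class_lab), peaks$peak_id),
                peak_host_gene = stats::setNames(as.list(host), peaks$peak_id),
                repeat_peaks = peaks$peak_id[rep_idx],
                planted_motif_positions = motif_truth)
  list(peaks = peaks, sequences = seqs, repeats = repeats, truth = truth)
}

#' Generate a knockout-vs-heterozygote replicate expression table
#'
#' Emits `n_bio_replicates * n_tech_replicates` columns per genotype
#' (default 2 x 2 per genotype, 8 columns). Planted positive targets are
#' reduced in the null genotype by their per-gene true fold (at least
#' `ko_fold`); planted negatives are increased; all other genes are
#' unchanged up to noise. Biological replicates receive independent log2
#' noise of SD `ko_noise_sd`; technical replicates add `ko_tech_noise_sd`
#' on top of their biological replicate.
#'
#' @param genes Gene table.
#' @param truth Truth list carrying `planted_positive_targets` and
#'   `planted_negative_targets` (from [generate_expression()]).
#' @param cfg A [sim_config()].
#' @return List with `ko` (genes x replicates linear matrix, columns
#'   `<genotype>_b<i>_t<j>`) and `truth` (list with `ko_effect_genes`, the
#'   per-gene true het/null linear fold).
#' @export
generate_ko_table <- function(genes, truth, cfg) {
  if (cfg$ko_fold <= 1) stop("ko_fold must be a linear ratio > 1")
  set.seed(stage_seed(cfg$seed, "ko"))
  ids <- genes$gene_id
  n <- length(ids)
  pos <- truth$planted_positive_targets
  neg <- truth$planted_negative_targets
  base <- stats::setNames(stats::runif(n, 4, 9), ids)
  eff <- stats::setNames(rep(0, n), ids)  # log2(het/null)
  spread <- function(k) cfg$ko_fold_log2_spread * stats::runif(k)
  eff[pos] <- log2(cfg$ko_fold) + spread(length(pos))
  eff[neg] <- -(log2(cfg$ko_fold) + spread(length(neg)))
  cols <- list()
  cn <- character(0)
  for (geno in c("het", "null")) {
    shift <- if (geno == "null") -eff else rep(0, n)
    for (b in seq_len(cfg$n_bio_replicates)) {
      bio <- base + shift + stats::rnorm(n, 0, cfg$ko_noise_sd)
      for (t in seq_len(cfg$n_tech_replicates)) {
        cols[[length(cols) + 1L]] <-
          round(2^(bio + stats::rnorm(n, 0, cfg$ko_tech_noise_sd)), 4)
        cn <- c(cn, sprintf("%s_b%d_t%d", geno, b, t))
      }
    }
  }
  ko <- do.call(cbind, cols)
  dimnames(ko) <- list(ids, cn)
  affected <- c(pos, neg)
  list(ko = ko,
       truth = list(ko_effect_genes =
                      stats::setNames(as.list(round(2^eff[affected], 6)), affected)))
}

## synthesize a pop4 coverage bedGraph from peak heights: a stepped
## triangular bump (100 bp steps over +/-500 bp) around each summit
peaks_to_coverage <- function(peaks, halfwidth = 500L, step = 100L) {
  if (nrow(peaks) == 0L)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      value = numeric(), stringsAsFactors = FALSE))
  pieces <- list()
  offs <- seq(-halfwidth, halfwidth - step, by = step)
  for (i in seq_len(nrow(peaks))) {
    centers <- offs + step / 2
    vals <- peaks$h4[i] * (1 - abs(centers) / halfwidth)
    s <- peaks$summit[i] + offs
    keep <- s >= 0 & vals > 0
    pieces[[i]] <- data.frame(chrom = peaks$chrom[i], start = s[keep],
                              end = s[keep] + step, value = vals[keep],
                              stringsAsFactors = FALSE)
  }
  cov <- do.call(rbind, pieces)
  ## flatten possible overlaps by summing within disjoint chunks
  out <- list()
  for (ch in sort(unique(cov$chrom))) {
    x <- cov[cov$chrom == ch, ]
    ir <- IRanges::IRanges(start = x$start + 1L, end = x$end)
    dj <- IRanges::disjoin(ir)
    ov <- IRanges::findOverlaps(dj, ir)
    val <- tapply(x$value[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
    keep <- as.integer(names(val))
    out[[ch]] <- data.frame(chrom = ch,
                            start = IRanges::start(dj)[keep] - 1L,
                            end = IRanges::end(dj)[keep],
                            value = round(as.numeric(val), 4),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the full synthetic study and write it to disk
#'
#' Runs the four generators in order, threading planted truth through, and
#' writes `genes.bed`, `exprA.tsv`, `exprB.tsv`, `peaks.bed`, `peaks.fa`,
#' `repeats.bed`, `coverage.bedGraph` (population-4 binding track derived
#' from peak heights), `ko.tsv` and `truth.json` into `outdir`. Identical
#' configs (including seed) reproduce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if missing); `NULL` skips
#'   writing and returns in-memory objects only.
#' @return Invisibly, a list with `genes`, `exprA`, `exprB`, `peaks`,
#'   `sequences`, `repeats`, `coverage`, `ko`, `truth` and `paths`.
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  genes <- generate_gene_models(cfg)
  ex <- generate_expression(genes, cfg)
  truth <- ex$truth
  attr(cfg, "planted_targets") <- c(truth$planted_positive_targets,
                                    truth$planted_negative_targets)
  pk <- generate_peaks_and_sequences(genes, cfg)
  truth <- c(truth, pk$truth)
  ko <- generate_ko_table(genes, truth, cfg)
  truth <- c(truth, ko$truth)
  coverage <- peaks_to_coverage(pk$peaks)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genes = file.path(outdir, "genes.bed"),
                  exprA = file.path(outdir, "exprA.tsv"),
                  exprB = file.path(outdir, "exprB.tsv"),
                  peaks = file.path(outdir, "peaks.bed"),
                  fasta = file.path(outdir, "peaks.fa"),
                  repeats = file.path(outdir, "repeats.bed"),
                  coverage = file.path(outdir, "coverage.bedGraph"),
                  ko = file.path(outdir, "ko.tsv"),
                  truth = file.path(outdir, "truth.json"))
    write_genes_bed(genes, paths$genes)
    write_expression_tsv(ex$exprA, paths$exprA)
    write_expression_tsv(ex$exprB, paths$exprB)
    write_peaks_bed(pk$peaks, paths$peaks)
    write_fasta(pk$sequences, paths$fasta)
    write_bed(pk$repeats, paths$repeats)
    write_bedgraph(coverage, paths$coverage)
    write_ko_tsv(ko$ko, paths$ko)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(genes = genes, exprA = ex$exprA, exprB = ex$exprB,
                 peaks = pk$peaks, sequences = pk$sequences,
                 repeats = pk$repeats, coverage = coverage, ko = ko$ko,
                 truth = truth, paths = paths))
}
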