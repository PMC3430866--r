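#' Pipeline configuration
#'
#' Collects every numeric threshold used downstream. Defaults are the
#' working values of the analysis: dynamic-gene filter (SD of log2 values
#' > 1 and a linear intensity above 100 in at least one population),
#' correlation cutoffs (>= 0.8 positive, <= -0.6 negative, both inclusive),
#' promoter window (+/-500 bp around the TSS), intergenic linking window
#' (50 kb), motif core size (middle 200 bp), repeat-masked fraction above
#' which a peak or core is excluded (0.6), knockout fold-change and p-value
#' thresholds (1.5, 0.05), binding heatmap half-window (5 kb) and the
#' peak-height correlation used to justify the early/late partition (0.80).
#'
#' @param sd_threshold Minimum standard deviation of the four log2(value+1)
#'   expression values for a gene to count as dynamic.
#' @param min_expression Minimum linear expression that must be exceeded in
#'   at least one population.
#' @param pos_cut,neg_cut Inclusive Pearson-correlation cutoffs for the
#'   positively and negatively correlated classes.
#' @param promoter_window_bp Half-width of the promoter window around a TSS.
#' @param intergenic_window_bp Maximum summit-to-gene distance for
#'   intergenic links.
#' @param core_bp Length of the central peak core used for motif scanning.
#' @param repeat_fraction Masked-base fraction above which a peak (or core)
#'   is excluded.
#' @param ko_fold Linear fold-change threshold for knockout differential
#'   calls.
#' @param ko_alpha P-value threshold for knockout differential calls.
#' @param heatmap_halfwindow_bp Half-window around summits for binding
#'   density matrices.
#' @param height_corr_threshold Peak-height Pearson correlation regarded as
#'   "very similar binding".
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sd_threshold = 1.0,
                            min_expression = 100,
                            pos_cut = 0.8,
                            neg_cut = -0.6,
                            promoter_window_bp = 500L,
                            intergenic_window_bp = 50000L,
                            core_bp = 200L,
                            repeat_fraction = 0.6,
                            ko_fold = 1.5,
                            ko_alpha = 0.05,
                            heatmap_halfwindow_bp = 5000L,
                            height_corr_threshold = 0.80) {
  stopifnot(sd_threshold > 0, min_expression > 0,
            pos_cut > 0, neg_cut < 0,
            promoter_window_bp > 0, intergenic_window_bp > 0,
            core_bp > 0, repeat_fraction > 0, repeat_fraction <= 1,
            ko_fold > 1, ko_alpha > 0, ko_alpha < 1,
            heatmap_halfwindow_bp > 0, height_corr_threshold > 0)
  structure(list(sd_threshold = sd_threshold,
                 min_expression = min_expression,
                 pos_cut = pos_cut, neg_cut = neg_cut,
                 promoter_window_bp = as.integer(promoter_window_bp),
                 intergenic_window_bp = as.integer(intergenic_window_bp),
                 core_bp = as.integer(core_bp),
                 repeat_fraction = repeat_fraction,
                 ko_fold = ko_fold, ko_alpha = ko_alpha,
                 heatmap_halfwindow_bp = as.integer(heatmap_halfwindow_bp),
                 height_corr_threshold = height_corr_threshold),
            class = "pipeline_config")
}

#' Simulation configuration
#'
#' Describes the synthetic study: a small two-chromosome genome, a gene
#' complement containing one designated regulator whose expression rises
#' monotonically across the four populations, planted positively and
#' negatively correlated target genes, ChIP peak sets split into a class
#' shared by populations 2-4 and a class specific to population 4, planted
#' IUPAC consensus motifs in peak sequences, a repeat mask, and a
#' knockout-vs-heterozygote replicate table with planted fold effects on
#' the target genes.
#'
#' @param n_genes Number of genes to place.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_peaks_shared,n_peaks_late Numbers of early-shared and
#'   late-only peaks.
#' @param regulator_gene Gene id of the regulator (must be one of the
#'   generated ids, `g0001` ... by default).
#' @param fraction_positive,fraction_negative Fractions of genes planted to
#'   correlate / anti-correlate with the regulator; must sum to at most 1.
#' @param expression_noise_sd Additive noise SD on the log2 scale for the
#'   expression matrices.
#' @param ko_fold Nominal (minimum) planted linear fold effect in the
#'   knockout table; must exceed 1.
#' @param ko_fold_log2_spread Planted per-gene effects are
#'   `ko_fold * 2^U(0, spread)`, emulating a continuum of effect sizes of
#'   which `ko_fold` is the weakest; 0 plants every effect exactly at
#'   `ko_fold`.
#' @param ko_noise_sd,ko_tech_noise_sd Biological and technical replicate
#'   noise SDs on the log2 scale for the knockout table.
#' @param n_bio_replicates,n_tech_replicates Replicate structure per
#'   genotype (defaults 2 x 2, i.e. 8 columns in total).
#' @param peak_width Width of generated peaks (bp).
#' @param loc_fractions Length-4 numeric vector of target fractions of
#'   peaks in promoters, gene bodies, intergenic space within the linking
#'   window, and intergenic space beyond it (unassignable); normalised to
#'   sum to 1.
#' @param repeat_peak_fraction Fraction of peaks constructed to overlap the
#'   emitted repeat mask by more than 60% of their length.
#' @param target_host_fraction Fraction of promoter/intragenic peaks whose
#'   host gene is drawn from the planted target genes rather than at
#'   random, so that binding evidence concentrates on true targets.
#' @param motifs Named character vector of IUPAC consensus motifs available
#'   for planting.
#' @param motif_probs Named numeric vector of per-peak planting
#'   probabilities for each motif in `motifs`; the novel motif is planted
#'   with probability `new_motif_promoter_prob` in promoter peaks instead.
#' @param new_motif_promoter_prob Planting probability of the novel motif
#'   in promoter peaks (promoter-enriched by construction).
#' @param seed Integer seed; together with the other fields it fully
#'   determines every emitted file.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       chrom_lengths = c(chr1 = 5000000L, chr2 = 5000000L),
                       n_peaks_shared = 30L,
                       n_peaks_late = 70L,
                       regulator_gene = "g0001",
                       fraction_positive = 0.15,
                       fraction_negative = 0.10,
                       expression_noise_sd = 0.25,
                       ko_fold = 1.5,
                       ko_fold_log2_spread = 1.0,
                       ko_noise_sd = 0.1,
                       ko_tech_noise_sd = 0.05,
                       n_bio_replicates = 2L,
                       n_tech_replicates = 2L,
                       peak_width = 400L,
                       loc_fractions = c(promoter = 0.20, intragenic = 0.30,
                                         intergenic_near = 0.30,
                                         intergenic_far = 0.20),
                       repeat_peak_fraction = 0.10,
                       target_host_fraction = 0.7,
                       motifs = c(runx = "TGYGGT", gata = "WGATAA",
                                  new = "TGTAGT"),
                       motif_probs = c(runx = 0.6, gata = 0.4, new = 0.05),
                       new_motif_promoter_prob = 0.8,
                       seed = 1L) {
  if (fraction_positive + fraction_negative > 1)
    stop("fraction_positive + fraction_negative must be <= 1")
  if (ko_fold <= 1) stop("ko_fold must be a linear ratio > 1")
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            n_genes >= 0, n_peaks_shared >= 0, n_peaks_late >= 0,
            expression_noise_sd >= 0, ko_fold_log2_spread >= 0,
            n_bio_replicates >= 1, n_tech_replicates >= 1,
            peak_width > 0, length(loc_fractions) == 4,
            all(loc_fractions >= 0), sum(loc_fractions) > 0,
            repeat_peak_fraction >= 0, repeat_peak_fraction <= 1,
            target_host_fraction >= 0, target_host_fraction <= 1,
            length(motifs) >= 1, all(names(motif_probs) %in% names(motifs)))
  structure(list(n_genes = as.integer(n_genes),
                 chrom_lengths = chrom_lengths,
                 n_peaks_shared = as.integer(n_peaks_shared),
                 n_peaks_late = as.integer(n_peaks_late),
                 regulator_gene = regulator_gene,
                 fraction_positive = fraction_positive,
                 fraction_negative = fraction_negative,
                 expression_noise_sd = expression_noise_sd,
                 ko_fold = ko_fold,
                 ko_fold_log2_spread = ko_fold_log2_spread,
                 ko_noise_sd = ko_noise_sd,
                 ko_tech_noise_sd = ko_tech_noise_sd,
                 n_bio_replicates = as.integer(n_bio_replicates),
                 n_tech_replicates = as.integer(n_tech_replicates),
                 peak_width = as.integer(peak_width),
                 loc_fractions = loc_fractions / sum(loc_fractions),
                 repeat_peak_fraction = repeat_peak_fraction,
                 target_host_fraction = target_host_fraction,
                 motifs = motifs,
                 motif_probs = motif_probs,
                 new_motif_promoter_prob = new_motif_promoter_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Deterministic per-stage seed derived from the run seed, so stages are
## reproducible independently of each other. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(genes = 11L, expression = 23L, peaks = 37L, ko = 53L,
               dynamics = 71L, saturation = 89L, som = 101L, null = 131L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

## round() in R rounds half to even; printed expectations in the field use
## conventional half-up rounding (284.5 -> 285).
round_half_up <- function(x) floor(x + 0.5)
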