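## Whole-pipeline orchestration: one reproducible run from a single
## structured configuration (an R list or a YAML file), emitting per-stage
## tables, a deterministic report.json and a run manifest with file
## digests.

default_run_config <- function() {
  list(simulate = TRUE,
       sim = list(),        # overrides for sim_config()
       pipeline = list(),   # overrides for pipeline_config()
       inputs = list(),     # file paths when simulate = FALSE
       n_permutations = 100L,
       som_grid = c(6L, 6L),
       som_epochs = 50L,
       saturation_depths = seq(0.1, 1, by = 0.1),
       motifs = c(runx = "TGYGGT", gata = "WGATAA", new = "TGTAGT"),
       seed = 1L)
}

resolve_run_config <- function(config) {
  base <- default_run_config()
  if (is.null(config)) return(base)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be NULL, a path or a list")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Run the full target-inference pipeline
#'
#' Executes simulate (optional) -> expression dynamics -> peak processing
#' -> peak annotation -> motif analysis -> knockout integration -> report,
#' in order, from one configuration. Any missing input file fails a
#' preflight check before any stage runs. One log line per stage reports
#' input and output sizes. Two runs with the same configuration and seed
#' produce identical `report.json`.
#'
#' @param config `NULL` (defaults: simulate a synthetic study), a path to
#'   a YAML file, or a list with any of the fields `simulate`, `sim`
#'   (overrides for [sim_config()]), `pipeline` (overrides for
#'   [pipeline_config()]), `inputs` (named paths `genes`, `exprA`,
#'   `exprB`, `peaks`, `fasta`, `repeats`, `ko` and optionally `coverage`
#'   when `simulate` is `FALSE`), `n_permutations`, `som_grid`,
#'   `som_epochs`, `saturation_depths`, `motifs` (named IUPAC consensus
#'   set to scan), `seed`. The regulator gene id is taken from
#'   `sim$regulator_gene` (simulated or not).
#' @param outdir Output directory for all emitted files.
#' @param seed Integer seed; overrides the config seed when given.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all stage results (`sim`, `dynamics`,
#'   `peaks`, `annotation`, `motifs`, `integration`), the `report` list,
#'   and `manifest`.
#' @export
run_pipeline <- function(config = NULL, outdir = tempfile("regonset_run_"),
                         seed = NULL, quiet = FALSE) {
  rc <- resolve_run_config(config)
  if (!is.null(seed)) rc$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  pcfg <- do.call(pipeline_config, rc$pipeline)

  ## --- inputs (simulate or preflight + read) -------------------------
  if (isTRUE(rc$simulate)) {
    scfg <- do.call(sim_config, c(rc$sim, list(seed = rc$seed)))
    sim <- simulate_dataset(scfg, outdir = file.path(outdir, "sim"))
    inputs <- sim$paths
    say("simulate: %d genes, %d peaks, %d repeat intervals",
        nrow(sim$genes), nrow(sim$peaks), nrow(sim$repeats))
  } else {
    sim <- NULL
    inputs <- rc$inputs
    need <- c("genes", "exprA", "exprB", "peaks", "fasta", "repeats", "ko")
    missing_names <- setdiff(need, names(inputs))
    if (length(missing_names) > 0)
      stop("config$inputs lacks: ", paste(missing_names, collapse = ", "))
    paths <- unlist(inputs[c(need, intersect("coverage", names(inputs)))])
    absent <- paths[!file.exists(paths)]
    if (length(absent) > 0)
      stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  genes <- read_genes_bed(inputs$genes)
  exprA <- read_expression_tsv(inputs$exprA, platform = "A")
  exprB <- read_expression_tsv(inputs$exprB, platform = "B")
  peaks <- read_peaks_bed(inputs$peaks)
  seqs <- read_fasta(inputs$fasta)
  repeats <- read_bed(inputs$repeats)
  ko <- read_ko_tsv(inputs$ko)
  coverage <- if (!is.null(inputs$coverage) && file.exists(inputs$coverage))
    read_bedgraph(inputs$coverage) else NULL
  regulator <- if (!is.null(sim)) sim$truth$regulator_gene else
    do.call(sim_config, rc$sim)$regulator_gene

  ## --- expression dynamics ------------------------------------------
  dynA <- filter_dynamic(exprA, pcfg)
  dynB <- filter_dynamic(exprB, pcfg)
  recA <- classify_correlations(correlate_with_regulator(exprA, regulator, dynA), pcfg)
  recB <- classify_correlations(correlate_with_regulator(exprB, regulator, dynB), pcfg)
  consensus <- platform_consensus(recA, recB)
  null_pcc <- randomized_control(exprA, regulator,
                                 n_permutations = rc$n_permutations,
                                 seed = rc$seed)
  som <- som_mosaic(exprA[dynA, , drop = FALSE],
                    grid_rows = rc$som_grid[1], grid_cols = rc$som_grid[2],
                    epochs = rc$som_epochs, seed = rc$seed)
  say("dynamics: %d/%d dynamic (A), %d/%d (B); consensus %d positive, %d negative",
      length(dynA), nrow(exprA), length(dynB), nrow(exprB),
      sum(consensus$label == "positive"), sum(consensus$label == "negative"))

  ## --- peak processing -----------------------------------------------
  filt <- filter_repeat_peaks(peaks, repeats, pcfg)
  part <- partition_peaks(filt$retained)
  sat <- saturation_curve(round_half_up(filt$retained$h4 * 10),
                          depths = rc$saturation_depths, seed = rc$seed)
  dens <- if (!is.null(coverage))
    density_matrix(filt$retained, coverage, pcfg) else NULL
  say("peaks: %d in, %d retained after repeat filter (%d excluded); %d '2,3,4', %d '4 only'",
      nrow(peaks), nrow(filt$retained), nrow(filt$excluded),
      sum(part$partition$partition == "2,3,4"),
      sum(part$partition$partition == "4 only"))

  ## --- annotation -----------------------------------------------------
  links <- assign_peaks(filt$retained, genes, pcfg)
  targets <- candidate_targets(links)
  breakdown <- location_breakdown(links, part$partition)
  say("annotate: %d links, %d candidate target genes", nrow(links),
      length(targets))

  ## --- motif analysis -------------------------------------------------
  cores <- extract_cores(filt$retained, seqs, repeats, pcfg)
  motif_hits <- lapply(rc$motifs, function(mo) {
    names(cores$cores)[vapply(cores$cores, function(s)
      nrow(scan_consensus(s, mo)) > 0, logical(1))]
  })
  ext <- extended_consensus_counts(cores$cores, "WGATA", "A")
  ann <- build_annotation_matrix(filt$retained, part$partition, links, motif_hits)
  clust <- cluster_annotation(ann)
  assoc <- motif_promoter_association(ann)
  say("motifs: %d cores (%d repeat-excluded); WGATA %d total, %d extended",
      length(cores$cores), nrow(cores$excluded), ext$n_total, ext$n_extended)

  ## --- integration ----------------------------------------------------
  ko_rec <- ko_differential(ko, pcfg)
  sets <- controlled_target_sets(consensus, ko_rec, targets)
  ## bound fractions are computed over the whole gene complement: genes
  ## outside the dynamic sets count as unclassified, as in a
  ## fraction-of-all-expressed-genes view
  consensus_all <- merge(data.frame(gene_id = genes$gene_id,
                                    stringsAsFactors = FALSE),
                         consensus, by = "gene_id", all.x = TRUE)
  consensus_all$label[is.na(consensus_all$label)] <- "unclassified"
  bound_frac <- bound_fraction_by_class(consensus_all, targets)
  universe <- intersect(intersect(rownames(exprA), rownames(exprB)),
                        genes$gene_id)
  pos_genes <- consensus$gene_id[consensus$label == "positive"]
  ov <- hypergeometric_overlap(intersect(pos_genes, universe),
                               intersect(targets, universe), universe)
  say("integrate: %d down/%d up in null; %d positively / %d negatively controlled",
      sum(ko_rec$direction == "down_in_null"),
      sum(ko_rec$direction == "up_in_null"),
      length(sets$positively_controlled),
      length(sets$negatively_controlled))

  ## --- outputs --------------------------------------------------------
  classes <- merge(merge(stats::setNames(recA[, c("gene_id", "pcc")],
                                         c("gene_id", "pccA")),
                         stats::setNames(recB[, c("gene_id", "pcc")],
                                         c("gene_id", "pccB")),
                         by = "gene_id", all = TRUE),
                   consensus, by = "gene_id", all.x = TRUE)
  utils::write.table(classes, file.path(outdir, "classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(part$partition, file.path(outdir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(links, file.path(outdir, "links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sat, file.path(outdir, "saturation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(targets, file.path(outdir, "targets.txt"))
  jsonlite::write_json(list(positively_controlled = sets$positively_controlled,
                            negatively_controlled = sets$negatively_controlled,
                            venn = sets$venn),
                       file.path(outdir, "controlled_sets.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  report <- list(
    seed = rc$seed,
    thresholds = unclass(pcfg),
    n_genes = nrow(genes),
    n_peaks_in = nrow(peaks),
    n_peaks_retained = nrow(filt$retained),
    partition_counts = as.list(table(part$partition$partition)),
    n_dynamic_A = length(dynA), n_dynamic_B = length(dynB),
    consensus_counts = as.list(table(consensus$label)),
    null_pcc_mean = round(mean(null_pcc), 6),
    n_links = nrow(links),
    n_candidate_targets = length(targets),
    location_breakdown = breakdown,
    wgata = ext[c("n_total", "n_extended", "n_expected")],
    new_motif_promoter_p = signif(assoc$p_value, 6),
    ko_counts = as.list(table(ko_rec$direction)),
    venn = sets$venn,
    positively_controlled = sets$positively_controlled,
    negatively_controlled = sets$negatively_controlled,
    bound_fraction_by_class = as.list(round(bound_frac, 6)),
    positive_vs_bound_overlap = ov)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = rc$seed,
                   config = rc[setdiff(names(rc), "inputs")],
                   version = as.character(utils::packageVersion("regonset")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   digests = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("report: %s", file.path(outdir, "report.json"))

  invisible(list(sim = sim, genes = genes, exprA = exprA, exprB = exprB,
                 dynamics = list(dynamic_A = dynA, dynamic_B = dynB,
                                 records_A = recA, records_B = recB,
                                 consensus = consensus, null_pcc = null_pcc,
                                 som = som),
                 peaks = list(all = peaks, retained = filt$retained,
                              excluded = filt$excluded,
                              partition = part$partition,
                              height_correlations = part$height_correlations,
                              saturation = sat, density = dens),
                 annotation = list(links = links, targets = targets,
                                   breakdown = breakdown),
                 motifs = list(cores = cores, hits = motif_hits,
                               extended = ext, annotation_matrix = ann,
                               cluster = clust, promoter_association = assoc),
                 integration = list(ko = ko_rec, sets = sets,
                                    bound_fraction = bound_frac,
                                    overlap = ov),
                 report = report, manifest = manifest, outdir = outdir))
}
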