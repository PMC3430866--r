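# The synthetic study generator: determinism, planted truth, and the
# structural contracts every downstream stage relies on.

test_that("gene models respect placement contracts", {
  cfg <- small_sim(seed = 7, n_genes = 200L,
                   chrom_lengths = c(chr1 = 5000000L, chr2 = 5000000L))
  genes <- generate_gene_models(cfg)
  expect_equal(nrow(genes), 200L)
  expect_true(all(genes$start < genes$end))
  expect_true(all(genes$strand %in% c("+", "-")))
  expect_equal(genes$tss[genes$strand == "+"], genes$start[genes$strand == "+"])
  expect_equal(genes$tss[genes$strand == "-"], genes$end[genes$strand == "-"] - 1L)
  # non-nested, non-overlapping within chromosome
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # emitted BED re-read with a generic parser agrees
  f <- withr::local_tempfile()
  write_genes_bed(genes, f)
  raw <- utils::read.table(f, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(raw), 200L)
  expect_equal(raw$V2, genes$start)
  expect_equal(raw$V6, genes$strand)

  expect_error(generate_gene_models(small_sim(n_genes = 0L)), "nothing to place")
  expect_error(
    generate_gene_models(sim_config(n_genes = 500L,
                                    chrom_lengths = c(tiny = 100000L))),
    "tiny")
})

test_that("intergenic gaps span both sides of the linking window", {
  genes <- generate_gene_models(small_sim(seed = 7, n_genes = 200L,
                                          chrom_lengths = c(chr1 = 5e6,
                                                            chr2 = 5e6)))
  gaps <- unlist(lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$start), ]
    g$start[-1] - g$end[-nrow(g)]
  }))
  expect_true(any(gaps < 50000))
  expect_true(any(gaps > 50000))
})

test_that("identical config and seed give identical outputs, on disk too", {
  cfg <- small_sim(seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$exprA, s2$exprA)
  expect_identical(s1$peaks, s2$peaks)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("noiseless planted targets correlate exactly +/-1 with the regulator", {
  cfg <- small_sim(seed = 3, expression_noise_sd = 0)
  genes <- generate_gene_models(cfg)
  ex <- generate_expression(genes, cfg)
  reg <- ex$exprA[cfg$regulator_gene, ]
  expect_true(all(diff(reg) > 0))  # strictly increasing
  rec <- correlate_with_regulator(ex$exprA, cfg$regulator_gene,
                                  c(ex$truth$planted_positive_targets,
                                    ex$truth$planted_negative_targets))
  pcc <- stats::setNames(rec$pcc, rec$gene_id)
  # positives copy the regulator profile: correlation exactly 1
  for (g in ex$truth$planted_positive_targets)
    expect_equal(unname(pcc[g]), 1.0, tolerance = 1e-6)
  # negatives carry the affine mirror (monotone decreasing against a
  # monotone increasing regulator): correlation -1 up to the +1
  # pseudo-count used on the log scale
  for (g in ex$truth$planted_negative_targets)
    expect_equal(unname(pcc[g]), -1.0, tolerance = 1e-3)
})

test_that("fraction_positive + fraction_negative > 1 is rejected", {
  expect_error(sim_config(fraction_positive = 0.7, fraction_negative = 0.5),
               "<= 1")
})

test_that("late-only peaks tower over populations 2 and 3; shared heights correlate", {
  sim <- simulate_dataset(small_sim(seed = 2))
  cls <- unlist(sim$truth$peak_class_truth)
  late <- sim$peaks[cls[sim$peaks$peak_id] == "late_only", ]
  expect_true(all(late$h4 > late$h2))
  expect_true(all(late$h4 > late$h3))
  expect_true(all(late$h4 >= 5 * pmax(late$h2, late$h3)))
  expect_true(all(!late$called2 & !late$called3 & late$called4))
  shared <- sim$peaks[cls[sim$peaks$peak_id] == "shared", ]
  expect_gt(stats::cor(shared$h2, shared$h3), 0.9)
  expect_gt(stats::cor(shared$h2, shared$h4), 0.9)
  expect_true(all(shared$called2 & shared$called3 & shared$called4))
})

test_that("planted motif instances are recoverable by brute-force scan", {
  sim <- simulate_dataset(sim_config(seed = 11))
  truth <- sim$truth$planted_motif_positions
  expect_gt(length(truth), 0)
  consensus <- c(TGCGGT = "TGYGGT", TGTGGT = "TGYGGT",
                 AGATAA = "WGATAA", TGATAA = "WGATAA", TGTAGT = "TGTAGT")
  for (pid in names(truth)) {
    seq <- sim$sequences[[pid]]
    rec <- truth[[pid]]
    for (k in seq_len(nrow(rec))) {
      iupac <- consensus[[rec$motif[k]]]
      hits <- naive_scan(seq, iupac)
      expect_true(any(hits$offset == rec$offset[k] &
                        hits$strand == rec$strand[k]),
                  info = sprintf("%s: %s@%d%s", pid, rec$motif[k],
                                 rec$offset[k], rec$strand[k]))
    }
  }
})

test_that("planted motif offsets lie inside their peak sequences", {
  sim <- simulate_dataset(small_sim(seed = 4))
  for (pid in names(sim$truth$planted_motif_positions)) {
    rec <- sim$truth$planted_motif_positions[[pid]]
    L <- nchar(sim$sequences[[pid]])
    expect_true(all(rec$offset >= 0 & rec$offset + nchar(rec$motif) <= L))
  }
})

test_that("designated repeat peaks overlap the mask by more than 60%", {
  sim <- simulate_dataset(small_sim(seed = 6))
  frac <- repeat_overlap_fraction(sim$peaks, sim$repeats)
  names(frac) <- sim$peaks$peak_id
  expect_true(all(frac[sim$truth$repeat_peaks] > 0.6))
  others <- setdiff(sim$peaks$peak_id, sim$truth$repeat_peaks)
  expect_true(all(frac[others] <= 0.6))
})

test_that("KO table plants the recorded fold effects", {
  # spread 0 and vanishing noise: ratio het/null is exactly the nominal fold
  cfg <- small_sim(seed = 3, ko_fold_log2_spread = 0,
                   ko_noise_sd = 1e-9, ko_tech_noise_sd = 0)
  genes <- generate_gene_models(cfg)
  ex <- generate_expression(genes, cfg)
  ko <- generate_ko_table(genes, ex$truth, cfg)
  het <- rowMeans(ko$ko[, grepl("^het", colnames(ko$ko))])
  nul <- rowMeans(ko$ko[, grepl("^null", colnames(ko$ko))])
  ratio <- het / nul
  for (g in ex$truth$planted_positive_targets)
    expect_equal(unname(ratio[g]), 1.5, tolerance = 1e-3)
  for (g in ex$truth$planted_negative_targets)
    expect_equal(unname(ratio[g]), 1 / 1.5, tolerance = 1e-3)
  non <- setdiff(rownames(ko$ko), unlist(ex$truth[c("planted_positive_targets",
                                                    "planted_negative_targets")]))
  expect_equal(unname(ratio[non]), rep(1, length(non)), tolerance = 1e-3)

  # with spread, recorded truth folds are reproduced and bounded below
  cfg2 <- small_sim(seed = 3, ko_noise_sd = 1e-9, ko_tech_noise_sd = 0)
  ko2 <- generate_ko_table(genes, ex$truth, cfg2)
  het2 <- rowMeans(ko2$ko[, grepl("^het", colnames(ko2$ko))])
  nul2 <- rowMeans(ko2$ko[, grepl("^null", colnames(ko2$ko))])
  eff <- unlist(ko2$truth$ko_effect_genes)
  for (g in ex$truth$planted_positive_targets) {
    expect_gte(eff[[g]], 1.5)
    expect_equal(unname(het2[g] / nul2[g]), eff[[g]], tolerance = 1e-3)
  }
  expect_error(generate_ko_table(genes, ex$truth, small_sim(ko_fold = 0.9)),
               "ko_fold")
})

test_that("truth invariants hold and files re-read losslessly", {
  d <- withr::local_tempdir()
  sim <- simulate_dataset(small_sim(seed = 9), d)
  tr <- sim$truth
  expect_length(intersect(tr$planted_positive_targets,
                          tr$planted_negative_targets), 0)
  expect_true(all(c(tr$planted_positive_targets, tr$planted_negative_targets,
                    names(tr$ko_effect_genes)) %in% sim$genes$gene_id))
  expect_setequal(names(tr$peak_class_truth), sim$peaks$peak_id)

  expect_identical(read_genes_bed(file.path(d, "genes.bed")), sim$genes)
  expect_identical(read_peaks_bed(file.path(d, "peaks.bed")), sim$peaks)
  backA <- read_expression_tsv(file.path(d, "exprA.tsv"), platform = "A")
  expect_equal(unclass(backA)[, ], sim$exprA[, ], tolerance = 0)
  expect_identical(read_fasta(file.path(d, "peaks.fa")), sim$sequences)
  ko <- read_ko_tsv(file.path(d, "ko.tsv"))
  expect_equal(ko[, ], sim$ko[, ], tolerance = 0)
  truth2 <- read_truth_json(file.path(d, "truth.json"))
  expect_setequal(truth2$planted_positive_targets, tr$planted_positive_targets)
})
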