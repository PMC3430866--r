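# Knockout differential calling, hypergeometric overlap and the triple
# intersection into controlled target sets.

mk_ko <- function(het, nul, ids = sprintf("g%d", seq_len(nrow(het)))) {
  m <- cbind(het, nul)
  colnames(m) <- c("het_b1_t1", "het_b1_t2", "het_b2_t1", "het_b2_t2",
                   "null_b1_t1", "null_b1_t2", "null_b2_t1", "null_b2_t2")
  rownames(m) <- ids
  m
}

test_that("KO differential calls fold and direction correctly", {
  # identical values in both genotypes: unchanged, fold 1
  flat <- matrix(100, 3, 4)
  ko <- mk_ko(flat, flat)
  for (meth in c("limma", "ttest")) {
    # limma warns (legitimately) that all residual variances are zero
    rec <- suppressWarnings(ko_differential(ko, method = meth))
    expect_equal(rec$fold, rep(1, 3))
    expect_equal(rec$direction, rep("unchanged", 3))
  }
  # het = 2x null with tiny variance: down_in_null
  set.seed(1)
  het <- matrix(200 * 2^stats::rnorm(400, 0, 0.02), 100, 4)
  nul <- matrix(100 * 2^stats::rnorm(400, 0, 0.02), 100, 4)
  rec <- ko_differential(mk_ko(het, nul))
  expect_true(all(rec$direction == "down_in_null"))
  expect_equal(mean(rec$fold), 2, tolerance = 0.05)
  # and the mirror image: up_in_null
  rec2 <- ko_differential(mk_ko(nul, het))
  expect_true(all(rec2$direction == "up_in_null"))
})

test_that("KO differential needs two biological replicates per genotype", {
  m <- matrix(100, 2, 4,
              dimnames = list(c("g1", "g2"),
                              c("het_b1_t1", "het_b1_t2",
                                "null_b1_t1", "null_b1_t2")))
  expect_error(ko_differential(m), "biological replicates")
})

test_that("the differential caller recovers planted KO effects", {
  # generator defaults; recovery is seed-averaged because planted folds
  # near the 1.5 detection boundary are individually recovered with
  # probability below one
  sens_pos <- sens_neg <- spec <- numeric(0)
  for (s in c(3L, 4L, 5L)) {
    cfg <- sim_config(seed = s)
    genes <- generate_gene_models(cfg)
    ex <- generate_expression(genes, cfg)
    ko <- generate_ko_table(genes, ex$truth, cfg)
    rec <- ko_differential(ko$ko)
    dir <- stats::setNames(rec$direction, rec$gene_id)
    pos <- ex$truth$planted_positive_targets
    neg <- ex$truth$planted_negative_targets
    sens_pos <- c(sens_pos, mean(dir[pos] == "down_in_null"))
    sens_neg <- c(sens_neg, mean(dir[neg] == "up_in_null"))
    non <- setdiff(rec$gene_id, c(pos, neg))
    spec <- c(spec, mean(dir[non] == "unchanged"))
  }
  expect_gte(mean(sens_pos), 0.9)
  expect_gte(mean(sens_neg), 0.9)
  # specificity: unplanted genes stay unchanged
  expect_gte(mean(spec), 0.99)
})

test_that("hypergeometric overlap matches closed-form and enumeration", {
  u <- sprintf("g%02d", 1:10)
  a <- u[1:5]; b <- u[c(1, 2, 3, 4)]
  out <- hypergeometric_overlap(a, b, u)
  expect_equal(out$overlap, 4L)
  # exhaustive enumeration over all C(10,4) draws of b
  draws <- utils::combn(10, 4)
  k_ge <- mean(apply(draws, 2, function(d) sum(d <= 5) >= 4))
  expect_equal(out$p_hyper, k_ge, tolerance = 1e-12)
  expect_equal(out$p_hyper, 5 / 210, tolerance = 1e-12)
  # forced maximal overlap and empty overlap both give p = 1
  expect_equal(hypergeometric_overlap(u, u, u)$p_hyper, 1)
  expect_equal(hypergeometric_overlap(u[1:3], u[4:6], u)$p_hyper, 1)
  expect_error(hypergeometric_overlap(c(a, "zz"), b, u), "outside universe")
})

test_that("hypergeometric enumeration holds across random small universes", {
  set.seed(8)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    u <- sprintf("x%02d", 1:N)
    a <- sample(u, sample(1:N, 1))
    b <- sample(u, sample(1:N, 1))
    out <- hypergeometric_overlap(a, b, u)
    draws <- utils::combn(N, length(b))
    in_a <- match(a, u)
    p_enum <- mean(apply(draws, 2, function(d)
      length(intersect(d, in_a)) >= out$overlap))
    expect_equal(out$p_hyper, p_enum, tolerance = 1e-12)
  }
})

test_that("hypergeometric tail matches Monte-Carlo draws on a larger universe", {
  set.seed(9)
  u <- sprintf("x%03d", 1:200)
  a <- sample(u, 60)
  b <- sample(u, 50)
  out <- hypergeometric_overlap(a, b, u)
  n_mc <- 1e5
  hits <- vapply(seq_len(n_mc), function(i)
    length(intersect(sample(u, 50), a)) >= out$overlap, logical(1))
  p_mc <- mean(hits)
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(out$p_hyper - p_mc), 3 * max(se, 1e-4))
})

test_that("controlled target sets follow the triple-intersection algebra", {
  labels <- data.frame(gene_id = c("p1", "p2", "p3", "n1", "n2", "u1"),
                       label = c("positive", "positive", "positive",
                                 "negative", "negative", "unclassified"),
                       stringsAsFactors = FALSE)
  ko <- data.frame(gene_id = c("p1", "p2", "p3", "n1", "n2", "u1"),
                   log2fc = 0, fold = 1, p_value = 1,
                   direction = c("down_in_null", "down_in_null", "unchanged",
                                 "up_in_null", "unchanged", "down_in_null"),
                   stringsAsFactors = FALSE)
  bound <- c("p1", "p3", "n1", "u1")
  out <- controlled_target_sets(labels, ko, bound)
  expect_equal(out$positively_controlled, "p1")
  expect_equal(out$negatively_controlled, "n1")
  # p2 is positive and KO-down but unbound; p3 positive and bound but not
  # KO-down: both excluded from the triple, visible in the pairwise counts
  expect_equal(out$venn$positive$ab, 2L)     # positive & down
  expect_equal(out$venn$positive$ac, 2L)     # positive & bound
  expect_equal(out$venn$positive$abc, 1L)
  # empty bound set empties both outputs
  none <- controlled_target_sets(labels, ko, character())
  expect_length(none$positively_controlled, 0)
  expect_length(none$negatively_controlled, 0)
  # set-algebra invariants
  v <- out$venn$positive
  expect_lte(v$abc, min(v$ab, v$ac, v$bc))
  expect_lte(v$ab, min(v$n_a, v$n_b))
})

test_that("reference co-binding fractions follow construction", {
  targets <- list(pos = sprintf("g%d", 1:10))
  refs <- list(f1 = sprintf("g%d", 1:8), f2 = sprintf("g%d", 1:8),
               f3 = sprintf("g%d", 1:8))
  out <- reference_cobinding(targets, refs)
  expect_equal(out$frac_all, 0.8)
  expect_equal(out$frac_any, 0.8)
  # empty references give zero fractions; universe references give 1
  expect_equal(reference_cobinding(targets, list())$frac_all, 0)
  expect_equal(reference_cobinding(targets,
                                   list(f = targets$pos))$frac_all, 1)
})

test_that("bound fractions per class are undefined for empty classes", {
  labels <- data.frame(gene_id = c("a", "b", "c"),
                       label = c("positive", "positive", "unclassified"),
                       stringsAsFactors = FALSE)
  f <- bound_fraction_by_class(labels, c("a"))
  expect_equal(unname(f["positive"]), 0.5)
  expect_true(is.na(f["negative"]))
  expect_equal(unname(f["unclassified"]), 0)
  f0 <- bound_fraction_by_class(labels, character())
  expect_equal(unname(f0["positive"]), 0)
  expect_true(all(f[!is.na(f)] >= 0 & f[!is.na(f)] <= 1))
})

test_that("genes near planted peaks are bound more often when positive", {
  sim <- simulate_dataset(sim_config(seed = 19))
  links <- assign_peaks(sim$peaks, sim$genes)
  targets <- candidate_targets(links)
  dyn <- filter_dynamic(sim$exprA)
  labels <- classify_correlations(
    correlate_with_regulator(sim$exprA, sim$truth$regulator_gene, dyn))
  all_labels <- data.frame(gene_id = sim$genes$gene_id,
                           stringsAsFactors = FALSE)
  all_labels$label <- labels$label[match(all_labels$gene_id, labels$gene_id)]
  all_labels$label[is.na(all_labels$label)] <- "unclassified"
  f <- bound_fraction_by_class(all_labels, targets)
  expect_gt(f[["positive"]], f[["unclassified"]])
})
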