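# Core extraction, IUPAC scanning on both strands, extended-consensus
# counting and the binary annotation matrix with its clustering.

test_that("core extraction takes the centred 200 bp and keeps short peaks whole", {
  peaks <- data.frame(peak_id = c("long", "short"), chrom = "chr1",
                      start = c(1000L, 5000L), end = c(1300L, 5150L),
                      summit = c(1150L, 5075L), h2 = 1, h3 = 1, h4 = 1,
                      called2 = TRUE, called3 = TRUE, called4 = TRUE,
                      stringsAsFactors = FALSE)
  seqs <- c(long = paste(rep(c("A", "C", "G"), length.out = 300), collapse = ""),
            short = paste(rep("T", 150), collapse = ""))
  out <- extract_cores(peaks, seqs, NULL)
  # 300 bp peak: bases [50, 250) of the sequence
  expect_equal(out$cores[["long"]], substr(seqs[["long"]], 51, 250))
  expect_equal(nchar(out$cores[["short"]]), 150L)
  # sequence length mismatch is an error naming the peak
  expect_error(extract_cores(peaks, c(long = "ACGT", short = seqs[["short"]]),
                             NULL), "long")
})

test_that("cores with more than 60% masked bases are excluded", {
  mk <- function(n_lower) {
    paste(c(rep("a", n_lower), rep("G", 200 - n_lower)), collapse = "")
  }
  peaks <- data.frame(peak_id = c("at121", "at120"), chrom = "chr1",
                      start = c(0L, 1000L), end = c(200L, 1200L),
                      summit = c(100L, 1100L), h2 = 1, h3 = 1, h4 = 1,
                      called2 = TRUE, called3 = TRUE, called4 = TRUE,
                      stringsAsFactors = FALSE)
  seqs <- c(at121 = mk(121), at120 = mk(120))
  out <- extract_cores(peaks, seqs, NULL)
  expect_equal(out$excluded$peak_id, "at121")
  expect_equal(names(out$cores), "at120")
  # same decision from a genomic repeat mask instead of soft-masking
  mask <- data.frame(chrom = "chr1", start = c(0L, 1000L),
                     end = c(121L, 1120L))
  seqs_up <- toupper(seqs)
  out2 <- extract_cores(peaks, seqs_up, mask)
  expect_equal(out2$excluded$peak_id, "at121")
  expect_equal(names(out2$cores), "at120")
})

test_that("IUPAC scanning resolves degenerate codes on both strands", {
  # Y matches C on the forward strand at offset 0
  h1 <- scan_consensus("TGCGGT", "TGYGGT")
  expect_equal(h1$offset, 0L)
  expect_equal(h1$strand, "+")
  # W matches A and T
  expect_equal(nrow(scan_consensus("AGATAA", "WGATAA")), 1L)
  expect_equal(nrow(scan_consensus("TGATAA", "WGATAA")), 1L)
  # reverse complement of TGCGGT: one minus-strand match
  h2 <- scan_consensus("ACCGCA", "TGYGGT")
  expect_equal(h2$strand, "-")
  expect_equal(h2$offset, 0L)
  # verify by complementing and rescanning
  h3 <- scan_consensus("TGCGGT", "TGYGGT")
  expect_equal(nrow(h3), 1L)
  # N in the subject matches no code, not even pattern N
  expect_equal(nrow(scan_consensus("TGNGGT", "TGYGGT")), 0L)
  expect_equal(nrow(scan_consensus("NNNNNN", "NNNNNN")), 0L)
  expect_error(scan_consensus("ACGT", "AXGT"), "IUPAC")
})

test_that("scanner agrees with the naive per-position matcher", {
  set.seed(123)
  motifs <- c("TGYGGT", "WGATAA", "TGTAGT", "RYSWKM", "NACGTN")
  for (i in 1:150) {
    seq <- random_dna(sample(20:500, 1))
    mo <- sample(motifs, 1)
    a <- scan_consensus(seq, mo)
    b <- naive_scan(seq, mo)
    expect_equal(a$offset, b$offset)
    expect_equal(a$strand, b$strand)
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  rc <- function(s) paste(rev(chartr("ACGT", "TGCA",
                                     strsplit(s, NULL)[[1]])), collapse = "")
  set.seed(5)
  for (i in 1:25) {
    seq <- random_dna(80)
    mo <- "TGYGGT"
    a <- scan_consensus(seq, mo)
    b <- scan_consensus(rc(seq), mo)
    # offset o on one strand maps to L - m - o on the other, strands swapped
    expect_equal(nrow(a), nrow(b))
    if (nrow(b) > 0) {
      mapped <- data.frame(offset = as.integer(nchar(seq) - nchar(mo) - b$offset),
                           strand = ifelse(b$strand == "+", "-", "+"),
                           stringsAsFactors = FALSE)
      mapped <- mapped[order(mapped$offset, mapped$strand), ]
      expect_equal(a$offset, mapped$offset)
      expect_equal(a$strand, mapped$strand)
    }
  }
})

test_that("extended-consensus counting is strand-aware and edge-safe", {
  # one forward WGATA followed by A; one followed by C
  cores <- c(p1 = "CCAGATAACC", p2 = "CCAGATACCC")
  out <- extended_consensus_counts(cores, "WGATA", "A")
  expect_equal(out$n_total, 2L)
  expect_equal(out$n_extended, 1L)
  # minus-strand instance: revcomp(TGATA) = TATCA; extension base sits 5'
  # of the match on the forward strand and must complement to A
  minus <- c(m = "CCTTATCACC")  # forward TTATCA: revcomp TGATAA
  om <- extended_consensus_counts(minus, "WGATA", "A")
  expect_equal(om$n_total, 1L)
  expect_equal(om$n_extended, 1L)
  # a match flush at the 3' edge counts in total but is not eligible
  edge <- c(e = "CCCCCAGATA")
  oe <- extended_consensus_counts(edge, "WGATA", "A")
  expect_equal(oe$n_total, 1L)
  expect_equal(oe$n_eligible, 0L)
  expect_equal(oe$n_extended, 0L)
  # empty input
  o0 <- extended_consensus_counts(character(), "WGATA", "A")
  expect_equal(c(o0$n_total, o0$n_extended, o0$n_expected), c(0L, 0L, 0L))
})

test_that("extended fraction on random sequence stays near the 1/4 background", {
  set.seed(77)
  cores <- vapply(1:300, function(i) random_dna(200), character(1))
  names(cores) <- sprintf("p%d", 1:300)
  out <- extended_consensus_counts(cores, "WGATA", "A")
  expect_gt(out$n_eligible, 100)
  # central 99% binomial interval around n_eligible / 4
  ci <- stats::qbinom(c(0.005, 0.995), out$n_eligible, 0.25)
  expect_gte(out$n_extended, ci[1])
  expect_lte(out$n_extended, ci[2])
})

test_that("annotation matrix encodes partition, location and motif hits", {
  peaks <- data.frame(peak_id = c("a", "b"), chrom = "chr1",
                      start = c(0L, 1000L), end = c(200L, 1200L),
                      summit = c(100L, 1100L), h2 = 1, h3 = 1, h4 = 1,
                      called2 = c(TRUE, FALSE), called3 = c(TRUE, FALSE),
                      called4 = TRUE, stringsAsFactors = FALSE)
  part <- partition_peaks(peaks)$partition
  links <- data.frame(peak_id = "a", gene_id = "g1", category = "promoter",
                      distance = 0L, stringsAsFactors = FALSE)
  hits <- list(new = character(), runx = "a", gata = character())
  m <- build_annotation_matrix(peaks, part, links, hits)
  expect_equal(unname(m["a", ]), c(1L, 1L, 0L, 1L, 0L))
  expect_equal(unname(m["b", ]), c(0L, 0L, 0L, 0L, 0L))
  # column sums equal independent per-feature counts
  expect_equal(unname(colSums(m)),
               c(sum(part$partition == "2,3,4"),
                 length(unique(links$peak_id[links$category == "promoter"])),
                 0L, 1L, 0L))
})

test_that("clustering groups identical binary rows contiguously", {
  m <- rbind(a = c(1L, 1L, 0L, 0L, 0L), b = c(0L, 0L, 1L, 1L, 1L),
             c = c(1L, 1L, 0L, 0L, 0L), d = c(0L, 0L, 1L, 1L, 1L))
  cl <- cluster_annotation(m)
  ord <- cl$order
  expect_setequal(ord, rownames(m))
  pos <- match(c("a", "c"), ord)
  expect_equal(abs(diff(pos)), 1L)
  # identical rows have distance zero and merge first
  expect_equal(min(cl$hclust$height), 0)
  # all-zero vs all-one rows sit at maximal Jaccard distance 1
  m2 <- rbind(z = rep(0L, 5), o = rep(1L, 5))
  d2 <- cluster_annotation(m2)$hclust$height
  expect_equal(max(d2), 1)
  # deterministic regardless of row order (rows pre-sorted by id)
  cl2 <- cluster_annotation(m[c(3, 1, 4, 2), ])
  expect_equal(cl2$order, cl$order)
  # single row: trivial order
  expect_equal(cluster_annotation(m[1, , drop = FALSE])$order, "a")
})

test_that("random binary fixtures keep identical rows adjacent in leaf order", {
  set.seed(55)
  for (i in 1:10) {
    m <- matrix(stats::rbinom(12 * 5, 1, 0.4), 12, 5)
    rownames(m) <- sprintf("p%02d", 1:12)
    ord <- cluster_annotation(m)$order
    key <- apply(m[ord, ], 1, paste, collapse = "")
    # identical patterns must form runs
    expect_equal(sum(key[-1] != key[-length(key)]) + 1L, length(unique(key)))
  }
})

test_that("promoter/new-motif association uses the Fisher exact test", {
  # motif planted only in promoter peaks: strongly significant
  m <- cbind(in_234 = 0L, promoter = rep(c(1L, 0L), each = 60),
             has_new_motif = rep(c(1L, 0L), each = 60),
             has_runx_motif = 0L, has_gata_motif = 0L)
  rownames(m) <- sprintf("p%03d", 1:120)
  out <- motif_promoter_association(m)
  expect_lt(out$p_value, 1e-6)
  expect_equal(unname(out$table["yes", "yes"]), 60L)
  # degenerate: every peak is a promoter peak -> p = 1
  m2 <- m; m2[, "promoter"] <- 1L
  expect_equal(motif_promoter_association(m2)$p_value, 1)
})

test_that("Fisher p agrees with full enumeration at fixed margins", {
  # enumerate all tables with the observed margins and sum the
  # probabilities of tables no more probable than the observed one
  enum_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    ks <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(ks, m, n, k)
    obs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  cases <- list(c(3, 1, 1, 3), c(5, 0, 0, 5), c(2, 2, 2, 2), c(1, 4, 3, 2),
                c(8, 2, 3, 7), c(0, 4, 4, 0))
  for (cs in cases) {
    tab <- matrix(cs, 2, byrow = TRUE)
    expect_equal(stats::fisher.test(tab)$p.value,
                 enum_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
  }
})
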