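# Shared fixtures, built in code.

# small, fast simulation config for unit tests (any default overridable)
small_sim <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 60L,
         chrom_lengths = c(chr1 = 2000000L, chr2 = 2000000L),
         n_peaks_shared = 12L, n_peaks_late = 28L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# naive per-position IUPAC matcher: the independent oracle for the scanner
naive_scan <- function(seq, motif) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
              N = "N")
    paste(rev(comp[strsplit(s, NULL)[[1]]]), collapse = "")
  }
  one <- function(seq, motif) {
    sl <- strsplit(seq, NULL)[[1]]
    ml <- strsplit(motif, NULL)[[1]]
    L <- length(sl); m <- length(ml)
    if (L < m) return(integer(0))
    hits <- integer(0)
    for (off in 0:(L - m)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        if (!sl[off + j] %in% sets[[ml[j]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, off)
    }
    hits
  }
  fwd <- one(seq, motif)
  rev <- one(seq, rc(motif))
  out <- rbind(
    if (length(fwd)) data.frame(offset = fwd, strand = "+"),
    if (length(rev)) data.frame(offset = rev, strand = "-"))
  if (is.null(out)) return(data.frame(offset = integer(), strand = character()))
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force all-pairs peak-to-gene assignment: oracle for assign_peaks()
brute_assign <- function(peaks, genes, promoter_bp = 500L, window_bp = 50000L) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    dt <- abs(s - g$tss)
    if (any(dt <= promoter_bp)) {
      for (j in which(dt <= promoter_bp))
        rows[[length(rows) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = g$gene_id[j],
          category = "promoter", distance = dt[j])
      next
    }
    inside <- s >= g$start & s < g$end
    if (any(inside)) {
      for (j in which(inside))
        rows[[length(rows) + 1]] <- data.frame(
          peak_id = peaks$peak_id[i], gene_id = g$gene_id[j],
          category = "intragenic", distance = 0L)
      next
    }
    left <- which(g$end <= s)
    if (length(left) > 0) {
      dl <- s - (g$end[left] - 1L)
      for (j in left[dl == min(dl)])
        if (s - (g$end[j] - 1L) <= window_bp)
          rows[[length(rows) + 1]] <- data.frame(
            peak_id = peaks$peak_id[i], gene_id = g$gene_id[j],
            category = "intergenic_5prime", distance = s - (g$end[j] - 1L))
    }
    right <- which(g$start > s)
    if (length(right) > 0) {
      dr <- g$start[right] - s
      for (j in right[dr == min(dr)])
        if (g$start[j] - s <= window_bp)
          rows[[length(rows) + 1]] <- data.frame(
            peak_id = peaks$peak_id[i], gene_id = g$gene_id[j],
            category = "intergenic_3prime", distance = g$start[j] - s)
    }
  }
  if (length(rows) == 0)
    return(data.frame(peak_id = character(), gene_id = character(),
                      category = character(), distance = integer()))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# random small gene/peak instance for oracle-equivalence tests
random_instance <- function(n_genes = 20, n_peaks = 20, chrom_len = 500000L) {
  starts <- sort(sample.int(chrom_len - 20000L, n_genes))
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                      chrom = "chrX", start = starts,
                      end = starts + sample(500:15000, n_genes, TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  summits <- sample.int(chrom_len, n_peaks)
  peaks <- data.frame(peak_id = sprintf("p%03d", seq_len(n_peaks)),
                      chrom = "chrX", start = pmax(0L, summits - 200L),
                      end = summits + 200L, summit = summits,
                      h2 = 1, h3 = 1, h4 = 1,
                      called2 = TRUE, called3 = TRUE, called4 = TRUE,
                      stringsAsFactors = FALSE)
  list(genes = genes, peaks = peaks)
}

sort_links <- function(l)
  l[order(l$peak_id, l$gene_id, l$category), c("peak_id", "gene_id",
                                               "category", "distance")]
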