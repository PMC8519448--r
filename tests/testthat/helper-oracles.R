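# Independent oracles used across the suite. They deliberately avoid the
# code paths they check: survival by exhaustive enumeration, haplotype
# k-mers by plain substring scans of explicit strings, and a linear FASTA
# scanner that bypasses the graph/path modules entirely.

NUCS4 <- c("A", "C", "G", "T")

# exhaustive survival function of a scaled matrix under an i.i.d.
# background: enumerate all 4^k sequences (k <= 8)
enum_survival <- function(spssm, bg, at_scores) {
  k <- spssm$width
  stopifnot(k <= 8)
  idx <- as.matrix(expand.grid(rep(list(1:4), k)))
  tot <- integer(nrow(idx))
  pr <- rep(1, nrow(idx))
  for (i in seq_len(k)) {
    tot <- tot + spssm$int_matrix[cbind(idx[, i], i)]
    pr <- pr * as.numeric(bg)[idx[, i]]
  }
  vapply(at_scores, function(s) sum(pr[tot >= s]), 0)
}

# all (start0, kmer) substrings of an explicit string
substring_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(data.frame(start = integer(0), seq = character(0)))
  st <- seq_len(n - k + 1L)
  data.frame(start = st - 1L, seq = substring(s, st, st + k - 1L),
             stringsAsFactors = FALSE)
}

# independent linear PSSM scan of a plain sequence string; uses the
# scoring primitives but none of the graph or path-scan code
linear_scan_oracle <- function(seqstr, motif, bg = uniform_background(),
                               pseudocount = 0.1) {
  prob <- pwm_to_probabilities(motif, bg, pseudocount)
  sp <- scale_pssm(build_pssm(prob, bg))
  tbl <- build_pvalue_table(sp, bg)
  k <- sp$width
  km <- substring_kmers(seqstr, k)
  rows <- list()
  for (i in seq_len(nrow(km))) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") km$seq[i] else vgmotif:::revcomp(km$seq[i])
      sc <- score_kmer(sp, s)
      rows[[length(rows) + 1L]] <- data.frame(
        start = km$start[i] + 1L, stop = km$start[i] + k, strand = strand,
        matched_sequence = s, score = round(unscale_score(sp, sc), 3),
        pvalue = score_pvalue(tbl, sc), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$pvalue, out$start, out$strand), ]
}

# small graph builders reused across files
gt1 <- function(a, b, sample = "S1") {
  matrix(c(a, b), 1, 2, dimnames = list(sample, NULL))
}

snp_bubble_graph <- function() {
  v <- variant_record("chrT", 4, "T", "G", gt1(0L, 1L))
  build_graph("ACGTACGT", list(v), chrom = "chrT")
}

two_snp_graph <- function() {
  # haplotypes 00 and 11 only (phased across both variants)
  g <- matrix(c(0L, 1L), 1, 2, dimnames = list("S1", NULL))
  v1 <- variant_record("chrT", 4, "T", "G", g)
  v2 <- variant_record("chrT", 9, "C", "A", g)
  build_graph("ACGTACGTCAGTC", list(v1, v2), chrom = "chrT")
}

random_count_pwm <- function(k, id = "RND") {
  m <- matrix(stats::rpois(4 * k, 5) + stats::runif(4 * k), 4, k)
  pwm(id, m)
}
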