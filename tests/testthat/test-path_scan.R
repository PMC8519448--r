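test_that("single-path enumeration yields plain substrings", {
  g <- build_graph("ACGT", chrom = "chrT")
  raw <- enumerate_kmer_paths(g, 0, 4, 2)
  expect_equal(raw$sequence, c("AC", "CG", "GT"))
  expect_equal(raw$ref_start, 0:2)
  expect_equal(unique(raw$path), "ref")
})

test_that("haplotype-mode enumeration equals the substring oracle", {
  g <- snp_bubble_graph()
  k <- 3
  raw <- enumerate_kmer_paths(g, 0, 8, k)
  strings <- list(ref = "ACGTACGT", `S1#0` = "ACGTACGT", `S1#1` = "ACGGACGT")
  for (nm in names(strings)) {
    got <- raw[raw$path == nm, ]
    want <- substring_kmers(strings[[nm]], k)
    expect_equal(got$sequence, want$seq, info = nm)
    expect_equal(got$ref_start, want$start, info = nm)
  }

  # indel graph: projections follow the left-anchor convention
  v <- variant_record("chrT", 4, "T", "TAA", gt1(0L, 1L))
  gi <- build_graph("ACGTACGT", list(v), chrom = "chrT")
  raw1 <- enumerate_kmer_paths(gi, 0, 8, 3)
  h1 <- raw1[raw1$path == "S1#1", ]
  want <- substring_kmers("ACGTAAACGT", 3)
  expect_equal(h1$sequence, want$seq)
  # inserted bases project to the left anchor end (reference coord 4)
  expect_equal(h1$ref_start, c(0:3, 4L, 4L, 4L, 5L))
})

test_that("window starts must fall inside the region", {
  g <- build_graph("ACGTACGT", chrom = "chrT")
  raw <- enumerate_kmer_paths(g, 2, 5, 3)
  expect_equal(raw$ref_start, 2:4)  # window at 4 extends past the edge
  expect_error(enumerate_kmer_paths(g, 5, 2, 3), "inverted")
})

test_that("aggregation counts haplotypes and flags reference membership", {
  g <- snp_bubble_graph()  # one sample, het 0|1 SNP
  hits <- aggregate_hits(enumerate_kmer_paths(g, 0, 8, 3), g, "r1")
  over <- hits[hits$ref_start == 3 & hits$strand == "+", ]
  ref_row <- over[over$sequence == "TAC", ]
  alt_row <- over[over$sequence == "GAC", ]
  expect_equal(ref_row$haplotype_count, 1L)
  expect_true(ref_row$in_reference)
  expect_equal(alt_row$haplotype_count, 1L)
  expect_false(alt_row$in_reference)

  # homozygous alt: alt k-mer carries both haplotypes, ref spelling none
  vh <- variant_record("chrT", 4, "T", "G", gt1(1L, 1L))
  gh <- build_graph("ACGTACGT", list(vh), chrom = "chrT")
  hh <- aggregate_hits(enumerate_kmer_paths(gh, 0, 8, 3), gh, "r1")
  oh <- hh[hh$ref_start == 3 & hh$strand == "+", ]
  expect_equal(oh[oh$sequence == "GAC", ]$haplotype_count, 2L)
  expect_equal(oh[oh$sequence == "TAC", ]$haplotype_count, 0L)
  expect_true(oh[oh$sequence == "TAC", ]$in_reference)

  # invariant window: single hit carrying all haplotypes
  inv <- hits[hits$ref_start == 0 & hits$strand == "+", ]
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$haplotype_count, 2L)
  expect_true(inv$in_reference)
})

test_that("SNP-site haplotype counts are conserved per site and strand", {
  set.seed(31)
  n_samples <- 6
  gt <- matrix(as.integer(runif(n_samples * 2) < 0.4), n_samples, 2,
               dimnames = list(sprintf("S%d", 1:n_samples), NULL))
  v <- variant_record("chrT", 10, "A", "G", gt)
  ref <- paste(sample(NUCS4, 20, replace = TRUE), collapse = "")
  substr(ref, 10, 10) <- "A"
  g <- build_graph(ref, list(v), chrom = "chrT")
  hits <- aggregate_hits(enumerate_kmer_paths(g, 0, 20, 4), g, "r1")
  sums <- tapply(hits$haplotype_count,
                 paste(hits$ref_start, hits$strand), sum)
  expect_true(all(sums == 2L * n_samples))
})

test_that("recombinant mode is a superset adding unobserved combinations", {
  g <- two_snp_graph()  # haplotypes 00 and 11 on ACGTACGTCAGTC
  k <- 7
  hap <- aggregate_hits(enumerate_kmer_paths(g, 0, 13, k), g, "r1")
  rec <- aggregate_hits(enumerate_kmer_paths(g, 0, 13, k,
                                             mode = "recombinant"), g, "r1")
  key <- function(h) paste(h$sequence, h$ref_start, h$strand)
  expect_true(all(key(hap) %in% key(rec)))

  # the 01 and 10 allele combinations appear only in recombinant mode
  s01 <- substring_kmers("ACGTACGTAAGTC", k)  # ref at 4, alt at 9
  s10 <- substring_kmers("ACGGACGTCAGTC", k)  # alt at 4, ref at 9
  span_both <- function(df) df[df$start <= 3 & df$start + k > 8, ]
  for (df in list(span_both(s01), span_both(s10))) {
    expect_true(nrow(df) > 0)
    expect_true(all(paste(df$seq, df$start, "+") %in% key(rec)))
    expect_false(any(paste(df$seq, df$start, "+") %in% key(hap)))
  }
  # recombinant-only hits carry no haplotype support
  only <- rec[!key(rec) %in% key(hap), ]
  expect_true(all(only$haplotype_count == 0L))

  expect_error(enumerate_kmer_paths(g, 0, 13, k, mode = "recombinant",
                                    max_walks = 3), "max_walks")
})

test_that("zero-variant graph hits match a direct FASTA scan", {
  ref <- "TTGACCGTAGGCATTTGA"
  g <- build_graph(ref, chrom = "chrT")
  hits <- aggregate_hits(enumerate_kmer_paths(g, 0, nchar(ref), 5), g, "r1")
  plus <- hits[hits$strand == "+", ]
  want <- substring_kmers(ref, 5)
  expect_equal(plus$sequence, want$seq)
  expect_equal(plus$ref_start, want$start)
  minus <- hits[hits$strand == "-", ]
  expect_equal(minus$sequence, vgmotif:::revcomp(want$seq))
})
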