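test_that("variant-free graph is a lossless single-path graph", {
  g <- build_graph("ACGTACGT", chrom = "chrT")
  expect_equal(path_sequence(g, g$ref_path), "ACGTACGT")
  expect_length(g$nodes, 1L)
  expect_equal(nrow(g$edges), 0L)
  expect_length(g$hap_paths, 0L)
})

test_that("a SNP forms a bubble and haplotypes spell substituted strings", {
  g <- snp_bubble_graph()
  expect_equal(path_sequence(g, g$ref_path), "ACGTACGT")
  expect_true(all(c("T", "G") %in% g$nodes))
  haps <- vapply(g$hap_paths, function(h) path_sequence(g, h$nodes), "")
  expect_setequal(haps, c("ACGTACGT", "ACGGACGT"))
  # phase 1 carries the alternative allele
  ph1 <- g$hap_paths[[which(vapply(g$hap_paths, `[[`, 0L, "phase") == 1L)]]
  expect_equal(path_sequence(g, ph1$nodes), "ACGGACGT")
})

test_that("deletions and insertions edit haplotype strings per VCF semantics", {
  # CG>C at pos 2 removes the G at reference position 3
  v <- variant_record("chrT", 2, "CG", "C", gt1(1L, 1L))
  g <- build_graph("ACGTACGT", list(v), chrom = "chrT")
  expect_equal(path_sequence(g, g$ref_path), "ACGTACGT")
  ed <- paste0(substr("ACGTACGT", 1, 2), substr("ACGTACGT", 4, 8))  # string edit
  for (h in g$hap_paths) expect_equal(path_sequence(g, h$nodes), ed)

  # T>TAA at pos 4 inserts AA after position 4 on phase 1 only
  v2 <- variant_record("chrT", 4, "T", "TAA", gt1(0L, 1L))
  g2 <- build_graph("ACGTACGT", list(v2), chrom = "chrT")
  haps <- vapply(g2$hap_paths, function(h) path_sequence(g2, h$nodes), "")
  expect_setequal(haps, c("ACGTACGT", "ACGTAAACGT"))
})

test_that("multi-allelic records get one branch per alternative allele", {
  v <- variant_record("chrT", 4, "T", c("G", "C"),
                      matrix(c(1L, 2L), 1, 2, dimnames = list("S1", NULL)))
  g <- build_graph("ACGTACGT", list(v), chrom = "chrT")
  haps <- vapply(g$hap_paths, function(h) path_sequence(g, h$nodes), "")
  expect_setequal(haps, c("ACGGACGT", "ACGCACGT"))
})

test_that("construction errors and overlap handling", {
  expect_error(build_graph("ACGTACGT", list(
    variant_record("chrT", 4, "A", "G", gt1(0L, 1L))), chrom = "chrT"),
    "REF mismatch")
  vs <- list(variant_record("chrT", 6, "C", "G", gt1(0L, 1L)),
             variant_record("chrT", 2, "C", "A", gt1(0L, 1L)))
  expect_error(build_graph("ACGTACGT", vs, chrom = "chrT"), "sorted")
  expect_error(variant_record("chrT", 4, "T", "<DEL>", gt1(0L, 1L)),
               "symbolic")
  expect_error(variant_record("chrT", 4, "T", "G",
                              matrix(c(0L, 3L), 1, 2)), "out of range")

  # overlapping second record is skipped, first wins
  ov <- list(variant_record("chrT", 2, "CGT", "C", gt1(0L, 1L)),
             variant_record("chrT", 4, "T", "G", gt1(0L, 1L)))
  expect_warning(g <- build_graph("ACGTACGT", ov, chrom = "chrT"),
                 "overlapping")
  haps <- vapply(g$hap_paths, function(h) path_sequence(g, h$nodes), "")
  expect_setequal(haps, c("ACGTACGT", "ACACGT"))
})

test_that("unphased genotypes are rejected and missing ones default to ref", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrT,length=8>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "chrT\t4\t.\tT\tG\t.\tPASS\t.\tGT\t0|1\t./."), tmp)
  expect_warning(vcf <- read_phased_vcf(tmp), "missing genotype")
  expect_equal(vcf$samples, c("S1", "S2"))
  expect_equal(vcf$variants[[1]]$gt["S2", ], c(0L, 0L))

  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrT,length=8>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "chrT\t4\t.\tT\tG\t.\tPASS\t.\tGT\t0/1"), tmp)
  expect_error(read_phased_vcf(tmp), "unphased")
})

test_that("path_sequence validates walks", {
  g <- snp_bubble_graph()
  expect_error(path_sequence(g, c(1L, 99L)), "unknown node")
  # both branch nodes of the bubble are never linked to each other
  branches <- which(g$node_start == 3 & g$node_span == 1)
  expect_error(path_sequence(g, branches), "nonexistent edge")
  n1 <- g$ref_path[1]
  expect_equal(path_sequence(g, n1), unname(g$nodes[n1]))
})

test_that("GFA serialization round-trips the data model", {
  g <- snp_bubble_graph()
  g2 <- read_gfa(write_gfa(g))
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$ref_path, g$ref_path)
  expect_equal(g2$hap_paths, g$hap_paths)
  expect_equal(g2$node_start, g$node_start)
  expect_equal(g2$node_span, g$node_span)
  expect_equal(g2$chrom, g$chrom)

  # indel graph round-trips too (projection re-derived from anchors)
  v <- variant_record("chrT", 4, "T", "TAA", gt1(0L, 1L))
  gi <- build_graph("ACGTACGT", list(v), chrom = "chrT")
  gi2 <- read_gfa(write_gfa(gi))
  expect_equal(gi2$node_start, gi$node_start)
  expect_equal(gi2$node_span, gi$node_span)

  # file round-trip
  tmp <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, tmp)
  expect_equal(read_gfa(tmp)$nodes, g$nodes)
})

test_that("hand-written GFA parses and malformed GFA is rejected", {
  txt <- "H\tVN:Z:1.0\nS\t1\tACG\nS\t2\tT\nS\t3\tGG\nL\t1\t+\t2\t+\t0M\nL\t2\t+\t3\t+\t0M\nP\tchrZ\t1+,2+,3+\t*"
  g <- read_gfa(txt)
  expect_length(g$nodes, 3L)
  expect_length(g$ref_path, 3L)
  expect_equal(path_sequence(g, g$ref_path), "ACGTGG")
  expect_equal(g$chrom, "chrZ")

  expect_error(read_gfa("H\tVN:Z:1.0\nS\t1"), "malformed")
  expect_error(read_gfa("H\tVN:Z:1.0\nS\t1\tACG\nP\tchrZ\t1+,7+\t*"),
               "unknown segment")
})

test_that("region_window selects bubble nodes by projection", {
  g <- snp_bubble_graph()
  all_win <- region_window(g, 0, 8)
  expect_setequal(all_win$nodes, seq_along(g$nodes))

  inside <- region_window(g, 0, 2)
  expect_equal(inside$nodes, g$ref_path[1])

  bubble <- region_window(g, 3, 4)
  branch_nodes <- which(g$node_start == 3 & g$node_span == 1)
  expect_true(all(branch_nodes %in% bubble$nodes))
  expect_length(bubble$nodes, 2L)

  expect_error(region_window(g, 5, 5), "inverted")
  expect_warning(w <- region_window(g, 6, 50), "clipped")
  expect_equal(w$end, 8L)
})
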