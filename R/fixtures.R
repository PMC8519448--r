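# Deterministic toy-data generator: FASTA + phased VCF + BED + motif
# files with planted motif instances, plus a manifest of expected
# significant occurrences computed by an independent oracle that
# enumerates explicit haplotype strings and scores them directly
# (no use of the graph, path-scan or scaled-scoring code).

#' A small built-in test motif
#'
#' Count matrix with a single strong consensus (10 counts on the
#' consensus base per column, 0 elsewhere); width <= 8 so the oracle can
#' enumerate all k-mers exhaustively.
#'
#' @param consensus consensus sequence (default "ACGTTGCA").
#' @param motif_id,name identifiers.
#' @param counts consensus count per column (default 10).
#' @return a [pwm] count matrix.
#' @export
toy_motif <- function(consensus = "ACGTTGCA", motif_id = "TOYM1",
                      name = "TOY", counts = 10) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(ch %in% NUCS))
  m <- matrix(0, 4, length(ch), dimnames = list(NUCS, NULL))
  m[cbind(match(ch, NUCS), seq_along(ch))] <- counts
  pwm(motif_id, m, name = name)
}

# --- independent oracle helpers (plain direct implementations) ---------

oracle_logodds <- function(pwm, bg, pseudocount) {
  m <- pwm$matrix
  p <- matrix(0, 4, ncol(m))
  for (i in seq_len(ncol(m)))
    p[, i] <- (m[, i] + pseudocount * bg) / (sum(m[, i]) + pseudocount)
  log2(p / bg)
}

oracle_score <- function(lo, seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], NUCS)
  if (anyNA(idx)) return(NA_real_)
  sum(lo[cbind(idx, seq_along(idx))])
}

# exhaustive real-score distribution over all 4^k sequences
oracle_score_distribution <- function(lo, bg) {
  k <- ncol(lo)
  stopifnot(k <= 8)
  idx <- as.matrix(expand.grid(rep(list(1:4), k)))
  scores <- numeric(nrow(idx))
  probs <- rep(1, nrow(idx))
  for (i in seq_len(k)) {
    scores <- scores + lo[cbind(idx[, i], i)]
    probs <- probs * bg[idx[, i]]
  }
  list(scores = scores, probs = probs)
}

oracle_pvalue <- function(dist, s) {
  vapply(s, function(x) sum(dist$probs[dist$scores >= x - 1e-9]), 0)
}

# apply one haplotype's alleles to the reference by string edits,
# tracking the projected reference coordinate of every base (bases
# introduced by an alternative allele project to the left anchor end)
oracle_haplotype <- function(ref_chars, variants, sample_i, phase) {
  chars <- ref_chars
  proj <- seq_along(ref_chars) - 1L
  ord <- order(vapply(variants, `[[`, 1L, "pos"), decreasing = TRUE)
  for (v in variants[ord]) {
    allele <- v$gt[sample_i, phase + 1L]
    if (allele == 0L) next
    a <- v$alts[allele]
    cp <- common_prefix_len(v$ref, a)
    start0 <- v$pos - 1L + cp
    ref_len <- nchar(v$ref) - cp
    alt_chars <- if (nchar(a) > cp) strsplit(substring(a, cp + 1L), "")[[1]]
                 else character(0)
    left <- if (start0 > 0L) seq_len(start0) else integer(0)
    right <- if (start0 + ref_len < length(chars))
      (start0 + ref_len + 1L):length(chars) else integer(0)
    chars <- c(chars[left], alt_chars, chars[right])
    proj <- c(proj[left], rep(start0, length(alt_chars)), proj[right])
  }
  list(chars = chars, proj = proj)
}

# enumerate, group and test k-mers of explicit strings; returns the
# expected-significant manifest rows for one motif over one region
oracle_manifest <- function(pwm, strings, region, bg, pseudocount,
                            p_threshold) {
  lo <- oracle_logodds(pwm, bg, pseudocount)
  dist <- oracle_score_distribution(lo, bg)
  k <- ncol(lo)
  ent <- list()
  for (nm in names(strings)) {
    st <- strings[[nm]]
    n <- length(st$chars)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      p0 <- st$proj[i]
      if (p0 < region[1] || p0 >= region[2]) next
      ent[[length(ent) + 1L]] <- list(
        path = nm, ref_start = p0,
        seq = paste(st$chars[i:(i + k - 1L)], collapse = ""))
    }
  }
  if (!length(ent)) return(NULL)
  dt <- data.table::rbindlist(ent)
  path <- ref_start <- NULL
  grp <- dt[, list(
    haplotype_count = data.table::uniqueN(path[path != "ref"]),
    in_reference = any(path == "ref")), by = list(seq, ref_start)]
  rows <- list()
  for (i in seq_len(nrow(grp))) {
    fw <- grp$seq[i]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fw else revcomp(fw)
      sc <- oracle_score(lo, s)
      if (is.na(sc)) next
      pv <- oracle_pvalue(dist, sc)
      if (pv < p_threshold)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          motif_id = pwm$motif_id, start = grp$ref_start[i] + 1L,
          stop = grp$ref_start[i] + k, strand = strand, sequence = s,
          flag = if (grp$in_reference[i]) "ref" else "non.ref",
          haplotype_count = grp$haplotype_count[i], pvalue = pv,
          score = sc)
    }
  }
  if (!length(rows)) NULL else data.table::rbindlist(rows)
}

write_toy_vcf <- function(path, chrom, chrom_len, variants, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom, chrom_len),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(variants, function(v) {
    gts <- apply(v$gt, 1, function(g) paste0(g[1], "|", g[2]))
    paste(c(v$chrom, v$pos, ".", v$ref, paste(v$alts, collapse = ","),
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
}

#' Generate a deterministic toy dataset with planted motif instances
#'
#' Draws a uniform-random background chromosome, plants motif consensus
#' instances (either into the reference or onto the alternative branch of
#' a dedicated heterozygous SNP), adds random phased SNPs and indels, and
#' writes FASTA, VCF, BED and JASPAR files. An expected-hit manifest is
#' computed by explicit haplotype-string enumeration with a direct
#' scoring/P-value oracle, independent of the scanning pipeline.
#'
#' @param out_dir output directory (created).
#' @param seed RNG seed; fixed seed gives byte-identical files.
#' @param chrom chromosome name.
#' @param chrom_len chromosome length (>= 200).
#' @param n_samples number of diploid samples.
#' @param n_snps,n_indels number of random background variants (the
#'   planted-site SNPs are extra).
#' @param allele_freq alternative-allele frequency used to draw phased
#'   genotypes for random variants.
#' @param planted list of plantings, each `list(motif = <pwm>, position =
#'   <1-based start>, branch = "ref"|"alt")`. An "alt" planting writes the
#'   consensus with one broken position into the reference and adds a SNP
#'   restoring the consensus, heterozygous (0|1) in sample 1.
#' @param p_threshold significance threshold used for the manifest.
#' @param pseudocount pseudocount used by the manifest oracle (match the
#'   scan's).
#' @return list with file paths (`fasta`, `vcf`, `bed`, `motifs`,
#'   `manifest`), the `manifest` table, `variants`, `samples`, the
#'   reference string and the motif list.
#' @export
make_toy_dataset <- function(out_dir, seed = 42, chrom = "chrT",
                             chrom_len = 600, n_samples = 10, n_snps = 8,
                             n_indels = 2, allele_freq = 0.3,
                             planted = list(list(motif = toy_motif(),
                                                 position = 301,
                                                 branch = "alt")),
                             p_threshold = 1e-4, pseudocount = 0.1) {
  stopifnot(chrom_len >= 200)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  bg <- rep(0.25, 4)
  samples <- sprintf("S%02d", seq_len(n_samples))
  ref_chars <- sample(NUCS, chrom_len, replace = TRUE)

  blocked <- rep(FALSE, chrom_len)  # no random variants near plantings
  motifs <- list()
  variants <- list()
  for (pl in planted) {
    motif <- pl$motif
    k <- motif$width
    pos <- as.integer(pl$position)
    if (pos < 2L || pos + k > chrom_len)
      stop("planted site at ", pos, " does not fit the chromosome")
    win <- max(1L, pos - k):min(chrom_len, pos + 2L * k)
    if (any(blocked[win]))
      stop("infeasible planting: site at ", pos, " overlaps another planting")
    blocked[win] <- TRUE
    cons <- NUCS[apply(motif$matrix, 2, which.max)]
    if (identical(pl$branch, "ref")) {
      ref_chars[pos:(pos + k - 1L)] <- cons
    } else if (identical(pl$branch, "alt")) {
      broken <- cons
      col <- (k + 1L) %/% 2L  # break the site mid-motif on the reference
      broken[col] <- setdiff(NUCS, cons[col])[1]
      ref_chars[pos:(pos + k - 1L)] <- broken
      gt <- matrix(0L, n_samples, 2, dimnames = list(samples, NULL))
      gt[1, 2] <- 1L  # het 0|1 in sample 1
      variants[[length(variants) + 1L]] <-
        variant_record(chrom, pos + col - 1L, broken[col], cons[col], gt)
    } else stop("planted branch must be 'ref' or 'alt'")
    if (!motif$motif_id %in% vapply(motifs, `[[`, "", "motif_id"))
      motifs[[length(motifs) + 1L]] <- motif
  }
  if (!length(motifs)) motifs <- list(toy_motif())

  draw_gt <- function() {
    g <- matrix(stats::rbinom(n_samples * 2L, 1L, allele_freq),
                n_samples, 2, dimnames = list(samples, NULL))
    storage.mode(g) <- "integer"
    g
  }
  occupy <- function(from, to) {
    from <- max(1L, from); to <- min(chrom_len, to)
    if (any(blocked[from:to])) return(FALSE)
    blocked[from:to] <<- TRUE
    TRUE
  }
  n_placed <- 0L; tries <- 0L
  while (n_placed < n_snps && tries < 50L * n_snps) {
    tries <- tries + 1L
    p <- sample.int(chrom_len - 2L, 1L) + 1L
    if (!occupy(p - 1L, p + 1L)) next
    alt <- sample(setdiff(NUCS, ref_chars[p]), 1L)
    variants[[length(variants) + 1L]] <-
      variant_record(chrom, p, ref_chars[p], alt, draw_gt())
    n_placed <- n_placed + 1L
  }
  n_placed <- 0L; tries <- 0L
  while (n_placed < n_indels && tries < 50L * max(1L, n_indels)) {
    tries <- tries + 1L
    len <- sample.int(3L, 1L)
    p <- sample.int(chrom_len - len - 3L, 1L) + 1L
    if (!occupy(p - 1L, p + len + 1L)) next
    if (stats::runif(1) < 0.5) {  # deletion
      refa <- paste(ref_chars[p:(p + len)], collapse = "")
      alt <- ref_chars[p]
    } else {                      # insertion
      refa <- ref_chars[p]
      alt <- paste(c(ref_chars[p], sample(NUCS, len, replace = TRUE)),
                   collapse = "")
    }
    variants[[length(variants) + 1L]] <-
      variant_record(chrom, p, refa, alt, draw_gt())
    n_placed <- n_placed + 1L
  }
  variants <- variants[order(vapply(variants, `[[`, 1L, "pos"))]

  reference <- paste(ref_chars, collapse = "")
  fasta <- file.path(out_dir, "reference.fa")
  writeLines(c(paste0(">", chrom), reference), fasta)
  vcf <- file.path(out_dir, "variants.vcf")
  write_toy_vcf(vcf, chrom, chrom_len, variants, samples)
  bed <- file.path(out_dir, "regions.bed")
  writeLines(sprintf("%s\t0\t%d\ttoy_region", chrom, chrom_len), bed)
  motif_path <- file.path(out_dir, "motifs.jaspar")
  writeLines(paste(vapply(motifs, write_jaspar, ""), collapse = ""),
             motif_path)

  # oracle manifest over explicit haplotype strings
  strings <- list(ref = list(chars = ref_chars,
                             proj = seq_len(chrom_len) - 1L))
  for (s in seq_len(n_samples)) for (ph in 0:1)
    strings[[paste0(samples[s], "#", ph)]] <-
      oracle_haplotype(ref_chars, variants, s, ph)
  manifest <- data.table::rbindlist(lapply(motifs, function(m)
    oracle_manifest(m, strings, c(0L, chrom_len), bg, pseudocount,
                    p_threshold)))
  if (!nrow(manifest))
    manifest <- data.table::data.table(
      motif_id = character(0), start = integer(0), stop = integer(0),
      strand = character(0), sequence = character(0), flag = character(0),
      haplotype_count = integer(0), pvalue = numeric(0), score = numeric(0))
  manifest[, chrom := chrom]
  data.table::setorder(manifest, start, strand)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  data.table::fwrite(manifest, manifest_path, sep = "\t")

  list(fasta = fasta, vcf = vcf, bed = bed, motif_file = motif_path,
       manifest_file = manifest_path, manifest = manifest[],
       variants = variants, samples = samples, reference = reference,
       motifs = motifs, chrom = chrom, chrom_len = chrom_len)
}
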