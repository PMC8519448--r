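# Full scan orchestration: enumerate, score, test, pool q-values, filter
# and classify candidate binding sites.

#' Scan a variation graph for motif occurrences
#'
#' For each motif the PWM is normalized, converted to a log-odds PSSM,
#' scaled to `[0, 1000]` and its exact P-value table built once. K-mer
#' hits are enumerated and aggregated over all regions, scored on both
#' strands, and q-values computed per motif over the pooled P-values of
#' all scored k-mer hits in all scanned regions.
#'
#' @param graph a [build_graph]/[read_gfa] result.
#' @param motifs a [pwm] or list of them (count or probability matrices).
#' @param regions data.frame/data.table with columns chrom, start, end
#'   (0-based half-open), e.g. from [read_bed_regions].
#' @param bg [background] (default uniform).
#' @param pseudocount pseudocount for [pwm_to_probabilities] (default 0.1).
#' @param p_threshold optional strict P-value cutoff (e.g. 1e-4); NULL
#'   returns every scored hit.
#' @param q_threshold optional strict q-value cutoff.
#' @param mode "haplotype" or "recombinant" (see [enumerate_kmer_paths]).
#' @param compute_qvalues set FALSE to skip BH (e.g. when pooling across
#'   chromosomes afterwards with [pool_qvalues]).
#' @param max_walks recombinant walk cap per region.
#' @return data.table of motif occurrences sorted by ascending P-value
#'   (ties by chrom, start, strand) with columns motif_id, motif_alt_id,
#'   sequence_name, chrom, start, stop (1-based inclusive), strand, score
#'   (unscaled log2-odds, 3 decimals), pvalue, qvalue, matched_sequence,
#'   haplotype_count, haplotype_fraction, reference ("ref"/"non.ref").
#' @export
scan_graph <- function(graph, motifs, regions, bg = uniform_background(),
                       pseudocount = 0.1, p_threshold = NULL,
                       q_threshold = NULL, mode = "haplotype",
                       compute_qvalues = TRUE, max_walks = 1e4) {
  stopifnot(inherits(graph, "variation_graph"))
  if (inherits(motifs, "pwm")) motifs <- list(motifs)
  if (!length(motifs)) stop("empty motif list: nothing to scan")
  regions <- data.table::as.data.table(regions)
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  if (nrow(regions) && any(regions$chrom != graph$chrom))
    stop("region chromosome(s) ", paste(unique(
      regions$chrom[regions$chrom != graph$chrom]), collapse = ","),
      " do not match graph chromosome ", graph$chrom)
  bg <- background(as.numeric(bg))
  n_hap <- length(graph$hap_paths)

  res <- lapply(motifs, function(motif) {
    prob <- pwm_to_probabilities(motif, bg, pseudocount)
    pssm <- build_pssm(prob, bg)
    sp <- scale_pssm(pssm)
    tbl <- build_pvalue_table(sp, bg)
    k <- sp$width
    hits <- data.table::rbindlist(lapply(seq_len(nrow(regions)), function(i) {
      rid <- sprintf("%s:%d-%d", regions$chrom[i], regions$start[i],
                     regions$end[i])
      raw <- enumerate_kmer_paths(graph, regions$start[i], regions$end[i],
                                  k, mode = mode, max_walks = max_walks)
      aggregate_hits(raw, graph, region_id = rid)
    }))
    if (!nrow(hits)) return(NULL)
    # windows dominated by Ns are uninformative and dropped
    n_count <- nchar(hits$sequence) - nchar(gsub("N", "", hits$sequence))
    hits <- hits[n_count <= k %/% 2L]
    if (!nrow(hits)) return(NULL)
    scaled <- score_kmers(sp, hits$sequence)
    occ <- data.table::data.table(
      motif_id = motif$motif_id, motif_alt_id = motif$name,
      sequence_name = hits$region_id, chrom = hits$chrom,
      start = hits$ref_start + 1L, stop = hits$ref_stop,
      strand = hits$strand,
      score = round(unscale_score(sp, scaled), 3),
      pvalue = score_pvalue(tbl, scaled),
      qvalue = NA_real_,
      matched_sequence = hits$sequence,
      haplotype_count = hits$haplotype_count,
      haplotype_fraction = if (n_hap > 0) hits$haplotype_count / n_hap
                           else NA_real_,
      reference = ifelse(hits$in_reference, "ref", "non.ref"))
    if (compute_qvalues) occ$qvalue <- benjamini_hochberg(occ$pvalue)
    occ
  })
  occ <- data.table::rbindlist(res)
  if (!nrow(occ)) return(empty_occurrences())
  occ <- apply_significance(occ, p_threshold, q_threshold)
  sort_occurrences(occ)
}

empty_occurrences <- function() {
  data.table::data.table(
    motif_id = character(0), motif_alt_id = character(0),
    sequence_name = character(0), chrom = character(0), start = integer(0),
    stop = integer(0), strand = character(0), score = numeric(0),
    pvalue = numeric(0), qvalue = numeric(0), matched_sequence = character(0),
    haplotype_count = integer(0), haplotype_fraction = numeric(0),
    reference = character(0))
}

sort_occurrences <- function(occ) {
  data.table::setorder(occ, pvalue, chrom, start, strand, motif_id)
  occ[]
}

#' Recompute q-values over pooled occurrences
#'
#' BH per motif over the pooled P-values of all rows; used after merging
#' per-chromosome scans so the pool spans every scanned region.
#'
#' @param occ occurrence table from [scan_graph] (possibly rbind-ed).
#' @return the table with `qvalue` recomputed, re-sorted.
#' @export
pool_qvalues <- function(occ) {
  if (!nrow(occ)) return(occ)
  occ <- data.table::as.data.table(occ)
  motif_id <- NULL
  occ[, qvalue := benjamini_hochberg(pvalue), by = motif_id]
  sort_occurrences(occ)
}

#' Filter occurrences by significance
#'
#' Strict (`<`) inequality filters on P-value and optionally q-value;
#' row order is preserved.
#'
#' @param occ occurrence table.
#' @param p_threshold P-value cutoff, or NULL for no P filter.
#' @param q_threshold q-value cutoff, or NULL for no q filter.
#' @return filtered table.
#' @export
apply_significance <- function(occ, p_threshold = NULL, q_threshold = NULL) {
  if (!is.null(p_threshold)) occ <- occ[occ$pvalue < p_threshold, ]
  if (!is.null(q_threshold)) occ <- occ[!is.na(occ$qvalue) &
                                          occ$qvalue < q_threshold, ]
  occ
}

#' Classify candidate binding sites by variant effect
#'
#' Groups the occurrences of one motif by site `(chrom, start, strand)`
#' and labels each site with at least one member passing the P-value
#' threshold:
#' \itemize{
#'   \item \code{non-ref-only}: no reference spelling passes — the site is
#'     gained on alternative haplotypes.
#'   \item \code{ref-only}: the reference spelling passes but no variant
#'     spelling does — the site is disrupted by variants.
#'   \item \code{shared-modulated}: reference and variant spellings both
#'     pass with different scores.
#'   \item \code{shared-equal}: otherwise (including invariant sites).
#' }
#'
#' @param occ occurrence table for a single motif.
#' @param p_threshold strict significance cutoff (default 1e-4).
#' @return list with `sites` (data.table: chrom, start, strand, category)
#'   and `summary` (category, n, percent).
#' @export
classify_sites <- function(occ, p_threshold = 1e-4) {
  occ <- data.table::as.data.table(occ)
  if (length(unique(occ$motif_id)) > 1L)
    stop("classify_sites expects occurrences of a single motif")
  chrom <- start <- strand <- NULL
  sites <- occ[, {
    pass <- pvalue < p_threshold
    is_ref <- reference == "ref"
    ref_pass <- any(pass & is_ref)
    nonref_pass <- any(pass & !is_ref)
    has_nonref <- any(!is_ref)
    cat <- if (!ref_pass && !nonref_pass) NA_character_
    else if (!ref_pass) "non-ref-only"
    else if (has_nonref && !nonref_pass) "ref-only"
    else if (nonref_pass &&
             length(unique(score[pass])) > 1L) "shared-modulated"
    else "shared-equal"
    list(category = cat)
  }, by = list(chrom, start, strand)]
  sites <- sites[!is.na(sites$category), ]
  category <- NULL
  summary <- sites[, list(n = .N), by = category]
  summary[, percent := 100 * n / sum(n)]
  data.table::setorder(summary, -n)
  list(sites = sites[], summary = summary[])
}
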