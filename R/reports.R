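# Report serialization: FIMO-style TSV, UCSC-loadable GFF3 and HTML.
# All output coordinates are 1-based inclusive (already so in the
# occurrence table); scores carry 3 decimals, P/q-values scientific.

fmt_score <- function(x) sprintf("%.3f", x)
fmt_p <- function(x) ifelse(is.na(x), "", sprintf("%.3g", x))
fmt_frac <- function(x) ifelse(is.na(x), "", sprintf("%.4g", x))

occurrence_strings <- function(occ) {
  data.table::data.table(
    motif_id = occ$motif_id, motif_alt_id = occ$motif_alt_id,
    sequence_name = occ$sequence_name,
    start = as.character(occ$start), stop = as.character(occ$stop),
    strand = occ$strand, score = fmt_score(occ$score),
    `p-value` = fmt_p(occ$pvalue), `q-value` = fmt_p(occ$qvalue),
    matched_sequence = occ$matched_sequence,
    haplotype_frequency = fmt_frac(occ$haplotype_fraction),
    reference = occ$reference)
}

#' Write occurrences as a FIMO-style TSV report
#'
#' Columns: motif_id, motif_alt_id, sequence_name, start, stop, strand,
#' score, p-value, q-value, matched_sequence, plus the two graph-specific
#' columns haplotype_frequency and reference ("ref"/"non.ref").
#'
#' @param occ occurrence table from [scan_graph].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_occurrence_tsv <- function(occ, path) {
  df <- occurrence_strings(occ)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

#' Write occurrences as a GFF3 custom track
#'
#' One `nucleotide_motif` feature per occurrence, 1-based inclusive
#' coordinates, attribute values percent-encoded per the GFF3 spec; the
#' file can be loaded on the UCSC genome browser as a custom track.
#'
#' @inheritParams write_occurrence_tsv
#' @export
write_occurrence_gff3 <- function(occ, path) {
  lines <- "##gff-version 3"
  if (nrow(occ)) {
    ids <- sprintf("%s_%s:%d-%d(%s)", occ$motif_id, occ$chrom, occ$start,
                   occ$stop, occ$strand)
    attrs <- sprintf(
      "Name=%s;ID=%s;pvalue=%s;qvalue=%s;sequence=%s;haplotype_frequency=%s;haplotype_count=%d;reference=%s",
      gff3_encode(occ$motif_id), gff3_encode(ids), fmt_p(occ$pvalue),
      fmt_p(occ$qvalue), gff3_encode(occ$matched_sequence),
      fmt_frac(occ$haplotype_fraction), occ$haplotype_count,
      occ$reference)
    lines <- c(lines, sprintf("%s\tvgmotif\tnucleotide_motif\t%d\t%d\t%s\t%s\t.\t%s",
                              occ$chrom, occ$start, occ$stop,
                              fmt_score(occ$score), occ$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write occurrences as a standalone HTML report
#'
#' Same columns and row order as the TSV report, as a plain HTML table.
#'
#' @inheritParams write_occurrence_tsv
#' @export
write_occurrence_html <- function(occ, path) {
  df <- occurrence_strings(occ)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                    collapse = ""), "</tr>")
  body <- if (nrow(df)) {
    cells <- vapply(seq_len(nrow(df)), function(i)
      paste0("<tr>", paste0("<td>", html_escape(unlist(df[i, ])), "</td>",
                            collapse = ""), "</tr>"), "")
    paste(cells, collapse = "\n")
  } else ""
  writeLines(c("<!DOCTYPE html>", "<html><head>",
               "<meta charset=\"utf-8\"/><title>vgmotif report</title>",
               "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font-family:monospace}</style>",
               "</head><body>", "<h1>vgmotif motif occurrence report</h1>",
               "<table>", head_row, body, "</table>", "</body></html>"),
             path)
  invisible(path)
}

#' Write the full report set (TSV + GFF3 + HTML)
#'
#' @param occ occurrence table from [scan_graph].
#' @param out_dir output directory (created if missing).
#' @param prefix file name prefix (default "vgmotif").
#' @param formats subset of c("tsv", "gff3", "html").
#' @return named character vector of written paths.
#' @export
write_reports <- function(occ, out_dir, prefix = "vgmotif",
                          formats = c("tsv", "gff3", "html")) {
  if (!length(formats)) stop("at least one report format is required")
  formats <- match.arg(formats, c("tsv", "gff3", "html"), several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(0)
  if ("tsv" %in% formats)
    out["tsv"] <- write_occurrence_tsv(occ, file.path(out_dir, paste0(prefix, ".tsv")))
  if ("gff3" %in% formats)
    out["gff3"] <- write_occurrence_gff3(occ, file.path(out_dir, paste0(prefix, ".gff3")))
  if ("html" %in% formats)
    out["html"] <- write_occurrence_html(occ, file.path(out_dir, paste0(prefix, ".html")))
  out
}
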