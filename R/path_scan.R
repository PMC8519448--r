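# K-mer window enumeration along graph paths and aggregation into
# located hits with haplotype multiplicity and reference membership.

.datatable.aware <- TRUE

#' Enumerate k-mer windows along graph paths in a region
#'
#' In haplotype mode a window of length k slides along the reference path
#' and every haplotype path; a window is kept when its projected start
#' coordinate lies inside `[start, end)` (it may extend up to k-1 bases
#' past the right edge). In recombinant mode, every directed walk through
#' the windowed subgraph spelling k bases is additionally enumerated,
#' regardless of haplotype support, up to `max_walks` walks per region.
#'
#' @param graph a [build_graph] result.
#' @param start,end 0-based half-open reference interval.
#' @param k motif width (>= 1).
#' @param mode "haplotype" (default) or "recombinant".
#' @param max_walks cap on recombinant walks per region (default 1e4).
#' @return data.table with columns `path` ("ref", "sample#phase" or
#'   "recombinant"), `ref_start` (projected 0-based start), `offset`
#'   (0-based position along the source path) and `sequence`.
#' @export
enumerate_kmer_paths <- function(graph, start, end, k,
                                 mode = c("haplotype", "recombinant"),
                                 max_walks = 1e4) {
  stopifnot(inherits(graph, "variation_graph"), k >= 1)
  mode <- match.arg(mode)
  if (start >= end) stop("inverted region: start must be < end")
  k <- as.integer(k)

  paths <- c(list(list(name = "ref", nodes = graph$ref_path)),
             lapply(graph$hap_paths, function(h)
               list(name = paste0(h$sample, "#", h$phase), nodes = h$nodes)))
  out <- lapply(paths, function(p) {
    if (!length(p$nodes)) return(NULL)
    s <- path_sequence(graph, p$nodes)
    proj <- path_projection(graph, p$nodes)
    n <- nchar(s)
    idx <- which(proj >= start & proj < end & seq_len(n) + k - 1L <= n)
    if (!length(idx)) return(NULL)
    data.table::data.table(path = p$name, ref_start = proj[idx],
                           offset = idx - 1L,
                           sequence = substring(s, idx, idx + k - 1L))
  })
  res <- data.table::rbindlist(out)

  if (mode == "recombinant") {
    win <- region_window(graph, start, end, flank = k - 1L)
    adj <- split(graph$edges$to, graph$edges$from)
    count <- 0L
    acc_start <- integer(0); acc_seq <- character(0)
    explode <- function() stop("recombinant walk count exceeds max_walks (",
                               max_walks, ") in window ", graph$chrom, ":",
                               start, "-", end)
    walk <- function(node, off, acc, origin) {
      nseq <- graph$nodes[[node]]
      need <- k - nchar(acc)
      take <- substring(nseq, off, min(nchar(nseq), off + need - 1L))
      acc <- paste0(acc, take)
      if (nchar(acc) == k) {
        count <<- count + 1L
        if (count > max_walks) explode()
        acc_start[count] <<- origin
        acc_seq[count] <<- acc
      } else {
        for (nxt in adj[[as.character(node)]]) walk(nxt, 1L, acc, origin)
      }
    }
    for (node in win$nodes) {
      nseq <- graph$nodes[[node]]
      len <- nchar(nseq)
      offs <- seq_len(len)
      proj <- if (graph$is_ref_node[node])
        graph$node_start[node] + offs - 1L
      else rep(graph$node_start[node], len)
      for (o in offs[proj >= start & proj < end])
        walk(node, o, "", proj[o])
    }
    if (count > 0L)
      res <- rbind(res, data.table::data.table(
        path = "recombinant", ref_start = acc_start[seq_len(count)],
        offset = NA_integer_, sequence = acc_seq[seq_len(count)]))
  }
  if (!nrow(res))
    res <- data.table::data.table(path = character(0), ref_start = integer(0),
                                  offset = integer(0), sequence = character(0))
  res
}

#' Aggregate raw k-mer windows into located hits
#'
#' Groups raw windows by `(sequence, ref_start)`; `haplotype_count` is the
#' number of distinct sample haplotype paths in the group (the reference
#' path is excluded and flagged separately via `in_reference`). Each
#' aggregated plus-strand hit is paired with a minus-strand hit carrying
#' the reverse-complement spelling at the same coordinates.
#'
#' @param raw data.table from [enumerate_kmer_paths] (one region, one k).
#' @param graph the source graph (for the chromosome name).
#' @param region_id identifier of the originating region.
#' @return data.table of k-mer hits: sequence, chrom, ref_start, ref_stop
#'   (0-based half-open), strand, haplotype_count, in_reference,
#'   region_id.
#' @export
aggregate_hits <- function(raw, graph, region_id = NA_character_) {
  cols <- c("sequence", "chrom", "ref_start", "ref_stop", "strand",
            "haplotype_count", "in_reference", "region_id")
  if (!nrow(raw)) {
    empty <- data.table::data.table(sequence = character(0), chrom = character(0),
                                    ref_start = integer(0), ref_stop = integer(0),
                                    strand = character(0), haplotype_count = integer(0),
                                    in_reference = logical(0), region_id = character(0))
    return(empty[, cols, with = FALSE])
  }
  path <- NULL; sequence <- NULL; ref_start <- NULL  # NSE note for R CMD check
  k <- nchar(raw$sequence[1])
  plus <- raw[, list(
    haplotype_count = data.table::uniqueN(path[!(path %in% c("ref", "recombinant"))]),
    in_reference = any(path == "ref")),
    by = list(sequence, ref_start)]
  plus[, `:=`(chrom = graph$chrom, ref_stop = ref_start + k, strand = "+",
              region_id = region_id)]
  minus <- data.table::copy(plus)
  minus[, `:=`(sequence = revcomp(sequence), strand = "-")]
  out <- rbind(plus, minus)
  data.table::setorder(out, ref_start, strand, sequence)
  out[, cols, with = FALSE]
}
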