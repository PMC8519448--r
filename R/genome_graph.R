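# Variation-graph construction from a reference chromosome plus phased
# variants, haplotype threading, GFA text persistence and region queries.
#
# Internal coordinates are 0-based half-open; VCF positions are converted
# on ingest. Nodes carry a reference projection: reference-path nodes
# project to their own reference interval, alternative-branch nodes to the
# reference coordinate of their bubble's left anchor end.

#' Construct a phased variant record
#'
#' @param chrom chromosome name.
#' @param pos 1-based reference position (VCF POS).
#' @param ref reference allele (non-empty A/C/G/T string).
#' @param alts character vector of alternative alleles.
#' @param gt integer matrix (n_samples x 2) of phased allele indices
#'   (0 = reference, i = i-th alt); row names are sample ids.
#' @return object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alts, gt) {
  stopifnot(is_string(chrom), length(pos) == 1L, pos >= 1,
            is_string(ref), nzchar(ref), is.character(alts), length(alts) >= 1L)
  gt <- as.matrix(gt)
  if (ncol(gt) != 2L) stop("genotype matrix must have two phase columns")
  storage.mode(gt) <- "integer"
  if (any(is.na(gt)) || any(gt < 0) || any(gt > length(alts)))
    stop("allele index out of range in genotypes")
  if (any(grepl("[][<>]", alts)) || !all(grepl("^[ACGTNacgtn]+$", alts)))
    stop("symbolic or breakend alleles are not supported")
  obj <- list(chrom = chrom, pos = as.integer(pos), ref = toupper(ref),
              alts = toupper(alts), gt = gt)
  class(obj) <- "variant_record"
  obj
}

#' Read phased variants from a VCF file
#'
#' Thin wrapper over `VariantAnnotation::readVcf`. Genotypes must be
#' phased (`0|1`); missing genotypes (`./.` or `.`) fall back to the
#' reference allele with a warning.
#'
#' @param path plain or bgzipped VCF with GT fields.
#' @return list with `variants` (list of [variant_record]) and `samples`.
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  samples <- colnames(gt)
  n_missing <- 0L
  variants <- lapply(seq_len(nrow(gt)), function(i) {
    alts <- as.character(altl[[i]])
    g <- gt[i, ]
    gm <- matrix(0L, nrow = length(samples), ncol = 2,
                 dimnames = list(samples, NULL))
    for (s in seq_along(samples)) {
      gs <- g[[s]]
      if (is.na(gs) || gs %in% c(".", "./.", ".|.")) {
        n_missing <<- n_missing + 1L
        next
      }
      if (grepl("/", gs, fixed = TRUE))
        stop("unphased genotype '", gs, "' at ", chrom[i], ":", pos[i],
             " (phased haplotypes are required)")
      a <- suppressWarnings(as.integer(strsplit(gs, "|", fixed = TRUE)[[1]]))
      if (length(a) != 2L || anyNA(a))
        stop("malformed genotype '", gs, "' at ", chrom[i], ":", pos[i])
      gm[s, ] <- a
    }
    variant_record(chrom[i], pos[i], ref[i], alts, gm)
  })
  if (n_missing > 0L)
    warning(n_missing, " missing genotype(s) set to the reference allele")
  list(variants = variants, samples = samples)
}

#' Read a reference genome from FASTA
#' @param path FASTA file.
#' @return named character vector, one element per chromosome.
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  out
}

#' Read genomic regions from a BED file
#' @param path BED file (3+ columns, 0-based half-open).
#' @return data.table with columns chrom, start, end, name.
#' @export
read_bed_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm)
}

#' Build a variation graph for one chromosome
#'
#' The reference is split into anchor nodes at variant boundaries; each
#' alternative allele becomes a branch node (a deletion becomes an edge
#' skipping reference bases, an insertion an extra node between anchors),
#' so variants form bubbles anchored by common reference sequence. One
#' haplotype path is threaded per sample per phase following its phased
#' genotypes. Variant records overlapping an earlier record are skipped
#' with a warning (first wins).
#'
#' @param reference chromosome sequence (character string or DNAString).
#' @param variants list of [variant_record] sorted by position, all on
#'   this chromosome, with REF alleles matching the reference.
#' @param chrom chromosome name (default taken from the first variant, or
#'   "ref" when there are none).
#' @param samples optional sample ids (defaults to the variants' samples);
#'   used to thread haplotype paths even through variant-free stretches.
#' @return object of class `variation_graph` with fields `nodes` (named
#'   character vector of node sequences), `edges` (data.table from/to),
#'   `ref_path`, `hap_paths`, `node_start` (reference projection),
#'   `node_span`, `is_ref_node`, `chrom`, `samples`, `length`.
#' @export
build_graph <- function(reference, variants = list(), chrom = NULL,
                        samples = NULL) {
  reference <- toupper(as.character(reference))
  stopifnot(is_string(reference), nzchar(reference))
  L <- nchar(reference)
  if (length(variants)) {
    chroms <- vapply(variants, `[[`, "", "chrom")
    if (length(unique(chroms)) != 1L)
      stop("variants span multiple chromosomes; build one graph per chromosome")
    chrom <- chrom %||% chroms[1]
    if (chrom != chroms[1]) stop("variant chromosome does not match 'chrom'")
    pos <- vapply(variants, `[[`, 1L, "pos")
    if (is.unsorted(pos)) stop("variants must be sorted by position")
    if (is.null(samples)) samples <- rownames(variants[[1]]$gt)
  }
  chrom <- chrom %||% "ref"
  samples <- samples %||% character(0)

  # normalize records into events with a shared varying interval
  events <- list()
  prev_end <- -1L
  ins_points <- integer(0)
  for (v in variants) {
    if (v$pos + nchar(v$ref) - 1L > L)
      stop("variant at ", v$chrom, ":", v$pos, " extends past the chromosome end")
    obs <- substr(reference, v$pos, v$pos + nchar(v$ref) - 1L)
    if (obs != v$ref)
      stop("REF mismatch at ", v$chrom, ":", v$pos, ": VCF says '", v$ref,
           "' but reference has '", obs, "'")
    cp <- min(vapply(v$alts, function(a) common_prefix_len(v$ref, a), 0L))
    start0 <- v$pos - 1L + cp
    end0 <- v$pos - 1L + nchar(v$ref)
    alt_seqs <- substring(v$alts, cp + 1L)
    if (start0 < prev_end ||
        (start0 == end0 && start0 %in% ins_points)) {
      warning("skipping variant at ", v$chrom, ":", v$pos,
              " overlapping an earlier record (first wins)")
      next
    }
    if (start0 == end0) ins_points <- c(ins_points, start0)
    prev_end <- max(prev_end, end0)
    events[[length(events) + 1L]] <-
      list(start = start0, end = end0, alt_seqs = alt_seqs, gt = v$gt)
  }

  ev_start <- vapply(events, `[[`, 0L, "start")
  ev_end <- vapply(events, `[[`, 0L, "end")
  bps <- sort(unique(c(0L, L, ev_start, ev_end)))
  seg_start <- bps[-length(bps)]
  seg_end <- bps[-1]
  keep <- seg_end > seg_start
  seg_start <- seg_start[keep]
  seg_end <- seg_end[keep]
  n_seg <- length(seg_start)

  node_seq <- substring(reference, seg_start + 1L, seg_end)
  node_start <- seg_start
  node_span <- seg_end - seg_start
  is_ref_node <- rep(TRUE, n_seg)
  next_id <- n_seg

  # per event: id of its reference-region segment (NA for insertions) and
  # ids of its alt branch nodes (NA for deletion branches)
  ev_ref_seg <- rep(NA_integer_, length(events))
  ev_alt_node <- vector("list", length(events))
  for (e in seq_along(events)) {
    if (ev_start[e] < ev_end[e])
      ev_ref_seg[e] <- match(ev_start[e], seg_start)
    alt_ids <- integer(length(events[[e]]$alt_seqs))
    for (a in seq_along(alt_ids)) {
      aseq <- events[[e]]$alt_seqs[a]
      if (nzchar(aseq)) {
        next_id <- next_id + 1L
        node_seq[next_id] <- aseq
        node_start[next_id] <- ev_start[e]
        node_span[next_id] <- ev_end[e] - ev_start[e]
        is_ref_node[next_id] <- FALSE
        alt_ids[a] <- next_id
      } else alt_ids[a] <- NA_integer_  # deletion: edge, not node
    }
    ev_alt_node[[e]] <- alt_ids
  }
  n_nodes <- next_id
  node_end <- node_start + ifelse(is_ref_node[seq_len(n_nodes)],
                                  node_span[seq_len(n_nodes)],
                                  node_span[seq_len(n_nodes)])
  # junction model: at every reference coordinate p, connect each node
  # ending at p to each node starting at p; zero-span insertion nodes sit
  # between the two layers; deletion alleles connect start/end junctions.
  e_from <- integer(0); e_to <- integer(0)
  add_edges <- function(from, to) {
    if (length(from) && length(to)) {
      g <- expand.grid(from = from, to = to)
      g <- g[g$from != g$to, , drop = FALSE]
      e_from <<- c(e_from, g$from); e_to <<- c(e_to, g$to)
    }
  }
  zero_span <- !is_ref_node[seq_len(n_nodes)] & node_span[seq_len(n_nodes)] == 0L
  junctions <- sort(unique(c(node_start[seq_len(n_nodes)], node_end)))
  for (p in junctions) {
    enders <- which(node_end == p & !zero_span)
    starters <- which(node_start[seq_len(n_nodes)] == p & !zero_span)
    ins <- which(zero_span & node_start[seq_len(n_nodes)] == p)
    add_edges(enders, starters)
    add_edges(enders, ins)
    add_edges(ins, starters)
  }
  for (e in seq_along(events)) {  # deletion skip edges
    if (any(is.na(ev_alt_node[[e]]))) {
      enders <- which(node_end == ev_start[e] & !zero_span)
      starters <- which(node_start[seq_len(n_nodes)] == ev_end[e] & !zero_span)
      ins <- which(zero_span & node_start[seq_len(n_nodes)] == ev_start[e])
      add_edges(c(enders, ins), starters)
    }
  }
  edges <- unique(data.table::data.table(from = e_from, to = e_to))
  data.table::setorder(edges, from, to)

  ref_path <- which(is_ref_node[seq_len(n_nodes)])
  ref_path <- ref_path[order(node_start[ref_path])]

  # thread haplotype paths
  ins_events <- which(ev_start == ev_end)
  hap_paths <- list()
  for (s in seq_along(samples)) {
    for (phase in 0:1) {
      path <- integer(0)
      for (seg in seq_len(n_seg)) {
        p <- seg_start[seg]
        for (e in ins_events[ev_start[ins_events] == p]) {
          allele <- events[[e]]$gt[s, phase + 1L]
          if (allele > 0L) path <- c(path, ev_alt_node[[e]][allele])
        }
        e <- match(seg, ev_ref_seg)
        if (!is.na(e)) {
          allele <- events[[e]]$gt[s, phase + 1L]
          if (allele == 0L) path <- c(path, seg)
          else {
            an <- ev_alt_node[[e]][allele]
            if (!is.na(an)) path <- c(path, an)  # NA = deletion, skip bases
          }
        } else path <- c(path, seg)
      }
      for (e in ins_events[ev_start[ins_events] == L]) {
        allele <- events[[e]]$gt[s, phase + 1L]
        if (allele > 0L) path <- c(path, ev_alt_node[[e]][allele])
      }
      hap_paths[[length(hap_paths) + 1L]] <-
        list(sample = samples[s], phase = phase, nodes = path)
    }
  }

  g <- list(nodes = stats::setNames(node_seq, as.character(seq_len(n_nodes))),
            edges = edges, ref_path = ref_path, hap_paths = hap_paths,
            node_start = node_start[seq_len(n_nodes)],
            node_span = node_span[seq_len(n_nodes)],
            is_ref_node = is_ref_node[seq_len(n_nodes)],
            chrom = chrom, samples = samples, length = L)
  class(g) <- "variation_graph"
  g
}

#' @export
print.variation_graph <- function(x, ...) {
  cat(sprintf("variation_graph %s: %d bp, %d nodes, %d edges, %d haplotype paths (%d samples)\n",
              x$chrom, x$length, length(x$nodes), nrow(x$edges),
              length(x$hap_paths), length(x$samples)))
  invisible(x)
}

edge_keys <- function(graph) paste(graph$edges$from, graph$edges$to)

#' Spell the sequence of a path through the graph
#'
#' @param graph a [build_graph] result.
#' @param path integer (or coercible) vector of node ids forming a walk
#'   over existing edges.
#' @return concatenated node sequences.
#' @export
path_sequence <- function(graph, path) {
  path <- as.integer(path)
  if (!length(path)) return("")
  if (any(path < 1L | path > length(graph$nodes)))
    stop("path references unknown node id(s)")
  if (length(path) > 1L) {
    steps <- paste(path[-length(path)], path[-1])
    bad <- !(steps %in% edge_keys(graph))
    if (any(bad))
      stop("path uses nonexistent edge(s): ", paste(steps[bad], collapse = ", "))
  }
  paste(graph$nodes[path], collapse = "")
}

# Reference projection of every base position along a path: positions in
# reference nodes map to their true coordinate, positions in alternative
# branch nodes all map to the bubble's left anchor end.
path_projection <- function(graph, path) {
  path <- as.integer(path)
  lens <- nchar(graph$nodes[path])
  unlist(lapply(seq_along(path), function(i) {
    n <- path[i]
    if (graph$is_ref_node[n]) graph$node_start[n] + seq_len(lens[i]) - 1L
    else rep(graph$node_start[n], lens[i])
  }), use.names = FALSE)
}

#' Windowed view of the graph around a reference region
#'
#' @param graph a `variation_graph`.
#' @param start,end 0-based half-open reference interval.
#' @param flank extra bases allowed past the right edge (use `k - 1` so
#'   motifs overlapping the boundary are found).
#' @return list with `nodes` (ids), `edges` (subset), `projection`
#'   (named node start coordinates) and the clipped `start`/`end`.
#' @export
region_window <- function(graph, start, end, flank = 0L) {
  stopifnot(inherits(graph, "variation_graph"))
  if (start >= end) stop("inverted region: start must be < end")
  if (start < 0) { warning("region start clipped to 0"); start <- 0L }
  if (end > graph$length) {
    warning("region extends past chromosome end; clipped")
    end <- graph$length
  }
  hi <- min(end + flank, graph$length)
  span <- pmax(graph$node_span, 1L)
  ids <- which(graph$node_start < hi & graph$node_start + span > start)
  edges <- graph$edges[graph$edges$from %in% ids & graph$edges$to %in% ids, ]
  list(nodes = ids, edges = edges,
       projection = stats::setNames(graph$node_start[ids], as.character(ids)),
       start = as.integer(start), end = as.integer(end))
}

#' Serialize a variation graph to GFA v1 text
#'
#' S-lines hold node sequences, L-lines edges (overlap 0M), P-lines the
#' reference path (named by chromosome) and haplotype paths (named
#' `sample#phase`).
#'
#' @param graph a `variation_graph`.
#' @param path optional file to write to.
#' @return the GFA text, invisibly when written to a file.
#' @export
write_gfa <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "variation_graph"))
  pline <- function(name, nodes)
    sprintf("P\t%s\t%s\t*", name,
            if (length(nodes)) paste0(nodes, "+", collapse = ",") else "")
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s", names(graph$nodes), unname(graph$nodes)),
             if (nrow(graph$edges))
               sprintf("L\t%d\t+\t%d\t+\t0M", graph$edges$from, graph$edges$to),
             pline(graph$chrom, graph$ref_path),
             vapply(graph$hap_paths, function(h)
               pline(paste0(h$sample, "#", h$phase), h$nodes), ""))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Read a variation graph from GFA v1 text
#'
#' The reference path is the P-line whose name contains no `#`; haplotype
#' paths are named `sample#phase`. Node projections are re-derived from
#' the reference path and bubble anchors.
#'
#' @param text GFA text, vector of lines, or a file path.
#' @return a `variation_graph`.
#' @export
read_gfa <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- as_lines(text)
  lines <- lines[nzchar(lines)]
  seqs <- character(0)
  e_from <- integer(0); e_to <- integer(0)
  paths <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rec <- f[1]
    if (rec == "H" || rec == "#") next
    if (rec == "S") {
      if (length(f) < 3L) stop("malformed GFA S-line: ", ln)
      seqs[f[2]] <- toupper(f[3])
    } else if (rec == "L") {
      if (length(f) < 6L) stop("malformed GFA L-line: ", ln)
      e_from <- c(e_from, f[2]); e_to <- c(e_to, f[4])
    } else if (rec == "P") {
      if (length(f) < 3L) stop("malformed GFA P-line: ", ln)
      ids <- if (nzchar(f[3]) && f[3] != "*")
        sub("[+-]$", "", strsplit(f[3], ",", fixed = TRUE)[[1]])
      else character(0)
      paths[[f[2]]] <- ids
    } else if (!rec %in% c("C", "W")) stop("malformed GFA line: ", ln)
  }
  ids <- names(seqs)
  if (any(!c(e_from, e_to, unlist(paths)) %in% ids))
    stop("GFA references an unknown segment")
  # renumber segments 1..n preserving file order
  remap <- stats::setNames(seq_along(ids), ids)
  n <- length(ids)
  node_seq <- unname(seqs)
  pnames <- names(paths)
  is_hap <- grepl("#", pnames, fixed = TRUE)
  if (sum(!is_hap) > 1L) stop("GFA holds more than one reference path")
  chrom <- if (any(!is_hap)) pnames[!is_hap][1] else "ref"
  ref_path <- if (any(!is_hap)) unname(remap[paths[[chrom]]]) else integer(0)
  node_start <- integer(n); node_span <- integer(n)
  is_ref <- rep(FALSE, n)
  off <- 0L
  for (nid in ref_path) {
    node_start[nid] <- off
    node_span[nid] <- nchar(node_seq[nid])
    is_ref[nid] <- TRUE
    off <- off + nchar(node_seq[nid])
  }
  edges <- unique(data.table::data.table(from = unname(remap[e_from]),
                                         to = unname(remap[e_to])))
  data.table::setorder(edges, from, to)
  # alt-node projection: left anchor end (max end of ref predecessors),
  # span up to the nearest ref successor start
  for (nid in which(!is_ref)) {
    preds <- edges$from[edges$to == nid]
    preds <- preds[is_ref[preds]]
    node_start[nid] <- if (length(preds))
      max(node_start[preds] + node_span[preds]) else 0L
    succs <- edges$to[edges$from == nid]
    succs <- succs[is_ref[succs]]
    node_span[nid] <- if (length(succs))
      max(0L, min(node_start[succs]) - node_start[nid]) else 0L
  }
  hap_paths <- lapply(pnames[is_hap], function(pn) {
    parts <- strsplit(pn, "#", fixed = TRUE)[[1]]
    list(sample = parts[1], phase = as.integer(parts[2]),
         nodes = unname(remap[paths[[pn]]]))
  })
  samples <- unique(vapply(hap_paths, `[[`, "", "sample"))
  g <- list(nodes = stats::setNames(node_seq, as.character(seq_len(n))),
            edges = edges, ref_path = ref_path, hap_paths = hap_paths,
            node_start = node_start, node_span = node_span,
            is_ref_node = is_ref, chrom = chrom, samples = samples,
            length = sum(nchar(node_seq[ref_path])))
  class(g) <- "variation_graph"
  g
}
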