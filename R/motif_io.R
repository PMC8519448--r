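# Motif model input/output: JASPAR and MEME minimal formats, background
# models, and count -> probability normalization.

#' Construct a position weight matrix object
#'
#' A PWM holds a 4 x k matrix of non-negative values (counts or
#' probabilities) with rows A, C, G, T and one column per motif position.
#'
#' @param motif_id motif identifier (e.g. "MA0139.1").
#' @param name motif name (e.g. "CTCF"); defaults to `motif_id`.
#' @param matrix numeric 4 x k matrix; rows are taken in A,C,G,T order and
#'   row names, if present, are used to reorder.
#' @return an object of class `pwm` with fields `motif_id`, `name`,
#'   `width`, `matrix` and `is_probability` (TRUE when every column sums to
#'   1 within 1e-6).
#' @export
pwm <- function(motif_id, matrix, name = motif_id) {
  stopifnot(is_string(motif_id), is_string(name))
  m <- as.matrix(matrix)
  if (nrow(m) != 4L)
    stop("PWM matrix must have exactly 4 rows (A, C, G, T)")
  if (ncol(m) < 1L)
    stop("PWM matrix must have width >= 1")
  if (!is.null(rownames(m))) {
    rn <- toupper(rownames(m))
    if (!setequal(rn, NUCS))
      stop("PWM row names must be A, C, G, T")
    m <- m[match(NUCS, rn), , drop = FALSE]
  }
  rownames(m) <- NUCS
  colnames(m) <- NULL
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("PWM entries must be finite and non-negative")
  obj <- list(motif_id = motif_id, name = name, width = ncol(m),
              matrix = m,
              is_probability = all(abs(colSums(m) - 1) <= 1e-6))
  class(obj) <- "pwm"
  obj
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), width %d, %s\n", x$motif_id, x$name, x$width,
              if (x$is_probability) "probabilities" else "counts"))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Construct a background nucleotide distribution
#'
#' @param probabilities numeric vector of 4 probabilities; names A,C,G,T
#'   (any order) or unnamed in A,C,G,T order. Each must lie in (0,1) and
#'   they must sum to 1 within 1e-9.
#' @return named numeric vector of class `nt_background`.
#' @export
background <- function(probabilities = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  p <- probabilities
  if (length(p) != 4L) stop("background must have 4 probabilities")
  if (is.null(names(p))) names(p) <- NUCS
  names(p) <- toupper(names(p))
  if (!setequal(names(p), NUCS)) stop("background names must be A, C, G, T")
  p <- p[NUCS]
  if (any(p <= 0) || any(p >= 1)) stop("background probabilities must be in (0,1)")
  if (abs(sum(p) - 1) > 1e-9) stop("background probabilities must sum to 1")
  class(p) <- "nt_background"
  p
}

#' Uniform background (0.25 per nucleotide)
#' @return `nt_background` object.
#' @export
uniform_background <- function() background()

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

parse_jaspar_record <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(trimws(lines[1]), ">"))
    stop("JASPAR record must start with a '>' header line")
  hdr <- split_fields(sub("^\\s*>", "", lines[1]))
  if (!length(hdr) || !nzchar(hdr[1])) stop("JASPAR header has no motif id")
  motif_id <- hdr[1]
  name <- if (length(hdr) >= 2) hdr[2] else motif_id
  rows <- list()
  for (ln in lines[-1]) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z])\\s*[:|]?\\s*\\[?([^]\\[]*)\\]?\\s*$", ln))[[1]]
    if (length(m) < 3) stop("malformed JASPAR matrix row: ", ln)
    nuc <- toupper(m[2])
    if (!nuc %in% NUCS)
      stop("unsupported nucleotide row '", nuc, "' in JASPAR record (alphabet must be ACGT)")
    if (nuc %in% names(rows)) stop("duplicate ", nuc, " row in JASPAR record")
    vals <- suppressWarnings(as.numeric(split_fields(m[3])))
    if (!length(vals) || anyNA(vals))
      stop("non-numeric values in JASPAR ", nuc, " row")
    rows[[nuc]] <- vals
  }
  missing <- setdiff(NUCS, names(rows))
  if (length(missing))
    stop("JASPAR record is missing nucleotide row(s): ",
         paste(missing, collapse = ", "))
  lens <- lengths(rows[NUCS])
  if (length(unique(lens)) != 1L)
    stop("JASPAR rows have unequal lengths (",
         paste(sprintf("%s=%d", NUCS, lens), collapse = ", "), ")")
  pwm(motif_id, do.call(rbind, rows[NUCS]), name = name)
}

#' Parse a single JASPAR-format motif record
#'
#' Accepts both the bracketed dialect (`A [ 1 2 3 ]`) and the bracket-free
#' one (`A 1 2 3`); nucleotide rows may appear in any order.
#'
#' @param text character scalar (with newlines) or vector of lines holding
#'   exactly one record: a `>ID NAME` header plus four nucleotide rows.
#' @return a [pwm] object. Counts are kept as given; `is_probability` is
#'   TRUE only when every column already sums to ~1.
#' @export
parse_jaspar <- function(text) {
  lines <- as_lines(text)
  hdrs <- which(startsWith(trimws(lines), ">"))
  if (length(hdrs) != 1L)
    stop("parse_jaspar expects exactly one record; got ", length(hdrs),
         " header lines (use read_motifs for multi-record files)")
  parse_jaspar_record(lines)
}

parse_jaspar_many <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdrs <- which(startsWith(trimws(lines), ">"))
  if (!length(hdrs)) stop("no JASPAR records found")
  bounds <- c(hdrs, length(lines) + 1L)
  lapply(seq_along(hdrs), function(i)
    parse_jaspar_record(lines[bounds[i]:(bounds[i + 1L] - 1L)]))
}

#' Serialize a PWM to JASPAR text
#' @param pwm a [pwm] object.
#' @return character scalar in bracketed JASPAR format.
#' @export
write_jaspar <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  fmt <- function(v) paste(format(v, trim = TRUE, scientific = FALSE,
                                  digits = 15), collapse = " ")
  paste0(">", pwm$motif_id, " ", pwm$name, "\n",
         paste(sprintf("%s  [ %s ]", NUCS,
                       vapply(seq_len(4), function(i) fmt(pwm$matrix[i, ]), "")),
               collapse = "\n"), "\n")
}

#' Parse a MEME minimal-format motif file
#'
#' Supports the minimal format: a `MEME version` line, `ALPHABET= ACGT`,
#' an optional `Background letter frequencies` block and one or more
#' `MOTIF` blocks with `letter-probability matrix:` headers.
#'
#' @param text character scalar or vector of lines.
#' @return a list of [pwm] objects (one per MOTIF block, in file order,
#'   each with `is_probability = TRUE`). If the file carries a background
#'   line, the parsed [background] is attached as attribute
#'   `"background"`.
#' @export
parse_meme <- function(text) {
  lines <- as_lines(text)
  if (!any(grepl("^\\s*MEME version", lines)))
    stop("not a MEME minimal file: missing 'MEME version' line")
  alph <- grep("^\\s*ALPHABET\\s*=", lines, value = TRUE)
  if (length(alph)) {
    a <- toupper(gsub("[^A-Za-z]", "", sub("^\\s*ALPHABET\\s*=", "", alph[1])))
    if (a != "ACGT")
      stop("unsupported alphabet '", a, "': only ACGT is supported")
  }
  bg <- NULL
  bgi <- grep("^\\s*Background letter frequencies", lines)
  if (length(bgi)) {
    f <- split_fields(lines[bgi[1] + 1L])
    if (length(f) != 8L) stop("malformed MEME background line")
    vals <- as.numeric(f[c(FALSE, TRUE)])
    names(vals) <- toupper(f[c(TRUE, FALSE)])
    bg <- background(vals)
  }
  starts <- grep("^\\s*MOTIF\\b", lines)
  if (!length(starts)) stop("MEME file contains no MOTIF blocks")
  motifs <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (j in seq_along(starts)) {
    blk <- lines[starts[j]:(bounds[j + 1L] - 1L)]
    hdr <- split_fields(blk[1])[-1]
    if (!length(hdr)) stop("MOTIF line without an identifier")
    mid <- hdr[1]
    mname <- if (length(hdr) >= 2) hdr[2] else mid
    lpi <- grep("^\\s*letter-probability matrix", blk)
    if (!length(lpi)) stop("MOTIF ", mid, ": missing letter-probability matrix header")
    hline <- blk[lpi[1]]
    w <- suppressWarnings(as.integer(sub(".*\\bw=\\s*([0-9]+).*", "\\1", hline)))
    al <- regmatches(hline, regexec("alength=\\s*([0-9]+)", hline))[[1]]
    if (length(al) == 2 && as.integer(al[2]) != 4L)
      stop("unsupported alphabet length ", al[2], " (only 4 supported)")
    body <- blk[-seq_len(lpi[1])]
    body <- body[nzchar(trimws(body))]
    rows <- list()
    for (ln in body) {
      f <- suppressWarnings(as.numeric(split_fields(ln)))
      if (anyNA(f)) break  # next keyword block (e.g. URL line)
      rows[[length(rows) + 1L]] <- f
    }
    if (is.na(w)) w <- length(rows)
    if (length(rows) < w)
      stop("MOTIF ", mid, ": expected ", w, " matrix rows, found ", length(rows))
    rows <- rows[seq_len(w)]
    if (any(lengths(rows) != 4L))
      stop("MOTIF ", mid, ": each matrix row must have 4 probabilities")
    m <- t(do.call(rbind, rows))
    sums <- colSums(m)
    if (any(abs(sums - 1) > 1e-3))
      stop("MOTIF ", mid, ": probability rows must sum to 1 (max deviation ",
           format(max(abs(sums - 1))), ")")
    m <- sweep(m, 2, sums, "/")  # renormalize tiny drift
    rownames(m) <- NUCS
    motifs[[j]] <- pwm(mid, m, name = mname)
  }
  attr(motifs, "background") <- bg
  motifs
}

#' Serialize PWMs to MEME minimal format
#' @param pwms a [pwm] or list of them (must be probability matrices).
#' @param bg optional [background] written as the background line.
#' @return character scalar with the MEME minimal text.
#' @export
write_meme <- function(pwms, bg = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "")
  if (!is.null(bg)) {
    out <- c(out, "Background letter frequencies",
             paste(sprintf("%s %.6f", NUCS, as.numeric(bg)), collapse = " "), "")
  }
  for (p in pwms) {
    if (!p$is_probability)
      stop("write_meme requires probability matrices (see pwm_to_probabilities)")
    out <- c(out, sprintf("MOTIF %s %s", p$motif_id, p$name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     p$width),
             vapply(seq_len(p$width), function(i)
               paste(sprintf("%.6f", p$matrix[, i]), collapse = "  "), ""),
             "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Convert a count (or probability) PWM to a probability PWM
#'
#' Applies the FIMO-style pseudocount scheme: with column count total
#' `N_i`, `p(b,i) = (c(b,i) + pseudocount * bg(b)) / (N_i + pseudocount)`.
#' A matrix already in probabilities is treated as counts with `N_i = 1`.
#'
#' @param pwm a [pwm] object.
#' @param bg [background] distribution (default uniform).
#' @param pseudocount non-negative pseudocount mass, spread over
#'   nucleotides proportionally to the background (default 0.1).
#' @return a probability [pwm]; every column sums to 1.
#' @export
pwm_to_probabilities <- function(pwm, bg = uniform_background(), pseudocount = 0.1) {
  stopifnot(inherits(pwm, "pwm"), pseudocount >= 0)
  bg <- background(as.numeric(bg))
  m <- pwm$matrix
  n <- colSums(m)
  if (any(n == 0) && pseudocount == 0)
    stop("degenerate column: zero total count with pseudocount = 0")
  p <- sweep(m + outer(as.numeric(bg), rep(pseudocount, pwm$width)), 2,
             n + pseudocount, "/")
  pwm(pwm$motif_id, p, name = pwm$name)
}

#' Read motifs from a file (JASPAR or MEME)
#'
#' Dispatches on content: files containing `MEME version` are parsed as
#' MEME minimal, everything else as (possibly multi-record) JASPAR.
#'
#' @param path path to a `.jaspar`/`.pfm` or `.meme` file.
#' @return list of [pwm]; MEME background, if any, attached as attribute
#'   `"background"`.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\s*MEME version", lines))) parse_meme(lines)
  else parse_jaspar_many(lines)
}

#' Read a background frequency file
#'
#' Plain two-column text (`A 0.25` per line, order free) or a single line
#' `A 0.3 C 0.2 G 0.2 T 0.3`.
#'
#' @param path file path.
#' @return [background] object.
#' @export
read_background <- function(path) {
  if (!file.exists(path)) stop("background file not found: ", path)
  f <- split_fields(paste(readLines(path, warn = FALSE), collapse = " "))
  f <- f[nzchar(f)]
  if (length(f) != 8L) stop("background file must hold 4 nucleotide/value pairs")
  vals <- as.numeric(f[c(FALSE, TRUE)])
  names(vals) <- toupper(f[c(TRUE, FALSE)])
  background(vals)
}
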