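# Log-odds scoring: PSSM construction, integer scaling to [0, 1000],
# k-mer scoring, exact DP P-values and Benjamini-Hochberg q-values.

#' Build a log-odds position-specific scoring matrix
#'
#' @param pwm probability [pwm] (see [pwm_to_probabilities]); all entries
#'   must be strictly positive.
#' @param bg [background] distribution.
#' @return object of class `pssm` with `logodds(b,i) = log2(p(b,i)/bg(b))`.
#' @export
build_pssm <- function(pwm, bg = uniform_background()) {
  stopifnot(inherits(pwm, "pwm"))
  if (!pwm$is_probability)
    stop("build_pssm requires a probability PWM (run pwm_to_probabilities first)")
  bg <- background(as.numeric(bg))
  if (any(pwm$matrix <= 0))
    stop("zero probability cell would give -Inf log-odds; ",
         "apply a pseudocount in pwm_to_probabilities")
  lo <- log2(sweep(pwm$matrix, 1, as.numeric(bg), "/"))
  obj <- list(motif_id = pwm$motif_id, name = pwm$name, width = pwm$width,
              logodds = lo, bg = bg)
  class(obj) <- "pssm"
  obj
}

#' Scale a PSSM to the integer range [0, 1000]
#'
#' Each column is shifted by its minimum and the whole matrix multiplied
#' by `1000 / sum(column ranges)` then rounded, so every attainable total
#' score of a k-mer lies in `[0, 1000]`. Rounding can push the sum of
#' columnwise maxima past 1000; in that case the maxima of the columns
#' with the largest upward rounding error are decremented by 1 until the
#' bound holds.
#'
#' @param pssm a [build_pssm] result with finite log-odds.
#' @return object of class `scaled_pssm` with fields `int_matrix`
#'   (4 x k non-negative integers), `offsets` (per-column minima),
#'   `scale` (real multiplier), `max_total` (sum of columnwise maxima,
#'   <= 1000), plus motif metadata, background and `strand`.
#' @export
scale_pssm <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  lo <- pssm$logodds
  if (any(!is.finite(lo))) stop("log-odds matrix has non-finite entries")
  offsets <- apply(lo, 2, min)
  ranges <- apply(lo, 2, max) - offsets
  total_range <- sum(ranges)
  if (total_range <= 0)
    stop("degenerate motif: all columns constant, matrix is uninformative")
  scale <- 1000 / total_range
  M <- round(sweep(lo, 2, offsets, "-") * scale)
  storage.mode(M) <- "integer"
  dimnames(M) <- list(NUCS, NULL)
  colmax <- apply(M, 2, max)
  excess <- sum(colmax) - 1000L
  if (excess > 0L) {
    err <- colmax - ranges * scale  # upward rounding error of each column max
    fix <- order(err, decreasing = TRUE)[seq_len(excess)]
    for (j in fix) {
      hit <- M[, j] == colmax[j]
      M[hit, j] <- M[hit, j] - 1L
      colmax[j] <- colmax[j] - 1L
    }
  }
  obj <- list(motif_id = pssm$motif_id, name = pssm$name, width = pssm$width,
              int_matrix = M, offsets = offsets, scale = scale,
              max_total = as.integer(sum(colmax)), bg = pssm$bg,
              strand = "+")
  class(obj) <- "scaled_pssm"
  obj
}

#' Reverse-complement a scaled scoring matrix
#'
#' `int_matrix'(b,i) = int_matrix(comp(b), k+1-i)`; scale and offset sum
#' are preserved, so scoring a sequence with the result equals scoring its
#' reverse complement with the original.
#'
#' @param spssm a [scale_pssm] result.
#' @return `scaled_pssm` for the opposite strand.
#' @export
reverse_complement_pssm <- function(spssm) {
  stopifnot(inherits(spssm, "scaled_pssm"))
  out <- spssm
  k <- spssm$width
  out$int_matrix <- spssm$int_matrix[COMP_IDX, rev(seq_len(k)), drop = FALSE]
  rownames(out$int_matrix) <- NUCS
  out$offsets <- rev(spssm$offsets)
  out$strand <- if (spssm$strand == "+") "-" else "+"
  out
}

check_kmer <- function(seq, k) {
  s <- toupper(seq)
  if (nchar(s) != k)
    stop("sequence length ", nchar(s), " does not match motif width ", k)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- match(ch, c(NUCS, "N"))
  if (anyNA(idx))
    stop("sequence contains non-ACGTN character(s): ",
         paste(unique(ch[is.na(idx)]), collapse = ""))
  idx
}

#' Score one k-mer with a scaled matrix
#'
#' @param spssm a `scaled_pssm`.
#' @param seq k-length string over A/C/G/T/N (case-insensitive). An N
#'   contributes the columnwise minimum, i.e. 0.
#' @return integer total score in `[0, max_total]`.
#' @export
score_kmer <- function(spssm, seq) {
  idx <- check_kmer(seq, spssm$width)
  keep <- idx <= 4L
  sum(spssm$int_matrix[cbind(idx[keep], which(keep))])
}

# Vectorized scorer used by the pipeline; seqs must all have width k and
# only ACGTN characters (callers pre-filter).
score_kmers <- function(spssm, seqs) {
  if (!length(seqs)) return(integer(0))
  k <- spssm$width
  ch <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  idx <- match(ch, c(NUCS, "N"))
  if (anyNA(idx)) stop("sequence contains non-ACGTN characters")
  pos <- rep.int(seq_len(k), length(seqs))
  v <- integer(length(idx))
  keep <- idx <= 4L
  v[keep] <- spssm$int_matrix[cbind(idx[keep], pos[keep])]
  as.integer(colSums(matrix(v, nrow = k)))
}

#' Recover the real log-odds score from a scaled score
#'
#' @param spssm a `scaled_pssm`.
#' @param s integer scaled score in `[0, 1000]`.
#' @return `s/scale + sum(offsets)`, the log2-odds value reported in
#'   output (accurate to `k/(2*scale)`).
#' @export
unscale_score <- function(spssm, s) {
  stopifnot(all(s >= 0), all(s <= 1000))
  s / spssm$scale + sum(spssm$offsets)
}

#' Exact score distribution and P-values by dynamic programming
#'
#' Convolves the per-column score distributions under an i.i.d. background
#' model: `Q_0 = {0 -> 1}`, `Q_i(x) = sum_b bg(b) Q_{i-1}(x - M(b,i))`.
#' The P-value of a hit with scaled score `s` is the inclusive upper tail
#' `P(total >= s)`.
#'
#' @param spssm a `scaled_pssm`.
#' @param bg [background]; defaults to the matrix's own background.
#' @return object of class `pvalue_table` with `pmf` and `survival`
#'   vectors indexed by score `0..max_total` (element `s + 1`).
#' @export
build_pvalue_table <- function(spssm, bg = spssm$bg) {
  stopifnot(inherits(spssm, "scaled_pssm"))
  bg <- background(as.numeric(bg))
  M <- spssm$int_matrix
  Q <- 1
  for (i in seq_len(spssm$width)) {
    cm <- max(M[, i])
    newQ <- numeric(length(Q) + cm)
    for (b in 1:4) {
      sh <- M[b, i]
      newQ[(sh + 1):(sh + length(Q))] <-
        newQ[(sh + 1):(sh + length(Q))] + bg[b] * Q
    }
    Q <- newQ
  }
  surv <- rev(cumsum(rev(Q)))
  surv <- pmin(surv, 1)
  obj <- list(pmf = Q, survival = surv,
              max_total = length(Q) - 1L, motif_id = spssm$motif_id)
  class(obj) <- "pvalue_table"
  obj
}

#' Look up P-values for scaled scores
#' @param table a [build_pvalue_table] result.
#' @param scores integer vector of scaled scores.
#' @return numeric vector of inclusive upper-tail P-values.
#' @export
score_pvalue <- function(table, scores) {
  stopifnot(inherits(table, "pvalue_table"), all(scores >= 0))
  table$survival[pmin(scores, table$max_total) + 1L]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, clamped
#' at 1, returned in the input order.
#'
#' @param pvalues numeric vector of P-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!length(pvalues)) stop("empty P-value list")
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("P-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q <- pvalues[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  # q >= p holds analytically; guard against last-ulp rounding in p*m/j
  pmax(out, pvalues)
}
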