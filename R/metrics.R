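#' Path-pair tallies from a count table
#'
#' The metrics count unordered pairs of matched synaptic terminals
#' (intracellular paths). For ground-truth neuron `i` with count-table row
#' `c[i, ]`:
#' \itemize{
#'   \item a *true positive* is a pair of its terminals found together on one
#'     reconstructed fragment: `TP(i) = sum_j choose(c[i,j], 2)` over real
#'     fragments `j`;
#'   \item a *false negative* is a pair of its terminals separated in the
#'     reconstruction, including pairs involving deleted terminals:
#'     `FN(i) = choose(c[i,del], 2) + sum over column pairs (del included) of
#'     c[i,j] * c[i,j']`, so that `TP(i) + FN(i) = choose(n_i, 2)` where
#'     `n_i` is the neuron's total terminal count;
#'   \item a *false positive* is a pair of terminals co-resident on one
#'     fragment that belong to different ground-truth neurons (or to inserted
#'     synapses); computed column-wise on the transposed table.
#' }
#'
#' False-positive attribution to individual neurons follows the halving
#' convention: a cross-neuron merge pair is charged half to each neuron; a
#' pair between a neuron's terminal and an inserted terminal is charged fully
#' to the neuron; pairs of inserted terminals are charged to the reserved
#' `"ins"` entry. The attributed values sum exactly to the global FP.
#'
#' @param table a [count_table()].
#' @return `count_tp` / `count_fn`: list with `global` and named per-neuron
#'   vector `by_neuron`. `count_fp`: list with `global`, `by_neuron`
#'   (attributed, includes an `"ins"` entry), and `incident_by_neuron`
#'   (every FP pair touching the neuron counted at full weight).
#' @export
count_tp <- function(table) {
  stopifnot(inherits(table, "nri_count_table"))
  body <- ct_body(table)
  by_neuron <- rowSums(choose(body, 2))
  list(global = sum(by_neuron), by_neuron = by_neuron)
}

#' @rdname count_tp
#' @export
count_fn <- function(table) {
  stopifnot(inherits(table, "nri_count_table"))
  full_rows <- unclass(table)[-1, , drop = FALSE]  # del column + body
  s <- rowSums(full_rows)
  q <- rowSums(full_rows^2)
  cross <- (s^2 - q) / 2                       # pairs in different columns
  by_neuron <- choose(ct_del(table), 2) + cross
  list(global = sum(by_neuron), by_neuron = by_neuron)
}

#' @rdname count_tp
#' @export
count_fp <- function(table) {
  stopifnot(inherits(table, "nri_count_table"))
  full_cols <- unclass(table)[, -1, drop = FALSE]  # ins row + body
  s <- colSums(full_cols)
  q <- colSums(full_cols^2)
  ins <- ct_ins(table)
  global <- sum(choose(ins, 2) + (s^2 - q) / 2)

  body <- ct_body(table)
  col_body <- colSums(body)
  # full weight for pairs with an inserted terminal, half weight for
  # cross-neuron merge pairs
  attributed <- as.vector(body %*% ins) +
    0.5 * rowSums(body * rep(col_body, each = nrow(body))) - 0.5 * rowSums(body^2)
  names(attributed) <- rownames(body)
  attributed <- c(ins = sum(choose(ins, 2)), attributed)
  # incident: all same-column pairs touching the neuron, full weight
  col_total <- colSums(unclass(table)[, -1, drop = FALSE])
  incident <- rowSums(body * rep(col_total, each = nrow(body))) - rowSums(body^2)
  names(incident) <- rownames(body)
  list(global = global, by_neuron = attributed, incident_by_neuron = incident)
}

#' f-beta score from path-pair tallies
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and the score is
#' the weighted harmonic mean `(1 + beta^2) P R / (beta^2 P + R)`; `beta = 1`
#' gives the NRI. Conventions at the boundaries: a zero precision or recall
#' denominator is read as "no errors of that type", so a tally with
#' `TP = FP = FN = 0` scores 1, while `TP = 0` with any error present
#' scores 0.
#'
#' @param tp,fp,fn non-negative path-pair counts.
#' @param beta precision/recall weighting of the f-score (default 1).
#' @return list of class `nri_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `score`, `beta`.
#' @export
#' @examples
#' nri_from_counts(tp = 1, fp = 2, fn = 2)$score  # 1/3
nri_from_counts <- function(tp, fp, fn, beta = 1) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, beta > 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else NaN
  score <- if (tp == 0 && fp + fn > 0) {
    0
  } else if (is.nan(precision) || is.nan(recall)) {
    0
  } else if (precision + recall == 0) {
    0
  } else {
    (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, score = score, beta = beta),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI (f%g): %.4f   [P %.4f, R %.4f;  TP %g, FP %g, FN %g]\n",
              x$beta, x$score, x$precision, x$recall, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Global NRI over a count table
#'
#' Tallies TP, FP and FN over every ground-truth neuron in the table and
#' returns the network-level f-beta score.
#'
#' @param table a [count_table()].
#' @param beta f-score weighting (default 1, the NRI).
#' @return an `nri_result` (see [nri_from_counts()]).
#' @export
global_nri <- function(table, beta = 1) {
  nri_from_counts(count_tp(table)$global, count_fp(table)$global,
                  count_fn(table)$global, beta = beta)
}

#' Single-neuron NRI
#'
#' True positives and false negatives of a single ground-truth neuron are
#' unambiguous (they live entirely in its count-table row). False positives
#' admit two conventions: `"attributed"` charges half of each cross-neuron
#' merge pair to each participant (so per-neuron FPs sum to the global FP),
#' while `"incident"` charges every false-positive pair touching the neuron
#' at full weight.
#'
#' @param table a [count_table()].
#' @param neuron ground-truth neuron id (a row label of the table).
#' @param attribution `"attributed"` (default) or `"incident"`.
#' @param beta f-score weighting.
#' @return an `nri_result`.
#' @export
neuron_nri <- function(table, neuron,
                       attribution = c("attributed", "incident"), beta = 1) {
  attribution <- match.arg(attribution)
  if (!neuron %in% rownames(table)[-1]) {
    stop("unknown ground-truth neuron: ", neuron, call. = FALSE)
  }
  tp <- count_tp(table)$by_neuron[[neuron]]
  fn <- count_fn(table)$by_neuron[[neuron]]
  fps <- count_fp(table)
  fp <- if (attribution == "attributed") fps$by_neuron[[neuron]] else
    fps$incident_by_neuron[[neuron]]
  nri_from_counts(tp, fp, fn, beta = beta)
}

#' Per-neuron score table
#'
#' Convenience wrapper: one row per ground-truth neuron with its tallies,
#' precision, recall and NRI.
#'
#' @inheritParams neuron_nri
#' @return data.frame with columns `neuron`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `nri`.
#' @export
nri_by_neuron <- function(table, attribution = c("attributed", "incident"),
                          beta = 1) {
  attribution <- match.arg(attribution)
  neurons <- rownames(table)[-1]
  rows <- lapply(neurons, function(n) {
    r <- neuron_nri(table, n, attribution = attribution, beta = beta)
    data.frame(neuron = n, tp = r$tp, fp = r$fp, fn = r$fn,
               precision = r$precision, recall = r$recall, nri = r$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Terminal-based adapted Rand index
#'
#' The Rand index over the partition of matched terminals into ground-truth
#' neurons versus reconstructed fragments, with the insertion row and
#' deletion column treated as additional neurons. TP, FN and FP sum over all
#' indices including the reserved row/column. By default TN is the number of
#' unordered terminal pairs lying in different rows *and* different columns,
#' which makes `TP + TN + FP + FN = choose(T, 2)` for `T` total terminals;
#' `tn_mode = "half_quadrant"` instead restricts TN to pairs ordered the same
#' way in both dimensions (`i < i'` and `j < j'`), a variant that undercounts
#' but is retained for literal comparison.
#'
#' @param table a [count_table()].
#' @param tn_mode `"pair_consistent"` (default) or `"half_quadrant"`.
#' @return list with `tp`, `fn`, `fp`, `tn`, `score`.
#' @export
adapted_rand <- function(table, tn_mode = c("pair_consistent", "half_quadrant")) {
  tn_mode <- match.arg(tn_mode)
  M <- unclass(table)
  total <- sum(M)
  tp <- sum(choose(M, 2))
  fn <- sum((rowSums(M)^2 - rowSums(M^2)) / 2)
  fp <- sum((colSums(M)^2 - colSums(M^2)) / 2)
  tn <- if (tn_mode == "pair_consistent") {
    choose(total, 2) - tp - fn - fp
  } else {
    # sum over i < i', j < j' of c[i,j] * c[i',j']
    I <- nrow(M); J <- ncol(M)
    acc <- 0
    for (i in seq_len(I - 1)) {
      for (j in seq_len(J - 1)) {
        acc <- acc + M[i, j] * sum(M[(i + 1):I, (j + 1):J])
      }
    }
    acc
  }
  denom <- tp + tn + fp + fn
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       score = if (denom > 0) (tp + tn) / denom else 1)
}

#' Normalized variation of information
#'
#' Treats the count table (including the insertion row and deletion column)
#' as the joint distribution of a matched terminal's ground-truth neuron and
#' reconstructed fragment, and returns the variation of information
#' `H(G|S) + H(S|G)` normalized by the joint entropy `H(G, S)` so the score
#' lies in \[0, 1\] (0 = perfect agreement). The value is invariant to the
#' logarithm base; natural logs are used internally. A table concentrated in
#' a single cell has `H(G, S) = 0` and both partitions trivially agree, so
#' the score is 0.
#'
#' @param table a [count_table()] with at least one nonzero entry.
#' @return list with `h_g_given_s`, `h_s_given_g`, `h_joint` (nats) and
#'   `score` (the NVI).
#' @export
normalized_vi <- function(table) {
  M <- unclass(table)
  total <- sum(M)
  if (total == 0) stop("normalized VI is undefined for an all-zero count table",
                       call. = FALSE)
  p <- M / total
  plogp <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  h_joint <- -plogp(p)
  h_rows <- -plogp(rowSums(p))
  h_cols <- -plogp(colSums(p))
  h_g_given_s <- h_joint - h_cols
  h_s_given_g <- h_joint - h_rows
  score <- if (h_joint > 0) (h_g_given_s + h_s_given_g) / h_joint else 0
  list(h_g_given_s = h_g_given_s, h_s_given_g = h_s_given_g,
       h_joint = h_joint, score = score)
}
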