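#' Match reconstruction synapses to ground-truth synapses by centroid
#'
#' Reconciles synapse identifiers between the two tables with a one-to-one,
#' minimum-total-distance bipartite assignment on Euclidean centroid
#' distance. A pair is only admissible when the centroids lie within
#' `max_distance` of each other; synapses for which no admissible partner is
#' assigned are reported as unmatched (ground-truth side: deletions;
#' reconstruction side: insertions).
#'
#' The distance cap is realised exactly, not by post-filtering: each synapse
#' carries an implicit "stay unassigned" slot at cost `max_distance`, so the
#' optimisation itself trades a long pairing against leaving both synapses
#' unmatched. Internally this is solved as a maximum-weight bipartite
#' matching (edge weight `2 * max_distance - distance` on admissible pairs),
#' which is algebraically the same augmented assignment problem.
#'
#' Polarity is deliberately ignored at this stage; agreement of pre/post
#' polarity is checked later when the count table is assembled.
#'
#' @param gt ground-truth [synapse_table()].
#' @param recon reconstruction [synapse_table()].
#' @param max_distance unassignment cap in nanometres (default 300).
#' @return An object of class `synapse_matching`: list with
#'   \describe{
#'     \item{pairs}{data.frame `gt_id`, `recon_id`, `distance` (nm).}
#'     \item{unmatched_gt}{character vector of unmatched ground-truth ids.}
#'     \item{unmatched_recon}{character vector of unmatched reconstruction ids.}
#'     \item{max_distance}{the cap used.}
#'   }
#' @export
#' @examples
#' gt <- synapse_table("s1", "a", "b", 0, 0, 0)
#' rec <- synapse_table("r1", "x", "y", 10, 0, 0, role = "reconstruction")
#' match_synapses(gt, rec)$pairs
match_synapses <- function(gt, recon, max_distance = 300) {
  stopifnot(inherits(gt, "synapse_table"), inherits(recon, "synapse_table"),
            is.numeric(max_distance), max_distance > 0)
  # deterministic tie-breaking: operate on id-sorted copies
  gt <- gt[order(gt$synapse_id), , drop = FALSE]
  recon <- recon[order(recon$synapse_id), , drop = FALSE]
  n <- nrow(gt); m <- nrow(recon)

  pairs <- data.frame(gt_id = character(), recon_id = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (n > 0 && m > 0) {
    cand <- candidate_pairs(as.matrix(gt[, c("x", "y", "z")]),
                            as.matrix(recon[, c("x", "y", "z")]),
                            max_distance)
    if (nrow(cand) > 0) {
      # bipartite graph: gt vertices 1..n, recon vertices n+1..n+m
      g <- igraph::make_bipartite_graph(
        types = c(rep(FALSE, n), rep(TRUE, m)),
        edges = as.vector(rbind(cand$gi, n + cand$rj))
      )
      w <- 2 * max_distance - cand$d
      res <- igraph::max_bipartite_match(g, weights = w, eps = 1e-9)
      mate <- res$matching[seq_len(n)]     # for each gt vertex, matched vertex or NA
      got <- which(!is.na(mate))
      if (length(got) > 0) {
        rj <- mate[got] - n
        d <- sqrt(rowSums((as.matrix(gt[got, c("x", "y", "z")]) -
                           as.matrix(recon[rj, c("x", "y", "z")]))^2))
        pairs <- data.frame(gt_id = gt$synapse_id[got],
                            recon_id = recon$synapse_id[rj],
                            distance = d, stringsAsFactors = FALSE)
        pairs <- pairs[order(pairs$gt_id), , drop = FALSE]
        rownames(pairs) <- NULL
      }
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_gt = setdiff(gt$synapse_id, pairs$gt_id),
    unmatched_recon = setdiff(recon$synapse_id, pairs$recon_id),
    max_distance = max_distance
  ), class = "synapse_matching")
}

# All (gt index, recon index, distance) pairs with distance <= cap.
# Chunked over gt rows to bound memory on large tables.
candidate_pairs <- function(gxyz, rxyz, cap) {
  n <- nrow(gxyz); m <- nrow(rxyz)
  chunk <- max(1L, floor(4e6 / max(m, 1L)))
  out <- vector("list", ceiling(n / chunk))
  k <- 0L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    block <- gxyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(rxyz^2), "+") -
      2 * tcrossprod(block, rxyz)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cap^2, arr.ind = TRUE)
    k <- k + 1L
    out[[k]] <- data.frame(gi = hit[, 1] + s - 1L, rj = hit[, 2],
                           d = sqrt(d2[hit]))
  }
  do.call(rbind, out[seq_len(k)])
}

#' @export
print.synapse_matching <- function(x, ...) {
  cat(sprintf(
    "<synapse_matching> %d pairs, %d deletions (unmatched GT), %d insertions (unmatched recon), cap %g nm\n",
    nrow(x$pairs), length(x$unmatched_gt), length(x$unmatched_recon),
    x$max_distance))
  invisible(x)
}

#' Write a matching as a two-column audit CSV
#'
#' @param matching a [match_synapses()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matching <- function(matching, path) {
  stopifnot(inherits(matching, "synapse_matching"))
  write.csv(matching$pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exhaustive assignment oracle (testing aid)
#'
#' Solves the same capped assignment problem as [match_synapses()] by
#' enumerating every partial injective assignment of rows to columns. Cost of
#' a solution = sum of assigned entries + `max_distance` for every unassigned
#' row and every unassigned column (the augmented "unassigned slot" cost).
#' Intended as an independent correctness oracle on tiny instances only.
#'
#' @param cost numeric distance matrix, at most 8 x 8.
#' @param max_distance unassignment cap; entries above it are inadmissible.
#' @return list with `pairs` (two-column matrix of row, col indices) and
#'   `total_cost` (augmented objective value).
#' @export
assignment_oracle <- function(cost, max_distance) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > 8 || m > 8) stop("assignment_oracle is limited to 8 x 8 instances",
                           call. = FALSE)
  best <- list(pairs = matrix(integer(), 0, 2),
               total_cost = (n + m) * max_distance)
  recurse <- function(i, used, pairs, acc) {
    if (i > n) {
      total <- acc + max_distance * (n - nrow(pairs)) +
        max_distance * (m - nrow(pairs))
      if (total < best$total_cost - 1e-12) {
        best <<- list(pairs = pairs, total_cost = total)
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, used, pairs, acc)  # row i unassigned
    for (j in seq_len(m)) {
      if (!used[j] && cost[i, j] <= max_distance) {
        used[j] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(i, j)), acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  if (n > 0 && m > 0) recurse(1L, logical(m), matrix(integer(), 0, 2), 0)
  best
}
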