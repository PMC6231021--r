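#' Synapse deletion model
#'
#' Removes a fixed fraction of synapses, selected uniformly at random without
#' replacement from the whole table. The number removed is
#' `round(fraction * N)` with half-up rounding.
#'
#' @param graph a [synapse_table()].
#' @param fraction fraction of synapses to delete, in \[0, 1\].
#' @param seed RNG seed.
#' @return a [synapse_table()] with role `"reconstruction"`.
#' @export
delete_synapses <- function(graph, fraction, seed = 1L) {
  stopifnot(inherits(graph, "synapse_table"), fraction >= 0, fraction <= 1)
  n <- nrow(graph)
  k <- floor(fraction * n + 0.5)
  keep <- with_seed(seed, {
    if (k > 0) setdiff(seq_len(n), sample.int(n, k)) else seq_len(n)
  })
  out <- graph[sort(keep), , drop = FALSE]
  synapse_table(out$synapse_id, out$pre_neuron, out$post_neuron,
                out$x, out$y, out$z, role = "reconstruction")
}

#' Synapse insertion model
#'
#' For every cross-neuron (axon, dendrite) segment pair, a spurious synapse
#' is inserted with the linear distance kernel probability (`p_max` below
#' `d1`, 0 above `d2`). Inserted synapses are flagged (`inserted = TRUE`),
#' placed at the midpoint of closest approach with a small (<= 10 nm) jitter,
#' and given fresh identifiers. Because candidate enumeration is
#' deterministic and one uniform draw is made per candidate, raising `p_max`
#' at a fixed seed only ever adds insertions (nested perturbations).
#'
#' @param morph a [network_morphology()].
#' @param kernel list with `p_max`, `d1`, `d2` (nm).
#' @param seed RNG seed.
#' @return the morphology with extra inserted synapses.
#' @export
insert_synapses <- function(morph, kernel, seed = 1L) {
  stopifnot(inherits(morph, "network_morphology"))
  seg <- morph$segments
  ax <- which(seg$kind == "axon")
  de <- which(seg$kind == "dendrite")
  cand <- cross_neuron_segment_pairs(seg, ax, de, kernel$d2)
  with_seed(seed, {
    u <- runif(nrow(cand))
    keep <- u < kernel_prob(cand$dist, kernel$p_max, kernel$d1, kernel$d2)
    acc <- cand[keep, , drop = FALSE]
    jit <- matrix(runif(3 * nrow(acc), -10, 10) / sqrt(3), ncol = 3)
    new_syn <- data.frame(
      synapse_id = sprintf("inserted%06d", seq_len(nrow(acc))),
      pre_neuron = seg$neuron[acc$i], post_neuron = seg$neuron[acc$j],
      x = acc$x + jit[, 1], y = acc$y + jit[, 2], z = acc$z + jit[, 3],
      pre_segment = seg$segment_id[acc$i],
      post_segment = seg$segment_id[acc$j],
      inserted = rep(TRUE, nrow(acc)), stringsAsFactors = FALSE)
    network_morphology(seg, rbind(morph$synapses, new_syn))
  })
}

#' Neuron split model
#'
#' Each cylindrical process segment is selected as a split site with the
#' linear kernel probability evaluated on its *diameter* (`p_max` below `d1`,
#' 0 above `d2`), so thin processes -- spine necks, distal dendrites, axons --
#' split preferentially. A split detaches the segment and its whole subtree
#' into a new fragment with a fresh identifier; the parent side keeps the
#' original identifier. Multiple splits compose: a segment belongs to the
#' fragment of its nearest selected ancestor (or itself). Synapses move with
#' their anchoring segments; centroids are untouched, so synapse matching
#' stays exact.
#'
#' @inheritParams insert_synapses
#' @return the morphology with relabelled fragments.
#' @export
split_neurons <- function(morph, kernel, seed = 1L) {
  stopifnot(inherits(morph, "network_morphology"))
  seg <- morph$segments
  sel <- with_seed(seed, {
    runif(nrow(seg)) < kernel_prob(seg$diameter, kernel$p_max,
                                   kernel$d1, kernel$d2)
  })
  # roots are never "split": detaching at a root is a no-op relabel
  sel[is.na(seg$parent)] <- FALSE
  label <- seg$neuron
  frag_counter <- new.env(parent = emptyenv())
  parent_idx <- match(seg$parent, seg$segment_id)
  # segments are stored parents-before-children, so one forward pass labels
  # every segment with its nearest selected ancestor's fragment
  for (r in seq_len(nrow(seg))) {
    if (sel[r]) {
      key <- seg$neuron[r]
      nxt <- (if (is.null(frag_counter[[key]])) 0L else frag_counter[[key]]) + 1L
      frag_counter[[key]] <- nxt
      label[r] <- sprintf("%s_split%03d", key, nxt)
    } else if (!is.na(parent_idx[r])) {
      label[r] <- label[parent_idx[r]]
    }
  }
  seg$neuron <- label
  seg$parent[sel] <- NA_character_  # detached subtree roots
  syn <- morph$synapses
  if (nrow(syn) > 0) {
    syn$pre_neuron <- label[match(syn$pre_segment, seg$segment_id)]
    syn$post_neuron <- label[match(syn$post_segment, seg$segment_id)]
  }
  network_morphology(seg, syn)
}

#' Neuron merge model
#'
#' For every cross-neuron segment pair, a merge event occurs with the linear
#' distance kernel probability. Whole neurons are merged wherever a merge is
#' indicated: neuron identifiers are unified over the connected components of
#' the merge-event graph, and every segment and synapse is relabelled to the
#' lexicographically smallest member of its component. Centroids are
#' untouched.
#'
#' @inheritParams insert_synapses
#' @return the morphology with merged neuron labels.
#' @export
merge_neurons <- function(morph, kernel, seed = 1L) {
  stopifnot(inherits(morph, "network_morphology"))
  seg <- morph$segments
  all_idx <- seq_len(nrow(seg))
  cand <- cross_neuron_segment_pairs(seg, all_idx, all_idx, kernel$d2)
  events <- with_seed(seed, {
    u <- runif(nrow(cand))
    cand[u < kernel_prob(cand$dist, kernel$p_max, kernel$d1, kernel$d2), ,
         drop = FALSE]
  })
  neurons <- sort(unique(seg$neuron))
  rep_of <- setNames(neurons, neurons)
  if (nrow(events) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = seg$neuron[events$i], to = seg$neuron[events$j]),
      directed = FALSE, vertices = data.frame(name = neurons))
    comp <- igraph::components(g)$membership
    split_names <- split(names(comp), comp)
    for (members in split_names) {
      rep_of[members] <- min(members)
    }
  }
  seg$neuron <- unname(rep_of[seg$neuron])
  syn <- morph$synapses
  if (nrow(syn) > 0) {
    syn$pre_neuron <- unname(rep_of[syn$pre_neuron])
    syn$post_neuron <- unname(rep_of[syn$post_neuron])
  }
  network_morphology(seg, syn)
}

#' Per-neuron perturbation diagnostics
#'
#' Measures how strongly each ground-truth neuron was affected by a
#' perturbation, for plotting against its NRI score:
#' \describe{
#'   \item{deleted_fraction}{fraction of the neuron's terminals in the
#'     deletion column, `c[i, del] / rowsum(i)`.}
#'   \item{foreign_fraction}{fraction of terminals on the neuron's host
#'     fragment that do not come from the neuron: with `j*` the fragment
#'     carrying most of the neuron's terminals,
#'     `(colsum(j*) - c[i, j*]) / colsum(j*)`. For neuron A merged with B and
#'     C this is `(nB + nC) / (nA + nB + nC)`.}
#'   \item{split_entropy}{Shannon entropy of the neuron's matched-terminal
#'     distribution across fragments, normalized by the logarithm of its
#'     matched-terminal count so the value lies in \[0, 1\] (1 = every
#'     terminal on its own fragment).}
#' }
#'
#' @param table a [count_table()].
#' @param kind one of `"deleted_fraction"`, `"foreign_fraction"`,
#'   `"split_entropy"`.
#' @return data.frame with columns `neuron`, `kind`, `value`.
#' @export
perturbation_scores <- function(table, kind = c("deleted_fraction",
                                                "foreign_fraction",
                                                "split_entropy")) {
  kind <- match.arg(kind)
  stopifnot(inherits(table, "nri_count_table"))
  body <- ct_body(table)
  del <- ct_del(table)
  neurons <- rownames(body)
  value <- switch(kind,
    deleted_fraction = {
      rs <- del + rowSums(body)
      ifelse(rs > 0, del / rs, 0)
    },
    foreign_fraction = {
      col_total <- colSums(unclass(table)[, -1, drop = FALSE])  # incl. ins
      vapply(seq_len(nrow(body)), function(i) {
        if (all(body[i, ] == 0)) return(0)
        j <- which.max(body[i, ])
        (col_total[j] - body[i, j]) / col_total[j]
      }, numeric(1))
    },
    split_entropy = {
      vapply(seq_len(nrow(body)), function(i) {
        n <- sum(body[i, ])
        if (n <= 1) return(0)
        p <- body[i, body[i, ] > 0] / n
        -sum(p * log(p)) / log(n)
      }, numeric(1))
    })
  data.frame(neuron = neurons, kind = kind, value = unname(value),
             stringsAsFactors = FALSE)
}

#' Crop a morphology to a region and relabel fragments
#'
#' Preprocessing for evaluation against a geometrically confined ground-truth
#' region: segments are clipped to an axis-aligned box, each neuron's
#' surviving segments are relabelled into one fragment per connected
#' component of the parent-link graph (a branch whose branching point lies
#' outside the box becomes its own fragment, exactly as a ground-truth
#' annotation confined to the box would label it), and synapses whose
#' centroid or anchoring segments fall outside the box are dropped.
#'
#' @param morph a [network_morphology()].
#' @param box_min,box_max numeric length-3 corners of the box, nanometres.
#' @return the cropped, relabelled morphology (possibly empty).
#' @export
crop_relabel <- function(morph, box_min, box_max) {
  stopifnot(inherits(morph, "network_morphology"),
            length(box_min) == 3, length(box_max) == 3,
            all(box_max >= box_min))
  seg <- morph$segments
  if (nrow(seg) == 0) return(morph)
  P0 <- as.matrix(seg[, c("x0", "y0", "z0")])
  P1 <- as.matrix(seg[, c("x1", "y1", "z1")])
  clip <- clip_segments_to_box(P0, P1, box_min, box_max)
  keep <- clip$keep
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) == 0) {
    return(network_morphology(seg, morph$synapses[0, , drop = FALSE]))
  }
  if (nrow(seg) > 0) {
    seg[, c("x0", "y0", "z0")] <- clip$P0[keep, , drop = FALSE]
    seg[, c("x1", "y1", "z1")] <- clip$P1[keep, , drop = FALSE]
  }
  # fragment = connected component of surviving parent links within a neuron
  parent_ok <- !is.na(seg$parent) & seg$parent %in% seg$segment_id
  g <- igraph::graph_from_data_frame(
    data.frame(from = seg$parent[parent_ok],
               to = seg$segment_id[parent_ok]),
    directed = FALSE,
    vertices = data.frame(name = seg$segment_id))
  comp <- igraph::components(g)$membership[seg$segment_id]
  frag <- paste0(seg$neuron, "_cc", comp)
  # stable fragment numbering per neuron, by first appearance
  frag <- stats::ave(frag, seg$neuron, FUN = function(f) {
    paste0(sub("_cc[0-9]+$", "", f[1]), "_cc",
           match(f, unique(f)))
  })
  seg$neuron <- frag
  seg$parent[!parent_ok] <- NA_character_

  syn <- morph$synapses
  if (nrow(syn) > 0) {
    inside <- syn$x >= box_min[1] & syn$x <= box_max[1] &
      syn$y >= box_min[2] & syn$y <= box_max[2] &
      syn$z >= box_min[3] & syn$z <= box_max[3]
    pre_i <- match(syn$pre_segment, seg$segment_id)
    post_i <- match(syn$post_segment, seg$segment_id)
    ok <- inside & !is.na(pre_i) & !is.na(post_i)
    syn <- syn[ok, , drop = FALSE]
    syn$pre_neuron <- seg$neuron[pre_i[ok]]
    syn$post_neuron <- seg$neuron[post_i[ok]]
  }
  network_morphology(seg, syn)
}

# Liang-Barsky clipping of segments P0->P1 to an axis-aligned box,
# vectorised over rows. Returns clipped endpoints and a keep mask.
clip_segments_to_box <- function(P0, P1, box_min, box_max) {
  d <- P1 - P0
  t0 <- rep(0, nrow(P0)); t1 <- rep(1, nrow(P0))
  keep <- rep(TRUE, nrow(P0))
  for (ax in 1:3) {
    p0 <- P0[, ax]; dd <- d[, ax]
    # entering/leaving parameters for the two slab planes
    zero <- abs(dd) < 1e-12
    keep <- keep & !(zero & (p0 < box_min[ax] | p0 > box_max[ax]))
    ta <- ifelse(zero, -Inf, (box_min[ax] - p0) / dd)
    tb <- ifelse(zero, Inf, (box_max[ax] - p0) / dd)
    lo <- pmin(ta, tb); hi <- pmax(ta, tb)
    t0 <- pmax(t0, lo); t1 <- pmin(t1, hi)
  }
  keep <- keep & (t0 <= t1)
  Q0 <- P0 + d * t0
  Q1 <- P0 + d * t1
  dimnames(Q0) <- NULL
  dimnames(Q1) <- NULL
  list(P0 = Q0, P1 = Q1, keep = keep)
}
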