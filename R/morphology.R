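#' Construct a network morphology
#'
#' A network morphology is the geometric substrate behind a brain graph:
#' each neuron is a tree of short cylindrical process segments rooted at the
#' soma, and each synapse is anchored on one presynaptic and one postsynaptic
#' segment. The geometric perturbation models (insertion, split, merge)
#' operate on this representation because their error probabilities depend on
#' inter-process distance or process diameter.
#'
#' @param segments data.frame with columns `segment_id`, `neuron`, `parent`
#'   (segment_id of the parent, `NA` for the root/soma segment), `x0, y0, z0`
#'   (start), `x1, y1, z1` (end), `diameter` (all lengths in nanometres) and
#'   `kind` (`"soma"`, `"axon"` or `"dendrite"`).
#' @param synapses data.frame in [synapse_table()] layout plus columns
#'   `pre_segment` and `post_segment` naming the anchoring segments. May be
#'   empty.
#' @return An object of class `network_morphology`: a list with elements
#'   `segments` and `synapses`.
#' @export
network_morphology <- function(segments, synapses = NULL) {
  seg_cols <- c("segment_id", "neuron", "parent", "x0", "y0", "z0",
                "x1", "y1", "z1", "diameter", "kind")
  missing <- setdiff(seg_cols, names(segments))
  if (length(missing) > 0) {
    stop("segments is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  segments <- as.data.frame(segments)[, seg_cols]
  segments$segment_id <- as.character(segments$segment_id)
  segments$neuron <- as.character(segments$neuron)
  segments$parent <- as.character(segments$parent)
  if (anyDuplicated(segments$segment_id)) {
    stop("duplicate segment_id values", call. = FALSE)
  }
  if (nrow(segments) > 0 && any(segments$diameter <= 0)) {
    stop("segment diameters must be > 0", call. = FALSE)
  }
  if (is.null(synapses)) {
    synapses <- data.frame(synapse_id = character(), pre_neuron = character(),
                           post_neuron = character(), x = numeric(),
                           y = numeric(), z = numeric(),
                           pre_segment = character(), post_segment = character(),
                           stringsAsFactors = FALSE)
  }
  synapses <- as.data.frame(synapses)
  if (!"inserted" %in% names(synapses)) synapses$inserted <- logical(nrow(synapses))
  morph <- structure(list(segments = segments, synapses = synapses),
                     class = "network_morphology")
  validate_morphology(morph)
  morph
}

validate_morphology <- function(morph) {
  seg <- morph$segments
  syn <- morph$synapses
  if (nrow(seg) > 0) {
    # parent links must form a forest: every non-root parent exists and
    # belongs to the same neuron; walking parents must terminate
    idx <- match(seg$parent, seg$segment_id)
    nonroot <- !is.na(seg$parent)
    if (any(nonroot & is.na(idx))) stop("parent segment not found", call. = FALSE)
    if (any(seg$neuron[idx[nonroot]] != seg$neuron[nonroot])) {
      stop("parent segment belongs to a different neuron", call. = FALSE)
    }
    if (any(nonroot)) {
      g <- igraph::graph_from_edgelist(
        cbind(seg$parent[nonroot], seg$segment_id[nonroot]), directed = TRUE)
      if (!igraph::is_forest(igraph::as_undirected(g))) {
        stop("segment parent links contain a cycle", call. = FALSE)
      }
    }
  }
  if (nrow(syn) > 0) {
    pre_idx <- match(syn$pre_segment, seg$segment_id)
    post_idx <- match(syn$post_segment, seg$segment_id)
    if (anyNA(pre_idx) || anyNA(post_idx)) {
      stop("synapse anchored on unknown segment", call. = FALSE)
    }
    if (any(seg$neuron[pre_idx] != syn$pre_neuron) ||
        any(seg$neuron[post_idx] != syn$post_neuron)) {
      stop("synapse anchor segment does not belong to the synapse's neuron",
           call. = FALSE)
    }
  }
  invisible(morph)
}

#' @export
print.network_morphology <- function(x, ...) {
  cat(sprintf("<network_morphology> %d neurons, %d segments, %d synapses\n",
              length(unique(x$segments$neuron)), nrow(x$segments),
              nrow(x$synapses)))
  invisible(x)
}

#' Write / read a network morphology as a pair of CSV files
#'
#' Segments go to `<path>` (one cylindrical segment per line: id, neuron,
#' parent, start xyz, end xyz, diameter, kind) and synapses with their anchor
#' segments to `<path>` with suffix `.synapses.csv` appended before writing.
#'
#' @param morph a [network_morphology()].
#' @param path path for the segments CSV; the synapse CSV is written next to
#'   it as `paste0(path, ".synapses.csv")`.
#' @return `path`, invisibly.
#' @export
write_morphology <- function(morph, path) {
  stopifnot(inherits(morph, "network_morphology"))
  write.csv(morph$segments, path, row.names = FALSE, quote = FALSE)
  write.csv(morph$synapses, paste0(path, ".synapses.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphology
#' @export
read_morphology <- function(path) {
  seg <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(segment_id = "character",
                                 neuron = "character", parent = "character"))
  seg$parent[seg$parent %in% c("", "NA")] <- NA_character_
  syn_path <- paste0(path, ".synapses.csv")
  syn <- NULL
  if (file.exists(syn_path)) {
    syn <- read.csv(syn_path, stringsAsFactors = FALSE,
                    colClasses = c(synapse_id = "character",
                                   pre_neuron = "character",
                                   post_neuron = "character",
                                   pre_segment = "character",
                                   post_segment = "character"))
  }
  network_morphology(seg, syn)
}

#' Extract the brain graph of a morphology
#'
#' Projects the placed synapses of a morphology down to the point-synapse
#' table the metrics consume: one record per synapse with its pre/post neuron
#' identifiers and centroid.
#'
#' @param morph a [network_morphology()].
#' @param role table role, default `"ground_truth"`.
#' @return a [synapse_table()].
#' @export
derive_graph <- function(morph, role = c("ground_truth", "reconstruction")) {
  stopifnot(inherits(morph, "network_morphology"))
  role <- match.arg(role)
  syn <- morph$synapses
  synapse_table(syn$synapse_id, syn$pre_neuron, syn$post_neuron,
                syn$x, syn$y, syn$z, role = role)
}
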