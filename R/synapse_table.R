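#' Construct a synapse table
#'
#' A synapse table is the point-synapse representation of a brain graph: one
#' row per directed synapse, giving the presynaptic neuron, the postsynaptic
#' neuron, and the (x, y, z) centroid of the synaptic cleft in nanometres.
#' Neuron and synapse identifiers are opaque strings; there is no assumption
#' that identifiers correspond between a ground-truth table and a
#' reconstruction table.
#'
#' @param synapse_id character vector of unique synapse identifiers.
#' @param pre_neuron character vector: presynaptic neuron of each synapse.
#' @param post_neuron character vector: postsynaptic neuron of each synapse.
#'   May equal `pre_neuron` (autapse).
#' @param x,y,z numeric centroid coordinates, nanometres.
#' @param role `"ground_truth"` or `"reconstruction"`.
#'
#' @return An object of class `synapse_table`: a data.frame with columns
#'   `synapse_id`, `pre_neuron`, `post_neuron`, `x`, `y`, `z` and a `role`
#'   attribute.
#' @export
#' @examples
#' gt <- synapse_table(
#'   synapse_id = c("A", "B"),
#'   pre_neuron = c("n1", "n1"), post_neuron = c("n2", "n2"),
#'   x = c(0, 100), y = c(0, 0), z = c(0, 0)
#' )
#' nrow(gt)
synapse_table <- function(synapse_id = character(), pre_neuron = character(),
                          post_neuron = character(), x = numeric(),
                          y = numeric(), z = numeric(),
                          role = c("ground_truth", "reconstruction")) {
  role <- match.arg(role)
  df <- data.frame(
    synapse_id = as.character(synapse_id),
    pre_neuron = as.character(pre_neuron),
    post_neuron = as.character(post_neuron),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  validate_synapse_table(df)
  structure(df, role = role, class = c("synapse_table", "data.frame"))
}

validate_synapse_table <- function(df) {
  if (anyDuplicated(df$synapse_id)) {
    dup <- unique(df$synapse_id[duplicated(df$synapse_id)])
    stop("duplicate synapse_id value(s): ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  coords <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(df) > 0 && !all(is.finite(coords))) {
    bad <- which(!apply(is.finite(coords), 1, all))
    stop("non-finite centroid coordinate at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> role=%s, %d synapses, %d pre / %d post neurons\n",
              attr(x, "role"), nrow(x),
              length(unique(x$pre_neuron)), length(unique(x$post_neuron))))
  if (nrow(x) > 0) print.data.frame(head(x, 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read a synapse table from a CSV file
#'
#' The file must be comma-separated with a header naming (at least) the
#' columns `synapse_id`, `pre_neuron`, `post_neuron`, `x`, `y`, `z`.
#' Row order is preserved.
#'
#' @param path path to an existing CSV file.
#' @param role `"ground_truth"` or `"reconstruction"`.
#' @return A [synapse_table()].
#' @export
read_synapse_table <- function(path, role = c("ground_truth", "reconstruction")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  required <- c("synapse_id", "pre_neuron", "post_neuron", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("synapse table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("x", "y", "z")) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      stop("non-numeric ", col, " coordinate at row ", bad[1],
           " of ", path, ": '", raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- val
  }
  synapse_table(raw$synapse_id, raw$pre_neuron, raw$post_neuron,
                raw$x, raw$y, raw$z, role = role)
}

#' Write a synapse table to CSV
#'
#' Writes the six canonical columns; `read_synapse_table()` on the result
#' reproduces the table record for record.
#'
#' @param table a [synapse_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(table, path) {
  stopifnot(inherits(table, "synapse_table"))
  df <- as.data.frame(table)[, c("synapse_id", "pre_neuron", "post_neuron",
                                 "x", "y", "z")]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a synapse table into its synaptic terminals
#'
#' Every synapse contributes exactly two terminals: a presynaptic terminal on
#' its presynaptic neuron and a postsynaptic terminal on its postsynaptic
#' neuron. Terminals are the unit the NRI metric counts: an intracellular
#' path is an unordered pair of terminals on the same neuron.
#'
#' @param table a [synapse_table()].
#' @return data.frame with columns `synapse_id`, `polarity` (`"pre"`/`"post"`)
#'   and `neuron`; `2 * nrow(table)` rows.
#' @export
terminals_of <- function(table) {
  stopifnot(inherits(table, "synapse_table"))
  data.frame(
    synapse_id = rep(table$synapse_id, 2L),
    polarity = rep(c("pre", "post"), each = nrow(table)),
    neuron = c(table$pre_neuron, table$post_neuron),
    stringsAsFactors = FALSE
  )
}

#' Convert a synapse table to an igraph brain graph
#'
#' Nodes are neuron identifiers, directed edges are synapses with centroid
#' coordinates as edge attributes. Mostly useful for export (e.g. GraphML via
#' [igraph::write_graph()]) and visual inspection.
#'
#' @param table a [synapse_table()].
#' @return an [igraph::igraph] directed multigraph.
#' @export
as_brain_graph <- function(table) {
  stopifnot(inherits(table, "synapse_table"))
  neurons <- sort(unique(c(table$pre_neuron, table$post_neuron)))
  igraph::graph_from_data_frame(
    data.frame(from = table$pre_neuron, to = table$post_neuron,
               synapse_id = table$synapse_id,
               x = table$x, y = table$y, z = table$z,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = neurons, stringsAsFactors = FALSE)
  )
}

#' Export a synapse table as GraphML
#'
#' @param table a [synapse_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(table, path) {
  igraph::write_graph(as_brain_graph(table), path, format = "graphml")
  invisible(path)
}
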