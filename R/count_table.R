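#' Construct a count table
#'
#' The count table is the sufficient statistic for all metrics in this
#' package: a non-negative integer matrix whose entry `c[i, j]` is the number
#' of matched synaptic terminals shared by ground-truth neuron `i` (rows) and
#' reconstructed fragment `j` (columns). Row `"ins"` holds terminals of
#' inserted synapses (present only in the reconstruction); column `"del"`
#' holds terminals of deleted synapses (present only in the ground truth).
#' The `("ins", "del")` cell is always 0.
#'
#' @param counts integer matrix. Either already carrying an `"ins"` first row
#'   and `"del"` first column (named exactly so), or a bare body matrix to
#'   which zero ins/del margins are added. Row names are ground-truth neuron
#'   ids and column names reconstructed fragment ids; unnamed dimensions get
#'   `g1..gI` / `s1..sJ`.
#' @return An object of class `nri_count_table` (an integer matrix).
#' @export
#' @examples
#' # one neuron split into two equal fragments
#' ct <- count_table(matrix(c(5, 5), 1, 2, dimnames = list("g1", c("s1", "s2"))))
#' global_nri(ct)
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("count table entries must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max pairs
  has_margins <- nrow(counts) > 0 && ncol(counts) > 0 &&
    identical(rownames(counts)[1], "ins") && identical(colnames(counts)[1], "del")
  if (!has_margins) {
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    }
    if (is.null(colnames(counts))) {
      colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    }
    counts <- rbind(0, cbind(0, counts))
    rownames(counts)[1] <- "ins"
    colnames(counts)[1] <- "del"
  }
  if ("ins" %in% rownames(counts)[-1] || "del" %in% colnames(counts)[-1]) {
    stop("'ins' and 'del' are reserved labels", call. = FALSE)
  }
  if (counts[1, 1] != 0) {
    stop("the (ins, del) cell must be 0", call. = FALSE)
  }
  structure(counts, class = c("nri_count_table", "matrix"))
}

#' @export
print.nri_count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d ground-truth neurons x %d reconstructed fragments (+ ins/del)\n",
              nrow(x) - 1L, ncol(x) - 1L))
  print(unclass(x))
  invisible(x)
}

# internal accessors
ct_body <- function(ct) unclass(ct)[-1, -1, drop = FALSE]
ct_del <- function(ct) unclass(ct)[-1, 1]
ct_ins <- function(ct) unclass(ct)[1, -1]

#' Build the count table from two synapse tables and a matching
#'
#' For every matched synapse pair the ground-truth presynaptic terminal and
#' the reconstruction presynaptic terminal share polarity and increment
#' `c[gt_pre, recon_pre]`; likewise the postsynaptic terminals increment
#' `c[gt_post, recon_post]`. A matched pair therefore contributes exactly two
#' matched terminals, giving the `2N` body total for `N` matched synapses.
#' Each unmatched ground-truth synapse adds its two terminals to the deletion
#' column; each unmatched reconstruction synapse adds its two terminals to
#' the insertion row. A reconstruction that reverses a synapse's direction is
#' penalised automatically: its presynaptic fragment column receives a
#' terminal from the ground-truth presynaptic neuron's row, creating the
#' false-positive and false-negative path pairs such a reversal implies.
#'
#' Neurons and fragments appear as rows/columns only if they carry at least
#' one terminal; objects without any synapse correspondence (e.g. glia) never
#' enter the table.
#'
#' @param gt,recon the [synapse_table()]s the matching was computed from.
#' @param matching a [match_synapses()] result.
#' @param segmentation_only if `TRUE`, unmatched synapses contribute nothing
#'   (insertion row and deletion column stay zero), so the score reflects
#'   segmentation quality among detected synapses only.
#' @param directed if `FALSE`, the pre/post polarity of each matched synapse
#'   pair is treated as unoriented: a pair whose identity orientation lands
#'   on cells with less support than its flipped orientation (judged against
#'   a provisional directed table) is flipped, so direction reversals are not
#'   penalised.
#' @return an [count_table()] object.
#' @export
build_count_table <- function(gt, recon, matching, segmentation_only = FALSE,
                              directed = TRUE) {
  stopifnot(inherits(gt, "synapse_table"), inherits(recon, "synapse_table"),
            inherits(matching, "synapse_matching"))
  gi <- match(matching$pairs$gt_id, gt$synapse_id)
  ri <- match(matching$pairs$recon_id, recon$synapse_id)
  ug <- match(matching$unmatched_gt, gt$synapse_id)
  ur <- match(matching$unmatched_recon, recon$synapse_id)
  if (anyNA(gi) || anyNA(ug)) {
    stop("matching references synapse ids absent from the ground-truth table",
         call. = FALSE)
  }
  if (anyNA(ri) || anyNA(ur)) {
    stop("matching references synapse ids absent from the reconstruction table",
         call. = FALSE)
  }
  if (length(gi) + length(ug) != nrow(gt) || length(ri) + length(ur) != nrow(recon)) {
    stop("matching does not partition the two synapse tables", call. = FALSE)
  }

  g_pre <- gt$pre_neuron[gi]; g_post <- gt$post_neuron[gi]
  r_pre <- recon$pre_neuron[ri]; r_post <- recon$post_neuron[ri]

  if (!directed && length(gi) > 0) {
    prov <- table(factor(paste0(c(g_pre, g_post), "\r", c(r_pre, r_post))))
    support <- function(a, b) {
      v <- prov[paste0(a, "\r", b)]
      ifelse(is.na(v), 0L, as.integer(v))
    }
    keep <- support(g_pre, r_pre) + support(g_post, r_post)
    flip <- support(g_pre, r_post) + support(g_post, r_pre)
    do_flip <- flip > keep
    tmp <- r_pre[do_flip]
    r_pre[do_flip] <- r_post[do_flip]
    r_post[do_flip] <- tmp
  }

  if (segmentation_only) {
    ug <- integer(); ur <- integer()
  }
  rows <- sort(unique(c(g_pre, g_post,
                        gt$pre_neuron[ug], gt$post_neuron[ug])))
  cols <- sort(unique(c(r_pre, r_post,
                        recon$pre_neuron[ur], recon$post_neuron[ur])))
  if ("ins" %in% rows || "del" %in% rows || "ins" %in% cols || "del" %in% cols) {
    stop("neuron ids 'ins' and 'del' are reserved", call. = FALSE)
  }
  M <- matrix(0, nrow = length(rows) + 1L, ncol = length(cols) + 1L,
              dimnames = list(c("ins", rows), c("del", cols)))
  add <- function(r, co) {
    if (length(r) == 0) return(invisible(NULL))
    t <- table(factor(r, levels = rownames(M)), factor(co, levels = colnames(M)))
    M <<- M + as.matrix(t)
  }
  add(c(g_pre, g_post), c(r_pre, r_post))
  add(c(gt$pre_neuron[ug], gt$post_neuron[ug]), rep("del", 2L * length(ug)))
  add(rep("ins", 2L * length(ur)), c(recon$pre_neuron[ur], recon$post_neuron[ur]))
  count_table(M)
}

#' Read / write a count table as CSV
#'
#' Layout mirrors the in-memory matrix: first column `del`, first row `ins`,
#' with ground-truth neuron ids as row names in the leading unnamed column.
#'
#' @param ct a [count_table()].
#' @param path file path.
#' @return `write_count_table`: `path` invisibly; `read_count_table`: a
#'   [count_table()].
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "nri_count_table"))
  df <- data.frame(neuron = rownames(ct), unclass(ct), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_table(m)
}
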