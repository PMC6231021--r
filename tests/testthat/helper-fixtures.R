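# Shared fixtures and independent oracles.

# The split/merge toy network: three synapses from one axon onto a dendrite
# whose spine head is split off in the reconstruction, plus a second neuron
# pair merged onto the dendrite's fragment.
fig1_gt <- function() {
  read_synapse_table(system.file("extdata", "fig1_ground_truth.csv",
                                 package = "nri"), role = "ground_truth")
}
fig1_recon <- function() {
  read_synapse_table(system.file("extdata", "fig1_reconstruction.csv",
                                 package = "nri"), role = "reconstruction")
}
fig1_count_table <- function() {
  gt <- fig1_gt(); rec <- fig1_recon()
  build_count_table(gt, rec, match_synapses(gt, rec))
}

random_synapse_table <- function(n, n_neurons = 5, role = "ground_truth",
                                 box = 10000, prefix = "s") {
  neurons <- paste0("n", seq_len(n_neurons))
  synapse_table(
    synapse_id = sprintf("%s%d", prefix, seq_len(n)),
    pre_neuron = sample(neurons, n, replace = TRUE),
    post_neuron = sample(neurons, n, replace = TRUE),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    role = role)
}

random_count_table <- function(max_dim = 6, max_entry = 5) {
  I <- sample.int(max_dim, 1)
  J <- sample.int(max_dim, 1)
  M <- matrix(sample(0:max_entry, (I + 1) * (J + 1), replace = TRUE),
              I + 1, J + 1)
  M[1, 1] <- 0
  rownames(M) <- c("ins", paste0("g", seq_len(I)))
  colnames(M) <- c("del", paste0("s", seq_len(J)))
  count_table(M)
}

# Independent path-pair oracle: expand the count table into individual
# terminals and classify every unordered terminal pair directly.
#   TP: same real row, same real column (same cell)
#   FN: same real row, different columns, or both in that row's deletion cell
#   FP: same real column, different rows, or both in that column's insertion
#       cell
# Pairs in different rows and different columns, pairs across insertion
# cells, and pairs across deletion cells are not counted.
pair_oracle <- function(ct) {
  M <- unclass(ct)
  idx <- which(M > 0, arr.ind = TRUE)
  r <- rep(idx[, 1], M[idx])
  co <- rep(idx[, 2], M[idx])
  n <- length(r)
  if (n < 2) return(list(tp = 0, fn = 0, fp = 0,
                         fp_by_neuron = numeric(0), tn = 0))
  same_row <- outer(r, r, "==")
  same_col <- outer(co, co, "==")
  real_row <- r > 1   # row 1 is "ins"
  real_col <- co > 1  # col 1 is "del"
  upper <- upper.tri(same_row)
  both_real_row <- outer(real_row, real_row, "&")
  both_real_col <- outer(real_col, real_col, "&")
  tp <- sum(upper & same_row & same_col & both_real_row & both_real_col)
  # FN: pairs within a real row that are not TPs (includes deletion-cell
  # pairs and row-vs-deletion pairs)
  fn <- sum(upper & same_row & both_real_row & !(same_col & both_real_col))
  # FP: pairs within a real column that are not TPs
  fp <- sum(upper & same_col & both_real_col & !(same_row & both_real_row))
  # attributed per-neuron FP: insertion-vs-row pairs full weight, cross-row
  # pairs half to each participant; insertion-insertion pairs to "ins"
  rows <- rownames(M)
  fp_by <- setNames(numeric(nrow(M)), rows)
  hits <- which(upper & same_col & both_real_col &
                  !(same_row & both_real_row), arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    a <- hits[k, 1]; b <- hits[k, 2]
    ra <- r[a]; rb <- r[b]
    if (ra == 1 && rb == 1) {
      fp_by["ins"] <- fp_by["ins"] + 1
    } else if (ra == 1) {
      fp_by[rows[rb]] <- fp_by[rows[rb]] + 1
    } else if (rb == 1) {
      fp_by[rows[ra]] <- fp_by[rows[ra]] + 1
    } else {
      fp_by[rows[ra]] <- fp_by[rows[ra]] + 0.5
      fp_by[rows[rb]] <- fp_by[rows[rb]] + 0.5
    }
  }
  tn <- sum(upper & !same_row & !same_col)
  list(tp = tp, fn = fn, fp = fp, fp_by_neuron = fp_by, tn = tn)
}

# A reconstruction built from a ground-truth table: every synapse copied
# with a small coordinate shift (well inside the cap), plus `extra` spurious
# synapses far outside the ground-truth bounding box.
rbind_tables <- function(gt, shift = 10, extra = 0) {
  n <- nrow(gt)
  ids <- c(paste0("r", seq_len(n)), if (extra > 0) paste0("x", seq_len(extra)))
  synapse_table(
    synapse_id = ids,
    pre_neuron = c(gt$pre_neuron, rep("spur_pre", extra)),
    post_neuron = c(gt$post_neuron, rep("spur_post", extra)),
    x = c(gt$x + shift, max(gt$x) + 1e6 + seq_len(extra) * 1e4),
    y = c(gt$y, rep(0, extra)),
    z = c(gt$z, rep(0, extra)),
    role = "reconstruction")
}

# A tiny two-neuron morphology handy for geometric tests: neuron "axo" has
# one axon segment running parallel (at `gap` nm) to neuron "den"'s dendrite
# segment; each neuron is rooted at a soma stub.
parallel_process_morphology <- function(gap = 100, length_nm = 10000,
                                        diameter = 200) {
  seg <- data.frame(
    segment_id = c("axo_soma", "axo_a1", "den_soma", "den_d1"),
    neuron = c("axo", "axo", "den", "den"),
    parent = c(NA, "axo_soma", NA, "den_soma"),
    x0 = c(-2000, 0, -2000, 0),
    y0 = c(0, 0, gap + diameter, gap + diameter),
    z0 = 0,
    x1 = c(-1000, length_nm, -1000, length_nm),
    y1 = c(0, 0, gap + diameter, gap + diameter),
    z1 = 0,
    diameter = c(5000, diameter, 5000, diameter),
    kind = c("soma", "axon", "soma", "dendrite"),
    stringsAsFactors = FALSE)
  network_morphology(seg)
}
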