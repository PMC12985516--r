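# Small in-code fixtures shared across test files.

# Minimal valid node table; scores chosen so pet calls 2/3 diseased
# nodes positive and mri 1/3 at cutoff 2.
make_toy_nodes <- function() {
  tibble::tibble(
    node_id = paste0("n", 1:6),
    patient_id = paste0("p", 1:6),
    level = c("II", "II", "III", "II", "VIII", "I"),
    pathology = rep(c("metastatic", "benign"), each = 3),
    mri_score = c(3L, 1L, 1L, 0L, 2L, 1L),
    pet_score = c(4L, 3L, 1L, 1L, 0L, 2L),
    laterality = c("left", "right", "left", "right", "left", "right")
  )
}

# Node table from explicit per-node calls (positive = score 3,
# negative = score 1), for constructing exact paired layouts.
nodes_from_calls <- function(diseased, pet_pos, mri_pos) {
  n <- length(diseased)
  tibble::tibble(
    node_id = sprintf("c%03d", seq_len(n)),
    patient_id = sprintf("cp%03d", seq_len(n)),
    level = rep("II", n),
    pathology = ifelse(diseased, "metastatic", "benign"),
    mri_score = ifelse(mri_pos, 3L, 1L),
    pet_score = ifelse(pet_pos, 3L, 1L)
  )
}

# Brute-force AUC over all diseased x benign score pairs, ties 1/2.
brute_force_auc <- function(pos, neg) {
  grid <- expand.grid(x = pos, y = neg)
  mean((grid$x > grid$y) + 0.5 * (grid$x == grid$y))
}

# Cluster bootstrap of a predictive-value difference: resample nodes
# (the clusters) with replacement and convert the resampled difference
# distribution into a two-sided p-value for H0: difference = 0.
bootstrap_pv_p <- function(nodes, which = "ppv", n_boot = 10000, seed = 1) {
  set.seed(seed)
  d <- nodes$pathology == "metastatic"
  ya <- nodes$pet_score >= 2
  yb <- nodes$mri_score >= 2
  if (which == "npv") {
    d <- !d
    ya <- !ya
    yb <- !yb
  }
  n <- nrow(nodes)
  diffs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    sum(d[idx] & ya[idx]) / sum(ya[idx]) -
      sum(d[idx] & yb[idx]) / sum(yb[idx])
  }, numeric(1))
  diffs <- diffs[is.finite(diffs)]
  2 * min(mean(diffs <= 0) + 0.5 * mean(diffs == 0),
          mean(diffs >= 0) + 0.5 * mean(diffs == 0), 0.5)
}
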