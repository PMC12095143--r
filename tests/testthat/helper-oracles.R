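# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# P(X >= k) for every k, by enumerating all q-subsets of a universe of N
# genes of which the first m belong to the pathway
hyper_enum_tail <- function(q, m, N) {
  if (q == 0) {
    counts <- 0L
  } else {
    draws <- utils::combn(N, q)
    counts <- colSums(draws <= m)
  }
  function(k) mean(counts >= k)
}

# two-sided exact rank-sum p by enumerating all assignments of the pooled
# sample to group a (no ties assumed)
wilcox_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# weighted degrees via symmetric adjacency-matrix row sums
adjacency_degrees <- function(network) {
  nodes <- network$nodes$node
  A <- matrix(0, length(nodes), length(nodes),
    dimnames = list(nodes, nodes)
  )
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    A[e$from, e$to] <- A[e$from, e$to] + e$weight
    A[e$to, e$from] <- A[e$to, e$from] + e$weight
  }
  rowSums(A)
}

# small two-drug map with a shared metabolite, for propagation tests
shared_metabolite_map <- function() {
  component_map(
    tibble::tibble(
      drug_id = c("d1", "d2", "d2"),
      metabolite_id = c("m1", "m1", "m2")
    ),
    tibble::tibble(
      metabolite_id = c("m1", "m2"),
      gene_symbol = c("T1", "T2")
    )
  )
}

# tiny ensemble used by several property tests
small_ensemble <- function(seed = 11, n = 12, ...) {
  generate_ensemble(synthetic_config(
    n_prescriptions = n, n_genes = 120, n_pathways = 8,
    pathway_size = c(5, 12), seed = seed, ...
  ))
}

gram_records <- function(values, ids = paste0("d", seq_along(values))) {
  tibble::tibble(
    drug_id = ids, quantity = values, unit = "gram", dynasty = "SongYuan"
  )
}
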