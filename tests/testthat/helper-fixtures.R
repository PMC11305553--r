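# Shared fixtures: small references and brute-force oracles used across files.

small_reference <- function(seed = 1, n_v = 5, n_d = 3, n_j = 2) {
  build_germline_reference(n_v, n_d, n_j, seed = seed)
}

# Brute-force single-linkage oracle: transitive closure of the adjacency
# matrix (edges at distance <= threshold), independent of the union-find path
# used by the package.
oracle_components <- function(distmat, threshold) {
  adj <- distmat <= threshold
  diag(adj) <- TRUE
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- apply(reach, 1L, function(r) min(which(r)))
  match(labels, unique(labels))
}

canon_labels <- function(x) match(x, unique(x))

# Direct R implementation of normalized Hamming with N wildcard, used as an
# oracle against the C++ path.
oracle_hamming <- function(a, b, wildcard = "N") {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  use <- ca != wildcard & cb != wildcard
  sum(ca[use] != cb[use]) / length(ca)
}

# Random junction-like strings of one length with controlled divergence.
random_junctions <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_string <- function(s, positions, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  }
  paste(ch, collapse = "")
}
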