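# Shared fixtures and independent oracles, all built in code.

toy_flora_records <- function() {
  data.frame(
    genus = c("Carex", "Carex", "Salix", "Salix", "Rosa", "Lemna", "Poa"),
    family = c("Cyperaceae", "Cyperaceae", "Salicaceae", "Salicaceae",
               "Rosaceae", "Araceae", "Poaceae"),
    flora = c("A", "B", "A", "B", "A", "A", "A"),
    n_nonhybrid = c(3, 3, 4, 6, 5, 1, 2),
    n_intrageneric_hybrids = c(1, 1, 0, 2, 3, 0, 0),
    n_intergeneric_hybrid_halves = c(0, 0, 1, 0, 0, 0, 0),
    unspecified_multiple = FALSE,
    stringsAsFactors = FALSE
  )
}

# BM deviates on a tree from a precomputed lower Cholesky factor.
bm_deviate <- function(L) as.numeric(L %*% rnorm(nrow(L)))

chol_lower <- function(C) t(chol(C + diag(1e-12 * mean(diag(C)), nrow(C))))

# Brute-force Benjamini-Hochberg step-up by its definition.
bh_brute_force <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  thresh <- which(sorted <= (seq_len(m) / m) * q)
  flags <- rep(FALSE, m)
  if (length(thresh) > 0) flags[ord[seq_len(max(thresh))]] <- TRUE
  flags
}

# Graph-theoretic d-separation oracle via the moralized ancestral graph.
dsep_oracle <- function(edges, x, y, Z) {
  nodes <- unique(c(as.vector(edges), x, y, Z))
  parents <- function(v) edges[edges[, 2] == v, 1]
  # ancestors of {x, y} union Z, inclusive
  anc <- unique(c(x, y, Z))
  repeat {
    more <- unique(unlist(lapply(anc, parents)))
    new_anc <- union(anc, more)
    if (length(new_anc) == length(anc)) break
    anc <- new_anc
  }
  sub <- edges[edges[, 1] %in% anc & edges[, 2] %in% anc, , drop = FALSE]
  # moralize: undirected edges plus marriages between co-parents
  und <- rbind(sub, sub[, 2:1, drop = FALSE])
  for (v in anc) {
    pa <- parents(v)
    pa <- pa[pa %in% anc]
    if (length(pa) > 1) {
      pairs <- t(combn(pa, 2))
      und <- rbind(und, pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  # remove conditioning nodes, test connectivity x -- y
  keep <- setdiff(anc, Z)
  und <- und[und[, 1] %in% keep & und[, 2] %in% keep, , drop = FALSE]
  reached <- x
  repeat {
    nb <- unique(und[und[, 1] %in% reached, 2])
    new_r <- union(reached, nb)
    if (length(new_r) == length(reached)) break
    reached <- new_r
  }
  !(y %in% reached)
}

# Random DAG over k nodes: edges go from earlier to later in a shuffled order.
random_dag <- function(k, p_edge = 0.4) {
  nodes <- sample(paste0("v", seq_len(k)))
  edges <- NULL
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (runif(1) < p_edge) edges <- rbind(edges, c(nodes[i], nodes[j]))
    }
  }
  list(nodes = sort(nodes), edges = edges)
}
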