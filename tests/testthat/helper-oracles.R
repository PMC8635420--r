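# Independent oracles used to cross-check the package's implementations.
# Each deliberately uses a different algorithm than the code under test.

# All-pairs BFS shortest-path enumeration betweenness (raw counts, undirected
# unweighted simple graph).  adj: list of integer neighbor vectors.
oracle_betweenness <- function(adj) {
  n <- length(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  runs <- lapply(seq_len(n), bfs)
  cb <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    st <- runs[[s]]$dist[t]
    if (is.infinite(st) || runs[[s]]$sigma[t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (runs[[s]]$dist[v] + runs[[t]]$dist[v] == st) {
        cb[v] <- cb[v] + runs[[s]]$sigma[v] * runs[[t]]$sigma[v] /
          runs[[s]]$sigma[t]
      }
    }
  }
  cb
}

# adjacency list of the collapsed undirected simple graph of a kg, in
# kg_entities() order
kg_adj <- function(kg) {
  ents <- kg_entities(kg)
  idx <- stats::setNames(seq_along(ents), ents)
  adj <- rep(list(integer(0)), length(ents))
  edges <- unique(t(apply(cbind(idx[kg$triples$head], idx[kg$triples$tail]),
                          1, sort)))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# random Erdos-Renyi kg with n nodes and edge probability p
random_er_kg <- function(n, p, seed) {
  pairs <- t(combn(n, 2))
  set.seed(seed)
  keep <- runif(nrow(pairs)) < p
  ids <- sprintf("n%02d", seq_len(n))
  tr <- tibble::tibble(head = ids[pairs[keep, 1]], relation = "e",
                       tail = ids[pairs[keep, 2]])
  if (nrow(tr) == 0) {
    tr <- tibble::tibble(head = ids[1], relation = "e", tail = ids[2])
  }
  kg_new(tr)
}

# AUROC by exhaustive positive-negative pair comparison, ties 1/2
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# AUPR by recomputing precision and recall from scratch at every distinct
# threshold (descending), summing precision * recall increment
oracle_aupr <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_recall <- 0
  area <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

# Bi-Interaction by the O(n^2 k) double sum
oracle_bi_interaction <- function(x, V) {
  n <- length(x); k <- ncol(V)
  out <- numeric(k)
  if (n < 2) return(out)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out <- out + (x[i] * V[i, ]) * (x[j] * V[j, ])
  }
  out
}

# small deterministic benchmark shared by pipeline-level tests
tiny_bench <- function(seed = 1, ...) {
  synth_generate(synth_config(drugs = 24, proteins = 18, diseases = 10,
                              pathways = 8, n_positives = 60,
                              edges_per_protein = 6, seed = seed, ...))
}

# fast pipeline configuration for plumbing-level tests
fast_config <- function(...) {
  dti_config(kge_dim = 8, kge_epochs = 5, pca_drug = 3, pca_protein = 3,
             nfm_k = 4, nfm_hidden = 8, nfm_epochs = 3, ...)
}
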