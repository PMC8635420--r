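#' DistMult triple score
#'
#' The DistMult score of a triple (h, r, t) is the bilinear form
#' \eqn{h^T \mathrm{diag}(r)\, t = \sum_i r_i h_i t_i}: RESCAL with the
#' relation matrix restricted to a diagonal.  The score is symmetric in h and
#' t.
#'
#' @param h,r,t Real vectors of equal length (entity, relation, entity
#'   embeddings).
#' @return A single number.
#' @export
#' @examples
#' distmult_score(c(1, 2), c(3, 4), c(5, 6))  # 63
distmult_score <- function(h, r, t) {
  if (length(h) != length(r) || length(h) != length(t)) {
    stop("distmult_score(): h, r, t must have equal length", call. = FALSE)
  }
  sum(r * h * t)
}

#' RESCAL triple score
#'
#' Full bilinear score \eqn{h^T M t}.  With `M = diag(r)` this reduces to
#' [distmult_score()].
#'
#' @param h,t Real vectors of length d.
#' @param M A d x d real matrix associated with the relation.
#' @return A single number.
#' @export
rescal_score <- function(h, M, t) {
  M <- as.matrix(M)
  if (nrow(M) != length(h) || ncol(M) != length(t)) {
    stop("rescal_score(): M must be length(h) x length(t)", call. = FALSE)
  }
  drop(crossprod(h, M %*% t))
}

#' Corrupt triples for negative sampling
#'
#' Produces `eta` corruptions per input triple, each replacing the head or
#' the tail (fair coin) with an entity drawn uniformly from the vocabulary.
#' Corruptions that reproduce a member of `known` (or the source triple) are
#' resampled, so the returned negatives are *filtered*: none is a known true
#' triple.  Deterministic given `seed`.
#'
#' @param triples Tibble with columns `head`, `relation`, `tail`.
#' @param entities Character vector: the entity vocabulary to draw from.
#' @param eta Corruptions per positive (>= 0).
#' @param seed Integer seed.
#' @param known Tibble of known true triples to filter against (typically the
#'   whole KG); the source triples are always filtered.
#' @return Tibble with columns `head`, `relation`, `tail`, `source` (index of
#'   the corrupted positive), in source-major order.
#' @export
corrupt_triples <- function(triples, entities, eta, seed,
                            known = triples) {
  stopifnot(eta >= 0)
  n <- nrow(triples)
  empty <- tibble::tibble(head = character(), relation = character(),
                          tail = character(), source = integer())
  if (eta == 0 || n == 0) return(empty)
  if (length(entities) < 2) {
    stop("corrupt_triples(): cannot corrupt with a vocabulary of size ",
         length(entities), call. = FALSE)
  }
  key <- function(h, r, t) paste(h, r, t, sep = "\t")
  known_keys <- unique(c(key(known$head, known$relation, known$tail),
                         key(triples$head, triples$relation, triples$tail)))
  src <- rep(seq_len(n), each = eta)
  out_h <- triples$head[src]
  out_r <- triples$relation[src]
  out_t <- triples$tail[src]
  local_seed(seed, {
    slot_tail <- stats::runif(length(src)) < 0.5  # TRUE: corrupt tail
    pending <- seq_along(src)
    for (round in 1:64) {
      if (length(pending) == 0) break
      draw <- entities[sample.int(length(entities), length(pending),
                                  replace = TRUE)]
      ph <- ifelse(slot_tail[pending], out_h[pending], draw)
      pt <- ifelse(slot_tail[pending], draw, out_t[pending])
      ok <- !(key(ph, out_r[pending], pt) %in% known_keys)
      idx <- pending[ok]
      out_h[idx] <- ph[ok]
      out_t[idx] <- pt[ok]
      pending <- pending[!ok]
    }
    # rejection exhausted: enumerate the untrue candidates of both slots
    for (i in pending) {
      free_t <- entities[!(key(out_h[i], out_r[i], entities) %in% known_keys)]
      free_h <- entities[!(key(entities, out_r[i], out_t[i]) %in% known_keys)]
      cand <- c(if (length(free_t)) paste0("t", free_t),
                if (length(free_h)) paste0("h", free_h))
      if (length(cand) == 0) {
        stop("corrupt_triples(): no untrue corruption exists for triple ",
             src[i], call. = FALSE)
      }
      pick <- cand[sample.int(length(cand), 1)]
      if (startsWith(pick, "t")) out_t[i] <- substring(pick, 2) else
        out_h[i] <- substring(pick, 2)
    }
  })
  tibble::tibble(head = out_h, relation = out_r, tail = out_t, source = src)
}

#' Train DistMult embeddings on a knowledge graph
#'
#' Learns d-dimensional vectors for every entity and relation so that true
#' triples score higher than filtered uniform corruptions.  The objective is
#' binary logistic loss on the DistMult score (positives vs `eta` corruptions
#' per positive) plus an L2 penalty on the embeddings touched by each batch,
#' minimized by Adam over mini-batches drawn without replacement each epoch.
#' Initialization is Xavier-uniform from `seed`; the whole run is
#' deterministic given the configuration, and `epochs = 0` returns the seeded
#' initialization untouched.
#'
#' @param kg A nonempty `kg` object.
#' @param dim Embedding dimension d (default 64).
#' @param epochs Training epochs (>= 0).
#' @param lr Adam learning rate.
#' @param eta Corruptions per positive triple.
#' @param l2 L2 coefficient on embeddings.
#' @param batch_size Positives per mini-batch.
#' @param seed Integer seed.
#' @return An object of class `kge_embeddings`: list with `entities` (matrix,
#'   one named row per entity), `relations` (matrix, one named row per
#'   relation), `dim`, `loss` (mean per-epoch training loss), and the
#'   configuration.
#' @export
train_kge <- function(kg, dim = 64, epochs = 100, lr = 0.01, eta = 5,
                      l2 = 1e-4, batch_size = 512, seed = 1) {
  stopifnot(dim >= 1, epochs >= 0, eta >= 0, lr > 0, kg_n_triples(kg) > 0)
  vocab <- kg_vocab(kg)
  ents <- names(vocab$entity_index)
  rels <- names(vocab$relation_index)
  ne <- length(ents); nr <- length(rels)
  limit <- sqrt(6 / dim)
  E <- R <- NULL
  local_seed(seed, {
    E <- matrix(stats::runif(ne * dim, -limit, limit), ne, dim,
                 dimnames = list(ents, NULL))
    R <- matrix(stats::runif(nr * dim, -limit, limit), nr, dim,
                 dimnames = list(rels, NULL))
  })
  loss_trace <- double(0)
  if (epochs > 0) {
    hi <- unname(vocab$entity_index[kg$triples$head])
    ri <- unname(vocab$relation_index[kg$triples$relation])
    ti <- unname(vocab$entity_index[kg$triples$tail])
    npos <- length(hi)
    adam <- list(mE = E * 0, vE = E * 0, mR = R * 0, vR = R * 0, t = 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    for (epoch in seq_len(epochs)) {
      neg <- corrupt_triples(kg$triples, ents, eta,
                             seed = seed_from(seed, 7001L + epoch),
                             known = kg$triples)
      all_h <- c(hi, unname(vocab$entity_index[neg$head]))
      all_r <- c(ri, unname(vocab$relation_index[neg$relation]))
      all_t <- c(ti, unname(vocab$entity_index[neg$tail]))
      all_y <- c(rep(1, npos), rep(0, nrow(neg)))
      perm <- NULL
      local_seed(seed_from(seed, 9001L + epoch), perm <- sample.int(length(all_y)))
      all_h <- all_h[perm]; all_r <- all_r[perm]; all_t <- all_t[perm]
      all_y <- all_y[perm]
      bs <- batch_size * (1 + eta)
      starts <- seq(1, length(all_y), by = bs)
      epoch_loss <- 0
      for (s in starts) {
        sel <- s:min(s + bs - 1, length(all_y))
        bh <- all_h[sel]; br <- all_r[sel]; bt <- all_t[sel]; by <- all_y[sel]
        He <- E[bh, , drop = FALSE]; Re <- R[br, , drop = FALSE]
        Te <- E[bt, , drop = FALSE]
        sc <- rowSums(He * Re * Te)
        p <- 1 / (1 + exp(-sc))
        epoch_loss <- epoch_loss - sum(by * log(pmax(p, 1e-12)) +
                                       (1 - by) * log(pmax(1 - p, 1e-12)))
        g <- (p - by) / length(sel)
        gH <- g * (Re * Te); gT <- g * (Re * He); gR <- g * (He * Te)
        rows_e <- sort(unique(c(bh, bt)))
        gE <- rowsum(rbind(gH, gT), group = c(bh, bt), reorder = TRUE) +
          l2 * E[rows_e, , drop = FALSE]
        rows_r <- sort(unique(br))
        gRm <- rowsum(gR, group = br, reorder = TRUE) +
          l2 * R[rows_r, , drop = FALSE]
        adam$t <- adam$t + 1
        corr <- sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        adam$mE[rows_e, ] <- b1 * adam$mE[rows_e, , drop = FALSE] + (1 - b1) * gE
        adam$vE[rows_e, ] <- b2 * adam$vE[rows_e, , drop = FALSE] + (1 - b2) * gE^2
        E[rows_e, ] <- E[rows_e, , drop = FALSE] -
          lr * corr * adam$mE[rows_e, , drop = FALSE] /
          (sqrt(adam$vE[rows_e, , drop = FALSE]) + eps)
        adam$mR[rows_r, ] <- b1 * adam$mR[rows_r, , drop = FALSE] + (1 - b1) * gRm
        adam$vR[rows_r, ] <- b2 * adam$vR[rows_r, , drop = FALSE] + (1 - b2) * gRm^2
        R[rows_r, ] <- R[rows_r, , drop = FALSE] -
          lr * corr * adam$mR[rows_r, , drop = FALSE] /
          (sqrt(adam$vR[rows_r, , drop = FALSE]) + eps)
      }
      epoch_loss <- epoch_loss / length(all_y)
      if (!is.finite(epoch_loss)) {
        stop("train_kge(): training diverged (non-finite loss) at epoch ",
             epoch, "; reduce the learning rate", call. = FALSE)
      }
      loss_trace <- c(loss_trace, epoch_loss)
    }
  }
  structure(
    list(entities = E, relations = R, dim = dim, loss = loss_trace,
         config = list(dim = dim, epochs = epochs, lr = lr, eta = eta,
                       l2 = l2, batch_size = batch_size, seed = seed)),
    class = "kge_embeddings")
}

#' @export
print.kge_embeddings <- function(x, ...) {
  cat("<kge_embeddings> d =", x$dim, "|", nrow(x$entities), "entities,",
      nrow(x$relations), "relations\n")
  if (length(x$loss)) {
    cat("  final training loss:", format(utils::tail(x$loss, 1), digits = 4), "\n")
  }
  invisible(x)
}

#' Filtered link-prediction ranking metrics
#'
#' For every test triple (h, r, t), scores all tail candidates (h, r, t') over
#' the entity vocabulary, removes candidates that reproduce a known true
#' triple other than the test triple itself (filtered protocol), and ranks
#' the test triple's score among the survivors, with tied scores receiving
#' their mean rank.  Reports the mean reciprocal rank (MRR) and Hits\@k.
#'
#' @param emb A `kge_embeddings` object.
#' @param tests Tibble of test triples (`head`, `relation`, `tail`), all ids
#'   present in `emb`.
#' @param kg A `kg` object whose triples define the filter set.
#' @param hits_at Integer vector of cutoffs for Hits\@k.
#' @return List with `ranks` (numeric vector, one per test triple), `mrr`,
#'   and `hits` (named vector).
#' @export
rank_triples <- function(emb, tests, kg, hits_at = c(1, 3, 10)) {
  unknown <- setdiff(unique(c(tests$head, tests$tail)), rownames(emb$entities))
  if (length(unknown) > 0) {
    stop("rank_triples(): unknown entity '", unknown[1], "'", call. = FALSE)
  }
  unknown_r <- setdiff(unique(tests$relation), rownames(emb$relations))
  if (length(unknown_r) > 0) {
    stop("rank_triples(): unknown relation '", unknown_r[1], "'", call. = FALSE)
  }
  ents <- rownames(emb$entities)
  known_keys <- paste(kg$triples$head, kg$triples$relation, kg$triples$tail,
                      sep = "\t")
  ranks <- purrr::map_dbl(seq_len(nrow(tests)), function(i) {
    h <- tests$head[i]; r <- tests$relation[i]; t <- tests$tail[i]
    sc <- drop(emb$entities %*% (emb$entities[h, ] * emb$relations[r, ]))
    cand_keys <- paste(h, r, ents, sep = "\t")
    keep <- !(cand_keys %in% known_keys) | ents == t
    sc <- sc[keep]
    st <- sc[ents[keep] == t]
    sum(sc > st) + (sum(sc == st) + 1) / 2
  })
  list(ranks = ranks,
       mrr = mean(1 / ranks),
       hits = stats::setNames(
         purrr::map_dbl(hits_at, ~ mean(ranks <= .x)),
         paste0("hits@", hits_at)))
}

#' Write / read an embedding table as TSV
#'
#' One row per id (`entity:` or `relation:` prefixed), columns `v1..vd`;
#' a `# dim = d` header line pins the dimension.
#'
#' @param emb A `kge_embeddings` object.
#' @param path File path.
#' @return `path` (writer) or a `kge_embeddings` object (reader).
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste0("# dim = ", emb$dim), con)
  fmt <- function(m, prefix) {
    paste0(prefix, rownames(m), "\t",
           apply(m, 1, function(v) paste(sprintf("%.17g", v), collapse = "\t")))
  }
  writeLines(fmt(emb$entities, "entity:"), con)
  writeLines(fmt(emb$relations, "relation:"), con)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  d <- as.integer(sub("# dim = ", "", lines[1], fixed = TRUE))
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- purrr::map_chr(parts, 1)
  vals <- purrr::map(parts, ~ as.double(.x[-1]))
  stopifnot(all(lengths(vals) == d))
  m <- do.call(rbind, vals)
  is_ent <- startsWith(ids, "entity:")
  E <- m[is_ent, , drop = FALSE]
  rownames(E) <- sub("^entity:", "", ids[is_ent])
  R <- m[!is_ent, , drop = FALSE]
  rownames(R) <- sub("^relation:", "", ids[!is_ent])
  structure(list(entities = E, relations = R, dim = d, loss = double(0),
                 config = list(dim = d)),
            class = "kge_embeddings")
}
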