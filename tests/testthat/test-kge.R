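test_that("DistMult scoring: hand values, symmetry, annihilation", {
  expect_equal(distmult_score(c(1, 2), c(3, 4), c(5, 6)), 63)
  expect_equal(distmult_score(rep(0, 4), rnorm(4), rnorm(4)), 0)
  set.seed(1)
  for (i in 1:20) {
    h <- rnorm(6); r <- rnorm(6); t <- rnorm(6)
    expect_equal(distmult_score(h, r, t), distmult_score(t, r, h))
  }
  expect_error(distmult_score(1:2, 1:3, 1:2), "equal length")
})

test_that("RESCAL scoring reduces to DistMult on diagonal relations", {
  h <- c(1, 0); t <- c(0, 1)
  expect_equal(rescal_score(h, matrix(c(0, 2, 1, 0), 2), t), 1)
  expect_equal(rescal_score(c(1, 2), diag(2), c(3, 4)), sum(c(1, 2) * c(3, 4)))
  set.seed(2)
  for (i in 1:50) {
    d <- sample(2:8, 1)
    h <- rnorm(d); r <- rnorm(d); t <- rnorm(d)
    expect_equal(rescal_score(h, diag(r), t), distmult_score(h, r, t),
                 tolerance = 1e-12)
  }
  expect_error(rescal_score(1:2, matrix(0, 3, 2), 1:2), "must be")
})

test_that("corruption sampling is filtered, single-slot, and deterministic", {
  tr <- tibble::tibble(head = c("a", "b"), relation = "r", tail = c("b", "c"))
  ents <- c("a", "b", "c", "d")
  expect_equal(nrow(corrupt_triples(tr, ents, 0, seed = 1)), 0)

  neg <- corrupt_triples(tr, ents, 5, seed = 3)
  expect_equal(nrow(neg), 10)
  src <- tr[neg$source, ]
  head_changed <- neg$head != src$head
  tail_changed <- neg$tail != src$tail
  expect_true(all(xor(head_changed, tail_changed)))
  expect_equal(neg$relation, src$relation)
  # filtered: never reproduces a known triple
  keys <- function(x) paste(x$head, x$relation, x$tail)
  expect_length(intersect(keys(neg), keys(tr)), 0)

  expect_identical(corrupt_triples(tr, ents, 5, seed = 3), neg)
  expect_false(identical(corrupt_triples(tr, ents, 5, seed = 4), neg))

  expect_error(corrupt_triples(tr, "a", 2, seed = 1), "vocabulary of size 1")
})

test_that("with two entities every corruption is the unique untrue triple", {
  # entities {a,b}; truths: a-r-b, b-r-a, a-r-a; the only untrue triple is
  # b-r-b, so filtered corruption of the two reachable sources must always
  # return it
  known <- tibble::tibble(head = c("a", "b", "a"), relation = "r",
                          tail = c("b", "a", "a"))
  for (seed in 1:10) {
    neg <- corrupt_triples(known[1:2, ], c("a", "b"), 2, seed = seed,
                           known = known)
    expect_true(all(neg$head == "b" & neg$tail == "b"))
  }
  # a source whose every single-slot corruption is true cannot be corrupted
  expect_error(corrupt_triples(known[3, ], c("a", "b"), 1, seed = 1,
                               known = known),
               "no untrue corruption")
})

test_that("KGE training is seeded, reproducible, and inert at zero epochs", {
  kg <- random_er_kg(12, 0.3, 9)
  e0a <- train_kge(kg, dim = 6, epochs = 0, seed = 5)
  e0b <- train_kge(kg, dim = 6, epochs = 0, seed = 5)
  expect_identical(e0a$entities, e0b$entities)
  expect_identical(e0a$relations, e0b$relations)

  e1 <- train_kge(kg, dim = 6, epochs = 3, eta = 2, seed = 5)
  e2 <- train_kge(kg, dim = 6, epochs = 3, eta = 2, seed = 5)
  expect_identical(e1$entities, e2$entities)
  expect_false(identical(e0a$entities, e1$entities))
  expect_true(all(is.finite(e1$loss)))
})

test_that("L2 regularization keeps embedding norms bounded during training", {
  b <- tiny_bench(seed = 2)
  emb <- train_kge(b$kg, dim = 8, epochs = 30, eta = 3, l2 = 1e-3,
                   lr = 0.05, seed = 1)
  expect_lt(max(abs(emb$entities)), 10)
  expect_true(all(is.finite(emb$entities)))
})

test_that("training separates planted within-block triples from cross-block", {
  # two blocks of entities; the relation holds only within blocks, so
  # held-out within-block triples should outscore cross-block ones
  blk <- function(ids) {
    tidyr::expand_grid(head = ids, tail = ids) |>
      dplyr::filter(.data$head != .data$tail) |>
      dplyr::mutate(relation = "same", .after = "head")
  }
  a <- sprintf("a%02d", 1:16); b <- sprintf("b%02d", 1:16)
  all_within <- dplyr::bind_rows(blk(a), blk(b))
  set.seed(11)
  hold <- sample(nrow(all_within), 16)
  kg <- kg_new(all_within[-hold, ])
  emb <- train_kge(kg, dim = 8, epochs = 60, eta = 4, lr = 0.05, seed = 3)
  score_of <- function(tr) {
    vapply(seq_len(nrow(tr)), function(i)
      distmult_score(emb$entities[tr$head[i], ], emb$relations[tr$relation[i], ],
                     emb$entities[tr$tail[i], ]), 0)
  }
  held_within <- score_of(all_within[hold, ])
  cross <- tibble::tibble(head = sample(a, 30, TRUE), relation = "same",
                          tail = sample(b, 30, TRUE))
  expect_gt(mean(held_within), mean(score_of(cross)))

  # ranking quality clears the random baseline by a wide margin
  rk <- rank_triples(emb, all_within[hold, ], kg)
  n_ent <- nrow(emb$entities)
  expect_gt(rk$hits[["hits@3"]], 5 * 3 / n_ent)
})

test_that("ranking metrics follow the tie and filter conventions", {
  E <- rbind(a = c(2, 0), b = c(1, 0), c = c(0.5, 0), d = c(0.1, 0))
  R <- rbind(r = c(1, 1))
  emb <- structure(list(entities = E, relations = R, dim = 2),
                   class = "kge_embeddings")
  kg <- kg_new(tibble::tibble(head = "a", relation = "r", tail = "b"))
  # head a fixed: candidate tails score prop. to first coordinate;
  # test triple (a,r,b) ranks 2nd among {a,b,c,d}
  tests <- tibble::tibble(head = "a", relation = "r", tail = "b")
  rk <- rank_triples(emb, tests, kg_new(tibble::tibble(
    head = character(), relation = character(), tail = character())[0, ]))
  expect_equal(rk$mrr, 0.5)

  # all-equal scores: mean tie rank (m + 1) / 2
  E2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1), d = c(1, 1))
  emb2 <- structure(list(entities = E2, relations = R, dim = 2),
                    class = "kge_embeddings")
  rk2 <- rank_triples(emb2, tests, kg)
  expect_equal(rk2$ranks, (4 + 1) / 2)

  # strictly top-ranked everywhere gives MRR 1
  rk3 <- rank_triples(emb, tibble::tibble(head = "b", relation = "r",
                                          tail = "a"), kg)
  expect_equal(rk3$mrr, 1.0)

  expect_error(rank_triples(emb, tibble::tibble(head = "zz", relation = "r",
                                                tail = "a"), kg), "zz")
})

test_that("embedding tables round-trip through TSV exactly", {
  kg <- random_er_kg(6, 0.5, 4)
  emb <- train_kge(kg, dim = 5, epochs = 2, eta = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embeddings(emb, path)
  back <- read_embeddings(path)
  expect_identical(back$entities, emb$entities)
  expect_identical(back$relations, emb$relations)
  expect_equal(back$dim, emb$dim)
})
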