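test_that("generated benchmarks match their configuration exactly", {
  cfg <- synth_config(drugs = 30, proteins = 20, diseases = 8, pathways = 6,
                      hubs = 1, n_positives = 80, edges_per_protein = 4,
                      fingerprint_bits = 32, seed = 21)
  b <- synth_generate(cfg)
  tmap <- kg_type_map(b$kg)
  expect_equal(sum(tmap == "drug"), 30)
  expect_equal(sum(tmap == "protein"), 20)
  expect_equal(sum(tmap == "disease"), 8)
  expect_equal(sum(tmap == "pathway"), 6)
  expect_equal(sum(tmap == "hub"), 1)
  expect_equal(nrow(b$positives), 80)
  expect_equal(nrow(b$proteins), 20)
  expect_equal(feature_width(b$drug_features), 32)
  # every DTI entity is in the KG
  expect_true(all(c(b$positives$drug, b$positives$protein) %in%
                    kg_entities(b$kg)))
  # hub edges: one per protein per hub
  hub_edges <- b$kg$triples[b$kg$triples$relation == "has_identifier", ]
  expect_equal(nrow(hub_edges), 20)
  # edge budget: DTI + protein annotations + drug share + hub
  n_prot_edges <- 20 * 4
  n_drug_edges <- round(n_prot_edges * 0.17 / 0.83)
  expect_equal(kg_n_triples(b$kg), 80 + n_prot_edges + n_drug_edges + 20)

  expect_error(synth_config(drugs = 3, proteins = 3, n_positives = 10),
               "more positives")
})

test_that("generation is a pure function of the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synth_write(synth_generate(synth_config(drugs = 15, proteins = 12,
                                          n_positives = 30, seed = 5)), d1)
  synth_write(synth_generate(synth_config(drugs = 15, proteins = 12,
                                          n_positives = 30, seed = 5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  b3 <- synth_generate(synth_config(drugs = 15, proteins = 12,
                                    n_positives = 30, seed = 6))
  b1 <- synth_generate(synth_config(drugs = 15, proteins = 12,
                                    n_positives = 30, seed = 5))
  expect_false(identical(b1$positives, b3$positives))
})

test_that("written benchmarks are readable by the package's own loaders", {
  b <- tiny_bench(seed = 22)
  dir <- withr::local_tempdir()
  synth_write(b, dir)
  kg <- read_triples(file.path(dir, "triples.tsv"),
                     type_map = file.path(dir, "entity_types.tsv"),
                     dti_relation = "interacts")
  expect_equal(kg$triples, b$kg$triples)
  expect_equal(kg_type_map(kg), kg_type_map(b$kg))
  expect_equal(read_fasta(file.path(dir, "proteins.fasta")), b$proteins)
  expect_equal(read_feature_table(file.path(dir, "drug_features.tsv")),
               dplyr::mutate(b$drug_features,
                             dplyr::across(-id, as.numeric)))
})

test_that("the planted signal is recoverable: label correlates with the latents", {
  # point-biserial correlation between <u_d, u_p> and the positive label
  for (seed in 1:5) {
    b <- synth_generate(synth_config(drugs = 50, proteins = 40,
                                     n_positives = 200, seed = seed))
    keys <- paste(b$positives$drug, b$positives$protein)
    set.seed(seed)
    drugs <- sample(rownames(b$truth$u_drug), 2000, TRUE)
    prots <- sample(rownames(b$truth$u_protein), 2000, TRUE)
    inner <- rowSums(b$truth$u_drug[drugs, ] * b$truth$u_protein[prots, ])
    label <- as.integer(paste(drugs, prots) %in% keys)
    expect_gt(cor(inner, label), 0)
  }
})

test_that("stronger planted effects give better oracle discrimination", {
  med_oracle_auroc <- function(effect) {
    vals <- vapply(1:5, function(seed) {
      b <- synth_generate(synth_config(drugs = 40, proteins = 30,
                                       n_positives = 120,
                                       effect_size = effect, seed = seed))
      neg <- sample_negatives(b$positives, rownames(b$truth$u_drug),
                              rownames(b$truth$u_protein), ratio = 5,
                              seed = seed)
      pairs <- dplyr::bind_rows(b$positives |> dplyr::mutate(label = 1), neg)
      sc <- rowSums(b$truth$u_drug[pairs$drug, ] *
                      b$truth$u_protein[pairs$protein, ])
      auroc(pairs$label, sc)
    }, 0)
    stats::median(vals)
  }
  a0 <- med_oracle_auroc(0)
  a1 <- med_oracle_auroc(1)
  a2 <- med_oracle_auroc(2)
  expect_lt(a0, a1)
  expect_lt(a1, a2)
})

test_that("the audit verifies composition, hubs, and degree structure", {
  b <- synth_generate(synth_config(seed = 31))
  a <- synth_audit(b)
  expect_true(a$protein_fraction_ok)
  expect_true(abs(a$protein_fraction - 0.83) <= 0.02)
  expect_setequal(a$composition$relation,
                  c("protein_pathway", "protein_disease", "drug_disease"))
  expect_equal(sum(a$composition$fraction), 1)
  # the identifier hub dominates centrality
  expect_equal(a$top_centrality$type[1], "hub")

  nohub <- synth_generate(synth_config(drugs = 60, proteins = 50,
                                       n_positives = 250, hubs = 0,
                                       seed = 31))
  cb <- betweenness_centrality(nohub$kg)
  expect_lt(max(cb$betweenness_norm), 0.5)
})

test_that("uninformative annotations flatten the KGE advantage (ablation direction)", {
  # with annotation affinity 0 the supporting KG carries no latent signal,
  # so the KGE view cannot beat chance on cold proteins
  aupr_for <- function(affinity) {
    vals <- vapply(1:3, function(seed) {
      b <- synth_generate(synth_config(drugs = 80, proteins = 60,
                                       diseases = 20, pathways = 15,
                                       n_positives = 400,
                                       annotation_affinity = affinity,
                                       seed = seed))
      plan <- make_folds(b$positives, "cold_protein", k = 4, ratio = 5,
                         seed = seed)
      fold <- plan$folds[[1]]
      cfg <- dti_config(mode = "kge_only", kge_dim = 16, kge_epochs = 60,
                        pca_drug = 6, pca_protein = 6, nfm_k = 8,
                        nfm_hidden = 16, nfm_epochs = 20, seed = seed)
      fit <- dti_fit(fold$train, b$kg, cfg)
      aupr(fold$test$label, dti_predict(fit, fold$test)$probability)
    }, 0)
    mean(vals)
  }
  expect_gt(aupr_for(3), aupr_for(0))
})
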