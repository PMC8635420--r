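#' Pipeline configuration
#'
#' One place for every tunable of the end-to-end pipeline; a single top-level
#' seed drives all randomness (embedding initialization, corruption sampling,
#' fold splitting, NFM batches).
#'
#' @param mode `"kge_nfm"` (full fusion, the default), `"kge_only"`
#'   (heterogeneous view alone; the ablation without structural
#'   characterization), or `"structure_only"` (fingerprints + CTD alone).
#' @param kge_dim DistMult embedding dimension.
#' @param kge_epochs,kge_lr,kge_eta,kge_l2,kge_batch DistMult training
#'   hyperparameters (see [train_kge()]).
#' @param pca_drug,pca_protein Reduced widths for the drug and protein
#'   entity embeddings; independent hyperparameters because the two entity
#'   families need not share a geometry.
#' @param nfm_k,nfm_hidden,nfm_activation,nfm_dropout,nfm_epochs,nfm_lr,nfm_batch,nfm_l2
#'   NFM hyperparameters (see [train_nfm()]).
#' @param seed Integer run seed.
#' @return A named list of class `dti_config`.
#' @export
dti_config <- function(mode = c("kge_nfm", "kge_only", "structure_only"),
                       kge_dim = 32, kge_epochs = 100, kge_lr = 0.02,
                       kge_eta = 5, kge_l2 = 1e-4, kge_batch = 512,
                       pca_drug = 8, pca_protein = 8,
                       nfm_k = 16, nfm_hidden = 32, nfm_activation = "relu",
                       nfm_dropout = 0.2, nfm_epochs = 30, nfm_lr = 0.01,
                       nfm_batch = 256, nfm_l2 = 1e-6, seed = 1) {
  structure(list(mode = match.arg(mode), kge_dim = kge_dim,
                 kge_epochs = kge_epochs, kge_lr = kge_lr, kge_eta = kge_eta,
                 kge_l2 = kge_l2, kge_batch = kge_batch,
                 pca_drug = pca_drug, pca_protein = pca_protein,
                 nfm_k = nfm_k, nfm_hidden = nfm_hidden,
                 nfm_activation = nfm_activation, nfm_dropout = nfm_dropout,
                 nfm_epochs = nfm_epochs, nfm_lr = nfm_lr,
                 nfm_batch = nfm_batch, nfm_l2 = nfm_l2,
                 seed = as.integer(seed)),
            class = "dti_config")
}

#' Fit a PCA model
#'
#' Centered principal components by descending explained variance.  The
#' per-component sign ambiguity is fixed by forcing the largest-magnitude
#' loading of each component to be positive, so the fit is fully
#' deterministic.
#'
#' @param x Numeric matrix (rows = entities, columns = dimensions), >= 2
#'   rows.
#' @param k Number of components, `k <= min(nrow - 1, ncol)`.
#' @return An object of class `pca_model`: list with `mean` (column means),
#'   `components` (k x dim, orthonormal rows), `explained_variance_ratio`.
#' @export
pca_fit <- function(x, k) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("pca_fit(): need at least 2 rows", call. = FALSE)
  if (k > min(nrow(x) - 1, ncol(x))) {
    stop("pca_fit(): k = ", k, " exceeds min(rows - 1, dim) = ",
         min(nrow(x) - 1, ncol(x)), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  comp <- t(pc$rotation[, seq_len(k), drop = FALSE])     # k x dim
  dimnames(comp) <- NULL
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  total_var <- sum(pc$sdev^2)
  structure(list(mean = unname(pc$center),
                 components = comp,
                 explained_variance_ratio = pc$sdev[seq_len(k)]^2 / total_var),
            class = "pca_model")
}

#' Project vectors onto a fitted PCA model
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param x Numeric vector or matrix with the training width.
#' @return Matrix of reduced coordinates (rows match input rows).
#' @export
pca_transform <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, 1, dimnames = list(NULL, NULL))
  if (ncol(x) != length(model$mean)) {
    stop("pca_transform(): input width ", ncol(x),
         " != training width ", length(model$mean), call. = FALSE)
  }
  out <- sweep(x, 2, model$mean) %*% t(model$components)
  dimnames(out) <- NULL
  out
}

# min-max scaling statistics from training rows only (leakage-safe);
# constant columns map to 0
minmax_fit <- function(m) {
  list(lo = apply(m, 2, min), hi = apply(m, 2, max))
}

minmax_apply <- function(stats, m) {
  span <- pmax(stats$hi - stats$lo, .Machine$double.eps)
  sweep(sweep(m, 2, stats$lo), 2, span, `/`)
}

#' Assemble per-pair instance vectors
#'
#' Concatenates, in fixed field order, the PCA-reduced drug embedding, the
#' PCA-reduced protein embedding, the (scaled) drug structural block and the
#' (scaled) protein structural block, recording the block offsets as a field
#' spec.  Blocks absent under the fitted mode (`"kge_only"`,
#' `"structure_only"`) are skipped consistently at fit and predict time.
#'
#' @param pairs Tibble with columns `drug`, `protein`.
#' @param fit A `dti_pipeline` object (or the subset of its components used
#'   here).
#' @return List with `x` (matrix, one row per pair) and `field_spec` (named
#'   integer vector of block widths).
#' @export
assemble_features <- function(pairs, fit) {
  blocks <- list()
  if (fit$config$mode != "structure_only") {
    missing_e <- setdiff(unique(c(pairs$drug, pairs$protein)),
                         rownames(fit$embeddings$entities))
    if (length(missing_e) > 0) {
      stop("assemble_features(): entity '", missing_e[1],
           "' has no knowledge-graph embedding; DTI prediction is scoped to ",
           "entities present in the KG", call. = FALSE)
    }
    blocks$drug_kge <-
      pca_transform(fit$pca_drug, fit$embeddings$entities[pairs$drug, ,
                                                          drop = FALSE])
    blocks$protein_kge <-
      pca_transform(fit$pca_protein, fit$embeddings$entities[pairs$protein, ,
                                                             drop = FALSE])
  }
  if (fit$config$mode != "kge_only") {
    miss_d <- setdiff(unique(pairs$drug), fit$drug_features$id)
    if (length(miss_d) > 0) {
      stop("assemble_features(): no structural features for drug '",
           miss_d[1], "'", call. = FALSE)
    }
    miss_p <- setdiff(unique(pairs$protein), fit$protein_features$id)
    if (length(miss_p) > 0) {
      stop("assemble_features(): no structural features for protein '",
           miss_p[1], "'", call. = FALSE)
    }
    dmat <- as.matrix(fit$drug_features[, -1])
    rownames(dmat) <- fit$drug_features$id
    pmat <- as.matrix(fit$protein_features[, -1])
    rownames(pmat) <- fit$protein_features$id
    blocks$drug_struct <- minmax_apply(fit$scale_drug,
                                       dmat[pairs$drug, , drop = FALSE])
    blocks$protein_struct <- minmax_apply(fit$scale_protein,
                                          pmat[pairs$protein, , drop = FALSE])
  }
  x <- do.call(cbind, unname(blocks))
  rownames(x) <- NULL
  list(x = x,
       field_spec = purrr::map_int(blocks, ncol))
}

#' Fit the full DTI prediction pipeline
#'
#' Stages, in order:
#' 1. *Embedding*: DistMult is trained on the supporting KG plus the
#'    **positive training pairs only**, added as triples under the KG's DTI
#'    relation.  Test interactions and negative samples never enter embedding
#'    training (leakage-safe by construction; audit with
#'    [leakage_audit()]).
#' 2. *Reduction*: PCA is fitted separately on the drug-entity and
#'    protein-entity embedding rows (the two families have different
#'    geometries).
#' 3. *Fusion and classification*: per-pair instances are assembled
#'    (PCA(drug KGE) | PCA(protein KGE) | drug structure | protein
#'    structure, with structural blocks min-max scaled by training-fold
#'    statistics) and a neural factorization machine is trained on the
#'    labeled pairs.
#'
#' @param train_pairs Labeled tibble (`drug`, `protein`, `label` in \{0,1\});
#'   both classes required.
#' @param kg A `kg` object.  Its DTI triples (if any) are dropped and
#'   replaced by `train_pairs`' positives.
#' @param config A [dti_config()].
#' @param drug_features,protein_features Optional precomputed feature tables
#'   (`id` + numeric columns).  Required in modes that use structure unless
#'   `smiles`/`sequences` are given instead.
#' @param smiles Optional tibble (`id`, `smiles`) used to compute
#'   fingerprints when `drug_features` is absent.
#' @param sequences Optional tibble (`id`, `sequence`) used to compute CTD
#'   descriptors when `protein_features` is absent.
#' @return An object of class `dti_pipeline`.
#' @export
dti_fit <- function(train_pairs, kg, config = dti_config(),
                    drug_features = NULL, protein_features = NULL,
                    smiles = NULL, sequences = NULL) {
  train_pairs <- tibble::as_tibble(train_pairs)
  stopifnot(all(c("drug", "protein", "label") %in% names(train_pairs)))
  dti_rel <- if (!is.na(kg$dti_relation)) kg$dti_relation else "interacts"
  pos <- train_pairs[train_pairs$label == 1, ]
  missing_e <- setdiff(unique(c(pos$drug, pos$protein)), kg_entities(kg))
  if (length(missing_e) > 0) {
    stop("dti_fit(): positive training pair entity '", missing_e[1],
         "' is absent from the KG", call. = FALSE)
  }
  support <- kg_supporting(kg)
  train_kg <- kg_new(
    dplyr::bind_rows(support$triples,
                     tibble::tibble(head = pos$drug, relation = dti_rel,
                                    tail = pos$protein)),
    entity_types = kg$entity_types, dti_relation = dti_rel,
    entities = kg_entities(kg))
  fit <- list(config = config, dti_relation = dti_rel,
              kge_train_triples = train_kg$triples)
  if (config$mode != "structure_only") {
    emb <- train_kge(train_kg, dim = config$kge_dim,
                     epochs = config$kge_epochs, lr = config$kge_lr,
                     eta = config$kge_eta, l2 = config$kge_l2,
                     batch_size = config$kge_batch, seed = config$seed)
    tmap <- kg_type_map(train_kg)
    drug_rows <- rownames(emb$entities)[tmap[rownames(emb$entities)] == "drug"]
    prot_rows <- rownames(emb$entities)[tmap[rownames(emb$entities)] == "protein"]
    fit$embeddings <- emb
    fit$pca_drug <- pca_fit(emb$entities[drug_rows, , drop = FALSE],
                            min(config$pca_drug, length(drug_rows) - 1))
    fit$pca_protein <- pca_fit(emb$entities[prot_rows, , drop = FALSE],
                               min(config$pca_protein, length(prot_rows) - 1))
  }
  if (config$mode != "kge_only") {
    if (is.null(drug_features)) {
      if (is.null(smiles)) {
        stop("dti_fit(): mode '", config$mode, "' needs drug_features or ",
             "smiles; silently zero-filling would corrupt training",
             call. = FALSE)
      }
      drug_features <- fingerprint_table(smiles)
    }
    if (is.null(protein_features)) {
      if (is.null(sequences)) {
        stop("dti_fit(): mode '", config$mode, "' needs protein_features or ",
             "sequences", call. = FALSE)
      }
      protein_features <- ctd_table(sequences)
    }
    fit$drug_features <- drug_features
    fit$protein_features <- protein_features
    train_d <- unique(train_pairs$drug)
    train_p <- unique(train_pairs$protein)
    dmat <- as.matrix(drug_features[drug_features$id %in% train_d, -1])
    pmat <- as.matrix(protein_features[protein_features$id %in% train_p, -1])
    fit$scale_drug <- minmax_fit(dmat)
    fit$scale_protein <- minmax_fit(pmat)
  }
  asm <- assemble_features(train_pairs, fit)
  nfm <- train_nfm(asm$x, train_pairs$label, k = config$nfm_k,
                   hidden = config$nfm_hidden,
                   activation = config$nfm_activation,
                   dropout = config$nfm_dropout, epochs = config$nfm_epochs,
                   lr = config$nfm_lr, batch_size = config$nfm_batch,
                   l2 = config$nfm_l2, seed = config$seed,
                   field_spec = asm$field_spec)
  fit$nfm <- nfm
  fit$field_spec <- asm$field_spec
  structure(fit, class = "dti_pipeline")
}

#' @export
print.dti_pipeline <- function(x, ...) {
  cat("<dti_pipeline> mode:", x$config$mode, "| fields:",
      paste(names(x$field_spec), x$field_spec, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Predict interaction probabilities for drug-protein pairs
#'
#' @param fit A `dti_pipeline` from [dti_fit()].
#' @param pairs Tibble with columns `drug`, `protein`; all entities must be
#'   known to the fitted pipeline (entities outside the KG are out of scope
#'   by design).
#' @return The input tibble with `score` and `probability` columns appended,
#'   in input order.
#' @export
dti_predict <- function(fit, pairs) {
  pairs <- tibble::as_tibble(pairs)
  asm <- assemble_features(pairs[, c("drug", "protein")], fit)
  out <- nfm_forward(asm$x, fit$nfm)
  pairs$score <- out$score
  pairs$probability <- out$probability
  pairs
}

#' Audit embedding training for test-set leakage
#'
#' Returns the intersection of the triples the pipeline's embedding stage was
#' trained on with the DTI triples of a test set; a correct fit always yields
#' zero rows.
#'
#' @param fit A `dti_pipeline`.
#' @param test_pairs Tibble with columns `drug`, `protein` (test-side pairs).
#' @return Tibble of offending triples (expected empty).
#' @export
leakage_audit <- function(fit, test_pairs) {
  test_triples <- tibble::tibble(head = test_pairs$drug,
                                 relation = fit$dti_relation,
                                 tail = test_pairs$protein)
  dplyr::inner_join(fit$kge_train_triples, test_triples,
                    by = c("head", "relation", "tail"))
}

#' Tidy the field layout of a fitted pipeline
#' @param x A `dti_pipeline` object.
#' @param ... Unused.
#' @return Tibble with one row per feature block: name, width, offset.
#' @export
tidy.dti_pipeline <- function(x, ...) {
  tibble::tibble(block = names(x$field_spec),
                 width = as.integer(x$field_spec),
                 offset = as.integer(c(0, unname(cumsum(utils::head(x$field_spec, -1))))))
}

#' One-row summary of a fitted pipeline
#' @param x A `dti_pipeline` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.dti_pipeline <- function(x, ...) {
  tibble::tibble(
    mode = x$config$mode,
    n_features = sum(x$field_spec),
    kge_dim = if (!is.null(x$embeddings)) x$embeddings$dim else NA_integer_,
    nfm_k = x$nfm$k,
    final_nfm_loss = utils::tail(attr(x$nfm, "loss") %||% NA_real_, 1),
    seed = x$config$seed)
}
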