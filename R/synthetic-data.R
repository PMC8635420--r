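#' Configuration for the synthetic DTI benchmark generator
#'
#' The generator plants a low-rank drug x protein interaction signal inside a
#' heterogeneous knowledge graph whose composition mirrors real DTI
#' benchmarks: typed entities (drugs, proteins, diseases, pathways, optional
#' identifier hubs), several relation types, and a strong protein-related
#' skew of the supporting information (real KGs of this kind carry roughly
#' 83% protein-related vs 17% drug-related edges, which is the default
#' composition knob here).
#'
#' @param drugs,proteins,diseases,pathways Entity counts (>= 1 each).
#' @param hubs Number of identifier hub nodes (>= 0); each hub connects to
#'   every protein, emulating the noisy identifier/annotation nodes that
#'   betweenness analysis flags for pruning.
#' @param latent_dim Dimension of the planted latent factors.
#' @param n_positives Number of positive DTI pairs to plant.
#' @param effect_size Coefficient on the latent inner product in the
#'   interaction logit (0 = no signal).
#' @param noise Standard deviation of the Gaussian noise added to the
#'   interaction logit.
#' @param edges_per_protein Annotation edges drawn per protein (split
#'   between pathway and disease partners).
#' @param protein_fraction Target fraction of supporting (non-DTI, non-hub)
#'   edges that are protein-related; the drug-side edge budget is derived
#'   from it.
#' @param annotation_affinity Strength of the preference for annotations
#'   whose latent vector aligns with the entity's (0 = uniform annotations,
#'   which makes the KG uninformative about the planted signal).
#' @param fingerprint_bits Width of the synthetic drug fingerprint block.
#' @param seq_len Length-2 integer range for generated protein sequences.
#' @param seed Integer seed; the whole benchmark is a deterministic function
#'   of this configuration.
#' @return A named list of class `synth_config`.
#' @export
synth_config <- function(drugs = 200, proteins = 150, diseases = 40,
                         pathways = 30, hubs = 1, latent_dim = 8,
                         n_positives = 1000, effect_size = 2.0, noise = 1.0,
                         edges_per_protein = 10, protein_fraction = 0.83,
                         annotation_affinity = 3, fingerprint_bits = 64,
                         seq_len = c(80, 200), seed = 1) {
  stopifnot(drugs >= 1, proteins >= 1, diseases >= 1, pathways >= 1,
            hubs >= 0, latent_dim >= 1, n_positives >= 1, effect_size >= 0,
            noise >= 0, protein_fraction > 0, protein_fraction < 1,
            fingerprint_bits >= 8, length(seq_len) == 2,
            seq_len[1] >= 2, seq_len[2] >= seq_len[1])
  if (n_positives > drugs * proteins) {
    stop("synth_config(): more positives requested (", n_positives,
         ") than drug x protein pairs (", drugs * proteins, ")",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic DTI benchmark
#'
#' Draws latent factors \eqn{u_d, u_p} per drug/protein (i.i.d. normal,
#' scaled so the inner product has unit variance) and plants positives by
#' weighted sampling without replacement with weight
#' \eqn{P(\text{interaction}) = \mathrm{logistic}(\text{effect} \cdot
#' \langle u_d, u_p \rangle + \text{noise} \cdot \varepsilon)}.
#' Supporting edges (protein-pathway, protein-disease, drug-disease) are
#' drawn so entities preferentially share annotations with aligned latent
#' vectors, making the KG informative about the planted signal; identifier
#' hubs connect to every protein to exercise centrality pruning.  Protein
#' sequences are generated with hydrophobicity-class frequencies tied to the
#' first latent coordinate (so CTD descriptors carry recoverable signal),
#' and drug fingerprints are deterministic random bits whose activation
#' probabilities are linked to the drug's latent vector.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `synth_benchmark`: list with `kg` (a [kg_new()]
#'   object, DTI relation `"interacts"`), `positives` (tibble `drug`,
#'   `protein`), `proteins` (tibble `id`, `sequence`), `drug_features`
#'   (synthetic fingerprint feature table), and `truth` (latent factor
#'   matrices `u_drug`, `u_protein` sufficient to recompute the planted
#'   interaction weights).
#' @export
synth_generate <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  did <- sprintf("d%03d", seq_len(cfg$drugs))
  pid <- sprintf("p%03d", seq_len(cfg$proteins))
  sid <- sprintf("dis%02d", seq_len(cfg$diseases))
  wid <- sprintf("pw%02d", seq_len(cfg$pathways))
  hid <- if (cfg$hubs > 0) sprintf("hub%d", seq_len(cfg$hubs)) else character()
  r <- cfg$latent_dim
  sdev <- r^(-1 / 4)
  res <- NULL
  local_seed(cfg$seed, {
    U_d <- matrix(stats::rnorm(cfg$drugs * r, sd = sdev), cfg$drugs, r,
                  dimnames = list(did, NULL))
    U_p <- matrix(stats::rnorm(cfg$proteins * r, sd = sdev), cfg$proteins, r,
                  dimnames = list(pid, NULL))
    U_s <- matrix(stats::rnorm(cfg$diseases * r, sd = sdev), cfg$diseases, r,
                  dimnames = list(sid, NULL))
    U_w <- matrix(stats::rnorm(cfg$pathways * r, sd = sdev), cfg$pathways, r,
                  dimnames = list(wid, NULL))

    # planted positives: P(interaction) = logistic(effect * <u_d, u_p> +
    # noise + bias), with the bias calibrated so the expected number of
    # interactions matches the requested count (interactions are sparse, so
    # the logistic model needs a negative intercept); exactly n_positives
    # pairs are then drawn without replacement with these probabilities
    inner <- U_d %*% t(U_p)                           # drugs x proteins
    logit <- cfg$effect_size * inner +
      matrix(stats::rnorm(length(inner), sd = cfg$noise), nrow(inner))
    target <- cfg$n_positives / length(inner)
    bias <- stats::uniroot(
      function(c) mean(logistic(as.vector(logit) + c)) - target,
      c(-50, 50), tol = 1e-10)$root
    w <- logistic(as.vector(logit) + bias)
    pick <- sample.int(length(w), cfg$n_positives, prob = w)
    positives <- tibble::tibble(
      drug = did[(pick - 1) %% cfg$drugs + 1],
      protein = pid[(pick - 1) %/% cfg$drugs + 1])

    # affinity-weighted annotation edges: per protein, a fixed number of
    # partners among pathways and diseases
    pick_partners <- function(u, partners_U, n_edges) {
      wts <- exp(cfg$annotation_affinity * drop(partners_U %*% u))
      rownames(partners_U)[sample.int(nrow(partners_U),
                                      min(n_edges, nrow(partners_U)),
                                      prob = wts)]
    }
    n_pw <- ceiling(cfg$edges_per_protein / 2)
    n_ds <- cfg$edges_per_protein - n_pw
    prot_edges <- purrr::map_dfr(seq_len(cfg$proteins), function(i) {
      dplyr::bind_rows(
        tibble::tibble(head = pid[i], relation = "protein_pathway",
                       tail = pick_partners(U_p[i, ], U_w, n_pw)),
        tibble::tibble(head = pid[i], relation = "protein_disease",
                       tail = pick_partners(U_p[i, ], U_s, n_ds)))
    })
    # drug-side budget from the composition knob
    n_drug_edges <- round(nrow(prot_edges) *
                            (1 - cfg$protein_fraction) / cfg$protein_fraction)
    per_drug <- diff(round(seq(0, n_drug_edges, length.out = cfg$drugs + 1)))
    drug_edges <- purrr::map_dfr(which(per_drug > 0), function(i) {
      tibble::tibble(head = did[i], relation = "drug_disease",
                     tail = pick_partners(U_d[i, ], U_s, per_drug[i]))
    })
    hub_edges <- purrr::map_dfr(hid, function(h) {
      tibble::tibble(head = pid, relation = "has_identifier", tail = h)
    })

    triples <- dplyr::bind_rows(
      tibble::tibble(head = positives$drug, relation = "interacts",
                     tail = positives$protein),
      prot_edges, drug_edges, hub_edges)
    types <- tibble::tibble(
      entity = c(did, pid, sid, wid, hid),
      type = c(rep("drug", cfg$drugs), rep("protein", cfg$proteins),
               rep("disease", cfg$diseases), rep("pathway", cfg$pathways),
               rep("hub", length(hid))))
    kg <- kg_new(triples, entity_types = types, dti_relation = "interacts",
                 entities = types$entity)

    # protein sequences: hydrophobicity-class frequency follows u_p[, 1]
    classes <- ctd_groups()$hydrophobicity
    seqs <- purrr::map_chr(seq_len(cfg$proteins), function(i) {
      len <- sample(seq(cfg$seq_len[1], cfg$seq_len[2]), 1)
      cw <- exp(c(1, 0, -1) * U_p[i, 1] / sdev)
      cls <- sample.int(3, len, replace = TRUE, prob = cw / sum(cw))
      paste(purrr::map_chr(cls, function(g) {
        residues <- strsplit(classes[g], "")[[1]]
        residues[sample.int(length(residues), 1)]
      }), collapse = "")
    })
    proteins <- tibble::tibble(id = pid, sequence = seqs)

    # synthetic fingerprints: bit activation linked to the drug latents
    proj <- matrix(stats::rnorm(r * cfg$fingerprint_bits), r)
    p_bit <- logistic(U_d %*% proj - 1)
    bits <- matrix(stats::rbinom(length(p_bit), 1, as.vector(p_bit)),
                   nrow(p_bit))
    colnames(bits) <- paste0("fp", seq_len(cfg$fingerprint_bits))
    drug_features <- dplyr::bind_cols(tibble::tibble(id = did),
                                      tibble::as_tibble(bits))

    res <- list(kg = kg, positives = positives, proteins = proteins,
                drug_features = drug_features,
                truth = list(u_drug = U_d, u_protein = U_p,
                             u_disease = U_s, u_pathway = U_w),
                config = cfg)
  })
  structure(res, class = "synth_benchmark")
}

#' @export
print.synth_benchmark <- function(x, ...) {
  cat("<synth_benchmark>", x$config$drugs, "drugs x", x$config$proteins,
      "proteins |", nrow(x$positives), "positive DTIs |",
      kg_n_triples(x$kg), "triples\n")
  invisible(x)
}

#' Audit a synthetic benchmark
#'
#' Reports the edge-type composition of the supporting KG (DTI and
#' identifier-hub edges excluded, since they are task data and injected
#' noise respectively), the fraction of supporting edges that are
#' protein-related, a degree summary, and the top of the betweenness
#' centrality ranking.
#'
#' @param bench A `synth_benchmark`.
#' @param tolerance Allowed absolute deviation of the protein-related
#'   fraction from the configured value (default 0.02).
#' @return List with `composition` (tibble relation/count/fraction),
#'   `protein_fraction`, `protein_fraction_ok`, `degree_summary`, and
#'   `top_centrality` (tibble).
#' @export
synth_audit <- function(bench, tolerance = 0.02) {
  kg <- bench$kg
  tmap <- kg_type_map(kg)
  support <- kg$triples[kg$triples$relation != kg$dti_relation, ]
  non_hub <- support[tmap[support$head] != "hub" & tmap[support$tail] != "hub", ]
  comp <- non_hub |>
    dplyr::count(.data$relation, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count))
  prot_rel <- tmap[non_hub$head] == "protein" | tmap[non_hub$tail] == "protein"
  frac <- mean(prot_rel)
  cb <- betweenness_centrality(kg)
  deg <- cb$degree
  list(composition = comp,
       protein_fraction = frac,
       protein_fraction_ok = abs(frac - bench$config$protein_fraction) <= tolerance,
       degree_summary = tibble::tibble(
         mean = mean(deg), median = stats::median(deg), max = max(deg)),
       top_centrality = utils::head(cb, 10))
}

#' Write a synthetic benchmark to disk in the standard formats
#'
#' Emits exactly the formats the rest of the package consumes: triple TSV
#' plus entity-type TSV, protein FASTA, drug feature-table TSV, positive
#' pair TSV, and a ground-truth JSON with the latent factors.
#'
#' @param bench A `synth_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
synth_write <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_triples(bench$kg, file.path(dir, "triples.tsv"),
                type_map = file.path(dir, "entity_types.tsv"))
  write_fasta(bench$proteins, file.path(dir, "proteins.fasta"))
  write_feature_table(bench$drug_features, file.path(dir, "drug_features.tsv"))
  readr::write_tsv(bench$positives, file.path(dir, "positives.tsv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(u_drug = bench$truth$u_drug, u_protein = bench$truth$u_protein,
         config = unclass(bench$config)[setdiff(names(bench$config), "")]),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
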