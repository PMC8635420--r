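#' Construct a knowledge graph from a triple table
#'
#' A knowledge graph (KG) is a deduplicated set of `(head, relation, tail)`
#' triples over typed biomedical entities, plus the name of the relation that
#' carries the drug-target interaction (DTI) edges.  Triples are stored as a
#' tibble; the graph is directed as written but treated as undirected wherever
#' topology matters (neighborhoods, centrality).
#'
#' @param triples A data frame with character columns `head`, `relation`,
#'   `tail`.  Duplicate rows are dropped (the KG is a set of facts).
#' @param entity_types Optional data frame with columns `entity`, `type`
#'   giving a type label (`"drug"`, `"protein"`, `"disease"`, `"pathway"`,
#'   `"hub"`, or `"other"`) per entity.  Entities not listed default to
#'   `"other"`.
#' @param dti_relation Relation id designating drug-target edges, or `NA` if
#'   the KG carries none.  Named explicitly because datasets name it
#'   differently; it is never inferred.
#' @param entities Optional character vector naming the full entity universe;
#'   entities listed here stay part of the KG even when no triple touches
#'   them (an entity can lose all its task edges to a test fold yet remain a
#'   legitimate, if uninformed, member of the graph).
#'
#' @return An object of class `kg`: a list with elements `triples` (tibble,
#'   in canonical head/relation/tail order), `entity_types` (tibble `entity`,
#'   `type` covering every entity), and `dti_relation`.
#' @export
#' @examples
#' kg <- kg_new(data.frame(head = "d1", relation = "binds", tail = "p1"),
#'              dti_relation = "binds")
#' kg_n_triples(kg)
kg_new <- function(triples, entity_types = NULL, dti_relation = NA_character_,
                   entities = NULL) {
  triples <- tibble::as_tibble(triples)
  if (nrow(triples) == 0 && !all(c("head", "relation", "tail") %in% names(triples))) {
    triples <- tibble::tibble(head = character(), relation = character(),
                              tail = character())
  }
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  triples <- dplyr::distinct(triples[, c("head", "relation", "tail")])
  bad <- triples$head == "" | triples$tail == "" | triples$relation == ""
  if (any(bad)) {
    stop("kg_new(): empty entity or relation id in triple row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  forbidden <- grepl("[\t\n]", paste(triples$head, triples$relation, triples$tail))
  if (any(forbidden)) {
    stop("kg_new(): tab or newline inside an id", call. = FALSE)
  }
  triples <- dplyr::arrange(triples, .data$head, .data$relation, .data$tail)
  ents <- sort(unique(c(triples$head, triples$tail, entities)))
  types <- tibble::tibble(entity = ents, type = "other")
  if (!is.null(entity_types) && nrow(tibble::as_tibble(entity_types)) > 0) {
    entity_types <- tibble::as_tibble(entity_types)
    stopifnot(all(c("entity", "type") %in% names(entity_types)))
    entity_types <- dplyr::distinct(entity_types, .data$entity, .keep_all = TRUE)
    types <- types |>
      dplyr::rows_update(
        dplyr::semi_join(entity_types[, c("entity", "type")], types, by = "entity"),
        by = "entity")
  }
  if (!is.na(dti_relation)) {
    dti <- triples[triples$relation == dti_relation, ]
    if (nrow(dti) > 0) {
      # entities left untyped acquire their type from their DTI role
      tmap <- stats::setNames(types$type, types$entity)
      tmap[intersect(unique(dti$head), names(tmap)[tmap == "other"])] <- "drug"
      tmap[intersect(unique(dti$tail), names(tmap)[tmap == "other"])] <- "protein"
      types$type <- unname(tmap[types$entity])
      ok <- tmap[dti$head] == "drug" & tmap[dti$tail] == "protein"
      if (!all(ok)) {
        stop("kg_new(): every '", dti_relation,
             "' triple must run drug -> protein; offending pair(s): ",
             paste(utils::head(paste(dti$head, dti$tail)[!ok], 3), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  structure(
    list(triples = triples, entity_types = types, dti_relation = dti_relation),
    class = "kg")
}

#' @export
print.kg <- function(x, ...) {
  cat("<kg> ", nrow(x$triples), " triples, ",
      nrow(x$entity_types), " entities, ",
      dplyr::n_distinct(x$triples$relation), " relations",
      if (!is.na(x$dti_relation)) paste0(" (DTI relation: '", x$dti_relation, "')"),
      "\n", sep = "")
  print(dplyr::count(x$entity_types, .data$type), n = Inf)
  invisible(x)
}

#' @rdname kg_new
#' @param kg A `kg` object.
#' @export
kg_n_triples <- function(kg) nrow(kg$triples)

#' @rdname kg_new
#' @export
kg_entities <- function(kg) kg$entity_types$entity

#' @rdname kg_new
#' @export
kg_relations <- function(kg) sort(unique(kg$triples$relation))

#' Named vector entity id -> type label
#' @param kg A `kg` object.
#' @return Named character vector.
#' @export
kg_type_map <- function(kg) {
  stats::setNames(kg$entity_types$type, kg$entity_types$entity)
}

#' Entity and relation index vocabularies
#'
#' Dense 1-based integer indices assigned by lexicographic sort of ids, so the
#' same KG always yields the same bijections without any seed.
#'
#' @param kg A `kg` object.
#' @return List with named integer vectors `entity_index` and `relation_index`.
#' @export
kg_vocab <- function(kg) {
  ents <- kg_entities(kg)
  rels <- sort(unique(kg$triples$relation))
  list(entity_index = stats::setNames(seq_along(ents), ents),
       relation_index = stats::setNames(seq_along(rels), rels))
}

#' Read a knowledge graph from a TSV triple file
#'
#' The dialect is UTF-8 TSV with columns `head`, `relation`, `tail` and
#' `#`-prefixed comment lines.  Duplicate triples are silently deduplicated;
#' line order never affects the resulting triple set.
#'
#' @param path Path to the triple TSV.
#' @param type_map Optional path to a 2-column TSV (`entity`\\t`type`), no
#'   header.  Entities absent from it get type `"other"`.
#' @param dti_relation Relation id designating DTI edges (see [kg_new()]).
#' @return A `kg` object.
#' @export
read_triples <- function(path, type_map = NULL, dti_relation = NA_character_) {
  if (!file.exists(path)) stop("read_triples(): no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    return(kg_new(tibble::tibble(head = character(), relation = character(),
                                 tail = character()),
                  dti_relation = dti_relation))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    stop("read_triples(): line ", line_no[bad], " has ", nf[bad],
         " tab-separated fields (expected 3)", call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  if (any(m[, c(1, 3)] == "")) {
    bad <- which(m[, 1] == "" | m[, 3] == "")[1]
    stop("read_triples(): empty entity id at line ", line_no[bad], call. = FALSE)
  }
  types <- NULL
  if (!is.null(type_map)) {
    types <- readr::read_tsv(type_map, col_names = c("entity", "type"),
                             col_types = "cc", comment = "#", progress = FALSE)
  }
  kg_new(tibble::tibble(head = m[, 1], relation = m[, 2], tail = m[, 3]),
         entity_types = types, dti_relation = dti_relation)
}

#' Write a knowledge graph to a TSV triple file
#'
#' Round-trips with [read_triples()]: reading the written file reproduces the
#' same triple set.
#'
#' @param kg A `kg` object.
#' @param path Output path.
#' @param type_map Optional path for the companion entity-type TSV.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path, type_map = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# head\trelation\ttail", con)
  if (nrow(kg$triples) > 0) {
    writeLines(paste(kg$triples$head, kg$triples$relation, kg$triples$tail,
                     sep = "\t"), con)
  }
  if (!is.null(type_map)) {
    readr::write_tsv(kg$entity_types, type_map, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Extract the first- or second-order neighborhood of seed entities
#'
#' Order 1 keeps every triple incident to a seed; order 2 additionally keeps
#' every triple incident to an entity touched by the order-1 set.  Incidence
#' is undirected.  The result is a sub-KG with inherited types.
#'
#' @param kg A `kg` object.
#' @param seeds Character vector of entity ids, all present in `kg`.
#' @param order 1 or 2.
#' @return A `kg` object (triple subset).
#' @export
extract_neighborhood <- function(kg, seeds, order = 1) {
  stopifnot(order %in% c(1, 2))
  unknown <- setdiff(seeds, kg_entities(kg))
  if (length(unknown) > 0) {
    stop("extract_neighborhood(): unknown seed entity '", unknown[1], "'",
         call. = FALSE)
  }
  incident <- function(tr, ents) tr$head %in% ents | tr$tail %in% ents
  sel <- incident(kg$triples, seeds)
  if (order == 2) {
    touched <- unique(c(kg$triples$head[sel], kg$triples$tail[sel], seeds))
    sel <- sel | incident(kg$triples, touched)
  }
  sub <- kg$triples[sel, ]
  kg_new(sub, entity_types = kg$entity_types, dti_relation = kg$dti_relation)
}

#' Remove entities (or whole entity types) and every incident triple
#'
#' Used to prune noisy identifier hub nodes flagged by the centrality report.
#' Removing absent entities is a no-op, and removal commutes:
#' removing `V1` then `V2` equals removing their union.
#'
#' @param kg A `kg` object.
#' @param victims Character vector of entity ids and/or type labels; any
#'   entity whose id or type matches is removed together with its triples.
#' @return A `kg` object.
#' @export
remove_nodes <- function(kg, victims) {
  tmap <- kg_type_map(kg)
  doomed <- names(tmap)[names(tmap) %in% victims | tmap %in% victims]
  keep <- !(kg$triples$head %in% doomed | kg$triples$tail %in% doomed)
  kg_new(kg$triples[keep, ], entity_types = kg$entity_types,
         dti_relation = kg$dti_relation,
         entities = setdiff(kg_entities(kg), doomed))
}

#' DTI pairs stored in a knowledge graph
#'
#' @param kg A `kg` object with a non-`NA` `dti_relation`.
#' @return Tibble with columns `drug`, `protein`.
#' @export
kg_dti_pairs <- function(kg) {
  stopifnot(!is.na(kg$dti_relation))
  dti <- kg$triples[kg$triples$relation == kg$dti_relation, ]
  tibble::tibble(drug = dti$head, protein = dti$tail)
}

#' Supporting knowledge graph: everything except the DTI edges
#'
#' The supporting KG is always available at training time; the DTI edges are
#' the task data that cross-validation splits.
#'
#' @param kg A `kg` object.
#' @return A `kg` object without DTI triples.
#' @export
kg_supporting <- function(kg) {
  if (is.na(kg$dti_relation)) return(kg)
  kg_new(kg$triples[kg$triples$relation != kg$dti_relation, ],
         entity_types = kg$entity_types, dti_relation = kg$dti_relation,
         entities = kg_entities(kg))
}
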