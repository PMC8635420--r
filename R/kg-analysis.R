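#' Betweenness centrality of every entity in a knowledge graph
#'
#' Treats the KG as an undirected simple graph (parallel edges from multiple
#' relations collapsed, self-loops dropped) and computes, for each node n,
#'
#' \deqn{C_b(n) = \sum_{s \ne n \ne t} \sigma_{st}(n) / \sigma_{st}}
#'
#' over unordered pairs \{s, t\}, where \eqn{\sigma_{st}} is the number of
#' shortest s-t paths and \eqn{\sigma_{st}(n)} the number passing through n.
#' Disconnected pairs contribute 0; endpoints are excluded.  Normalized
#' betweenness divides by the maximum possible count (N-1)(N-2)/2, i.e.
#' multiplies the raw value by 2/((N-1)(N-2)); for N < 3 the normalized value
#' is defined as 0.  Normalization always uses the total node count N, also
#' on disconnected graphs (one convention, documented here).
#'
#' In biomedical KGs only a few nodes carry high betweenness; they are
#' typically identifier/annotation hubs that bridge otherwise unrelated parts
#' of the graph, and are candidates for [remove_nodes()].
#'
#' @param kg A `kg` object.
#' @return A tibble with one row per entity: `entity`, `type`, `degree`
#'   (number of distinct neighbors in the collapsed simple graph),
#'   `betweenness` (raw count), `betweenness_norm` (in `[0, 1]`), and `rank`
#'   (1-based, by descending betweenness, ties broken by entity id).
#' @export
#' @examples
#' star <- kg_new(data.frame(head = "hub", relation = "r",
#'                           tail = paste0("leaf", 1:4)))
#' betweenness_centrality(star)
betweenness_centrality <- function(kg) {
  ents <- kg_entities(kg)
  n <- length(ents)
  if (n == 0) {
    return(tibble::tibble(entity = character(), type = character(),
                          degree = integer(), betweenness = double(),
                          betweenness_norm = double(), rank = integer()))
  }
  g <- kg_igraph(kg)
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  deg <- igraph::degree(g, loops = FALSE)
  norm_factor <- if (n >= 3) 2 / ((n - 1) * (n - 2)) else 0
  out <- tibble::tibble(
    entity = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = as.double(raw),
    betweenness_norm = as.double(raw) * norm_factor)
  out <- dplyr::left_join(out, kg$entity_types, by = "entity")
  out <- dplyr::arrange(out, dplyr::desc(.data$betweenness), .data$entity)
  out$rank <- seq_len(nrow(out))
  out[, c("entity", "type", "degree", "betweenness", "betweenness_norm", "rank")]
}

# undirected simple igraph over all KG entities (isolated typed entities kept)
kg_igraph <- function(kg) {
  edges <- kg$triples[kg$triples$head != kg$triples$tail, c("head", "tail")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = kg_entities(kg))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Top-k entities by betweenness centrality
#'
#' Convenience report for spotting identifier hub nodes worth pruning with
#' [remove_nodes()].  If `top_k` exceeds the number of entities, all rows are
#' returned.
#'
#' @param kg A `kg` object.
#' @param top_k Number of rows to keep (>= 1).
#' @return The first `top_k` rows of [betweenness_centrality()].
#' @export
centrality_report <- function(kg, top_k = 20) {
  stopifnot(top_k >= 1)
  utils::head(betweenness_centrality(kg), top_k)
}

#' Write a centrality report as TSV
#'
#' @param report Tibble from [betweenness_centrality()] or
#'   [centrality_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centrality_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}

#' Degree versus betweenness scatter for a knowledge graph
#'
#' The classic diagnostic: identifier hubs sit in the upper-right corner.
#'
#' @param kg A `kg` object.
#' @param label_top Entities to label (by betweenness rank).
#' @return A ggplot object.
#' @export
plot_centrality <- function(kg, label_top = 3) {
  cb <- betweenness_centrality(kg)
  ggplot2::ggplot(cb, ggplot2::aes(x = .data$degree, y = .data$betweenness_norm,
                                   colour = .data$type)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_text(
      data = utils::head(cb, label_top),
      mapping = ggplot2::aes(label = .data$entity),
      vjust = -0.6, show.legend = FALSE, size = 3) +
    ggplot2::labs(x = "degree", y = "normalized betweenness centrality") +
    ggplot2::theme_minimal()
}
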