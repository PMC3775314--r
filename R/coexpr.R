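#' Correlation profile of a seed gene against all other genes
#'
#' Pearson correlation of the seed gene's expression with every other gene
#' in the matrix. Genes with zero variance are dropped with a warning
#' (flat probes are common on arrays). Missing values are handled with the
#' pairwise-complete rule.
#'
#' @param expression genes x subjects matrix.
#' @param seed_gene seed gene identifier (must be a row).
#' @param region optional region label stored on the result.
#' @return tibble of class `correlation_profile`: columns `gene`, `r`;
#'   attributes `seed_gene`, `region`, `n_subjects`.
#' @examples
#' cohort <- simulate_coexpression_cohort(sim_config(seed = 1))
#' prof <- seed_correlations(cohort$BA11, "SST", region = "BA11")
#' @export
seed_correlations <- function(expression, seed_gene, region = NA_character_) {
  if (!seed_gene %in% rownames(expression)) {
    stop("seed gene '", seed_gene, "' not found in expression matrix",
         call. = FALSE)
  }
  if (ncol(expression) < 3) {
    stop("seed_correlations: needs >= 3 subjects", call. = FALSE)
  }
  others <- setdiff(rownames(expression), seed_gene)
  v <- apply(expression[others, , drop = FALSE], 1, stats::var, na.rm = TRUE)
  flat <- names(v)[!is.na(v) & v == 0]
  if (length(flat) > 0) {
    warning("dropping ", length(flat), " zero-variance gene(s): ",
            paste(utils::head(flat, 5), collapse = ", "),
            if (length(flat) > 5) ", ..." else "", call. = FALSE)
    others <- setdiff(others, flat)
  }
  r <- drop(stats::cor(expression[seed_gene, ],
                       t(expression[others, , drop = FALSE]),
                       use = "pairwise.complete.obs"))
  out <- tibble::tibble(gene = others, r = unname(r))
  attr(out, "seed_gene") <- seed_gene
  attr(out, "region") <- region
  attr(out, "n_subjects") <- ncol(expression)
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Average two regions' correlation profiles behind a similarity gate
#'
#' Region-specific seed-gene correlation profiles may only be averaged if
#' they agree: the Pearson correlation between the two r-vectors (over the
#' shared gene universe) must reach `min_similarity`, otherwise an error
#' carrying the observed similarity is raised. Genes present in only one
#' profile are dropped with a message.
#'
#' @param profile_a,profile_b outputs of [seed_correlations()] for the same
#'   seed gene.
#' @param min_similarity gate on cross-region profile correlation
#'   (default 0.95).
#' @return a `correlation_profile` tibble of element-wise mean correlations,
#'   with attribute `similarity`.
#' @export
average_profiles <- function(profile_a, profile_b, min_similarity = 0.95) {
  sa <- attr(profile_a, "seed_gene"); sb <- attr(profile_b, "seed_gene")
  if (!identical(sa, sb)) {
    stop("profiles have different seed genes: ", sa, " vs ", sb,
         call. = FALSE)
  }
  common <- intersect(profile_a$gene, profile_b$gene)
  dropped <- length(union(profile_a$gene, profile_b$gene)) - length(common)
  if (dropped > 0) {
    message("average_profiles: dropping ", dropped,
            " gene(s) absent from one profile")
  }
  ra <- profile_a$r[match(common, profile_a$gene)]
  rb <- profile_b$r[match(common, profile_b$gene)]
  similarity <- stats::cor(ra, rb)
  if (is.na(similarity) || similarity < min_similarity) {
    stop(sprintf(
      "cross-region profile similarity %.4f below gate %.3f; not averaging",
      similarity, min_similarity), call. = FALSE)
  }
  out <- tibble::tibble(gene = common, r = (ra + rb) / 2)
  attr(out, "seed_gene") <- sa
  attr(out, "region") <- paste(attr(profile_a, "region"),
                               attr(profile_b, "region"), sep = "+")
  attr(out, "n_subjects") <- attr(profile_a, "n_subjects")
  attr(out, "similarity") <- similarity
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Select the top positively correlated genes
#'
#' Keeps genes with correlation strictly above `r_min`, sorts by
#' decreasing correlation (ties broken by gene label for determinism) and
#' truncates to the top `k`. Defaults select the top 200 genes with
#' r > 0.725.
#'
#' @param profile a `correlation_profile` (or tibble with `gene`, `r`).
#' @param k maximum number of genes returned.
#' @param r_min strict lower correlation threshold.
#' @return tibble (`gene`, `r`) ordered by decreasing r; may have fewer
#'   than `k` rows.
#' @export
select_top <- function(profile, k = 200L, r_min = 0.725) {
  stopifnot(k >= 1, r_min >= -1, r_min <= 1)
  kept <- profile[profile$r > r_min, , drop = FALSE]
  ord <- order(-kept$r, kept$gene)
  out <- tibble::as_tibble(kept[ord, c("gene", "r")])
  utils::head(out, k)
}

#' Build a thresholded weighted co-expression network
#'
#' Computes all pairwise Pearson correlations within a gene panel and
#' keeps edges with correlation strictly greater than `threshold`,
#' retaining the correlation as edge weight. Panel genes missing from the
#' matrix are skipped with a warning.
#'
#' @param expression genes x subjects matrix.
#' @param gene_panel genes to include as nodes.
#' @param threshold minimum (strict) edge correlation, in (0, 1).
#' @return object of class `gene_network`: list with `nodes`, `edges`
#'   (tibble from, to, weight; from < to lexicographically), `threshold`.
#' @examples
#' cohort <- simulate_coexpression_cohort(sim_config(seed = 1))
#' net <- build_network(cohort$BA11, sim_config()$gaba_panel)
#' net$edges
#' @export
build_network <- function(expression, gene_panel, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  found <- intersect(gene_panel, rownames(expression))
  missing <- setdiff(gene_panel, found)
  if (length(missing) > 0) {
    warning("build_network: skipping absent gene(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(found) < 2) {
    stop("build_network: fewer than 2 panel genes found", call. = FALSE)
  }
  cm <- stats::cor(t(expression[found, , drop = FALSE]),
                   use = "pairwise.complete.obs")
  idx <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(cm)[idx[, 1]],
    to = colnames(cm)[idx[, 2]],
    weight = cm[idx]
  )
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(
    list(nodes = found, edges = edges, threshold = threshold,
         cor_matrix = cm),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (r > ", x$threshold, ", strict)\n", sep = "")
  invisible(x)
}

#' Extract the core module around a set of seed genes
#'
#' The core module is the set of seed genes plus their common neighbors:
#' nodes adjacent to at least `quota` of the seeds (default: a majority,
#' `ceiling(length(seeds) / 2)`). If the seeds fall in different connected
#' components the union is still returned, with attribute
#' `disconnected = TRUE` and a warning.
#'
#' @param network a `gene_network`.
#' @param seeds seed genes; must be nodes of the network.
#' @param quota minimum number of seeds a node must touch to join.
#' @return sorted character vector of module genes, with attribute
#'   `disconnected`.
#' @export
core_module <- function(network, seeds,
                        quota = ceiling(length(seeds) / 2)) {
  if (!all(seeds %in% network$nodes)) {
    stop("core_module: seed(s) not in network: ",
         paste(setdiff(seeds, network$nodes), collapse = ", "),
         call. = FALSE)
  }
  edges <- network$edges
  adj_count <- stats::setNames(integer(length(network$nodes)), network$nodes)
  for (s in seeds) {
    nb <- c(edges$to[edges$from == s], edges$from[edges$to == s])
    adj_count[nb] <- adj_count[nb] + 1L
  }
  members <- sort(union(seeds, names(adj_count)[adj_count >= quota]))

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  comp <- igraph::components(g)$membership
  disconnected <- length(unique(comp[seeds])) > 1
  if (disconnected) {
    warning("core_module: seeds lie in different components; returning union",
            call. = FALSE)
  }
  attr(members, "disconnected") <- disconnected
  members
}

#' Convert a gene network to an igraph object
#' @param network a `gene_network`.
#' @return an undirected weighted igraph graph.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Export a network as GraphML
#' @param network a `gene_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export a network as a Cytoscape-loadable weighted edge list (TSV)
#' @param network a `gene_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(
    data.frame(source = network$edges$from, target = network$edges$to,
               weight = network$edges$weight),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
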