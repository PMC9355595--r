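# Regulatory-network integration: map DE entities onto co-expression
# modules, collect degradome-validated miRNA -> transcription-factor pairs,
# attach co-expression neighborhoods, and export the assembled network in
# Cytoscape-loadable formats.

#' Map differential-expression results onto co-expression modules
#'
#' @param de_results DE table (from [de_screen()]); only `is_de` rows are
#'   mapped.
#' @param labels named module assignment (entity -> module).
#' @return data.frame `id`, `module` (NA for DE entities that were filtered
#'   out before network construction).
#' @export
map_to_modules <- function(de_results, labels) {
  de_ids <- unique(de_results$id[de_results$is_de])
  data.frame(id = de_ids,
             module = unname(labels[de_ids]),
             stringsAsFactors = FALSE)
}

#' Most correlated neighbors of a focus entity
#'
#' Ranks entities by absolute Pearson correlation with the focus profile and
#' returns the top `k` (ties broken lexicographically by id).
#'
#' @param focus_id focus entity (must be a row of `mat`).
#' @param mat expression matrix (entities x samples).
#' @param k number of neighbors.
#' @param restrict optional id set to rank within (e.g. the focus module).
#' @return data.frame `id`, `r`, ordered by decreasing `|r|`.
#' @export
cor_neighbors <- function(focus_id, mat, k, restrict = NULL) {
  if (k <= 0) return(data.frame(id = character(), r = numeric(),
                                stringsAsFactors = FALSE))
  if (!focus_id %in% rownames(mat)) {
    stop("focus entity not in matrix: ", focus_id, call. = FALSE)
  }
  pool <- setdiff(if (is.null(restrict)) rownames(mat)
                  else intersect(restrict, rownames(mat)), focus_id)
  if (length(pool) == 0) return(data.frame(id = character(), r = numeric(),
                                           stringsAsFactors = FALSE))
  r <- suppressWarnings(as.numeric(
    stats::cor(t(mat[pool, , drop = FALSE]), mat[focus_id, ])))
  names(r) <- pool
  r[is.na(r)] <- 0
  ord <- order(-abs(r), names(r))
  sel <- ord[seq_len(min(k, length(ord)))]
  data.frame(id = names(r)[sel], r = unname(r[sel]),
             stringsAsFactors = FALSE)
}

#' Degradome-validated miRNA -> transcription-factor targeting edges
#'
#' Keeps validated cleavage calls (`kept == TRUE`) whose target carries a
#' transcription-factor annotation and whose miRNA is differentially
#' expressed; one edge per (miRNA, target) pair.
#'
#' @param calls cleavage-call table from [validate_targets()].
#' @param tf_annotation data.frame `gene_id`, `family`.
#' @param demirs ids of differentially expressed miRNAs.
#' @return data.frame `mirna_id`, `target_id`, `family`, `score`.
#' @export
mirna_tf_pairs <- function(calls, tf_annotation, demirs) {
  sel <- calls$kept & calls$transcript_id %in% tf_annotation$gene_id &
    calls$mirna_id %in% demirs
  edges <- calls[sel, c("mirna_id", "transcript_id", "score"), drop = FALSE]
  names(edges)[2] <- "target_id"
  edges <- edges[!duplicated(edges[c("mirna_id", "target_id")]), ,
                 drop = FALSE]
  edges$family <- tf_annotation$family[match(edges$target_id,
                                             tf_annotation$gene_id)]
  rownames(edges) <- NULL
  edges[, c("mirna_id", "target_id", "family", "score")]
}

#' Stage-mean expression correlation of miRNA--target pairs
#'
#' Pearson correlation of the per-stage mean miRNA expression against the
#' per-stage mean target expression. Pairs with a constant profile are
#' reported with `NA`.
#'
#' @param mirna_em miRNA `expr_matrix` (e.g. TPM).
#' @param gene_em gene `expr_matrix` (e.g. FPKM).
#' @param pairs data.frame `mirna_id`, `target_id`.
#' @param stage_order stage ordering (default: order of appearance).
#' @return `pairs` with an added `r` column.
#' @export
expression_correlation <- function(mirna_em, gene_em, pairs,
                                   stage_order = NULL) {
  stopifnot(inherits(mirna_em, "expr_matrix"), inherits(gene_em, "expr_matrix"))
  if (is.null(stage_order)) stage_order <- unique(mirna_em$samples$stage)
  stage_means <- function(em, id) {
    v <- em$values[id, ]
    vapply(stage_order, function(s) {
      mean(v[em$samples$stage == s])
    }, numeric(1))
  }
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i) {
    mid <- pairs$mirna_id[i]; tid <- pairs$target_id[i]
    if (!mid %in% rownames(mirna_em$values) ||
        !tid %in% rownames(gene_em$values)) return(NA_real_)
    a <- stage_means(mirna_em, mid); b <- stage_means(gene_em, tid)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  pairs
}

#' Assemble the miRNA--TF regulatory network
#'
#' Nodes are the differentially expressed miRNAs with validated
#' transcription-factor targets inside the trait-associated modules, those
#' TFs, and the `k_neighbors` most correlated module genes of each TF; edges
#' are directed targeting edges (miRNA -> TF, weighted by duplex score) and
#' undirected co-expression edges (TF -- neighbor, weighted by `|r|`, stored
#' with canonical endpoint ordering).
#'
#' @param targeting_edges edge table from [mirna_tf_pairs()].
#' @param mat gene expression matrix used for neighbor ranking.
#' @param labels named module assignment.
#' @param trait_modules labels of the trait-associated modules.
#' @param k_neighbors neighbors per TF (default 10).
#' @param restrict_neighbors restrict neighbors to the TF's module
#'   (default TRUE).
#' @param de_genes optional ids of DE genes (marked on nodes).
#' @return object of class `regulatory_network`: `nodes` (id, role, module,
#'   de), `edges` (source, target, type, weight).
#' @export
assemble_network <- function(targeting_edges, mat, labels, trait_modules,
                             k_neighbors = 10L, restrict_neighbors = TRUE,
                             de_genes = character()) {
  if (length(trait_modules) == 0) {
    warning("no trait-associated modules; returning an empty network")
    targeting_edges <- targeting_edges[0, , drop = FALSE]
  } else {
    in_trait <- labels[targeting_edges$target_id] %in% trait_modules
    in_trait[is.na(in_trait)] <- FALSE
    targeting_edges <- targeting_edges[in_trait, , drop = FALSE]
  }
  nodes <- list(); edges <- list()
  add_node <- function(id, role) {
    nodes[[id]] <<- data.frame(
      id = id, role = role,
      module = if (id %in% names(labels)) unname(labels[id])
               else NA_character_,
      de = id %in% de_genes, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(targeting_edges))) {
    mid <- targeting_edges$mirna_id[i]
    tid <- targeting_edges$target_id[i]
    add_node(mid, "miRNA")
    add_node(tid, "TF")
    edges[[length(edges) + 1L]] <- data.frame(
      source = mid, target = tid, type = "targeting",
      weight = targeting_edges$score[i], stringsAsFactors = FALSE)
    if (k_neighbors > 0 && tid %in% rownames(mat)) {
      restrict <- if (restrict_neighbors)
        names(labels)[labels == labels[tid]] else NULL
      nb <- cor_neighbors(tid, mat, k_neighbors, restrict)
      for (j in seq_len(nrow(nb))) {
        if (is.null(nodes[[nb$id[j]]])) add_node(nb$id[j], "gene")
        ends <- sort(c(tid, nb$id[j]))
        edges[[length(edges) + 1L]] <- data.frame(
          source = ends[1], target = ends[2], type = "coexpression",
          weight = abs(nb$r[j]), stringsAsFactors = FALSE)
      }
    }
  }
  node_df <- if (length(nodes)) do.call(rbind, unname(nodes))
    else data.frame(id = character(), role = character(),
                    module = character(), de = logical(),
                    stringsAsFactors = FALSE)
  edge_df <- if (length(edges)) {
    e <- do.call(rbind, edges)
    e[!duplicated(e[c("source", "target", "type")]), , drop = FALSE]
  } else data.frame(source = character(), target = character(),
                    type = character(), weight = numeric(),
                    stringsAsFactors = FALSE)
  rownames(node_df) <- rownames(edge_df) <- NULL
  structure(list(nodes = node_df, edges = edge_df),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$role == "miRNA"), " miRNA, ",
      sum(x$nodes$role == "TF"), " TF, ",
      sum(x$nodes$role == "gene"), " gene), ",
      nrow(x$edges), " edges (",
      sum(x$edges$type == "targeting"), " targeting)\n", sep = "")
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes a SIF file (`source TAB type TAB target`), node and edge attribute
#' TSVs, and a GraphML file loadable in Cytoscape.
#'
#' @param net a `regulatory_network`.
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>_nodes.tsv`, `<prefix>_edges.tsv`, `<prefix>.graphml`.
#' @return the written paths, invisibly.
#' @export
write_network <- function(net, prefix) {
  sif <- file.path(paste0(prefix, ".sif"))
  utils::write.table(net$edges[, c("source", "type", "target")], sif,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  nodes_f <- paste0(prefix, "_nodes.tsv")
  edges_f <- paste0(prefix, "_edges.tsv")
  utils::write.table(net$nodes, nodes_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edges_f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gml <- paste0(prefix, ".graphml")
  if (nrow(net$nodes)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$nodes)
    igraph::write_graph(g, gml, format = "graphml")
  } else {
    igraph::write_graph(igraph::make_empty_graph(), gml, format = "graphml")
  }
  invisible(c(sif, nodes_f, edges_f, gml))
}
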