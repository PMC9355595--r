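# Weighted co-expression network construction: expression filtering,
# soft-thresholded adjacency, topological overlap, hierarchical module
# detection with a minimum module size and a grey pool, eigengenes,
# similarity-based module merging, module-trait association, and top-kME
# hub selection.

MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

#' Filter lowly expressed entities before network construction
#'
#' Keeps entities expressed at or above `min_value` in at least
#' `min_fraction` of samples and with a per-entity standard deviation above
#' `min_sd` (defaults: 2 across 70\% of samples, SD > 0.25).
#'
#' @param em an `expr_matrix` in FPKM or TPM units.
#' @param min_value expression floor (default 2).
#' @param min_fraction fraction of samples at/above the floor (default 0.7).
#' @param min_sd standard-deviation floor, exclusive (default 0.25).
#' @return filtered `expr_matrix`.
#' @export
filter_expressed <- function(em, min_value = 2, min_fraction = 0.7,
                             min_sd = 0.25) {
  stopifnot(inherits(em, "expr_matrix"))
  if (!em$units %in% c("FPKM", "TPM")) {
    stop("filter_expressed expects FPKM or TPM units", call. = FALSE)
  }
  frac <- rowMeans(em$values >= min_value)
  sds <- apply(em$values, 1, stats::sd)
  keep <- frac >= min_fraction & sds > min_sd
  out <- em
  out$values <- em$values[keep, , drop = FALSE]
  out
}

#' Soft-thresholded co-expression adjacency
#'
#' `a_ij = |pearson(x_i, x_j)|^beta` (unsigned, the default) or
#' `((1 + r)/2)^beta` (signed); diagonal 1.
#'
#' @param mat numeric matrix, entities in rows, samples in columns.
#' @param beta soft-threshold power (genes 9, miRNAs 8 in the shipped
#'   profile).
#' @param signed use the signed transform (default FALSE).
#' @return symmetric adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(mat, beta, signed = FALSE) {
  stopifnot(beta > 0)
  r <- stats::cor(t(mat))
  a <- if (signed) ((1 + r) / 2)^beta else abs(r)^beta
  a[is.na(a)] <- 0
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i` the connectivity
#' `sum_u a_iu` over `u != i`; diagonal 1.
#'
#' @param adj symmetric adjacency matrix in `[0, 1]` with unit diagonal.
#' @return symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
tom <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-10)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  a <- adj
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  t_ <- (l + a) / denom
  diag(t_) <- 1
  dimnames(t_) <- dimnames(adj)
  t_
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at a static height into branches; branches smaller than
#' `min_module_size` are pooled into the unassigned `"grey"` module. Modules
#' are labelled from a fixed color palette in decreasing size order, so
#' labelling is reproducible for a given input.
#'
#' @param tom_mat topological overlap matrix with entity dimnames.
#' @param min_module_size minimal branch size (default 50).
#' @param cut_height static tree-cut height on `1 - TOM` (default 0.99).
#' @return list of class `coexpr_modules`: `labels` (named character vector,
#'   entity -> module color), `dendro` (the hclust tree), `sizes`,
#'   `cut_height`, `min_module_size`.
#' @export
detect_modules <- function(tom_mat, min_module_size = 50L,
                           cut_height = 0.99) {
  ids <- rownames(tom_mat)
  if (is.null(ids)) stop("TOM must carry entity names", call. = FALSE)
  if (nrow(tom_mat) < 2) {
    labels <- stats::setNames(rep("grey", nrow(tom_mat)), ids)
    return(structure(list(labels = labels, dendro = NULL,
                          sizes = table(labels), cut_height = cut_height,
                          min_module_size = min_module_size),
                     class = "coexpr_modules"))
  }
  d <- stats::as.dist(1 - tom_mat)
  h <- stats::hclust(d, method = "average")
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(raw))
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord)) {
      col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i]
             else paste0("module", i)
      labels[raw == as.integer(ord[i])] <- col
    }
  }
  labels <- stats::setNames(labels, ids)
  structure(list(labels = labels, dendro = h, sizes = table(labels),
                 cut_height = cut_height, min_module_size = min_module_size),
            class = "coexpr_modules")
}

#' @export
print.coexpr_modules <- function(x, ...) {
  cat("co-expression modules:\n")
  print(sort(x$sizes, decreasing = TRUE))
  invisible(x)
}

#' Module eigengene
#'
#' First principal component of the row-standardized member profiles, scaled
#' to unit variance and sign-oriented so the mean correlation of members
#' with the eigengene is non-negative.
#'
#' @param member_mat numeric matrix of member profiles (members x samples).
#' @return per-sample numeric vector (unit variance).
#' @export
eigengene <- function(member_mat) {
  member_mat <- as.matrix(member_mat)
  if (nrow(member_mat) == 0) stop("empty module", call. = FALSE)
  xs <- t(scale(t(member_mat)))
  xs[!is.finite(xs)] <- 0
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  e <- as.numeric(scale(e))
  cors <- suppressWarnings(stats::cor(t(xs), e))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  stats::setNames(e, colnames(member_mat))
}

#' Eigengenes for every detected module
#'
#' @param labels named module assignment (entity -> color); `"grey"` is
#'   skipped.
#' @param mat expression matrix (entities x samples) covering the entities.
#' @return samples x modules matrix of eigengenes.
#' @export
module_eigengenes <- function(labels, mat) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0) {
    return(matrix(numeric(0), nrow = ncol(mat), ncol = 0,
                  dimnames = list(colnames(mat), NULL)))
  }
  eg <- vapply(mods, function(m) {
    eigengene(mat[names(labels)[labels == m], , drop = FALSE])
  }, numeric(ncol(mat)))
  rownames(eg) <- colnames(mat)
  eg
}

#' Merge similar modules by eigengene correlation
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' at or above `merge_similarity`, recomputing the merged eigengene, until no
#' pair remains above the threshold.
#'
#' @param labels named module assignment (entity -> color).
#' @param mat expression matrix (entities x samples).
#' @param merge_similarity correlation threshold (default 0.8).
#' @return updated named label vector (merged modules take the label of the
#'   larger member, ties by palette order).
#' @export
merge_modules <- function(labels, mat, merge_similarity = 0.8) {
  stopifnot(merge_similarity > 0, merge_similarity < 1)
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eg <- module_eigengenes(labels, mat)
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[best[1], best[2]] < merge_similarity) break
    a <- mods[best[1]]; b <- mods[best[2]]
    na_ <- sum(labels == a); nb_ <- sum(labels == b)
    winner <- if (na_ > nb_) a else if (nb_ > na_) b
      else mods[min(best)]
    loser <- if (winner == a) b else a
    labels[labels == loser] <- winner
  }
  labels
}

#' Module--trait association
#'
#' Pearson correlation of each module eigengene with a per-sample trait
#' (e.g. bud break rate), with a two-sided p-value from the t distribution
#' with `n - 2` degrees of freedom.
#'
#' @param eigengenes samples x modules matrix.
#' @param trait per-sample numeric vector.
#' @return data.frame: `module`, `r`, `p`.
#' @export
module_trait <- function(eigengenes, trait) {
  stopifnot(nrow(eigengenes) == length(trait))
  n <- length(trait)
  r <- as.numeric(stats::cor(eigengenes, trait))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(module = colnames(eigengenes), r = r, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Module membership (kME) of entities
#'
#' @param mat expression matrix (entities x samples).
#' @param eg eigengene vector for one module.
#' @return named numeric vector of Pearson correlations with the eigengene.
#' @export
kme <- function(mat, eg) {
  v <- suppressWarnings(as.numeric(stats::cor(t(mat), eg)))
  stats::setNames(v, rownames(mat))
}

#' Select hub entities of a module
#'
#' The `ceil(top_frac * module size)` members (at least one) with the
#' highest module membership (kME), ties broken lexicographically by id.
#'
#' @param labels named module assignment.
#' @param mat expression matrix covering the members.
#' @param module module label.
#' @param eigengenes samples x modules eigengene matrix.
#' @param top_frac fraction of members selected (default 0.001, the top
#'   0.1\%).
#' @return data.frame: `id`, `kme`, ordered by decreasing kME.
#' @export
select_hubs <- function(labels, mat, module, eigengenes, top_frac = 0.001) {
  members <- names(labels)[labels == module]
  if (length(members) == 0) stop("empty module ", module, call. = FALSE)
  eg <- eigengenes[, module]
  km <- kme(mat[members, , drop = FALSE], eg)
  n_hub <- max(1L, ceiling(top_frac * length(members)))
  ord <- order(-km, names(km))
  sel <- ord[seq_len(min(n_hub, length(ord)))]
  data.frame(id = names(km)[sel], kme = unname(km[sel]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full co-expression pipeline on a filtered matrix
#'
#' Adjacency, TOM, module detection, merging, eigengenes, trait association,
#' and per-entity kME, with the shipped parameter defaults.
#'
#' @param mat numeric matrix (entities x samples), already expression
#'   filtered and transformed as desired.
#' @param trait per-sample trait vector (optional).
#' @param beta soft power.
#' @param min_module_size,cut_height,merge_similarity see the individual
#'   steps.
#' @param signed signed network (default FALSE).
#' @param prune_p significance level for membership pruning: after module
#'   detection, members whose module membership (kME) is not significant at
#'   this level under the correlation t-test are returned to the grey pool
#'   (default 0.05; `NULL` disables). Average-linkage branches under a
#'   static cut tend to absorb unconnected entities; this removes them.
#' @return list of class `coexpr_result`: `labels`, `eigengenes`,
#'   `trait_assoc`, `kme` (entity -> kME within its module), `dendro`.
#' @export
coexpr_network <- function(mat, trait = NULL, beta = 9,
                           min_module_size = 50L, cut_height = 0.99,
                           merge_similarity = 0.8, signed = FALSE,
                           prune_p = 0.05) {
  adj <- adjacency(mat, beta, signed = signed)
  tm <- tom(adj)
  det <- detect_modules(tm, min_module_size, cut_height)
  labels <- merge_modules(det$labels, mat, merge_similarity)
  if (!is.null(prune_p)) {
    n <- ncol(mat)
    t_crit <- stats::qt(1 - prune_p / 2, df = n - 2)
    r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
    eg0 <- module_eigengenes(labels, mat)
    for (m in colnames(eg0)) {
      mem <- names(labels)[labels == m]
      km0 <- kme(mat[mem, , drop = FALSE], eg0[, m])
      labels[mem[!is.na(km0) & km0 < r_crit]] <- "grey"
    }
  }
  eg <- module_eigengenes(labels, mat)
  kmes <- stats::setNames(rep(NA_real_, length(labels)), names(labels))
  for (m in colnames(eg)) {
    mem <- names(labels)[labels == m]
    kmes[mem] <- kme(mat[mem, , drop = FALSE], eg[, m])
  }
  assoc <- if (!is.null(trait) && ncol(eg) > 0) module_trait(eg, trait)
           else NULL
  structure(list(labels = labels, eigengenes = eg, trait_assoc = assoc,
                 kme = kmes, dendro = det$dendro),
            class = "coexpr_result")
}

#' @export
print.coexpr_result <- function(x, ...) {
  cat("co-expression network: ", length(unique(setdiff(x$labels, "grey"))),
      " modules over ", length(x$labels), " entities (",
      sum(x$labels == "grey"), " unassigned)\n", sep = "")
  if (!is.null(x$trait_assoc)) {
    ord <- order(-abs(x$trait_assoc$r))
    cat("top trait association: ", x$trait_assoc$module[ord[1]],
        " (r = ", round(x$trait_assoc$r[ord[1]], 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Export a module dendrogram as Newick text
#'
#' @param dendro an `hclust` object (from [detect_modules()]).
#' @param path output file.
#' @export
write_dendrogram_newick <- function(dendro, path) {
  if (is.null(dendro)) stop("no dendrogram available", call. = FALSE)
  recurse <- function(i) {
    if (i < 0) return(dendro$labels[-i])
    kids <- dendro$merge[i, ]
    sprintf("(%s,%s):%g", recurse(kids[1]), recurse(kids[2]),
            dendro$height[i])
  }
  writeLines(paste0(recurse(nrow(dendro$merge)), ";"), path)
  invisible(path)
}
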