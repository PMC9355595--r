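# Expression containers, TPM normalization, and the negative-binomial
# differential-expression screen applied between adjacent developmental
# stages (genes: |log2FC| > 1.5, adjusted P < 0.05; miRNAs: log2FC >= 1,
# FDR < 0.05).

#' Construct an expression matrix with sample metadata
#'
#' A lightweight container (in the spirit of a DGEList) holding an entities
#' x samples numeric matrix, per-sample metadata, and a units tag.
#'
#' @param values numeric matrix, entities in rows, samples in columns.
#' @param stage per-sample stage labels (length = ncol).
#' @param replicate per-sample replicate index (length = ncol).
#' @param units one of `"count"`, `"FPKM"`, `"TPM"`.
#' @return object of class `expr_matrix` with elements `values`, `samples`
#'   (data.frame: sample, stage, replicate), `units`.
#' @export
expr_matrix <- function(values, stage, replicate = NULL,
                        units = c("count", "FPKM", "TPM")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("expression matrix must have sample (column) names", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    stop("expression matrix must have entity (row) names", call. = FALSE)
  }
  if (any(values < 0)) stop("negative expression values", call. = FALSE)
  if (length(stage) != ncol(values)) {
    stop("stage metadata must cover every sample", call. = FALSE)
  }
  if (is.null(replicate)) replicate <- stats::ave(seq_along(stage), stage,
                                                  FUN = seq_along)
  structure(list(values = values,
                 samples = data.frame(sample = colnames(values),
                                      stage = as.character(stage),
                                      replicate = as.integer(replicate),
                                      stringsAsFactors = FALSE),
                 units = units),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " entities x ", ncol(x$values),
      " samples [", x$units, "], stages: ",
      paste(unique(x$samples$stage), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' TPM-normalize a count matrix
#'
#' `TPM = count / column_total * 1e6`, the tag-count formulation used for
#' miRNA libraries (no length correction). Every output column sums to 1e6.
#'
#' @param em an `expr_matrix` with `units = "count"`.
#' @return an `expr_matrix` with `units = "TPM"`.
#' @export
tpm_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$units != "count") stop("tpm_normalize expects counts", call. = FALSE)
  totals <- colSums(em$values)
  if (any(totals == 0)) {
    stop("all-zero count column(s): ",
         paste(colnames(em$values)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  out <- em
  out$values <- sweep(em$values, 2, totals, "/") * 1e6
  out$units <- "TPM"
  out
}

# Median-of-ratios library size factors (geometric-mean reference over
# entities positive in every sample); falls back to column totals scaled to
# geometric mean 1 when no all-positive reference exists.
size_factors <- function(counts) {
  pos <- rowSums(counts == 0) == 0
  if (any(pos)) {
    ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(col) {
      stats::median(col / ref)
    })
    if (all(is.finite(sf)) && all(sf > 0)) return(sf)
  }
  tot <- colSums(counts)
  tot / exp(mean(log(tot)))
}

#' Differential-expression screen between two sample groups
#'
#' Library sizes are normalized by median-of-ratios (column totals when no
#' all-positive reference entity exists). Per entity, the log2 fold change is
#' `log2((mean_b + c) / (mean_a + c))` on normalized counts with pseudocount
#' `c = 0.5`; the p-value comes from a Wald test under a negative-binomial
#' model with a per-entity method-of-moments dispersion (floored at 1e-4)
#' moderated toward the dataset median with `prior_df` prior degrees of
#' freedom, referred to a t distribution with `nA + nB - 2 + prior_df`
#' degrees of freedom; FDR by Benjamini--Hochberg. An entity is called differentially expressed when its
#' absolute log2 fold change exceeds `lfc_threshold` (strictly when
#' `strict_lfc`, at-or-above otherwise) and its FDR is below `alpha`.
#'
#' @param em an `expr_matrix` of counts.
#' @param group_a,group_b sample name vectors (disjoint, >= 2 each).
#' @param lfc_threshold log2 fold-change threshold (genes 1.5, miRNAs 1).
#' @param alpha FDR threshold (default 0.05).
#' @param strict_lfc if TRUE (gene rule) require `|lfc| > threshold`, else
#'   (miRNA rule) `|lfc| >= threshold`.
#' @param pseudocount pseudocount `c` (default 0.5).
#' @param dispersion_floor minimal NB dispersion (default 1e-4).
#' @param prior_df prior degrees of freedom for dispersion moderation
#'   (default 4).
#' @param comparison label stored in the result (e.g. "EndodorI_vs_EndodorII").
#' @return data.frame: `id`, `log2fc`, `p`, `fdr`, `is_de`, `direction`,
#'   `comparison`.
#' @export
de_screen <- function(em, group_a, group_b, lfc_threshold = 1.5,
                      alpha = 0.05, strict_lfc = TRUE, pseudocount = 0.5,
                      dispersion_floor = 1e-4, prior_df = 4,
                      comparison = "A_vs_B") {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$units != "count") stop("de_screen expects counts", call. = FALSE)
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("at least 2 replicates required per group", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(em$values))
  if (length(missing)) stop("unknown sample(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  counts <- em$values[, c(group_a, group_b), drop = FALSE]
  sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  ya <- y[, group_a, drop = FALSE]; yb <- y[, group_b, drop = FALSE]
  na <- ncol(ya); nb <- ncol(yb)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  va <- apply(ya, 1, stats::var); vb <- apply(yb, 1, stats::var)
  pooled_var <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  mu <- (na * ma + nb * mb) / (na + nb)
  disp <- pmax((pooled_var - mu) / pmax(mu, 1e-8)^2, dispersion_floor)
  # Empirical-Bayes moderation: shrink the noisy per-entity dispersion
  # toward the dataset median with prior_df pseudo-replicates, and refer
  # the Wald statistic to a t distribution with the augmented degrees of
  # freedom. At 3 replicates per group the raw method-of-moments estimate
  # is too unstable to test against directly.
  df_resid <- na + nb - 2
  disp_prior <- stats::median(disp)
  disp_mod <- (prior_df * disp_prior + df_resid * disp) /
    (prior_df + df_resid)
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  # delta-method variance of the log-mean per group
  v_log <- (1 / na) * (1 / (ma + pseudocount) + disp_mod) +
    (1 / nb) * (1 / (mb + pseudocount) + disp_mod)
  se <- sqrt(v_log) / log(2)
  tstat <- log2fc / se
  p <- 2 * stats::pt(-abs(tstat), df = df_resid + prior_df)
  p[ma + mb == 0] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  exceeds <- if (strict_lfc) abs(log2fc) > lfc_threshold
             else abs(log2fc) >= lfc_threshold
  is_de <- exceeds & fdr < alpha
  data.frame(id = rownames(counts), log2fc = log2fc, p = p, fdr = fdr,
             is_de = is_de,
             direction = ifelse(log2fc >= 0, "up", "down"),
             comparison = comparison,
             stringsAsFactors = FALSE, row.names = NULL)
}
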