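# Hypergeometric term enrichment with Benjamini-Hochberg FDR control.

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `m` annotated entities among `n`
#' candidates drawn from a background of `N` entities of which `M` carry the
#' annotation:
#' `P = 1 - sum_{i=0}^{m-1} C(M, i) C(N - M, n - i) / C(N, n)`.
#' Computed in log space for stability; `m = 0` gives `P = 1`.
#'
#' @param N background size.
#' @param n candidate-set size.
#' @param M annotated entities in the background.
#' @param m annotated entities among the candidates.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_p <- function(N, n, M, m) {
  if (any(c(N, n, M, m) < 0) || m > min(n, M) || N < max(n, M)) {
    stop("invalid hypergeometric counts (need m <= min(n, M) <= N)",
         call. = FALSE)
  }
  if (m == 0) return(1)
  i <- 0:(m - 1)
  terms <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  p <- 1 - sum(exp(terms))
  min(max(p, 0), 1)
}

#' Term enrichment of a candidate set
#'
#' Tests each annotation term for over-representation among the candidates
#' with the upper-tail hypergeometric test and controls the FDR across
#' tested terms by Benjamini--Hochberg. Terms with no candidate overlap
#' (`m = 0`) are excluded from testing so they do not dilute the FDR; they
#' are absent from the result.
#'
#' @param candidates entity ids (must be a subset of the background).
#' @param annotations data.frame with columns `entity`, `term`, and
#'   optionally `name`, `namespace`.
#' @param background background entity ids; defaults to every entity in
#'   `annotations`.
#' @param alpha FDR significance threshold (default 0.05, at-or-below).
#' @return data.frame: `term`, `name`, `namespace`, `N`, `n`, `M`, `m`,
#'   `p`, `fdr`, `significant`, ordered by p.
#' @export
enrich <- function(candidates, annotations, background = NULL,
                   alpha = 0.05) {
  if (is.null(background)) background <- unique(annotations$entity)
  background <- unique(background)
  candidates <- unique(candidates)
  outside <- setdiff(candidates, background)
  if (length(outside)) {
    stop("candidate(s) outside the background: ",
         paste(utils::head(outside, 10), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[annotations$entity %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(candidates)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    tset <- unique(ann$entity[ann$term == tm])
    m <- length(intersect(tset, candidates))
    if (m == 0) return(NULL)
    meta <- ann[ann$term == tm, , drop = FALSE][1, ]
    data.frame(term = tm,
               name = if ("name" %in% names(ann)) meta$name else tm,
               namespace = if ("namespace" %in% names(ann)) meta$namespace
                           else NA_character_,
               N = N, n = n, M = length(tset), m = m,
               p = hypergeom_p(N, n, length(tset), m),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term = character(), name = character(),
                      namespace = character(), N = integer(), n = integer(),
                      M = integer(), m = integer(), p = numeric(),
                      fdr = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr <= alpha
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
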