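#' geNorm pairwise stability values
#'
#' For candidate reference genes in a log2 expression (or Ct) matrix, the
#' pairwise variation \code{V[j, k]} is the standard deviation over samples
#' of the difference of the two genes' log2 values (the log2 expression
#' ratio), and the stability \code{M[j]} is the mean of \code{V[j, k]} over
#' all other candidates. Stable reference genes co-vary with each other, so
#' a low M marks a good reference.
#'
#' @param m numeric matrix, genes x samples, log2 scale.
#' @return named vector of M values.
#' @export
genorm_m <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  p <- nrow(m)
  v <- matrix(0, p, p)
  for (j in seq_len(p - 1)) {
    for (k in (j + 1):p) {
      v[j, k] <- v[k, j] <- stats::sd(m[j, ] - m[k, ], na.rm = TRUE)
    }
  }
  stats::setNames(rowSums(v) / (p - 1), rownames(m))
}

#' Rank candidate reference genes by geNorm stability
#'
#' Iteratively computes stability values M for the remaining candidates and
#' drops the least stable (highest M) gene, recording the order of
#' elimination; the genes surviving longest are the best references.
#' Candidates with more than \code{max_missing} missing values are excluded
#' up front with a warning.
#'
#' @param m numeric matrix, genes x samples, log2 scale.
#' @param candidates candidate gene ids (default: all rows); at least 3.
#' @param max_missing maximum tolerated fraction of missing values.
#' @return data.frame with \code{gene}, \code{M} (stability at the
#'   elimination step), \code{rank} (1 = most stable) ordered best first.
#' @export
genorm_rank <- function(m, candidates = rownames(m), max_missing = 0.2) {
  stopifnot(ncol(m) >= 2)
  candidates <- intersect(candidates, rownames(m))
  if (length(candidates) < 3) stop("need at least 3 candidate genes")
  miss <- rowMeans(is.na(m[candidates, , drop = FALSE]))
  if (any(miss > max_missing)) {
    warning("excluding candidates with too many missing values: ",
            paste(candidates[miss > max_missing], collapse = ", "))
    candidates <- candidates[miss <= max_missing]
    if (length(candidates) < 3) stop("fewer than 3 candidates remain")
  }
  remaining <- candidates
  out <- data.frame(gene = character(), M = numeric(),
                    stringsAsFactors = FALSE)
  while (length(remaining) > 2) {
    mm <- genorm_m(m[remaining, , drop = FALSE])
    worst <- names(which.max(mm))
    out <- rbind(out, data.frame(gene = worst, M = unname(mm[worst])))
    remaining <- setdiff(remaining, worst)
  }
  mm <- genorm_m(m[remaining, , drop = FALSE])
  mm <- sort(mm, decreasing = TRUE)
  out <- rbind(out, data.frame(gene = names(mm), M = unname(mm)))
  out$rank <- rev(seq_len(nrow(out)))
  out[order(out$rank), c("gene", "M", "rank")]
}
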