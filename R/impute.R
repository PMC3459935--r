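#' k-nearest-neighbour imputation in gene space
#'
#' Fills each missing (gene, sample) entry with the distance-weighted mean
#' of the k nearest genes, nearness being Euclidean distance on the samples
#' both genes observe (scaled to a per-sample distance so genes with
#' different missingness are comparable). Only genes observed at the target
#' sample can donate. A zero-distance neighbour (an exact duplicate)
#' dominates the weights, so the imputed value equals the duplicate's.
#' When fewer than \code{k} donors exist at a sample, all available donors
#' are used.
#'
#' @param m numeric matrix, genes x samples, with NAs to fill.
#' @param k number of neighbour genes.
#' @return complete matrix.
#' @export
knn_impute <- function(m, k = 10) {
  stopifnot(is.matrix(m), k >= 1)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("gene(s) missing everywhere: ",
         paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", "))
  }
  out <- m
  nas <- which(is.na(m), arr.ind = TRUE)
  if (!nrow(nas)) return(out)
  for (g in unique(nas[, 1])) {
    cols <- nas[nas[, 1] == g, 2]
    x <- m[g, ]
    d <- rep(NA_real_, nrow(m))
    for (h in seq_len(nrow(m))) {
      if (h == g) next
      shared <- !is.na(x) & !is.na(m[h, ])
      if (sum(shared) >= 2) {
        d[h] <- sqrt(mean((x[shared] - m[h, shared])^2))
      }
    }
    for (j in cols) {
      ok <- which(!is.na(d) & !is.na(m[, j]))
      if (!length(ok)) {
        stop("gene ", rownames(m)[g] %||% g, " has no complete ",
             "neighbour at sample ", colnames(m)[j] %||% j)
      }
      nb <- ok[order(d[ok])][seq_len(min(k, length(ok)))]
      w <- 1 / pmax(d[nb], 1e-12)
      out[g, j] <- sum(w * m[nb, j]) / sum(w)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
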