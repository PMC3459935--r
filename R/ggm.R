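#' Group-wise and pooled covariance matrices
#'
#' Standardizes columns to zero mean, unit variance within each group, then
#' returns each group's empirical covariance and the pooled covariance over
#' all (standardized) observations. These are the inputs of the intertwined
#' sparse inference.
#'
#' @param x numeric matrix, observations x variables.
#' @param groups group label per row (2 groups downstream, any number
#'   here).
#' @param standardize standardize within group first (default TRUE).
#' @return list with \code{by_group} (named list of covariance matrices),
#'   \code{pooled}, and \code{n} (observations per group).
#' @export
group_covariances <- function(x, groups, standardize = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(groups))
  groups <- as.character(groups)
  for (g in unique(groups)) {
    if (sum(groups == g) < 2) stop("group ", g, " has < 2 observations")
  }
  if (standardize) {
    for (g in unique(groups)) {
      i <- groups == g
      sds <- apply(x[i, , drop = FALSE], 2, stats::sd)
      if (any(sds == 0)) {
        stop("constant column(s) in group ", g, ": ",
             paste(colnames(x)[sds == 0], collapse = ", "))
      }
      x[i, ] <- scale(x[i, , drop = FALSE])
    }
  }
  by_group <- lapply(split(seq_len(nrow(x)), groups),
                     function(i) stats::cov(x[i, , drop = FALSE]))
  list(by_group = by_group, pooled = stats::cov(x),
       n = table(groups))
}

#' Intertwine a group covariance with the pooled covariance
#'
#' Convex combination \code{alpha * S_group + (1 - alpha) * S_pooled}.
#' Mixing each group's covariance with the covariance over all groups
#' biases the two inferred networks toward common structure, reflecting
#' shared functionality between the groups.
#'
#' @param s_group group covariance.
#' @param s_pooled pooled covariance of identical dimension.
#' @param alpha_mix mixing weight in \code{[0, 1]}; 1 = group only,
#'   0 = pooled only.
#' @return mixed covariance matrix.
#' @export
intertwine <- function(s_group, s_pooled, alpha_mix = 0.5) {
  stopifnot(alpha_mix >= 0, alpha_mix <= 1)
  if (!identical(dim(s_group), dim(s_pooled))) {
    stop("covariance shape mismatch")
  }
  alpha_mix * s_group + (1 - alpha_mix) * s_pooled
}

# Lasso solved by coordinate descent in covariance form:
# minimize 0.5 b' S11 b - s12' b + lambda ||b||_1.
# Only needs the covariance matrix, not raw data.
lasso_cov_cd <- function(s11, s12, lambda, tol = 1e-10, maxit = 10000L,
                         b = numeric(length(s12))) {
  p <- length(s12)
  for (it in seq_len(maxit)) {
    delta <- 0
    for (k in seq_len(p)) {
      r <- s12[k] - sum(s11[k, -k] * b[-k])
      bk <- sign(r) * max(abs(r) - lambda, 0) / s11[k, k]
      delta <- max(delta, abs(bk - b[k]))
      b[k] <- bk
    }
    if (delta < tol) return(b)
  }
  stop("lasso coordinate descent did not converge within ", maxit,
       " sweeps (lambda = ", lambda, ")")
}

#' Sparse Gaussian graphical model by neighborhood selection
#'
#' Estimates the conditional-independence graph from a covariance matrix by
#' node-wise lasso regressions (each variable on all others, solved in
#' covariance form by coordinate descent). Under the \code{"AND"} policy an
#' edge i-j is kept only when both directional regressions select it, which
#' curbs false-positive edges; \code{"OR"} keeps either. A sparse precision
#' estimate is rebuilt from the regressions (residual-variance scaling,
#' symmetrized by averaging) and masked to the selected support.
#'
#' @param s covariance matrix (symmetric; typically standardized /
#'   intertwined).
#' @param lambda non-negative l1 penalty.
#' @param policy \code{"AND"} (default) or \code{"OR"} edge symmetrization.
#' @param beta_init optional warm-start coefficient matrix (as returned in
#'   \code{$beta}), used by the density calibration to speed up the path.
#' @return list of class \code{ggm_fit}: \code{adjacency} (logical,
#'   symmetric, empty diagonal), \code{precision}, \code{beta} (node-wise
#'   coefficients), \code{lambda}, \code{policy}.
#' @export
sparse_ggm_infer <- function(s, lambda, policy = c("AND", "OR"),
                             beta_init = NULL) {
  policy <- match.arg(policy)
  stopifnot(is.matrix(s), nrow(s) == ncol(s), lambda >= 0)
  if (max(abs(s - t(s))) > 1e-8) stop("covariance not symmetric")
  p <- nrow(s)
  beta <- matrix(0, p, p, dimnames = dimnames(s))
  tau2 <- numeric(p)
  for (j in seq_len(p)) {
    b0 <- if (is.null(beta_init)) numeric(p - 1) else beta_init[j, -j]
    b <- lasso_cov_cd(s[-j, -j, drop = FALSE], s[-j, j], lambda, b = b0)
    beta[j, -j] <- b
    tau2[j] <- max(s[j, j] - sum(b * s[-j, j]), 1e-8)
  }
  nz <- beta != 0
  adj <- if (policy == "AND") nz & t(nz) else nz | t(nz)
  diag(adj) <- FALSE
  theta <- -(beta / tau2 + t(beta / tau2)) / 2
  diag(theta) <- 1 / tau2
  theta[!adj & row(theta) != col(theta)] <- 0
  structure(list(adjacency = adj, precision = theta, beta = beta,
                 lambda = lambda, policy = policy),
            class = "ggm_fit")
}

#' Partial correlations from a precision matrix
#'
#' \code{rho[i, j] = -theta[i, j] / sqrt(theta[i, i] * theta[j, j])}, with
#' unit diagonal.
#'
#' @param theta symmetric precision matrix with positive diagonal.
#' @return partial-correlation matrix.
#' @export
partial_correlation <- function(theta) {
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  if (max(abs(theta - t(theta))) > 1e-8) stop("precision not symmetric")
  d <- diag(theta)
  if (any(d <= 0)) stop("non-positive diagonal in precision matrix")
  rho <- -theta / sqrt(outer(d, d))
  diag(rho) <- 1
  rho
}

edge_pairs <- function(adj) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  nodes <- rownames(adj) %||% as.character(seq_len(nrow(adj)))
  paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "|")
}

#' Assemble a group network object
#'
#' @param fit a \code{ggm_fit}.
#' @param group group label.
#' @return object of class \code{ggm_network}: \code{nodes},
#'   \code{adjacency}, \code{weights} (partial correlations on edges, 0
#'   elsewhere), \code{lambda}, \code{density}, \code{group},
#'   \code{degree}, \code{betweenness}.
#' @export
ggm_network <- function(fit, group = NA_character_) {
  adj <- fit$adjacency
  p <- nrow(adj)
  nodes <- rownames(adj) %||% as.character(seq_len(p))
  rho <- partial_correlation(fit$precision)
  w <- ifelse(adj, rho, 0)
  diag(w) <- 0
  n_pairs <- p * (p - 1) / 2
  net <- structure(
    list(nodes = nodes, adjacency = adj, weights = w, lambda = fit$lambda,
         density = sum(adj[upper.tri(adj)]) / n_pairs, group = group,
         degree = NULL, betweenness = NULL),
    class = "ggm_network")
  m <- network_metrics(net)
  net$degree <- m$degree
  net$betweenness <- m$betweenness
  net
}

#' @export
print.ggm_network <- function(x, ...) {
  cat("ggm_network", if (!is.na(x$group)) paste0("[", x$group, "]"), ":",
      length(x$nodes), "nodes,", sum(x$adjacency[upper.tri(x$adjacency)]),
      "edges (density", sprintf("%.3f", x$density), ") at lambda",
      sprintf("%.4g", x$lambda), "\n")
  invisible(x)
}

#' Calibrate the penalty to a target edge density
#'
#' Bisects the lasso penalty until the inferred network's edge density
#' (edges divided by node pairs) is as close as attainable to the target —
#' exact whenever \code{target x pairs} is an integer the solution path
#' passes through. Ties between penalties achieving the same deviation are
#' broken toward the smaller penalty (the denser network). Density is
#' non-increasing in the penalty along the path.
#'
#' @param s covariance matrix.
#' @param target target density in \code{(0, 1)} (15\% by default, the
#'   construction density used for readable networks).
#' @param policy edge symmetrization policy.
#' @param group group label stored on the returned network.
#' @param max_iter bisection iterations.
#' @return list with \code{lambda}, \code{network} (a
#'   \code{ggm_network}), \code{achieved_density}.
#' @export
calibrate_density <- function(s, target = 0.15, policy = "AND",
                              group = NA_character_, max_iter = 50L) {
  stopifnot(target > 0, target < 1)
  p <- nrow(s)
  n_pairs <- p * (p - 1) / 2
  target_edges <- target * n_pairs
  n_edges <- function(fit) sum(fit$adjacency[upper.tri(fit$adjacency)])

  lo <- 0
  hi <- max(abs(s[row(s) != col(s)])) + 1e-6
  fit_hi <- sparse_ggm_infer(s, hi, policy)
  if (n_edges(fit_hi) > target_edges) {
    stop("target density not bracketed: even the maximal penalty leaves ",
         n_edges(fit_hi), " edges")
  }
  best <- list(lambda = hi, fit = fit_hi,
               dev = abs(n_edges(fit_hi) - target_edges))
  warm <- fit_hi$beta
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fit <- sparse_ggm_infer(s, mid, policy, beta_init = warm)
    warm <- fit$beta
    e <- n_edges(fit)
    dev <- abs(e - target_edges)
    if (dev < best$dev || (dev == best$dev && mid < best$lambda)) {
      best <- list(lambda = mid, fit = fit, dev = dev)
    }
    if (e > target_edges) lo <- mid else hi <- mid
    if (dev == 0 && e == round(target_edges)) {
      # exact hit; keep tightening toward smaller lambda ties only
      if (abs(target_edges - round(target_edges)) < 1e-9) break
    }
  }
  net <- ggm_network(best$fit, group = group)
  list(lambda = best$lambda, network = net,
       achieved_density = net$density)
}

#' Degree and betweenness centrality of a network
#'
#' Degree counts incident edges; betweenness counts, for every node, the
#' fraction of shortest paths between other node pairs passing through it
#' (unweighted graph).
#'
#' @param net a \code{ggm_network} (or any object with a logical
#'   \code{adjacency}).
#' @return list with named \code{degree} and \code{betweenness} vectors.
#' @export
network_metrics <- function(net) {
  adj <- if (inherits(net, "ggm_network")) net$adjacency else net
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  list(degree = stats::setNames(igraph::degree(g), rownames(adj)),
       betweenness = stats::setNames(
         igraph::betweenness(g, directed = FALSE), rownames(adj)))
}

#' Shared-edge fraction between two networks
#'
#' Reports the edge overlap under three conventions, since "fraction of
#' edges in common" can be read against either network's edge count or
#' their union: Jaccard (intersection over union) and intersection over
#' each network's edges, all as percentages.
#'
#' @param net_a,net_b \code{ggm_network}s over the same node set.
#' @return list \code{n_shared}, \code{jaccard}, \code{frac_a},
#'   \code{frac_b} (percent).
#' @export
shared_edge_fraction <- function(net_a, net_b) {
  if (!identical(net_a$nodes, net_b$nodes)) stop("node sets differ")
  ea <- edge_pairs(net_a$adjacency)
  eb <- edge_pairs(net_b$adjacency)
  ns <- length(intersect(ea, eb))
  pct <- function(num, den) if (den == 0) 100 else 100 * num / den
  list(n_shared = ns,
       jaccard = pct(ns, length(union(ea, eb))),
       frac_a = pct(ns, length(ea)),
       frac_b = pct(ns, length(eb)))
}

#' Export a network to GraphML or an edge-list TSV
#'
#' Nodes carry degree and betweenness attributes; edges carry the
#' partial-correlation weight and its sign. The file round-trips through
#' [import_network()].
#'
#' @param net a \code{ggm_network}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"edgelist"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency * 1,
                                             mode = "undirected")
    igraph::V(g)$name <- net$nodes
    igraph::V(g)$degree <- unname(net$degree)
    igraph::V(g)$betweenness <- unname(net$betweenness)
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- net$weights[el]
    igraph::E(g)$rho <- w
    igraph::E(g)$sign <- ifelse(w >= 0, "+", "-")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
    d <- data.frame(from = net$nodes[idx[, 1]], to = net$nodes[idx[, 2]],
                    rho = net$weights[idx],
                    sign = ifelse(net$weights[idx] >= 0, "+", "-"))
    utils::write.table(d[order(d$from, d$to), ], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Re-import an exported network
#'
#' @param path file written by [export_network()].
#' @param format \code{"graphml"} or \code{"edgelist"}.
#' @param nodes node set (required for \code{"edgelist"}, which stores
#'   only connected nodes).
#' @return list with \code{adjacency} and \code{weights} matrices.
#' @export
import_network <- function(path, format = c("graphml", "edgelist"),
                           nodes = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- igraph::V(g)$name
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    w <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    el <- igraph::as_edgelist(g)
    if (nrow(el)) {
      rho <- igraph::E(g)$rho
      for (i in seq_len(nrow(el))) {
        adj[el[i, 1], el[i, 2]] <- adj[el[i, 2], el[i, 1]] <- TRUE
        w[el[i, 1], el[i, 2]] <- w[el[i, 2], el[i, 1]] <- rho[i]
      }
    }
  } else {
    if (is.null(nodes)) stop("nodes required for edge-list import")
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    adj <- matrix(FALSE, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    w <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(d))) {
      adj[d$from[i], d$to[i]] <- adj[d$to[i], d$from[i]] <- TRUE
      w[d$from[i], d$to[i]] <- w[d$to[i], d$from[i]] <- d$rho[i]
    }
  }
  list(adjacency = adj, weights = w)
}

#' Infer the two group networks with intertwined covariances
#'
#' Convenience wrapper over the full network stage: standardized group and
#' pooled covariances, intertwining, and per-group density calibration.
#'
#' @param x observations x variables matrix.
#' @param groups group label per row (two groups).
#' @param alpha_mix covariance mixing weight.
#' @param target density target.
#' @param policy edge symmetrization policy.
#' @return named list of \code{ggm_network}s (one per group).
#' @export
infer_group_networks <- function(x, groups, alpha_mix = 0.5,
                                 target = 0.15, policy = "AND") {
  cv <- group_covariances(x, groups)
  lapply(stats::setNames(nm = names(cv$by_group)), function(g) {
    s <- intertwine(cv$by_group[[g]], cv$pooled, alpha_mix)
    calibrate_density(s, target = target, policy = policy,
                      group = g)$network
  })
}
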