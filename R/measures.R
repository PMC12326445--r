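#' Sample variance of node strengths
#'
#' Measures network heterogeneity: the spread of the node strength
#' distribution (n - 1 denominator).
#'
#' @param net A `weighted_network`.
#' @return Scalar variance.
#' @export
strength_variance <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_nodes(net) < 2) stop("need at least 2 nodes", call. = FALSE)
  stats::var(node_strengths(net))
}

#' Strength assortativity
#'
#' Pearson-type correlation of endpoint node strengths over the network's
#' edges: sums run over all ordered pairs (i, j) with \eqn{W_{ij} > 0}, so
#' each undirected edge contributes in both directions and the statistic
#' reduces to the standard Newman form on binary graphs. Positive values mean
#' strong nodes preferentially attach to strong nodes.
#'
#' On strength-regular networks every endpoint strength is equal and the
#' ratio is 0/0; `NA` is returned with a warning rather than a misleading 0.
#'
#' @param net A `weighted_network`.
#' @return Scalar in \[-1, 1\], or `NA` when undefined.
#' @export
assortativity <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  s <- rowSums(w)
  idx <- which(w > 0, arr.ind = TRUE)      # ordered pairs, both directions
  if (nrow(idx) < 2) stop("need at least one edge", call. = FALSE)
  si <- s[idx[, 1]]
  sj <- s[idx[, 2]]
  m_inv <- 1 / nrow(idx)
  mid <- (m_inv * sum((si + sj) / 2))^2
  num <- m_inv * sum(si * sj) - mid
  den <- m_inv * sum((si^2 + sj^2) / 2) - mid
  if (den <= .Machine$double.eps * max(1, mid)) {
    warning("assortativity undefined: all endpoint strengths equal",
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Normalised weighted clustering coefficient
#'
#' Onnela's weighted clustering coefficient averaged over nodes, divided by
#' the graph density P = 2M / (n(n-1)):
#' \deqn{\gamma = C / P, \quad
#'   C_i = \frac{\sum_{j,k} (\tilde w_{ij} \tilde w_{jk} \tilde w_{ki})^{1/3}}
#'              {k_i (k_i - 1)},}
#' with weights normalised by the network maximum,
#' \eqn{\tilde w = W / \max(W)}. Nodes of degree < 2 contribute 0. Measures
#' segregation into local clusters relative to what the density affords.
#'
#' @param net A `weighted_network`.
#' @return Scalar gamma >= 0.
#' @export
clustering_norm <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  n <- nrow(w)
  if (n < 3) stop("need at least 3 nodes", call. = FALSE)
  m <- sum(w > 0) / 2
  if (m == 0) stop("edgeless network has no clustering", call. = FALSE)
  wt <- (w / max(w))^(1 / 3)
  tri <- diag(wt %*% wt %*% wt)           # counts ordered (j, k) pairs
  k <- rowSums(w > 0)
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  p <- 2 * m / (n * (n - 1))
  mean(ci) / p
}

#' Global routing efficiency
#'
#' Mean inverse weighted shortest-path distance over ordered node pairs,
#' \eqn{E_{rout} = \sum_{i \ne j} (1/d_{ij}) / (n(n-1))}, with edge lengths
#' taken as the reciprocal of the weight (strong connections are short).
#' Unreachable pairs contribute 0, so disconnected networks are handled
#' gracefully.
#'
#' @param net A `weighted_network`.
#' @param length_transform Edge weight-to-length map; only `"inverse"`
#'   (\eqn{\ell = 1/w}) is provided.
#' @return Scalar efficiency >= 0.
#' @export
routing_efficiency <- function(net, length_transform = "inverse") {
  stopifnot(inherits(net, "weighted_network"))
  length_transform <- match.arg(length_transform, "inverse")
  n <- n_nodes(net)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  len <- 1 / igraph::E(g)$weight
  d <- igraph::distances(g, weights = len)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global diffusion efficiency
#'
#' Mean inverse mean first-passage time (MFPT) over ordered node pairs,
#' \eqn{E_{diff} = \sum_{i \ne j} (1/t_{ij}) / (n(n-1))}, for the
#' weight-proportional random walk with transition matrix
#' \eqn{P_{ij} = W_{ij} / s_i}. MFPTs are computed in closed form from the
#' chain's fundamental matrix \eqn{Z = (I - P + \mathbf{1}\pi^\top)^{-1}}
#' with stationary distribution \eqn{\pi_j = s_j / \sum_k s_k}:
#' \eqn{t_{ij} = (Z_{jj} - Z_{ij}) / \pi_j}. Complements routing efficiency
#' with a random-walk (non-shortest-path) view of communication.
#'
#' @param net A `weighted_network`; must be connected (MFPTs are infinite
#'   otherwise — restrict to the largest component first).
#' @return Scalar efficiency > 0.
#' @export
diffusion_efficiency <- function(net) {
  t <- mean_first_passage_times(net)
  n <- nrow(t)
  inv <- 1 / t
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean first-passage time matrix of the weight-proportional random walk
#'
#' @param net A connected `weighted_network`.
#' @return n-by-n matrix with `t[i, j]` the expected number of steps from i
#'   to first arrival at j; diagonal 0.
#' @export
mean_first_passage_times <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  w <- net$weights
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  if (igraph::components(g)$no > 1) {
    stop("network is disconnected: mean first-passage times are infinite; ",
         "restrict to the largest connected component first", call. = FALSE)
  }
  s <- rowSums(w)
  p <- w / s
  pi <- s / sum(s)
  z <- solve(diag(n) - p + matrix(pi, n, n, byrow = TRUE))
  t <- (matrix(diag(z), n, n, byrow = TRUE) - z) /
    matrix(pi, n, n, byrow = TRUE)
  diag(t) <- 0
  dimnames(t) <- dimnames(w)
  t
}

#' All graph measures for one network
#'
#' Computes RSV, hRSV at the requested window sizes, and the five comparison
#' measures (strength variance, assortativity, normalised clustering, routing
#' and diffusion efficiency) plus mean edge weight, returning one tidy row.
#' Individual measure failures (e.g. diffusion efficiency on a disconnected
#' network) are recorded as `NA` with a warning naming the measure, so a
#' cohort run is not aborted by one pathological subject.
#'
#' @param net A `weighted_network`.
#' @param windows Integer vector of hRSV window sizes (default `c(4, 21)`).
#' @param corrected Use the edge-corrected relative strength form.
#' @param population_strengths Optional cohort-mean strength vector used to
#'   order the hRSV windows.
#' @return One-row tibble of measures; hRSV columns are named `hrsv_w<w>`.
#' @export
all_measures <- function(net, windows = c(4, 21), corrected = TRUE,
                         population_strengths = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  ordering <- if (is.null(population_strengths)) "own_strength" else
    "population_mean_strength"
  safe <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("measure '%s' failed: %s", name, conditionMessage(e)),
              call. = FALSE)
      NA_real_
    })
  }
  w <- net$weights
  out <- tibble::tibble(
    mean_edge_weight = mean(w[upper.tri(w)][w[upper.tri(w)] > 0]),
    rsv = safe("rsv", rsv(net, corrected)$rsv),
    strength_variance = safe("strength_variance", strength_variance(net)),
    assortativity = safe("assortativity", suppressWarnings(assortativity(net))),
    clustering_norm = safe("clustering_norm", clustering_norm(net)),
    routing_efficiency = safe("routing_efficiency", routing_efficiency(net)),
    diffusion_efficiency = safe("diffusion_efficiency",
                                diffusion_efficiency(net))
  )
  for (wsz in windows) {
    out[[paste0("hrsv_w", wsz)]] <- safe(
      paste0("hrsv_w", wsz),
      hrsv(net, wsz, corrected, ordering,
           population_strengths = population_strengths)$hrsv)
  }
  out
}
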