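#' Node strengths of a weighted network
#'
#' The strength of node i is the sum of the weights of its adjacent edges,
#' \eqn{s_i = \sum_j W_{ij}} — the weighted analogue of degree.
#'
#' @param net A `weighted_network`.
#' @return Named numeric vector of length n.
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  rowSums(net$weights)
}

#' Relative node strengths
#'
#' The relative strength of node i compares its strength with those of its
#' direct neighbours. The plain form is the node's strength divided by the
#' mean strength of its neighbours,
#' \deqn{r_i = s_i / \left( \frac{1}{|N(i)|} \sum_{j \in N(i)} s_j \right).}
#' The edge-corrected form removes the connecting edge's weight from both
#' strengths before forming each neighbour ratio, and inverts the mean of the
#' neighbour-to-self ratios:
#' \deqn{r_i = \left[ \frac{1}{|N(i)|} \sum_{j \in N(i)}
#'       \frac{s_j - W_{ij}}{s_i - W_{ij}} \right]^{-1},}
#' which removes the bias a single strong reciprocal connection induces on
#' the comparison. Disabling the correction recovers the plain form.
#'
#' A node whose strength is exhausted by the connecting edge makes a
#' corrected term degenerate (`s_i - W_ij = 0`, e.g. a leaf); by default such
#' terms are dropped from the mean with a warning, and a node whose every
#' term is degenerate falls back to its plain (uncorrected) ratio so the
#' result stays finite and positive. `degenerate = "error"` raises instead.
#'
#' @param net A `weighted_network`.
#' @param corrected Use the edge-subtraction form (default `TRUE`).
#' @param degenerate How to handle degenerate corrected terms: `"skip"`
#'   (drop, with a warning) or `"error"`.
#' @return A tibble with columns `node`, `strength`, `rel_strength`, plus
#'   attribute `corrected`.
#' @examples
#' star <- weighted_network(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
#'                                c(1, 0, 0, 0), c(1, 0, 0, 0)))
#' relative_strengths(star, corrected = FALSE)
#' @export
relative_strengths <- function(net, corrected = TRUE,
                               degenerate = c("skip", "error")) {
  stopifnot(inherits(net, "weighted_network"))
  degenerate <- match.arg(degenerate)
  w <- net$weights
  n <- nrow(w)
  s <- rowSums(w)
  deg <- rowSums(w > 0)
  if (any(deg == 0)) {
    stop("isolated node(s): ",
         paste(net$node_labels[deg == 0], collapse = ", "), call. = FALSE)
  }
  r <- numeric(n)
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (!corrected) {
      r[i] <- s[i] / mean(s[nb])
    } else {
      denom <- s[i] - w[i, nb]
      numer <- s[nb] - w[i, nb]
      bad <- denom <= 0
      if (any(bad)) {
        if (degenerate == "error") {
          stop(sprintf("degenerate corrected term at node %s (s_i - W_ij <= 0)",
                       net$node_labels[i]), call. = FALSE)
        }
        n_degenerate <- n_degenerate + sum(bad)
        denom <- denom[!bad]
        numer <- numer[!bad]
      }
      m_terms <- if (length(denom)) mean(numer / denom) else 0
      if (m_terms <= 0) {
        # every term degenerate (leaf) or every neighbour's residual
        # strength zero (pure hub): fall back to the plain ratio rather
        # than emit an infinity
        n_degenerate <- n_degenerate + (length(denom) > 0)
        r[i] <- s[i] / mean(s[nb])
      } else {
        r[i] <- 1 / m_terms
      }
    }
  }
  if (n_degenerate > 0) {
    warning(sprintf("%d degenerate edge-corrected term(s) dropped", n_degenerate),
            call. = FALSE)
  }
  out <- tibble::tibble(node = net$node_labels, strength = unname(s),
                        rel_strength = r)
  attr(out, "corrected") <- corrected
  out
}

#' Relative Strength Variability (RSV)
#'
#' The sample standard deviation of the relative node strengths over all
#' nodes,
#' \deqn{V_{rel} = \sqrt{ \frac{1}{n-1} \sum_i (r_i - \mu_r)^2 }.}
#' RSV is high when strong and weak nodes interconnect (core-periphery
#' mixing, star-like networks) and low when edges stay within similar
#' strength bands. The squared (variance) form is reported alongside.
#'
#' @inheritParams relative_strengths
#' @return One-row tibble: `rsv` (sample SD), `variance`, `mu_r`, `n_nodes`,
#'   `corrected`.
#' @examples
#' star <- weighted_network(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
#'                                c(1, 0, 0, 0), c(1, 0, 0, 0)))
#' rsv(star, corrected = FALSE)$rsv  # 4/3
#' @export
rsv <- function(net, corrected = TRUE, degenerate = c("skip", "error")) {
  stopifnot(inherits(net, "weighted_network"))
  if (n_nodes(net) < 2) stop("RSV needs at least 2 nodes", call. = FALSE)
  prof <- relative_strengths(net, corrected, degenerate)
  r <- prof$rel_strength
  tibble::tibble(rsv = stats::sd(r), variance = stats::var(r),
                 mu_r = mean(r), n_nodes = length(r), corrected = corrected)
}

#' Hierarchical RSV: sliding-window relative strength variability
#'
#' Nodes are sorted in ascending order of a strength basis (their own
#' strengths, or a supplied population-mean strength vector for cohort
#' analyses; ties broken by node order). A window of `window_size` = w
#' consecutive ranked nodes is slid from the weakest to the strongest node,
#' giving n - w + 1 windows; the sample standard deviation of the relative
#' strengths inside each window is taken and the mean over windows is the
#' hRSV value. Small windows measure connectivity-pattern diversity among
#' similarly ranked nodes (a statistical-complexity reading); at w = n the
#' measure collapses exactly to the global [rsv()].
#'
#' @inheritParams relative_strengths
#' @param window_size Integer w, 2 <= w <= n. Conventional choices are 4
#'   (small window) and about n/4 (21 for an 85-node parcellation).
#' @param ordering `"own_strength"` or `"population_mean_strength"`.
#' @param population_strengths Length-n vector of cohort-mean node strengths,
#'   required when `ordering = "population_mean_strength"`.
#' @return An `hrsv_result`: one-row tibble with `hrsv`, `window_size`,
#'   `n_windows`, `ordering`, `corrected`, and the per-window SDs in the
#'   attribute `per_window` (also available via [tidy()]).
#' @export
hrsv <- function(net, window_size, corrected = TRUE,
                 ordering = c("own_strength", "population_mean_strength"),
                 population_strengths = NULL,
                 degenerate = c("skip", "error")) {
  stopifnot(inherits(net, "weighted_network"))
  ordering <- match.arg(ordering)
  n <- n_nodes(net)
  if (window_size < 2 || window_size > n) {
    stop("window_size must satisfy 2 <= w <= n", call. = FALSE)
  }
  prof <- relative_strengths(net, corrected, degenerate)
  basis <- switch(ordering,
    own_strength = prof$strength,
    population_mean_strength = {
      if (is.null(population_strengths) || length(population_strengths) != n) {
        stop("population_strengths (length n) required for population ordering",
             call. = FALSE)
      }
      population_strengths
    })
  r_sorted <- prof$rel_strength[order(basis)]
  per_window <- windowed_sd(r_sorted, window_size)
  out <- tibble::tibble(hrsv = mean(per_window),
                        window_size = as.integer(window_size),
                        n_windows = length(per_window),
                        ordering = ordering, corrected = corrected)
  attr(out, "per_window") <- per_window
  class(out) <- c("hrsv_result", class(out))
  out
}

# sample SDs of all length-w contiguous windows of x (already sorted)
windowed_sd <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n - w + 1), function(k) stats::sd(x[k:(k + w - 1)]),
         numeric(1))
}

#' @export
tidy.hrsv_result <- function(x, ...) {
  pw <- attr(x, "per_window")
  tibble::tibble(window = seq_along(pw), sd = pw)
}

#' @export
glance.hrsv_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
autoplot.hrsv_result <- function(object, ...) {
  d <- tidy.hrsv_result(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window, y = .data$sd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$hrsv, linetype = "dashed") +
    ggplot2::labs(x = "window (ascending strength rank)",
                  y = "relative-strength SD within window",
                  title = sprintf("hRSV profile (w = %d, mean = %.4g)",
                                  object$window_size, object$hrsv))
}

#' Partition nodes into strength tiers
#'
#' Ranks nodes in descending order of a strength basis and cuts the ranking
#' into `n_tiers` contiguous blocks of near-equal size (sizes differ by at
#' most one; the larger blocks go to the top tiers). Tier 1 holds the
#' highest-strength nodes — for connectomes, the rich-club / hub end of the
#' hierarchy.
#'
#' @param strength_basis Numeric vector (node strengths or cohort means).
#' @param n_tiers Number of tiers (default 4).
#' @return Tibble with `node_index`, `basis`, `rank`, `tier`.
#' @examples
#' assign_tiers(85:1, 4) |> dplyr::count(tier)   # 22, 21, 21, 21
#' @export
assign_tiers <- function(strength_basis, n_tiers = 4) {
  n <- length(strength_basis)
  if (n_tiers < 1) stop("n_tiers must be >= 1", call. = FALSE)
  if (n < n_tiers) stop("need at least one node per tier", call. = FALSE)
  sizes <- rep(n %/% n_tiers, n_tiers)
  extra <- n %% n_tiers
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(-strength_basis)  # descending; ties by original order
  tier <- integer(n)
  tier[ord] <- rep(seq_len(n_tiers), times = sizes)
  rank_desc <- integer(n)
  rank_desc[ord] <- seq_len(n)
  tibble::tibble(node_index = seq_len(n), basis = strength_basis,
                 rank = rank_desc, tier = tier)
}

#' Windowed variability within strength tiers
#'
#' Computes the sliding-window relative-strength SD restricted to each
#' tier's nodes: relative strengths come from the full network, the window
#' slides over the tier's nodes only, in ascending order of the same
#' strength basis used for tier assignment.
#'
#' @inheritParams hrsv
#' @param tiers Tier assignment from [assign_tiers()] on the same nodes.
#' @return Tibble with one row per tier: `tier`, `n_nodes`, `hrsv`,
#'   `n_windows`.
#' @export
tier_hrsv <- function(net, tiers, window_size, corrected = TRUE,
                      degenerate = c("skip", "error")) {
  stopifnot(inherits(net, "weighted_network"))
  n <- n_nodes(net)
  if (nrow(tiers) != n) stop("tier assignment does not match network size",
                             call. = FALSE)
  prof <- relative_strengths(net, corrected, degenerate)
  purrr::map_dfr(sort(unique(tiers$tier)), function(t) {
    idx <- tiers$node_index[tiers$tier == t]
    if (length(idx) < window_size) {
      stop(sprintf("tier %d has %d nodes, fewer than window size %d",
                   t, length(idx), window_size), call. = FALSE)
    }
    basis <- tiers$basis[match(idx, tiers$node_index)]
    r_sorted <- prof$rel_strength[idx][order(basis)]
    pw <- windowed_sd(r_sorted, window_size)
    tibble::tibble(tier = t, n_nodes = length(idx), hrsv = mean(pw),
                   n_windows = length(pw))
  })
}
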