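#' Generate a synthetic weighted network
#'
#' Produces weighted, undirected networks from archetypal families used to
#' validate strength-variability measures:
#'
#' * `er` — Erdős–Rényi G(n, m): m edges sampled uniformly.
#' * `geometric` — random geometric graph: uniform points on the unit square,
#'   the m spatially closest pairs connected.
#' * `hetero_geometric` — geometric graph with heavy-tailed per-node radii
#'   (Pareto, shape `pareto_alpha`): pairs ranked by distance scaled down by
#'   the endpoint radii, giving a heterogeneous degree distribution. These
#'   are the structurally diverse networks on which windowed variability
#'   (statistical complexity) is high.
#' * `star_like` / `core_periphery` — a designated hub set (10% / 25% of
#'   nodes) densely tied to the periphery, sparse periphery–periphery ties;
#'   high global RSV by construction.
#' * `lattice` / `regular` — ring lattice of even degree; the regular,
#'   strength-homogeneous end of the spectrum (RSV = 0 under uniform
#'   weights).
#'
#' Edge count is fixed at `round(density * n(n-1)/2)` wherever the family
#' permits (the ring lattice rounds to the nearest even degree). Weights are
#' drawn per the weight model: `uniform` (all 1), `lognormal`
#' (iid, meanlog 0, sdlog `lognormal_sigma`), or `distance_decay`
#' (\eqn{1/(\epsilon + d_{ij})} using the generator's point positions).
#' Output is reproducible bit-for-bit for a fixed seed.
#'
#' @param family Generator family tag (see above).
#' @param n Node count (>= 4); default 85, matching a Desikan–Killiany
#'   connectome parcellation.
#' @param density Target edge density in (0, 1]; default 0.6, typical of a
#'   group-thresholded structural connectome.
#' @param weight_model `"uniform"`, `"lognormal"` or `"distance_decay"`.
#' @param seed Integer seed.
#' @param lognormal_sigma sdlog of lognormal weights (default 0.5).
#' @param pareto_alpha Tail index of the heterogeneous radii (default 2).
#' @param core_frac Hub fraction override for the hub families.
#' @return A `weighted_network` with `weight_kind = "other"`.
#' @examples
#' net <- generate_network("hetero_geometric", n = 40, density = 0.3, seed = 1)
#' rsv(net)
#' @export
generate_network <- function(family = c("er", "geometric", "hetero_geometric",
                                        "star_like", "core_periphery",
                                        "lattice", "regular"),
                             n = 85, density = 0.6,
                             weight_model = c("lognormal", "uniform",
                                              "distance_decay"),
                             seed = 1, lognormal_sigma = 0.5,
                             pareto_alpha = 2, core_frac = NULL) {
  family <- match.arg(family)
  weight_model <- match.arg(weight_model)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must be in (0, 1]",
                                        call. = FALSE)
  n_pairs <- n * (n - 1) / 2
  m <- round(density * n_pairs)
  if (m < 1) stop("density too low: no edges at this n", call. = FALSE)

  withr::with_seed(seed, {
    pos <- cbind(stats::runif(n), stats::runif(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d <- sqrt((pos[pairs[, 1], 1] - pos[pairs[, 2], 1])^2 +
              (pos[pairs[, 1], 2] - pos[pairs[, 2], 2])^2)

    chosen <- switch(family,
      er = sample(n_pairs, m),
      geometric = order(d)[seq_len(m)],
      hetero_geometric = {
        radii <- (1 - stats::runif(n))^(-1 / pareto_alpha)  # Pareto(alpha)
        score <- d / (radii[pairs[, 1]] + radii[pairs[, 2]])
        order(score)[seq_len(m)]
      },
      star_like = hub_pairs(pairs, n, m, core_frac %||% 0.1),
      core_periphery = hub_pairs(pairs, n, m, core_frac %||% 0.25),
      lattice = ,
      regular = {
        k <- max(2, 2 * round(density * (n - 1) / 2))  # even ring degree
        if (k > n - 1) k <- if ((n - 1) %% 2 == 0) n - 1 else n - 2
        ring <- ring_lattice_pairs(pairs, n, k)
        ring
      })

    w <- matrix(0, n, n)
    weights <- switch(weight_model,
      uniform = rep(1, length(chosen)),
      lognormal = stats::rlnorm(length(chosen), 0, lognormal_sigma),
      distance_decay = 1 / (0.05 + d[chosen]))
    idx <- cbind(pairs[chosen, 1], pairs[chosen, 2])
    w[idx] <- weights
    w[idx[, c(2, 1)]] <- weights
    weighted_network(w)
  })
}

# select m pairs favouring a hub core: one hub tie per periphery node is
# guaranteed (no isolated nodes), then the remaining core-involving pairs in
# random order, then periphery-periphery pairs
hub_pairs <- function(pairs, n, m, core_frac) {
  n_core <- max(1, round(core_frac * n))
  if (m < n - n_core) {
    stop("density too low for a connected hub archetype", call. = FALSE)
  }
  core <- seq_len(n_core)
  anchor <- vapply(setdiff(seq_len(n), core), function(v) {
    hub <- sample(core, 1)
    which((pairs[, 1] == min(hub, v)) & (pairs[, 2] == max(hub, v)))
  }, integer(1))
  involves_core <- pairs[, 1] %in% core | pairs[, 2] %in% core
  first <- sample(setdiff(which(involves_core), anchor))
  rest <- sample(which(!involves_core))
  c(anchor, first, rest)[seq_len(m)]
}

# ring lattice: each node tied to its k/2 nearest neighbours on each side
ring_lattice_pairs <- function(pairs, n, k) {
  half <- k / 2
  keep <- logical(nrow(pairs))
  for (idx in seq_len(nrow(pairs))) {
    gap <- pairs[idx, 2] - pairs[idx, 1]
    ring_gap <- min(gap, n - gap)
    keep[idx] <- ring_gap <= half
  }
  which(keep)
}

#' Generate a synthetic cohort with between-subject variability
#'
#' Builds a base network from the generator spec, then derives one network
#' per subject by (i) multiplying each edge weight by iid lognormal noise
#' (sdlog = `subject_noise`) and (ii) dropping each edge independently with
#' probability `dropout`. Subject metadata (age in years, sex, MRI site) is
#' drawn to resemble a large ageing-cohort imaging study: age normal with
#' mean 63.9 and SD 7.65 truncated to \[44.6, 82.7\], 46.6% male, three sites
#' with visit shares 58/16/26%.
#'
#' @inheritParams generate_network
#' @param n_subjects Number of subjects.
#' @param subject_noise sdlog of the per-edge multiplicative lognormal noise
#'   (0 disables weight noise).
#' @param dropout Per-edge dropout probability per subject (default 0.1).
#' @param ... Passed on to [generate_network()].
#' @return A `cohort` with metadata columns `age`, `sex`, `site`.
#' @export
generate_cohort <- function(family = "hetero_geometric", n = 85,
                            density = 0.6, n_subjects = 50,
                            subject_noise = 0.25, dropout = 0.1, seed = 1,
                            ...) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (subject_noise < 0) stop("subject_noise must be >= 0", call. = FALSE)
  base <- generate_network(family, n = n, density = density, seed = seed, ...)
  ut <- upper.tri(base$weights)
  withr::with_seed(seed + 1L, {
    nets <- lapply(seq_len(n_subjects), function(s) {
      w <- base$weights
      noise <- matrix(1, n, n)
      noise[ut] <- stats::rlnorm(sum(ut), 0, subject_noise)
      keep <- matrix(TRUE, n, n)
      if (dropout > 0) keep[ut] <- stats::runif(sum(ut)) >= dropout
      w[ut] <- w[ut] * noise[ut] * keep[ut]
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      weighted_network(w, base$node_labels, base$weight_kind)
    })
    metadata <- tibble::tibble(
      age = pmin(pmax(stats::rnorm(n_subjects, 63.92, 7.65), 44.6), 82.7),
      sex = factor(ifelse(stats::runif(n_subjects) < 0.466, "M", "F"),
                   levels = c("F", "M")),
      site = factor(sample(c("Site1", "Site2", "Site3"), n_subjects,
                           replace = TRUE, prob = c(0.58, 0.16, 0.26)))
    )
    cohort(nets, paste0("S", seq_len(n_subjects)), metadata)
  })
}
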