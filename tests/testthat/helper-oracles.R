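# Independent straight-line oracles: deliberately naive loop code with no
# shared internals with the package, used to cross-check the vectorised
# implementations.

oracle_strengths <- function(w) {
  sapply(seq_len(nrow(w)), function(i) sum(w[i, ]))
}

oracle_rel_strengths <- function(w, corrected = FALSE) {
  n <- nrow(w)
  s <- oracle_strengths(w)
  r <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (!corrected) {
      r[i] <- s[i] / mean(s[nb])
    } else {
      terms <- c()
      for (j in nb) {
        den <- s[i] - w[i, j]
        if (den > 0) terms <- c(terms, (s[j] - w[i, j]) / den)
      }
      if (length(terms) == 0 || mean(terms) <= 0) {
        r[i] <- s[i] / mean(s[nb])
      } else {
        r[i] <- 1 / mean(terms)
      }
    }
  }
  r
}

oracle_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

oracle_rsv <- function(w, corrected = FALSE) {
  oracle_sd(oracle_rel_strengths(w, corrected))
}

oracle_hrsv <- function(w, wsize, corrected = FALSE, basis = NULL) {
  r <- oracle_rel_strengths(w, corrected)
  if (is.null(basis)) basis <- oracle_strengths(w)
  r <- r[order(basis)]
  n <- length(r)
  sds <- numeric(n - wsize + 1)
  for (k in seq_len(n - wsize + 1)) {
    sds[k] <- oracle_sd(r[k:(k + wsize - 1)])
  }
  mean(sds)
}

# all-pairs shortest paths by Floyd-Warshall on lengths 1/w
oracle_routing_efficiency <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) total <- total + 1 / d[i, j]
    }
  }
  total / (n * (n - 1))
}

# Monte-Carlo mean first-passage time of the weight-proportional walk;
# returns the mean and its standard error over n_walkers walkers
oracle_mfpt_mc <- function(w, from, to, n_walkers = 2000, max_steps = 1e5) {
  n <- nrow(w)
  p <- w / rowSums(w)
  pos <- rep(from, n_walkers)
  steps <- rep(NA_real_, n_walkers)
  active <- rep(TRUE, n_walkers)
  t <- 0
  while (any(active) && t < max_steps) {
    t <- t + 1
    cur <- pos                       # snapshot so each walker moves once
    for (node in unique(cur[active])) {
      at <- which(active & cur == node)
      pos[at] <- sample.int(n, length(at), replace = TRUE, prob = p[node, ])
    }
    arrived <- active & pos == to
    steps[arrived] <- t
    active[arrived] <- FALSE
  }
  stopifnot(!any(active))
  list(mean = mean(steps), se = sd(steps) / sqrt(n_walkers))
}

# connected random graph with integer weights in {1, 2, 3}
rand_graph_123 <- function(n, p_edge = 0.6) {
  repeat {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- runif(length(ut)) < p_edge
    w[ut[on]] <- sample(1:3, sum(on), replace = TRUE)
    w <- w + t(w)
    if (all(rowSums(w) > 0) && is_connected_bfs(w)) return(w)
  }
}

is_connected_bfs <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# convenience constructors
star4 <- function() {
  weighted_network(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0),
                         c(1, 0, 0, 0)))
}

k_complete <- function(n, weight = 1) {
  weighted_network(matrix(weight, n, n) - diag(weight, n))
}
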