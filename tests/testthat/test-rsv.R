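test_that("relative strengths match hand-derived values on canonical graphs", {
  # complete graph: both forms give r = 1 everywhere
  k4 <- k_complete(4)
  for (corr in c(TRUE, FALSE)) {
    expect_equal(relative_strengths(k4, corrected = corr)$rel_strength,
                 rep(1, 4))
  }
  # star: uncorrected r_center = 3, r_leaf = 1/3
  st <- star4()
  r <- relative_strengths(st, corrected = FALSE)$rel_strength
  expect_equal(r, c(3, 1 / 3, 1 / 3, 1 / 3))

  # weighted triangle strengths by hand
  tri <- weighted_network(rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))
  expect_equal(unname(node_strengths(tri)), c(4, 3, 5))

  # isolated node is a named error
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
  expect_error(relative_strengths(weighted_network(w)), "R3")
})

test_that("corrected-form degeneracy is skipped with a warning or raised", {
  st <- star4()  # every leaf has s - W = 0 on its only edge
  expect_warning(r <- relative_strengths(st, corrected = TRUE), "degenerate")
  expect_error(relative_strengths(st, corrected = TRUE,
                                  degenerate = "error"), "degenerate")
  # the center's terms (s_c - W = 2 > 0) survive: r_center finite
  expect_true(all(is.finite(r$rel_strength)))
})

test_that("corrected and uncorrected forms agree with the loop oracle", {
  withr::local_seed(11)
  for (rep in 1:50) {
    w <- rand_graph_123(sample(4:6, 1))
    net <- weighted_network(w)
    for (corr in c(FALSE, TRUE)) {
      got <- suppressWarnings(
        relative_strengths(net, corrected = corr)$rel_strength)
      expect_equal(got, oracle_rel_strengths(w, corr), tolerance = 1e-12)
    }
  }
})

test_that("rsv is the sample SD of relative strengths; star value is 4/3", {
  expect_equal(rsv(star4(), corrected = FALSE)$rsv, 4 / 3)
  res <- rsv(k_complete(4))
  expect_equal(res$rsv, 0)
  expect_equal(res$variance, 0)
  expect_equal(res$mu_r, 1)
  # variance field is the square of the reported SD
  w <- rand_graph_123(5)
  r2 <- rsv(weighted_network(w), corrected = FALSE)
  expect_equal(r2$variance, r2$rsv^2)
  expect_error(rsv(weighted_network(matrix(0, 1, 1))), "2 nodes")
})

test_that("hrsv slides rank windows and collapses to rsv at w = n", {
  withr::local_seed(23)
  for (rep in 1:20) {
    w <- rand_graph_123(6)
    net <- weighted_network(w)
    res <- hrsv(net, 4, corrected = FALSE)
    expect_equal(res$n_windows, 3)  # n - w + 1
    expect_equal(length(attr(res, "per_window")), 3)
    expect_equal(res$hrsv, oracle_hrsv(w, 4), tolerance = 1e-12)
    expect_equal(hrsv(net, 6, corrected = FALSE)$hrsv,
                 rsv(net, corrected = FALSE)$rsv)
  }
  net <- weighted_network(rand_graph_123(6))
  expect_error(hrsv(net, 1), "window_size")
  expect_error(hrsv(net, 7), "window_size")
  expect_equal(hrsv(k_complete(5), 3)$hrsv, 0)
})

test_that("population-mean ordering reranks the windows", {
  withr::local_seed(31)
  w <- rand_graph_123(6)
  net <- weighted_network(w)
  pop <- rev(seq_len(6))  # deliberately different from own strengths
  got <- hrsv(net, 3, corrected = FALSE,
              ordering = "population_mean_strength",
              population_strengths = pop)
  expect_equal(got$hrsv, oracle_hrsv(w, 3, basis = pop), tolerance = 1e-12)
  expect_error(hrsv(net, 3, ordering = "population_mean_strength"),
               "population_strengths")
})

test_that("rsv and hrsv match the loop oracle over many random graphs", {
  withr::local_seed(97)
  for (rep in 1:300) {
    n <- sample(4:6, 1)
    w <- rand_graph_123(n)
    net <- weighted_network(w)
    expect_equal(rsv(net, corrected = FALSE)$rsv, oracle_rsv(w),
                 tolerance = 1e-12)
    wsize <- sample(2:n, 1)
    expect_equal(hrsv(net, wsize, corrected = FALSE)$hrsv,
                 oracle_hrsv(w, wsize), tolerance = 1e-12)
  }
})

test_that("r, rsv and hrsv are invariant under global weight scaling", {
  withr::local_seed(5)
  w <- rand_graph_123(6)
  net <- weighted_network(w)
  for (c in c(0.01, 3, 1e4)) {
    scaled <- weighted_network(w * c)
    for (corr in c(FALSE, TRUE)) {
      suppressWarnings({       # corrected terms may degenerate at leaves
        expect_equal(relative_strengths(scaled, corr)$rel_strength,
                     relative_strengths(net, corr)$rel_strength,
                     tolerance = 1e-12)
        expect_equal(rsv(scaled, corr)$rsv, rsv(net, corr)$rsv,
                     tolerance = 1e-12)
        expect_equal(hrsv(scaled, 3, corr)$hrsv, hrsv(net, 3, corr)$hrsv,
                     tolerance = 1e-12)
      })
    }
  }
})

test_that("regular uniform graphs have r = 1 and zero variability", {
  ring <- generate_network("regular", n = 16, density = 0.4,
                           weight_model = "uniform", seed = 2)
  expect_equal(relative_strengths(ring)$rel_strength, rep(1, 16))
  expect_equal(rsv(ring)$rsv, 0)
  for (w in c(2, 5, 16)) expect_equal(hrsv(ring, w)$hrsv, 0)
})

test_that("tier assignment partitions ranks with larger blocks on top", {
  t85 <- assign_tiers(stats::runif(85), 4)
  expect_equal(as.integer(table(t85$tier)), c(22, 21, 21, 21))
  t8 <- assign_tiers(8:1, 4)
  expect_equal(as.integer(table(t8$tier)), c(2, 2, 2, 2))
  # highest strength lands in tier 1
  basis <- c(10, 9, 8, 7, 6, 5)
  expect_equal(assign_tiers(basis, 3)$tier[1], 1L)
  expect_equal(assign_tiers(basis, 3)$tier[6], 3L)
  expect_error(assign_tiers(1:3, 0), "n_tiers")
  expect_error(assign_tiers(1:3, 4), "per tier")
})

test_that("tier_hrsv restricts windows to tiers and matches the oracle", {
  withr::local_seed(12)
  w <- rand_graph_123(12, p_edge = 0.7)
  net <- weighted_network(w)
  s <- rowSums(w)
  tiers <- assign_tiers(s, 4)
  res <- tier_hrsv(net, tiers, window_size = 2, corrected = FALSE)
  expect_equal(nrow(res), 4)
  r_full <- oracle_rel_strengths(w)
  for (t in 1:4) {
    idx <- tiers$node_index[tiers$tier == t]
    r_t <- r_full[idx][order(s[idx])]
    sds <- sapply(seq_len(length(r_t) - 1),
                  function(k) oracle_sd(r_t[k:(k + 1)]))
    expect_equal(res$hrsv[res$tier == t], mean(sds), tolerance = 1e-12)
  }
  # tier of exactly window size: single window
  expect_equal(res$n_windows[1], length(which(tiers$tier == 1)) - 1)
  expect_error(tier_hrsv(net, tiers, window_size = 4), "fewer than window")
  # all-equal relative strengths give zero in every tier
  k <- k_complete(8)
  tk <- assign_tiers(node_strengths(k), 4)
  expect_equal(tier_hrsv(k, tk, 2)$hrsv, rep(0, 4))
})

test_that("hrsv_result supports tidy, glance and autoplot", {
  net <- generate_network("er", n = 12, density = 0.6, seed = 4)
  res <- hrsv(net, 4)
  td <- tidy(res)
  expect_equal(nrow(td), res$n_windows)
  expect_equal(mean(td$sd), res$hrsv)
  expect_s3_class(glance(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
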