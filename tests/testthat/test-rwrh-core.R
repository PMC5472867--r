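test_that("seed vector splits mass eta to diseases, 1-eta to genes", {
  net <- micro_net()
  p0 <- build_seed_vector(net, "g1", "d1", eta = 0.7)
  expect_equal(unname(p0), c(0.3, 0, 0, 0.7, 0))
  expect_equal(sum(p0), 1)

  # disease class: eta mass split over the class
  p0c <- build_seed_vector(net, "g1", c("d1", "d2"), eta = 0.7)
  expect_equal(unname(p0c), c(0.3, 0, 0, 0.35, 0.35))

  # case-study arithmetic: 21 seed genes, one disease
  net21 <- random_hetnet(1, n_g = 30, n_d = 3)
  seeds <- net21$genes[1:21]
  p21 <- build_seed_vector(net21, seeds, net21$diseases[1], eta = 0.7)
  expect_equal(unname(p21[seeds]), rep(0.3 / 21, 21))
  expect_equal(unname(p21[net21$diseases[1]]), 0.7)

  # no known genes: all mass on the seed disease(s)
  p0e <- build_seed_vector(net, character(), "d1", eta = 0.7)
  expect_equal(unname(p0e), c(0, 0, 0, 1, 0))

  expect_error(build_seed_vector(net, "g1", character()),
    class = "rwrhnet_parameter_error"
  )
  expect_error(build_seed_vector(net, "gX", "d1"), "gX",
    class = "rwrhnet_validation_error"
  )
})

test_that("micro-network steady state matches the direct linear solve", {
  net <- micro_net()
  tm <- build_transition(net, lambda = 0.5)
  p0 <- build_seed_vector(net, "g1", "d1", eta = 0.7)
  ss <- rwrh_steady_state(tm, p0, gamma = 0.5, tol = 1e-12)
  # values pinned from the dense linear solve before the build
  expect_equal(unname(ss$p), c(
    0.2916666666666667, 0.0833333333333333, 0.0208333333333333,
    0.4833333333333333, 0.1208333333333333
  ), tolerance = 1e-9)
  oracle <- linear_solve_oracle(tm$M, p0, 0.5)
  expect_lt(sum(abs(ss$p - oracle)), 1e-10)
  # g1 scores highest among genes
  gene_scores <- ss$p[net$genes]
  expect_equal(names(which.max(gene_scores)), "g1")
})

test_that("power iteration agrees with the linear solve on random networks", {
  for (seed in 1:20) {
    net <- random_hetnet(seed)
    gam <- c(0.3, 0.5, 0.7)[(seed %% 3) + 1]
    tm <- build_transition(net, lambda = 0.6)
    seeds_d <- net$diseases[1]
    seeds_g <- known_genes(net, seeds_d)
    p0 <- build_seed_vector(net, seeds_g, seeds_d, eta = 0.7)
    ss <- rwrh_steady_state(tm, p0, gamma = gam, tol = 1e-12)
    oracle <- linear_solve_oracle(tm$M, p0, gam)
    expect_lt(sum(abs(ss$p - oracle)), 1e-8)
    expect_equal(sum(ss$p), 1, tolerance = 1e-9)
  }
})

test_that("every iterate conserves probability mass", {
  net <- random_hetnet(4)
  tm <- build_transition(net, lambda = 0.6)
  p0 <- build_seed_vector(net, character(), net$diseases[1])
  Mt <- Matrix::t(tm$M)
  p <- p0
  for (i in 1:50) {
    p <- as.numeric(0.5 * (Mt %*% p)) + 0.5 * p0
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("the fixed point does not depend on the starting vector", {
  net <- random_hetnet(8)
  tm <- build_transition(net, lambda = 0.6)
  p0 <- build_seed_vector(net, known_genes(net, net$diseases[1]),
    net$diseases[1],
    eta = 0.7
  )
  tol <- 1e-11
  ss_seed <- rwrh_steady_state(tm, p0, gamma = 0.5, tol = tol)
  uniform <- rep(1 / nrow(tm$M), nrow(tm$M))
  ss_unif <- rwrh_steady_state(tm, p0, gamma = 0.5, tol = tol, p_start = uniform)
  expect_lt(sum(abs(ss_seed$p - ss_unif$p)), 10 * tol)
})

test_that("gamma near 1 pins the steady state to the seed vector", {
  net <- micro_net()
  tm <- build_transition(net, lambda = 0.5)
  p0 <- build_seed_vector(net, "g1", "d1", eta = 0.7)
  ss <- rwrh_steady_state(tm, p0, gamma = 0.999999, tol = 1e-12)
  expect_lt(sum(abs(ss$p - p0)), 1e-5)
})

test_that("non-convergence raises a condition carrying the last iterate", {
  net <- micro_net()
  tm <- build_transition(net, lambda = 0.5)
  p0 <- build_seed_vector(net, "g1", "d1", eta = 0.7)
  err <- tryCatch(
    rwrh_steady_state(tm, p0, gamma = 0.5, tol = 1e-14, max_iter = 3),
    rwrhnet_no_convergence = function(e) e
  )
  expect_s3_class(err, "rwrhnet_no_convergence")
  expect_length(err$p_last, 5)
  expect_equal(sum(err$p_last), 1, tolerance = 1e-9)
})

test_that("increasing eta increases the steady-state mass on the disease layer", {
  net <- micro_net()
  tm <- build_transition(net, lambda = 0.5)
  masses <- vapply(seq(0.1, 0.9, 0.1), function(eta) {
    p0 <- build_seed_vector(net, "g1", "d1", eta = eta)
    sum(linear_solve_oracle(tm$M, p0, 0.5)[4:5])
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
})

test_that("candidate ranking sorts by score with lexicographic tie-break", {
  net <- micro_net()
  p_inf <- c(g1 = 0.3, g2 = 0.5, g3 = 0.3, d1 = 0.6, d2 = 0.1)
  r <- rank_candidates(net, p_inf, c("g1", "g2", "g3"), "d2")
  genes <- r[r$type == "gene", ]
  expect_equal(genes$id, c("g2", "g1", "g3")) # tie g1/g3 broken by id
  expect_equal(genes$rank, 1:3)
  expect_equal(r$id[r$type == "disease"], "d2")

  # empty candidate sets give empty rankings
  expect_equal(nrow(rank_candidates(net, p_inf, character(), character())), 0)

  # overlap with the seed set is rejected
  expect_error(
    rank_candidates(net, p_inf, "g1", character(), seed_genes = "g1"),
    class = "rwrhnet_validation_error"
  )
})

test_that("rwrh_rank composes seeding, propagation and ranking", {
  net <- micro_net()
  fit <- rwrh_rank(net, "d1", params = rwrh_params(gamma = 0.5, lambda = 0.5))
  # seed genes default to the bipartite-known genes of d1
  expect_equal(fit$seed_genes, "g1")
  expect_equal(sort(fit$ranking$id[fit$ranking$type == "gene"]), c("g2", "g3"))
  expect_equal(fit$ranking$id[fit$ranking$type == "disease"], "d2")
  # scores come from the steady state of the same network
  oracle <- linear_solve_oracle(
    build_transition(net, 0.5)$M,
    build_seed_vector(net, "g1", "d1", 0.7), 0.5
  )
  expect_equal(
    fit$ranking$score[fit$ranking$id == "g2"],
    unname(oracle[2]),
    tolerance = 1e-8
  )

  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_true(all(td$is_seed[td$id %in% c("g1", "d1")]))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 3)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("seeds in one component dominate nodes in another", {
  # two disconnected gene/disease islands; only restart mass reaches island 2
  gn <- gene_network(tibble::tibble(
    from = c("g1", "g3"), to = c("g2", "g4")
  ))
  dn <- disease_network(tibble::tibble(
    from = c("dA", "dC"), to = c("dB", "dD"), weight = 1
  ))
  bp <- bipartite_assoc(tibble::tibble(
    disease = c("dA", "dC"), gene = c("g1", "g3")
  ))
  net <- assemble_heterogeneous(gn, dn, bp)
  tm <- build_transition(net, lambda = 0.5)
  p0 <- build_seed_vector(net, "g1", "dA", eta = 0.7)
  p <- linear_solve_oracle(tm$M, p0, 0.5)
  names(p) <- c(net$genes, net$diseases)
  island2 <- c("g3", "g4", "dC", "dD")
  expect_equal(unname(p[island2]), rep(0, 4))
  expect_gt(min(p[c("g1", "dA")]), max(p[island2]))
})
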