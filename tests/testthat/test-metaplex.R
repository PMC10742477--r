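test_that("metaplex DOF layout matches the complex and resolution", {
  K <- fig4_complex()
  M <- build_metaplex(K, nodes_per_edge = 20)
  expect_equal(M$n_dof, 5L + 6L * 20L + 2L * 210L)  # 545
  expect_equal(M$labels, simplex_labels(K))
  expect_equal(sum(M$measure), 13)

  # every sink-source joins dimension-adjacent domains
  gaps <- vapply(M$sink_sources, function(ss) {
    abs(M$domains[[ss$i]]$dim - M$domains[[ss$j]]$dim)
  }, 1L)
  expect_true(all(gaps == 1L))

  # incidences: 2 couplings per edge + 3 per triangle
  expect_length(M$sink_sources, 6L * 2L + 2L * 3L)

  expect_error(build_metaplex(clique_complex(smx_graph(data.frame(
    from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4)
  )), max_dim = 3), 4), "dimension <= 2")
})

test_that("triangle sides are matched one-to-one onto their edge domains", {
  K <- k3_complex()
  M <- build_metaplex(K, nodes_per_edge = 3)
  tri_ss <- Filter(function(ss) M$domains[[ss$i]]$dim == 2L, M$sink_sources)
  expect_length(tri_ss, 3L)
  for (ss in tri_ss) {
    expect_equal(nrow(ss$pairs), 3L)
    # one-to-one: no node reused on either side
    expect_false(anyDuplicated(ss$pairs[, 1]) > 0)
    expect_false(anyDuplicated(ss$pairs[, 2]) > 0)
  }
  # matched boundary nodes carry identical positions along the side:
  # endpoints of the side coincide with the edge-domain endpoints
  for (ss in tri_ss) {
    expect_equal(ss$pairs[, 2], 1:3)
  }
})

test_that("the assembled generator is symmetric, conservative and Metzler", {
  for (M in list(build_metaplex(fig4_complex(), 5),
                 build_metaplex(k3_complex(), 4, kappa = 2.5),
                 two_domain_metaplex(nodes_per_edge = 9))) {
    S <- M$S
    expect_zero_matrix(S - Matrix::t(S))
    expect_lt(max(abs(Matrix::colSums(S))), 1e-12)
    expect_lt(max(abs(S %*% rep(1, M$n_dof))), 1e-12)
    off <- S - Matrix::Diagonal(x = Matrix::diag(S))
    expect_lte(max(as.matrix(off)), 0)
    expect_equal(length(M$D), M$n_dof)
    expect_true(all(M$D > 0))
  }
})

test_that("a connected metaplex has a one-dimensional kernel of constants", {
  M <- build_metaplex(fig4_complex(), 5)
  ev <- eigen(as.matrix(M$S), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 1L)
  expect_gte(min(ev), -1e-10)
})

test_that("transition matrix summarizes coupling conductances with zero column sums", {
  # two identical domains, one unit coupling: the worked 2x2 example
  for (sep in c(FALSE, TRUE)) {
    Tm <- transition_matrix(two_domain_metaplex(separated = sep))
    expect_equal(unname(Tm), matrix(c(-1, 1, 1, -1), 2))
  }

  M <- build_metaplex(fig4_complex(), 4)
  Tm <- transition_matrix(M)
  expect_equal(unname(Tm), unname(t(Tm)))
  expect_lt(max(abs(colSums(Tm))), 1e-12)

  # aggregating the coupling part of S over domains reproduces T
  C <- M$S - Matrix::bdiag(lapply(M$domains, function(d) d$stiffness))
  nd <- length(M$domains)
  agg <- matrix(0, nd, nd)
  grp <- rep(seq_len(nd), vapply(M$domains, function(d) d$n_nodes, 1L))
  Cd <- as.matrix(C)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      agg[i, j] <- sum(Cd[grp == i, grp == j])
    }
  }
  expect_equal(-agg, unname(Tm), tolerance = 1e-12)
})

test_that("normalized conductance mode spreads kappa across matched pairs", {
  Mp <- build_metaplex(k3_complex(), 5, kappa = 1, kappa_mode = "per_pair")
  Mn <- build_metaplex(k3_complex(), 5, kappa = 1, kappa_mode = "normalized")
  Tp <- transition_matrix(Mp)
  Tn <- transition_matrix(Mn)
  # triangle-edge couplings: 5 pairs of kappa vs 5 pairs of kappa/5
  tri <- which(Mp$dims == 2L)
  edge <- which(Mp$dims == 1L)[1]
  expect_equal(Tp[tri, edge], 5)
  expect_equal(Tn[tri, edge], 1)
})

test_that("metaplex export writes readable plain-text artifacts", {
  M <- two_domain_metaplex(nodes_per_edge = 4)
  stem <- withr::local_tempfile()
  paths <- write_metaplex(M, stem)
  S2 <- Matrix::readMM(paste0(stem, "_S.mtx"))
  expect_equal(as.matrix(S2), as.matrix(M$S), tolerance = 1e-12)
  mass <- utils::read.csv(paste0(stem, "_mass.csv"))
  expect_equal(mass$mass, M$D)
})
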