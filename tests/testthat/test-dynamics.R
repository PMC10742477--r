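test_that("initial conditions carry exactly the requested mass", {
  M <- build_metaplex(fig4_complex(), 5)

  u <- initial_condition(M, ic_delta("2:1-2-3", mass = 1))
  expect_equal(sum(M$D * u), 1, tolerance = 1e-12)
  rng <- M$offsets[12] + seq_len(M$domains[[12]]$n_nodes)
  expect_equal(unique(u[rng]), 1)      # unit measure: density equals mass
  expect_equal(sum(abs(u[-rng])), 0)

  Mk <- build_metaplex(k3_complex(), 4)
  u_deg <- initial_condition(Mk, "degree")
  totals0 <- vapply(seq_along(Mk$domains), function(i) {
    r <- Mk$offsets[i] + seq_len(Mk$domains[[i]]$n_nodes)
    sum(Mk$D[r] * u_deg[r])
  }, 1)
  expect_equal(totals0[Mk$dims == 0L], rep(2, 3))  # every K3 vertex has degree 2
  expect_equal(totals0[Mk$dims > 0L], rep(0, 4))

  tab <- data.frame(simplex = c("0:1", "1:3-4"), mass = c(0.3, 1.7))
  u_tab <- initial_condition(M, tab)
  expect_equal(sum(M$D * u_tab), 2, tolerance = 1e-12)

  u_rnd <- initial_condition(M, ic_uniform_random(seed = 11))
  expect_true(all(u_rnd >= 0))
  expect_equal(u_rnd, initial_condition(M, ic_uniform_random(seed = 11)))

  expect_error(initial_condition(M, ic_delta("2:9-9-9")), "unknown simplex")
})

test_that("metaplex diffusion conserves mass, preserves positivity and reaches consensus", {
  M <- build_metaplex(fig4_complex(), 5)
  u0 <- initial_condition(M, fig3_ic())
  cons <- consensus_value(u0, M)
  expect_equal(cons, 3 / 13, tolerance = 1e-12)

  traj <- integrate_metaplex(M, u0, diffusion_config(dt = 0.02, n_steps = 8000))
  expect_lt(traj$mass_drift, 1e-8)
  expect_gte(traj$min_state, -1e-10)
  # all DOF densities, not just totals, settle at the consensus value
  expect_lt(max(abs(traj$states[, ncol(traj$states)] - cons)), 1e-6)
  final <- traj$totals[, ncol(traj$totals)]
  expect_lt(max(abs(final - cons)), 1e-6)

  expect_error(integrate_metaplex(M, rep(1, 3), diffusion_config()), "DOFs")
})

test_that("positivity holds for random nonnegative initial conditions", {
  M <- build_metaplex(fig4_complex(), 3)
  for (s in 1:50) {
    u0 <- initial_condition(M, ic_uniform_random(seed = 1000 + s))
    traj <- integrate_metaplex(M, u0, diffusion_config(dt = 0.05, n_steps = 60))
    expect_gte(traj$min_state, -1e-10)
    expect_lt(traj$mass_drift, 1e-10)
  }
})

test_that("an isolated domain relaxes to its own uniform density", {
  dom <- discretize_simplex(2, 6)
  M <- metaplexr:::new_metaplex(list(dom), list(), labels = "2:a-b-c", dims = 2L)
  u0 <- numeric(M$n_dof)
  u0[1] <- 2 / M$D[1]   # all mass on one corner node
  traj <- integrate_metaplex(M, u0, diffusion_config(dt = 0.01, n_steps = 3000))
  expect_equal(unname(traj$totals[1, ncol(traj$totals)]), 2, tolerance = 1e-10)
  expect_lt(max(abs(traj$states[, ncol(traj$states)] - 2)), 1e-6)
})

test_that("per-simplex totals reproduce the IC and stay summed to the total mass", {
  M <- build_metaplex(fig4_complex(), 4)
  tab <- data.frame(simplex = c("0:2", "1:3-5", "2:3-4-5"), mass = c(0.5, 1, 0.25))
  traj <- integrate_metaplex(M, initial_condition(M, tab),
                             diffusion_config(dt = 0.02, n_steps = 500))
  t0 <- traj$totals[, 1]
  expect_equal(unname(t0[match(tab$simplex, traj$labels)]), tab$mass, tolerance = 1e-12)
  expect_equal(unname(t0[setdiff(seq_len(13), match(tab$simplex, traj$labels))]),
               rep(0, 10), tolerance = 1e-12)
  expect_lt(max(abs(colSums(traj$totals) - 1.75)), 1e-10)
})

test_that("the long-time state matches the dense null-space projection of S", {
  M <- build_metaplex(fig4_complex(), 3)
  u0 <- initial_condition(M, ic_uniform_random(seed = 5))
  traj <- integrate_metaplex(M, u0, diffusion_config(dt = 0.05, n_steps = 6000))

  # oracle: D-orthogonal projection of u0 onto ker(S), computed by SVD
  sv <- svd(as.matrix(M$S))
  kernel <- sv$u[, sv$d < 1e-10 * max(sv$d), drop = FALSE]
  proj <- kernel %*% solve(crossprod(kernel, M$D * kernel), crossprod(kernel, M$D * u0))
  expect_equal(traj$states[, ncol(traj$states)], as.numeric(proj), tolerance = 1e-8)
})

test_that("implicit Euler and Crank-Nicolson agree to first order in dt", {
  M <- build_metaplex(k3_complex(), 4)
  u0 <- initial_condition(M, ic_delta("0:1", mass = 1))
  at_t1 <- function(scheme, dt) {
    traj <- integrate_metaplex(M, u0, diffusion_config(dt = dt, n_steps = round(1 / dt),
                                                       scheme = scheme, save_every = 1))
    traj$states[, ncol(traj$states)]
  }
  gap <- function(dt) max(abs(at_t1("implicit_euler", dt) - at_t1("crank_nicolson", dt)))
  g1 <- gap(0.02)
  g2 <- gap(0.01)
  expect_gt(g1 / g2, 1.6)   # halving dt about halves the scheme gap
  expect_lt(g2, 0.02)
})

test_that("return probability stabilizes for the metaplex and vanishes for Hodge blocks", {
  K <- fig4_complex()
  M <- build_metaplex(K, 5)
  traj <- integrate_metaplex(M, ic_delta("2:1-2-3", mass = 1),
                             diffusion_config(dt = 0.05, n_steps = 5000))
  rp <- return_probability(traj, "2:1-2-3")
  expect_equal(rp$p[1], 1)
  expect_equal(rp$p[nrow(rp)], 1 / 13, tolerance = 1e-4)
  expect_true(all(rp$p > 0))

  H <- hodge_laplacians(K)
  htraj <- simulate_hodge(H, data.frame(simplex = "2:1-2-3", mass = 1),
                          c(0, 1, 5, 20, 60))
  hrp <- return_probability(htraj, "2:1-2-3")
  expect_equal(hrp$p[1], 1)
  expect_lt(abs(hrp$p[nrow(hrp)]), 1e-10)

  expect_error(return_probability(traj, "0:4"), "no initial mass")
})

test_that("near-empty triangles are flagged as candidate holes", {
  # two triangles sharing only vertex 3: seed all mass in one of them and
  # look before the density has crossed over
  K <- fig4_complex()
  M <- build_metaplex(K, 5)
  traj <- integrate_metaplex(M, ic_delta("2:1-2-3", mass = 1),
                             diffusion_config(dt = 0.01, n_steps = 50, save_every = 1))
  holes <- detect_holes(traj, theta = 0.1, t_eval = 0.5)
  expect_true("2:3-4-5" %in% holes$simplex)
  expect_false("2:1-2-3" %in% holes$simplex)
  # depletion is strongest away from the boundary feeding the triangle
  expect_lt(holes$interior_boundary_ratio[holes$simplex == "2:3-4-5"], 1)

  # theta = 0 can flag nothing
  expect_equal(nrow(detect_holes(traj, theta = 0, t_eval = 0.5)), 0L)

  # a state at consensus has no holes at any theta < 1
  traj_end <- integrate_metaplex(M, ic_delta("2:1-2-3", mass = 1),
                                 diffusion_config(dt = 0.05, n_steps = 6000))
  expect_equal(nrow(detect_holes(traj_end, theta = 0.99,
                                 t_eval = traj_end$times[length(traj_end$times)])), 0L)
})

test_that("model comparison separates the conservative metaplex from the Hodge flow", {
  K <- fig4_complex()
  M <- build_metaplex(K, 5)
  cmp <- compare_models(K, M, fig3_ic(), diffusion_config(dt = 0.05, n_steps = 2000))
  s <- cmp$summary
  expect_equal(s$model, c("hodge", "metaplex"))
  expect_false(s$conservative[1])
  expect_true(s$conservative[2])
  expect_true(s$positive[2])
  expect_gte(s$min_value[2], -1e-10)
  # Hodge settles far from global consensus; metaplex reaches it
  expect_gt(s$consensus_distance[1], 0.1)
  expect_lt(s$consensus_distance[2], 1e-3)
  # continuous intra-simplex diffusion makes metaplex convergence slower
  expect_gt(s$convergence_time[2], s$convergence_time[1])
  expect_identical(cmp$hodge$times, cmp$metaplex$times)
})

test_that("the two-domain variants share a steady state but not transients", {
  run <- function(sep) {
    M <- two_domain_metaplex(separated = sep, nodes_per_edge = 11)
    u0 <- numeric(M$n_dof)
    u0[M$offsets[1] + 11] <- 1 / M$D[M$offsets[1] + 11]  # right end of domain 1
    integrate_metaplex(M, u0, diffusion_config(dt = 0.01, n_steps = 2000, save_every = 1))
  }
  a <- run(FALSE)
  b <- run(TRUE)
  expect_identical(a$times, b$times)
  mid <- which.min(abs(a$times - 2))
  expect_gt(abs(a$totals[1, mid] - b$totals[1, mid]), 1e-3)
  expect_equal(a$totals[, ncol(a$totals)], b$totals[, ncol(b$totals)], tolerance = 1e-6)
  expect_lt(a$mass_drift, 1e-10)
  expect_lt(b$mass_drift, 1e-10)
})

test_that("trajectory tidiers and CSV export expose the totals table", {
  M <- build_metaplex(k3_complex(), 3)
  traj <- integrate_metaplex(M, ic_delta("0:1"), diffusion_config(dt = 0.1, n_steps = 20))
  td <- tidy(traj)
  expect_equal(sort(unique(td$simplex)), sort(M$labels))
  gl <- glance(traj)
  expect_equal(gl$total_mass, 1, tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$simplex, M$labels)
  expect_equal(back[[2]], unname(traj$totals[, 1]))
  p <- ggplot2::ggplot_build(autoplot(traj))
  expect_gt(length(p$data), 0)
})
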