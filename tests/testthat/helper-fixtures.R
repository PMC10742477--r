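# shared fixtures and small utilities for the suite

k3_complex <- function() {
  clique_complex(smx_graph(data.frame(from = c(1, 1, 2), to = c(2, 3, 3))))
}

# seeded family of random clique complexes used by the operator property tests
random_complex_family <- function(n_complexes = 20L, n_vertices = 10L, p = 0.4) {
  lapply(seq_len(n_complexes), function(s) random_clique_complex(n_vertices, p, seed = s))
}

# the canonical pathological initial condition: unit mass on node 1,
# edge (1,2) and triangle (1,2,3)
fig3_ic <- function() {
  data.frame(simplex = c("0:1", "1:1-2", "2:1-2-3"), mass = 1)
}

expect_zero_matrix <- function(m, tol = 1e-12) {
  expect_lt(max(abs(as.matrix(m))), tol)
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
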