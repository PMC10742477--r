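#' Integration settings for metaplex diffusion
#'
#' @param dt Time step (default 0.01).
#' @param n_steps Number of steps (default 10000).
#' @param scheme `"implicit_euler"` (unconditionally positivity-preserving;
#'   the default) or `"crank_nicolson"` (second order, used for
#'   consistency checks).
#' @param steady_tol Optional early-stopping threshold on the relative
#'   state change per step; `NULL` runs all `n_steps`.
#' @param save_every Keep every k-th state column; defaults to thinning to
#'   at most ~1000 saved frames. Running extrema and mass drift are always
#'   tracked over every step, not just saved frames.
#' @param seed Integer seed for stochastic initial conditions.
#' @return A list of class `diffusion_config`.
#' @export
diffusion_config <- function(dt = 0.01, n_steps = 10000L,
                             scheme = c("implicit_euler", "crank_nicolson"),
                             steady_tol = NULL, save_every = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, n_steps >= 1)
  if (is.null(save_every)) save_every <- max(1L, as.integer(floor(n_steps / 1000)))
  structure(
    list(dt = dt, n_steps = as.integer(n_steps), scheme = scheme,
         steady_tol = steady_tol, save_every = as.integer(save_every), seed = seed),
    class = "diffusion_config"
  )
}

#' Build an initial density vector on a metaplex
#'
#' @param M A `metaplex`.
#' @param spec One of:
#'   \itemize{
#'     \item `ic_delta(simplex, mass)`: constant density `mass / measure`
#'       on the named domain (unit measure makes the density equal the
#'       mass), zero elsewhere;
#'     \item `"degree"`: each 0-simplex holds mass equal to its vertex
#'       degree in the 1-skeleton, higher simplices start empty;
#'     \item `"degree-normalized"`: mass 1 on every 0-simplex;
#'     \item `ic_uniform_random(seed)`: independent per-simplex masses
#'       from U(0, 1), each spread uniformly over its domain;
#'     \item a data frame with columns `simplex` (labels as in
#'       [simplex_labels()]) and `mass`, spread uniformly per domain.
#'   }
#' @param seed Optional seed overriding the one in `spec`.
#' @return Numeric density vector of length `M$n_dof`.
#' @export
initial_condition <- function(M, spec, seed = NULL) {
  stopifnot(inherits(M, "metaplex"))
  if (is.character(spec) && length(spec) == 1L) {
    if (spec %in% c("degree", "degree-normalized")) {
      if (is.null(M$complex)) stop("degree initial condition needs an underlying complex", call. = FALSE)
      E <- if (length(M$complex$simplices) >= 2L) M$complex$simplices[[2L]] else
        matrix(integer(0), ncol = 2L)
      deg <- tabulate(c(E[, 1L], E[, 2L]) + 1L, nbins = nrow(M$complex$simplices[[1L]]))
      mass <- numeric(length(M$domains))
      mass[M$dims == 0L] <- if (spec == "degree") deg else 1
      return(spread_masses(M, mass))
    }
    stop("unknown initial-condition spec: ", spec, call. = FALSE)
  }
  if (is.data.frame(spec)) {
    idx <- match(spec$simplex, M$labels)
    if (anyNA(idx)) stop("unknown simplex id: ", spec$simplex[which(is.na(idx))[1L]], call. = FALSE)
    mass <- numeric(length(M$domains))
    mass[idx] <- spec$mass
    return(spread_masses(M, mass))
  }
  if (inherits(spec, "ic_delta")) {
    di <- match(spec$simplex, M$labels)
    if (is.na(di)) stop("unknown simplex id: ", spec$simplex, call. = FALSE)
    mass <- numeric(length(M$domains))
    mass[di] <- spec$mass
    return(spread_masses(M, mass))
  }
  if (inherits(spec, "ic_uniform_random")) {
    s <- if (!is.null(seed)) seed else spec$seed
    if (!is.null(s)) set.seed(s)
    return(spread_masses(M, stats::runif(length(M$domains))))
  }
  stop("unrecognized initial-condition spec", call. = FALSE)
}

#' @rdname initial_condition
#' @param simplex Simplex label, e.g. `"2:1-2-3"`.
#' @param mass Total mass to place.
#' @export
ic_delta <- function(simplex, mass = 1) {
  structure(list(simplex = simplex, mass = mass), class = "ic_delta")
}

#' @rdname initial_condition
#' @export
ic_uniform_random <- function(seed = NULL) {
  structure(list(seed = seed), class = "ic_uniform_random")
}

# per-domain masses -> uniform densities (density = mass / measure)
spread_masses <- function(M, mass) {
  u0 <- numeric(M$n_dof)
  for (i in seq_along(M$domains)) {
    if (mass[i] != 0) {
      rng <- M$offsets[i] + seq_len(M$domains[[i]]$n_nodes)
      u0[rng] <- mass[i] / M$measure[i]
    }
  }
  u0
}

#' Integrate diffusion on a metaplex
#'
#' Advances `D * du/dt = -S %*% u` with the scheme in `cfg`. Implicit
#' Euler solves `(D + dt * S) u_{k+1} = D * u_k` with a single sparse
#' Cholesky factorization reused across steps; because `1' S = 0` the
#' total mass `sum(D * u)` is conserved to round-off at every step, and
#' because `D + dt * S` is an M-matrix the solution stays nonnegative for
#' nonnegative initial data at any step size.
#'
#' @param M A `metaplex`.
#' @param u0 Initial density vector (see [initial_condition()]), or an
#'   initial-condition spec accepted by it.
#' @param cfg A [diffusion_config()].
#' @return A `metaplex_trajectory`: `times` (saved grid), `states`
#'   (DOF x saved times), `totals` (simplex x saved times mass matrix),
#'   `min_state` / `mass_drift` tracked over every step, `labels`, `dims`,
#'   `metaplex`, `converged_at` (time when the relative step change first
#'   dropped below `steady_tol`, or `NA`).
#' @export
integrate_metaplex <- function(M, u0, cfg = diffusion_config()) {
  stopifnot(inherits(M, "metaplex"), inherits(cfg, "diffusion_config"))
  if (!is.numeric(u0)) u0 <- initial_condition(M, u0, seed = cfg$seed)
  if (length(u0) != M$n_dof) {
    stop(sprintf("u0 has length %d; metaplex has %d DOFs", length(u0), M$n_dof), call. = FALSE)
  }
  Dg <- Matrix::Diagonal(x = M$D)
  dt <- cfg$dt
  if (cfg$scheme == "implicit_euler") {
    A <- Dg + dt * M$S
    rhs_of <- function(u) M$D * u
  } else {
    A <- Dg + (dt / 2) * M$S
    B <- Dg - (dt / 2) * M$S
    rhs_of <- function(u) as.numeric(B %*% u)
  }
  fac <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A), "CsparseMatrix"),
                          LDL = FALSE, perm = TRUE)
  u <- u0
  mass0 <- sum(M$D * u0)
  min_state <- min(u0)
  max_drift <- 0
  saved <- list(u0)
  saved_t <- 0
  converged_at <- NA_real_
  for (k in seq_len(cfg$n_steps)) {
    u_new <- as.numeric(Matrix::solve(fac, rhs_of(u)))
    step_change <- max(abs(u_new - u)) / max(max(abs(u)), 1e-300)
    u <- u_new
    min_state <- min(min_state, min(u))
    max_drift <- max(max_drift, abs(sum(M$D * u) - mass0))
    if (k %% cfg$save_every == 0L || k == cfg$n_steps) {
      saved[[length(saved) + 1L]] <- u
      saved_t <- c(saved_t, k * dt)
    }
    if (is.na(converged_at) && step_change < 1e-300 + (cfg$steady_tol %||% -1)) {
      converged_at <- k * dt
      if (!is.null(cfg$steady_tol)) break
    }
  }
  states <- do.call(cbind, saved)
  traj <- structure(
    list(
      times = saved_t, states = states,
      min_state = min_state, mass_drift = max_drift,
      labels = M$labels, dims = M$dims, metaplex = M,
      config = cfg, converged_at = converged_at
    ),
    class = "metaplex_trajectory"
  )
  traj$totals <- per_simplex_totals(traj, M)
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate a trajectory to one mass value per simplex
#'
#' Sums `D * u` over the nodes of each domain, turning the continuous
#' state into the same shape of observable the Hodge block model evolves:
#' one number per simplex per time.
#'
#' @param traj A `metaplex_trajectory`.
#' @param M The `metaplex` (defaults to the one stored in `traj`).
#' @return Matrix (simplices x times) with simplex labels as rownames.
#' @export
per_simplex_totals <- function(traj, M = traj$metaplex) {
  agg <- Matrix::sparseMatrix(
    i = rep(seq_along(M$domains), vapply(M$domains, function(d) d$n_nodes, 1L)),
    j = seq_len(M$n_dof),
    x = M$D,
    dims = c(length(M$domains), M$n_dof)
  )
  out <- as.matrix(agg %*% traj$states)
  rownames(out) <- M$labels
  out
}

#' Consensus value of a metaplex initial condition
#'
#' The diffusion steady state on a connected metaplex is the uniform
#' density `sum(D * u0) / total measure`; with unit-measure domains each
#' simplex then holds `total mass / number of simplices`.
#'
#' @param u0 Initial density vector.
#' @param M A `metaplex`.
#' @return Scalar consensus density.
#' @export
consensus_value <- function(u0, M) {
  sum(M$D * u0) / sum(M$measure)
}

#' Return probability of a seeded simplex
#'
#' For a trajectory started as a delta on one simplex, the fraction of the
#' initial mass found back on that simplex over time. On a connected
#' metaplex this stabilizes at the strictly positive consensus share;
#' under the Hodge model, blocks with vanishing Betti number decay to
#' zero instead.
#'
#' @param traj A `metaplex_trajectory` or `hodge_trajectory`.
#' @param seed_simplex Simplex label, e.g. `"2:1-2-3"`.
#' @return Tibble with columns `time` and `p`.
#' @export
return_probability <- function(traj, seed_simplex) {
  idx <- match(seed_simplex, traj$labels)
  if (is.na(idx)) stop("unknown simplex id: ", seed_simplex, call. = FALSE)
  m0 <- traj$totals[idx, 1L]
  if (abs(m0) < 1e-300) stop("seed simplex holds no initial mass", call. = FALSE)
  tibble::tibble(time = traj$times, p = traj$totals[idx, ] / m0)
}

#' Detect near-empty triangles (candidate topological holes)
#'
#' A triangle whose total mass at a pre-consensus snapshot stays below
#' `theta` times the consensus value is barely visited by the diffusing
#' density: it behaves like a hole rather than a filled 2-simplex. The
#' interior/boundary density ratio (mean over interior nodes vs mean over
#' boundary nodes) reported alongside shows whether depletion is
#' concentrated at the centre.
#'
#' @param traj A `metaplex_trajectory`.
#' @param M The metaplex (defaults to the trajectory's).
#' @param theta Fraction of the consensus value below which a triangle is
#'   flagged, `0 <= theta < 1`.
#' @param t_eval Snapshot time (must lie on the saved grid); defaults to
#'   the earliest saved time at which the global relative change per step
#'   falls below 1e-4, i.e. a late pre-consensus snapshot.
#' @return Tibble of flagged triangles: `simplex`, `mass`,
#'   `interior_boundary_ratio`, plus attributes `t_eval` and `consensus`.
#' @export
detect_holes <- function(traj, M = traj$metaplex, theta = 0.1, t_eval = NULL) {
  stopifnot(inherits(traj, "metaplex_trajectory"), theta >= 0, theta < 1)
  if (is.null(t_eval)) t_eval <- default_snapshot_time(traj)
  ti <- match(TRUE, abs(traj$times - t_eval) < 1e-12)
  if (is.na(ti)) stop("t_eval does not lie on the saved time grid", call. = FALSE)
  cons <- consensus_value(traj$states[, 1L], M)
  tri <- which(M$dims == 2L)
  flagged <- tri[traj$totals[tri, ti] < theta * cons]
  ratio <- vapply(flagged, function(di) {
    dom <- M$domains[[di]]
    rng <- M$offsets[di] + seq_len(dom$n_nodes)
    u <- traj$states[rng, ti]
    bnd <- unique(unlist(dom$faces))
    interior <- setdiff(seq_len(dom$n_nodes), bnd)
    if (length(interior) == 0L) return(NA_real_)
    mean(u[interior]) / max(mean(u[bnd]), 1e-300)
  }, 1)
  out <- tibble::tibble(
    simplex = M$labels[flagged],
    mass = traj$totals[flagged, ti],
    interior_boundary_ratio = ratio
  )
  attr(out, "t_eval") <- traj$times[ti]
  attr(out, "consensus") <- cons
  out
}

# earliest saved time where the per-step relative change drops below 1e-4
default_snapshot_time <- function(traj) {
  if (ncol(traj$states) < 2L) return(traj$times[1L])
  dt_saved <- diff(traj$times)
  step <- traj$config$dt %||% dt_saved[1L]
  for (k in seq_along(dt_saved)) {
    rel <- max(abs(traj$states[, k + 1L] - traj$states[, k])) /
      max(max(abs(traj$states[, k])), 1e-300)
    per_step <- rel * step / dt_saved[k]
    if (per_step < 1e-4) return(traj$times[k + 1L])
  }
  traj$times[length(traj$times)]
}

#' Side-by-side diagnostics of the Hodge and metaplex diffusion models
#'
#' Runs both models from the same per-simplex mass table (a block state
#' for the Hodge Laplacian; uniform within-domain densities for the
#' metaplex) on the same time grid and reports, per model: the minimum
#' value attained (negative values flag unphysical densities), the
#' maximum drift of the total mass (non-zero flags a non-conservative
#' process), the sup-distance of the final per-simplex state from the
#' global consensus, and the time at which the model first comes within
#' `conv_tol` of its own final state.
#'
#' @param K A `simplicial_complex`.
#' @param M A `metaplex` built from `K`.
#' @param u0_table Data frame with columns `simplex`, `mass`.
#' @param cfg A [diffusion_config()]; its grid is shared by both models.
#' @param conv_tol Sup-norm tolerance defining the convergence time.
#' @return A list of class `model_comparison` with tibble `summary`
#'   (one row per model) and the two trajectories.
#' @export
compare_models <- function(K, M, u0_table, cfg = diffusion_config(), conv_tol = 1e-3) {
  stopifnot(inherits(K, "simplicial_complex"), inherits(M, "metaplex"))
  H <- hodge_laplacians(K)
  u0 <- initial_condition(M, u0_table)
  mtraj <- integrate_metaplex(M, u0, cfg)
  htraj <- simulate_hodge(H, u0_table, mtraj$times)

  cons <- consensus_value(u0, M)
  h_final <- htraj$totals[, ncol(htraj$totals)]
  m_final <- mtraj$totals[, ncol(mtraj$totals)]
  h_mass <- colSums(htraj$totals)
  m_mass <- colSums(mtraj$totals)
  h_cons_target <- mean(htraj$totals[, 1L])

  conv_time <- function(totals, times) {
    final <- totals[, ncol(totals)]
    dist <- apply(abs(totals - final), 2L, max)
    times[match(TRUE, dist < conv_tol)]
  }
  summary <- tibble::tibble(
    model = c("hodge", "metaplex"),
    min_value = c(min(htraj$states), mtraj$min_state),
    mass_drift = c(max(abs(h_mass - h_mass[1L])), mtraj$mass_drift),
    consensus_distance = c(max(abs(h_final - h_cons_target)), max(abs(m_final - cons))),
    convergence_time = c(conv_time(htraj$totals, htraj$times),
                         conv_time(mtraj$totals, mtraj$times)),
    conservative = c(max(abs(h_mass - h_mass[1L])) < 1e-8, mtraj$mass_drift < 1e-8),
    positive = c(min(htraj$states) >= -1e-10, mtraj$min_state >= -1e-10)
  )
  structure(
    list(summary = summary, hodge = htraj, metaplex = mtraj, consensus = cons),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) x$summary

#' @method tidy metaplex_trajectory
#' @export
tidy.metaplex_trajectory <- function(x, ...) {
  df <- as.data.frame(x$totals)
  names(df) <- as.character(seq_along(x$times))
  df$simplex <- x$labels
  df$dim <- x$dims
  out <- tidyr::pivot_longer(df, cols = -c("simplex", "dim"),
                             names_to = ".tidx", values_to = "mass")
  out$time <- x$times[as.integer(out$.tidx)]
  out$.tidx <- NULL
  tibble::as_tibble(out[, c("simplex", "dim", "time", "mass")])
}

#' @method glance metaplex_trajectory
#' @export
glance.metaplex_trajectory <- function(x, ...) {
  tibble::tibble(
    n_dof = nrow(x$states),
    n_simplices = length(x$labels),
    total_mass = sum(x$totals[, 1L]),
    mass_drift = x$mass_drift,
    min_state = x$min_state,
    consensus = consensus_value(x$states[, 1L], x$metaplex),
    converged_at = x$converged_at
  )
}

#' @method autoplot metaplex_trajectory
#' @export
autoplot.metaplex_trajectory <- function(object, ...) {
  df <- tidy(object)
  cons <- consensus_value(object$states[, 1L], object$metaplex)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mass,
                                   group = .data$simplex,
                                   colour = factor(.data$dim))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = cons, linetype = 3) +
    ggplot2::labs(x = "time", y = "mass per simplex", colour = "dim",
                  title = "Metaplex diffusion, per-simplex totals") +
    ggplot2::theme_minimal()
}

#' Write a trajectory's per-simplex totals as CSV
#'
#' Rows are simplices labelled `"dim:tuple"`, columns are times.
#'
#' @param traj A `metaplex_trajectory` or `hodge_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  m <- traj$totals
  df <- data.frame(simplex = rownames(m) %||% traj$labels, m, check.names = FALSE)
  names(df) <- c("simplex", sprintf("t=%g", traj$times))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
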