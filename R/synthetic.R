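#' Simulation configuration
#'
#' Parameters of the paired-dataset simulator. Defaults describe the
#' standard benchmark regime used throughout the package's tests: a
#' moderately sized reference (500 cells, 200 genes) paired with a spatial
#' section (300 spots) measuring a 60-gene panel — spatial panels are far
#' smaller than reference gene sets in practice — with three time-tercile
#' cell types, mild Gaussian noise, and spot coordinates laid on a gradient
#' correlated with developmental time.
#'
#' @param n_ref_cells,n_spots,n_genes,n_shared_genes dataset sizes
#' @param n_types number of cell types (equal-frequency time bins)
#' @param gamma_range,alpha_range uniform sampling ranges for per-gene
#'   degradation ratio and transcription rate (splicing rate fixed at 1:
#'   only the ratio gamma/beta is identifiable from (u, s) shapes)
#' @param switch_time_range range of the per-gene induction-to-repression
#'   switch time as a fraction of the trajectory, in (0, 1)
#' @param time_scale kinetic time units spanned by the full trajectory
#'   (default 10). Rates are per kinetic time unit, so with the splicing
#'   rate fixed at 1 a horizon of 10 lets genes approach their induction
#'   steady state before switching — the regime the steady-state estimator
#'   assumes. Cell pseudotime stays on \[0, 1\].
#' @param noise_sd sd of additive Gaussian noise, clipped at 0
#' @param spatial_layout `"gradient"` (x tracks time), `"radial"` (distance
#'   from center tracks time) or `"clusters"` (one blob per type)
#' @param omega_true optional per-type weights in \[0, 1\]; when set, spot
#'   expression magnitudes are re-synthesized so each spot's mean nonzero
#'   expression follows `omega * T + (1 - omega) * D` plus noise
#' @param seed integer seed; mandatory, all randomness flows from it
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_ref_cells = 500, n_spots = 300,
                              n_genes = 200,
                              n_shared_genes = min(60, n_genes),
                              n_types = 3,
                              gamma_range = c(0.3, 1.5),
                              alpha_range = c(2, 8),
                              switch_time_range = c(0.3, 0.8),
                              time_scale = 10,
                              noise_sd = 0.1,
                              spatial_layout = c("gradient", "radial", "clusters"),
                              omega_true = NULL, seed) {
  spatial_layout <- match.arg(spatial_layout)
  sv_assert(!missing(seed) && is.numeric(seed) && length(seed) == 1,
            "`seed` is mandatory")
  sv_assert(n_shared_genes <= n_genes,
            "n_shared_genes must not exceed n_genes")
  for (r in list(gamma_range, alpha_range, switch_time_range)) {
    sv_assert(length(r) == 2 && r[1] <= r[2] && r[1] > 0, "ranges must be ordered and positive")
  }
  sv_assert(noise_sd >= 0, "noise_sd must be non-negative")
  sv_assert(time_scale > 0, "time_scale must be positive")
  structure(
    list(n_ref_cells = n_ref_cells, n_spots = n_spots, n_genes = n_genes,
         n_shared_genes = n_shared_genes, n_types = n_types,
         gamma_range = gamma_range, alpha_range = alpha_range,
         switch_time_range = switch_time_range, time_scale = time_scale,
         noise_sd = noise_sd,
         spatial_layout = spatial_layout, omega_true = omega_true,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# exact solution of du/dt = alpha - beta u, ds/dt = beta u - gamma s
# from state (u0, s0); beta = 1 throughout
ode_state <- function(tau, alpha, gamma, u0 = 0, s0 = 0, beta = 1) {
  eb <- exp(-beta * tau)
  eg <- exp(-gamma * tau)
  u <- u0 * eb + alpha / beta * (1 - eb)
  cross <- if (abs(gamma - beta) < 1e-8) {
    (alpha - beta * u0) * tau * eb
  } else {
    (alpha - beta * u0) / (gamma - beta) * (eg - eb)
  }
  s <- s0 * eg + alpha / gamma * (1 - eg) + cross
  list(u = u, s = s)
}

# noiseless (u, s) at times for one gene with induction until t0, then
# repression (alpha = 0) from the switch state
gene_kinetics <- function(times, alpha, gamma, t0) {
  ind <- times <= t0
  u <- s <- numeric(length(times))
  st <- ode_state(times[ind], alpha, gamma)
  u[ind] <- st$u; s[ind] <- st$s
  if (any(!ind)) {
    sw <- ode_state(t0, alpha, gamma)
    st <- ode_state(times[!ind] - t0, 0, gamma, u0 = sw$u, s0 = sw$s)
    u[!ind] <- st$u; s[!ind] <- st$s
  }
  list(u = u, s = s)
}

draw_gene_params <- function(config) {
  list(
    alpha = runif(config$n_genes, config$alpha_range[1], config$alpha_range[2]),
    gamma = runif(config$n_genes, config$gamma_range[1], config$gamma_range[2]),
    switch_time = runif(config$n_genes, config$switch_time_range[1],
                        config$switch_time_range[2])
  )
}

kinetics_matrices <- function(times, params, noise_sd, time_scale = 1) {
  n <- length(times); g <- length(params$alpha)
  U <- S <- matrix(0, n, g)
  for (j in seq_len(g)) {
    ks <- gene_kinetics(times * time_scale, params$alpha[j], params$gamma[j],
                        params$switch_time[j] * time_scale)
    U[, j] <- ks$u; S[, j] <- ks$s
  }
  V <- U - sweep(S, 2, params$gamma, "*")   # velocity before noise, beta = 1
  if (noise_sd > 0) {
    U <- pmax(U + matrix(rnorm(n * g, sd = noise_sd), n, g), 0)
    S <- pmax(S + matrix(rnorm(n * g, sd = noise_sd), n, g), 0)
  }
  list(U = U, S = S, V = V)
}

#' Simulate splicing kinetics along a pseudotime trajectory
#'
#' Each gene follows the two-phase splicing ODE: induction at rate alpha
#' from the zero state until its switch time, then repression (alpha = 0)
#' with continuous state, both solved in closed form. Cells are assigned
#' uniform times on \[0, 1\]. True velocity `u - gamma * s` is recorded
#' before noise corruption.
#'
#' @param config a [simulation_config()]
#' @param n_obs number of cells (default `config$n_ref_cells`)
#' @return list with matrices `U`, `S` (obs x genes) and `truth` (list:
#'   `alpha`, `gamma`, `switch_time`, `time`, `velocity`)
#' @export
simulate_kinetics <- function(config, n_obs = config$n_ref_cells) {
  withr::with_seed(config$seed, {
    params <- draw_gene_params(config)
    times <- runif(n_obs)
    km <- kinetics_matrices(times, params, config$noise_sd, config$time_scale)
    list(U = km$U, S = km$S,
         truth = list(alpha = params$alpha, gamma = params$gamma,
                      switch_time = params$switch_time, time = times,
                      velocity = km$V))
  })
}

type_labels <- function(times, breaks, n_types) {
  cut(times, breaks = breaks, include.lowest = TRUE,
      labels = paste0("type_", seq_len(n_types))) |> as.character()
}

layout_coords <- function(times, layout, noise_sd, labels = NULL) {
  n <- length(times)
  switch(layout,
    gradient = cbind(x = times + noise_sd * 0.2 * rnorm(n), y = runif(n)),
    radial = {
      theta <- runif(n, 0, 2 * pi)
      r <- pmax(0, times + noise_sd * 0.2 * rnorm(n))
      cbind(x = r * cos(theta), y = r * sin(theta))
    },
    clusters = {
      tys <- sv_sort(unique(labels))
      ang <- 2 * pi * (seq_along(tys) - 1) / length(tys)
      centers <- cbind(cos(ang), sin(ang))
      ci <- match(labels, tys)
      centers[ci, ] + matrix(rnorm(2 * n, sd = 0.05 + 0.05 * noise_sd), n, 2)
    })
}

#' Simulate a paired reference + spatial dataset with ground truth
#'
#' Reference cells and spatial spots are drawn from the same per-gene
#' kinetic model (spots are held-out cells), guaranteeing shared latent
#' structure. The reference carries all genes with spliced/unspliced
#' layers and time-quantile cell-type labels; the spatial dataset carries
#' only total expression on a random `n_shared_genes` panel plus 2-D
#' coordinates laid out per `spatial_layout` so that position correlates
#' with developmental time.
#'
#' @param config a [simulation_config()]
#' @return list with `ref` and `spatial` ([omics_dataset()]s) and `truth`
#'   (list: `gamma`, `alpha`, `switch_time`, `ref_time`, `spot_time`,
#'   `ref_velocity`, `spot_velocity`, `ref_labels`, `spot_labels`,
#'   `shared_genes`, `omega_true`)
#' @export
simulate_paired <- function(config) {
  withr::with_seed(config$seed, {
    params <- draw_gene_params(config)
    gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
    shared <- sort(sample(config$n_genes, config$n_shared_genes))

    t_ref <- runif(config$n_ref_cells)
    t_sp <- runif(config$n_spots)
    km_ref <- kinetics_matrices(t_ref, params, config$noise_sd, config$time_scale)
    km_sp <- kinetics_matrices(t_sp, params, config$noise_sd, config$time_scale)

    breaks <- quantile(t_ref, probs = seq(0, 1, length.out = config$n_types + 1),
                       names = FALSE)
    lab_ref <- type_labels(t_ref, breaks, config$n_types)
    lab_sp <- type_labels(pmin(pmax(t_sp, breaks[1]), breaks[length(breaks)]),
                          breaks, config$n_types)
    coords <- layout_coords(t_sp, config$spatial_layout, config$noise_sd,
                            labels = lab_sp)

    X_sp <- (km_sp$S + km_sp$U)[, shared, drop = FALSE]
    if (!is.null(config$omega_true)) {
      om <- rep_len(config$omega_true, config$n_types)
      Tn <- minmax01(t_sp)
      Dn <- minmax01(distance_from_origin(coords))
      ty_i <- match(lab_sp, paste0("type_", seq_len(config$n_types)))
      target <- om[ty_i] * Tn + (1 - om[ty_i]) * Dn +
        rnorm(config$n_spots, sd = config$noise_sd)
      target <- pmax(target, 0) + 0.5   # keep magnitudes positive
      cur <- mean_nonzero_expression(X_sp)
      fac <- ifelse(cur > 0, target / cur, 1)
      X_sp <- X_sp * fac
    }

    ref <- omics_dataset(
      km_ref$S + km_ref$U, gene_ids = gene_ids,
      obs_ids = sprintf("cell_%04d", seq_len(config$n_ref_cells)),
      spliced = km_ref$S, unspliced = km_ref$U, labels = lab_ref,
      pseudotime = t_ref
    )
    spatial <- omics_dataset(
      X_sp, gene_ids = gene_ids[shared],
      obs_ids = sprintf("spot_%04d", seq_len(config$n_spots)),
      coords = coords
    )
    list(ref = ref, spatial = spatial,
         truth = list(gamma = params$gamma, alpha = params$alpha,
                      switch_time = params$switch_time,
                      ref_time = t_ref, spot_time = t_sp,
                      ref_velocity = km_ref$V, spot_velocity = km_sp$V,
                      ref_labels = lab_ref, spot_labels = lab_sp,
                      shared_genes = shared,
                      omega_true = config$omega_true))
  })
}

#' Simulate pseudo-spatiotemporal regulation data
#'
#' Direct generator for the time-versus-space weighting model: per type,
#' times and distances are uniform on \[0, 1\] and the response is
#' `Y = omega * T + (1 - omega) * D + noise`. Used to test omega recovery
#' without running the full pipeline.
#'
#' @param omega numeric vector of true per-type weights in \[0, 1\]
#' @param n_per_type observations per type
#' @param noise_sd Gaussian noise sd on Y
#' @param seed integer seed
#' @return list with vectors `t`, `d`, `y`, `types` and `omega_true`
#' @export
simulate_omega_data <- function(omega, n_per_type = 500, noise_sd = 0.05,
                                seed) {
  sv_assert(all(omega >= 0 & omega <= 1), "`omega` must lie in [0, 1]")
  withr::with_seed(seed, {
    k <- length(omega)
    n <- k * n_per_type
    types <- rep(sprintf("type_%02d", seq_len(k)), each = n_per_type)
    t <- runif(n); d <- runif(n)
    y <- rep(omega, each = n_per_type) * t +
      rep(1 - omega, each = n_per_type) * d + rnorm(n, sd = noise_sd)
    list(t = t, d = d, y = y, types = types, omega_true = omega)
  })
}
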