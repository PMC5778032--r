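#' Icosphere mesh generator
#'
#' Recursive midpoint subdivision of a regular icosahedron with deduplicated
#' midpoints projected to the sphere. Order k gives `10 * 4^k + 2` vertices
#' and `20 * 4^k` faces; order 5 yields 10,242 vertices, the resolution of
#' the fsaverage5 standard cortical surface (per hemisphere), which this mesh
#' stands in for in offline tests. The default radius of 100 mm gives
#' near-cortical edge spacing (~3.3 mm at order 5).
#'
#' @param order subdivision order, integer in [0, 7].
#' @param radius sphere radius in mm.
#' @return a [surface_mesh()] (mask all-true). Deterministic.
#' @export
#' @examples
#' make_icosphere(0)   # the icosahedron itself
#' nrow(make_icosphere(3)$vertices)  # 642
make_icosphere <- function(order = 0L, radius = 100) {
  order <- as.integer(order)
  if (is.na(order) || order < 0L || order > 7L)
    stop("'order' must be an integer in [0, 7]")
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(faces) <- "integer"
  for (k in seq_len(order)) {
    nv <- nrow(verts)
    e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
    e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    key <- (as.numeric(e[, 1L]) - 1) * nv + e[, 2L]
    uniq <- !duplicated(key)
    mid_id <- nv + match(key, key[uniq])   # new vertex index per edge
    mids <- (verts[e[uniq, 1L], , drop = FALSE] +
               verts[e[uniq, 2L], , drop = FALSE]) / 2
    verts <- rbind(verts, mids)
    nf <- nrow(faces)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m13 <- mid_id[2L * nf + seq_len(nf)]
    faces <- rbind(
      cbind(faces[, 1L], m12, m13),
      cbind(m12, faces[, 2L], m23),
      cbind(m13, m23, faces[, 3L]),
      cbind(m12, m23, m13))
    storage.mode(faces) <- "integer"
  }
  verts <- verts * (radius / sqrt(rowSums(verts^2)))
  surface_mesh(verts, faces)
}

#' Simulate BOLD-like series with a dominant group nearing criticality
#'
#' Generative stand-in for the dynamical-network-biomarker regime: a shared
#' latent AR(1) process `u(t) = rho * u(t-1) + e(t)` drives a connected patch
#' of vertices (the "dominant group", a graph-distance ball around a seed
#' vertex), while every vertex carries an independent background AR(1)
#' `b_i(t) = phi * b_i(t-1) + e_i(t)`. Group vertices observe
#' `lambda * u + b_i`, others `b_i`. As `rho -> 1` the latent variance
#' `sigma^2 / (1 - rho^2)` diverges, so within-group correlation and group SD
#' rise while correlation with the outside stays low — exactly the three DNB
#' signatures the criticality index is built to detect. All processes start
#' from their stationary distribution.
#'
#' @param mesh a [surface_mesh()].
#' @param seed_vertex center of the dominant-group patch.
#' @param group_radius graph-distance radius of the patch (default 2, the
#'   scale of a second-order neighborhood).
#' @param rho criticality parameter, AR(1) coefficient of the shared latent;
#'   in [0, 1).
#' @param lambda group loading on the latent (>= 0).
#' @param phi background AR(1) coefficient, in (-1, 1).
#' @param sigma innovation SD (BOLD units).
#' @param n_time number of timepoints. The default 235 mirrors a 478-second
#'   scan at TR = 2 s with 4 equilibration volumes dropped.
#' @param tr repetition time in seconds (metadata only).
#' @param seed optional RNG seed for exact reproducibility.
#' @return list with `series` (V x n_time matrix), logical `group`
#'   (ground-truth membership), `latent` (the shared u(t)), and the call
#'   parameters in `spec`.
#' @export
simulate_dnb_series <- function(mesh, seed_vertex = 1L, group_radius = 2L,
                                rho = 0.95, lambda = 1, phi = 0.3,
                                sigma = 1, n_time = 235L, tr = 2,
                                seed = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (abs(rho) >= 1 || abs(phi) >= 1)
    stop("non-stationary coefficients: need |rho| < 1 and |phi| < 1")
  if (lambda < 0) stop("'lambda' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  v <- n_vertices(mesh)
  nb <- build_neighborhoods(mesh, order = max(1L, group_radius))
  group <- logical(v)
  group[seed_vertex] <- TRUE
  if (group_radius >= 1L) group[nb$neighbors[[seed_vertex]]] <- TRUE
  u <- ar1_series(n_time, rho, sigma)
  b <- ar1_matrix(v, n_time, phi, sigma)
  series <- b
  series[group, ] <- series[group, , drop = FALSE] +
    lambda * matrix(u, nrow = sum(group), ncol = n_time, byrow = TRUE)
  list(series = series, group = group, latent = u,
       spec = list(seed_vertex = seed_vertex, group_radius = group_radius,
                   rho = rho, lambda = lambda, phi = phi, sigma = sigma,
                   n_time = n_time, tr = tr, seed = seed))
}

# stationary AR(1): x_1 ~ N(0, sigma^2/(1-a^2)), x_t = a x_{t-1} + N(0, sigma^2)
ar1_series <- function(n, a, sigma) {
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, 0, sigma / sqrt(1 - a^2))
  innov <- stats::rnorm(n - 1L, 0, sigma)
  for (t in 2:n) x[t] <- a * x[t - 1L] + innov[t - 1L]
  x
}

ar1_matrix <- function(v, n, a, sigma) {
  x <- matrix(0, v, n)
  x[, 1L] <- stats::rnorm(v, 0, sigma / sqrt(1 - a^2))
  for (t in 2:n) x[, t] <- a * x[, t - 1L] + stats::rnorm(v, 0, sigma)
  x
}

#' Simulate a multi-group cohort of vertex maps
#'
#' Builds per-subject per-vertex maps as `base pattern + group effects +
#' covariate slopes + iid Gaussian noise`, together with a subject table
#' (group, age, sex, education and optional behavioral scores), mirroring a
#' four-arm clinical design. Effects are planted in declared vertex clusters
#' of declared magnitude; covariate defaults echo typical elderly-cohort
#' ranges (age ~ N(67, 8) years, education ~ N(11, 4.5) years, sex ~
#' Bernoulli(0.4)).
#'
#' @param mesh a [surface_mesh()] (or an integer vertex count for mesh-free
#'   GLM simulations).
#' @param group_sizes named integer vector, e.g. `c(NC = 30, SCD = 30)`; every
#'   size >= 2.
#' @param effects list of effect specs, each a list with `group`, `vertices`
#'   (integer indices) and `delta` (shift in map units). Clusters of two
#'   effects for the same group must not overlap.
#' @param base per-vertex baseline map (default 0).
#' @param age_slope,education_slope,sex_effect common covariate effects on the
#'   maps (per year / per year / additive), defaults 0.
#' @param noise_sd iid noise SD in map units.
#' @param behavioral if `TRUE`, adds MMSE/AVLT/MoCA-like score columns with
#'   group-dependent means.
#' @param seed optional RNG seed.
#' @return list with `maps` (subjects x V), `design` (data frame), and
#'   `effects` echoed back.
#' @export
simulate_cohort <- function(mesh, group_sizes, effects = list(),
                            base = NULL, age_slope = 0, education_slope = 0,
                            sex_effect = 0, noise_sd = 1,
                            behavioral = FALSE, seed = NULL) {
  v <- if (inherits(mesh, "surface_mesh")) n_vertices(mesh) else as.integer(mesh)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("'group_sizes' must be a named vector")
  if (any(group_sizes < 2L)) stop("every group needs at least 2 subjects")
  for (ef in effects) {
    if (!all(c("group", "vertices", "delta") %in% names(ef)))
      stop("each effect needs 'group', 'vertices', 'delta'")
    if (any(ef$vertices < 1L | ef$vertices > v))
      stop("effect vertices out of range")
  }
  by_group <- split(effects, vapply(effects, `[[`, "", "group"))
  for (efs in by_group) {
    vs <- unlist(lapply(efs, `[[`, "vertices"))
    if (anyDuplicated(vs))
      stop("overlapping effect clusters for group ", efs[[1L]]$group)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(base)) base <- numeric(v)
  n <- sum(group_sizes)
  grp <- rep(names(group_sizes), group_sizes)
  design <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n)),
    group = grp,
    age = stats::rnorm(n, 67, 8),
    sex = stats::rbinom(n, 1L, 0.4),
    education = pmax(0, stats::rnorm(n, 11, 4.5)),
    stringsAsFactors = FALSE)
  if (behavioral) {
    score_means <- list(MMSE = 28, AVLT = 10, MoCA = 26)
    impair <- (match(grp, names(group_sizes)) - 1) /
      max(1, length(group_sizes) - 1)
    design$MMSE <- stats::rnorm(n, score_means$MMSE - 10 * impair, 2.5)
    design$AVLT <- stats::rnorm(n, score_means$AVLT - 6 * impair, 2.2)
    design$MoCA <- stats::rnorm(n, score_means$MoCA - 12 * impair, 3)
  }
  maps <- matrix(base, nrow = n, ncol = v, byrow = TRUE)
  maps <- maps + outer(design$age - 67, rep(age_slope, v)) +
    outer(design$education - 11, rep(education_slope, v)) +
    outer(design$sex, rep(sex_effect, v))
  for (ef in effects) {
    rows <- which(grp == ef$group)
    maps[rows, ef$vertices] <- maps[rows, ef$vertices] + ef$delta
  }
  maps <- maps + matrix(stats::rnorm(n * v, 0, noise_sd), n, v)
  list(maps = maps, design = design, effects = effects)
}
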