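#' Run configuration
#'
#' Assembles and validates the settings driving the pipeline commands. The
#' defaults reproduce the standard analysis settings: second-order
#' neighborhoods, signed correlation averaging, 10-mm FWHM smoothing, and an
#' FDR level of 0.05/2 (Benjamini-Hochberg at the halved level, one half per
#' contrast direction).
#'
#' @param mesh path to the surface file (or a second path for the right
#'   hemisphere via `mesh_rh`).
#' @param series path to the BOLD series file.
#' @param mesh_rh,mask,subjects optional paths: right-hemisphere surface,
#'   cortex mask, subject table CSV.
#' @param order neighborhood order (default 2).
#' @param mode `"signed"` or `"absolute"` correlation averaging.
#' @param epsilon denominator guard for the criticality ratio.
#' @param fwhm_mm smoothing FWHM in mm (default 10).
#' @param alpha FDR level (default 0.025 = 0.05/2).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the provenance sidecar.
#' @param extra named list merged in (e.g. parsed YAML).
#' @return a `run_config` list.
#' @export
run_config <- function(mesh = NULL, series = NULL, mesh_rh = NULL,
                       mask = NULL, subjects = NULL, order = 2L,
                       mode = "signed", epsilon = 1e-6, fwhm_mm = 10,
                       alpha = 0.025, out_dir = ".", seed = NULL,
                       extra = list()) {
  cfg <- list(mesh = mesh, series = series, mesh_rh = mesh_rh, mask = mask,
              subjects = subjects, order = as.integer(order), mode = mode,
              epsilon = epsilon, fwhm_mm = fwhm_mm, alpha = alpha,
              out_dir = out_dir, seed = seed)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  if (!cfg$mode %in% c("signed", "absolute"))
    stop("mode must be 'signed' or 'absolute'")
  if (cfg$order < 1L) stop("order must be >= 1")
  if (cfg$fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)")
  class(cfg) <- "run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @param overrides named list taking precedence over the file (e.g. parsed
#'   command-line flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) vals[[nm]] <- overrides[[nm]]
  known <- names(formals(run_config))
  known <- setdiff(known, "extra")
  do.call(run_config, c(vals[intersect(names(vals), known)],
                        list(extra = vals[setdiff(names(vals), known)])))
}

load_config_mesh <- function(cfg) {
  if (is.null(cfg$mesh)) stop("config is missing 'mesh'")
  lh <- read_surface(cfg$mesh, mask = cfg$mask)
  if (!is.null(cfg$mesh_rh)) merge_hemispheres(lh, read_surface(cfg$mesh_rh))
  else lh
}

provenance_sidecar <- function(cfg, path, extra = list()) {
  side <- c(list(
    package = "vifc",
    version = as.character(utils::packageVersion("vifc")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    timestamp_free = TRUE), extra)
  jsonlite::write_json(side, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Compute criticality maps for one subject (pipeline command)
#'
#' Loads the mesh and series, builds neighborhoods, computes the criticality
#' index and its three components, smooths each map along the surface, and
#' writes `vifc`, `std`, `corr_in`, `corr_out` maps plus a JSON provenance
#' sidecar into the output directory.
#'
#' @param cfg a [run_config()].
#' @param map_format output extension: `"curv"`, `"txt"`, `"csv"` or `"gii"`.
#' @return (invisibly) list with the `vertex_maps` and the written paths.
#' @export
run_compute <- function(cfg, map_format = "curv") {
  stopifnot(inherits(cfg, "run_config"))
  mesh <- load_config_mesh(cfg)
  if (is.null(cfg$series)) stop("config is missing 'series'")
  series <- read_series(cfg$series)
  if (nrow(series) != n_vertices(mesh))
    stop("series has ", nrow(series), " rows but mesh has ",
         n_vertices(mesh), " vertices; nothing computed")
  nbhd <- build_neighborhoods(mesh, cfg$order)
  maps <- compute_vifc(series, nbhd, mode = cfg$mode, epsilon = cfg$epsilon)
  if (cfg$fwhm_mm > 0) maps <- smooth_vertex_maps(maps, mesh, cfg$fwhm_mm)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in c("vifc", "std", "corr_in", "corr_out")) {
    paths[[nm]] <- file.path(cfg$out_dir, paste0(nm, ".", map_format))
    write_map(maps[[nm]], paths[[nm]])
  }
  paths$sidecar <- file.path(cfg$out_dir, "provenance.json")
  provenance_sidecar(cfg, paths$sidecar, extra = list(
    n_vertices = n_vertices(mesh),
    n_masked = sum(mesh$mask),
    n_undefined = maps$n_undefined,
    smoothed = maps$smoothed,
    neighborhood_isolated = nbhd$n_isolated))
  invisible(list(maps = maps, paths = paths))
}

#' Simulate a criticality dataset (pipeline command)
#'
#' Generates an icosphere and a DNB-structured series, writing the surface,
#' the series, the ground-truth group mask and a sidecar to the output
#' directory.
#'
#' @param cfg a [run_config()]; recognized extra keys: `icosphere_order`
#'   (default 3), `radius`, `rho`, `lambda`, `phi`, `sigma`, `n_time`,
#'   `seed_vertex`, `group_radius`.
#' @return (invisibly) list of written paths.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- function(nm, default) if (is.null(cfg[[nm]])) default else cfg[[nm]]
  mesh <- make_icosphere(g("icosphere_order", 3L), g("radius", 100))
  sim <- simulate_dnb_series(
    mesh, seed_vertex = g("seed_vertex", 1L),
    group_radius = g("group_radius", 2L), rho = g("rho", 0.95),
    lambda = g("lambda", 1), phi = g("phi", 0.3), sigma = g("sigma", 1),
    n_time = g("n_time", 235L), seed = cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mesh = file.path(cfg$out_dir, "mesh.txt"),
    series = file.path(cfg$out_dir, "series.csv"),
    group = file.path(cfg$out_dir, "group_truth.txt"),
    sidecar = file.path(cfg$out_dir, "provenance.json"))
  write_surface_plaintext(mesh, paths$mesh)
  write_series(sim$series, paths$series)
  writeLines(as.character(as.integer(sim$group)), paths$group)
  provenance_sidecar(cfg, paths$sidecar,
                     extra = list(n_group = sum(sim$group)))
  invisible(paths)
}

#' Group GLM, FDR, clusters and behavioral correlations (pipeline command)
#'
#' Reads per-subject maps and the subject table, fits the vertex-wise
#' two-group GLM with per-group offsets and slopes, applies BH FDR at the
#' configured level, extracts suprathreshold clusters, and computes partial
#' correlations of cluster-mean values with the requested behavioral columns
#' (Bonferroni divisor = number of clusters found). Writes the p/sign maps,
#' the cluster table CSV and a correlation report.
#'
#' @param cfg a [run_config()] with `subjects` set; extra keys: `groups`
#'   (length-2 character, required), `covariates` (default age/sex/education),
#'   `behavioral` (character vector of score columns, may be empty),
#'   `map_files` (explicit per-subject map paths; default
#'   `<out_dir>/maps/<subject>.curv`).
#' @param maps optional in-memory subjects x V matrix (bypasses `map_files`).
#' @param mesh optional in-memory mesh (bypasses `cfg$mesh`).
#' @return (invisibly) list with `glm`, `fdr`, `clusters`, `correlations`,
#'   and written `paths`.
#' @export
run_glm <- function(cfg, maps = NULL, mesh = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(mesh)) mesh <- load_config_mesh(cfg)
  if (is.null(cfg$subjects)) stop("config is missing 'subjects'")
  design <- utils::read.csv(cfg$subjects, stringsAsFactors = FALSE)
  if (!"group" %in% names(design))
    stop("subject table must contain a 'group' column: ", cfg$subjects)
  if (is.null(cfg$groups) || length(cfg$groups) != 2L)
    stop("config must declare 'groups' (two labels to contrast)")
  covariates <- if (is.null(cfg$covariates)) c("age", "sex", "education")
  else cfg$covariates
  if (is.null(maps)) {
    files <- if (!is.null(cfg$map_files)) cfg$map_files
    else file.path(cfg$out_dir, "maps", paste0(design$subject, ".curv"))
    maps <- do.call(rbind, lapply(files, read_map))
  }
  fit <- fit_vertexwise_glm(maps, design, cfg$groups, covariates)
  fdr <- fdr_correct(fit$p, cfg$alpha)
  clusters <- extract_clusters(mesh, fdr$mask, fit$p, fit$sign)
  behavioral <- if (is.null(cfg$behavioral)) character(0) else cfg$behavioral
  correlations <- list()
  if (nrow(clusters) && length(behavioral)) {
    sel <- design$group %in% cfg$groups
    covs <- design[sel, covariates, drop = FALSE]
    for (ci in seq_len(nrow(clusters))) {
      members <- cluster_members(mesh, fdr$mask, fit$sign,
                                 clusters$peak_vertex[ci])
      cl_mean <- rowMeans(maps[sel, members, drop = FALSE])
      for (bv in behavioral) {
        pc <- partial_correlation(cl_mean, design[[bv]][sel], covs,
                                  n_comparisons = nrow(clusters))
        correlations[[length(correlations) + 1L]] <- data.frame(
          cluster = ci, peak_vertex = clusters$peak_vertex[ci],
          score = bv, r = pc$r, p = pc$p, n = pc$n,
          significant = pc$significant)
      }
    }
  }
  correlations <- if (length(correlations)) do.call(rbind, correlations)
  else data.frame(cluster = integer(0), peak_vertex = integer(0),
                  score = character(0), r = numeric(0), p = numeric(0),
                  n = integer(0), significant = logical(0))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    p_map = file.path(cfg$out_dir, "glm_p.curv"),
    sign_map = file.path(cfg$out_dir, "glm_sign.curv"),
    clusters = file.path(cfg$out_dir, "clusters.csv"),
    correlations = file.path(cfg$out_dir, "correlations.csv"),
    sidecar = file.path(cfg$out_dir, "provenance.json"))
  write_map(fit$p, paths$p_map)
  write_map(as.numeric(fit$sign), paths$sign_map)
  utils::write.csv(clusters, paths$clusters, row.names = FALSE)
  utils::write.csv(correlations, paths$correlations, row.names = FALSE)
  provenance_sidecar(cfg, paths$sidecar, extra = list(
    n_significant = fdr$n_significant, fdr_threshold = fdr$threshold,
    n_clusters = nrow(clusters)))
  invisible(list(glm = fit, fdr = fdr, clusters = clusters,
                 correlations = correlations, paths = paths))
}
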