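#' Standardize a BOLD series matrix
#'
#' Row-wise z-scoring: each vertex's time series is centered and divided by
#' its sample standard deviation (denominator N-1). The returned `sd` is the
#' STD term of the criticality index. Constant rows (zero SD) are flagged
#' invalid and zeroed so they drop out of all correlation sums.
#'
#' @param x numeric V x N matrix, one BOLD time series per vertex.
#' @return list with `z` (V x N standardized matrix), `mean`, `sd`, and
#'   logical `valid` (`sd > 0`).
#' @export
standardize_series <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 timepoints to standardize (got ", n, ")")
  m <- rowMeans(x)
  xc <- x - m
  sd <- sqrt(rowSums(xc^2) / (n - 1))
  valid <- sd > 0
  z <- xc / ifelse(valid, sd, 1)
  z[!valid, ] <- 0
  list(z = z, mean = m, sd = sd, valid = valid)
}

# Pairwise-correlation sums for every vertex: over its neighborhood (in) and
# over all usable vertices except itself (tot). Signed mode uses the exact
# O(V*N) identity sum_k corr(i,k) = z_i . colSums(z) / (N-1); absolute mode
# computes |corr| in row blocks of bounded memory.
pair_corr_sums <- function(z, nbhd, mode, use, include_self = FALSE,
                           block_size = 1024L) {
  v <- nrow(z)
  n <- ncol(z)
  pairs_i <- rep.int(seq_len(v), lengths(nbhd$neighbors))
  pairs_j <- unlist(nbhd$neighbors, use.names = FALSE)
  if (length(pairs_j)) {
    keep <- use[pairs_j] & use[pairs_i]
    pairs_i <- pairs_i[keep]; pairs_j <- pairs_j[keep]
  }
  w <- Matrix::sparseMatrix(i = pairs_i, j = pairs_j, x = 1, dims = c(v, v))
  in_n <- as.numeric(Matrix::rowSums(w))
  tot_n <- ifelse(use, sum(use) - 1, 0)
  if (mode == "signed") {
    s <- colSums(z[use, , drop = FALSE])
    tot_sum <- as.numeric(z %*% s) / (n - 1) - as.numeric(use)
    in_sum <- rowSums(z * as.matrix(w %*% z)) / (n - 1)
  } else {
    tot_sum <- numeric(v)
    in_sum <- numeric(v)
    zu <- t(z[use, , drop = FALSE])
    use_idx <- which(use)
    wu <- w[, use_idx, drop = FALSE]
    for (start in seq(1L, v, by = block_size)) {
      b <- start:min(start + block_size - 1L, v)
      a <- abs(z[b, , drop = FALSE] %*% zu) / (n - 1)
      tot_sum[b] <- rowSums(a) - as.numeric(use[b])
      in_sum[b] <- as.numeric(Matrix::rowSums(a * wu[b, , drop = FALSE]))
    }
  }
  if (include_self) {
    in_sum <- in_sum + as.numeric(use)
    in_n <- in_n + as.numeric(use)
  }
  list(in_sum = in_sum, in_n = in_n, tot_sum = tot_sum, tot_n = tot_n)
}

#' Mean correlation with the neighborhood cluster
#'
#' Per-vertex average Pearson correlation between a vertex and the members of
#' its order-k neighborhood (the DNB "within-group" correlation). In
#' `absolute` mode the average is taken over `|corr|`.
#'
#' @param z standardized matrix from [standardize_series()] (the `z` element,
#'   or the full list).
#' @param nbhd a [build_neighborhoods()] index built on the same mesh.
#' @param mode `"signed"` (average raw correlations) or `"absolute"`.
#' @param valid optional logical vector of usable vertices; defaults to the
#'   `valid` flags in `z` when the full list is passed.
#' @return numeric vector; `NA` for masked-out, invalid, or neighborless
#'   vertices.
#' @export
mean_corr_in <- function(z, nbhd, mode = c("signed", "absolute"),
                         valid = NULL) {
  mode <- match.arg(mode)
  if (is.list(z)) { if (is.null(valid)) valid <- z$valid; z <- z$z }
  if (is.null(valid)) valid <- rep(TRUE, nrow(z))
  use <- valid & nbhd$mask
  s <- pair_corr_sums(z, nbhd, mode, use)
  out <- ifelse(use & s$in_n > 0, s$in_sum / s$in_n, NA_real_)
  out
}

#' Mean correlation with vertices outside the neighborhood
#'
#' Per-vertex average Pearson correlation between a vertex and every usable
#' vertex beyond its neighborhood cluster (the DNB "outside-group"
#' correlation, the denominator of the criticality index). Signed mode uses an
#' exact O(V*N) fast path; absolute mode a blocked O(V^2*N) sweep.
#'
#' @inheritParams mean_corr_in
#' @param block_size rows per block in absolute mode.
#' @return numeric vector; `NA` for masked-out or invalid vertices. An empty
#'   outside set (tiny mesh with a large neighborhood order) is an error
#'   naming the vertex.
#' @export
mean_corr_out <- function(z, nbhd, mode = c("signed", "absolute"),
                          valid = NULL, block_size = 1024L) {
  mode <- match.arg(mode)
  if (is.list(z)) { if (is.null(valid)) valid <- z$valid; z <- z$z }
  if (is.null(valid)) valid <- rep(TRUE, nrow(z))
  use <- valid & nbhd$mask
  s <- pair_corr_sums(z, nbhd, mode, use, block_size = block_size)
  out_n <- s$tot_n - s$in_n
  bad <- use & out_n <= 0
  if (any(bad))
    stop("outside set is empty for vertex ", which(bad)[1L],
         ": mesh too small for neighborhood order ", nbhd$order)
  ifelse(use, (s$tot_sum - s$in_sum) / out_n, NA_real_)
}

#' Vertex-wise Index of Functional Criticality
#'
#' Computes, for every masked vertex i with a non-constant time series,
#' `vIFC(i) = STD(i) * Corr_in(i) / Corr_out(i)`:
#' the sample standard deviation of the BOLD series times the mean Pearson
#' correlation with the order-k neighborhood cluster, divided by the mean
#' correlation with all vertices outside it. Under dynamical-network-biomarker
#' theory a vertex group nearing a critical transition shows rising
#' within-group correlation, falling outside correlation and rising variance,
#' so vIFC rises sharply in such a group.
#'
#' @param series numeric V x N matrix of per-vertex BOLD time series.
#' @param nbhd a [build_neighborhoods()] index (order 2 for the standard
#'   second-order neighborhood cluster).
#' @param mode `"signed"` averages raw correlations (the index as written);
#'   `"absolute"` averages `|corr|`, following the absolute-value form of the
#'   DNB conditions. Signed mode enables the exact O(V*N) denominator path.
#' @param epsilon non-negative guard: vertices with `|Corr_out| <= epsilon`
#'   get an undefined (NA) index rather than an unbounded ratio.
#' @param include_self if `TRUE` the vertex itself joins its neighborhood
#'   cluster for `Corr_in` (adds corr(i,i)=1 to the average); default `FALSE`.
#' @param block_size rows per block for absolute mode.
#' @return An object of class `vertex_maps`: list with numeric vectors `std`,
#'   `corr_in`, `corr_out`, `vifc` (NA = undefined), logical `defined`, the
#'   `mode`, a `smoothed` flag, and `n_undefined`.
#' @export
#' @examples
#' mesh <- make_icosphere(2)
#' sim <- simulate_dnb_series(mesh, rho = 0.95, seed = 1)
#' maps <- compute_vifc(sim$series, build_neighborhoods(mesh, 2))
#' maps
compute_vifc <- function(series, nbhd, mode = c("signed", "absolute"),
                         epsilon = 1e-6, include_self = FALSE,
                         block_size = 1024L) {
  mode <- match.arg(mode)
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  series <- as.matrix(series)
  if (nrow(series) != length(nbhd$neighbors))
    stop("series has ", nrow(series), " rows but the neighborhood index has ",
         length(nbhd$neighbors), " vertices")
  if (ncol(series) < 3L) stop("need at least 3 timepoints (got ",
                              ncol(series), ")")
  std <- standardize_series(series)
  use <- std$valid & nbhd$mask
  s <- pair_corr_sums(std$z, nbhd, mode, use, include_self = include_self,
                      block_size = block_size)
  # corr_out always excludes the neighborhood AND the vertex itself, whether
  # or not the self was folded into corr_in
  self_term <- if (include_self) as.numeric(use) else 0
  out_n <- s$tot_n - (s$in_n - self_term)
  bad <- use & out_n <= 0
  if (any(bad))
    stop("outside set is empty for vertex ", which(bad)[1L],
         ": mesh too small for neighborhood order ", nbhd$order)
  corr_in <- ifelse(use & s$in_n > 0, s$in_sum / s$in_n, NA_real_)
  corr_out <- ifelse(use, (s$tot_sum - (s$in_sum - self_term)) / out_n,
                     NA_real_)
  defined <- use & !is.na(corr_in) & !is.na(corr_out) &
    abs(corr_out) > epsilon
  vifc <- ifelse(defined, std$sd * corr_in / corr_out, NA_real_)
  structure(
    list(std = ifelse(nbhd$mask, std$sd, NA_real_),
         corr_in = corr_in, corr_out = corr_out, vifc = vifc,
         defined = defined, mode = mode, smoothed = FALSE,
         n_undefined = sum(nbhd$mask) - sum(defined)),
    class = "vertex_maps")
}

#' @export
print.vertex_maps <- function(x, ...) {
  cat("vertex_maps (", x$mode, if (x$smoothed) ", smoothed" else "",
      "): ", length(x$vifc), " vertices, ", x$n_undefined,
      " undefined\n", sep = "")
  cat("  vIFC range:",
      paste(signif(range(x$vifc, na.rm = TRUE), 4), collapse = " .. "), "\n")
  invisible(x)
}

#' Rank-based separation AUC
#'
#' Area under the ROC curve for separating two vertex classes by a score:
#' the probability that a random positive outranks a random negative
#' (Wilcoxon/Mann-Whitney form). Used to quantify how well the criticality
#' index isolates a simulated dominant group. NA scores are dropped.
#'
#' @param scores numeric vector.
#' @param positive logical vector, `TRUE` for the target class.
#' @return AUC in [0, 1].
#' @export
separation_auc <- function(scores, positive) {
  keep <- !is.na(scores)
  scores <- scores[keep]; positive <- as.logical(positive)[keep]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need scores from both classes")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
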