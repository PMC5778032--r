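# Independent reference implementations used as oracles. These deliberately
# avoid the package's computational paths: plain double loops over cor(),
# igraph shortest paths, and raw-data stats:: tests.

# neighborhoods by all-pairs graph distance (igraph oracle)
oracle_neighborhoods <- function(mesh, order) {
  e <- mesh_edges(mesh)
  keep <- mesh$mask[e[, 1]] & mesh$mask[e[, 2]]
  g <- igraph::graph_from_edgelist(e[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(mesh$vertices) - igraph::vcount(g)))
  d <- igraph::distances(g)
  lapply(seq_len(nrow(mesh$vertices)), function(i) {
    if (!mesh$mask[i]) return(NULL)
    sort(which(d[i, ] >= 1 & d[i, ] <= order & mesh$mask))
  })
}

# naive per-pair Pearson vIFC (double loop over cor())
oracle_vifc <- function(series, nbhd, mask = NULL, mode = "signed",
                        epsilon = 1e-6, include_self = FALSE) {
  v <- nrow(series)
  if (is.null(mask)) mask <- rep(TRUE, v)
  sds <- apply(series, 1, stats::sd)
  use <- sds > 0 & mask
  cm <- suppressWarnings(stats::cor(t(series)))
  f <- if (mode == "absolute") abs else identity
  corr_in <- corr_out <- vifc <- rep(NA_real_, v)
  for (i in which(use)) {
    inner <- nbhd$neighbors[[i]]
    inner <- inner[use[inner]]
    outer_set <- setdiff(which(use), c(nbhd$neighbors[[i]], i))
    if (include_self) inner <- c(inner, i)
    if (length(inner)) corr_in[i] <- mean(f(cm[i, inner]))
    corr_out[i] <- mean(f(cm[i, outer_set]))
    if (!is.na(corr_in[i]) && abs(corr_out[i]) > epsilon)
      vifc[i] <- sds[i] * corr_in[i] / corr_out[i]
  }
  list(std = ifelse(mask, sds, NA_real_), corr_in = corr_in,
       corr_out = corr_out, vifc = vifc)
}

# BH step-up by direct enumeration of the k*alpha/m bounds
oracle_bh <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- which(p[ord] <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(k)) rej[ord[seq_len(max(k))]] <- TRUE
  rej
}

# raw sample with exactly the requested first two moments
moment_matched_sample <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# smallest connected patch: a vertex plus its order-1 ring
planted_patch <- function(mesh, center) {
  nb <- build_neighborhoods(mesh, 1L)
  sort(c(center, nb$neighbors[[center]]))
}
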