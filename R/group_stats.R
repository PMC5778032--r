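#' Vertex-wise two-group GLM with per-group offsets and slopes
#'
#' Fits, at every vertex, an ordinary-least-squares model with a separate
#' intercept and separate covariate slopes for each of the two contrasted
#' groups (the "different offset, different slope" coding used by
#' surface-based group analyses). Covariates are mean-centered across the two
#' contrasted groups, so the tested contrast — the difference of group
#' intercepts — is the adjusted group difference at the average covariate
#' profile. Returns a two-sided t-test p-value and the effect sign per
#' vertex.
#'
#' @param maps numeric subjects x V matrix of per-vertex values (rows ordered
#'   as `design`).
#' @param design data frame with a `group` column plus the covariate columns.
#' @param groups length-2 character vector: the contrasted group labels; the
#'   contrast is `groups[1] - groups[2]`.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "sex", "education")`; may be empty).
#' @return list with per-vertex `p`, `sign`, `estimate` (intercept
#'   difference), `t`, the residual `df`, and logical `tested` (`FALSE` for
#'   vertices dropped because a subject value was missing).
#' @export
fit_vertexwise_glm <- function(maps, design, groups,
                               covariates = c("age", "sex", "education")) {
  maps <- as.matrix(maps)
  if (nrow(maps) != nrow(design))
    stop("maps has ", nrow(maps), " rows but design has ", nrow(design),
         " subjects")
  if (!"group" %in% names(design)) stop("design must have a 'group' column")
  if (length(groups) != 2L) stop("'groups' must name exactly two groups")
  missing_cov <- setdiff(covariates, names(design))
  if (length(missing_cov))
    stop("design lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  sel <- design$group %in% groups
  design <- design[sel, , drop = FALSE]
  maps <- maps[sel, , drop = FALSE]
  if (any(table(factor(design$group, levels = groups)) < 2L))
    stop("need at least 2 subjects in each contrasted group")
  if (length(covariates) && anyNA(design[covariates]))
    stop("covariates must be complete for GLM inclusion")
  ind_a <- as.numeric(design$group == groups[1L])
  ind_b <- as.numeric(design$group == groups[2L])
  x <- cbind(ind_a, ind_b)
  colnames(x) <- paste0("offset_", groups)
  for (cv in covariates) {
    c_ctr <- design[[cv]] - mean(design[[cv]])
    x <- cbind(x, c_ctr * ind_a, c_ctr * ind_b)
    colnames(x)[ncol(x) - 1:0] <- paste0(cv, "_", groups)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "),
         " (e.g. a constant covariate within one group)")
  }
  n <- nrow(x); p <- ncol(x)
  df <- n - p
  if (df < 1L) stop("no residual degrees of freedom (n = ", n, ", p = ", p, ")")
  tested <- colSums(is.na(maps)) == 0L
  v <- ncol(maps)
  est <- tval <- pval <- rep(NA_real_, v)
  sgn <- rep(NA_integer_, v)
  if (any(tested)) {
    y <- maps[, tested, drop = FALSE]
    coefs <- qr.coef(qx, y)
    res <- y - x %*% coefs
    sigma2 <- colSums(res^2) / df
    cc <- c(1, -1, rep(0, p - 2L))
    unpivot <- order(qx$pivot)
    xtx_inv <- chol2inv(qr.R(qx))[unpivot, unpivot, drop = FALSE]
    cvar <- drop(t(cc) %*% xtx_inv %*% cc)
    e <- coefs[1L, ] - coefs[2L, ]
    tv <- e / sqrt(cvar * sigma2)
    tv[sigma2 == 0 & e == 0] <- 0
    est[tested] <- e
    tval[tested] <- tv
    pval[tested] <- 2 * stats::pt(-abs(tv), df)
    sgn[tested] <- sign(e)
  }
  list(p = pval, sign = sgn, estimate = est, t = tval, df = df,
       tested = tested)
}

#' Benjamini-Hochberg FDR significance mask
#'
#' Step-up false-discovery-rate control over a vector of p-values. For signed
#' two-direction vertex contrasts, pass the halved level (e.g. `alpha =
#' 0.05/2`) to add a two-direction Bonferroni on top of BH.
#'
#' @param p numeric p-values in [0,1]; NAs (untested vertices) are ignored
#'   and stay unselected.
#' @param alpha FDR level in (0,1).
#' @return list with logical `mask` (same length as `p`), the `threshold`
#'   (largest rejected p, 0 if none), and `n_significant`.
#' @export
fdr_correct <- function(p, alpha = 0.025) {
  if (!length(p)) return(list(mask = logical(0), threshold = 0,
                              n_significant = 0L))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0,1)")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0,1]")
  padj <- stats::p.adjust(p[ok], method = "BH")
  mask <- logical(length(p))
  mask[ok] <- padj <= alpha
  thr <- if (any(mask)) max(p[mask]) else 0
  list(mask = mask, threshold = thr, n_significant = sum(mask))
}

#' Extract suprathreshold clusters on the mesh
#'
#' Connected components of the significance mask over mesh edges, split by
#' contrast direction, summarized in the conventional cluster-table schema:
#' signed peak `-log10(p)` (negative when the first group is lower), peak
#' vertex index, surface area (sum of member vertex areas, mm^2), and member
#' count. Rows are sorted by `|peak|` descending, ties broken by the lowest
#' peak vertex index.
#'
#' @param mesh a [surface_mesh()].
#' @param mask logical significance vector of length V.
#' @param p per-vertex p-values.
#' @param sign per-vertex effect direction (-1/0/1); clusters never mix
#'   directions. Pass `NULL` to treat the mask as one direction.
#' @return data frame with columns `direction` (`"greater"`/`"less"`),
#'   `peak_log10p` (signed), `peak_vertex`, `size_mm2`, `n_vertices`, and
#'   `hemisphere` when the mesh carries per-vertex hemisphere tags.
#' @export
extract_clusters <- function(mesh, mask, p, sign = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- n_vertices(mesh)
  if (length(mask) != v) stop("mask length must equal vertex count")
  if (is.null(sign)) sign <- rep(1L, v)
  areas <- vertex_areas(mesh)
  empty <- data.frame(direction = character(0), peak_log10p = numeric(0),
                      peak_vertex = integer(0), size_mm2 = numeric(0),
                      n_vertices = integer(0),
                      stringsAsFactors = FALSE)
  rows <- list()
  for (dir_sign in c(1, -1)) {
    sel <- which(mask & !is.na(sign) & sign == dir_sign)
    if (!length(sel)) next
    e <- mesh_edges(mesh)
    keep <- e[, 1L] %in% sel & e[, 2L] %in% sel
    g <- igraph::graph_from_edgelist(
      matrix(match(e[keep, ], sel), ncol = 2L), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    for (k in seq_len(max(comp))) {
      members <- sel[comp == k]
      lp <- -log10(pmax(p[members], .Machine$double.xmin))
      peak_i <- members[which(lp == max(lp))]
      peak_i <- min(peak_i)
      row <- data.frame(
        direction = if (dir_sign > 0) "greater" else "less",
        peak_log10p = dir_sign * max(lp),
        peak_vertex = peak_i,
        size_mm2 = sum(areas[members]),
        n_vertices = length(members),
        stringsAsFactors = FALSE)
      if (!is.null(mesh$hemisphere) && length(mesh$hemisphere) == v)
        row$hemisphere <- mesh$hemisphere[peak_i]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    if (!is.null(mesh$hemisphere) && length(mesh$hemisphere) == v)
      empty$hemisphere <- character(0)
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(-abs(out$peak_log10p), out$peak_vertex)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Membership vector of clusters
#'
#' Convenience companion to [extract_clusters()]: returns, for one cluster
#' row, the vertex indices belonging to it (reconstructed from the mask).
#'
#' @param mesh,mask,sign as in [extract_clusters()].
#' @param peak_vertex the cluster's peak vertex.
#' @return integer vector of member vertex indices.
#' @export
cluster_members <- function(mesh, mask, sign, peak_vertex) {
  dir_sign <- sign[peak_vertex]
  sel <- which(mask & !is.na(sign) & sign == dir_sign)
  e <- mesh_edges(mesh)
  keep <- e[, 1L] %in% sel & e[, 2L] %in% sel
  g <- igraph::graph_from_edgelist(
    matrix(match(e[keep, ], sel), ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(sel) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sel[comp == comp[match(peak_vertex, sel)]]
}

#' Partial correlation controlling for covariates
#'
#' Residualizes both variables on an intercept plus the covariates by least
#' squares and correlates the residuals; the p-value is t-based with
#' `n - n_covariates - 2` degrees of freedom. Used to relate cluster-mean
#' criticality values to behavioral scores (MMSE, AVLT, MoCA) while
#' controlling age, sex and education, with a Bonferroni divisor for the
#' number of clusters tested.
#'
#' @param x,y numeric vectors (pairs with any NA in x, y or covariates are
#'   dropped listwise).
#' @param covariates optional numeric matrix / data frame of covariates.
#' @param n_comparisons Bonferroni divisor applied to `alpha`.
#' @param alpha nominal level before division.
#' @return list with `r`, `p`, `df`, `n`, `significant`, and `defined`
#'   (`FALSE` when a residual has zero variance, e.g. y is an exact linear
#'   function of the covariates).
#' @export
partial_correlation <- function(x, y, covariates = NULL, n_comparisons = 1L,
                                alpha = 0.05) {
  covariates <- if (is.null(covariates)) matrix(numeric(0), length(x), 0)
  else as.matrix(covariates)
  ok <- !is.na(x) & !is.na(y) & rowSums(is.na(covariates)) == 0L
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x); q <- ncol(covariates)
  if (n < q + 3L) stop("need at least ", q + 3L,
                       " complete observations (got ", n, ")")
  basis <- cbind(1, covariates)
  rx <- stats::lm.fit(basis, x)$residuals
  ry <- stats::lm.fit(basis, y)$residuals
  if (stats::sd(rx) < 1e-12 * max(1, stats::sd(x)) ||
      stats::sd(ry) < 1e-12 * max(1, stats::sd(y)))
    return(list(r = NA_real_, p = NA_real_, df = n - q - 2L, n = n,
                significant = FALSE, defined = FALSE))
  r <- stats::cor(rx, ry)
  df <- n - q - 2L
  tt <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tt), df)
  list(r = r, p = p, df = df, n = n,
       significant = p < alpha / n_comparisons, defined = TRUE)
}

#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the omnibus F test exactly from per-group `(n, mean, SD)`
#' triples, as needed when only a demographics table is available.
#' `var_equal = TRUE` gives the classical ANOVA: between-group sum of squares
#' from the n-weighted means about the grand mean, within-group sum of
#' squares `sum((n_g - 1) * SD_g^2)`. `var_equal = FALSE` gives the Welch
#' heteroscedastic F (the form matched by unequal-variance post hoc
#' procedures such as Dunnett's T3), mirroring [stats::oneway.test()].
#' SDs are taken as sample SDs (denominator n-1), the standard convention for
#' "mean +/- SD" reporting.
#'
#' @param n integer vector of group sizes (each >= 2).
#' @param mean numeric vector of group means.
#' @param sd numeric vector of group SDs (>= 0).
#' @param var_equal assume equal variances (classical F) or not (Welch).
#' @return list with `f`, `df1`, `df2`, `p`, and `defined` (`FALSE` when all
#'   means coincide and the within-group variance is 0, leaving F 0/0).
#' @export
#' @examples
#' # four-group age comparison from a demographics table
#' anova_from_summaries(n = c(34, 67, 42, 54),
#'                      mean = c(69.86, 66.08, 66.01, 67.22),
#'                      sd = c(9.00, 9.35, 8.0, 6.15))$f
anova_from_summaries <- function(n, mean, sd, var_equal = TRUE) {
  k <- length(n)
  if (k < 2L) stop("need at least 2 groups")
  if (length(mean) != k || length(sd) != k)
    stop("'n', 'mean' and 'sd' must have equal length")
  if (any(n < 2L)) stop("every group needs n >= 2")
  if (any(sd < 0)) stop("SDs must be non-negative")
  if (var_equal) {
    ntot <- sum(n)
    grand <- sum(n * mean) / ntot
    ssb <- sum(n * (mean - grand)^2)
    ssw <- sum((n - 1) * sd^2)
    df1 <- k - 1
    df2 <- ntot - k
    if (ssw == 0) {
      if (ssb == 0)
        return(list(f = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                    defined = FALSE))
      return(list(f = Inf, df1 = df1, df2 = df2, p = 0, defined = TRUE))
    }
    f <- (ssb / df1) / (ssw / df2)
    return(list(f = f, df1 = df1, df2 = df2,
                p = stats::pf(f, df1, df2, lower.tail = FALSE),
                defined = TRUE))
  }
  if (any(sd == 0)) stop("Welch form requires positive SD in every group")
  w <- n / sd^2
  sw <- sum(w)
  mw <- sum(w * mean) / sw
  a <- sum(w * (mean - mw)^2) / (k - 1)
  tmp <- sum((1 - w / sw)^2 / (n - 1))
  b <- 2 * (k - 2) / (k^2 - 1) * tmp
  if (a == 0)
    return(list(f = NA_real_, df1 = k - 1, df2 = NA_real_, p = NA_real_,
                defined = FALSE))
  f <- a / (1 + b)
  df2 <- (k^2 - 1) / (3 * tmp)
  list(f = f, df1 = k - 1, df2 = df2,
       p = stats::pf(f, k - 1, df2, lower.tail = FALSE), defined = TRUE)
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square (`sum (O-E)^2 / E`, no continuity correction)
#' with `(r-1)(c-1)` degrees of freedom, as used for group-by-sex count
#' comparisons in demographics tables.
#'
#' @param counts matrix of non-negative integer counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
#' @examples
#' chisq_from_counts(rbind(M = c(12, 30, 16, 21), F = c(22, 37, 26, 33)))
chisq_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0))
    stop("a zero row or column margin gives zero expected counts; ",
         "collapse those categories first")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
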