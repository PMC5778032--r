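make_design <- function(n_per, groups = c("PAT", "NC")) {
  n <- n_per * length(groups)
  data.frame(
    subject = sprintf("s%03d", seq_len(n)),
    group = rep(groups, each = n_per),
    age = rnorm(n, 67, 8),
    sex = rbinom(n, 1, 0.5),
    education = rnorm(n, 11, 4),
    stringsAsFactors = FALSE)
}

test_that("GLM contrast is exactly zero when both groups share the maps", {
  set.seed(50)
  des <- make_design(10)
  half <- matrix(rnorm(10 * 30), 10)
  maps <- rbind(half, half)
  des$age <- rep(des$age[1:10], 2)   # identical covariates too
  des$sex <- rep(des$sex[1:10], 2)
  des$education <- rep(des$education[1:10], 2)
  fit <- fit_vertexwise_glm(maps, des, c("PAT", "NC"))
  expect_equal(fit$estimate, rep(0, 30), tolerance = 1e-10)
})

test_that("GLM matches lm() with explicit per-group offset/slope coding", {
  set.seed(51)
  des <- make_design(15)
  maps <- matrix(rnorm(30 * 5), 30)
  maps[, 2] <- maps[, 2] + 2 * (des$group == "PAT") + 0.05 * des$age
  fit <- fit_vertexwise_glm(maps, des, c("PAT", "NC"))
  for (vtx in 1:5) {
    d <- des
    d$y <- maps[, vtx]
    d$age <- d$age - mean(d$age)
    d$sex <- d$sex - mean(d$sex)
    d$education <- d$education - mean(d$education)
    ref <- lm(y ~ 0 + group + group:age + group:sex + group:education,
              data = d)
    cf <- coef(ref)
    est <- unname(cf["groupPAT"] - cf["groupNC"])
    expect_equal(fit$estimate[vtx], est, tolerance = 1e-10)
    # p-value from the same contrast via the covariance matrix
    vc <- vcov(ref)
    cvec <- as.numeric(names(cf) == "groupPAT") -
      as.numeric(names(cf) == "groupNC")
    tref <- est / sqrt(drop(t(cvec) %*% vc %*% cvec))
    pref <- 2 * pt(-abs(tref), df.residual(ref))
    expect_equal(fit$p[vtx], pref, tolerance = 1e-10)
  }
})

test_that("GLM errors are informative for bad designs and missing data", {
  set.seed(52)
  des <- make_design(8)
  maps <- matrix(rnorm(16 * 4), 16)
  des$sex[des$group == "PAT"] <- 1  # single-sex group -> collinear column
  expect_error(fit_vertexwise_glm(maps, des, c("PAT", "NC")),
               "rank deficient.*sex", perl = TRUE)
  des2 <- make_design(8)
  expect_error(fit_vertexwise_glm(maps, des2, c("PAT", "XX")), "2 subjects")
  des2$age[3] <- NA
  expect_error(fit_vertexwise_glm(maps, des2, c("PAT", "NC")), "complete")
  des3 <- make_design(8)
  maps[3, 2] <- NA  # vertex with a missing subject is dropped + flagged
  fit <- fit_vertexwise_glm(maps, des3, c("PAT", "NC"))
  expect_false(fit$tested[2])
  expect_true(is.na(fit$p[2]))
  expect_true(all(fit$tested[-2]))
})

test_that("a strong planted shift is detected in almost every replicate", {
  # true intercept shift of 2 noise-SDs, n = 30 + 30
  hits <- 0L
  for (rep_i in 1:200) {
    set.seed(600 + rep_i)
    des <- make_design(30)
    y <- rnorm(60) + 2 * (des$group == "PAT")
    fit <- fit_vertexwise_glm(matrix(y, ncol = 1), des, c("PAT", "NC"))
    hits <- hits + (fit$p[1] < 0.05)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("BH mask matches direct step-up enumeration and is alpha-monotone", {
  expect_true(all(fdr_correct(rep(0.001, 8), 0.025)$mask))
  expect_false(any(fdr_correct(rep(1, 8), 0.05)$mask))
  p <- c(0.001, 0.02, 0.2, 0.9)
  expect_equal(fdr_correct(p, 0.05)$mask, oracle_bh(p, 0.05))
  set.seed(70)
  for (i in 1:20) {
    p <- runif(50)^2
    a1 <- fdr_correct(p, 0.01)$mask
    a2 <- fdr_correct(p, 0.05)$mask
    expect_equal(a1, oracle_bh(p, 0.01))
    expect_equal(a2, oracle_bh(p, 0.05))
    expect_true(all(a2[a1]))  # rejections grow with alpha
  }
  # NAs (untested vertices) pass through unselected
  res <- fdr_correct(c(0.001, NA, 0.9), 0.05)
  expect_equal(res$mask, c(TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(numeric(0), 0.05)$n_significant, 0L)
})

test_that("cluster extraction reports components, peaks, areas and counts", {
  m <- make_icosphere(2)
  v <- nrow(m$vertices)
  empty <- extract_clusters(m, rep(FALSE, v), runif(v), rep(1L, v))
  expect_equal(nrow(empty), 0)

  # two disjoint blobs: a 7-vertex patch and a 4-vertex patch
  blob1 <- planted_patch(m, 5L)
  nb <- build_neighborhoods(m, 1L)
  far <- which.max(colSums((t(m$vertices) - m$vertices[5L, ])^2))
  blob2 <- sort(c(far, nb$neighbors[[far]][1:3]))
  stopifnot(length(intersect(blob1, blob2)) == 0)
  mask <- rep(FALSE, v); mask[c(blob1, blob2)] <- TRUE
  set.seed(80)
  p <- runif(v, 0.5, 1)
  p[c(blob1, blob2)] <- runif(length(blob1) + length(blob2), 1e-8, 1e-3)
  sgn <- rep(1L, v)
  tab <- extract_clusters(m, mask, p, sgn)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$n_vertices, c(length(blob1), length(blob2)))
  va <- vertex_areas(m)
  expect_setequal(round(tab$size_mm2, 6),
                  round(c(sum(va[blob1]), sum(va[blob2])), 6))
  expect_equal(tab$peak_log10p[1], max(-log10(p[mask])))

  # singleton cluster
  mask1 <- rep(FALSE, v); mask1[9] <- TRUE
  tab1 <- extract_clusters(m, mask1, p, sgn)
  expect_equal(tab1$n_vertices, 1L)
  expect_equal(tab1$size_mm2, va[9])
  expect_equal(tab1$peak_vertex, 9L)
})

test_that("clusters never mix contrast directions", {
  m <- make_icosphere(1)
  v <- nrow(m$vertices)
  patch <- planted_patch(m, 3L)
  mask <- rep(FALSE, v); mask[patch] <- TRUE
  sgn <- rep(1L, v)
  sgn[patch[1:2]] <- -1L  # adjacent but opposite direction
  p <- rep(1e-4, v)
  tab <- extract_clusters(m, mask, p, sgn)
  expect_equal(sum(tab$direction == "greater"), 1L)
  expect_equal(sum(tab$direction == "less"), 1L)
  expect_equal(sum(tab$n_vertices), length(patch))
  expect_true(all(tab$peak_log10p[tab$direction == "less"] < 0))
})

test_that("cluster areas are invariant to vertex relabeling", {
  set.seed(81)
  m <- make_icosphere(1)
  v <- nrow(m$vertices)
  patch <- planted_patch(m, 7L)
  mask <- rep(FALSE, v); mask[patch] <- TRUE
  p <- runif(v); p[patch] <- 1e-5
  tab <- extract_clusters(m, mask, p, rep(1L, v))
  perm <- sample(v)
  inv <- order(perm)
  m2 <- surface_mesh(m$vertices[perm, ],
                     matrix(inv[m$faces], ncol = 3), m$mask[perm])
  tab2 <- extract_clusters(m2, mask[perm], p[perm], rep(1L, v))
  expect_equal(tab2$size_mm2, tab$size_mm2, tolerance = 1e-9)
  expect_equal(tab2$n_vertices, tab$n_vertices)
})

test_that("partial correlation recovers trivial and closed-form cases", {
  set.seed(90)
  x <- rnorm(40)
  res <- partial_correlation(x, x)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # y exactly equal to a covariate -> zero residual variance, flagged
  cv <- rnorm(40)
  res2 <- partial_correlation(x, cv, covariates = cbind(cv))
  expect_false(res2$defined)
  expect_true(is.na(res2$r))

  # trivariate Gaussian with population partial correlation 0.5
  set.seed(91)
  n <- 5000
  z <- rnorm(n)
  e <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, .5, .5, 1), 2))
  x <- 1.3 * z + e[, 1]
  y <- -0.8 * z + e[, 2]
  res3 <- partial_correlation(x, y, covariates = cbind(z))
  expect_equal(res3$r, 0.5, tolerance = 0.03)
  expect_equal(res3$df, n - 3)

  # matches ppcor-style formula via lm residuals on multiple covariates
  set.seed(92)
  covs <- matrix(rnorm(60 * 3), 60)
  x <- rnorm(60); y <- rnorm(60)
  res4 <- partial_correlation(x, y, covs, n_comparisons = 9)
  rx <- resid(lm(x ~ covs)); ry <- resid(lm(y ~ covs))
  expect_equal(res4$r, cor(rx, ry), tolerance = 1e-12)
  expect_equal(res4$significant, res4$p < 0.05 / 9)

  expect_error(partial_correlation(1:3, 1:3, covariates = cbind(1:3)),
               "complete observations")
})

test_that("summary ANOVA equals raw-data ANOVA on moment-matched samples", {
  set.seed(100)
  for (rep_i in 1:5) {
    k <- sample(2:5, 1)
    n <- sample(5:40, k, replace = TRUE)
    mu <- rnorm(k, 10, 3)
    sd_ <- runif(k, 0.5, 4)
    raw <- mapply(moment_matched_sample, n, mu, sd_, SIMPLIFY = FALSE)
    y <- unlist(raw)
    g <- factor(rep(seq_len(k), n))
    got <- anova_from_summaries(n, mu, sd_)
    ref <- anova(aov(y ~ g))
    expect_equal(got$f, ref[["F value"]][1], tolerance = 1e-9)
    expect_equal(got$p, ref[["Pr(>F)"]][1], tolerance = 1e-9)
    refw <- oneway.test(y ~ g, var.equal = FALSE)
    gotw <- anova_from_summaries(n, mu, sd_, var_equal = FALSE)
    expect_equal(gotw$f, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(gotw$df2, unname(refw$parameter[2]), tolerance = 1e-6)
    expect_equal(gotw$p, refw$p.value, tolerance = 1e-9)
  }
})

test_that("summary ANOVA handles degenerate groups", {
  expect_equal(anova_from_summaries(c(5, 5), c(3, 3), c(1, 1))$f, 0)
  res <- anova_from_summaries(c(5, 5), c(3, 3), c(0, 0))
  expect_false(res$defined)
  expect_error(anova_from_summaries(5, 3, 1), "2 groups")
  expect_error(anova_from_summaries(c(5, 1), c(3, 4), c(1, 1)), "n >= 2")
})

test_that("chi-square from counts matches hand computation", {
  expect_equal(chisq_from_counts(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  prop <- outer(c(100, 150), c(0.2, 0.3, 0.5))
  expect_equal(chisq_from_counts(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chisq_from_counts(rbind(c(1, 0), c(2, 0))), "collapse")
  expect_error(chisq_from_counts(rbind(c(-1, 2), c(2, 3))), "non-negative")
})
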