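sheet_row <- function(id, sex, age, batch = "A", group = "control") {
  data.frame(sample_id = id, group_label = group, sex = sex, age = age,
             batch = batch, array_type = "EPIC", cohort_role = "pool",
             stringsAsFactors = FALSE)
}

test_that("matched controls honour exact variables and nearest age", {
  cases <- sheet_row("C1", "F", 10, group = "case")
  pool <- rbind(sheet_row("K1", "F", 9), sheet_row("K2", "F", 30),
                sheet_row("K3", "M", 10))
  m <- match_controls(cases, pool, ratio = 1)
  expect_equal(m$matches$C1, "K1")

  m2 <- match_controls(cases, pool, ratio = 2)
  expect_setequal(m2$matches$C1, c("K1", "K2"))

  cases_m <- sheet_row("C1", "M", 10, group = "case")
  pool_f <- rbind(sheet_row("K1", "F", 9), sheet_row("K2", "F", 11))
  expect_error(match_controls(cases_m, pool_f, ratio = 1), "insufficient")
})

test_that("matching is without replacement with deterministic tie-breaks", {
  cases <- rbind(sheet_row("C1", "F", 10, group = "case"),
                 sheet_row("C2", "F", 10, group = "case"))
  pool <- rbind(sheet_row("K1", "F", 10), sheet_row("K2", "F", 10),
                sheet_row("K3", "F", 12), sheet_row("K4", "F", 12))
  m <- match_controls(cases, pool, ratio = 2)
  expect_equal(anyDuplicated(m$control_ids), 0L)
  # C1 processed first takes the two age-10 controls, ties by id order
  expect_equal(m$matches$C1, c("K1", "K2"))
  expect_equal(m$matches$C2, c("K3", "K4"))
})

test_that("per-probe OLS matches closed forms", {
  set.seed(3)
  n1 <- 5; n0 <- 7
  ids <- paste0("s", 1:(n1 + n0))
  labels <- stats::setNames(rep(c(1, 0), c(n1, n0)), ids)
  beta <- matrix(runif(20 * 12, 0.2, 0.8), 20, 12,
                 dimnames = list(paste0("p", 1:20), ids))
  fit <- fit_probe_models(beta, labels)
  md <- rowMeans(beta[, 1:n1]) - rowMeans(beta[, n1 + 1:n0])
  expect_equal(unname(fit$delta_beta), unname(md), tolerance = 1e-12)
  expect_equal(fit$df, 12 - 2)

  # n = 2 per group, no covariates: residual df = n - 2
  f2 <- fit_probe_models(beta[, c(1, 2, 6, 7)],
                         labels[c(1, 2, 6, 7)])
  expect_equal(f2$df, 2L)

  # a covariate orthogonal to the label leaves delta_beta unchanged
  ortho <- stats::setNames(rep(c(1, -1), 6), ids)  # balanced within labels?
  ortho[1:n1] <- rep(c(1, -1), length.out = n1)
  ortho[n1 + 1:n0] <- rep(c(1, -1), length.out = n0)
  ortho <- ortho - ave(ortho, labels)  # centre within groups -> orthogonal
  cp <- cbind(cov = ortho, pad = 1 - ortho)
  rownames(cp) <- ids
  fit_cov <- fit_probe_models(beta, labels, cell_proportions = cp)
  expect_equal(fit_cov$delta_beta, fit$delta_beta, tolerance = 1e-10)

  # rank-deficient design errors
  cp_bad <- cbind(c1 = as.numeric(labels), c2 = 1 - as.numeric(labels))
  rownames(cp_bad) <- ids
  expect_error(fit_probe_models(beta, labels, cp_bad), "rank-deficient")
})

test_that("variance squeezing handles the degenerate and limit cases", {
  s2 <- rep(0.02, 50)
  sq <- squeeze_variances(s2, df = 10)
  expect_identical(sq$prior$d0, Inf)
  expect_equal(unname(sq$post_var), s2, tolerance = 1e-9)

  prior_inf <- list(d0 = Inf, s02 = 0.5)
  fit <- list(delta_beta = stats::setNames(c(0.1, -0.2), c("a", "b")),
              s2 = c(1, 2), df = 4, v = 0.5)
  tab <- moderated_t_test(fit, prior_inf)
  expect_equal(tab$t, c(0.1, -0.2) / sqrt(0.5 * 0.5), tolerance = 1e-12)

  expect_error(squeeze_variances(c(rep(0.1, 20), -1), 5), "positive")
  expect_error(squeeze_variances(rep(0.1, 5), 5), "at least 10")
})

test_that("prior recovery and agreement with the established EB implementation", {
  set.seed(42)
  d0 <- 4; s02 <- 0.02; df <- 10
  s2 <- s02 * d0 / rchisq(20000, d0) * (rchisq(20000, df) / df)
  sq <- squeeze_variances(s2, df)
  expect_lt(abs(sq$prior$d0 - d0) / d0, 0.2)
  expect_lt(abs(sq$prior$s02 - s02) / s02, 0.1)

  skip_if_not_installed("limma")
  ref <- limma::squeezeVar(s2, df = df)
  expect_equal(sq$prior$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(sq$prior$s02, ref$var.prior, tolerance = 1e-6)
  expect_equal(unname(sq$post_var), unname(ref$var.post), tolerance = 1e-8)
})

test_that("moderated t reduces to the textbook t-test at d0 = 0", {
  set.seed(8)
  ids <- paste0("s", 1:16)
  labels <- stats::setNames(rep(c(1, 0), each = 8), ids)
  beta <- matrix(runif(30 * 16), 30, 16, dimnames = list(paste0("p", 1:30), ids))
  fit <- fit_probe_models(beta, labels)
  tab <- moderated_t_test(fit, list(d0 = 0, s02 = 1))
  for (i in c(1, 7, 30)) {
    tt <- t.test(beta[i, 1:8], beta[i, 9:16], var.equal = TRUE)
    expect_equal(unname(tab$t[i]), unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
  # zero effect gives t = 0, p = 1
  fit0 <- fit
  fit0$delta_beta[1] <- 0
  tab0 <- moderated_t_test(fit0, list(d0 = 0, s02 = 1))
  expect_equal(tab0$t[1], 0)
  expect_equal(tab0$p[1], 1)
  # doubling the posterior sd halves t
  t1 <- moderated_t_test(fit, list(d0 = Inf, s02 = 0.01))$t
  t2 <- moderated_t_test(fit, list(d0 = Inf, s02 = 0.04))$t
  expect_equal(t1, 2 * t2, tolerance = 1e-12)
})

test_that("full moderated pipeline agrees with limma on the same design", {
  skip_if_not_installed("limma")
  set.seed(13)
  ids <- paste0("s", 1:20)
  labels <- stats::setNames(rep(c(1, 0), each = 10), ids)
  cp <- matrix(runif(40), 20, 2, dimnames = list(ids, c("c1", "c2")))
  cp <- cp / rowSums(cp)
  beta <- matrix(runif(200 * 20, 0.1, 0.9), 200, 20,
                 dimnames = list(paste0("p", 1:200), ids))
  fit <- fit_probe_models(beta, labels, cp)
  tab <- dmp_table(fit)
  design <- cbind(1, labels, cp[, 1])
  lfit <- limma::eBayes(limma::lmFit(beta, design))
  ord <- match(rownames(beta), tab$probe_id)
  expect_equal(tab$t[ord], unname(lfit$t[, 2]), tolerance = 1e-8)
  # p-values only to 1e-3: with an infinite prior df this package uses the
  # normal reference while the reference implementation caps total df at
  # the pooled residual df
  expect_equal(tab$p[ord], unname(lfit$p.value[, 2]), tolerance = 1e-3)
})

test_that("Benjamini-Hochberg matches hand enumeration and the brute-force oracle", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0,1")

  set.seed(2)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("probe AUC enumerates case-control pairs with tie handling", {
  expect_equal(probe_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(probe_auc(rep(0.5, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_equal(probe_auc(c(0.2, 0.3, 0.25, 0.4), c(1, 1, 0, 0)), 0.75)
  expect_error(probe_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("correlation pruning drops near-duplicates in rank order", {
  set.seed(9)
  n <- 40
  base <- rnorm(n)
  beta <- rbind(p1 = pnorm(base), p2 = pnorm(base),        # r = 1 duplicate
                p3 = runif(n), p4 = runif(n))              # independent
  colnames(beta) <- paste0("s", 1:n)
  expect_equal(prune_correlated(rownames(beta), beta), c("p1", "p3", "p4"))

  # constructed pair with r ~ 0.95: lower-ranked member dropped
  y <- pnorm(0.95 * scale(base) + sqrt(1 - 0.95^2) * rnorm(n))
  beta2 <- rbind(a = pnorm(base), b = as.numeric(y))
  colnames(beta2) <- paste0("s", 1:n)
  r <- abs(cor(beta2["a", ], beta2["b", ]))
  if (r > 0.9) expect_equal(prune_correlated(c("a", "b"), beta2), "a")
  expect_equal(prune_correlated(c("a", "b"), beta2, r_max = 0.999), c("a", "b"))
})

test_that("silhouette separation behaves at its extremes", {
  set.seed(21)
  n <- 20
  ids <- paste0("s", 1:(2 * n))
  labels <- stats::setNames(rep(c(1, 0), each = n), ids)
  tight <- cbind(matrix(rnorm(10 * n, 0, 0.01), 10),
                 matrix(rnorm(10 * n, 5, 0.01), 10))
  colnames(tight) <- ids
  rownames(tight) <- paste0("p", 1:10)
  expect_gt(evaluate_separation(tight, labels), 0.9)

  homog <- matrix(rnorm(10 * 2 * n), 10, 2 * n,
                  dimnames = list(paste0("p", 1:10), ids))
  perm <- stats::setNames(sample(labels), ids)
  expect_lt(abs(evaluate_separation(homog, perm)), 0.1)

  # duplicating every sample leaves the score unchanged
  dup <- cbind(tight, tight)
  colnames(dup) <- c(ids, paste0("d", ids))
  lab_dup <- stats::setNames(c(labels, labels), colnames(dup))
  expect_equal(evaluate_separation(dup, lab_dup),
               evaluate_separation(tight, labels), tolerance = 1e-2)

  expect_error(evaluate_separation(tight[0, ], labels), "empty")
})

test_that("episignature selection sweeps cutoffs deterministically", {
  set.seed(31)
  ids <- paste0("s", 1:30)
  labels <- stats::setNames(rep(c(1, 0), c(10, 20)), ids)
  beta <- matrix(runif(100 * 30, 0.3, 0.7), 100, 30,
                 dimnames = list(paste0("p", 1:100), ids))
  beta[1:20, 1:10] <- beta[1:20, 1:10] - 0.25   # informative block
  fit <- fit_probe_models(beta, labels)
  dmp <- dmp_table(fit)

  sel1 <- select_episignature(dmp, beta, labels, cutoff_grid = 20)
  ranked <- dmp$probe_id[1:20]
  expect_equal(sel1$probes, prune_correlated(ranked, beta))
  expect_true(sel1$significant)
  expect_true(all(sel1$probes %in% paste0("p", 1:20)))
  expect_error(select_episignature(dmp, beta, labels, cutoff_grid = numeric(0)),
               "empty")
})

test_that("classical MDS reproduces known geometries", {
  # equilateral triangle, all pairwise distances 1
  d <- matrix(1, 3, 3) - diag(3)
  xy <- classical_mds(d)
  expect_equal(as.matrix(dist(xy)), as.matrix(as.dist(d)), tolerance = 1e-8)

  set.seed(4)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  d2 <- as.matrix(dist(pts))
  xy2 <- classical_mds(d2)
  expect_equal(as.matrix(dist(xy2)), d2, tolerance = 1e-8)

  d0 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(abs(suppressWarnings(classical_mds(d0))) < 1e-12))

  d_bad <- d2; d_bad[1, 2] <- 99
  expect_error(classical_mds(d_bad), "symmetric")
})

test_that("hierarchical clustering matches exhaustive complete linkage", {
  set.seed(6)
  x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  hc <- hierarchical_clustering(x)
  expect_equal(as.matrix(stats::cophenetic(hc)),
               `dimnames<-`(complete_linkage_bruteforce(x), dimnames(as.matrix(stats::cophenetic(hc)))),
               tolerance = 1e-10)

  # duplicated points merge first at height 0
  y <- rbind(a = c(0, 0), a2 = c(0, 0), b = c(5, 5), b2 = c(5, 5))
  hcy <- hierarchical_clustering(y)
  expect_equal(sort(hcy$height)[1:2], c(0, 0))
  expect_true(all(diff(hcy$height) >= -1e-12))  # nondecreasing merge heights

  # newick re-parses to a tree over the same tips
  tree <- ape::read.tree(text = attr(hcy, "newick"))
  expect_setequal(tree$tip.label, rownames(y))
  expect_error(hierarchical_clustering(rbind(c(NA, 1), c(1, 2))), "missing")
})
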