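# Matched-control selection, moderated differential methylation with
# empirical-Bayes variance shrinkage, multiple-testing control, and
# correlation-pruned probe-set selection scored by case/control
# separation.

#' Select matched controls for a set of cases
#'
#' Greedy nearest-neighbour matching without replacement. Cases are
#' processed in sample-id order; each requires `ratio` controls matching
#' exactly on the categorical variables (`exact_on`) and nearest on age,
#' with ties in absolute age difference broken by control id order. If
#' any case cannot be served the call fails listing it — matching
#' constraints are never silently relaxed.
#'
#' @param cases Sample-sheet rows for the cases.
#' @param pool Sample-sheet rows for the candidate controls (disjoint
#'   from cases).
#' @param ratio Controls per case (default 4).
#' @param exact_on Categorical columns requiring exact equality.
#' @param nearest_on Numeric column minimised in absolute difference.
#' @return A list with `matches` (named list case id -> control ids),
#'   `control_ids` (all selected controls) and the matching settings.
#' @export
match_controls <- function(cases, pool, ratio = 4,
                           exact_on = c("sex", "batch", "array_type"),
                           nearest_on = "age") {
  if (ratio < 1) stop("ratio must be >= 1")
  if (length(intersect(cases$sample_id, pool$sample_id)) > 0)
    stop("pool overlaps cases")
  pool_free <- rep(TRUE, nrow(pool))
  matches <- list()
  for (ci in order(cases$sample_id)) {
    case <- cases[ci, ]
    elig <- pool_free
    for (v in exact_on) elig <- elig & (pool[[v]] == case[[v]])
    if (sum(elig) < ratio)
      stop(sprintf("insufficient eligible controls for case '%s' (%d of %d needed)",
                   case$sample_id, sum(elig), ratio))
    cand <- which(elig)
    dist <- abs(pool[[nearest_on]][cand] - case[[nearest_on]])
    ord <- cand[order(dist, pool$sample_id[cand])]
    take <- ord[seq_len(ratio)]
    matches[[case$sample_id]] <- pool$sample_id[take]
    pool_free[take] <- FALSE
  }
  list(matches = matches,
       control_ids = unname(unlist(matches)),
       ratio = ratio, exact_on = exact_on, nearest_on = nearest_on)
}

#' Fit per-probe linear models for differential methylation
#'
#' For every probe, ordinary least squares of the beta value on an
#' intercept, a case indicator, and the cell-proportion covariates (one
#' cell type dropped to avoid the sum-to-one singularity). Returns the
#' case-indicator coefficient (the adjusted case-control beta
#' difference), the residual variance, the residual degrees of freedom
#' and the unscaled coefficient variance from the design.
#'
#' @param beta Probes x samples matrix restricted to cases and controls.
#' @param labels Named 0/1 vector (1 = case) over `colnames(beta)`.
#' @param cell_proportions Optional samples x cell-types fraction matrix;
#'   the last cell-type column is dropped from the design.
#' @return A list with vectors `delta_beta`, `s2` (residual variance),
#'   `df` (residual df), scalar `v` (unscaled variance of the case
#'   coefficient) and the design matrix.
#' @export
fit_probe_models <- function(beta, labels, cell_proportions = NULL) {
  samples <- colnames(beta)
  lab <- labels[samples]
  if (anyNA(lab)) stop("labels missing for some samples")
  if (anyNA(beta)) stop("beta matrix must be complete (filter first)")
  X <- cbind(intercept = 1, case = as.numeric(lab))
  if (!is.null(cell_proportions)) {
    cp <- cell_proportions[samples, -ncol(cell_proportions), drop = FALSE]
    X <- cbind(X, cp)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])]
    stop(sprintf("design is rank-deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  # all-probe OLS in one sweep: coef = Y X (X'X)^-1, residuals by subtraction
  coefs <- beta %*% X %*% xtx_inv
  fitted <- coefs %*% t(X)
  res <- beta - fitted
  df <- ncol(beta) - ncol(X)
  if (df < 1) stop("not enough samples for the design")
  s2 <- rowSums(res^2) / df
  list(delta_beta = coefs[, "case"], s2 = s2, df = df,
       v = xtx_inv["case", "case"], design = X)
}

# Newton inversion of the trigamma function, used when moment-matching
# the variance prior. Monotone decreasing, so the iteration is safe.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < tol) break
  }
  x
}

#' Empirical-Bayes shrinkage of per-probe variances
#'
#' Estimates a scaled inverse-chi-squared prior (d0, s0^2) for the
#' residual variances by moment matching on z = log s^2: the excess of
#' Var(z) over trigamma(df/2) estimates trigamma(d0/2), inverted
#' numerically; the mean equation yields s0^2. When the observed
#' dispersion does not exceed the chi-squared sampling dispersion, d0 is
#' infinite and every posterior variance equals s0^2. Posterior
#' (squeezed) variances are (d0 s0^2 + df s^2) / (d0 + df).
#'
#' @param s2 Positive per-probe residual variances (>= 10 probes).
#' @param df Residual degrees of freedom (scalar).
#' @return A list with `prior` (list d0, s02) and `post_var`.
#' @export
squeeze_variances <- function(s2, df) {
  if (length(s2) < 10) stop("need at least 10 probes to estimate the prior")
  if (any(s2 <= 0)) stop("variances must be positive")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
  } else {
    # no excess dispersion beyond chi-squared sampling: infinite prior df,
    # and the pooled variance is the plain mean
    d0 <- Inf
    s02 <- mean(s2)
    post <- rep(s02, length(s2))
    names(post) <- names(s2)
  }
  list(prior = list(d0 = d0, s02 = s02), post_var = post)
}

#' Moderated t-statistics and p-values
#'
#' t = delta_beta / (s_tilde * sqrt(v)) with s_tilde^2 the squeezed
#' variance; two-sided p-values from the t distribution on d0 + df
#' degrees of freedom (standard normal when d0 is infinite). With d0 = 0
#' the statistic reduces to the ordinary t-test.
#'
#' @param fit Result of [fit_probe_models()].
#' @param prior A variance prior list (d0, s02), e.g. from
#'   [squeeze_variances()]. `post_var` is recomputed from it.
#' @return A data.frame (one row per probe): `probe_id`, `delta_beta`,
#'   `t`, `df_total`, `p`, `direction`.
#' @export
moderated_t_test <- function(fit, prior) {
  if (fit$v <= 0) stop("unscaled coefficient variance must be positive")
  d0 <- prior$d0
  if (is.infinite(d0)) {
    post <- rep(prior$s02, length(fit$s2))
    df_total <- Inf
  } else {
    post <- (d0 * prior$s02 + fit$df * fit$s2) / (d0 + fit$df)
    df_total <- d0 + fit$df
  }
  tstat <- fit$delta_beta / sqrt(post * fit$v)
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(tstat))
       else 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(probe_id = names(fit$delta_beta) %||% seq_along(tstat),
             delta_beta = unname(fit$delta_beta), t = unname(tstat),
             df_total = df_total, p = unname(p),
             direction = ifelse(fit$delta_beta < 0, "hypo", "hyper"),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, mapped back to the input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Build a DMP table from a model fit
#'
#' Convenience wrapper running variance squeezing, moderated t-tests and
#' BH adjustment, returning the table sorted by adjusted then raw p.
#'
#' @param fit Result of [fit_probe_models()].
#' @return A DMP data.frame with `adj_p` added.
#' @export
dmp_table <- function(fit) {
  sq <- squeeze_variances(fit$s2, fit$df)
  tab <- moderated_t_test(fit, sq$prior)
  tab$adj_p <- benjamini_hochberg(tab$p)
  tab[order(tab$adj_p, tab$p, -abs(tab$delta_beta), tab$probe_id), ]
}

#' Direction-agnostic probe AUC
#'
#' Mann-Whitney AUC of a single probe's beta values separating cases
#' from controls, folded as max(A, 1 - A) so that it measures importance
#' irrespective of direction. Ties count one half.
#'
#' @param values Numeric beta values for one probe.
#' @param labels Logical or 0/1 vector, TRUE/1 = case.
#' @return AUC in \[0.5, 1\].
#' @export
probe_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(auc, 1 - auc)
}

#' Prune correlated probes
#'
#' Greedy scan in the given rank order: a probe is dropped iff its
#' absolute Pearson correlation (across samples) with any
#' already-retained probe exceeds `r_max`.
#'
#' @param candidates Probe ids ordered by importance (best first).
#' @param beta Probes x samples matrix containing the candidates.
#' @param r_max Correlation ceiling (default 0.9).
#' @return Retained probe ids, in rank order.
#' @export
prune_correlated <- function(candidates, beta, r_max = 0.9) {
  miss <- setdiff(candidates, rownames(beta))
  if (length(miss) > 0) stop(sprintf("candidate probe(s) missing from beta: %s", miss[1L]))
  if (length(candidates) <= 1) return(candidates)
  x <- t(beta[candidates, , drop = FALSE])
  cm <- abs(suppressWarnings(stats::cor(x)))
  cm[is.na(cm)] <- 0
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    if (!any(keep) || all(cm[i, keep] <= r_max)) keep[i] <- TRUE
  }
  candidates[keep]
}

#' Case/control separation score
#'
#' Mean silhouette width of the case/control labelling under Euclidean
#' distance on the given probe subset; 1 means tight, well-separated
#' label-pure clusters, 0 no structure.
#'
#' @param beta Probes x samples matrix restricted to the probe set.
#' @param labels Named binary vector over samples.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
evaluate_separation <- function(beta, labels) {
  if (nrow(beta) == 0) stop("empty probe set")
  lab <- as.integer(as.logical(labels[colnames(beta)])) + 1L
  if (length(unique(lab)) < 2 || min(table(lab)) < 2)
    stop("need >= 2 samples per class")
  d <- stats::dist(t(beta))
  sil <- cluster::silhouette(lab, d)
  mean(sil[, "sil_width"])
}

#' Select the episignature probe set
#'
#' Sweeps candidate cutoffs: each grid entry below 1 is an adjusted-p
#' threshold, each entry >= 1 a top-n size. For each cutoff the top
#' probes (ranked by adjusted p, ties by |delta_beta| descending then
#' probe id) are pruned for inter-probe correlation and scored by
#' case/control silhouette; the highest-scoring set wins, ties going to
#' the smaller set. A selection whose best score is below
#' `min_separation` is flagged non-significant.
#'
#' @param dmp A DMP table (from [dmp_table()]).
#' @param beta Probes x samples matrix (cases + controls).
#' @param labels Named binary vector over samples.
#' @param cutoff_grid Numeric vector of adjusted-p thresholds (< 1)
#'   and/or set sizes (>= 1).
#' @param r_max Correlation-pruning ceiling.
#' @param min_separation Silhouette below which the selection is flagged.
#' @return A list with `probes`, `score`, `cutoff`, `significant`, and
#'   the per-cutoff sweep log.
#' @export
select_episignature <- function(dmp, beta, labels,
                                cutoff_grid = c(1e-8, 1e-6, 1e-4, 0.01, 0.05),
                                r_max = 0.9, min_separation = 0.25) {
  if (length(cutoff_grid) == 0) stop("cutoff grid is empty")
  ranked <- dmp[order(dmp$adj_p, -abs(dmp$delta_beta), dmp$probe_id), ]
  sweep <- list()
  best <- NULL
  for (cut in cutoff_grid) {
    cand <- if (cut < 1) ranked$probe_id[ranked$adj_p < cut]
            else utils::head(ranked$probe_id, round(cut))
    if (length(cand) < 2) {
      sweep[[as.character(cut)]] <- list(cutoff = cut, n_candidates = length(cand),
                                         n_retained = length(cand), score = NA_real_)
      next
    }
    retained <- prune_correlated(cand, beta, r_max)
    score <- evaluate_separation(beta[retained, , drop = FALSE], labels)
    sweep[[as.character(cut)]] <- list(cutoff = cut, n_candidates = length(cand),
                                       n_retained = length(retained), score = score)
    better <- is.null(best) || score > best$score + 1e-12 ||
      (abs(score - best$score) <= 1e-12 && length(retained) < length(best$probes))
    if (better) best <- list(probes = retained, score = score, cutoff = cut)
  }
  if (is.null(best)) {
    # nothing significant at any cutoff (e.g. a null cohort): report an
    # empty, non-significant selection rather than failing
    best <- list(probes = character(0), score = NA_real_, cutoff = NA_real_)
  }
  best$significant <- isTRUE(best$score >= min_separation)
  best$r_max <- r_max
  best$auc <- vapply(best$probes, function(pr)
    probe_auc(beta[pr, ], labels[colnames(beta)]), numeric(1))
  if (length(best$probes) == 0) best$auc <- numeric(0)
  best$sweep <- sweep
  best
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centres -D^2/2 and eigendecomposes it, returning the top-k
#' coordinates scaled by the square root of the eigenvalues; negative
#' eigenvalues are truncated at zero. Deterministic up to axis sign.
#'
#' @param d A symmetric distance matrix (zero diagonal) or `dist`.
#' @param k Number of dimensions (default 2).
#' @return Samples x k coordinate matrix.
#' @export
classical_mds <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < k) {
    # degenerate case (e.g. all points identical): pad with zero axes
    coords <- cbind(coords, matrix(0, nrow(d), k - ncol(coords)))
    rownames(coords) <- rownames(d)
  }
  colnames(coords) <- paste0("MDS", seq_len(k))
  coords
}

#' Hierarchical clustering with newick export
#'
#' Agglomerative clustering (complete linkage by default, the common
#' heatmap default) of samples under Euclidean distance on the supplied
#' probe subset; the merge tree is serialisable to newick with branch
#' lengths derived from merge heights.
#'
#' @param x Samples x features matrix (note: samples in rows).
#' @param method Linkage (default "complete").
#' @return The `hclust` object with the newick string attached as
#'   attribute `newick`.
#' @export
hierarchical_clustering <- function(x, method = "complete") {
  if (anyNA(x)) stop("input contains missing values")
  if (nrow(x) < 2) stop("need at least 2 samples")
  hc <- stats::hclust(stats::dist(x), method = method)
  attr(hc, "newick") <- ape::write.tree(ape::as.phylo(hc))
  hc
}

#' Cut a dendrogram into k groups
#'
#' @param hc An `hclust` tree.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_dendrogram <- function(hc, k = 2) stats::cutree(hc, k = k)
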