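# Probe filtering, reference-based cell-composition estimation, and the
# PCA outlier screen: everything between the raw beta matrix and the
# differential-methylation model.

#' Filter probes before modeling
#'
#' Removes probes in a fixed precedence order, tallying each probe under
#' the first rule that removes it: (1) SNP-overlapping probes, (2)
#' cross-reactive probes, (3) probes on chrX/chrY, (4) probes with a
#' detection p-value above `p_threshold` in any sample, (5) probes with
#' any missing beta value. Filtering is idempotent.
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest Probe manifest covering the matrix's probes.
#' @param detection_p Optional detection-p matrix, same shape as `beta`.
#' @param p_threshold Detection p-value cutoff (default 0.1); a probe is
#'   dropped when any sample exceeds it.
#' @return A list with the filtered `beta` and a `report` of per-rule
#'   removal counts plus the retained count.
#' @export
filter_probes <- function(beta, manifest, detection_p = NULL, p_threshold = 0.1) {
  if (p_threshold < 0 || p_threshold > 1) stop("p_threshold must be in [0,1]")
  probes <- rownames(beta)
  mi <- match(probes, manifest$probe_id)
  if (anyNA(mi)) stop(sprintf("probe '%s' absent from manifest", probes[which(is.na(mi))[1L]]))
  man <- manifest[mi, ]
  removed_by <- rep(NA_character_, length(probes))
  removed_by[man$snp_overlap] <- "snp_overlap"
  mark <- function(cond, rule) {
    sel <- is.na(removed_by) & cond
    removed_by[sel] <<- rule
  }
  mark(man$cross_reactive, "cross_reactive")
  mark(man$chrom %in% c("chrX", "chrY"), "sex_chromosome")
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(beta)))
      stop("detection_p shape differs from beta")
    dp <- detection_p[probes, colnames(beta), drop = FALSE]
    mark(apply(dp > p_threshold, 1L, any), "detection_p")
  }
  mark(apply(is.na(beta), 1L, any), "missingness")
  keep <- is.na(removed_by)
  rules <- c("snp_overlap", "cross_reactive", "sex_chromosome", "detection_p", "missingness")
  counts <- vapply(rules, function(r) sum(removed_by == r, na.rm = TRUE), 0L)
  report <- list(removed = counts, retained = sum(keep),
                 input = length(probes),
                 retained_probes = probes[keep])
  stopifnot(report$retained + sum(report$removed) == report$input)
  list(beta = beta[keep, , drop = FALSE], report = report)
}

# Exact simplex-constrained least squares by support enumeration: for a
# small number of cell types K, every support (subset of nonzero weights)
# admits a closed-form equality-constrained solution; the feasible one
# with minimal residual is the global constrained optimum.
simplex_lsq <- function(R, b) {
  k <- ncol(R)
  best <- NULL; best_rss <- Inf
  for (mask in seq_len(2^k - 1L)) {
    sup <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    Rs <- R[, sup, drop = FALSE]
    A <- crossprod(Rs)
    one <- rep(1, length(sup))
    KKT <- rbind(cbind(2 * A, one), c(one, 0))
    rhs <- c(2 * crossprod(Rs, b), 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_along(sup)]
    if (any(w < -1e-9)) next
    rss <- sum((b - Rs %*% w)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best <- numeric(k); best[sup] <- pmax(w, 0)
    }
  }
  best / sum(best)
}

#' Estimate leukocyte proportions by reference-based deconvolution
#'
#' For each sample solves the constrained least-squares problem
#' \eqn{\min_w \|b - R w\|^2} subject to \eqn{w \ge 0}, \eqn{\sum w = 1},
#' where `R` holds reference beta profiles (probes x cell types)
#' restricted to the reference probes present in the sample. The solve is
#' exact (support enumeration over the small number of cell types) and
#' deterministic.
#'
#' @param beta Probes x samples beta matrix.
#' @param reference Probes x cell-types matrix of reference beta values;
#'   its probes must be a subset of `beta`'s.
#' @param probes Optional subset of reference probes to use (defaults to
#'   all reference probes found in `beta`).
#' @return Samples x cell-types matrix of fractions, each row summing
#'   to 1.
#' @export
estimate_cell_proportions <- function(beta, reference, probes = NULL) {
  ref_probes <- probes %||% intersect(rownames(reference), rownames(beta))
  if (length(ref_probes) < ncol(reference))
    stop("fewer informative reference probes than cell types")
  R <- reference[ref_probes, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    dep <- colnames(R)[setdiff(seq_len(ncol(R)), qrR$pivot[seq_len(qrR$rank)])]
    stop(sprintf("reference is rank-deficient; collinear cell types: %s",
                 paste(dep, collapse = ", ")))
  }
  B <- beta[ref_probes, , drop = FALSE]
  out <- t(vapply(seq_len(ncol(B)), function(j) simplex_lsq(R, B[, j]),
                  numeric(ncol(R))))
  dimnames(out) <- list(colnames(beta), colnames(reference))
  out
}

#' Screen samples for PCA outliers
#'
#' Projects centred samples onto the top `k_components` principal axes
#' and flags any sample whose score on some axis lies more than
#' `sd_threshold` robust standard deviations (1.4826 x MAD) from the
#' axis median. Flagged samples are reported, never dropped: exclusion is
#' an analyst decision.
#'
#' @param beta Probes x samples beta matrix (complete rows only).
#' @param k_components Number of principal axes to inspect.
#' @param sd_threshold Robust-SD multiple beyond which a score flags.
#' @return Character vector of flagged sample ids (possibly empty), with
#'   the score matrix attached as attribute `scores`.
#' @export
pca_outlier_screen <- function(beta, k_components = 3, sd_threshold = 3) {
  n <- ncol(beta)
  if (n < 4) stop("outlier screen needs at least 4 samples")
  if (k_components >= n) stop("k_components must be < number of samples")
  x <- t(beta[stats::complete.cases(beta), , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k_components)
  scores <- pc$x[, seq_len(k_components), drop = FALSE]
  flagged <- apply(scores, 2L, function(s) {
    m <- stats::median(s); d <- stats::mad(s)
    if (d == 0) rep(FALSE, length(s)) else abs(s - m) > sd_threshold * d
  })
  ids <- rownames(scores)[apply(flagged, 1L, any)]
  attr(ids, "scores") <- scores
  ids
}
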