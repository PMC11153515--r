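# Cross-cohort DMP overlap and relatedness: each cohort contributes a
# signature (its top DMPs and a median methylation-difference profile);
# signatures are compared by shared-probe percentages and clustered into
# a newick tree with per-cohort size and mean-difference attributes.

#' Top differentially methylated probes of a cohort
#'
#' Probes with adjusted p below `alpha`, ranked by adjusted p (ties by
#' |delta_beta| descending, then probe id), truncated at `cap` — i.e.
#' n = min(#significant DMPs, cap).
#'
#' @param dmp A DMP table.
#' @param cap Maximum number of probes (default 500).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return Character vector of probe ids (possibly empty).
#' @export
top_dmps <- function(dmp, cap = 500, alpha = 0.05) {
  sig <- dmp[dmp$adj_p < alpha, ]
  sig <- sig[order(sig$adj_p, -abs(sig$delta_beta), sig$probe_id), ]
  utils::head(sig$probe_id, cap)
}

#' Build a cohort signature
#'
#' Bundles a cohort's DMP table, its top DMP set, and its median
#' methylation-difference profile: per probe, the median over case
#' samples of the sample's beta minus the mean control beta.
#'
#' @param id Cohort identifier.
#' @param dmp The cohort's DMP table.
#' @param beta Probes x samples beta matrix.
#' @param case_ids,control_ids Sample ids of the cohort's cases and of
#'   its (matched) controls.
#' @param cap,alpha Passed to [top_dmps()].
#' @return An object of class `cohort_signature`.
#' @export
cohort_signature <- function(id, dmp, beta, case_ids, control_ids,
                             cap = 500, alpha = 0.05) {
  diffs <- beta[, case_ids, drop = FALSE] -
    rowMeans(beta[, control_ids, drop = FALSE])
  profile <- apply(diffs, 1L, stats::median)
  sig <- list(id = id, dmp = dmp, top = top_dmps(dmp, cap, alpha),
              profile = profile, mean_diff = mean(profile[top_dmps(dmp, cap, alpha)]))
  class(sig) <- "cohort_signature"
  sig
}

#' Pairwise DMP overlap percentages between cohorts
#'
#' Entry (y, x) is the percentage of cohort y's top probes that also
#' occur in cohort x's top set: 100 |top(y) n top(x)| / |top(y)|. The
#' diagonal is 100; the matrix is generally asymmetric. A cohort with an
#' empty top set yields a zero row with a warning.
#'
#' @param signatures List of `cohort_signature` objects with unique ids.
#' @return Square percentage matrix with cohort-id dimnames.
#' @export
overlap_matrix <- function(signatures) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  ids <- vapply(signatures, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate cohort ids")
  tops <- lapply(signatures, `[[`, "top")
  names(tops) <- ids
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (y in ids) {
    if (length(tops[[y]]) == 0) {
      warning(sprintf("cohort '%s' has no significant DMPs; zero overlap row", y))
      next
    }
    for (x in ids) {
      m[y, x] <- 100 * length(intersect(tops[[y]], tops[[x]])) / length(tops[[y]])
    }
  }
  m
}

#' Shared-probe pair table
#'
#' Long-format table of every cohort pair with the shared-probe count
#' and both directed overlap percentages (the data behind circos-style
#' displays).
#'
#' @param signatures List of `cohort_signature` objects.
#' @return A data.frame: cohort_a, cohort_b, shared, pct_a_in_b,
#'   pct_b_in_a.
#' @export
shared_probe_pairs <- function(signatures) {
  ids <- vapply(signatures, `[[`, "", "id")
  tops <- stats::setNames(lapply(signatures, `[[`, "top"), ids)
  pairs <- utils::combn(ids, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    shared <- length(intersect(tops[[a]], tops[[b]]))
    data.frame(cohort_a = a, cohort_b = b, shared = shared,
               pct_a_in_b = if (length(tops[[a]])) 100 * shared / length(tops[[a]]) else 0,
               pct_b_in_a = if (length(tops[[b]])) 100 * shared / length(tops[[b]]) else 0,
               stringsAsFactors = FALSE)
  }))
}

#' Relatedness tree over cohort signatures
#'
#' Aggregates each cohort to its median methylation-difference profile
#' restricted to the union of all cohorts' top DMP sets, clusters the
#' profiles hierarchically under Euclidean distance (same engine as
#' discovery), and returns the newick tree plus per-cohort node
#' attributes: the number of selected DMPs (node size) and the global
#' mean methylation difference over the cohort's own top set (node
#' colour value; negative = net hypomethylation).
#'
#' @param signatures List of `cohort_signature` objects (>= 2).
#' @param method Linkage passed to [hierarchical_clustering()].
#' @return A list: `newick`, `hclust`, `attributes` (data.frame cohort,
#'   n_dmps, mean_diff), `universe` (the union probe set).
#' @export
cohort_tree <- function(signatures, method = "complete") {
  ids <- vapply(signatures, `[[`, "", "id")
  universe <- sort(unique(unlist(lapply(signatures, `[[`, "top"))))
  if (length(universe) == 0) stop("probe universe is empty (no cohort has DMPs)")
  prof <- t(vapply(signatures, function(s) {
    p <- s$profile[universe]
    p[is.na(p)] <- 0
    unname(p)
  }, numeric(length(universe))))
  rownames(prof) <- ids
  hc <- hierarchical_clustering(prof, method = method)
  attrs <- data.frame(
    cohort = ids,
    n_dmps = vapply(signatures, function(s) length(s$top), 0L),
    mean_diff = vapply(signatures, function(s)
      if (length(s$top)) mean(s$profile[s$top]) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  list(newick = attr(hc, "newick"), hclust = hc, attributes = attrs,
       universe = universe)
}
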