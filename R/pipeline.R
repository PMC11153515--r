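# Orchestration: the end-to-end discovery workflow (filter -> match ->
# differential methylation -> selection -> train -> annotate) and the
# validation workflow (score + co-clustering), with seeded determinism
# and a config hash embedded in every output file.

#' Hash a configuration object
#'
#' MD5 of the deparsed configuration, used to stamp outputs so a run is
#' auditable against its settings.
#'
#' @param config Any serialisable R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config, control = "all"), f)
  unname(tools::md5sum(f))
}

#' Matched case-control differential methylation and probe selection
#'
#' The analysis core shared by the discovery pipeline and
#' cross-validation: select matched controls for the given cases, fit
#' per-probe linear models adjusted for cell proportions, squeeze
#' variances, compute moderated t / BH adjusted p, and select the
#' episignature probe set by the cutoff sweep.
#'
#' @param beta Filtered probes x samples beta matrix.
#' @param sheet Sample sheet.
#' @param cell_proportions Samples x cell-types fractions.
#' @param case_ids Case sample ids to analyse (default: discovery cases).
#' @param ratio Matching ratio (controls per case).
#' @param cutoff_grid Passed to [select_episignature()].
#' @param r_max Correlation-pruning ceiling.
#' @return A list: `match`, `fit`, `dmp` (table), `selection`, `labels`.
#' @export
run_case_control_analysis <- function(beta, sheet, cell_proportions,
                                      case_ids = NULL, ratio = 4,
                                      cutoff_grid = c(1e-8, 1e-6, 1e-4, 0.01, 0.05),
                                      r_max = 0.9) {
  if (is.null(case_ids))
    case_ids <- sort(sheet$sample_id[sheet$group_label == "case" &
                                       sheet$cohort_role == "discovery"])
  cases <- sheet[sheet$sample_id %in% case_ids, ]
  pool <- sheet[sheet$group_label == "control", ]
  mres <- match_controls(cases, pool, ratio = ratio)
  ids <- c(case_ids, mres$control_ids)
  labels <- stats::setNames(as.integer(ids %in% case_ids), ids)
  sub <- beta[, ids, drop = FALSE]
  fit <- fit_probe_models(sub, labels, cell_proportions[ids, , drop = FALSE])
  dmp <- dmp_table(fit)
  sel <- select_episignature(dmp, sub, labels, cutoff_grid = cutoff_grid,
                             r_max = r_max)
  list(match = mres, fit = fit, dmp = dmp, selection = sel, labels = labels)
}

#' Run the discovery pipeline end to end
#'
#' Executes preprocessing (probe filtering, deconvolution, PCA outlier
#' screen), matched-control selection, moderated differential
#' methylation, episignature selection, SVM training with the 75/25
#' partition, CGI/gene annotation of the selected probes and DMR
#' detection. When `out_dir` is given every artifact is written as TSV
#' stamped with the config hash; identical config and inputs reproduce
#' byte-identical outputs.
#'
#' @param beta Probes x samples beta matrix (unfiltered).
#' @param detection_p Optional detection-p matrix.
#' @param sheet Sample sheet.
#' @param manifest Probe manifest.
#' @param cell_reference Probes x cell-types reference beta profiles.
#' @param cgis,genes Optional CGI intervals and gene models; annotation
#'   is skipped when absent.
#' @param params List of thresholds overriding [default_params()].
#' @param out_dir Optional output directory.
#' @return A list with every stage's result (`filter`, `outliers`,
#'   `cell_proportions`, `analysis`, `partition`, `model`, `annotation`,
#'   `dmrs`, `config_hash`, `log`).
#' @export
run_discovery_pipeline <- function(beta, detection_p = NULL, sheet, manifest,
                                   cell_reference, cgis = NULL, genes = NULL,
                                   params = list(), out_dir = NULL) {
  p <- utils::modifyList(default_params(), params)
  cfg_hash <- config_hash(list(params = p, samples = sheet$sample_id,
                               probes = dim(beta)))
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE))
    log[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  validate_sample_sheet(sheet)
  filt <- tick("preprocess", {
    validate_beta_matrix(beta)
    filter_probes(beta, manifest, detection_p, p_threshold = p$detection_p)
  })
  cellp <- tick("deconvolution",
                estimate_cell_proportions(filt$beta, cell_reference))
  outl <- tick("outlier_screen",
               pca_outlier_screen(filt$beta, k_components = p$pca_k,
                                  sd_threshold = p$pca_sd))
  if (length(outl) > 0)
    warning(sprintf("PCA outlier screen flagged: %s (not dropped)",
                    paste(outl, collapse = ", ")))
  ana <- tick("discovery",
              run_case_control_analysis(filt$beta, sheet, cellp,
                                        ratio = p$match_ratio,
                                        cutoff_grid = p$cutoff_grid,
                                        r_max = p$r_max))
  case_ids <- names(ana$labels)[ana$labels == 1]
  part <- tick("partition",
               assemble_training_partition(
                 sheet, case_ids, ana$match$control_ids,
                 fraction = p$train_fraction, seed = p$seed,
                 exclude = sheet$sample_id[sheet$cohort_role == "validation"]))
  model <- tick("train", train_mvp(filt$beta, part, ana$selection$probes))
  annot <- NULL; dmrs <- NULL
  if (!is.null(cgis) && !is.null(genes)) {
    sel_man <- manifest[manifest$probe_id %in% ana$selection$probes, ]
    annot <- tick("annotate", list(
      cgi = annotate_cgi_context(sel_man, cgis, p$shore_bp, p$shelf_bp),
      gene = annotate_gene_context(sel_man, genes, p$promoter_bp, p$promoter_plus_bp)))
    dmrs <- tick("dmr", detect_dmrs(ana$dmp, manifest,
                                    min_probes = p$dmr_min_probes,
                                    max_span = p$dmr_max_span,
                                    alpha = p$alpha))
  }
  res <- list(filter = filt$report, outliers = outl,
              cell_proportions = cellp, analysis = ana, partition = part,
              model = model, annotation = annot, dmrs = dmrs,
              params = p, config_hash = cfg_hash, log = log)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Default pipeline parameters
#'
#' The numeric constants of the workflow: detection-p cutoff 0.1, DMP
#' significance 0.05, matching ratio 4, training fraction 0.75, MVP
#' report bound 0.75, holdout rounds 20 at fraction 0.25, top-n cap 500,
#' DMR window (5 probes / 1000 bp), shore/shelf 2/4 kb, promoter 1 kb
#' and promoter+ 5 kb.
#'
#' @return Named list of defaults.
#' @export
default_params <- function() {
  list(detection_p = 0.1, alpha = 0.05, match_ratio = 4,
       train_fraction = 0.75, mvp_bound = 0.75, threshold = 0.5,
       holdout_rounds = 20, holdout_frac = 0.25, top_cap = 500,
       dmr_min_probes = 5, dmr_max_span = 1000,
       shore_bp = 2000, shelf_bp = 4000,
       promoter_bp = 1000, promoter_plus_bp = 5000,
       cutoff_grid = c(1e-8, 1e-6, 1e-4, 0.01, 0.05),
       r_max = 0.9, pca_k = 3, pca_sd = 3, seed = 1L)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cm <- paste("config_hash:", res$config_hash)
  write_table(res$analysis$dmp, file.path(out_dir, "dmp_table.tsv"), comment = cm)
  write_table(data.frame(probe_id = res$analysis$selection$probes,
                         auc = unname(res$analysis$selection$auc)),
              file.path(out_dir, "episignature_probes.tsv"), comment = cm)
  write_matrix(res$cell_proportions, file.path(out_dir, "cell_proportions.tsv"),
               id_col = "sample_id", comment = cm)
  fr <- res$filter
  write_table(data.frame(rule = c(names(fr$removed), "retained"),
                         count = c(unname(fr$removed), fr$retained)),
              file.path(out_dir, "filter_report.tsv"), comment = cm)
  if (!is.null(res$dmrs)) write_table(res$dmrs, file.path(out_dir, "dmrs.tsv"), comment = cm)
  if (!is.null(res$annotation)) {
    write_table(res$annotation$cgi$context, file.path(out_dir, "cgi_context.tsv"), comment = cm)
    write_table(res$annotation$gene$context, file.path(out_dir, "gene_context.tsv"), comment = cm)
  }
  invisible(out_dir)
}

#' Run the validation workflow
#'
#' Scores validation samples with a trained model, then re-embeds the
#' discovery cases, their matched controls and the validation samples by
#' MDS and hierarchical clustering on the frozen probe set, reporting
#' for each validation sample its MVP score, its cluster at the 2-cut,
#' and whether it co-clusters with the discovery cases.
#'
#' @param beta Filtered probes x samples beta matrix covering discovery,
#'   matched-control and validation samples.
#' @param discovery Result of [run_discovery_pipeline()] (or any list
#'   with `model` and `analysis`).
#' @param validation_ids Sample ids to validate (non-empty).
#' @return A list: `scores`, `mds`, `hclust`, `report` (data.frame
#'   sample_id, mvp, cluster, co_clusters_with_cases).
#' @export
run_validation_pipeline <- function(beta, discovery, validation_ids) {
  if (length(validation_ids) == 0) stop("validation set is empty")
  model <- discovery$model
  ana <- discovery$analysis
  miss <- setdiff(validation_ids, colnames(beta))
  if (length(miss) > 0) stop(sprintf("validation sample(s) missing: %s", miss[1L]))
  scores <- score_mvp(model, beta[, validation_ids, drop = FALSE])
  ids <- c(names(ana$labels), validation_ids)
  sub <- t(beta[model$probes, ids, drop = FALSE])
  hc <- hierarchical_clustering(sub)
  cl <- cut_dendrogram(hc, k = 2)
  mds <- classical_mds(stats::dist(sub), k = 2)
  case_ids <- names(ana$labels)[ana$labels == 1]
  case_cluster <- as.integer(names(which.max(table(cl[case_ids]))))
  report <- data.frame(sample_id = validation_ids,
                       mvp = unname(scores[validation_ids]),
                       cluster = unname(cl[validation_ids]),
                       co_clusters_with_cases = unname(cl[validation_ids]) == case_cluster,
                       stringsAsFactors = FALSE)
  list(scores = scores, mds = mds, hclust = hc, report = report)
}
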