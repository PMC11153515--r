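# SVM training with the study's partition scheme, Platt-calibrated
# methylation-variant-pathogenicity (MVP) scoring, and the two
# cross-validation protocols (leave-one-out and repeated 25% holdout).

#' Assemble the SVM training partition
#'
#' Label 1 is the cases; label 0 is their matched controls plus a seeded
#' `fraction` draw (stratified per cohort) of every other available
#' sample — unmatched pool controls and other-disorder cohorts. The
#' remaining samples of those cohorts are reserved for testing. All
#' cases and all matched controls always train.
#'
#' @param sheet Sample sheet.
#' @param case_ids Case sample ids (label 1).
#' @param matched_control_ids Matched-control sample ids (label 0).
#' @param fraction Fraction of each other cohort assigned to training
#'   (default 0.75).
#' @param seed Integer seed for the stratified draw.
#' @param exclude Sample ids excluded entirely (e.g. validation cases).
#' @return A list with `train_ids`, `train_labels` (named 0/1),
#'   `test_ids`, `fraction`, `seed`.
#' @export
assemble_training_partition <- function(sheet, case_ids, matched_control_ids,
                                        fraction = 0.75, seed = 1L,
                                        exclude = character(0)) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  others <- sheet[!(sheet$sample_id %in% c(case_ids, matched_control_ids, exclude)), ]
  if (nrow(others) == 0) stop("no other samples available for the 75/25 draw")
  train_other <- character(0); test_other <- character(0)
  with_seed(derive_seed(seed, "partition"), {
    for (g in unique(others$group_label)) {
      ids <- sort(others$sample_id[others$group_label == g])
      n_train <- round(length(ids) * fraction)
      tr <- sort(sample(ids, n_train))
      train_other <- c(train_other, tr)
      test_other <- c(test_other, setdiff(ids, tr))
    }
  })
  train_ids <- c(case_ids, matched_control_ids, train_other)
  labels <- stats::setNames(c(rep(1L, length(case_ids)),
                              rep(0L, length(matched_control_ids) + length(train_other))),
                            train_ids)
  list(train_ids = train_ids, train_labels = labels,
       test_ids = test_other, fraction = fraction, seed = seed)
}

# Platt scaling with the regularised targets from Platt (1999):
# t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2). The fractional targets keep
# the fitted sigmoid finite even when the training classes are linearly
# separable; fitting uses the standard IRLS of glm.
fit_platt <- function(decision, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  t_pos <- (n_pos + 1) / (n_pos + 2); t_neg <- 1 / (n_neg + 2)
  target <- ifelse(labels == 1, t_pos, t_neg)
  fit <- suppressWarnings(stats::glm(target ~ decision,
                                     family = stats::quasibinomial("logit")))
  list(a = unname(stats::coef(fit)["decision"]),
       b = unname(stats::coef(fit)["(Intercept)"]))
}

#' Train the MVP classifier
#'
#' Linear-kernel support vector machine on the probe-restricted beta
#' matrix with inverse-class-frequency weights, followed by sigmoid
#' (Platt) probability calibration of the decision values. The probe set
#' is frozen into the model: scoring later requires exactly those
#' probes.
#'
#' @param beta Probes x samples matrix containing all training samples.
#' @param partition Result of [assemble_training_partition()].
#' @param probe_set Episignature probe ids (frozen).
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `mvp_model`.
#' @export
train_mvp <- function(beta, partition, probe_set, cost = 1) {
  miss <- setdiff(probe_set, rownames(beta))
  if (length(miss) > 0)
    stop(sprintf("probe set absent from beta matrix: %s", paste(utils::head(miss, 5), collapse = ", ")))
  x <- t(beta[probe_set, partition$train_ids, drop = FALSE])
  y <- partition$train_labels[partition$train_ids]
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  yf <- factor(y, levels = c(0, 1))
  cw <- length(y) / (2 * table(yf))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw, probability = FALSE)
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  # e1071 orients the decision value toward the first class label of the
  # "i/j" pair; standardise so larger = more case-like
  flip <- if (colnames(dv)[1] == "0/1") -1 else 1
  dec <- as.numeric(dv) * flip
  platt <- fit_platt(dec, y)
  platt$a <- max(platt$a, 0)  # calibration must be monotone increasing
  model <- list(probes = probe_set, svm = fit, flip = flip,
                calibration = platt, partition = partition,
                classes = levels(yf))
  class(model) <- "mvp_model"
  model
}

#' Score samples with a trained MVP model
#'
#' Applies the frozen SVM and the sigmoid calibration, returning for
#' each sample a methylation-variant-pathogenicity score in \[0, 1\],
#' monotone in the SVM decision value.
#'
#' @param model An `mvp_model`.
#' @param beta Probes x samples matrix containing every frozen probe.
#' @return Named numeric vector of MVP scores.
#' @export
score_mvp <- function(model, beta) {
  miss <- setdiff(model$probes, rownames(beta))
  if (length(miss) > 0)
    stop(sprintf("missing frozen probe(s): %s", paste(utils::head(miss, 5), collapse = ", ")))
  x <- t(beta[model$probes, , drop = FALSE])
  dec <- as.numeric(attr(stats::predict(model$svm, x, decision.values = TRUE),
                         "decision.values")) * model$flip
  scores <- stats::plogis(model$calibration$a * dec + model$calibration$b)
  stats::setNames(scores, colnames(beta))
}

#' Cross-validate the full discovery-to-scoring pipeline
#'
#' Per round the entire pipeline — matched-control selection,
#' differential methylation, probe selection and SVM training — is re-run
#' on the retained samples only, so held-out samples influence nothing;
#' held-out samples are then scored and classified at `threshold`.
#' `mode = "loo"` holds out one discovery case per round;
#' `mode = "repeated_holdout"` holds out a seeded 25% of cases (their
#' matched controls are re-derived from the retained cases, so the
#' held-out cases' controls never enter training).
#'
#' @param beta Filtered probes x samples beta matrix.
#' @param sheet Sample sheet.
#' @param cell_proportions Samples x cell-types matrix for the model
#'   covariates.
#' @param mode "loo" or "repeated_holdout".
#' @param rounds Number of rounds (repeated_holdout only; default 20).
#' @param holdout_frac Fraction of cases held out per round (default
#'   0.25).
#' @param ratio Matching ratio.
#' @param cutoff_grid Passed to [select_episignature()].
#' @param threshold MVP classification threshold (default 0.5).
#' @param seed Integer seed.
#' @return A list of class `cv_result`: per-round holdout ids, scores,
#'   classifications, training ids; and summary accuracy.
#' @export
cross_validate <- function(beta, sheet, cell_proportions,
                           mode = c("loo", "repeated_holdout"),
                           rounds = 20, holdout_frac = 0.25, ratio = 4,
                           cutoff_grid = c(1e-8, 1e-6, 1e-4, 0.01, 0.05),
                           threshold = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (rounds < 1) stop("rounds must be >= 1")
  case_ids <- sort(sheet$sample_id[sheet$group_label == "case" &
                                     sheet$cohort_role == "discovery"])
  holdouts <- if (mode == "loo") {
    lapply(case_ids, identity)
  } else {
    n_hold <- max(1L, round(length(case_ids) * holdout_frac))
    with_seed(derive_seed(seed, "cv"), {
      lapply(seq_len(rounds), function(r) sort(sample(case_ids, n_hold)))
    })
  }
  res <- vector("list", length(holdouts))
  for (r in seq_along(holdouts)) {
    held <- holdouts[[r]]
    retained_cases <- setdiff(case_ids, held)
    fitres <- run_case_control_analysis(beta, sheet, cell_proportions,
                                        case_ids = retained_cases,
                                        ratio = ratio, cutoff_grid = cutoff_grid)
    part <- assemble_training_partition(sheet, retained_cases,
                                        fitres$match$control_ids,
                                        seed = seed + r,
                                        exclude = c(held, sheet$sample_id[sheet$cohort_role == "validation"]))
    model <- train_mvp(beta, part, fitres$selection$probes)
    sc <- score_mvp(model, beta[, held, drop = FALSE])
    res[[r]] <- list(held_out = held, scores = sc,
                     classified_case = sc >= threshold,
                     train_ids = part$train_ids,
                     n_probes = length(fitres$selection$probes))
  }
  all_scores <- unlist(lapply(res, `[[`, "scores"))
  out <- list(mode = mode, rounds = res, threshold = threshold,
              accuracy = mean(all_scores >= threshold))
  class(out) <- "cv_result"
  out
}
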