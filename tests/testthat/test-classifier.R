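make_sheet <- function(n_cases, n_ctrl, n_other) {
  n <- n_cases + n_ctrl + n_other
  data.frame(sample_id = sprintf("s%03d", 1:n),
             group_label = rep(c("case", "control", "other"), c(n_cases, n_ctrl, n_other)),
             sex = "F", age = 10, batch = "b1", array_type = "EPIC",
             cohort_role = rep(c("discovery", "pool", "pool"), c(n_cases, n_ctrl, n_other)),
             stringsAsFactors = FALSE)
}

test_that("training partition implements the 75/25 composition", {
  sheet <- make_sheet(6, 10, 40)
  cases <- sheet$sample_id[1:6]
  matched <- sheet$sample_id[7:12]
  part <- assemble_training_partition(sheet, cases, matched, seed = 3)
  others <- setdiff(sheet$sample_id, c(cases, matched))
  expect_length(intersect(part$train_ids, others), 33)  # 0.75 of 4 ctrl + 40 other
  expect_length(part$test_ids, 11)
  expect_true(all(cases %in% part$train_ids))
  expect_false(any(cases %in% part$test_ids))
  expect_length(intersect(part$train_ids, part$test_ids), 0)
  expect_equal(unname(part$train_labels[cases]), rep(1L, 6))
  expect_equal(unname(part$train_labels[matched]), rep(0L, 6))

  part2 <- assemble_training_partition(sheet, cases, matched, seed = 3)
  expect_identical(part, part2)
  expect_error(assemble_training_partition(sheet, cases, matched, fraction = 1.5),
               "fraction")
})

toy_model <- function(shift = -0.2, n_probes = 12, seed = 17) {
  set.seed(seed)
  sheet <- make_sheet(8, 16, 20)
  ids <- sheet$sample_id
  beta <- matrix(runif(n_probes * length(ids), 0.4, 0.6), n_probes, length(ids),
                 dimnames = list(paste0("p", 1:n_probes), ids))
  cases <- ids[sheet$group_label == "case"]
  beta[, cases] <- pmax(beta[, cases] + shift, 0.01)
  part <- assemble_training_partition(sheet, cases, ids[9:24], seed = 1)
  list(beta = beta, sheet = sheet, part = part, cases = cases)
}

test_that("the SVM separates a shifted toy cohort and freezes its probes", {
  tm <- toy_model()
  model <- train_mvp(tm$beta, tm$part, rownames(tm$beta))
  tr_scores <- score_mvp(model, tm$beta[, tm$part$train_ids])
  pred <- as.integer(tr_scores >= 0.5)
  expect_equal(pred, unname(tm$part$train_labels[tm$part$train_ids]))

  expect_error(train_mvp(tm$beta[-1, ], tm$part, rownames(tm$beta)), "absent")
  expect_error(score_mvp(model, tm$beta[-1, ]), "missing frozen")

  one_class <- tm$part
  one_class$train_labels[] <- 0L
  expect_error(train_mvp(tm$beta, one_class, rownames(tm$beta)), "both classes")
})

test_that("MVP scores live in [0,1] and increase with case-like shifts", {
  tm <- toy_model()
  model <- train_mvp(tm$beta, tm$part, rownames(tm$beta))
  sc <- score_mvp(model, tm$beta)
  expect_true(all(sc >= 0 & sc <= 1))

  # push a control towards the case profile: score must not decrease
  ctrl <- tm$sheet$sample_id[20]
  shifts <- seq(0, -0.25, by = -0.05)
  scores <- vapply(shifts, function(s) {
    b <- tm$beta[, ctrl, drop = FALSE] + s
    colnames(b) <- "probe_shifted"
    unname(score_mvp(model, pmax(b, 0.001)))
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("without a real signature, held-out scores carry no discrimination", {
  # a signal-free cohort: labels are arbitrary, so the trained scorer
  # cannot discriminate held-out "cases" from the rest
  tm <- toy_model(shift = 0)
  set.seed(99)
  held <- c(tm$cases[6:8], setdiff(colnames(tm$beta), tm$cases)[1:14])
  train <- setdiff(colnames(tm$beta), held)
  labels <- stats::setNames(as.integer(train %in% tm$cases), train)
  truth <- as.integer(held %in% tm$cases)
  aucs <- vapply(1:5, function(i) {
    perm <- list(train_ids = train,
                 train_labels = stats::setNames(sample(labels), train),
                 test_ids = held, fraction = 0.5, seed = i)
    model <- train_mvp(tm$beta, perm, rownames(tm$beta))
    sc <- score_mvp(model, tm$beta[, held])
    rk <- rank(sc)
    pos <- truth == 1
    (sum(rk[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.3)
})

test_that("cross-validation re-runs the pipeline without leakage", {
  tc <- tiny_sim()
  sim <- tc$sim
  filt <- filter_probes(sim$beta, tc$ann$manifest, sim$detection_p)
  cellp <- estimate_cell_proportions(filt$beta, sim$cell_reference)
  cv <- cross_validate(filt$beta, sim$sheet, cellp, mode = "repeated_holdout",
                       rounds = 3, ratio = 4, seed = 5)
  for (r in cv$rounds) {
    expect_length(intersect(r$held_out, r$train_ids), 0)
    expect_true(all(r$scores >= 0 & r$scores <= 1))
  }
  expect_error(cross_validate(filt$beta, sim$sheet, cellp, rounds = 0), "rounds")

  # LOO holds each discovery case out exactly once and classifies it a case
  loo <- cross_validate(filt$beta, sim$sheet, cellp, mode = "loo", seed = 5)
  held <- unlist(lapply(loo$rounds, `[[`, "held_out"))
  disc <- sim$sheet$sample_id[sim$sheet$cohort_role == "discovery"]
  expect_setequal(held, disc)
  expect_equal(anyDuplicated(held), 0L)
  expect_true(all(unlist(lapply(loo$rounds, `[[`, "classified_case"))))
})
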