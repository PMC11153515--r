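# Synthetic EPIC-like cohort generator with planted episignatures.
#
# The generator emulates the data a blood methylation study measures:
# bimodal probe baselines, Dirichlet leukocyte composition acting through
# cell-type reference profiles, batch shifts on the logit (M-value) scale,
# a planted case signature specified directly in beta units, sporadic
# detection failures, and flagged SNP-overlap / cross-reactive /
# sex-chromosome probes. Additional "other-disorder" cohorts carry their
# own disjoint planted signatures, standing in for a reference database
# of known episignatures.

#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults mirror
#' the study design the package models: 24 discovery + 5 validation
#' cases, a planted signature of 296 probes of which 98.6% are
#' hypomethylated with a mean case-control beta shift of 0.10, a control
#' pool of 200, and two other-disorder cohorts of 20 samples each.
#'
#' @param seed Integer seed; all randomness flows from it via per-stage
#'   derived sub-seeds.
#' @param n_probes Number of probes on the synthetic array.
#' @param chrom_layout Named integer vector of chromosome lengths (bp).
#' @param n_cases,n_controls Number of affected cases / pool controls.
#' @param n_validation_cases Cases held out of discovery for validation.
#' @param other_cohorts Data.frame with columns `name`, `n`,
#'   `signature_size` describing other-disorder cohorts.
#' @param signature_size Number of planted case-signature probes.
#' @param frac_hypo Fraction of signature probes hypomethylated in cases.
#' @param delta_beta Mean absolute case-control beta shift on signature
#'   probes (beta units).
#' @param noise_sd I.i.d. technical noise sd on the logit scale.
#' @param n_cell_types Number of leukocyte reference cell types.
#' @param dirichlet_alpha Dirichlet concentration for per-sample cell
#'   fractions (length `n_cell_types`, recycled if scalar).
#' @param cell_probe_fraction Fraction of probes whose expected beta is a
#'   cell-fraction-weighted mix of reference profiles.
#' @param batch_levels Batch level names.
#' @param batch_sd Sd of the per-batch, per-probe additive logit shift.
#' @param detection_fail_rate Per-entry probability a detection p-value
#'   exceeds 0.1 (a failed measurement).
#' @param snp_overlap_rate,cross_reactive_rate Probe flag rates.
#' @param sex_chrom_probe_fraction Fraction of probes on chrX/chrY.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 10000L,
                       chrom_layout = NULL,
                       n_cases = 24L,
                       n_controls = 200L,
                       n_validation_cases = 5L,
                       other_cohorts = data.frame(
                         name = c("disorderA", "disorderB"),
                         n = c(20L, 20L),
                         signature_size = c(200L, 200L),
                         stringsAsFactors = FALSE),
                       signature_size = 296L,
                       frac_hypo = 0.986,
                       delta_beta = 0.10,
                       noise_sd = 0.15,
                       n_cell_types = 6L,
                       dirichlet_alpha = c(6, 3, 2, 1.5, 1, 0.8),
                       cell_probe_fraction = 0.2,
                       batch_levels = c("batch1", "batch2"),
                       batch_sd = 0.05,
                       detection_fail_rate = 1e-4,
                       snp_overlap_rate = 0.02,
                       cross_reactive_rate = 0.02,
                       sex_chrom_probe_fraction = 0.03) {
  if (is.null(chrom_layout)) {
    chrom_layout <- stats::setNames(rep(2e6L, 8L), paste0("chr", 1:8))
  }
  dirichlet_alpha <- rep_len(dirichlet_alpha, n_cell_types)
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              chrom_layout = chrom_layout, n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_validation_cases = as.integer(n_validation_cases),
              other_cohorts = other_cohorts,
              signature_size = as.integer(signature_size),
              frac_hypo = frac_hypo, delta_beta = delta_beta,
              noise_sd = noise_sd, n_cell_types = as.integer(n_cell_types),
              dirichlet_alpha = dirichlet_alpha,
              cell_probe_fraction = cell_probe_fraction,
              batch_levels = batch_levels, batch_sd = batch_sd,
              detection_fail_rate = detection_fail_rate,
              snp_overlap_rate = snp_overlap_rate,
              cross_reactive_rate = cross_reactive_rate,
              sex_chrom_probe_fraction = sex_chrom_probe_fraction)
  rates <- c(frac_hypo, cell_probe_fraction, detection_fail_rate,
             snp_overlap_rate, cross_reactive_rate, sex_chrom_probe_fraction)
  if (any(rates < 0 | rates > 1)) stop("sim_config: all rates must be in [0,1]")
  if (snp_overlap_rate + cross_reactive_rate + sex_chrom_probe_fraction > 1)
    stop("sim_config: flag fractions exceed 1")
  total_sig <- signature_size + sum(other_cohorts$signature_size)
  if (total_sig > n_probes) stop("sim_config: planted signatures exceed n_probes")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-stage sub-seed so adding a stage never shifts the
# draws of an earlier one.
derive_seed <- function(seed, stage) {
  offsets <- c(annotation = 11L, cohort = 23L, split = 37L, partition = 41L,
               cv = 53L, noise = 67L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 7919 + off * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)
clip_beta <- function(b) pmin(pmax(b, 0.001), 0.999)

#' Simulate array annotation: manifest, CpG islands, genes
#'
#' Places probes on the configured chromosome layout with clusters seeded
#' near CpG islands, assigns the configured fractions of sex-chromosome
#' and flagged probes, and lays out islands and BED12 gene models so that
#' every CGI context (island/shore/shelf/inter-CGI) and gene context
#' (promoter, promoter+, UTRs, CDS, intron, intergenic) is occupied.
#'
#' @param config A [sim_config()].
#' @return A list with `manifest` (data.frame), `cgis` (BED-style
#'   data.frame) and `genes` (BED12-style data.frame).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "annotation"), {
    autosomes <- names(config$chrom_layout)
    sex_chroms <- c("chrX", "chrY")
    n <- config$n_probes
    n_sex <- round(n * config$sex_chrom_probe_fraction)
    n_auto <- n - n_sex

    # CpG islands: several per autosome, 500-1500 bp long
    cgi_list <- list()
    for (chr in autosomes) {
      len <- config$chrom_layout[[chr]]
      n_cgi <- max(3L, round(len / 4e5))
      starts <- sort(sample.int(len - 20000L, n_cgi))
      widths <- sample(500:1500, n_cgi, replace = TRUE)
      cgi_list[[chr]] <- data.frame(chrom = chr, start = starts,
                                    end = starts + widths,
                                    name = paste0("CGI_", chr, "_", seq_len(n_cgi)),
                                    stringsAsFactors = FALSE)
    }
    cgis <- do.call(rbind, cgi_list)
    rownames(cgis) <- NULL

    # probes: 40% clustered around island neighbourhoods (island through
    # shelf), the rest uniform, to populate every CGI context
    place_on <- sample(autosomes, n_auto, replace = TRUE,
                       prob = config$chrom_layout / sum(config$chrom_layout))
    pos <- integer(n_auto)
    for (i in seq_len(n_auto)) {
      chr <- place_on[i]
      len <- config$chrom_layout[[chr]]
      if (stats::runif(1) < 0.4) {
        ci <- cgis[cgis$chrom == chr, ]
        row <- ci[sample.int(nrow(ci), 1L), ]
        centre <- (row$start + row$end) / 2
        p <- round(centre + stats::rnorm(1, 0, 2500))
        pos[i] <- min(max(p, 1L), len)
      } else {
        pos[i] <- sample.int(len, 1L)
      }
    }
    sex_chr <- if (n_sex > 0) sample(sex_chroms, n_sex, replace = TRUE, prob = c(0.8, 0.2)) else character(0)
    sex_pos <- if (n_sex > 0) sample.int(1e6L, n_sex, replace = TRUE) else integer(0)
    manifest <- data.frame(
      probe_id = sprintf("cg%08d", seq_len(n)),
      chrom = c(place_on, sex_chr),
      pos = c(pos, sex_pos),
      strand = sample(c("+", "-"), n, replace = TRUE),
      snp_overlap = FALSE, cross_reactive = FALSE,
      stringsAsFactors = FALSE)
    # flags only on autosomal probes kept distinct from sex chromosomes
    auto_idx <- which(!manifest$chrom %in% sex_chroms)
    n_snp <- round(n * config$snp_overlap_rate)
    n_xr <- round(n * config$cross_reactive_rate)
    flagged <- sample(auto_idx, min(n_snp + n_xr, length(auto_idx)))
    manifest$snp_overlap[flagged[seq_len(min(n_snp, length(flagged)))]] <- TRUE
    if (length(flagged) > n_snp)
      manifest$cross_reactive[flagged[(n_snp + 1):length(flagged)]] <- TRUE

    # genes: BED12 models with 3 exons, UTRs and CDS; a fraction of probes
    # will fall upstream (promoter / promoter+), inside exons or introns
    gene_list <- list()
    gi <- 0L
    for (chr in autosomes) {
      len <- config$chrom_layout[[chr]]
      n_gene <- max(4L, round(len / 3e5))
      starts <- sort(sample(seq(10000L, len - 60000L), n_gene))
      for (s in starts) {
        gi <- gi + 1L
        span <- sample(8000:40000, 1L)
        e <- s + span
        strand <- sample(c("+", "-"), 1L)
        ex_n <- 3L
        ex_sizes <- sample(300:1200, ex_n, replace = TRUE)
        gap <- (span - sum(ex_sizes)) %/% ex_n
        ex_rel <- cumsum(c(0L, ex_sizes[-ex_n] + gap))
        thick_start <- s + ex_rel[1] + round(ex_sizes[1] / 2)
        thick_end <- s + ex_rel[ex_n] + round(ex_sizes[ex_n] / 2)
        gene_list[[gi]] <- data.frame(
          chrom = chr, start = s, end = e, name = sprintf("GENE%04d", gi),
          score = 0L, strand = strand, thick_start = thick_start,
          thick_end = thick_end, item_rgb = "0", block_count = ex_n,
          block_sizes = paste0(paste(ex_sizes, collapse = ","), ","),
          block_starts = paste0(paste(ex_rel, collapse = ","), ","),
          stringsAsFactors = FALSE)
      }
    }
    genes_bed12 <- do.call(rbind, gene_list)
    genes <- parse_bed12_df(genes_bed12)
    list(manifest = manifest, cgis = cgis[order(cgis$chrom, cgis$start), ], genes = genes)
  })
}

# Shared with read_bed12: turn raw BED12 columns into the validated
# gene-model data.frame with absolute exon coordinates.
parse_bed12_df <- function(df) {
  n <- nrow(df)
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    sizes <- as.integer(strsplit(sub(",$", "", df$block_sizes[i]), ",")[[1]])
    rel <- as.integer(strsplit(sub(",$", "", df$block_starts[i]), ",")[[1]])
    exon_starts[[i]] <- df$start[i] + rel
    exon_ends[[i]] <- df$start[i] + rel + sizes
  }
  out <- df[, c("chrom", "start", "end", "name", "score", "strand",
                "thick_start", "thick_end")]
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Simulate a methylation cohort with planted signatures
#'
#' Generates, in order: per-probe bimodal baseline means; per-sample
#' Dirichlet cell fractions acting through a cell-type reference on the
#' cell-informative probes; per-batch additive logit shifts; the planted
#' case signature (a `delta_beta` shift in beta units, hypomethylated for
#' `frac_hypo` of signature probes) plus disjoint planted signatures for
#' each other-disorder cohort; i.i.d. logit-normal noise; and a
#' detection-p matrix in which a `detection_fail_rate` fraction of
#' entries exceed 0.1. The returned truth object records everything.
#'
#' @param config A [sim_config()].
#' @param annotation Result of [simulate_annotation()] (regenerated from
#'   `config` when omitted).
#' @return A list with `beta`, `detection_p`, `sheet`, `cell_reference`
#'   (probes x cell types), `truth`.
#' @export
simulate_cohort <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  manifest <- annotation$manifest
  with_seed(derive_seed(config$seed, "cohort"), {
    n_probes <- config$n_probes
    probe_ids <- manifest$probe_id

    # sample sheet: cases, controls, other-disorder cohorts. Sex and batch
    # are assigned round-robin within each group (a balanced design), ages
    # drawn uniformly; a single array type.
    oc <- config$other_cohorts
    groups <- c(rep("case", config$n_cases + config$n_validation_cases),
                rep("control", config$n_controls),
                rep(oc$name, oc$n))
    n_samples <- length(groups)
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    sexes <- batches <- character(n_samples)
    for (g in unique(groups)) {
      idx <- which(groups == g)
      sexes[idx] <- rep_len(c("F", "M"), length(idx))
      batches[idx] <- rep_len(config$batch_levels, length(idx))
    }
    ages <- round(stats::runif(n_samples, 1, 35), 1)
    sheet <- data.frame(sample_id = sample_ids, group_label = groups,
                        sex = sexes, age = ages, batch = batches,
                        array_type = "EPIC",
                        cohort_role = "pool", stringsAsFactors = FALSE)

    # (i) bimodal baselines
    comp <- stats::runif(n_probes) < 0.5
    baseline <- ifelse(comp, stats::rbeta(n_probes, 2, 18), stats::rbeta(n_probes, 18, 2))
    names(baseline) <- probe_ids

    # (ii) cell reference + per-sample Dirichlet fractions
    cell_types <- paste0("cell", seq_len(config$n_cell_types))
    n_cell_probes <- round(n_probes * config$cell_probe_fraction)
    # restrict cell-informative probes to clean autosomes so deconvolution
    # survives filtering
    clean <- which(!manifest$snp_overlap & !manifest$cross_reactive &
                     !manifest$chrom %in% c("chrX", "chrY"))
    cell_probes <- sort(sample(clean, min(n_cell_probes, length(clean))))
    cell_ref <- matrix(rep(baseline, config$n_cell_types), ncol = config$n_cell_types,
                       dimnames = list(probe_ids, cell_types))
    shift <- matrix(stats::rnorm(length(cell_probes) * config$n_cell_types, 0, 1.2),
                    nrow = length(cell_probes))
    cell_ref[cell_probes, ] <- expit(logit(clip_beta(baseline[cell_probes])) + shift)
    fractions <- rdirichlet(n_samples, config$dirichlet_alpha)
    dimnames(fractions) <- list(sample_ids, cell_types)

    # expected beta per probe/sample before batch, effects, noise
    mu <- matrix(baseline, nrow = n_probes, ncol = n_samples,
                 dimnames = list(probe_ids, sample_ids))
    mu[cell_probes, ] <- cell_ref[cell_probes, ] %*% t(fractions)

    # planted signatures: disjoint across cohorts, on clean autosomal
    # non-cell probes so they survive filtering and aren't confounded.
    # Hypomethylation is planted on methylated baselines and
    # hypermethylation on unmethylated ones: a CpG can only lose
    # methylation it has, and saturated baselines would otherwise clip
    # into degenerate, mutually duplicated probes.
    plantable <- setdiff(clean, cell_probes)
    hypo_pool <- plantable[baseline[plantable] >= 0.55 & baseline[plantable] <= 0.92]
    hyper_pool <- plantable[baseline[plantable] >= 0.08 & baseline[plantable] <= 0.45]
    n_hypo_all <- round(c(config$signature_size * config$frac_hypo,
                          oc$signature_size * 0.5))
    n_hyper_all <- c(config$signature_size, oc$signature_size) - n_hypo_all
    if (sum(n_hypo_all) > length(hypo_pool) || sum(n_hyper_all) > length(hyper_pool))
      stop("not enough clean probes in the plantable baseline bands")
    hypo_draw <- sample(hypo_pool, sum(n_hypo_all))
    hyper_draw <- sample(hyper_pool, sum(n_hyper_all))
    take <- function(pool, counts, k) {
      lo <- c(0, cumsum(counts))[k] + 1L
      pool[lo:(lo + counts[k] - 1L)]
    }
    cohort_names <- c("case", oc$name)
    signatures <- list()
    for (k in seq_along(cohort_names)) {
      idx_k <- c(if (n_hypo_all[k] > 0) take(hypo_draw, n_hypo_all, k),
                 if (n_hyper_all[k] > 0) take(hyper_draw, n_hyper_all, k))
      dir_k <- rep(c(-1, 1), c(n_hypo_all[k], n_hyper_all[k]))
      mag_k <- config$delta_beta * stats::runif(length(idx_k), 0.6, 1.4)
      signatures[[cohort_names[k]]] <- data.frame(
        probe_id = probe_ids[idx_k],
        direction = ifelse(dir_k < 0, "hypo", "hyper"),
        delta = dir_k * mag_k, stringsAsFactors = FALSE)
    }
    overlap <- duplicated(unlist(lapply(signatures, `[[`, "probe_id")))
    if (any(overlap)) stop("internal error: planted signatures overlap")

    # per-individual effect heterogeneity: the strength of an affected
    # individual's episignature varies around the probe effect
    for (g in names(signatures)) {
      cols <- which(groups == (if (g == "case") "case" else g))
      sig <- signatures[[g]]
      ridx <- match(sig$probe_id, probe_ids)
      het <- matrix(pmax(stats::rnorm(length(ridx) * length(cols), 1, 0.3), 0),
                    nrow = length(ridx))
      mu[ridx, cols] <- clip_beta(mu[ridx, cols] + sig$delta * het)
    }

    # (iii) batch shift and (v) noise on the logit scale
    m <- logit(clip_beta(mu))
    batch_shift <- matrix(stats::rnorm(n_probes * length(config$batch_levels), 0, config$batch_sd),
                          nrow = n_probes,
                          dimnames = list(probe_ids, config$batch_levels))
    m <- m + batch_shift[, batches]
    m <- m + stats::rnorm(length(m), 0, config$noise_sd)
    beta <- expit(m)

    # (vi) detection p
    fail <- matrix(stats::runif(length(beta)) < config$detection_fail_rate,
                   nrow = n_probes)
    detp <- matrix(stats::runif(length(beta), 0, 0.1), nrow = n_probes,
                   dimnames = dimnames(beta))
    detp[fail] <- stats::runif(sum(fail), 0.1 + 1e-9, 1)

    truth <- list(signatures = signatures,
                  cell_fractions = fractions,
                  labels = stats::setNames(groups, sample_ids),
                  baseline = baseline,
                  cell_probes = probe_ids[cell_probes])
    sheet <- split_discovery_validation(sheet, config)
    list(beta = beta, detection_p = detp, sheet = sheet,
         cell_reference = cell_ref, truth = truth)
  })
}

#' Assign discovery / validation roles to case samples
#'
#' Randomly (seeded) divides the case samples into a discovery cohort and
#' a validation cohort of the configured sizes; every non-case sample is
#' assigned to the pool.
#'
#' @param sheet A sample sheet.
#' @param config A [sim_config()]; `n_cases` discovery and
#'   `n_validation_cases` validation cases are drawn.
#' @param seed Optional seed override (defaults to the config seed).
#' @return The sheet with `cohort_role` filled in.
#' @export
split_discovery_validation <- function(sheet, config, seed = NULL) {
  case_idx <- which(sheet$group_label == "case")
  n_disc <- config$n_cases
  n_val <- config$n_validation_cases
  if (length(case_idx) != n_disc + n_val)
    stop(sprintf("split: %d cases cannot be divided into %d + %d",
                 length(case_idx), n_disc, n_val))
  seed <- seed %||% derive_seed(config$seed, "split")
  with_seed(seed, {
    sheet$cohort_role <- "pool"
    disc <- sort(sample(case_idx, n_disc))
    sheet$cohort_role[disc] <- "discovery"
    sheet$cohort_role[setdiff(case_idx, disc)] <- "validation"
  })
  sheet
}

#' Write every simulated artifact to a directory
#'
#' Emits the beta matrix, detection-p matrix, sample sheet, manifest,
#' CGI BED, gene BED12, cell reference and truth tables in the package's
#' on-disk formats, all of which pass the core readers' validation.
#'
#' @param sim Result of [simulate_cohort()].
#' @param annotation Result of [simulate_annotation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, annotation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(sim$beta, file.path(dir, "beta.tsv"))
  write_matrix(sim$detection_p, file.path(dir, "detection_p.tsv"))
  utils::write.csv(sim$sheet, file.path(dir, "samples.csv"), row.names = FALSE, quote = FALSE)
  write_table(annotation$manifest, file.path(dir, "manifest.tsv"))
  bed <- annotation$cgis
  utils::write.table(bed, file.path(dir, "cgi.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- annotation$genes
  bed12 <- data.frame(g$chrom, g$start, g$end, g$name, g$score, g$strand,
                      g$thick_start, g$thick_end, "0",
                      vapply(g$exon_starts, length, 1L),
                      vapply(seq_len(nrow(g)), function(i)
                        paste0(paste(g$exon_ends[[i]] - g$exon_starts[[i]], collapse = ","), ","), ""),
                      vapply(seq_len(nrow(g)), function(i)
                        paste0(paste(g$exon_starts[[i]] - g$start[i], collapse = ","), ","), ""))
  utils::write.table(bed12, file.path(dir, "genes.bed12"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_matrix(sim$cell_reference, file.path(dir, "cell_reference.tsv"))
  write_table(sim$truth$signatures$case, file.path(dir, "truth_signature.tsv"))
  write_matrix(sim$truth$cell_fractions, file.path(dir, "truth_cell_fractions.tsv"),
               id_col = "sample_id")
  invisible(dir)
}
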