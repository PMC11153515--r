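# Shared fixtures and independent oracles. Everything is built in code;
# the tiny simulation keeps unit tests fast while the acceptance suite
# uses the default study-sized configuration.

tiny_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, n_probes = 800L,
               chrom_layout = stats::setNames(rep(5e5L, 4L), paste0("chr", 1:4)),
               n_cases = 8L, n_controls = 64L, n_validation_cases = 2L,
               other_cohorts = data.frame(name = "disorderZ", n = 12L,
                                          signature_size = 30L,
                                          stringsAsFactors = FALSE),
               signature_size = 40L)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config()
      ann <- simulate_annotation(cfg)
      cache <<- list(cfg = cfg, ann = ann, sim = simulate_cohort(cfg, ann))
    }
    cache
  }
})

# brute-force Benjamini-Hochberg step-up: adj_(i) = min_{j>=i} min(1, m p_(j)/j)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive complete-linkage agglomeration, returning the cophenetic
# distance matrix (label-order independent summary of the merge tree)
complete_linkage_bruteforce <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# brute-force DMR caller: enumerate every window of position-sorted
# probes, keep windows of >= min_probes consecutive significant probes
# spanning <= max_span, merge overlapping windows per chromosome
dmr_bruteforce <- function(probe_id, chrom, pos, sig, min_probes = 5, max_span = 1000) {
  ord <- order(chrom, pos)
  probe_id <- probe_id[ord]; chrom <- chrom[ord]; pos <- pos[ord]; sig <- sig[ord]
  regions <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    member <- logical(length(idx))
    for (i in seq_along(idx)) {
      for (j in seq(i, length(idx))) {
        w <- idx[i:j]
        if (!all(sig[w])) break
        if (j - i + 1 >= min_probes && pos[idx[j]] - pos[idx[i]] <= max_span)
          member[i:j] <- TRUE
      }
    }
    r <- rle(member)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      w <- idx[starts[k]:ends[k]]
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = min(pos[w]) - 1L, end = max(pos[w]),
        n_probes = length(w), stringsAsFactors = FALSE)
    }
  }
  if (length(regions) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0)))
  out <- do.call(rbind, regions)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# minimal manifest builder for annotation tests
make_manifest <- function(pos, chrom = "chr1", probe_id = sprintf("p%03d", seq_along(pos))) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos, strand = "+",
             snp_overlap = FALSE, cross_reactive = FALSE, stringsAsFactors = FALSE)
}

make_beta <- function(values, probe_ids, sample_ids) {
  matrix(values, nrow = length(probe_ids), ncol = length(sample_ids),
         dimnames = list(probe_ids, sample_ids))
}
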