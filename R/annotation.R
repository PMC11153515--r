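# CGI-context and gene-context annotation of probes, and detection of
# differentially methylated regions (DMRs). Interval arithmetic goes
# through GenomicRanges; probe positions are 1-based points, interval
# files 0-based half-open (BED), converted at the boundary.

probes_as_granges <- function(manifest) {
  GenomicRanges::GRanges(manifest$chrom,
                         IRanges::IRanges(start = manifest$pos, width = 1L),
                         probe_id = manifest$probe_id)
}

intervals_as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         name = df$name)
}

#' Annotate probes relative to CpG islands
#'
#' Assigns each probe one of `island` (inside a CGI), `shore` (within
#' 0-2 kb of an island boundary), `shelf` (within 2-4 kb) or `inter_cgi`
#' (anything farther, including probes on chromosomes with no islands).
#' Categories are mutually exclusive with precedence
#' island > shore > shelf > inter_cgi; distances are measured on the
#' probe's own chromosome only.
#'
#' @param manifest Probe manifest (probe_id, chrom, pos).
#' @param cgis BED-style CGI data.frame (0-based half-open).
#' @param shore_bp,shelf_bp Outer limits of shore and shelf (default
#'   2000 / 4000 bp).
#' @return A list with `context` (data.frame probe_id, cgi_context,
#'   distance) and `percent` (named percentages summing to 100).
#' @export
annotate_cgi_context <- function(manifest, cgis, shore_bp = 2000, shelf_bp = 4000) {
  pr <- probes_as_granges(manifest)
  ci <- intervals_as_granges(cgis)
  n <- nrow(manifest)
  dist_bp <- rep(Inf, n)
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(pr, ci))
  qi <- S4Vectors::queryHits(hits)
  # GRanges distance counts strictly-between bases: a probe 1 bp past a
  # boundary has distance 0, so the boundary offset is distance + 1 for
  # non-overlapping pairs and 0 inside.
  d <- S4Vectors::mcols(hits)$distance
  inside <- d == 0 &
    suppressWarnings(IRanges::overlapsAny(pr[qi], ci))
  dist_bp[qi] <- ifelse(inside, 0, d + 1)
  context <- ifelse(dist_bp == 0, "island",
             ifelse(dist_bp <= shore_bp, "shore",
             ifelse(dist_bp <= shelf_bp, "shelf", "inter_cgi")))
  out <- data.frame(probe_id = manifest$probe_id, cgi_context = context,
                    distance = ifelse(is.finite(dist_bp), dist_bp, NA_real_),
                    stringsAsFactors = FALSE)
  lev <- c("island", "shore", "shelf", "inter_cgi")
  pct <- 100 * vapply(lev, function(l) mean(context == l), numeric(1))
  list(context = out, percent = pct)
}

gene_category_ranges <- function(genes, promoter_bp = 1000, promoter_plus_bp = 5000) {
  mk <- function(chrom, start0, end0) {
    keep <- end0 > start0
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start = start0[keep] + 1L, end = end0[keep]))
  }
  plus <- genes$strand == "+"
  tss0 <- ifelse(plus, genes$start, genes$end - 1L)  # 0-based TSS base
  # promoter: 1..promoter_bp upstream of the TSS; promoter+: next 4 kb
  prom_start <- ifelse(plus, tss0 - promoter_bp, tss0 + 1L)
  prom_end <- ifelse(plus, tss0, tss0 + 1L + promoter_bp)
  promp_start <- ifelse(plus, tss0 - promoter_plus_bp, tss0 + 1L + promoter_bp)
  promp_end <- ifelse(plus, tss0 - promoter_bp, tss0 + 1L + promoter_plus_bp)
  exon_chrom <- rep(genes$chrom, lengths(genes$exon_starts))
  exon_strand <- rep(genes$strand, lengths(genes$exon_starts))
  ex_s <- unlist(genes$exon_starts); ex_e <- unlist(genes$exon_ends)
  thick_s <- rep(genes$thick_start, lengths(genes$exon_starts))
  thick_e <- rep(genes$thick_end, lengths(genes$exon_starts))
  cds_s <- pmax(ex_s, thick_s); cds_e <- pmin(ex_e, thick_e)
  left_s <- ex_s; left_e <- pmin(ex_e, thick_s)    # exon part before thick
  right_s <- pmax(ex_s, thick_e); right_e <- ex_e  # exon part after thick
  five_s <- ifelse(exon_strand == "+", left_s, right_s)
  five_e <- ifelse(exon_strand == "+", left_e, right_e)
  three_s <- ifelse(exon_strand == "+", right_s, left_s)
  three_e <- ifelse(exon_strand == "+", right_e, left_e)
  list(promoter = mk(genes$chrom, pmax(prom_start, 0), prom_end),
       promoter_plus = mk(genes$chrom, pmax(promp_start, 0), promp_end),
       five_utr = mk(exon_chrom, five_s, five_e),
       cds = mk(exon_chrom, cds_s, cds_e),
       three_utr = mk(exon_chrom, three_s, three_e),
       gene_body = mk(genes$chrom, genes$start, genes$end))
}

#' Annotate probes relative to gene models
#'
#' Strand-aware gene-context annotation: `promoter` covers 0-1 kb
#' upstream of the TSS, `promoter_plus` 1-5 kb upstream; 5'/3' UTRs and
#' CDS come from the BED12 thick coordinates intersected with exons;
#' `intron` is inside a gene span but outside every exon; `intergenic`
#' applies iff no other category does. Probes overlapping several genes
#' collect every applicable category; the single-label summary uses the
#' precedence promoter > promoter_plus > five_utr > cds > three_utr >
#' intron > intergenic.
#'
#' @param manifest Probe manifest.
#' @param genes Gene models from [read_bed12()] (or the simulator).
#' @param promoter_bp,promoter_plus_bp Upstream extents (default 1000 /
#'   5000 bp).
#' @return A list with `context` (probe_id, categories
#'   (comma-separated), gene_context (single label)) and `percent`.
#' @export
annotate_gene_context <- function(manifest, genes, promoter_bp = 1000,
                                  promoter_plus_bp = 5000) {
  pr <- probes_as_granges(manifest)
  cats <- gene_category_ranges(genes, promoter_bp, promoter_plus_bp)
  n <- nrow(manifest)
  member <- vapply(cats, function(gr)
    suppressWarnings(IRanges::overlapsAny(pr, gr)), logical(n))
  if (is.null(dim(member))) member <- matrix(member, nrow = n,
                                             dimnames = list(NULL, names(cats)))
  exonic <- member[, "five_utr"] | member[, "cds"] | member[, "three_utr"]
  intron <- member[, "gene_body"] & !exonic
  lab_order <- c("promoter", "promoter_plus", "five_utr", "cds", "three_utr", "intron")
  mm <- cbind(member[, c("promoter", "promoter_plus", "five_utr", "cds", "three_utr"),
                     drop = FALSE],
              intron = intron)
  single <- apply(mm, 1L, function(r) if (any(r)) lab_order[which(r)[1L]] else "intergenic")
  all_cats <- apply(mm, 1L, function(r)
    if (any(r)) paste(lab_order[r], collapse = ",") else "intergenic")
  out <- data.frame(probe_id = manifest$probe_id, categories = all_cats,
                    gene_context = single, stringsAsFactors = FALSE)
  lev <- c(lab_order, "intergenic")
  pct <- 100 * vapply(lev, function(l) mean(single == l), numeric(1))
  list(context = out, percent = pct)
}

#' Detect differentially methylated regions
#'
#' A DMR is a run of at least `min_probes` manifest-consecutive
#' significant probes (adjusted p < `alpha`, no intervening
#' non-significant probe when sorted by position) whose positional span
#' is at most `max_span` bp. Overlapping qualifying windows are merged
#' into maximal DMRs; coordinates are reported as the 0-based half-open
#' hull of the member CpG positions.
#'
#' @param dmp DMP table with `probe_id` and `adj_p` (and `delta_beta`).
#' @param manifest Probe manifest with positions for the DMP probes.
#' @param min_probes Minimum probes per region (default 5).
#' @param max_span Maximum span in bp (default 1000).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return A data.frame of DMRs (possibly empty): chrom, start, end,
#'   n_probes, probe_ids (comma-separated), mean_delta_beta.
#' @export
detect_dmrs <- function(dmp, manifest, min_probes = 5, max_span = 1000, alpha = 0.05) {
  mi <- match(dmp$probe_id, manifest$probe_id)
  if (anyNA(mi)) stop("DMP probes missing from manifest")
  tab <- data.frame(probe_id = dmp$probe_id, chrom = manifest$chrom[mi],
                    pos = manifest$pos[mi], adj_p = dmp$adj_p,
                    delta_beta = dmp$delta_beta, stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), ]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_probes = integer(0), probe_ids = character(0),
                      mean_delta_beta = numeric(0), stringsAsFactors = FALSE)
  out <- list()
  for (chr in unique(tab$chrom)) {
    tc <- tab[tab$chrom == chr, ]
    sig <- tc$adj_p < alpha
    # maximal runs of consecutive significant probes
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_probes)) {
      run <- tc[starts[k]:ends[k], ]
      m <- nrow(run)
      # qualifying windows inside the run, merged into maximal regions
      in_dmr <- logical(m)
      for (i in seq_len(m - min_probes + 1L)) {
        for (j in seq(i + min_probes - 1L, m)) {
          if (run$pos[j] - run$pos[i] <= max_span) in_dmr[i:j] <- TRUE
          else break
        }
      }
      rr <- rle(in_dmr)
      re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
      for (q in which(rr$values)) {
        block <- run[rs[q]:re[q], ]
        if (nrow(block) < min_probes) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr, start = min(block$pos) - 1L, end = max(block$pos),
          n_probes = nrow(block),
          probe_ids = paste(block$probe_id, collapse = ","),
          mean_delta_beta = mean(block$delta_beta), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
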