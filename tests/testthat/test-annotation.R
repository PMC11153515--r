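# Hand-built fixtures: one island at chr1:[10000,11000) (0-based
# half-open, i.e. 1-based bases 10001..11000).
cgi_fixture <- data.frame(chrom = "chr1", start = 10000L, end = 11000L,
                          name = "CGI1", stringsAsFactors = FALSE)

test_that("CGI context follows the island/shore/shelf distance bands exactly", {
  man <- make_manifest(c(10500,   # inside the island
                         11500,   # 500 bp past the boundary -> shore
                         9000,    # 1000 bp before the start -> shore
                         12999,   # 1999 bp -> shore (inner edge)
                         13000,   # 2000 bp -> shore (outer edge inclusive)
                         13001,   # 2001 bp -> shelf
                         14500,   # 3500 bp -> shelf
                         15000,   # 4000 bp -> shelf (outer edge inclusive)
                         17000))  # 6000 bp -> inter_cgi
  ctx <- annotate_cgi_context(man, cgi_fixture)
  expect_equal(ctx$context$cgi_context,
               c("island", "shore", "shore", "shore", "shore",
                 "shelf", "shelf", "shelf", "inter_cgi"))
  expect_equal(sum(ctx$percent), 100, tolerance = 0.1)

  # probes on a chromosome with no islands are inter_cgi, not an error
  man2 <- make_manifest(5000, chrom = "chr9")
  expect_equal(annotate_cgi_context(man2, cgi_fixture)$context$cgi_context,
               "inter_cgi")

  # category assignment is invariant to interval-file ordering
  cgi2 <- rbind(data.frame(chrom = "chr1", start = 50000L, end = 50600L,
                           name = "CGI2", stringsAsFactors = FALSE), cgi_fixture)
  ctx2 <- annotate_cgi_context(man, cgi2)
  expect_equal(ctx2$context$cgi_context, ctx$context$cgi_context)
})

# a + strand gene chr1:[20000,30000) with 2 exons and CDS (thick)
# [20500,29500), and a - strand gene chr2:[40000,50000)
gene_fixture <- local({
  f <- tempfile(fileext = ".bed12")
  writeLines(c(
    "chr1\t20000\t30000\tGENEP\t0\t+\t20500\t29500\t0\t2\t1000,1000,\t0,9000,",
    "chr2\t40000\t50000\tGENEM\t0\t-\t40500\t49500\t0\t2\t1000,1000,\t0,9000,"),
    f)
  read_bed12(f)
})

test_that("gene context is strand-aware with the declared precedence", {
  man <- make_manifest(
    c(19500,   # 500 bp upstream of + TSS -> promoter
      19001,   # 1000 bp upstream -> promoter (outer edge)
      19000,   # 1001 bp upstream -> promoter_plus
      17000,   # 3 kb upstream -> promoter_plus
      15001,   # 5 kb upstream -> promoter_plus (outer edge)
      15000,   # 5001 bp upstream -> intergenic
      20300,   # first exon before CDS start -> five_utr
      20700,   # first exon inside thick -> cds
      25000,   # between exons -> intron
      29700,   # last exon after CDS end -> three_utr
      31000))  # past the gene -> intergenic
  ctx <- annotate_gene_context(man, gene_fixture)
  expect_equal(ctx$context$gene_context,
               c("promoter", "promoter", "promoter_plus", "promoter_plus",
                 "promoter_plus", "intergenic", "five_utr", "cds", "intron",
                 "three_utr", "intergenic"))
  expect_equal(sum(ctx$percent), 100, tolerance = 0.1)

  # minus strand: upstream means higher coordinates
  man_m <- make_manifest(c(50500, 53000, 49800, 40300), chrom = "chr2")
  ctx_m <- annotate_gene_context(man_m, gene_fixture)
  expect_equal(ctx_m$context$gene_context,
               c("promoter", "promoter_plus", "five_utr", "three_utr"))

  # gene-free contig
  man_f <- make_manifest(1000, chrom = "chrUn")
  expect_equal(annotate_gene_context(man_f, gene_fixture)$context$gene_context,
               "intergenic")
})

test_that("intergenic applies iff no other category does", {
  tc <- tiny_sim()
  ctx <- annotate_gene_context(tc$ann$manifest, tc$ann$genes)
  inter <- ctx$context$gene_context == "intergenic"
  expect_true(all(ctx$context$categories[inter] == "intergenic"))
  expect_true(all(ctx$context$categories[!inter] != "intergenic"))
})

make_dmp <- function(man, sig) {
  data.frame(probe_id = man$probe_id,
             delta_beta = ifelse(sig, -0.1, 0),
             adj_p = ifelse(sig, 0.001, 0.5), stringsAsFactors = FALSE)
}

test_that("DMR detection applies the 5-probe / 1-kb rule", {
  # 5 consecutive significant probes spanning 900 bp -> one DMR
  man <- make_manifest(c(1000, 1200, 1500, 1700, 1900, 5000))
  dmrs <- detect_dmrs(make_dmp(man, c(rep(TRUE, 5), FALSE)), man)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(dmrs$n_probes, 5L)
  expect_equal(c(dmrs$start, dmrs$end), c(999L, 1900L))

  # 5 significant probes spanning 1200 bp with no 5-subset within 1 kb
  man2 <- make_manifest(c(1000, 1300, 1600, 1900, 2200))
  expect_equal(nrow(detect_dmrs(make_dmp(man2, rep(TRUE, 5)), man2)), 0L)

  # 4 significant probes in 200 bp: below min_probes
  man3 <- make_manifest(c(1000, 1050, 1100, 1200))
  expect_equal(nrow(detect_dmrs(make_dmp(man3, rep(TRUE, 4)), man3)), 0L)

  # an intervening non-significant probe breaks the run
  man4 <- make_manifest(c(1000, 1100, 1200, 1300, 1400, 1500))
  sig4 <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(nrow(detect_dmrs(make_dmp(man4, sig4), man4)), 0L)
})

test_that("DMR caller equals brute-force window enumeration", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    man <- make_manifest(sort(sample.int(5000, n)),
                         chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    sig <- runif(n) < 0.6
    got <- detect_dmrs(make_dmp(man, sig), man)
    want <- dmr_bruteforce(man$probe_id, man$chrom, man$pos, sig)
    expect_equal(got[, c("chrom", "start", "end", "n_probes")], want,
                 ignore_attr = TRUE)
  }
})

test_that("sparsely planted signatures yield the negative DMR finding", {
  # significant probes spaced > 1 kb apart can never form a region
  man <- make_manifest(seq(1000, by = 1500, length.out = 30))
  sig <- rep(c(TRUE, FALSE), 15)
  expect_equal(nrow(detect_dmrs(make_dmp(man, sig), man)), 0L)
})
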