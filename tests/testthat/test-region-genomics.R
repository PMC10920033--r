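test_that("overlap_filter applies a strict >80% rule", {
  feats <- data.frame(chrom = "chr1", start = 0, end = 100)
  wins <- data.frame(chrom = "chr1",
                     start = c(51, 52, 200), end = c(111, 112, 260),
                     id = c("w49", "w48", "w0"), stringsAsFactors = FALSE)
  # 60-base windows overlapping the feature by 49 (81.7%), 48 (80%), 0
  kept <- overlap_filter(wins, feats, min_frac = 0.8)
  expect_identical(kept$id, "w49")
  expect_error(overlap_filter(wins, feats, min_frac = 0), "contract error")
  expect_error(overlap_filter(wins, feats, min_frac = 1.2), "contract error")
})

test_that("overlap_filter counts bases against the union of features", {
  feats <- data.frame(chrom = "chr1", start = c(0, 30), end = c(35, 60))
  wins <- data.frame(chrom = "chr1", start = 0, end = 60)
  expect_equal(nrow(overlap_filter(wins, feats, 0.9)), 1)  # union covers all
})

test_that("intron/intergenic ARs require >=1 base of CE overlap", {
  ars <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                    end = c(60, 160, 260, 360),
                    category = c("intron", "intergenic", "CDS", "intron"),
                    stringsAsFactors = FALSE)
  ces <- data.frame(chrom = "chr1", start = c(59, 360), end = c(61, 420))
  out <- ar_ce_overlap(ars, ces)
  # intron [0,60) overlaps CE by 1 base -> kept; intergenic no overlap ->
  # dropped; CDS passes unconditionally; intron [300,360) touches CE start
  # 360 only half-open -> no shared base -> dropped
  expect_equal(out$start, c(0, 200))
})

test_that("gene flanks are strand-aware and clipped", {
  g <- mk_gene("g1", 2000, 3000)
  fl <- gene_flanks(g, distance = 5000, chrom_length = 6000)
  expect_equal(c(fl$upstream$start, fl$upstream$end), c(0, 2000))
  expect_equal(c(fl$downstream$start, fl$downstream$end), c(3000, 6000))
  gm <- mk_gene("g2", 2000, 3000, strand = "-")
  flm <- gene_flanks(gm, distance = 500)
  expect_equal(c(flm$upstream$start, flm$upstream$end), c(3000, 3500))
  expect_equal(c(flm$downstream$start, flm$downstream$end), c(1500, 2000))
  # flank fully clipped away
  g0 <- mk_gene("g3", 0, 100)
  expect_null(gene_flanks(g0, 5000)$upstream)
})

test_that("associate_genes routes categories and 5-kb flanks correctly", {
  genes <- list(mk_gene("gA", 10000, 12000, feat("CDS", 10000, 12000)),
                mk_gene("gB", 30000, 31000))
  ars <- data.frame(
    chrom = "chr1",
    start = c(10100, 25500, 50000),
    end = c(10160, 25560, 50060),
    category = c("CDS", "intergenic", "intergenic"),
    gene_ids = c("gA", "", ""),
    window_id = c("w1", "w2", "w3"), stringsAsFactors = FALSE)
  ces <- data.frame(chrom = "chr1", start = 25500, end = 25560)
  assoc <- associate_genes(ars, ces, genes, ce_overlap_required = TRUE)
  expect_identical(assoc$sets$CDS, "gA")
  # w2 lies in gB's upstream flank [25000,30000) and overlaps a CE
  expect_identical(assoc$sets$upstream5kb, "gB")
  # w3 has no CE overlap -> contributes nothing
  expect_false("w3" %in% assoc$links$window_id)
  # without the CE rule w3 is outside every flank anyway
  assoc2 <- associate_genes(ars, ces, genes, ce_overlap_required = FALSE)
  expect_false("w3" %in% assoc2$links$window_id)
})

test_that("fisher_enrichment matches fisher.test", {
  for (tab in list(c(20, 80, 10, 190), c(5, 5, 5, 5), c(1, 0, 10, 100))) {
    got <- fisher_enrichment(tab[1], tab[2], tab[3], tab[4])
    want <- fisher.test(matrix(tab, 2, byrow = TRUE),
                        alternative = "greater")
    expect_equal(got$p, want$p.value, tolerance = 1e-12)
  }
  got2 <- fisher_enrichment(20, 80, 10, 190, sided = "two")
  want2 <- fisher.test(matrix(c(20, 80, 10, 190), 2, byrow = TRUE))
  expect_equal(got2$p, want2$p.value, tolerance = 1e-9)
  # sample odds ratio is ad/bc, infinite when bc = 0
  expect_equal(fisher_enrichment(20, 80, 10, 190)$odds_ratio,
               (20 * 190) / (80 * 10))
  expect_equal(fisher_enrichment(1, 0, 10, 100)$odds_ratio, Inf)
  # zero margin -> p = 1
  expect_equal(fisher_enrichment(0, 0, 10, 100)$p, 1)
})

test_that("chi_square_2x2 matches chisq.test without correction", {
  got <- chi_square_2x2(30, 70, 10, 90)
  want <- chisq.test(matrix(c(30, 10, 70, 90), 2), correct = FALSE)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p, want$p.value)
  expect_equal(got$df, 1)
  expect_error(chi_square_2x2(0, 0, 10, 90), "contract error")
})

test_that("ncrna_fisher builds exclusive and inclusive backgrounds", {
  # set: 100 regions, 20 ncRNA; all: 1000 regions, 50 ncRNA
  ex <- ncrna_fisher(100, 20, 1000, 50, "exclusive")
  want_ex <- fisher.test(matrix(c(20, 80, 30, 870), 2, byrow = TRUE),
                         alternative = "greater")
  expect_equal(ex$p, want_ex$p.value, tolerance = 1e-12)
  inc <- ncrna_fisher(100, 20, 1000, 50, "inclusive")
  want_inc <- fisher.test(matrix(c(20, 80, 50, 950), 2, byrow = TRUE),
                          alternative = "greater")
  expect_equal(inc$p, want_inc$p.value, tolerance = 1e-12)
})

test_that("common_accelerated_genes intersects lineages and flags shared windows", {
  mk_assoc <- function(df) structure(list(links = df,
                                          sets = list()),
                                     class = "gene_association")
  a <- mk_assoc(data.frame(gene_id = c("g1", "g2", "g3"),
                           category = "CDS",
                           window_id = c("w1", "w2", "w3"),
                           stringsAsFactors = FALSE))
  b <- mk_assoc(data.frame(gene_id = c("g2", "g3", "g4"),
                           category = c("intron", "CDS", "CDS"),
                           window_id = c("w9", "w3", "w4"),
                           stringsAsFactors = FALSE))
  cg <- common_accelerated_genes(a, b)
  expect_identical(cg$gene_id, c("g2", "g3"))
  expect_identical(cg$same_window, c(FALSE, TRUE))
})

test_that("proportion_pct reproduces fixed-precision printed percentages", {
  expect_equal(proportion_pct(1, 3, 2), 33.33)
  expect_equal(proportion_pct(571365933, 1081644591, 1), 52.8)
})
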