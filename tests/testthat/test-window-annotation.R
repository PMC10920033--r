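ref_block <- function(start, len, nsp = 3, chrom = "chr1") {
  set.seed(start + len)
  sp <- c("refsp", paste0("sp", seq_len(nsp - 1)))
  rows <- do.call(rbind, lapply(sp, function(s) {
    txt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    mk_row(s, if (s == "refsp") chrom else s,
           if (s == "refsp") start else 0, txt, srcSize = 100000)
  }))
  maf_block(rows)
}

test_that("annotation priority is CDS > 5'UTR > 3'UTR > intron > intergenic", {
  genes <- list(
    mk_gene("gA", 0, 300, rbind(feat("CDS", 50, 120),
                                feat("five_prime_UTR", 0, 50),
                                feat("three_prime_UTR", 120, 180))),
    mk_gene("gB", 100, 250, feat("CDS", 100, 160)))
  segs <- assign_annotation(list(ref_block(0, 300)), genes)
  df <- do.call(rbind, lapply(segs, function(s)
    data.frame(start = s$start, end = s$end, category = s$category,
               ids = paste(s$gene_ids, collapse = ","))))
  # CDS beats UTR and intron wherever gB's CDS overlaps gA's UTR/intron
  expect_identical(df$category[df$start == 0], "five_prime_UTR")
  expect_identical(df$category[df$start == 50], "CDS")      # gA CDS
  expect_identical(df$category[df$start == 120], "CDS")     # gB CDS wins 3'UTR
  expect_identical(df$ids[df$start == 120], "gB")
  expect_identical(df$category[df$start == 180], "intron")  # gA+gB introns
  expect_identical(df$category[df$start == 250], "intron")  # gA only
  expect_true(all(diff(df$start) > 0))
})

test_that("a region in the CDS of two genes keeps both gene IDs", {
  genes <- list(mk_gene("g1", 0, 100, feat("CDS", 20, 80)),
                mk_gene("g2", 0, 100, feat("CDS", 50, 100)))
  segs <- assign_annotation(list(ref_block(0, 100)), genes)
  dual <- Filter(function(s) s$start == 50 && s$end == 80, segs)
  expect_length(dual, 1)
  expect_identical(dual[[1]]$category, "CDS")
  expect_setequal(dual[[1]]$gene_ids, c("g1", "g2"))
})

test_that("ncRNA gene bodies without CDS/UTR classify as intron", {
  genes <- list(gene_model("nc1", "chr1", 10, 70, "+", "lncRNA",
                           feat("exon", 10, 70)))
  segs <- assign_annotation(list(ref_block(0, 100)), genes)
  cats <- vapply(segs, `[[`, character(1), "category")
  starts <- vapply(segs, `[[`, numeric(1), "start")
  expect_identical(cats[starts == 10], "intron")
  expect_identical(cats[starts == 0], "intergenic")
  expect_identical(cats[starts == 70], "intergenic")
})

test_that("blocks outside every gene are intergenic with no gene IDs", {
  segs <- assign_annotation(list(ref_block(5000, 80)),
                            list(mk_gene("g1", 0, 100)))
  expect_length(segs, 1)
  expect_identical(segs[[1]]$category, "intergenic")
  expect_length(segs[[1]]$gene_ids, 0)
})

test_that("segmentation requires a gap-free reference row", {
  b <- mk_block(mk_row("refsp", "chr1", 0, "AC-GT"),
                mk_row("spB", "spB", 0, "ACGGT"))
  expect_error(assign_annotation(list(b), list()), "gap-free")
})

test_that("window splitting follows the 10/60/20 rules exactly", {
  seg <- function(len) list(chrom = "chr1", start = 0, end = len,
                            category = "intergenic",
                            gene_ids = character(0),
                            seqs = matrix("A", 2, len,
                                          dimnames = list(c("a", "b"), NULL)))
  lens <- function(len) {
    w <- suppressMessages(split_windows(list(seg(len))))
    vapply(w, function(x) x$end - x$start, numeric(1))
  }
  expect_length(lens(9), 0)                      # dropped
  expect_equal(lens(10), 10)                     # kept as is
  expect_equal(lens(45), 45)
  expect_equal(lens(99), 99)
  expect_equal(lens(100), c(60, 40))
  expect_equal(lens(120), c(60, 60))
  expect_equal(lens(130), c(60, 70))             # tail 10 < 20 merged
  expect_equal(lens(139), c(60, 79))             # largest merged window
  expect_equal(lens(140), c(60, 60, 20))         # tail 20 stands alone
  expect_equal(lens(315), c(60, 60, 60, 60, 75))
  # windows partition the segment from the left end
  w <- suppressMessages(split_windows(list(seg(315))))
  expect_equal(vapply(w, `[[`, numeric(1), "start"),
               c(0, 60, 120, 180, 240))
  expect_true(all(vapply(w, function(x) x$end - x$start, numeric(1)) >= 10))
  expect_true(all(vapply(w, function(x) x$end - x$start, numeric(1)) <= 99))
})

test_that("window concatenation reproduces the segment's columns", {
  sq <- matrix(sample(c("A", "C", "G", "T"), 2 * 130, replace = TRUE), 2,
               dimnames = list(c("a", "b"), NULL))
  seg <- list(chrom = "chr1", start = 100, end = 230,
              category = "CDS", gene_ids = "g1", seqs = sq)
  w <- split_windows(list(seg))
  expect_identical(do.call(cbind, lapply(w, `[[`, "seqs")), sq)
  expect_identical(w[[1]]$window_id, "chr1:100-160")
  expect_identical(w[[2]]$window_id, "chr1:160-230")
  expect_identical(w[[1]]$category, "CDS")
})

test_that("windows with fewer than two informative species are untestable", {
  sq <- matrix("N", 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  sq["a", ] <- "A"
  seg <- list(chrom = "chr1", start = 0, end = 30, category = "intergenic",
              gene_ids = character(0), seqs = sq)
  w <- split_windows(list(seg))
  expect_false(w[[1]]$testable)
  sq["b", 1] <- "C"
  seg$seqs <- sq
  expect_true(split_windows(list(seg))[[1]]$testable)
})
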