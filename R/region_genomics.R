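# Downstream interval analyses: AR/CE overlap, gene association with 5-kb
# flanks, ncRNA-overlap filtering, enrichment tests, habitat-matched
# common genes and summary statistics.

#' @importFrom stats chisq.test dhyper phyper
NULL

# data.frame (0-based half-open) -> GRanges (1-based closed)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}

# overlapped bases of each query interval with the union of the subject
overlap_bases <- function(query, subject) {
  if (!nrow(query)) return(numeric(0))
  if (!nrow(subject)) return(numeric(nrow(query)))
  q <- df_to_granges(query)
  s <- GenomicRanges::reduce(df_to_granges(subject))
  hits <- GenomicRanges::findOverlaps(q, s)
  ov <- rep(0, nrow(query))
  if (length(hits)) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[as.integer(names(agg))] <- as.numeric(agg)
  }
  ov
}

#' Keep windows overlapping features above a fraction threshold
#'
#' A window is kept when strictly more than `min_frac` of its bases lie in
#' the union of the feature intervals (the ">80%" ncRNA rule with
#' `min_frac = 0.8`).
#'
#' @param windows `data.frame` with chrom, start, end (0-based half-open).
#' @param features `data.frame` with chrom, start, end.
#' @param min_frac Fraction in (0, 1], strict `>`.
#' @return Subset of `windows`.
#' @export
overlap_filter <- function(windows, features, min_frac = 0.8) {
  if (min_frac <= 0 || min_frac > 1)
    stop("contract error: min_frac must be in (0, 1]")
  if (!nrow(windows)) return(windows)
  frac <- overlap_bases(windows, features) / (windows$end - windows$start)
  windows[frac > min_frac, , drop = FALSE]
}

#' Restrict intron/intergenic ARs to those overlapping a conserved element
#'
#' ARs of category intron or intergenic are kept only when they overlap at
#' least one base of any all-branch CE (CEs standing in for putative
#' functional elements); other categories pass through untouched.
#'
#' @param ars AR calls `data.frame` (chrom, start, end, category, ...).
#' @param ces CE calls `data.frame` (chrom, start, end, ...).
#' @return Subset of `ars`.
#' @export
ar_ce_overlap <- function(ars, ces) {
  if (!nrow(ars)) return(ars)
  scoped <- ars$category %in% c("intron", "intergenic")
  if (!any(scoped)) return(ars)
  keep <- rep(TRUE, nrow(ars))
  ov <- overlap_bases(ars[scoped, , drop = FALSE], ces)
  keep[scoped] <- ov >= 1
  ars[keep, , drop = FALSE]
}

#' 5' and 3' flanking intervals of a gene
#'
#' Upstream is 5' of the gene span by its strand; both flanks are clipped
#' to `[0, chrom_length)`.
#'
#' @param gene A `gene_model`.
#' @param distance Flank width in bases (default 5000).
#' @param chrom_length Optional chromosome length for right clipping.
#' @return List with `upstream` and `downstream` intervals (`NULL` when a
#'   flank is empty after clipping).
#' @export
gene_flanks <- function(gene, distance = 5000, chrom_length = Inf) {
  left <- c(max(0, gene$start - distance), gene$start)
  right <- c(gene$end, min(chrom_length, gene$end + distance))
  mk <- function(se) if (se[1] < se[2])
    genomic_interval(gene$chrom, se[1], se[2], gene$strand) else NULL
  if (gene$strand == "+") list(upstream = mk(left), downstream = mk(right))
  else list(upstream = mk(right), downstream = mk(left))
}

AR_GENE_CATEGORIES <- c("CDS", "three_prime_UTR", "five_prime_UTR",
                        "intron", "upstream5kb", "downstream5kb")

split_gene_ids <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ",", fixed = TRUE)[[1]]
}

#' Associate accelerated regions with genes
#'
#' CDS/UTR/intron ARs contribute their window gene IDs to that category's
#' gene set; intergenic ARs contribute every gene whose 5-kb upstream or
#' downstream flank they overlap by at least one base. When
#' `ce_overlap_required` is set, intron/intergenic ARs must first overlap
#' an all-branch CE ([ar_ce_overlap()]).
#'
#' @param ars AR calls for one lineage (chrom, start, end, category,
#'   gene_ids, window_id).
#' @param ces CE calls (used when `ce_overlap_required`).
#' @param genes List of `gene_model`.
#' @param ce_overlap_required Apply the CE-overlap rule.
#' @param flank_distance Flank width (default 5000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return A `gene_association` object: `sets` (category -> gene IDs),
#'   `links` data.frame (gene_id, category, window_id).
#' @export
associate_genes <- function(ars, ces, genes, ce_overlap_required = TRUE,
                            flank_distance = 5000, chrom_lengths = NULL) {
  if (ce_overlap_required) ars <- ar_ce_overlap(ars, ces)
  links <- list()
  add <- function(gid, cat, wid)
    links[[length(links) + 1]] <<- data.frame(
      gene_id = gid, category = cat, window_id = wid,
      stringsAsFactors = FALSE)
  genic <- ars[ars$category %in% c("CDS", "three_prime_UTR",
                                   "five_prime_UTR", "intron"), ,
               drop = FALSE]
  for (i in seq_len(nrow(genic)))
    for (gid in split_gene_ids(genic$gene_ids[i]))
      add(gid, genic$category[i], genic$window_id[i])
  inter <- ars[ars$category == "intergenic", , drop = FALSE]
  if (nrow(inter)) {
    for (g in genes) {
      cl <- if (!is.null(chrom_lengths) && g$chrom %in% names(chrom_lengths))
        chrom_lengths[[g$chrom]] else Inf
      fl <- gene_flanks(g, flank_distance, cl)
      for (side in c("upstream", "downstream")) {
        iv <- fl[[side]]
        if (is.null(iv)) next
        hit <- inter$chrom == iv$chrom & inter$start < iv$end &
          inter$end > iv$start
        for (i in which(hit))
          add(g$gene_id, paste0(side, "5kb"), inter$window_id[i])
      }
    }
  }
  links <- if (length(links)) unique(do.call(rbind, links))
           else data.frame(gene_id = character(), category = character(),
                           window_id = character(), stringsAsFactors = FALSE)
  sets <- lapply(setNames(AR_GENE_CATEGORIES, AR_GENE_CATEGORIES),
                 function(cat) sort(unique(links$gene_id[links$category == cat])))
  structure(list(sets = sets, links = links), class = "gene_association")
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric exact test with the sample odds ratio `ad/bc` (infinite
#' when `bc = 0`); rows are groups, columns with/without the property. A
#' zero margin gives p = 1.
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @param sided `"greater"` (enrichment of the property in group 1) or
#'   `"two"`.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(a, b, c, d, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  # double precision: genome-scale counts overflow integer products
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  odds <- if (b * c == 0) Inf else (a * d) / (b * c)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(list(odds_ratio = odds, p = 1))
  m <- a + c; n <- b + d; k <- a + b
  if (sided == "greater") {
    p <- phyper(a - 1, m, n, k, lower.tail = FALSE)
  } else {
    xs <- max(0, k - n):min(k, m)
    dx <- dhyper(xs, m, n, k)
    p <- sum(dx[dx <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  list(odds_ratio = odds, p = min(1, p))
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param a,b,c,d Cell counts.
#' @return List with `statistic`, `df` (1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2)
  if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) <= 0))
    stop("contract error: zero expected count")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1, p = ct$p.value)
}

#' Genes commonly accelerated in two lineages
#'
#' A gene is reported when it carries an AR-derived association in both
#' lineages, in any (possibly different) annotation category;
#' `same_window` marks genes for which one identical alignment window is
#' accelerated in both lineages.
#'
#' @param assoc_a,assoc_b `gene_association` objects for the two lineages.
#' @return `data.frame(gene_id, same_window)`.
#' @export
common_accelerated_genes <- function(assoc_a, assoc_b) {
  ga <- unique(assoc_a$links$gene_id)
  gb <- unique(assoc_b$links$gene_id)
  common <- sort(intersect(ga, gb))
  same <- vapply(common, function(g) {
    wa <- assoc_a$links$window_id[assoc_a$links$gene_id == g]
    wb <- assoc_b$links$window_id[assoc_b$links$gene_id == g]
    length(intersect(wa, wb)) > 0
  }, logical(1))
  data.frame(gene_id = common, same_window = unname(same),
             stringsAsFactors = FALSE)
}

#' Percentage from integer counts at fixed precision
#'
#' @param num,den Numerator and denominator.
#' @param digits Decimal places.
#' @return `round(100 * num / den, digits)`.
#' @export
proportion_pct <- function(num, den, digits = 2) round(100 * num / den, digits)

#' ncRNA enrichment of a region set against all aligned regions
#'
#' Builds the 2x2 table (regions overlapping ncRNA vs not) and applies the
#' one-sided Fisher test of [fisher_enrichment()]. The exclusive background
#' removes the set from the all-regions group so the rows are disjoint; the
#' inclusive background compares against all aligned regions as printed.
#'
#' @param n_set,k_set Regions in the set and those overlapping ncRNA.
#' @param n_all,k_all The same counts over all aligned regions.
#' @param background_mode `"exclusive"` (default) or `"inclusive"`.
#' @return List with `odds_ratio` and `p`.
#' @export
ncrna_fisher <- function(n_set, k_set, n_all, k_all,
                         background_mode = c("exclusive", "inclusive")) {
  background_mode <- match.arg(background_mode)
  if (background_mode == "exclusive")
    fisher_enrichment(k_set, n_set - k_set, k_all - k_set,
                      (n_all - n_set) - (k_all - k_set))
  else
    fisher_enrichment(k_set, n_set - k_set, k_all, n_all - k_all)
}

#' Pipeline summary report
#'
#' Aggregates alignment coverage, CE extent, per-category base fractions,
#' per-branch AR counts and ncRNA-overlap enrichment into one list of
#' recomputable statistics. All percentages derive from the integer
#' numerators/denominators also included in the report.
#'
#' @param blocks Curated multi-species blocks (aligned-base accounting).
#' @param windows Windows from [split_windows()].
#' @param results FDR-corrected scan results.
#' @param calls Element calls from [call_elements()].
#' @param genes List of `gene_model` (ncRNA spans from biotype).
#' @param ref_length Reference genome length in bases.
#' @param ncrna_min_frac ncRNA-overlap fraction threshold (default 0.8).
#' @param background_mode Fisher background (see details in vignette).
#' @return Nested list of counts, percentages and p-values.
#' @export
summary_report <- function(blocks, windows, results, calls, genes,
                           ref_length, ncrna_min_frac = 0.8,
                           background_mode = "exclusive") {
  aligned <- sum(vapply(blocks, function(b) b$rows$size[1], numeric(1)))
  wt <- windows_table(windows)
  wt$len <- wt$end - wt$start
  total_window_bases <- sum(wt$len)
  ces <- calls[calls$kind == "all_branch_CE", , drop = FALSE]
  ce_bases <- sum(ces$end - ces$start)
  cat_bases <- tapply(wt$len, wt$category, sum)
  ncrna <- Filter(function(g) g$biotype %in% NCRNA_BIOTYPES, genes)
  ncrna_df <- data.frame(
    chrom = vapply(ncrna, `[[`, character(1), "chrom"),
    start = vapply(ncrna, `[[`, numeric(1), "start"),
    end = vapply(ncrna, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE)
  n_all <- nrow(wt)
  k_all <- nrow(overlap_filter(wt, ncrna_df, ncrna_min_frac))
  ars <- calls[calls$kind == "AR", , drop = FALSE]
  per_branch <- lapply(split(ars, ars$branch), function(d) {
    n <- nrow(d)
    k <- nrow(overlap_filter(d, ncrna_df, ncrna_min_frac))
    fe <- ncrna_fisher(n, k, n_all, k_all, background_mode)
    list(n_windows = n, total_bases = sum(d$end - d$start),
         ncrna_windows = k, ncrna_pct = proportion_pct(k, n, 2),
         fisher_p = fe$p, odds_ratio = fe$odds_ratio)
  })
  k_ce <- nrow(overlap_filter(ces, ncrna_df, ncrna_min_frac))
  fe_ce <- ncrna_fisher(nrow(ces), k_ce, n_all, k_all, background_mode)
  list(
    aligned_bases = aligned, reference_length = ref_length,
    coverage_pct = proportion_pct(aligned, ref_length, 1),
    n_windows = n_all, total_window_bases = total_window_bases,
    ce = list(n_windows = nrow(ces), total_bases = ce_bases,
              pct_of_alignment = proportion_pct(ce_bases,
                                                total_window_bases, 2),
              ncrna_windows = k_ce,
              ncrna_pct = proportion_pct(k_ce, max(1, nrow(ces)), 2),
              fisher_p = fe_ce$p),
    category_bases = as.list(cat_bases),
    ncrna_all = list(n_windows = n_all, ncrna_windows = k_all,
                     ncrna_pct = proportion_pct(k_all, n_all, 2)),
    ar_by_branch = per_branch)
}
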