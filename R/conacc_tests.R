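# Per-window conservation/acceleration likelihood-ratio tests, CONACC
# scores, BH-FDR correction and element calling.

#' @importFrom stats pchisq p.adjust
NULL

# one-sided p-values from the boundary-corrected LRT: the null distribution
# of T = 2(lnL1 - lnL0) for a one-parameter scale tested at its null value
# is the 1/2 chi2_0 + 1/2 chi2_1 mixture, and the direction of departure
# carries the sign. p_cons + p_acc = 1; both equal 0.5 at T = 0.
lrt_directional_p <- function(T, scale_hat) {
  p_dir <- 0.5 * pchisq(T, df = 1, lower.tail = FALSE)
  if (scale_hat < 1) list(p_cons = p_dir, p_acc = 1 - p_dir)
  else if (scale_hat > 1) list(p_cons = 1 - p_dir, p_acc = p_dir)
  else list(p_cons = 0.5, p_acc = 0.5)
}

scan_result_row <- function(window, mode, fit) {
  T <- max(0, 2 * (fit$loglik - fit$loglik_null))
  dir <- if (fit$scale < 1) "conservation" else "acceleration"
  p2 <- lrt_directional_p(T, fit$scale)
  p <- if (dir == "conservation") p2$p_cons else p2$p_acc
  data.frame(
    window_id = window$window_id, chrom = window$chrom,
    start = window$start, end = window$end, category = window$category,
    gene_ids = paste(window$gene_ids, collapse = ","), mode = mode,
    lnL0 = fit$loglik_null, lnL1 = fit$loglik, scale = fit$scale,
    T = T, direction = dir, p = p, p_cons = p2$p_cons, p_acc = p2$p_acc,
    q = NA_real_, stringsAsFactors = FALSE)
}

#' All-branch conservation/acceleration test for one window
#'
#' Likelihood-ratio test of a single rate multiplier rho applied to every
#' branch of the neutral tree against rho = 1. The one-sided p-value uses
#' the boundary-corrected half-chi-square mixture; direction is
#' conservation when rho-hat < 1.
#'
#' @param window A window from [split_windows()] (needs `seqs` and
#'   coordinates) or a bare character matrix.
#' @param neutral List with `tree` (phylo) and `model` (`subst_model`).
#' @return One-row `data.frame` (`NULL` when the window is untestable).
#' @export
test_window_all_branch <- function(window, neutral) {
  window <- as_window(window)
  fit <- fit_global_scale(neutral$tree, neutral$model, window$seqs)
  if (is.na(fit$scale)) return(NULL)
  scan_result_row(window, "all_branch", fit)
}

#' Branch acceleration/conservation test for one window
#'
#' Likelihood-ratio test of a rate multiplier lambda applied only to the
#' named branch; direction is acceleration when lambda-hat > 1.
#'
#' @param window A window (see [test_window_all_branch()]).
#' @param neutral List with `tree` and `model`.
#' @param branch Branch name (see [branch_names()]).
#' @return One-row `data.frame` (`NULL` when untestable).
#' @export
test_window_branch <- function(window, neutral, branch) {
  window <- as_window(window)
  fit <- tryCatch(
    fit_branch_scale(neutral$tree, neutral$model, window$seqs, branch),
    warning = function(w) list(scale = NA_real_))
  if (is.na(fit$scale)) return(NULL)
  scan_result_row(window, paste0("branch:", branch), fit)
}

as_window <- function(w) {
  if (is.matrix(w))
    list(window_id = "window", chrom = "chr", start = 0, end = ncol(w),
         category = "intergenic", gene_ids = character(0), seqs = w)
  else w
}

#' CONACC score of scan results
#'
#' Signed -log10 of the one-sided p-value in the fitted direction:
#' positive for conservation, negative for acceleration, 0 when p = 1.
#'
#' @param results Scan result `data.frame` (columns `direction`, `p`).
#' @return Numeric vector of scores.
#' @export
conacc_score <- function(results) {
  s <- -log10(results$p)
  ifelse(results$direction == "conservation", s, -s)
}

#' Benjamini-Hochberg FDR correction by test family
#'
#' Conservation p-values of the all-branch scan form one family across all
#' windows; acceleration p-values form one family per target branch. For a
#' bare numeric vector the plain BH adjustment is returned.
#'
#' @param results Scan result `data.frame` (columns `mode`, `p_cons`,
#'   `p_acc`) or numeric p-value vector.
#' @return Results with `q` filled (or adjusted numeric vector).
#' @export
correct_fdr <- function(results) {
  if (is.numeric(results)) return(p.adjust(results, method = "BH"))
  for (mo in unique(results$mode)) {
    idx <- which(results$mode == mo)
    p_family <- if (mo == "all_branch") results$p_cons[idx]
                else results$p_acc[idx]
    results$q[idx] <- p.adjust(p_family, method = "BH")
  }
  results
}

#' Call conserved elements and accelerated regions at an FDR threshold
#'
#' All-branch CEs are windows whose conservation-family q-value is
#' strictly below `alpha`; ARs are windows whose acceleration-family
#' q-value for a target branch is strictly below `alpha`.
#'
#' @param results FDR-corrected scan results (see [correct_fdr()]).
#' @param alpha FDR threshold (default 0.05, strict `<`).
#' @return `data.frame`: chrom, start, end, window_id, kind
#'   (`all_branch_CE`/`AR`), branch (ARs), q, category, gene_ids.
#' @export
call_elements <- function(results, alpha = 0.05) {
  hit <- results[!is.na(results$q) & results$q < alpha, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), window_id = character(),
                      kind = character(), branch = character(),
                      q = numeric(), category = character(),
                      gene_ids = character(), stringsAsFactors = FALSE))
  data.frame(
    chrom = hit$chrom, start = hit$start, end = hit$end,
    window_id = hit$window_id,
    kind = ifelse(hit$mode == "all_branch", "all_branch_CE", "AR"),
    branch = ifelse(hit$mode == "all_branch", NA_character_,
                    sub("^branch:", "", hit$mode)),
    q = hit$q, category = hit$category, gene_ids = hit$gene_ids,
    stringsAsFactors = FALSE)
}

#' Scan windows for conservation and branch acceleration
#'
#' Runs the all-branch test and one branch test per target branch on every
#' testable window, attaches CONACC scores and family-wise BH q-values.
#'
#' @param windows Output of [split_windows()].
#' @param neutral List with `tree` and `model`.
#' @param branches Character vector of target branch names (default: all
#'   terminal branches).
#' @return Scan result `data.frame`, one row per window x mode.
#' @export
scan_windows <- function(windows, neutral,
                         branches = neutral$tree$tip.label) {
  rows <- vector("list", length(windows) * (1 + length(branches)))
  k <- 0L
  skipped <- 0L
  for (w in windows) {
    if (!isTRUE(w$testable)) { skipped <- skipped + 1L; next }
    sdat <- encode_sites(w$seqs, taxa = neutral$tree$tip.label)
    w2 <- w; w2$seqs <- sdat
    r <- suppressWarnings(test_window_all_branch(w2, neutral))
    if (!is.null(r)) { k <- k + 1L; rows[[k]] <- r }
    for (br in branches) {
      r <- suppressWarnings(test_window_branch(w2, neutral, br))
      if (!is.null(r)) { k <- k + 1L; rows[[k]] <- r }
    }
  }
  if (skipped > 0)
    message(skipped, " untestable window(s) skipped")
  if (k == 0L) stop("no testable windows")
  res <- do.call(rbind, rows[seq_len(k)])
  res$conacc <- conacc_score(res)
  correct_fdr(res)
}
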