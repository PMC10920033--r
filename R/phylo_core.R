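#' @importFrom stats optimize optim qgamma pgamma setNames
NULL

BASES <- c("A", "C", "G", "T")
EXCH_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a GTR(+gamma) substitution model
#'
#' A time-reversible nucleotide substitution model parameterised by
#' stationary base frequencies and six symmetric exchangeabilities
#' (GT fixed to 1 for identifiability). The rate matrix is normalised to
#' one expected substitution per site at scale 1, so branch lengths are in
#' expected substitutions per site. Optional discrete-gamma rate variation
#' (equal-weight categories) models among-site rate heterogeneity.
#'
#' @param pi Stationary frequencies, length 4, order A,C,G,T; must be
#'   positive and is renormalised to sum to 1.
#' @param exch Exchangeabilities, length 6, order AC,AG,AT,CG,CT,GT;
#'   rescaled so GT = 1.
#' @param gamma_shape Optional gamma shape alpha (> 0); `NULL` disables
#'   rate variation.
#' @param n_rate_categories Number of discrete gamma categories (used only
#'   when `gamma_shape` is set).
#' @param scale Overall rate multiplier applied on top of branch lengths.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(pi = rep(0.25, 4), exch = rep(1, 6),
                        gamma_shape = NULL, n_rate_categories = 4L,
                        scale = 1) {
  pi <- as.numeric(pi)
  exch <- as.numeric(exch)
  stopifnot(length(pi) == 4, all(pi > 0), length(exch) == 6, all(exch > 0),
            scale > 0)
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  pi <- pi / sum(pi)
  exch <- exch / exch[6]
  names(pi) <- BASES
  names(exch) <- EXCH_NAMES
  structure(list(pi = pi, exch = exch, gamma_shape = gamma_shape,
                 n_rate_categories = if (is.null(gamma_shape)) 1L
                                     else as.integer(n_rate_categories),
                 scale = scale),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("GTR substitution model\n")
  cat("  pi:  ", paste(sprintf("%s=%.4f", BASES, x$pi), collapse = " "), "\n")
  cat("  exch:", paste(sprintf("%s=%.3f", EXCH_NAMES, x$exch), collapse = " "), "\n")
  if (!is.null(x$gamma_shape))
    cat(sprintf("  gamma: alpha=%.3f, %d categories\n",
                x$gamma_shape, x$n_rate_categories))
  invisible(x)
}

# Unnormalised GTR generator from pi and exchangeabilities, then scaled so
# the expected rate -sum(pi_i q_ii) equals 1.
gtr_rate_matrix <- function(model) {
  pi <- model$pi
  r <- model$exch
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in seq_len(6)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- r[k] * pi[j]
    Q[j, i] <- r[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigendecomposition of the reversible rate matrix in symmetrised form:
# S = D Q D^{-1} with D = diag(sqrt(pi)) is symmetric, so
# P(t) = U exp(L t) U^{-1} with U = D^{-1} V, U^{-1} = V' D.
gtr_eigen <- function(model) {
  Q <- gtr_rate_matrix(model)
  d <- sqrt(model$pi)
  S <- Q * outer(d, 1 / d)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(vals = e$values,
       U = e$vectors / d,          # diag(1/d) %*% V
       Uinv = t(e$vectors) * rep(d, each = 4))  # t(V) %*% diag(d)
}

# Transition probability matrix over effective branch length t.
gtr_prob_matrix <- function(eig, t) {
  P <- eig$U %*% (exp(eig$vals * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

# Mean rates of k equal-probability categories of Gamma(alpha, alpha).
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  r <- k * diff(pgamma(q, shape = alpha + 1, rate = alpha))
  r / (sum(r) / k)  # guard rounding: mean exactly 1
}

model_rates <- function(model) {
  if (is.null(model$gamma_shape)) 1
  else discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
}

#' Attach rate-scaling parameters to a phylogeny
#'
#' Wraps an `ape` phylo object with a global rate multiplier and optional
#' per-branch multipliers. Branches are named after their child node (tip
#' label, or internal node label when present). The effective length of a
#' branch is `length * global_scale * branch_scale`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param global_scale Positive multiplier applied to every branch.
#' @param branch_scales Named numeric vector of per-branch multipliers;
#'   names must match `branch_names(tree)`.
#' @return An object of class `scaled_tree`.
#' @export
scaled_tree <- function(tree, global_scale = 1, branch_scales = NULL) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            global_scale > 0)
  if (!is.null(branch_scales)) {
    stopifnot(all(branch_scales > 0), !is.null(names(branch_scales)))
    bad <- setdiff(names(branch_scales), branch_names(tree))
    if (length(bad))
      stop("unknown branch name(s): ", paste(bad, collapse = ", "))
  }
  structure(list(tree = tree, global_scale = global_scale,
                 branch_scales = branch_scales),
            class = "scaled_tree")
}

#' Branch names of a rooted tree
#'
#' Each branch is identified by its child node: the tip label for terminal
#' branches, the internal node label (or `node<N>`) for internal branches.
#' Returned in the order of `tree$edge` rows.
#'
#' @param tree A `phylo` object.
#' @return Character vector, one name per edge.
#' @export
branch_names <- function(tree) {
  labs <- c(tree$tip.label,
            if (!is.null(tree$node.label)) tree$node.label
            else rep("", tree$Nnode))
  ch <- tree$edge[, 2]
  out <- labs[ch]
  blank <- is.na(out) | !nzchar(out)
  out[blank] <- paste0("node", ch[blank])
  out
}

as_scaled_tree <- function(tree) {
  if (inherits(tree, "scaled_tree")) tree else scaled_tree(tree)
}

effective_lengths <- function(stree) {
  len <- stree$tree$edge.length * stree$global_scale
  if (!is.null(stree$branch_scales)) {
    nm <- branch_names(stree$tree)
    idx <- match(names(stree$branch_scales), nm)
    len[idx] <- len[idx] * stree$branch_scales
  }
  len
}

#' Encode and compress alignment columns for likelihood computation
#'
#' Converts a character matrix of aligned bases (rows = taxa, columns =
#' sites; alphabet A,C,G,T plus N/- for missing) into integer codes and
#' collapses identical site patterns with weights. Taxa in `taxa` that are
#' absent from the matrix contribute all-missing rows.
#'
#' @param x Character matrix with rownames giving taxon labels, or an
#'   existing `site_data` object (returned unchanged).
#' @param taxa Taxon order required downstream (defaults to rownames).
#' @return A `site_data` object: integer code matrix (1..4, NA missing),
#'   pattern weights, taxon order, and original site count.
#' @export
encode_sites <- function(x, taxa = rownames(x)) {
  if (inherits(x, "site_data")) return(x)
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  codes <- matrix(NA_integer_, length(taxa), ncol(x),
                  dimnames = list(taxa, NULL))
  hit <- intersect(taxa, rownames(x))
  up <- toupper(x[hit, , drop = FALSE])
  codes[hit, ] <- match(up, BASES)
  # collapse identical patterns
  if (ncol(codes) > 1) {
    key <- apply(codes, 2, function(cc) paste(ifelse(is.na(cc), 5L, cc),
                                              collapse = ""))
    first <- !duplicated(key)
    w <- as.vector(table(factor(key, levels = key[first])))
    codes <- codes[, first, drop = FALSE]
  } else w <- rep(1, ncol(codes))
  structure(list(codes = codes, weights = as.numeric(w), taxa = taxa,
                 n_sites = sum(w)),
            class = "site_data")
}

# 4 x npat tip partial-likelihood matrix; missing bases give all-ones.
tip_partial <- function(code_row, npat) {
  M <- matrix(0, 4, npat)
  obs <- which(!is.na(code_row))
  if (length(obs)) M[cbind(code_row[obs], obs)] <- 1
  miss <- setdiff(seq_len(npat), obs)
  if (length(miss)) M[, miss] <- 1
  M
}

# postorder traversal structure of a tree, computed once per topology;
# perm maps original edge indices into postorder edge order
postorder_struct <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  parents <- unique(E[, 1])
  perm <- match(paste(phy$edge[, 1], phy$edge[, 2]),
                paste(E[, 1], E[, 2]))
  list(E = E, elen = po$edge.length, parents = parents,
       child_edges = lapply(parents, function(p) which(E[, 1] == p)),
       ntip = length(phy$tip.label), nnode = phy$Nnode, perm = perm)
}

# precomputed state for repeated likelihood evaluations on one topology,
# model and site set; elen is supplied per evaluation in original edge order
lik_context <- function(phy, model, sd) {
  ps <- postorder_struct(phy)
  npat <- ncol(sd$codes)
  list(ps = ps, eig = gtr_eigen(model), pi = model$pi,
       rates = model_rates(model), weights = sd$weights,
       tip_parts = lapply(seq_len(ps$ntip), function(i)
         tip_partial(sd$codes[i, ], npat)),
       npat = npat)
}

ctx_column_logliks <- function(ctx, elen, eig = ctx$eig, pi = ctx$pi,
                               rates = ctx$rates) {
  ps <- ctx$ps
  ps$elen <- numeric(length(elen))
  ps$elen[ctx$ps$perm] <- elen   # original edge order -> postorder order
  if (length(rates) == 1L) {
    pruning_column_loglik(ps, eig, pi, ctx$tip_parts, rates)
  } else {
    lls <- vapply(rates, function(r)
      pruning_column_loglik(ps, eig, pi, ctx$tip_parts, r),
      numeric(ctx$npat))
    if (ctx$npat == 1L) lls <- matrix(lls, nrow = 1)
    mx <- apply(lls, 1, max)
    mx + log(rowMeans(exp(lls - mx)))
  }
}

ctx_loglik <- function(ctx, elen, eig = ctx$eig, pi = ctx$pi,
                       rates = ctx$rates)
  sum(ctx$weights * ctx_column_logliks(ctx, elen, eig, pi, rates))

# Per-column log-likelihoods by Felsenstein pruning at one rate multiplier.
# Handles polytomies; rescales partials per internal node to avoid underflow.
pruning_column_loglik <- function(ps, eig, pi, tip_parts, rate) {
  E <- ps$E
  npat <- ncol(tip_parts[[1]])
  partial <- vector("list", ps$ntip + ps$nnode)
  partial[seq_len(ps$ntip)] <- tip_parts
  scaler <- numeric(npat)
  for (k in seq_along(ps$parents)) {
    M <- matrix(1, 4, npat)
    for (ei in ps$child_edges[[k]]) {
      P <- gtr_prob_matrix(eig, ps$elen[ei] * rate)
      M <- M * (P %*% partial[[E[ei, 2]]])
    }
    mx <- pmax(M[1, ], M[2, ], M[3, ], M[4, ])
    mx[mx <= 0] <- 1
    partial[[ps$parents[k]]] <- M / rep(mx, each = 4)
    scaler <- scaler + log(mx)
  }
  root <- ps$parents[length(ps$parents)]
  lik <- colSums(partial[[root]] * pi)
  log(lik) + scaler
}

#' Phylogenetic log-likelihood by the pruning algorithm
#'
#' Felsenstein's pruning algorithm for a GTR(+gamma) model on a rooted
#' tree, with N and gap treated as missing data (marginalised). With
#' discrete-gamma rate variation the per-column likelihood is the
#' equal-weight average over categories.
#'
#' @param tree A `phylo` or `scaled_tree`.
#' @param model A `subst_model`.
#' @param columns Character matrix (taxa x sites) or `site_data`.
#' @return Total log-likelihood in nats.
#' @export
log_likelihood <- function(tree, model, columns) {
  st <- as_scaled_tree(tree)
  sd <- encode_sites(columns, taxa = st$tree$tip.label)
  if (sd$n_sites < 1) stop("need at least one column")
  ctx <- lik_context(st$tree, model, sd)
  val <- ctx_loglik(ctx, effective_lengths(st) * model$scale)
  if (!is.finite(val)) stop("non-finite log-likelihood")
  val
}

column_logliks <- function(st, model, sd) {
  ctx <- lik_context(st$tree, model, sd)
  ctx_column_logliks(ctx, effective_lengths(st) * model$scale)
}

window_testable <- function(sd) {
  sum(rowSums(!is.na(sd$codes)) > 0) >= 2
}

scale_bounds <- c(1e-6, 100)

# Maximise lnL over a single positive scale parameter (log-parameterised),
# guaranteeing the result dominates the neutral value 1.
optimize_scale <- function(objective, bounds = scale_bounds) {
  f <- function(lx) objective(exp(lx))
  opt <- optimize(f, interval = log(bounds), maximum = TRUE, tol = 1e-8)
  cand <- c(exp(opt$maximum), 1, bounds)
  vals <- c(opt$objective, vapply(cand[-1], objective, numeric(1)))
  best <- which.max(vals)
  list(scale = cand[best], loglik = vals[best])
}

#' Fit a global rate scale to alignment columns
#'
#' Maximum-likelihood estimate of a single multiplier rho applied to every
#' branch of the neutral tree: rho < 1 indicates conservation, rho > 1
#' acceleration.
#'
#' @param tree Neutral `phylo`/`scaled_tree`.
#' @param model Neutral `subst_model`.
#' @param columns Character matrix or `site_data`.
#' @return List with `scale` (rho-hat), `loglik` at the optimum, and
#'   `loglik_null` at rho = 1.
#' @export
fit_global_scale <- function(tree, model, columns) {
  st <- as_scaled_tree(tree)
  sd <- encode_sites(columns, taxa = st$tree$tip.label)
  if (!window_testable(sd)) {
    warning("window untestable: fewer than two taxa with data")
    return(list(scale = NA_real_, loglik = NA_real_, loglik_null = NA_real_))
  }
  ctx <- lik_context(st$tree, model, sd)
  base_elen <- effective_lengths(st) * model$scale
  obj <- function(rho) ctx_loglik(ctx, base_elen * rho)
  res <- optimize_scale(obj)
  res$loglik_null <- obj(1)
  res
}

#' Fit a rate scale on named target branches
#'
#' Maximum-likelihood estimate of a multiplier lambda applied only to the
#' named branch(es), all other branches held at their neutral lengths:
#' lambda > 1 indicates lineage-specific acceleration.
#'
#' @param tree Neutral `phylo`/`scaled_tree`.
#' @param model Neutral `subst_model`.
#' @param columns Character matrix or `site_data`.
#' @param target_branches Character vector of branch names (see
#'   [branch_names()]).
#' @return List with `scale` (lambda-hat), `loglik`, `loglik_null`.
#' @export
fit_branch_scale <- function(tree, model, columns, target_branches) {
  st <- as_scaled_tree(tree)
  nm <- branch_names(st$tree)
  bad <- setdiff(target_branches, nm)
  if (length(bad)) stop("branch not in tree: ", paste(bad, collapse = ", "))
  sd <- encode_sites(columns, taxa = st$tree$tip.label)
  if (!window_testable(sd)) {
    warning("window untestable: fewer than two taxa with data")
    return(list(scale = NA_real_, loglik = NA_real_, loglik_null = NA_real_))
  }
  # require data on each side of the target branch for terminal targets
  tip_targets <- intersect(target_branches, st$tree$tip.label)
  if (length(tip_targets)) {
    have <- rowSums(!is.na(sd$codes)) > 0
    if (!any(have[tip_targets]) || !any(have[setdiff(sd$taxa, tip_targets)])) {
      warning("window untestable: no data on one side of the target branch")
      return(list(scale = NA_real_, loglik = NA_real_, loglik_null = NA_real_))
    }
  }
  ctx <- lik_context(st$tree, model, sd)
  base_elen <- effective_lengths(st) * model$scale
  target_idx <- which(nm %in% target_branches)
  obj <- function(lambda) {
    elen <- base_elen
    elen[target_idx] <- elen[target_idx] * lambda
    ctx_loglik(ctx, elen)
  }
  res <- optimize_scale(obj)
  res$loglik_null <- obj(1)
  res
}

#' Simulate alignment columns under a scaled tree and model
#'
#' Draws the root state from the stationary distribution and evolves it
#' down the tree with the model's transition matrices over effective
#' branch lengths; discrete-gamma categories (if any) are drawn per site.
#'
#' @param tree `phylo` or `scaled_tree` defining topology, lengths, scales.
#' @param model A `subst_model`.
#' @param n Number of columns.
#' @param seed Optional integer seed for reproducibility.
#' @return Character matrix (taxa x n) of bases.
#' @export
simulate_columns <- function(tree, model, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- as_scaled_tree(tree)
  phy <- st$tree
  phy$edge.length <- effective_lengths(st) * model$scale
  eig <- gtr_eigen(model)
  ntip <- length(phy$tip.label)
  rates <- model_rates(model)
  cat_idx <- if (length(rates) > 1L)
    sample.int(length(rates), n, replace = TRUE) else rep(1L, n)
  po <- ape::reorder.phylo(phy, "postorder")
  E <- po$edge
  elen <- po$edge.length
  root <- E[nrow(E), 1]
  states <- matrix(NA_integer_, ntip + phy$Nnode, n)
  states[root, ] <- sample.int(4, n, replace = TRUE, prob = model$pi)
  # preorder = reverse postorder edge order
  for (ei in rev(seq_len(nrow(E)))) {
    p <- E[ei, 1]; ch <- E[ei, 2]
    out <- integer(n)
    for (k in unique(cat_idx)) {
      sel <- which(cat_idx == k)
      P <- gtr_prob_matrix(eig, elen[ei] * rates[k])
      ps <- states[p, sel]
      for (s in 1:4) {
        ss <- sel[ps == s]
        if (length(ss))
          out[ss] <- sample.int(4, length(ss), replace = TRUE, prob = P[s, ])
      }
    }
    states[ch, ] <- out
  }
  m <- matrix(BASES[states[seq_len(ntip), , drop = FALSE]], ntip, n)
  rownames(m) <- phy$tip.label
  m
}
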