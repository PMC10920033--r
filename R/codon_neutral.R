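# Codon-usage analysis, unbiased fourfold-degenerate site extraction and
# neutral GTR model fitting on a fixed topology.

# sense codons grouped by encoded amino acid (standard genetic code)
genetic_code_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

# the eight fourfold-degenerate codon quartets, by two-base prefix
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Count codons in coding sequences
#'
#' @param cds Character vector of in-frame CDS sequences (lengths divisible
#'   by 3); stop codons and codons containing N/- are ignored.
#' @return Named integer vector over the 61 sense codons.
#' @export
count_codons <- function(cds) {
  sense <- sort(unlist(genetic_code_families(), use.names = FALSE))
  counts <- setNames(integer(length(sense)), sense)
  for (s in cds) {
    s <- toupper(s)
    n <- nchar(s)
    if (n %% 3 != 0) stop("data error: CDS length not divisible by 3")
    cods <- substring(s, seq(1, n, 3), seq(3, n, 3))
    cods <- cods[cods %in% sense]
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  counts
}

#' Relative synonymous codon usage per species
#'
#' RSCU of codon c in a synonymous family of size k with counts n is
#' `k * n_c / sum(n)`; families with zero total usage yield NA.
#'
#' @param cds_by_species Named list: species -> named codon counts (as
#'   from [count_codons()]) or character vector of CDS sequences.
#' @return A `codon_usage_table`: counts and rscu matrices (species x
#'   codon) plus an empty bias matrix (see [flag_biased_codons()]).
#' @export
compute_rscu <- function(cds_by_species) {
  fam <- genetic_code_families()
  sense <- sort(unlist(fam, use.names = FALSE))
  counts <- t(vapply(cds_by_species, function(x) {
    if (is.character(x)) x <- count_codons(x)
    stopifnot(!is.null(names(x)))
    if (any(x < 0)) stop("contract error: negative codon counts")
    out <- setNames(numeric(length(sense)), sense)
    common <- intersect(names(x), sense)
    out[common] <- x[common]
    out
  }, numeric(length(sense))))
  rscu <- counts
  rscu[] <- NA_real_
  for (f in fam) {
    k <- length(f)
    tot <- rowSums(counts[, f, drop = FALSE])
    for (cod in f) rscu[, cod] <- ifelse(tot > 0, k * counts[, cod] / tot,
                                         NA_real_)
  }
  biased <- matrix("none", nrow(rscu), ncol(rscu), dimnames = dimnames(rscu))
  structure(list(counts = counts, rscu = rscu, biased = biased,
                 flagged = FALSE),
            class = "codon_usage_table")
}

#' Flag codons with biased usage
#'
#' A codon is flagged `under` when its RSCU is strictly below `low` and
#' `over` when strictly above `high` (defaults 0.6 and 1.6); values at the
#' boundaries are unbiased. NA RSCU (unused family) is left unflagged.
#'
#' @param table A `codon_usage_table`.
#' @param low,high RSCU bounds.
#' @return The table with the `biased` matrix filled.
#' @export
flag_biased_codons <- function(table, low = 0.6, high = 1.6) {
  b <- table$biased
  b[] <- "none"
  b[!is.na(table$rscu) & table$rscu < low] <- "under"
  b[!is.na(table$rscu) & table$rscu > high] <- "over"
  table$biased <- b
  table$flagged <- TRUE
  table
}

#' Select fourfold-degenerate families free of codon-usage bias
#'
#' Starting from the eight fourfold-degenerate quartets, a family is
#' dropped when any of its four codons is flagged biased (under or over).
#' With `rule = "any"` (default) a flag in any species suffices; with
#' `rule = "all"` the codon must be biased in every species.
#'
#' @param table A flagged `codon_usage_table`.
#' @param rule `"any"` or `"all"`.
#' @return Character vector of retained two-base family prefixes.
#' @export
select_unbiased_4d_families <- function(table, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (!isTRUE(table$flagged))
    stop("contract error: call flag_biased_codons() first")
  keep <- character()
  for (pref in FOURFOLD_PREFIXES) {
    quartet <- paste0(pref, BASES)
    fl <- table$biased[, quartet, drop = FALSE] != "none"
    codon_biased <- if (rule == "any") apply(fl, 2, any) else apply(fl, 2, all)
    if (!any(codon_biased)) keep <- c(keep, pref)
  }
  if (!length(keep))
    stop("no unbiased fourfold-degenerate family left; review RSCU thresholds")
  keep
}

#' Extract unbiased fourfold-degenerate sites from codon alignments
#'
#' A third-codon-position column is extracted when every species with a
#' non-missing codon carries a codon of a retained family and all those
#' codons share the same two-base prefix; species with gaps or N at the
#' codon contribute N.
#'
#' @param codon_alignments Named list of per-gene alignments, each a named
#'   character vector (species -> aligned CDS, equal lengths divisible by
#'   3) over the same taxa.
#' @param families Retained family prefixes (see
#'   [select_unbiased_4d_families()]).
#' @return A `fourfold_sites` object: taxa, base matrix (taxa x sites) and
#'   per-site source (gene, codon index).
#' @export
extract_4d_sites <- function(codon_alignments, families) {
  taxa <- names(codon_alignments[[1]])
  cols <- list()
  src_gene <- character()
  src_codon <- integer()
  for (g in seq_along(codon_alignments)) {
    aln <- toupper(codon_alignments[[g]])
    stopifnot(identical(sort(names(aln)), sort(taxa)))
    aln <- aln[taxa]
    len <- unique(nchar(aln))
    if (length(len) != 1 || len %% 3 != 0)
      stop("data error: codon alignment length not divisible by 3")
    ncod <- len / 3
    for (ci in seq_len(ncod)) {
      cod <- substring(aln, 3 * ci - 2, 3 * ci)
      missing <- grepl("[^ACGT]", cod)
      if (all(missing)) next
      pref <- substr(cod[!missing], 1, 2)
      if (length(unique(pref)) != 1) next
      if (!pref[1] %in% families) next
      col <- rep("N", length(taxa))
      col[!missing] <- substr(cod[!missing], 3, 3)
      cols[[length(cols) + 1]] <- col
      gname <- if (!is.null(names(codon_alignments)))
        names(codon_alignments)[g] else as.character(g)
      src_gene <- c(src_gene, gname)
      src_codon <- c(src_codon, ci)
    }
  }
  m <- if (length(cols)) do.call(cbind, cols)
       else matrix(character(), length(taxa), 0)
  rownames(m) <- taxa
  structure(list(taxa = taxa, columns = m,
                 source = data.frame(gene_id = src_gene,
                                     codon_index = src_codon,
                                     stringsAsFactors = FALSE)),
            class = "fourfold_sites")
}

# empirical base frequencies of a site matrix, floored to stay positive
empirical_pi <- function(x) {
  tab <- table(factor(x[x %in% BASES], levels = BASES))
  pi <- as.numeric(tab) + 1e-3
  pi / sum(pi)
}

#' Fit the neutral substitution model on a fixed topology
#'
#' Maximises the pruning-algorithm log-likelihood over branch lengths,
#' exchangeabilities and (optionally) a discrete-gamma shape by coordinate
#' ascent; stationary frequencies are fixed at the empirical base
#' frequencies of the site set. Under a reversible model the two branches
#' meeting at the root are confounded (only their sum is identifiable):
#' their total is fitted and divided between them in proportion to their
#' starting values (equal by default).
#'
#' @param sites A `fourfold_sites` object or character matrix (taxa x
#'   sites).
#' @param topology Rooted `phylo`; branch lengths are ignored and refitted.
#' @param use_gamma Fit a 4-category discrete-gamma shape.
#' @param tol Convergence tolerance on the log-likelihood between sweeps.
#' @param max_sweeps Sweep cap.
#' @return List: `tree` (fitted branch lengths, original root and labels),
#'   `model` (`subst_model`), `loglik`.
#' @export
fit_neutral_model <- function(sites, topology, use_gamma = FALSE,
                              tol = 1e-6, max_sweeps = 30) {
  x <- if (inherits(sites, "fourfold_sites")) sites$columns else sites
  stopifnot(inherits(topology, "phylo"))
  if (ncol(x) < 1) stop("need at least one site column")
  if (length(topology$tip.label) < 2) stop("need at least two taxa")
  if (!all(topology$tip.label %in% rownames(x)))
    stop("topology leaves must be contained in the site-set taxa")
  sd <- encode_sites(x, taxa = topology$tip.label)
  constant <- all(apply(sd$codes, 2, function(cc) {
    u <- unique(cc[!is.na(cc)]); length(u) <= 1
  }))
  if (constant)
    warning("all columns constant: branch lengths unidentifiable, ",
            "driven to the lower bound")
  phy <- topology
  phy$edge.length <- rep(0.1, nrow(phy$edge))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  root_edges <- which(phy$edge[, 1] == root)
  tie_root <- length(root_edges) == 2L
  root_prop <- if (tie_root)
    phy$edge.length[root_edges] / sum(phy$edge.length[root_edges]) else NULL
  pi <- empirical_pi(x[topology$tip.label, , drop = FALSE])
  exch <- rep(1, 6)
  alpha <- if (use_gamma) 1 else NULL
  make_model <- function(exch, alpha)
    subst_model(pi = pi, exch = exch, gamma_shape = alpha)
  model <- make_model(exch, alpha)
  ctx <- lik_context(phy, model, sd)
  eig <- gtr_eigen(model)
  rates <- model_rates(model)
  lnL_elen <- function(elen) ctx_loglik(ctx, elen, eig = eig, rates = rates)
  elen <- phy$edge.length
  cur <- lnL_elen(elen)
  bl_bounds <- c(1e-8, 10)
  free_edges <- if (tie_root) setdiff(seq_len(nrow(phy$edge)), root_edges)
                else seq_len(nrow(phy$edge))
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    # branch lengths, one at a time
    for (ei in free_edges) {
      f <- function(lb) { e <- elen; e[ei] <- exp(lb); lnL_elen(e) }
      o <- optimize(f, log(bl_bounds), maximum = TRUE, tol = 1e-7)
      if (o$objective >= cur) {
        elen[ei] <- exp(o$maximum)
        cur <- o$objective
      }
    }
    if (tie_root) {
      f <- function(lb) {
        e <- elen; e[root_edges] <- exp(lb) * root_prop; lnL_elen(e)
      }
      o <- optimize(f, log(bl_bounds), maximum = TRUE, tol = 1e-7)
      if (o$objective >= cur) {
        elen[root_edges] <- exp(o$maximum) * root_prop
        cur <- o$objective
      }
    }
    # exchangeabilities (GT fixed at 1)
    g <- function(le) {
      m <- make_model(c(exp(le), 1), alpha)
      ctx_loglik(ctx, elen, eig = gtr_eigen(m), rates = rates)
    }
    o <- optim(log(exch[1:5]), g, method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = 400, reltol = 1e-9))
    if (o$value >= cur) {
      exch <- c(exp(o$par), 1)
      model <- make_model(exch, alpha)
      eig <- gtr_eigen(model)
      cur <- o$value
    }
    if (use_gamma) {
      h <- function(la) {
        m <- make_model(exch, exp(la))
        ctx_loglik(ctx, elen, eig = eig, rates = model_rates(m))
      }
      o <- optimize(h, log(c(0.05, 50)), maximum = TRUE, tol = 1e-6)
      if (o$objective >= cur) {
        alpha <- exp(o$maximum)
        model <- make_model(exch, alpha)
        rates <- model_rates(model)
        cur <- o$objective
      }
    }
    if (cur - prev < tol) break
  }
  phy$edge.length <- elen
  if (!is.finite(cur)) stop("numerical error: non-finite likelihood")
  list(tree = phy, model = model, loglik = cur)
}

#' Serialize a fitted neutral model to JSON
#' @param fit Result of [fit_neutral_model()].
#' @param path Output file.
#' @export
write_neutral_model <- function(fit, path) {
  obj <- list(pi = unname(fit$model$pi), exch = unname(fit$model$exch),
              gamma_shape = fit$model$gamma_shape,
              n_rate_categories = fit$model$n_rate_categories,
              tree_newick = ape::write.tree(fit$tree),
              loglik = fit$loglik)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted neutral model from JSON
#' @param path JSON file from [write_neutral_model()].
#' @return List with `tree`, `model`, `loglik`.
#' @export
read_neutral_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- subst_model(pi = obj$pi, exch = obj$exch,
                       gamma_shape = obj$gamma_shape,
                       n_rate_categories = if (is.null(obj$n_rate_categories))
                         4L else obj$n_rate_categories)
  list(tree = read_newick(obj$tree_newick), model = model,
       loglik = obj$loglik)
}
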