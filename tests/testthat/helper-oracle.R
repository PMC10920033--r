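# Brute-force likelihood oracle, independent of the package's pruning code:
# GTR matrix built by hand, matrix exponential via ape::matexpo, and the
# likelihood summed over every assignment of states to internal nodes.

BF_BASES <- c("A", "C", "G", "T")

bf_gtr_q <- function(pi, exch) {
  Q <- matrix(0, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Q[i, j] <- exch[k] * pi[j]
    Q[j, i] <- exch[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-diag(Q) * pi)
}

bf_gamma_rates <- function(alpha, k) {
  if (is.null(alpha) || k == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  r <- k * diff(pgamma(q, shape = alpha + 1, rate = alpha))
  r / (sum(r) / k)
}

# column: named character vector tip -> base (N or - = missing)
bf_column_loglik <- function(tree, model, column) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Q <- bf_gtr_q(model$pi, model$exch)
  rates <- bf_gamma_rates(model$gamma_shape, model$n_rate_categories)
  tip_states <- function(ch) {
    ch <- toupper(ch)
    if (ch %in% BF_BASES) match(ch, BF_BASES) else 1:4
  }
  total <- 0
  for (r in rates) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      ape::matexpo(Q * tree$edge.length[e] * r * model$scale))
    grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
    s <- 0
    for (gi in seq_len(nrow(grid))) {
      a <- grid[gi, ]
      pr <- unname(model$pi[a[1]])  # node ntip+1 is the root in ape numbering
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        ps <- a[par - ntip]
        pr <- pr * if (ch <= ntip)
          sum(P[[e]][ps, tip_states(column[tree$tip.label[ch]])])
        else P[[e]][ps, a[ch - ntip]]
      }
      s <- s + pr
    }
    total <- total + s / length(rates)
  }
  log(total)
}

# random rooted tree with 3-5 tips, random model, random column
bf_random_instance <- function(allow_missing = TRUE, allow_gamma = TRUE) {
  ntaxa <- sample(3:5, 1)
  tr <- ape::rtree(ntaxa, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.01, 1.5)
  pi <- as.numeric(rdirichlet1(rep(2, 4)))
  exch <- runif(6, 0.2, 5)
  gamma <- if (allow_gamma && runif(1) < 0.3) runif(1, 0.2, 3) else NULL
  model <- subst_model(pi = pi, exch = exch, gamma_shape = gamma,
                       n_rate_categories = 3L)
  alphabet <- if (allow_missing) c(BF_BASES, "N", "-") else BF_BASES
  column <- setNames(sample(alphabet, ntaxa, replace = TRUE), tr$tip.label)
  # keep the column testable (>= 2 taxa with data)
  if (sum(column %in% BF_BASES) < 2)
    column[1:2] <- sample(BF_BASES, 2, replace = TRUE)
  list(tree = tr, model = model, column = column)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), alpha, 1)
  g / sum(g)
}
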