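test_that("subst_model normalises frequencies and fixes GT = 1", {
  m <- subst_model(pi = c(3, 2, 2, 3), exch = c(2, 8, 2, 2, 8, 2))
  expect_equal(sum(m$pi), 1)
  expect_equal(unname(m$exch["GT"]), 1)
  expect_equal(unname(m$exch["AG"]), 4)
  expect_error(subst_model(pi = c(0, 1, 1, 1)))
  expect_error(subst_model(gamma_shape = -1))
})

test_that("pruning equals the Jukes-Cantor closed form on two taxa", {
  tr <- read_newick("(a:0.1,b:0.15);")
  m <- subst_model()  # equal pi, equal exch = JC69
  t <- 0.25           # total path length
  p_same <- 0.25 + 0.75 * exp(-4 / 3 * t)
  p_diff <- 0.25 - 0.25 * exp(-4 / 3 * t)
  col_same <- matrix(c("A", "A"), 2, dimnames = list(c("a", "b"), NULL))
  col_diff <- matrix(c("A", "C"), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(log_likelihood(tr, m, col_same), log(0.25 * p_same),
               tolerance = 1e-12)
  expect_equal(log_likelihood(tr, m, col_diff), log(0.25 * p_diff),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- bf_random_instance()
    got <- log_likelihood(inst$tree, inst$model,
                          matrix(inst$column, ncol = 1,
                                 dimnames = list(names(inst$column), NULL)))
    want <- bf_column_loglik(inst$tree, inst$model, inst$column)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("all-missing taxa and pattern compression do not change the likelihood", {
  tr <- read_newick("((a:0.1,b:0.2):0.1,(c:0.3,d:0.1):0.2);")
  m <- subst_model(pi = c(0.3, 0.2, 0.2, 0.3), exch = c(1, 4, 1, 1, 4, 1))
  cols <- simulate_columns(tr, m, 50, seed = 5)
  # duplicated columns: compressed likelihood equals the plain sum
  ll1 <- log_likelihood(tr, m, cols)
  ll2 <- sum(vapply(seq_len(ncol(cols)), function(j)
    log_likelihood(tr, m, cols[, j, drop = FALSE]), numeric(1)))
  expect_equal(ll1, ll2, tolerance = 1e-9)
  # a taxon with N everywhere equals dropping no information beyond it
  colsN <- cols
  colsN["d", ] <- "N"
  sdN <- encode_sites(colsN)
  expect_true(all(is.na(sdN$codes["d", ])))
  expect_true(is.finite(log_likelihood(tr, m, colsN)))
})

test_that("scaled_tree applies global and branch multipliers", {
  tr <- default_tree(0.05)
  st <- scaled_tree(tr, global_scale = 0.2)
  m <- subst_model()
  cols <- simulate_columns(tr, m, 20, seed = 9)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 0.2
  expect_equal(log_likelihood(st, m, cols), log_likelihood(tr2, m, cols),
               tolerance = 1e-10)
  nm <- branch_names(tr)
  st2 <- scaled_tree(tr, branch_scales = c(A_sagrei = 3))
  tr3 <- tr
  tr3$edge.length[nm == "A_sagrei"] <- tr$edge.length[nm == "A_sagrei"] * 3
  expect_equal(log_likelihood(st2, m, cols), log_likelihood(tr3, m, cols),
               tolerance = 1e-10)
  expect_error(scaled_tree(tr, branch_scales = c(nosuch = 2)),
               "unknown branch")
})

test_that("branch_names uses tip labels and internal node labels", {
  nm <- branch_names(default_tree())
  expect_true("TC_open" %in% nm)
  expect_true(all(default_tree()$tip.label %in% nm))
  expect_equal(length(nm), nrow(default_tree()$edge))
})

test_that("likelihood agrees with phangorn's pml", {
  skip_if_not_installed("phangorn")
  tr <- read_newick("((a:0.12,b:0.2):0.15,(c:0.3,d:0.08):0.2);")
  m <- subst_model(pi = c(0.35, 0.15, 0.2, 0.3),
                   exch = c(0.8, 3.2, 1.1, 0.9, 4.1, 1))
  cols <- simulate_columns(tr, m, 200, seed = 17)
  dat <- phangorn::phyDat(cols, type = "DNA")
  # phangorn order: a=AC, c=AG, e=AT, b=CG, d=CT, f=GT
  Q <- unname(m$exch[c("AC", "AG", "AT", "CG", "CT", "GT")])
  fit <- phangorn::pml(ape::unroot(tr), dat, bf = unname(m$pi), Q = Q)
  expect_equal(log_likelihood(tr, m, cols), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("fit_global_scale recovers implanted conservation and acceleration", {
  tr <- default_tree(0.05)
  m <- default_model()
  cons <- simulate_columns(scaled_tree(tr, global_scale = 0.1), m, 500,
                           seed = 3)
  acc <- simulate_columns(scaled_tree(tr, global_scale = 5), m, 500,
                          seed = 4)
  f1 <- fit_global_scale(tr, m, cons)
  f2 <- fit_global_scale(tr, m, acc)
  expect_lt(f1$scale, 0.3)
  expect_gt(f2$scale, 3)
  expect_gte(f1$loglik, f1$loglik_null)
  expect_gte(f2$loglik, f2$loglik_null)
})

test_that("fit_branch_scale recovers a single accelerated branch", {
  tr <- default_tree(0.05)
  m <- default_model()
  st <- scaled_tree(tr, branch_scales = c(A_sagrei = 8))
  cols <- simulate_columns(st, m, 2000, seed = 6)
  f <- fit_branch_scale(tr, m, cols, "A_sagrei")
  expect_gt(f$scale, 4)
  expect_lt(f$scale, 16)
  # neutral branch should fit near 1
  f0 <- fit_branch_scale(tr, m, simulate_columns(tr, m, 2000, seed = 7),
                         "A_sagrei")
  expect_gt(f0$scale, 0.6)
  expect_lt(f0$scale, 1.6)
  expect_error(fit_branch_scale(tr, m, cols, "not_a_branch"), "not in tree")
})

test_that("untestable windows return NA with a warning", {
  tr <- default_tree(0.05)
  m <- default_model()
  one_sp <- matrix("N", 8, 10, dimnames = list(tr$tip.label, NULL))
  one_sp["A_sagrei", ] <- "A"
  expect_warning(f <- fit_global_scale(tr, m, one_sp), "untestable")
  expect_true(is.na(f$scale))
  # data only on the target side of a terminal branch
  expect_warning(fb <- fit_branch_scale(tr, m, one_sp, "A_sagrei"),
                 "untestable")
  expect_true(is.na(fb$scale))
})

test_that("simulated base composition converges to the stationary distribution", {
  tr <- default_tree(0.6)
  m <- subst_model(pi = c(0.4, 0.1, 0.1, 0.4))
  cols <- simulate_columns(tr, m, 6000, seed = 8)
  freq <- table(factor(cols, levels = c("A", "C", "G", "T"))) / length(cols)
  expect_equal(as.numeric(freq), unname(m$pi), tolerance = 0.03)
  # seeded simulation is reproducible
  expect_identical(simulate_columns(tr, m, 50, seed = 1),
                   simulate_columns(tr, m, 50, seed = 1))
})

test_that("discrete-gamma model averages categories (matches brute force)", {
  set.seed(23)
  tr <- ape::rtree(4, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
  m <- subst_model(pi = c(0.3, 0.2, 0.25, 0.25), exch = c(1, 3, 1, 1, 3, 1),
                   gamma_shape = 0.5, n_rate_categories = 4L)
  col <- setNames(c("A", "C", "G", "T"), tr$tip.label)
  got <- log_likelihood(tr, m, matrix(col, ncol = 1,
                                      dimnames = list(names(col), NULL)))
  expect_equal(got, bf_column_loglik(tr, m, col), tolerance = 1e-10)
})
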