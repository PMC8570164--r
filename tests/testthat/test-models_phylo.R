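test_that("GTR rate matrix: Jukes-Cantor limit, detailed balance, unit rate", {
  # equal exchangeabilities + uniform frequencies = JC: off-diagonals 1/3
  Q <- build_rate_matrix(gtr_params())
  expect_equal(Q[row(Q) != col(Q)], rep(1 / 3, 12), tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:5) {
    p <- random_gtr_params()
    Q <- build_rate_matrix(p)
    pi <- p$base_freqs
    expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # normalised expected rate
    expect_equal(sum(pi * -diag(Q)), 1, tolerance = 1e-12)
  }
})

test_that("transition probabilities: identity at t = 0, JC closed form, ergodic limit", {
  p <- gtr_params()
  Q <- build_rate_matrix(p)
  expect_identical(transition_probs(Q, 0, base_freqs = p$base_freqs), diag(4))
  P <- transition_probs(Q, 0.1, rate = 1, base_freqs = p$base_freqs)
  expect_equal(diag(P), rep(1 / 4 + 3 / 4 * exp(-0.4 / 3), 4),
               tolerance = 1e-12)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
  set.seed(42)
  pr <- random_gtr_params()
  Qr <- build_rate_matrix(pr)
  Pinf <- transition_probs(Qr, 500, base_freqs = pr$base_freqs)
  for (i in 1:4)
    expect_equal(unname(Pinf[i, ]), pr$base_freqs, tolerance = 1e-8)
  expect_true(all(Pinf >= 0))
})

test_that("discrete gamma rates: degenerate shape, quadrature check, exact mean", {
  expect_equal(discrete_gamma_rates(1e6), rep(1, 4), tolerance = 1e-2)
  # shape 1 = unit exponential: category means between quartile boundaries
  # via direct numerical integration
  cuts <- c(0, qexp(c(0.25, 0.5, 0.75)), Inf)
  oracle <- vapply(1:4, function(c) {
    integrate(function(x) x * dexp(x), cuts[c], cuts[c + 1],
              rel.tol = 1e-12)$value * 4
  }, 0)
  expect_equal(discrete_gamma_rates(1, 4), oracle / mean(oracle),
               tolerance = 1e-8)
  for (shape in c(0.2, 0.8, 3.7))
    expect_equal(mean(discrete_gamma_rates(shape, 4)), 1, tolerance = 1e-10)
})

test_that("pruning matches closed forms on two taxa and identity on zero branches", {
  tr <- ape::read.tree(text = "(a:0.07,b:0.03);")
  par <- gtr_params(gamma_shape = 1e7)   # effectively rate-homogeneous
  same <- pp_alignment(matrix(c("A", "A"), 2, 1,
                              dimnames = list(c("a", "b"), NULL)))
  t <- 0.1
  expect_equal(pruning_log_likelihood(tr, same, par),
               log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))), tolerance = 1e-6)
  # zero-length pendant duplicate taxon contributes its partner's state
  tr3 <- ape::read.tree(text = "((a:0.0,b:0.0):0.05,c:0.05);")
  aln3 <- pp_alignment(matrix(c("G", "G", "G"), 3, 1,
                              dimnames = list(c("a", "b", "c"), NULL)))
  tr2 <- ape::read.tree(text = "(a:0.05,c:0.05);")
  aln2 <- pp_alignment(matrix(c("G", "G"), 2, 1,
                              dimnames = list(c("a", "c"), NULL)))
  expect_equal(pruning_log_likelihood(tr3, aln3, par),
               pruning_log_likelihood(tr2, aln2, par), tolerance = 1e-12)
})

test_that("pruning equals exhaustive ancestral-state enumeration (20 seeded cases)", {
  set.seed(77)
  for (case in 1:20) {
    ntax <- sample(3:4, 1)
    tr <- ape::rtree(ntax)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.6)
    par <- random_gtr_params()
    aln <- simulate_alignment(tr, par, 4)
    expect_equal(pruning_log_likelihood(tr, aln, par),
                 brute_force_loglik(tr, aln, par), tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to site order and handles ambiguity codes", {
  set.seed(78)
  tr <- fixed_tree4()
  par <- random_gtr_params()
  aln <- simulate_alignment(tr, par, 40)
  perm <- sample(40)
  aln_perm <- pp_alignment(aln$mat[, perm])
  expect_equal(pruning_log_likelihood(tr, aln, par),
               pruning_log_likelihood(tr, aln_perm, par), tolerance = 1e-12)
  # all-missing column contributes zero log likelihood
  mat <- aln$mat
  mat[, 1] <- c("N", "-", "?", "N")
  with_missing <- pp_alignment(mat)
  expect_equal(pruning_log_likelihood(tr, with_missing, par),
               pruning_log_likelihood(tr, pp_alignment(mat[, -1]), par),
               tolerance = 1e-10)
  # R = {A, G}: likelihood is the sum of the two resolved likelihoods
  m1 <- aln$mat[, 1:3]; m1[1, 2] <- "R"
  mA <- m1; mA[1, 2] <- "A"
  mG <- m1; mG[1, 2] <- "G"
  lR <- pruning_log_likelihood(tr, pp_alignment(m1), par)
  lA <- pruning_log_likelihood(tr, pp_alignment(mA), par)
  lG <- pruning_log_likelihood(tr, pp_alignment(mG), par)
  expect_equal(exp(lR), exp(lA) + exp(lG), tolerance = 1e-12)
})

test_that("site-partitioned likelihood is exactly the single-block value", {
  set.seed(79)
  tr <- fixed_tree4()
  par <- random_gtr_params()
  aln <- simulate_alignment(tr, par, 12)
  full <- pruning_log_likelihood(tr, aln, par)
  for (N in c(1, 2, 3, 4, 12))
    expect_identical(site_partition_log_likelihood(tr, aln, par, N), full)
  expect_error(site_partition_log_likelihood(tr, aln, par, 13), "N")
  # site_range restricts to a contiguous block
  expect_equal(pruning_log_likelihood(tr, aln, par, site_range = c(1, 5)) +
                 pruning_log_likelihood(tr, aln, par, site_range = c(6, 12)),
               full, tolerance = 1e-12)
})

test_that("taxon mismatches between tree and alignment are reported", {
  tr <- fixed_tree4()
  aln <- pp_alignment(matrix("A", 3, 2,
                             dimnames = list(c("a", "b", "x"), NULL)))
  expect_error(pruning_log_likelihood(tr, aln, gtr_params()), "mismatch.*x")
})

test_that("alignment simulator: star-tree identity, frequency recovery, determinism", {
  # zero-length branches: every taxon copies the root state
  tr <- fixed_tree4()
  tr0 <- tr; tr0$edge.length[] <- 0
  aln0 <- simulate_alignment(tr0, gtr_params(), 50, seed = 5)
  expect_true(all(apply(aln0$mat, 2, function(col) length(unique(col)) == 1)))
  # very long branches: empirical frequencies approach pi
  trL <- tr; trL$edge.length[] <- 50
  pi <- c(0.4, 0.3, 0.2, 0.1)
  par <- gtr_params(base_freqs = pi)
  alnL <- simulate_alignment(trL, par, 2000, seed = 6)
  emp <- table(factor(alnL$mat, levels = c("A", "C", "G", "T"))) / (4 * 2000)
  se <- sqrt(pi * (1 - pi) / (4 * 2000))
  expect_true(all(abs(as.numeric(emp) - pi) < 3 * se))
  # fixed seed reproducibility
  expect_identical(simulate_alignment(tr, par, 30, seed = 7)$mat,
                   simulate_alignment(tr, par, 30, seed = 7)$mat)
})

test_that("FASTA and relaxed PHYLIP round-trip through the readers", {
  tr <- fixed_tree4()
  aln <- simulate_alignment(tr, gtr_params(), 25, seed = 8)
  fa <- tempfile(fileext = ".fasta")
  write_alignment(aln, fa)
  expect_identical(read_alignment(fa)$mat, aln$mat)
  ph <- tempfile(fileext = ".phy")
  writeLines(c("4 25", paste(aln$taxa,
                             apply(aln$mat, 1, paste, collapse = ""))), ph)
  expect_identical(read_alignment(ph)$mat, aln$mat)
  bad <- tempfile()
  writeLines(c(">t1", "ACGT", ">t2", "ACG"), bad)
  expect_error(read_alignment(bad), "unequal")
})

test_that("phylo log prior is proper and matches its factors", {
  tr <- fixed_tree4()
  par <- gtr_params(gamma_shape = 0.9)
  lp <- phylo_log_prior(tr, par)
  manual <- sum(dexp(tr$edge.length, 10, log = TRUE)) +
    lgamma(6) + lgamma(4) + dexp(0.9, 1, log = TRUE)
  expect_equal(lp, manual, tolerance = 1e-12)
})

test_that("phylo end-to-end: PS and SS agree and are seed-stable", {
  set.seed(90)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  par <- gtr_params(c(1, 2, 1, 1, 2, 1), c(0.3, 0.2, 0.3, 0.2),
                    gamma_shape = 0.8)
  aln <- simulate_alignment(tr, par, 300, seed = 90)
  model <- phylo_gtr_model(tr, aln, N = 1)
  sch <- make_powers(20)
  res <- sapply(1:2, function(s) {
    cfg <- stone_run_config(L = 400, T = 4, burnin_frac = 0.2,
                            preburn_iters = 200, seed = 500 + s)
    e <- estimate_both(run_sequential(model, sch, cfg))
    c(ps = e$ps$log_ml, ss = e$ss$log_ml)
  })
  # estimator-consistency diagnostic: PS vs SS within 0.5 log units
  expect_lt(abs(res["ps", 1] - res["ss", 1]), 0.5)
  expect_lt(abs(res["ps", 2] - res["ss", 2]), 0.5)
  # stability across seeds within 1 log unit
  expect_lt(abs(res["ss", 1] - res["ss", 2]), 1)
  expect_lt(abs(res["ps", 1] - res["ps", 2]), 1)
})
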