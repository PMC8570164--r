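# shared fixtures, all built in code

# model whose log likelihood is a constant for every state
constant_ll_model <- function(c = -5) {
  pp_model(
    name = "constant",
    log_prior = function(values) stats::dnorm(values$x, log = TRUE),
    log_likelihood = function(values) c,
    moves = list(move_sliding("x", delta = 1)),
    initial_state = function() list(x = stats::rnorm(1))
  )
}

# discrete 3-state toy target: exact transition matrix of the tempered chain
# under a symmetric propose-other-state-uniformly kernel, built from the
# package's acceptance probability
toy3_transition_matrix <- function(lik, prior, beta) {
  P <- matrix(0, 3, 3)
  ll <- log(lik); lp <- log(prior)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    a <- tempered_acceptance(ll[j], ll[i], lp[j], lp[i],
                             log_hastings = 0, beta = beta)
    P[i, j] <- a / 2
  }
  diag(P) <- 1 - rowSums(P)
  P
}

stationary_of <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

new_state_for_test <- function(m)
  powerpost:::new_state(m, m$initial_state())

# small fixed 4-taxon tree with branch lengths, deterministic
fixed_tree4 <- function() {
  ape::read.tree(text = "((a:0.12,b:0.08):0.10,(c:0.25,d:0.05):0.15);")
}

random_gtr_params <- function() {
  gtr_params(stats::runif(6, 0.5, 2), stats::runif(4, 0.5, 2),
             gamma_shape = stats::runif(1, 0.3, 2))
}

# exhaustive-enumeration phylogenetic likelihood: sums over every ancestral
# state assignment at the internal nodes (independent oracle for pruning)
brute_force_loglik <- function(tree, alignment, params) {
  Q <- build_rate_matrix(params)
  pi <- params$base_freqs
  rates <- discrete_gamma_rates(params$gamma_shape, params$n_categories)
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  el <- tre$edge.length
  ntip <- length(tree$tip.label)
  nn <- ntip + tre$Nnode
  code <- c(A = 1, C = 2, G = 3, T = 4)
  total <- 0
  for (s in seq_len(alignment$n_sites)) {
    obs <- code[alignment$mat[match(tree$tip.label, alignment$taxa), s]]
    Ls <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(edge)), function(e)
        transition_probs(Q, el[e], rate = r))
      ints <- (ntip + 1):nn
      grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
      for (g in seq_len(nrow(grid))) {
        st <- integer(nn)
        st[1:ntip] <- obs
        st[ints] <- grid[g, ]
        pr <- pi[st[ntip + 1]]
        for (e in seq_len(nrow(edge)))
          pr <- pr * Ps[[e]][st[edge[e, 1]], st[edge[e, 2]]]
        Ls <- Ls + pr / length(rates)
      }
    }
    total <- total + log(Ls)
  }
  total
}

# independent trapezoid-rule oracle for path sampling
trapezoid_oracle <- function(powers, samples) {
  means <- apply(samples, 1, mean)
  total <- 0
  for (k in seq_len(length(powers) - 1))
    total <- total + (means[k] + means[k + 1]) * (powers[k + 1] - powers[k]) / 2
  total
}
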