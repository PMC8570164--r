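## GTR + discrete-gamma likelihood on a fixed rooted tree, evaluated by
## Felsenstein pruning, plus an alignment simulator. Trees are ape "phylo"
## objects; alignments are character matrices with IUPAC ambiguity support.

NUC <- c("A", "C", "G", "T")

# IUPAC codes -> 4-vector of compatible states (gap/?/N are all-ones:
# missing data contributes no information)
iupac_partial <- local({
  tab <- list(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), "-" = c(1, 1, 1, 1), "?" = c(1, 1, 1, 1),
    "." = c(1, 1, 1, 1)
  )
  tab
})

#' GTR + gamma substitution model parameters
#'
#' @param exchangeabilities positive 6-vector in canonical order
#'   AC, AG, AT, CG, CT, GT; normalised to sum to 1.
#' @param base_freqs positive 4-vector of stationary frequencies (A, C, G,
#'   T); normalised to sum to 1.
#' @param gamma_shape shape of the gamma distribution of site rates, > 0.
#' @param n_categories number of discrete gamma rate categories.
#' @return object of class \code{gtr_params}.
#' @export
gtr_params <- function(exchangeabilities = rep(1 / 6, 6),
                       base_freqs = rep(0.25, 4),
                       gamma_shape = 1, n_categories = 4L) {
  if (length(exchangeabilities) != 6L || any(exchangeabilities <= 0))
    stop("'exchangeabilities' must be 6 positive values", call. = FALSE)
  if (length(base_freqs) != 4L || any(base_freqs <= 0))
    stop("'base_freqs' must be 4 positive values", call. = FALSE)
  if (gamma_shape <= 0)
    stop("'gamma_shape' must be > 0", call. = FALSE)
  structure(list(
    exchangeabilities = exchangeabilities / sum(exchangeabilities),
    base_freqs = base_freqs / sum(base_freqs),
    gamma_shape = gamma_shape, n_categories = as.integer(n_categories)
  ), class = "gtr_params")
}

#' Build the normalised GTR rate matrix
#'
#' Off-diagonals are \eqn{q_{ij} = r_{ij}\pi_j} with exchangeabilities r in
#' canonical order AC, AG, AT, CG, CT, GT; rows sum to zero and the matrix is
#' rescaled so the expected substitution rate at stationarity,
#' \eqn{-\sum_i \pi_i q_{ii}}, is 1 (branch lengths are then expected
#' substitutions per site).
#'
#' @param params a \code{\link{gtr_params}}.
#' @return 4x4 rate matrix with dimnames A, C, G, T.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "gtr_params"))
  r <- params$exchangeabilities
  pi <- params$base_freqs
  if (any(pi == 0))
    stop("'base_freqs' must all be positive", call. = FALSE)
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (p in seq_len(6)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    R[i, j] <- r[p]; R[j, i] <- r[p]
  }
  Q <- R * rep(pi, each = 4)         # q_ij = r_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))           # expected rate at stationarity
  Q / mu
}

# eigendecomposition of Q via the reversibly symmetrised matrix; reused for
# every branch/category within one likelihood evaluation
gtr_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))         # diag(sq) Q diag(1/sq), symmetric
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(vals = e$values,
       right = (1 / sq) * e$vectors,         # diag(1/sq) V
       left = t(e$vectors * sq))             # V' diag(sq)
}

#' Transition probability matrix exp(rate * t * Q)
#'
#' Computed by eigendecomposition of the reversibly symmetrised rate matrix.
#' A zero elapsed length returns the exact identity matrix; tiny negative
#' entries from round-off are clamped to zero.
#'
#' @param rate_matrix 4x4 GTR rate matrix from \code{\link{build_rate_matrix}}.
#' @param t branch length (expected substitutions per site), >= 0.
#' @param rate rate-category multiplier.
#' @param decomp optional precomputed \code{gtr_eigen} decomposition.
#' @param base_freqs stationary frequencies (needed unless \code{decomp} is
#'   given); defaults to the frequencies implied by the rate matrix rows.
#' @return 4x4 stochastic matrix.
#' @export
transition_probs <- function(rate_matrix, t, rate = 1, decomp = NULL,
                             base_freqs = NULL) {
  stopifnot(t >= 0, rate >= 0)
  if (t * rate == 0) return(diag(4))
  if (is.null(decomp)) {
    if (is.null(base_freqs))
      base_freqs <- stationary_freqs(rate_matrix)
    decomp <- gtr_eigen(rate_matrix, base_freqs)
  }
  P <- decomp$right %*% (exp(decomp$vals * t * rate) * decomp$left)
  P[P < 0] <- 0
  P
}

# stationary distribution of a reversible rate matrix (left null vector)
stationary_freqs <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Discrete gamma rate multipliers
#'
#' Mean-of-category discretisation of a gamma(shape, shape) site-rate
#' distribution: the support is cut at its \code{ncat}-quantiles and each
#' category is assigned the conditional mean of the density on its interval,
#' then the multipliers are renormalised so their average is exactly 1.
#'
#' @param shape gamma shape parameter, > 0.
#' @param ncat number of categories.
#' @return numeric vector of ncat rate multipliers, increasing, mean 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  stopifnot(shape > 0, ncat >= 1)
  if (ncat == 1L) return(1)
  cuts <- stats::qgamma(seq_len(ncat - 1L) / ncat, shape = shape, rate = shape)
  p_hi <- c(stats::pgamma(cuts, shape = shape + 1, rate = shape), 1)
  p_lo <- c(0, stats::pgamma(cuts, shape = shape + 1, rate = shape))
  r <- ncat * (p_hi - p_lo)   # conditional means x ncat (equal-probability cuts)
  r / mean(r)
}

#' DNA alignment container
#'
#' @param mat character matrix, rows = taxa (rownames required), columns =
#'   sites; entries are IUPAC nucleotide codes, with gap and ambiguity codes
#'   treated as (partially) missing data.
#' @return object of class \code{pp_alignment}: \code{taxa}, \code{mat},
#'   \code{n_sites}.
#' @export
pp_alignment <- function(mat) {
  mat <- as.matrix(mat)
  mat[] <- toupper(mat)
  if (is.null(rownames(mat)))
    stop("alignment matrix must have taxon rownames", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), names(iupac_partial))
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(taxa = rownames(mat), mat = mat, n_sites = ncol(mat)),
            class = "pp_alignment")
}

#' @export
print.pp_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa x %d sites\n",
              length(x$taxa), x$n_sites))
  invisible(x)
}

#' Read a DNA alignment from FASTA or relaxed sequential PHYLIP
#'
#' FASTA is detected by a leading '>'. The relaxed PHYLIP dialect expects a
#' header line "ntaxa nsites" followed by one "name sequence" line per taxon
#' (whitespace-separated, names of any length).
#'
#' @param path file path.
#' @return a \code{\link{pp_alignment}}.
#' @export
read_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file", call. = FALSE)
  if (startsWith(trimws(lines[1]), ">")) {
    hdr <- grep("^>", lines)
    taxa <- sub("^>\\s*", "", lines[hdr])
    taxa <- sub("\\s.*$", "", taxa)
    seqs <- character(length(hdr))
    bounds <- c(hdr, length(lines) + 1L)
    for (i in seq_along(hdr)) {
      body <- lines[seq.int(bounds[i] + 1L, bounds[i + 1L] - 1L)]
      seqs[i] <- gsub("\\s", "", paste(body, collapse = ""))
    }
  } else {
    dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    taxa <- vapply(rows, `[`, "", 1L)
    seqs <- vapply(rows, function(r) paste(r[-1], collapse = ""), "")
    if (!is.na(dims[1]) && length(taxa) != dims[1])
      stop("PHYLIP header declares ", dims[1], " taxa but file has ",
           length(taxa), call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths", call. = FALSE)
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- taxa
  pp_alignment(mat)
}

#' Write an alignment to FASTA
#'
#' @param alignment a \code{\link{pp_alignment}}.
#' @param path output file path.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$taxa)) {
    writeLines(paste0(">", alignment$taxa[i]), con)
    writeLines(paste(alignment$mat[i, ], collapse = ""), con)
  }
  invisible(path)
}

# compress columns to unique site patterns; returns leaf partials per pattern
compress_patterns <- function(mat) {
  key <- apply(mat, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  index <- match(key, key[first])
  list(pat = mat[, first, drop = FALSE],
       weights = tabulate(index, nbins = sum(first)),
       index = index)
}

check_taxa <- function(tree, alignment) {
  missing_aln <- setdiff(tree$tip.label, alignment$taxa)
  missing_tree <- setdiff(alignment$taxa, tree$tip.label)
  if (length(missing_aln) || length(missing_tree))
    stop("taxon mismatch between tree and alignment; ",
         "missing from alignment: [",
         paste(missing_aln, collapse = ", "),
         "]; missing from tree: [",
         paste(missing_tree, collapse = ", "), "]", call. = FALSE)
}

# partials are stored npat x 4 (patterns in rows, states in columns). This
# computes partial %*% t(P) with explicit elementwise column operations, so
# each pattern's value is computed independently of the others
# (bit-reproducible under any regrouping of sites, unlike a BLAS gemm).
pmat_times <- function(P, part) {
  out <- part   # same shape; every element overwritten below
  p1 <- part[, 1L]; p2 <- part[, 2L]; p3 <- part[, 3L]; p4 <- part[, 4L]
  out[, 1L] <- P[1L] * p1 + P[5L] * p2 + P[9L] * p3 + P[13L] * p4
  out[, 2L] <- P[2L] * p1 + P[6L] * p2 + P[10L] * p3 + P[14L] * p4
  out[, 3L] <- P[3L] * p1 + P[7L] * p2 + P[11L] * p3 + P[15L] * p4
  out[, 4L] <- P[4L] * p1 + P[8L] * p2 + P[12L] * p3 + P[16L] * p4
  out
}

# tree traversal + pattern structures that do not depend on the parameter
# values; precomputed once per (tree, alignment, site block)
pruning_context <- function(tree, alignment, sites) {
  cp <- compress_patterns(alignment$mat[, sites, drop = FALSE])
  ntip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  leaf_part <- vector("list", ntip)
  for (tip in seq_len(ntip)) {
    chars <- cp$pat[match(tree$tip.label[tip], alignment$taxa), ]
    leaf_part[[tip]] <- t(vapply(chars, function(ch) iupac_partial[[ch]],
                                 numeric(4)))   # npat x 4
  }
  list(edge = tre$edge,
       ntip = ntip, nnode = ntip + tre$Nnode,
       npat = length(cp$weights), index = cp$index,
       leaf_part = leaf_part)
}

# per-site log likelihood vector for a set of columns (pruning algorithm);
# edge lengths are taken from `el` (postorder edge order) so the MCMC can
# move branch lengths without rebuilding the context
persite_loglik <- function(tree, alignment, params, sites, ctx = NULL,
                           el = NULL) {
  if (is.null(ctx)) ctx <- pruning_context(tree, alignment, sites)
  if (is.null(el)) el <- ape::reorder.phylo(tree, "postorder")$edge.length
  edge <- ctx$edge
  Q <- build_rate_matrix(params)
  decomp <- gtr_eigen(Q, params$base_freqs)
  rates <- discrete_gamma_rates(params$gamma_shape, params$n_categories)
  pi <- params$base_freqs
  root <- ctx$ntip + 1L
  right <- decomp$right
  left <- decomp$left
  lik_pat <- numeric(ctx$npat)        # mixture over categories
  for (r in rates) {
    partial <- vector("list", ctx$nnode)
    for (e in seq_len(nrow(edge))) {
      child <- edge[e, 2L]
      cpart <- if (child <= ctx$ntip) ctx$leaf_part[[child]]
               else partial[[child]]
      # exp(r * t * Q) inlined from the cached eigendecomposition
      P <- right %*% (exp(decomp$vals * (el[e] * r)) * left)
      P[P < 0] <- 0
      v <- pmat_times(P, cpart)
      parent <- edge[e, 1L]
      partial[[parent]] <- if (is.null(partial[[parent]])) v
                           else partial[[parent]] * v
    }
    lik_pat <- lik_pat +
      (pi[1] * partial[[root]][, 1L] + pi[2] * partial[[root]][, 2L] +
       pi[3] * partial[[root]][, 3L] + pi[4] * partial[[root]][, 4L]) /
      params$n_categories
  }
  log(lik_pat)[ctx$index]
}

#' Phylogenetic log likelihood by Felsenstein pruning
#'
#' GTR + discrete-gamma likelihood of an alignment on a fixed rooted tree,
#' computed by the pruning (sum-product) algorithm: partial likelihoods are
#' propagated from the tips to the root in post-order, ancestral states and
#' rate categories are marginalised, and per-site log likelihoods are summed
#' in site order. Gap/ambiguity codes contribute partial (all-compatible)
#' leaf vectors.
#'
#' @param tree rooted ape \code{phylo} with branch lengths.
#' @param alignment a \code{\link{pp_alignment}} whose taxa match the tree's
#'   tip labels.
#' @param params a \code{\link{gtr_params}}.
#' @param site_range optional \code{c(first, last)} restricting the
#'   evaluation to a contiguous block of columns.
#' @return the log likelihood (a single number).
#' @export
pruning_log_likelihood <- function(tree, alignment, params,
                                   site_range = NULL) {
  stopifnot(inherits(alignment, "pp_alignment"), inherits(params, "gtr_params"))
  check_taxa(tree, alignment)
  sites <- if (is.null(site_range)) seq_len(alignment$n_sites) else {
    if (length(site_range) != 2L || site_range[1] < 1 ||
        site_range[2] > alignment$n_sites || site_range[1] > site_range[2])
      stop("'site_range' out of bounds", call. = FALSE)
    seq.int(site_range[1], site_range[2])
  }
  sum(persite_loglik(tree, alignment, params, sites))
}

#' Site-partitioned likelihood evaluation
#'
#' Splits the alignment columns into N contiguous blocks, evaluates each
#' block independently (the distributed-likelihood scheme that shares one
#' likelihood computation among N CPUs), and combines the per-site values in
#' fixed site order. The result is bit-identical to the single-block
#' evaluation: per-pattern arithmetic does not depend on which other columns
#' share a block, and both paths reduce the same per-site vector.
#'
#' @inheritParams pruning_log_likelihood
#' @param N number of contiguous column blocks, 1 <= N <= site count.
#' @return the log likelihood.
#' @export
site_partition_log_likelihood <- function(tree, alignment, params, N) {
  stopifnot(inherits(alignment, "pp_alignment"))
  S <- alignment$n_sites
  if (N < 1 || N > S)
    stop("'N' must satisfy 1 <= N <= number of sites", call. = FALSE)
  check_taxa(tree, alignment)
  bounds <- floor(S * (0:N) / N)
  per_site <- vector("list", N)
  for (b in seq_len(N)) {
    sites <- seq.int(bounds[b] + 1L, bounds[b + 1L])
    per_site[[b]] <- persite_loglik(tree, alignment, params, sites)
  }
  sum(unlist(per_site))
}

#' Log prior for the phylogenetic model
#'
#' Independent exponential(rate 10) priors on branch lengths, flat Dirichlet
#' priors on the exchangeability and base-frequency simplexes, and an
#' exponential(rate 1) prior on the gamma shape. (A simple proper prior on
#' the fixed-topology tree; clock and diversification tree priors are out of
#' scope.)
#'
#' @param tree rooted ape \code{phylo} with branch lengths.
#' @param params a \code{\link{gtr_params}}.
#' @return the log prior density.
#' @export
phylo_log_prior <- function(tree, params) {
  sum(stats::dexp(tree$edge.length, rate = 10, log = TRUE)) +
    ddirichlet_log(params$exchangeabilities, rep(1, 6)) +
    ddirichlet_log(params$base_freqs, rep(1, 4)) +
    stats::dexp(params$gamma_shape, rate = 1, log = TRUE)
}

#' Simulate an alignment under GTR + discrete gamma
#'
#' Draws root states from the stationary frequencies, assigns each site a
#' gamma rate category uniformly, and evolves states down the tree with the
#' model's transition probabilities. Deterministic for a given seed.
#'
#' @param tree rooted ape \code{phylo} with branch lengths.
#' @param params a \code{\link{gtr_params}}.
#' @param n_sites number of sites to simulate.
#' @param seed optional integer seed (uses the current RNG when NULL).
#' @return a \code{\link{pp_alignment}}.
#' @export
simulate_alignment <- function(tree, params, n_sites, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge
  el <- tre$edge.length
  Q <- build_rate_matrix(params)
  decomp <- gtr_eigen(Q, params$base_freqs)
  rates <- discrete_gamma_rates(params$gamma_shape, params$n_categories)
  cat_of_site <- sample.int(params$n_categories, n_sites, replace = TRUE)
  root <- ntip + 1L
  states <- matrix(NA_integer_, ntip + tre$Nnode, n_sites)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                               prob = params$base_freqs)
  for (e in rev(seq_len(nrow(edge)))) {      # preorder: root -> tips
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    Ps <- lapply(rates, function(r)
      transition_probs(Q, el[e], rate = r, decomp = decomp))
    for (s in seq_len(n_sites)) {
      p <- Ps[[cat_of_site[s]]][states[parent, s], ]
      states[child, s] <- sample.int(4L, 1L, prob = p)
    }
  }
  mat <- matrix(NUC[states[seq_len(ntip), , drop = FALSE]], ntip, n_sites)
  rownames(mat) <- tree$tip.label
  pp_alignment(mat)
}

#' Build the phylogenetic model for the power posterior engine
#'
#' Fixed rooted topology; free parameters are all branch lengths, the GTR
#' exchangeability and base-frequency simplexes, and the gamma shape. Moves:
#' a multiplicative scale move on each branch length and on the shape, and
#' Dirichlet simplex moves on both simplexes. The likelihood is evaluated by
#' \code{\link{site_partition_log_likelihood}} with \code{N} column blocks
#' (numerically identical for any N).
#'
#' @param tree rooted ape \code{phylo} with branch lengths (topology fixed).
#' @param alignment a \code{\link{pp_alignment}}.
#' @param N column blocks per likelihood evaluation.
#' @param n_categories discrete gamma categories.
#' @param lambda_brlen,lambda_shape,conc_simplex move tuning parameters.
#' @return a \code{\link{pp_model}}.
#' @export
phylo_gtr_model <- function(tree, alignment, N = 1L, n_categories = 4L,
                            lambda_brlen = 1, lambda_shape = 1,
                            conc_simplex = 200) {
  check_taxa(tree, alignment)
  n_edge <- nrow(tree$edge)
  # precompute traversal/pattern structures per likelihood block, and the
  # original-edge -> postorder-edge permutation for branch lengths
  S <- alignment$n_sites
  bounds <- floor(S * (0:N) / N)
  ctxs <- lapply(seq_len(N), function(b)
    pruning_context(tree, alignment, seq.int(bounds[b] + 1L, bounds[b + 1L])))
  post_edge <- ape::reorder.phylo(tree, "postorder")$edge
  perm <- match(paste(post_edge[, 1], post_edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  values_to_params <- function(values)
    gtr_params(values$exch, values$freqs, values$shape, n_categories)
  moves <- c(
    lapply(seq_len(n_edge), function(i)
      move_scale("brlens", lambda = lambda_brlen, index = i)),
    list(move_scale("shape", lambda = lambda_shape),
         move_simplex("exch", conc = conc_simplex),
         move_simplex("freqs", conc = conc_simplex))
  )
  pp_model(
    name = "phylo_gtr",
    log_prior = function(values) {
      if (any(values$brlens <= 0) || values$shape <= 0 ||
          any(values$exch <= 0) || any(values$freqs <= 0)) return(-Inf)
      sum(stats::dexp(values$brlens, rate = 10, log = TRUE)) +
        ddirichlet_log(values$exch, rep(1, 6)) +
        ddirichlet_log(values$freqs, rep(1, 4)) +
        stats::dexp(values$shape, rate = 1, log = TRUE)
    },
    log_likelihood = function(values) {
      params <- values_to_params(values)
      el <- values$brlens[perm]
      sum(unlist(lapply(ctxs, function(ctx)
        persite_loglik(tree, alignment, params, sites = NULL,
                       ctx = ctx, el = el))))
    },
    moves = moves,
    initial_state = function() list(
      brlens = stats::rexp(n_edge, rate = 10),
      exch = rdirichlet1(rep(1, 6)),
      freqs = rdirichlet1(rep(1, 4)),
      shape = stats::rexp(1, rate = 1)
    )
  )
}
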