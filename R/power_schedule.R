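#' Generate a beta-quantile power schedule
#'
#' Builds the ordered vector of K tempering powers used for a power posterior
#' analysis. The i-th power (0-based, ascending) is the i/(K-1) quantile of a
#' Beta(alpha, 1) distribution, i.e. \eqn{\beta_i = (i/(K-1))^{1/\alpha}}.
#' With the default \code{alpha = 0.3} most powers fall close to 0, where the
#' expected log-likelihood changes most rapidly, which is where a numerical
#' approximation of the marginal likelihood needs the finest grid.
#'
#' Powers are stored in decreasing order -- the execution order, running from
#' the posterior (\eqn{\beta = 1}) down to the prior (\eqn{\beta = 0}) so that
#' the final state of each simulation seeds the next. Estimators re-sort
#' ascending internally.
#'
#' @param K integer, number of stones (power posterior simulations), >= 2.
#'   Both endpoints 0 and 1 are included among the K powers.
#' @param alpha positive shape parameter of the Beta(alpha, 1) quantile rule.
#'   \code{alpha = 1} gives an evenly spaced grid.
#' @return An object of class \code{power_schedule}: a list with
#'   \code{powers} (decreasing, \code{powers[1] == 1}, \code{powers[K] == 0}),
#'   \code{K}, and \code{alpha}.
#' @examples
#' s <- make_powers(11)
#' s$powers
#' @export
make_powers <- function(K, alpha = 0.3) {
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K != floor(K) || K < 2)
    stop("'K' must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number", call. = FALSE)
  K <- as.integer(K)
  i <- seq_len(K) - 1L
  asc <- (i / (K - 1L))^(1 / alpha)
  # endpoints exact by construction: 0^x = 0, 1^x = 1
  structure(list(powers = rev(asc), K = K, alpha = alpha),
            class = "power_schedule")
}

#' @export
print.power_schedule <- function(x, ...) {
  cat(sprintf("Power schedule: K = %d stones, Beta(%g, 1) quantiles\n",
              x$K, x$alpha))
  cat(sprintf("  beta: %s ... %s (posterior -> prior)\n",
              format(x$powers[1]), format(x$powers[x$K])))
  invisible(x)
}

#' Partition a power schedule into consecutive per-worker blocks
#'
#' Splits the K stones into M consecutive blocks of (near-)equal size, one per
#' worker. Block m (1-based) covers 0-based stone indices
#' \eqn{K - \lfloor (m-1)K/M \rfloor - 1} down to \eqn{K - \lfloor mK/M \rfloor},
#' in decreasing-power order, so for K = 128 and M = 4 the first block holds
#' indices 127..96, the second 95..64, and so on. When K is not a multiple of
#' M some blocks receive one extra stone; block sizes are always
#' \eqn{\lfloor K/M \rfloor} or \eqn{\lceil K/M \rceil}. Consecutive blocks
#' keep each worker's powers similar to one another, which shortens the
#' per-stone burn-in when chain state is carried from stone to stone.
#'
#' @param schedule a \code{power_schedule} from \code{\link{make_powers}}.
#' @param M integer worker count, 1 <= M <= K.
#' @param N integer, CPUs assigned to each likelihood evaluation (recorded in
#'   the plan; see \code{\link{allocate_cpus}}).
#' @return An object of class \code{block_plan}: list with \code{blocks} (a
#'   list of M integer vectors of 0-based stone indices, each decreasing),
#'   \code{M}, \code{N}, and \code{K}.
#' @export
partition_blocks <- function(schedule, M, N = 1L) {
  stopifnot(inherits(schedule, "power_schedule"))
  K <- schedule$K
  if (!is.numeric(M) || length(M) != 1L || is.na(M) || M != floor(M) ||
      M < 1 || M > K)
    stop("'M' must be an integer with 1 <= M <= K", call. = FALSE)
  M <- as.integer(M)
  blocks <- vector("list", M)
  for (m in seq_len(M)) {
    hi <- K - floor((m - 1) * K / M) - 1
    lo <- K - floor(m * K / M)
    blocks[[m]] <- as.integer(hi:lo)
  }
  structure(list(blocks = blocks, M = M, N = as.integer(N), K = K),
            class = "block_plan")
}

#' @export
print.block_plan <- function(x, ...) {
  cat(sprintf("Block plan: K = %d stones over M = %d workers (N = %d per likelihood)\n",
              x$K, x$M, x$N))
  for (m in seq_along(x$blocks)) {
    b <- x$blocks[[m]]
    cat(sprintf("  worker %d: stones %d..%d (%d stones)\n",
                m, b[1], b[length(b)], length(b)))
  }
  invisible(x)
}

#' Split a CPU budget between stone blocks and likelihood evaluation
#'
#' Given M_total CPUs, assigns N CPUs to each (site-partitioned) likelihood
#' evaluation and the rest to parallel stone blocks. The default
#' \eqn{N = \lfloor \sqrt{M_{total}} \rfloor} gives the best overall runtime
#' for the combined parallelisation scheme; any leftover CPUs
#' (\code{M_total - workers * N}) are left idle so every likelihood
#' evaluation is identically partitioned.
#'
#' @param M_total total CPUs available, >= 1.
#' @param N_override optional explicit N, 1 <= N_override <= M_total.
#' @return list with \code{workers} and \code{N}, \code{workers * N <= M_total}.
#' @export
allocate_cpus <- function(M_total, N_override = NULL) {
  if (!is.numeric(M_total) || length(M_total) != 1L || is.na(M_total) ||
      M_total != floor(M_total) || M_total < 1)
    stop("'M_total' must be a single integer >= 1", call. = FALSE)
  if (is.null(N_override)) {
    N <- floor(sqrt(M_total))
  } else {
    if (!is.numeric(N_override) || length(N_override) != 1L ||
        N_override != floor(N_override) || N_override < 1 ||
        N_override > M_total)
      stop("'N_override' must be an integer with 1 <= N_override <= M_total",
           call. = FALSE)
    N <- N_override
  }
  list(workers = max(1L, as.integer(floor(M_total / N))), N = as.integer(N))
}
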