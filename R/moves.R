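## Move kernels. Each kernel is a list(name, propose, scale); propose(values)
## returns list(values = <updated named list>, log_hastings = <numeric>) or
## NULL when not applicable. log_hastings is log q(old|new) - log q(new|old).

#' Sliding-window move
#'
#' Adds a uniform(-delta, delta) perturbation to a real-valued parameter.
#' Symmetric, so the Hastings term is 0. With finite \code{lower}/\code{upper}
#' bounds the proposal is reflected back into the interval, which keeps the
#' kernel symmetric (zero Hastings term) on a bounded support such as a
#' probability in (0, 1).
#'
#' @param param name of the scalar parameter to perturb.
#' @param delta half-width of the proposal window.
#' @param lower,upper optional reflecting bounds.
#' @return a move kernel.
#' @export
move_sliding <- function(param, delta = 1, lower = -Inf, upper = Inf) {
  stopifnot(delta > 0, lower < upper)
  width <- upper - lower
  list(
    name = paste0("sliding[", param, "]"),
    scale = delta,
    propose = function(values) {
      x <- values[[param]] + stats::runif(1, -delta, delta)
      if (is.finite(width)) {
        # reflect until inside; delta is assumed < width so one pass suffices
        while (x < lower || x > upper) {
          if (x < lower) x <- 2 * lower - x
          if (x > upper) x <- 2 * upper - x
        }
      }
      values[[param]] <- x
      list(values = values, log_hastings = 0)
    }
  )
}

#' Multiplicative scale move
#'
#' Multiplies a positive parameter by \code{exp(lambda * (u - 0.5))} with
#' u ~ uniform(0, 1). The Hastings correction is the log of the multiplier
#' (equivalently \code{log(new) - log(old)}), as for any scale kernel that is
#' uniform on the log scale. Positivity is preserved for every draw. When the
#' named parameter is a vector (e.g. all branch lengths), \code{index} selects
#' one component.
#'
#' @param param name of the positive parameter.
#' @param lambda tuning parameter: width of the log-scale window.
#' @param index optional component index within a vector-valued parameter.
#' @return a move kernel.
#' @export
move_scale <- function(param, lambda = 1, index = NULL) {
  stopifnot(lambda > 0)
  nm <- if (is.null(index)) param else paste0(param, "[", index, "]")
  list(
    name = paste0("scale[", nm, "]"),
    scale = lambda,
    propose = function(values) {
      m <- exp(lambda * (stats::runif(1) - 0.5))
      if (is.null(index)) {
        values[[param]] <- values[[param]] * m
      } else {
        values[[param]][index] <- values[[param]][index] * m
      }
      list(values = values, log_hastings = log(m))
    }
  )
}

#' Dirichlet simplex move
#'
#' Proposes a new simplex from a Dirichlet distribution centred on the current
#' value, with concentration parameter \code{conc * current + 1}. The Hastings
#' term is the reverse minus the forward Dirichlet log density. Large
#' \code{conc} concentrates the proposal near the current point.
#'
#' @param param name of the simplex parameter.
#' @param conc concentration (tuning) parameter, > 0.
#' @return a move kernel.
#' @export
move_simplex <- function(param, conc = 100) {
  stopifnot(conc > 0)
  list(
    name = paste0("simplex[", param, "]"),
    scale = conc,
    propose = function(values) {
      cur <- values[[param]]
      a_fwd <- conc * cur + 1
      prop <- rdirichlet1(a_fwd)
      if (any(prop <= 0)) return(NULL)   # degenerate draw, skip
      a_rev <- conc * prop + 1
      lh <- ddirichlet_log(cur, a_rev) - ddirichlet_log(prop, a_fwd)
      values[[param]] <- prop
      list(values = values, log_hastings = lh)
    }
  )
}

# one Dirichlet(alpha) draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

ddirichlet_log <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}
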