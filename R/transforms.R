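#' Closed-form cell-count trajectories
#'
#' Both compartments relax exponentially toward patient-specific plateaus:
#' normal WBCs recover at rate `a` toward `x_star` while leukemic
#' (BCR-ABL1-positive) cells decline at rate `b` toward `y_star`,
#' \deqn{x(t) = x^* + (x_0 - x^*) e^{-a t}, \quad
#'       y(t) = y^* + (y_0 - y^*) e^{-b t}.}
#' The kinetics are linear and scalar so the solution is exact; no
#' numerical integration is involved.
#'
#' @param params Named list with `a`, `b`, `x_star`, `y_star`, `x0`, `y0`
#'   (see [dynamics_params()]).
#' @param times Numeric vector of times (months), non-negative.
#' @return A data.frame with columns `time`, `x` (normal WBC) and `y`
#'   (leukemic cells), in cells/ul.
#' @examples
#' th <- list(a = 0.5, b = 0.8, x_star = 6000, y_star = 5,
#'            x0 = 2000, y0 = 5e4)
#' simulate_counts(th, seq(0, 24, by = 3))
#' @export
simulate_counts <- function(params, times) {
  params <- dynamics_params(params)
  times <- as.numeric(times)
  stopifnot(all(is.finite(times)), all(times >= 0))
  data.frame(
    time = times,
    x = params$x_star + (params$x0 - params$x_star) * exp(-params$a * times),
    y = params$y_star + (params$y0 - params$y_star) * exp(-params$b * times)
  )
}

#' Per-patient dynamics parameters
#'
#' Validates and normalizes the six per-patient parameters of the
#' two-compartment kinetics: recovery rate `a` (1/month), reduction rate
#' `b` (1/month), plateaus `x_star`, `y_star` and initial counts `x0`,
#' `y0` (cells/ul). All rates must be positive and all counts
#' non-negative.
#'
#' @param params Named list or `dynamics_params` object.
#' @return An object of class `dynamics_params`.
#' @export
dynamics_params <- function(params) {
  if (inherits(params, "dynamics_params")) return(params)
  need <- c("a", "b", "x_star", "y_star", "x0", "y0")
  if (!all(need %in% names(params))) {
    stop("dynamics parameters require fields: ", paste(need, collapse = ", "))
  }
  p <- lapply(params[need], as.numeric)
  if (!all(vapply(p, function(v) length(v) == 1L && is.finite(v), logical(1)))) {
    stop("all dynamics parameters must be finite scalars")
  }
  if (p$a <= 0 || p$b <= 0) stop("rates a and b must be positive")
  if (p$x_star < 0 || p$y_star < 0 || p$x0 < 0 || p$y0 < 0) {
    stop("cell counts and plateaus must be non-negative")
  }
  structure(p, class = "dynamics_params")
}

#' Convert cell counts to an IS measurement
#'
#' The international-scale transcript ratio generated by `x` normal and
#' `y` leukemic cells is
#' \deqn{\mathrm{IS} = \max\!\left(\frac{y}{c x + y} \times k_{IS}
#'       \times 100,\; 0.0032\right),}
#' where `c` is the ratio of per-cell ABL1 expression in normal WBCs to
#' that in leukemic cells and the floor is the assay detection limit.
#'
#' @param x,y Normal and leukemic cell counts (cells/ul), non-negative,
#'   vectorized; `x + y` must be positive elementwise.
#' @param c_ratio ABL1 expression ratio, positive scalar.
#' @param consts [model_constants()].
#' @return IS values (percent), clamped at the detection limit.
#' @examples
#' counts_to_is(9000, 1000, c_ratio = 1)    # 12%
#' counts_to_is(9000, 0, c_ratio = 1)       # clamped at 0.0032%
#' @export
counts_to_is <- function(x, y, c_ratio, consts = model_constants()) {
  stopifnot(c_ratio > 0, all(x >= 0), all(y >= 0))
  if (any(x + y <= 0)) stop("x + y must be positive to form an IS ratio")
  pmax(y / (c_ratio * x + y) * consts$k_is * 100, consts$detection_limit)
}

#' Invert an (IS, WBC) pair to cell counts
#'
#' Solves the measurement model for the leukemic count,
#' \deqn{\hat y = \frac{c \cdot \mathrm{IS}}{100 k_{IS} + (c - 1)
#'       \mathrm{IS}} \cdot \mathrm{WBC},}
#' and returns the normal count as the remainder `WBC - y`. Only valid for
#' uncensored IS values (strictly above the detection floor); censored
#' values carry no information about the exact leukemic count and must be
#' handled by the caller.
#'
#' @param is_pct IS values (percent), strictly above the detection limit,
#'   vectorized.
#' @param wbc Total WBC counts (cells/ul), positive, vectorized.
#' @param c_ratio ABL1 expression ratio, positive scalar.
#' @param consts [model_constants()].
#' @return A data.frame with columns `x` and `y` (cells/ul).
#' @export
is_wbc_to_counts <- function(is_pct, wbc, c_ratio, consts = model_constants()) {
  stopifnot(c_ratio > 0, all(wbc > 0))
  if (any(is_pct <= consts$detection_limit)) {
    stop("is_wbc_to_counts requires IS strictly above the detection limit (",
         consts$detection_limit, "%); censored values cannot be inverted")
  }
  denom <- 100 * consts$k_is + (c_ratio - 1) * is_pct
  if (any(denom <= 0)) stop("non-positive denominator in IS inversion")
  y <- c_ratio * is_pct / denom * wbc
  data.frame(x = wbc - y, y = y)
}

#' Smallest leukemic plateau detectable above the IS floor
#'
#' The leukemic plateau at which the modelled IS sits exactly at the
#' detection limit, given the normal-WBC plateau: the solution of
#' \eqn{y / (c x^* + y) \cdot k_{IS} \cdot 100 = d} for `y`, i.e.
#' \eqn{y^*_{min} = d c x^* / (100 k_{IS} - d)}. Used as the lower
#' constraint on `y_star` in the cohort fit so fitted trajectories stay
#' above the floor.
#'
#' @param c_ratio ABL1 expression ratio, positive.
#' @param x_star Normal-WBC plateau (cells/ul), positive; vectorized.
#' @param consts [model_constants()].
#' @return `y_star_min` (cells/ul).
#' @export
min_cml_convergence <- function(c_ratio, x_star, consts = model_constants()) {
  stopifnot(c_ratio > 0, all(x_star > 0))
  d <- consts$detection_limit
  if (consts$k_is * 100 <= d) {
    stop("detection limit must be below the IS scale maximum k_is * 100")
  }
  d * c_ratio * x_star / (consts$k_is * 100 - d)
}
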