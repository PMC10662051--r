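#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a change-point fit
#'
#' @param x A `tug_changepoints` object from [anneal_track()].
#' @param ... Unused.
#' @return Tibble of change points with per-segment slopes.
#' @method tidy tug_changepoints
#' @export
tidy.tug_changepoints <- function(x, ...) {
  cp <- x$cp
  slope <- c(diff(cp$x_nm) / diff(cp$t_s), NA_real_)
  tibble::tibble(t_s = cp$t_s, x_nm = cp$x_nm, slope_to_next = slope)
}

#' @rdname tidy.tug_changepoints
#' @method glance tug_changepoints
#' @export
glance.tug_changepoints <- function(x, ...) {
  tibble::tibble(H = x$H, E_err = x$E_err, n_cp = x$n_cp,
                 acceptance_rate = x$acceptance_rate,
                 mu_cost = x$mu_cost)
}

#' Tidy a weighted KS test
#'
#' @param x A `tug_ks` object from [weighted_ks_test()].
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p.value`, effective sizes.
#' @method tidy tug_ks
#' @export
tidy.tug_ks <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic), p.value = x$p.value,
                 n_eff1 = x$n_eff[["n1"]], n_eff2 = x$n_eff[["n2"]],
                 method = x$method, alternative = x$alternative)
}

#' @rdname tidy.tug_ks
#' @method glance tug_ks
#' @export
glance.tug_ks <- function(x, ...) tidy.tug_ks(x)
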