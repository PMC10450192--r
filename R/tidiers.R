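# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.velocity_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
tidy.profile_fit <- function(x, ...) {
  tibble::tibble(term = c("log10_v_intercept", "slope_per_pct"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.profile_fit <- function(x, ...) {
  tibble::tibble(v_at_100 = x$v_at_100, decade_filling = x$decade_filling,
                 n_bins = x$n_bins,
                 r_squared = summary(x$lm)$r.squared)
}

#' @export
tidy.pt_fit <- function(x, ...) {
  x$per_bin
}

#' @export
glance.pt_fit <- function(x, ...) {
  tibble::tibble(d_overall = x$d_overall, d_se = x$d_se,
                 n_bins = nrow(x$per_bin),
                 temperature = x$temperature)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "xmin"),
                 estimate = c(x$alpha, x$xmin),
                 std_error = c(x$alpha_se, NA_real_))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, alpha_se = x$alpha_se, xmin = x$xmin,
                 n_tail = x$n_tail, ks_distance = x$ks_distance,
                 ks_exponential = x$ks_exponential,
                 exponential_preferred = x$exponential_preferred,
                 gof_p = x$gof_p)
}

#' @export
tidy.exponential_fit <- function(x, ...) {
  tibble::tibble(term = "rate", estimate = x$rate,
                 std_error = x$rate / sqrt(x$n))
}

#' @export
glance.exponential_fit <- function(x, ...) {
  tibble::tibble(rate = x$rate, n = x$n, ks_distance = x$ks_distance)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law tail fit (CSN): alpha = %.3f +/- %.3f, xmin = %.4g, n_tail = %d, KS = %.4f\n",
              x$alpha, x$alpha_se, x$xmin, as.integer(x$n_tail),
              x$ks_distance))
  invisible(x)
}

#' @export
print.pt_fit <- function(x, ...) {
  cat(sprintf("Prandtl-Tomlinson fit: d = %.3f nm (SE %.3f) over %d bins\n",
              x$d_overall, x$d_se, nrow(x$per_bin)))
  invisible(x)
}
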