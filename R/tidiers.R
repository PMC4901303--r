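# broom-style tidiers for the package's fitted/test objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a placement comparison
#'
#' @param x A `placement_test` from [constrained_topology_compare()].
#' @param ... Unused.
#' @return One row per candidate placement: `placement`, `taxa`, `lnl`.
#' @export
tidy.placement_test <- function(x, ...) {
  tibble::tibble(
    placement = c("group_a", "group_b"),
    taxa = c(paste(x$group_a, collapse = ","),
             paste(x$group_b, collapse = ",")),
    lnl = c(x$lnl_a, x$lnl_b)
  )
}

#' Glance at a placement comparison
#'
#' @inheritParams tidy.placement_test
#' @return A one-row tibble: `focal`, `lnl_a`, `lnl_b`, `delta_lnl`,
#'   `preferred`, `model`.
#' @export
glance.placement_test <- function(x, ...) {
  tibble::tibble(focal = x$focal, lnl_a = x$lnl_a, lnl_b = x$lnl_b,
                 delta_lnl = x$delta_lnl, preferred = x$preferred,
                 model = x$model)
}

#' Tidy an hr-proximity permutation test
#'
#' @param x An `hr_proximity_test`.
#' @param ... Unused.
#' @return A one-row tibble: `observed`, `null_mean`, `p_value`,
#'   `n_points`, `n_perm`.
#' @export
tidy.hr_proximity_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = x$null_mean,
                 p_value = x$p_value, n_points = x$n_points,
                 n_perm = x$n_perm)
}

#' @rdname tidy.hr_proximity_test
#' @export
glance.hr_proximity_test <- function(x, ...) tidy.hr_proximity_test(x)

#' Tidy a fragment-profile comparison
#'
#' @param x A `profile_comparison` from [compare_profiles()].
#' @param ... Unused.
#' @return The per-pair tibble with `observed`, `expected`, `rel_error`,
#'   `within_tol`.
#' @export
tidy.profile_comparison <- function(x, ...) x$pairs

#' Glance at a fragment-profile comparison
#'
#' @inheritParams tidy.profile_comparison
#' @return A one-row tibble: `n_pairs`, `n_unmatched_observed`,
#'   `n_unmatched_expected`, `max_rel_error`, `tol_frac`, `pass`.
#' @export
glance.profile_comparison <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    n_unmatched_observed = length(x$unmatched_observed),
    n_unmatched_expected = length(x$unmatched_expected),
    max_rel_error = if (nrow(x$pairs)) max(x$pairs$rel_error) else NA_real_,
    tol_frac = x$tol_frac, pass = x$pass
  )
}
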