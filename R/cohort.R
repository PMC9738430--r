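#' Specification of a two-class Gaussian feature cohort
#'
#' Describes groups of labeled feature vectors to simulate: one row of
#' `groups` per (tissue, state, magnification) cell, with a mean and SD for
#' each of the five phase-contrast parameters. Draws are independent
#' Gaussians per parameter (no cross-parameter covariance is modeled).
#'
#' @param groups Data frame with columns `tissue`, `state` (healthy/tumoral),
#'   `magnification`, and `<param>_mean` / `<param>_sd` for each of `riv`,
#'   `sc`, `af`, `fd`, `os`.
#' @param n_per_group Draws per group (>= 2).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, n_per_group, seed = 1L) {
  stopifnot(is.data.frame(groups), n_per_group >= 2)
  needed <- c("tissue", "state", "magnification",
              paste0(rep(.parameters, each = 2), c("_mean", "_sd")))
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols))
    stop("groups is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(groups$state %in% c("healthy", "tumoral")))
    stop("state must be 'healthy' or 'tumoral'")
  sds <- as.matrix(groups[, paste0(.parameters, "_sd")])
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  structure(list(groups = as_tibble(groups),
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build a cohort spec from the bundled reference group statistics
#'
#' Convenience wrapper: selects tissues/magnifications from
#' [reference_group_stats()], pivots to the wide per-group layout and returns
#' a [cohort_spec()].
#'
#' @param tissues,magnifications Subsets to include (default: all).
#' @param n_per_group Draws per (tissue, state, magnification) group.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
reference_cohort_spec <- function(tissues = NULL, magnifications = NULL,
                                  n_per_group = 100L, seed = 1L) {
  stats <- reference_group_stats()
  if (!is.null(tissues)) stats <- stats[stats$tissue %in% tissues, ]
  if (!is.null(magnifications))
    stats <- stats[stats$magnification %in% magnifications, ]
  if (!nrow(stats)) stop("no reference rows match the requested subset")
  wide <- tidyr::pivot_wider(stats,
                             names_from = "parameter",
                             values_from = c("mean", "sd"),
                             names_glue = "{parameter}_{.value}")
  cohort_spec(wide, n_per_group = n_per_group, seed = seed)
}

#' Generate a labeled feature cohort
#'
#' Draws `n_per_group` independent Gaussian feature vectors per group of the
#' spec. Reproducible for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `tissue`, `state`, `magnification` and the
#'   five parameters `riv`, `sc`, `af`, `fd`, `os`.
#' @export
#' @examples
#' spec <- reference_cohort_spec("ganglion", "20x", n_per_group = 5, seed = 1)
#' generate_feature_cohort(spec)
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups
  n <- spec$n_per_group
  withr::with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      draws <- lapply(.parameters, function(p) {
        rnorm(n, mean = g[[paste0(p, "_mean")]][i],
              sd = g[[paste0(p, "_sd")]][i])
      })
      names(draws) <- .parameters
      tibble(tissue = g$tissue[i], state = g$state[i],
             magnification = g$magnification[i], !!!draws)
    })
    dplyr::bind_rows(rows)
  })
}
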