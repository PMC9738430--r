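#' Per-group descriptive statistics of a feature cohort
#'
#' Mean and sample standard deviation (divisor n - 1) of every parameter for
#' every (tissue, state, magnification) group, in deterministic order
#' (tissue, magnification, state, parameter). Groups with fewer than two
#' observations get an `NA` standard deviation.
#'
#' @param cohort Feature tibble with `tissue`, `state`, `magnification` and
#'   parameter columns.
#' @param parameters Parameter columns to summarize (default: whichever of
#'   the five canonical parameters are present).
#' @return Tibble: `tissue`, `state`, `magnification`, `parameter`, `n`,
#'   `mean`, `sd`.
#' @export
group_summary <- function(cohort, parameters = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(parameters))
    parameters <- intersect(.parameters, names(cohort))
  if (!length(parameters)) stop("no parameter columns found")
  long <- tidyr::pivot_longer(
    cohort[, c("tissue", "state", "magnification", parameters)],
    dplyr::all_of(parameters), names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$tissue, .data$magnification, .data$state,
                    .data$parameter),
    n = sum(is.finite(.data$value)),
    mean = mean(.data$value[is.finite(.data$value)]),
    sd = if (sum(is.finite(.data$value)) >= 2)
      sd(.data$value[is.finite(.data$value)]) else NA_real_,
    .groups = "drop")
  dplyr::arrange(out, .data$tissue, .data$magnification, .data$state,
                 .data$parameter)[, c("tissue", "state", "magnification",
                                      "parameter", "n", "mean", "sd")]
}

#' Worked mean-difference comparison between healthy and tumoral groups
#'
#' Absolute difference of group means, rounded to the parameter's reporting
#' precision (RIV 4 decimals, SC 2, AF 5, FD 3, OS 2), and a flag for
#' whether the difference exceeds both, one, or neither of the two group
#' standard deviations -- the screening heuristic used before the formal
#' ANOVA: a difference larger than both SDs marks a promising discriminator.
#'
#' @param summary_h,summary_t One-row data frames (healthy and tumoral) with
#'   `tissue`, `magnification`, `parameter`, `mean`, `sd`, as produced by
#'   [group_summary()] or taken from [reference_group_stats()].
#' @return One-row tibble: keys, `mean_healthy`, `mean_tumoral`, `abs_diff`
#'   (rounded), `sd_healthy`, `sd_tumoral`, `exceeds` in
#'   `c("both", "one", "neither")`.
#' @export
#' @examples
#' s <- reference_group_stats()
#' h <- s[s$tissue == "ganglion" & s$magnification == "20x" &
#'        s$parameter == "sc" & s$state == "healthy", ]
#' t <- s[s$tissue == "ganglion" & s$magnification == "20x" &
#'        s$parameter == "sc" & s$state == "tumoral", ]
#' mean_difference(h, t)   # abs_diff 25.39, exceeds both SDs
mean_difference <- function(summary_h, summary_t) {
  keys <- c("tissue", "magnification", "parameter")
  if (!identical(unname(unlist(summary_h[1, keys])),
                 unname(unlist(summary_t[1, keys]))))
    stop("summaries must refer to the same tissue, magnification and parameter")
  p <- summary_h$parameter[1]
  digits <- if (p %in% names(.param_digits)) .param_digits[[p]] else 4L
  d <- round(abs(summary_t$mean[1] - summary_h$mean[1]), digits)
  over <- sum(d > c(summary_h$sd[1], summary_t$sd[1]))
  tibble(tissue = summary_h$tissue[1],
         magnification = summary_h$magnification[1],
         parameter = p,
         mean_healthy = summary_h$mean[1], mean_tumoral = summary_t$mean[1],
         abs_diff = d,
         sd_healthy = summary_h$sd[1], sd_tumoral = summary_t$sd[1],
         exceeds = c("neither", "one", "both")[over + 1])
}

#' One-way analysis of variance
#'
#' Standard one-way ANOVA: F = MS_between / MS_within with an
#' F-distribution p-value (Snedecor F). Degenerate inputs follow the usual
#' conventions: zero within-group variance with unequal means gives p = 0
#' (infinite F); all values equal gives F = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2), or a
#'   data frame with columns `value` and `group`.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.005).
#' @return An object of class `anova_result`: `F`, `p_value`, `df_between`,
#'   `df_within`, `significant`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))   # F = 13.5 on (1, 4) df
one_way_anova <- function(groups, alpha = 0.005) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df_b <- length(groups) - 1L
  df_w <- length(values) - length(groups)
  # a perfect fit (zero within-group variance) is handled explicitly below,
  # so the fitter's unreliable-F warning for that case is redundant
  tab <- suppressWarnings(anova(lm(values ~ g)))
  msb <- tab$`Mean Sq`[1]
  msw <- tab$`Mean Sq`[2]
  if (msw == 0) {
    if (msb == 0) { f <- 0; p <- 1 } else { f <- Inf; p <- 0 }
  } else {
    f <- msb / msw
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = f, p_value = p, df_between = df_b, df_within = df_w,
                 significant = p < alpha),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Healthy-versus-tumoral significance screen
#'
#' One-way ANOVA per (parameter, magnification, tissue) cell, comparing the
#' healthy and tumoral groups, with cells below the significance level
#' flagged. No multiple-testing correction is applied; the number of tests
#' performed is recorded in the `n_tests` attribute.
#'
#' @param cohort Feature tibble (see [group_summary()]).
#' @param alpha Significance level (default 0.005).
#' @param parameters Parameter columns to screen.
#' @return Tibble: `parameter`, `magnification`, `tissue`, `F`, `p_value`,
#'   `significant`; cells missing a state are `NA` with a warning.
#' @export
significance_table <- function(cohort, alpha = 0.005, parameters = NULL) {
  stopifnot(is.data.frame(cohort))
  if (is.null(parameters))
    parameters <- intersect(.parameters, names(cohort))
  cells <- expand.grid(parameter = parameters,
                       magnification = sort(unique(cohort$magnification)),
                       tissue = sort(unique(cohort$tissue)),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- cohort[cohort$tissue == cells$tissue[i] &
                    cohort$magnification == cells$magnification[i], ]
    h <- sub[[cells$parameter[i]]][sub$state == "healthy"]
    t <- sub[[cells$parameter[i]]][sub$state == "tumoral"]
    h <- h[is.finite(h)]; t <- t[is.finite(t)]
    if (length(h) < 2 || length(t) < 2) {
      warning(sprintf("cell %s/%s/%s lacks both states; p-value left blank",
                      cells$parameter[i], cells$magnification[i],
                      cells$tissue[i]))
      return(tibble(parameter = cells$parameter[i],
                    magnification = cells$magnification[i],
                    tissue = cells$tissue[i], F = NA_real_,
                    p_value = NA_real_, significant = NA))
    }
    a <- one_way_anova(list(h, t), alpha = alpha)
    tibble(parameter = cells$parameter[i],
           magnification = cells$magnification[i],
           tissue = cells$tissue[i], F = a$F, p_value = a$p_value,
           significant = a$significant)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}
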