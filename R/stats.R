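#' Group summary statistics
#'
#' Sample mean, SD (n - 1 denominator) and standard error of the mean per
#' group, the form in which group readouts are conventionally reported
#' (mean +/- SEM).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length.
#' @return A tibble with columns `group`, `n`, `mean`, `sd`, `sem`.
#' @export
#' @examples
#' group_summary(c(2, 4, 6, 1, 1, 1), rep(c("a", "b"), each = 3))
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (any(tab < 2L)) {
    stop("group_summary: every group needs n >= 2", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = values, group = groups), group),
    n = dplyr::n(), mean = mean(value), sd = stats::sd(value),
    .groups = "drop")
  out$sem <- out$sd / sqrt(out$n)
  out
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition; the p-value comes
#' from the F distribution with (k - 1, n - k) degrees of freedom. When the
#' within-group variance is zero and the group means are equal, F is
#' undefined and reported as missing.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups, each n >= 2).
#' @return A list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
    stop("one_way_anova: need >= 2 groups with n >= 2 each", call. = FALSE)
  }
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  ssb <- sum(table(groups) * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  df_b <- k - 1L
  df_w <- n - k
  if (ssw == 0) {
    # no within-group variance: F undefined when the means agree too
    if (ssb == 0) {
      return(list(F = NA_real_, df_between = df_b, df_within = df_w,
                  p = NA_real_))
    }
    return(list(F = Inf, df_between = df_b, df_within = df_w, p = 0))
  }
  Fv <- (ssb / df_b) / (ssw / df_w)
  list(F = Fv, df_between = df_b, df_within = df_w,
       p = stats::pf(Fv, df_b, df_w, lower.tail = FALSE))
}

#' Pearson product-moment correlation
#'
#' Correlation record in the form used by the TH-correlation table: r, the
#' two-sided p-value from the t transform `t = r * sqrt((n - 2) / (1 - r^2))`
#' with n - 2 degrees of freedom, and n. Zero variance in either argument
#' yields a missing record with a warning.
#'
#' @param x,y Numeric vectors (pairwise complete observations are used;
#'   n >= 3 required).
#' @return A one-row tibble with columns `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("pearson_cor: need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_cor: zero variance, correlation undefined",
            call. = FALSE)
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Percent loss relative to control
#'
#' `100 * (1 - mean(treated) / mean(control))`; the summary used for
#' lesion-induced depletion of a marker (e.g. TH-positive neurons).
#'
#' @param treated,control Numeric vectors (or scalars) of marker levels.
#' @return Percent loss.
#' @export
percent_loss <- function(treated, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc <= 0) {
    stop("percent_loss: control mean must be positive", call. = FALSE)
  }
  100 * (1 - mean(treated) / mc)
}

# Table rows of the correlation report: per-paw parameters and whole-run
# scalars, in the conventional order.
.cor_parameters <- list(
  per_paw = c("stance", "stride_length", "swing_speed", "step_cycle",
              "duty_cycle", "initial_dual_stance", "terminal_dual_stance"),
  whole = c("support_diagonal", "support_three", "support_four",
            "speed_variation", "cadence", "bos_hind")
)

#' Correlation table of gait readouts against TH level
#'
#' Builds the correlation report: for every gait parameter (per paw where the
#' parameter is paw-specific) the Pearson correlation of per-animal values
#' against the per-animal SN TH level, with its two-sided p-value. Per-animal
#' values are the means over that animal's runs (runs are replicate crossings,
#' not independent animals). Open-field distance is appended when
#' trajectories are available. Both groups are pooled by default; set
#' `groups` to restrict.
#'
#' @param gait_tbl Tidy gait table from [cohort_gait_table()].
#' @param animals Animal table with columns `animal` and `th_sn` (e.g.
#'   `cohort$animals`).
#' @param trajectories Optional named list of trajectories (per animal) for
#'   the open-field row.
#' @param groups Optional subset of groups to include (default: all).
#' @return A tibble with columns `parameter`, `paw`, `r`, `p`, `n`.
#' @export
correlation_table <- function(gait_tbl, animals, trajectories = NULL,
                              groups = NULL) {
  if (!is.null(groups)) {
    gait_tbl <- gait_tbl[gait_tbl$group %in% groups, ]
    animals <- animals[animals$group %in% groups, ]
  }
  miss <- sum(!is.finite(animals$th_sn))
  if (miss > 0) {
    message(sprintf("correlation_table: dropping %d animal(s) with missing TH",
                    miss))
    animals <- animals[is.finite(animals$th_sn), ]
  }
  per_animal <- dplyr::summarise(
    dplyr::group_by(gait_tbl, animal, parameter, paw),
    value = mean(value, na.rm = TRUE), .groups = "drop")
  per_animal <- dplyr::inner_join(per_animal,
                                  animals[c("animal", "th_sn")],
                                  by = "animal")
  rec <- function(param, paw_sel) {
    sub <- per_animal[per_animal$parameter == param &
                        (if (is.na(paw_sel)) is.na(per_animal$paw)
                         else per_animal$paw %in% paw_sel), ]
    if (nrow(sub) < 3L) return(NULL)
    dplyr::mutate(pearson_cor(sub$value, sub$th_sn),
                  parameter = param, paw = paw_sel, .before = 1L)
  }
  rows <- c(
    unlist(lapply(.cor_parameters$per_paw, function(pp) {
      lapply(PAWS, function(pw) rec(pp, pw))
    }), recursive = FALSE),
    lapply(.cor_parameters$whole, function(pp) rec(pp, NA_character_))
  )
  out <- dplyr::bind_rows(rows)
  if (!is.null(trajectories)) {
    dist <- vapply(animals$animal, function(a) {
      tr <- trajectories[[a]]
      if (is.null(tr)) return(NA_real_)
      path_length(tr)$total_distance
    }, numeric(1))
    ok <- is.finite(dist)
    if (sum(ok) >= 3L) {
      out <- dplyr::bind_rows(out, dplyr::mutate(
        pearson_cor(dist[ok], animals$th_sn[ok]),
        parameter = "openfield_distance", paw = NA_character_, .before = 1L))
    }
  }
  out
}
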