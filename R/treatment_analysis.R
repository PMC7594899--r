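# Tumour treatment-response analysis: calliper volumes, per-group growth
# summaries, Kaplan-Meier survival, exact rank-sum test for small groups.

#' Tumour volume from calliper width and length
#'
#' The standard ellipsoid approximation for flank tumours:
#' volume = width^2 x length / 2, with width the smaller calliper axis.
#'
#' @param width_mm,length_mm Calliper measurements, mm; must be >= 0.
#' @return Volume in mm^3, vectorised.
#' @export
#' @examples
#' tumour_volume(8, 8) # 256
tumour_volume <- function(width_mm, length_mm) {
  if (any(width_mm < 0) || any(length_mm < 0)) {
    stopf("calliper measurements must be >= 0")
  }
  width_mm^2 * length_mm / 2
}

#' Add the derived volume column to a measurement table
#'
#' @param records Data frame with `width_mm` and `length_mm` columns.
#' @return The input with a `volume_mm3` column appended.
#' @export
add_tumour_volume <- function(records) {
  dplyr::mutate(records,
                volume_mm3 = tumour_volume(.data$width_mm, .data$length_mm))
}

#' Per-group, per-day tumour growth summary
#'
#' Mean volume and standard error of the mean for each group at each
#' measurement day. An animal stops contributing after its event day
#' (surviving-animals convention: tumour size is summarised over the
#' animals still on study, not carried forward).
#'
#' @param records Data frame with columns `animal_id`, `group`, `day`,
#'   `width_mm`, `length_mm` (or a precomputed `volume_mm3`), and
#'   optionally `event_day`.
#' @return A tibble with `group`, `day`, `n`, `mean_volume_mm3`,
#'   `sem_mm3`.
#' @export
growth_summary <- function(records) {
  if (!"volume_mm3" %in% names(records)) records <- add_tumour_volume(records)
  if ("event_day" %in% names(records)) {
    records <- dplyr::filter(records, .data$day <= .data$event_day)
  }
  records |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_volume_mm3 = mean(.data$volume_mm3),
      sem_mm3 = stats::sd(.data$volume_mm3) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_mm3 = dplyr::if_else(.data$n == 1L, 0, .data$sem_mm3))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of survival from event days and event indicators
#' (event = humane endpoint reached; censoring = alive at study end).
#' Computed with [survival::survfit()].
#'
#' @param records Data frame with one row per animal: `event_day`, `event`
#'   (logical or 0/1), and optionally `group`; or supply `event_days` and
#'   `event_flags` vectors directly.
#' @param event_days,event_flags Alternative vector interface.
#' @return A `km_estimate` tibble: `group` (when present), `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `std_err`.
#' @export
#' @examples
#' km_estimate(event_days = c(5, 10, 15), event_flags = c(TRUE, FALSE, TRUE))
km_estimate <- function(records = NULL, event_days = NULL, event_flags = NULL) {
  if (is.null(records)) {
    records <- tibble::tibble(event_day = event_days,
                              event = as.logical(event_flags))
  }
  records <- dplyr::distinct(
    records,
    dplyr::across(dplyr::any_of(c("animal_id", "group", "event_day", "event")))
  )
  has_group <- "group" %in% names(records)
  fit <- if (has_group) {
    survival::survfit(survival::Surv(event_day, event) ~ group, data = records)
  } else {
    survival::survfit(survival::Surv(event_day, event) ~ 1, data = records)
  }
  s <- summary(fit, censored = TRUE)
  out <- tibble::tibble(
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    survival = s$surv,
    std_err = s$std.err
  )
  if (has_group) {
    out <- dplyr::bind_cols(
      tibble::tibble(group = sub("^group=", "", as.character(s$strata))),
      out
    )
  }
  class(out) <- c("km_estimate", class(out))
  out
}

#' Survival probability at given times from a KM estimate
#'
#' Right-continuous step-function evaluation.
#'
#' @param km A `km_estimate` (single stratum).
#' @param times Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, times) {
  vapply(times, function(t) {
    past <- km$time <= t
    if (!any(past)) 1 else km$survival[max(which(past))]
  }, numeric(1))
}

#' Plot a Kaplan-Meier estimate
#'
#' @param object A `km_estimate`.
#' @param ... Unused.
#' @return A ggplot step plot of survival over time, by group when present.
#' @export
autoplot.km_estimate <- function(object, ...) {
  df <- tibble::as_tibble(object)
  has_group <- "group" %in% names(df)
  pad <- function(d) dplyr::bind_rows(
    dplyr::mutate(dplyr::slice_head(d, n = 1), time = 0, survival = 1,
                  n_event = 0, n_censor = 0),
    d
  )
  df <- if (has_group) {
    dplyr::group_modify(dplyr::group_by(df, .data$group), ~ pad(.x)) |>
      dplyr::ungroup()
  } else {
    pad(df)
  }
  aes <- if (has_group) {
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$survival)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "day", y = "survival fraction")
}

# Mann-Whitney U from midranks: U_A = R_A - n_A (n_A + 1) / 2.
u_from_ranks <- function(ranks_a, n_a) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

#' Exact two-sided rank-sum (Mann-Whitney) test for small groups
#'
#' Computes the Mann-Whitney U statistic and an exact two-sided p-value by
#' full enumeration of all group labelings of the pooled sample, which is
#' the appropriate test for the small group sizes of preclinical studies.
#' Ties are handled by midranks with the permutation null over the observed
#' pooled values, so the p-value remains exact under ties. The two-sided
#' p-value is `P(|U - n1 n2 / 2| >= |U_obs - n1 n2 / 2|)` under the
#' enumeration null, which for tie-free data equals the classical
#' double-tail exact p.
#'
#' @param x,y Numeric vectors for the two groups; combined length <= 20
#'   (the enumeration bound).
#' @return A `rank_sum_exact` list: `statistic` (U of `x`), `p_value`,
#'   `n_x`, `n_y`, `ties`, `method`.
#' @export
#' @examples
#' rank_sum_exact(c(1, 2), c(3, 4)) # U = 0, p = 1/3
rank_sum_exact <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("both groups must be non-empty")
  if (n1 + n2 > 20L) {
    stopf("combined n = %d exceeds the exact-enumeration bound of 20", n1 + n2)
  }
  pooled <- c(x, y)
  ranks <- rank(pooled) # midranks under ties
  u_obs <- u_from_ranks(ranks[seq_len(n1)], n1)
  centre <- n1 * n2 / 2

  labelings <- utils::combn(n1 + n2, n1)
  u_all <- apply(labelings, 2L, function(idx) u_from_ranks(ranks[idx], n1))
  p <- mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-9)

  structure(
    list(statistic = u_obs, p_value = p, n_x = n1, n_y = n2,
         ties = anyDuplicated(pooled) > 0L,
         method = "exact two-sided Mann-Whitney (full enumeration)"),
    class = "rank_sum_exact"
  )
}

#' @export
print.rank_sum_exact <- function(x, ...) {
  cat(sprintf("%s\nU = %g (n = %d, %d), exact two-sided p = %.4g%s\n",
              x$method, x$statistic, x$n_x, x$n_y, x$p_value,
              if (x$ties) " (midranks; ties present)" else ""))
  invisible(x)
}

#' @rdname rank_sum_exact
#' @param x A `rank_sum_exact` object (for `tidy`/`glance`).
#' @param ... Unused.
#' @export
tidy.rank_sum_exact <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 method = x$method)
}

#' @rdname rank_sum_exact
#' @export
glance.rank_sum_exact <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n_x = x$n_x, n_y = x$n_y, ties = x$ties)
}

#' Per-day group comparison of tumour volumes
#'
#' Applies [rank_sum_exact()] to the two groups' volumes at each measurement
#' day on which both groups still have animals on study. Reported per day,
#' without multiplicity adjustment, as an exploratory treatment-response
#' profile.
#'
#' @param records Measurement table as in [growth_summary()]; `group` must
#'   have exactly two levels.
#' @return A tibble with `day`, `n_a`, `n_b`, `statistic`, `p_value`.
#' @export
compare_groups_by_day <- function(records) {
  if (!"volume_mm3" %in% names(records)) records <- add_tumour_volume(records)
  if ("event_day" %in% names(records)) {
    records <- dplyr::filter(records, .data$day <= .data$event_day)
  }
  groups <- sort(unique(records$group))
  if (length(groups) != 2L) stopf("need exactly two groups")
  records |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) {
      a <- d$volume_mm3[d$group == groups[1]]
      b <- d$volume_mm3[d$group == groups[2]]
      if (length(a) == 0L || length(b) == 0L) return(tibble::tibble())
      t <- rank_sum_exact(a, b)
      tibble::tibble(n_a = length(a), n_b = length(b),
                     statistic = t$statistic, p_value = t$p_value)
    }) |>
    dplyr::ungroup()
}

#' Read a treatment measurement table from CSV
#'
#' Expects the header
#' `animal_id,group,day,width_mm,length_mm,event_day,event`.
#'
#' @param path CSV path.
#' @return A tibble with `volume_mm3` appended.
#' @export
read_treatment_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "day", "width_mm", "length_mm")
  if (!all(need %in% names(df))) {
    stopf("need columns %s", paste(need, collapse = ", "))
  }
  if ("event" %in% names(df)) df$event <- as.logical(df$event)
  add_tumour_volume(tibble::as_tibble(df))
}

#' Plot per-group growth curves
#'
#' Group mean volume over time with SEM error bars.
#'
#' @param records Measurement table (see [growth_summary()]).
#' @return A ggplot object.
#' @export
plot_growth <- function(records) {
  gs <- growth_summary(records)
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$day, y = .data$mean_volume_mm3,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_volume_mm3 - .data$sem_mm3,
                   ymax = .data$mean_volume_mm3 + .data$sem_mm3),
      width = 0.6
    ) +
    ggplot2::labs(x = "day post-injection", y = expression(volume ~ (mm^3)))
}
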