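# Library-scale screening: every drug is simulated against every
# expression profile at a fixed relative inhibition (default 0.9, the
# setting used to tabulate predicted drug effects), and per-drug
# cancer-vs-healthy differences are tested to rank therapeutic
# windows.

#' Screen a drug library across expression profiles
#'
#' For each profile a fresh copy of the model is constrained with the
#' bound rule; for each drug the target reactions are mapped by
#' structural analogy ([map_drug_to_reactions()]) and relative growth
#' under inhibition `i` is computed. Drugs mapping to no reaction get
#' relative growth 1 and are flagged. Profiles are independent: no
#' information flows between them.
#'
#' @param drugs Fingerprinted drug table (rows with `role == "drug"`
#'   of a fingerprinted library).
#' @param model An unconstrained [metabolic_model()].
#' @param profiles List of [expression_profile()]s with group labels.
#' @param metabolite_library Fingerprinted metabolite table.
#' @param i Relative inhibition (default 0.9).
#' @param rule A [bound_rule()].
#' @param threshold Tanimoto pairing threshold.
#' @param baseline_mode,baseline_n,seed Passed to [baseline_rates()].
#' @param ... Further arguments to [map_drug_to_reactions()].
#' @return An object of class `screen_result`: tibble with columns
#'   `drug`, `profile`, `group`, `relative_growth`, `n_targets`,
#'   `mapped`.
#' @export
screen_drugs <- function(drugs, model, profiles, metabolite_library,
                         i = 0.9, rule = bound_rule(), threshold = 0.9,
                         baseline_mode = "vertex_mean", baseline_n = 50,
                         seed = 1, ...) {
  if (length(profiles) == 0L) abort("no profiles supplied")
  # target maps depend only on structures, not on profiles
  maps <- map(seq_len(nrow(drugs)), function(d) {
    suppressWarnings(
      map_drug_to_reactions(drugs[d, ], model, metabolite_library,
                            threshold = threshold, ...))
  })
  rows <- list()
  for (p in seq_along(profiles)) {
    prof <- profiles[[p]]
    cm <- apply_expression_constraints(model, prof, rule)
    base <- fba_max(cm)
    if (base$status != "optimal" || base$objective_value <= 0) {
      abort(paste0("profile '", attr(prof, "label"),
                   "' yields no feasible growth"))
    }
    for (d in seq_along(maps)) {
      tm <- maps[[d]]
      rg <- if (nrow(tm) == 0L) 1 else {
        bl <- baseline_rates(cm, tm, mode = baseline_mode,
                             n = baseline_n, seed = seed)
        res <- fba_max(apply_inhibition(cm, bl, i))
        if (res$status != "optimal") NA_real_
        else res$objective_value / base$objective_value
      }
      rows[[length(rows) + 1L]] <- tibble(
        drug = drugs$id[[d]],
        profile = attr(prof, "label"),
        group = attr(prof, "group"),
        relative_growth = rg,
        n_targets = nrow(tm),
        mapped = nrow(tm) > 0L
      )
    }
  }
  structure(bind_rows(rows),
            class = c("screen_result", class(tibble())),
            inhibition = i)
}

#' Two-sample pooled t-test of a therapeutic window
#'
#' Two-tailed Student's t-test with pooled variance comparing relative
#' growth between cancer and healthy profiles. Direction is
#' `sign(mean_healthy - mean_cancer)`: positive means the cancer group
#' is more impaired (the therapeutic-window direction). Degenerate
#' inputs: equal means with zero pooled variance give `t = 0, p = 1`;
#' unequal means with zero variance give infinite `t` and `p = 0`.
#'
#' @param values Numeric vector of relative growth values.
#' @param groups Character vector (`"cancer"` / `"healthy"`), same
#'   length.
#' @return A one-row tibble `mean_cancer`, `mean_healthy`,
#'   `t_statistic`, `p_value`, `direction`.
#' @export
window_test <- function(values, groups) {
  xc <- values[groups == "cancer"]
  xh <- values[groups == "healthy"]
  if (length(xc) < 2L || length(xh) < 2L) {
    abort("each group needs at least 2 values")
  }
  n1 <- length(xc); n2 <- length(xh)
  m1 <- mean(xc); m2 <- mean(xh)
  sp2 <- ((n1 - 1) * stats::var(xc) + (n2 - 1) * stats::var(xh)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    t_stat <- if (m1 == m2) 0 else sign(m2 - m1) * Inf
    p <- if (m1 == m2) 1 else 0
  } else {
    t_stat <- (m2 - m1) / se
    p <- 2 * pt(-abs(t_stat), df = n1 + n2 - 2)
  }
  tibble(mean_cancer = m1, mean_healthy = m2,
         t_statistic = t_stat, p_value = p,
         direction = sign(m2 - m1))
}

#' Rank therapeutic windows from a screen
#'
#' Per drug, tests cancer vs healthy relative growth
#' ([window_test()]), attaches Benjamini-Hochberg q-values across the
#' library (raw p-values are kept alongside), and sorts by q-value
#' then effect size. Only drugs with the cancer group more affected
#' (`direction > 0`) and `q <= alpha` are flagged as windows.
#'
#' @param result A [screen_drugs()] result.
#' @param alpha Significance level for the window flag (default 0.05).
#' @param use_raw_p Flag windows on raw p-values instead of q-values
#'   (compatibility with uncorrected per-drug testing).
#' @return A tibble of class `window_ranking`, one row per drug:
#'   test statistics, `q_value`, `effect` (mean_healthy -
#'   mean_cancer), `window` (logical).
#' @export
rank_windows <- function(result, alpha = 0.05, use_raw_p = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  per_drug <- result |>
    filter(.data$group %in% c("cancer", "healthy")) |>
    group_by(.data$drug) |>
    summarise(test = list(window_test(.data$relative_growth,
                                      .data$group)),
              .groups = "drop") |>
    tidyr::unnest("test")
  per_drug$q_value <- p.adjust(per_drug$p_value, method = "BH")
  per_drug$effect <- per_drug$mean_healthy - per_drug$mean_cancer
  crit <- if (use_raw_p) per_drug$p_value else per_drug$q_value
  per_drug$window <- per_drug$direction > 0 & crit <= alpha
  out <- per_drug |>
    arrange(.data$q_value, desc(.data$effect), .data$drug)
  structure(out, class = c("window_ranking", class(tibble())),
            alpha = alpha)
}

#' @rdname screen_drugs
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) as_tibble(x)

#' @rdname screen_drugs
#' @export
glance.screen_result <- function(x, ...) {
  tibble(n_drugs = length(unique(x$drug)),
         n_profiles = length(unique(x$profile)),
         inhibition = attr(x, "inhibition"))
}

#' @rdname screen_drugs
#' @param object A `screen_result`.
#' @export
autoplot.screen_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$profile, y = .data$drug,
                               fill = .data$relative_growth)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(fill = "relative\ngrowth") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
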