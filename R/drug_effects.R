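# Simulation of competitive inhibition: a drug is mapped to candidate
# target reactions through its structural analogy to metabolites (and
# optional EC annotations), the targets' baseline rates are estimated
# on the uninhibited model, and their bounds are tightened to a
# fraction of baseline before re-maximizing growth.

# hub metabolites excluded from analogy mapping by default: an analog
# of water or ATP would "target" half the network
default_currency_kegg <- function() {
  c("C00001",  # H2O
    "C00002", "C00008", "C00020",  # ATP/ADP/AMP
    "C00003", "C00004", "C00005", "C00006",  # NAD(H), NADP(H)
    "C00080",  # H+
    "C00009", "C00013",  # phosphate, PPi
    "C00010", "C00024",  # CoA, acetyl-CoA
    "C00007", "C00011")  # O2, CO2
}

#' Map a drug to candidate target reactions in a model
#'
#' Finds metabolites structurally analogous to the drug
#' ([find_analog_pairs()] at `threshold`), then collects the
#' gene-associated reactions in which those metabolites participate —
#' a competitive inhibitor blocks the enzyme whichever direction the
#' reaction runs, so both substrate and product side count unless
#' `substrate_only`. Reactions whose genes carry an EC number matching
#' one of the drug's annotated targets (via `gene_ec_map`) are added
#' with provenance `annotated_target`. Currency hubs are excluded from
#' the analogy route.
#'
#' @param drug One-row fingerprinted compound table (the drug).
#' @param model A [metabolic_model()] whose metabolites carry
#'   `kegg_id` accessions matching the metabolite library ids.
#' @param metabolite_library Fingerprinted compound table of
#'   metabolites, ids = KEGG accessions.
#' @param threshold Tanimoto pairing threshold (strict; default 0.9).
#' @param substrate_only If `TRUE`, only reactions consuming the
#'   analog metabolite are targeted.
#' @param currency_kegg KEGG accessions never used for analogy
#'   mapping.
#' @param gene_ec_map Optional tibble `gene`, `ec` linking model genes
#'   to EC numbers, enabling the annotated-target route.
#' @return A tibble of class `drug_target_map` with columns
#'   `reaction`, `provenance`; attribute `analogs` holds the analog
#'   pair table. Zero rows (with a warning) when nothing maps.
#' @export
map_drug_to_reactions <- function(drug, model, metabolite_library,
                                  threshold = 0.9,
                                  substrate_only = FALSE,
                                  currency_kegg = default_currency_kegg(),
                                  gene_ec_map = NULL) {
  stopifnot(inherits(model, "metabolic_model"), nrow(drug) == 1L)
  mets <- metabolite_library[!metabolite_library$id %in% currency_kegg, ]
  pairs <- find_analog_pairs(drug, mets, threshold = threshold)

  has_genes <- map_int(model$reactions$genes, length) > 0L
  target <- character(0)
  if (nrow(pairs)) {
    analog_met_ids <- model$metabolites$id[
      model$metabolites$kegg_id %in% pairs$metabolite_id]
    hit <- map_lgl(model$reactions$stoichiometry, function(s) {
      coef <- s[names(s) %in% analog_met_ids]
      if (substrate_only) any(coef < 0) else length(coef) > 0L
    })
    target <- model$reactions$id[hit & has_genes]
  }
  out <- tibble(reaction = target,
                provenance = rep("metabolite_analogy", length(target)))

  if (!is.null(gene_ec_map) && "ecs" %in% names(drug) &&
      length(drug$ecs[[1]])) {
    hit_genes <- gene_ec_map$gene[
      map_lgl(gene_ec_map$ec,
              function(e) any(map_lgl(drug$ecs[[1]], ~ ec_match(e, .x))))]
    ann <- model$reactions$id[
      map_lgl(model$reactions$genes, ~ any(.x %in% hit_genes))]
    ann <- setdiff(ann, out$reaction)
    out <- bind_rows(out, tibble(reaction = ann,
                                 provenance = rep("annotated_target",
                                                  length(ann))))
  }
  if (nrow(out) == 0L) {
    warn(paste0("drug '", drug$id[[1]],
                "' maps to no reaction (no analog, no annotation)"))
  }
  structure(out, class = c("drug_target_map", class(out)),
            drug_id = drug$id[[1]], analogs = pairs)
}

#' Baseline rates of target reactions in the uninhibited model
#'
#' The optimal flux distribution is typically degenerate, so "the rate
#' in absence of the drug" is ambiguous. Default `vertex_mean`: mean
#' absolute flux over `n` sampled optimal vertices
#' ([sample_optimal_vertices()]); `single_lp` takes the absolute flux
#' of one optimal solution.
#'
#' @param model A constrained [metabolic_model()] with a feasible
#'   optimum.
#' @param targets Character vector of target reaction ids (or a
#'   `drug_target_map`).
#' @param mode `"vertex_mean"` (default) or `"single_lp"`.
#' @param n Vertex samples for `vertex_mean`.
#' @param seed Seed for the vertex sampler.
#' @return Named numeric vector of baseline rates (absolute fluxes).
#' @export
baseline_rates <- function(model, targets,
                           mode = c("vertex_mean", "single_lp"),
                           n = 100, seed = 1) {
  mode <- match.arg(mode)
  targets <- target_ids(targets)
  if (!all(targets %in% model$reactions$id)) {
    abort("unknown target reaction id")
  }
  if (mode == "single_lp") {
    res <- fba_max(model)
    if (res$status != "optimal") abort("baseline model is not solvable")
    fl <- setNames(res$fluxes$flux, res$fluxes$reaction)
    return(abs(fl[targets]))
  }
  smp <- sample_optimal_vertices(model, n = n, seed = seed)
  colMeans(abs(smp$samples[, targets, drop = FALSE]))
}

target_ids <- function(targets) {
  if (is.data.frame(targets)) unique(targets$reaction) else unique(targets)
}

#' Inhibit target reactions relative to their baseline rates
#'
#' Relative inhibition `i` rescales each target's upper bound to
#' `(1 - i) * baseline` (and the lower bound to the negated value for
#' reversible targets); `i = 0.9` constrains a reaction to 0.1 times
#' its uninhibited rate. Targets with zero baseline are pinned to zero
#' for any `i > 0`. Returns a modified copy.
#'
#' @param model A [metabolic_model()].
#' @param baselines Named baseline rates from [baseline_rates()].
#' @param i Relative inhibition in `[0, 1]`.
#' @return A new [metabolic_model()].
#' @export
apply_inhibition <- function(model, baselines, i) {
  if (i < 0 || i > 1) abort("relative inhibition must be in [0, 1]")
  ids <- names(baselines)
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) abort("unknown target reaction id")
  new_ub <- (1 - i) * unname(baselines)
  model$reactions$upper_bound[idx] <-
    pmin(model$reactions$upper_bound[idx], new_ub)
  rev <- model$reactions$reversible[idx]
  model$reactions$lower_bound[idx] <-
    ifelse(rev, pmax(model$reactions$lower_bound[idx], -new_ub),
           pmin(model$reactions$lower_bound[idx],
                model$reactions$upper_bound[idx]))
  model
}

#' Relative growth under inhibition of target reactions
#'
#' Ratio of the maximal growth rate with the targets inhibited by
#' fraction `i` to the uninhibited maximal growth rate. Because the
#' baseline solution scaled by `(1 - i)` stays feasible, the value is
#' always at least `1 - i`; it equals 1 when alternative pathways
#' fully compensate.
#'
#' @inheritParams baseline_rates
#' @param i Relative inhibition in `[0, 1]`.
#' @param baselines Optional precomputed [baseline_rates()] (computed
#'   on `model` if missing).
#' @return Relative growth in `[1 - i, 1]` (up to solver tolerance).
#' @export
relative_growth <- function(model, targets, i, baselines = NULL,
                            mode = c("vertex_mean", "single_lp"),
                            n = 100, seed = 1) {
  base <- fba_max(model)
  if (base$status != "optimal") abort("baseline model is not solvable")
  if (base$objective_value <= 0) abort("no growth to inhibit")
  if (is.null(baselines)) {
    baselines <- baseline_rates(model, targets, mode = mode,
                                n = n, seed = seed)
  }
  inh <- apply_inhibition(model, baselines, i)
  res <- fba_max(inh)
  if (res$status != "optimal") abort("inhibited model is not solvable")
  res$objective_value / base$objective_value
}

#' Inhibition-response curve of a drug target set
#'
#' Sweeps relative inhibition over `grid` (default 0 to 1 in steps of
#' 0.001, 1001 points) and records relative growth at each point. The
#' curve starts at 1, never increases, and is bounded below by
#' `1 - i`.
#'
#' @inheritParams relative_growth
#' @param grid Inhibition grid in `[0, 1]`.
#' @return A tibble of class `inhibition_response` with columns
#'   `inhibition`, `relative_growth`; attributes `baseline_growth` and
#'   `baseline_rates`.
#' @export
inhibition_sweep <- function(model, targets, grid = seq(0, 1, by = 0.001),
                             baselines = NULL,
                             mode = c("vertex_mean", "single_lp"),
                             n = 100, seed = 1) {
  targets <- target_ids(targets)
  if (length(targets) == 0L) abort("empty target set")
  base <- fba_max(model)
  if (base$status != "optimal") abort("baseline model is not solvable")
  if (base$objective_value <= 0) abort("no growth to inhibit")
  if (is.null(baselines)) {
    baselines <- baseline_rates(model, targets, mode = mode,
                                n = n, seed = seed)
  }
  rg <- map_dbl(grid, function(i) {
    res <- fba_max(apply_inhibition(model, baselines, i))
    if (res$status != "optimal") return(NA_real_)
    res$objective_value / base$objective_value
  })
  structure(tibble(inhibition = grid, relative_growth = rg),
            class = c("inhibition_response", class(tibble())),
            baseline_growth = base$objective_value,
            baseline_rates = baselines)
}

#' @rdname inhibition_sweep
#' @param object An `inhibition_response`.
#' @param ... Unused.
#' @export
autoplot.inhibition_response <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$inhibition,
                               y = .data$relative_growth)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "relative inhibition",
                  y = "relative growth",
                  caption = "dashed: no-compensation floor 1 - i") +
    ggplot2::ylim(0, 1)
}
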