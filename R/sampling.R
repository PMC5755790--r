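# Characterization of alternative optima. The optimum of an
# expression-constrained FBA problem is almost always degenerate: many
# flux distributions achieve the same maximal growth. The sampler
# fixes the objective at its optimum (within a small relative slack to
# survive solver tolerance) and maximizes independent random linear
# costs, each solve landing on a corner (vertex) of the optimal face.

#' Sample corners of the optimal face
#'
#' Runs FBA, constrains the objective flux to its optimal value (slack
#' `rel_tol` relative), then solves `n` linear programs with
#' independent random objective vectors (components uniform on
#' `[-1, 1]`, seeded). Each solution is a vertex of the (relaxed)
#' optimal face; their spread quantifies flux uncertainty.
#'
#' @param model A [metabolic_model()].
#' @param objective Reaction id whose optimum defines the face;
#'   defaults to the biomass reaction.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the sample set is reproducible.
#' @param rel_tol Relative slack on the optimum equality.
#' @return An object of class `optimal_face_sample`: list with
#'   `samples` (n x reactions matrix), `objective`, `optimum`, `n`,
#'   `seed`.
#' @export
sample_optimal_vertices <- function(model,
                                    objective = model$biomass_reaction_id,
                                    n = 100, seed = 1, rel_tol = 1e-6) {
  stopifnot(inherits(model, "metabolic_model"))
  if (n < 1) abort("n must be >= 1")
  base <- fba_max(model, objective)
  if (base$status != "optimal") {
    abort(paste0("base model not optimal (status: ", base$status, ")"))
  }
  p <- model_lp_parts(model)
  nr <- length(p$ids)
  j <- match(objective, p$ids)
  opt <- base$objective_value
  slack <- rel_tol * max(abs(opt), 1e-9)
  # keep objective at its optimum: -v_j <= -(opt - slack)
  eA <- matrix(0, 1, nr); eA[1, j] <- -1
  eb <- -(opt - slack)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  samples <- matrix(NA_real_, n, nr, dimnames = list(NULL, p$ids))
  for (k in seq_len(n)) {
    cost <- runif(nr, -1, 1)
    sol <- solve_lp(p$S, p$lb, p$ub, cost, extra_A = eA, extra_b = eb)
    if (sol$status != "optimal") {
      abort("optimal-face subproblem failed to solve")
    }
    samples[k, ] <- sol$v
  }
  structure(list(samples = samples, objective = objective,
                 optimum = opt, n = n, seed = seed),
            class = "optimal_face_sample")
}

#' @export
print.optimal_face_sample <- function(x, ...) {
  cat("<optimal_face_sample> ", x$n, " vertices, optimum ",
      format(x$optimum), " (", x$objective, ")\n", sep = "")
  invisible(x)
}

#' Per-reaction summary of an optimal-face sample
#'
#' Sample mean, standard deviation (n - 1 denominator), minimum and
#' maximum of each reaction's flux across the sampled vertices. A
#' single-sample input yields sd 0 with a warning.
#'
#' @param sample An [sample_optimal_vertices()] result.
#' @return A tibble `reaction`, `mean`, `sd`, `min`, `max`.
#' @export
flux_statistics <- function(sample) {
  stopifnot(inherits(sample, "optimal_face_sample"))
  if (sample$n == 0L) abort("empty sample")
  if (sample$n == 1L) warn("single sample: standard deviations are 0")
  s <- sample$samples
  tibble(
    reaction = colnames(s),
    mean = unname(colMeans(s)),
    sd = if (sample$n == 1L) rep(0, ncol(s))
         else unname(apply(s, 2, sd)),
    min = unname(apply(s, 2, min)),
    max = unname(apply(s, 2, max))
  )
}

#' @rdname flux_statistics
#' @param x An `optimal_face_sample`.
#' @param ... Unused.
#' @export
tidy.optimal_face_sample <- function(x, ...) flux_statistics(x)

#' @rdname flux_statistics
#' @export
glance.optimal_face_sample <- function(x, ...) {
  tibble(objective = x$objective, optimum = x$optimum, n = x$n,
         seed = x$seed)
}

#' Mean squared error of sampled fluxes against measured values
#'
#' For each measured reaction, the mean over sampled vertices of the
#' squared deviation between predicted and observed flux (units
#' flux^2), the figure of merit used to compare constraint-based
#' predictors against measured uptake/secretion rates.
#'
#' @param sample An [sample_optimal_vertices()] result.
#' @param observed Named numeric vector (or tibble `reaction`, `flux`)
#'   of measured fluxes.
#' @return A tibble `reaction`, `observed`, `predicted_mean`, `mse`.
#' @export
flux_mse <- function(sample, observed) {
  stopifnot(inherits(sample, "optimal_face_sample"))
  if (is.data.frame(observed)) {
    observed <- setNames(observed$flux, observed$reaction)
  }
  missing <- setdiff(names(observed), colnames(sample$samples))
  if (length(missing)) {
    abort(paste0("reaction not in prediction: ",
                 paste(missing, collapse = ", ")))
  }
  ids <- names(observed)
  pred <- unname(colMeans(sample$samples[, ids, drop = FALSE]))
  mse <- map_dbl(ids, function(r) {
    mean((sample$samples[, r] - observed[[r]])^2)
  })
  tibble(reaction = ids, observed = unname(observed),
         predicted_mean = pred, mse = mse)
}
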