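# Internal linear-programming layer.
#
# pracma::linprog solves min c'x with x >= 0; fluxes can be negative,
# so variables are shifted by their (finite) lower bounds. Infinite
# bounds are capped at BIG_BOUND; an optimum whose solution escapes to
# that scale on a capped variable is classified as unbounded (pracma's
# own error codes conflate unbounded with infeasible).
BIG_BOUND <- 1e6

# maximize obj'v subject to S v = 0, extra_A v <= extra_b, lb <= v <= ub
solve_lp <- function(S, lb, ub, obj, extra_A = NULL, extra_b = NULL) {
  n <- length(obj)
  capped <- !is.finite(lb) | !is.finite(ub)
  lb2 <- pmax(lb, -BIG_BOUND)
  ub2 <- pmin(ub, BIG_BOUND)
  if (any(lb2 > ub2)) {
    return(list(status = "infeasible", objective = NA_real_, v = NULL))
  }
  # shift x = v - lb2 so x >= 0
  A_ineq <- diag(n)
  b_ineq <- ub2 - lb2
  if (!is.null(extra_A)) {
    A_ineq <- rbind(A_ineq, extra_A)
    b_ineq <- c(b_ineq, extra_b - as.numeric(extra_A %*% lb2))
  }
  beq <- -as.numeric(S %*% lb2)
  # the underlying simplex randomizes pivot tie-breaks through the
  # global RNG; pin it locally so solves are deterministic and the
  # caller's RNG stream is untouched
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  )
  set.seed(104729L)
  res <- tryCatch(
    pracma::linprog(cc = obj, A = A_ineq, b = b_ineq,
                    Aeq = if (nrow(S)) S else NULL,
                    beq = if (nrow(S)) beq else NULL,
                    maxiter = max(200L, 40L * n), maximize = TRUE),
    error = function(e) NULL
  )
  if (is.null(res) || is.na(res$fval) || res$errno != 1) {
    return(list(status = "infeasible", objective = NA_real_, v = NULL))
  }
  v <- res$x + lb2
  if (any(capped & abs(v) > 0.5 * BIG_BOUND)) {
    return(list(status = "unbounded", objective = Inf, v = NULL))
  }
  list(status = "optimal", objective = sum(obj * v), v = v)
}

# assemble LP ingredients from a model
model_lp_parts <- function(model) {
  list(S = stoichiometric_matrix(model),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

#' Maximize a reaction flux by flux balance analysis
#'
#' Solves the linear program: maximize the flux of
#' `objective` subject to steady state (`S v = 0` over internal
#' metabolites) and the box constraints of the model. This is standard
#' FBA with the biomass reaction as default objective, so the optimal
#' value is the predicted maximal growth rate.
#'
#' @param model A [metabolic_model()].
#' @param objective Reaction id to maximize; defaults to the model's
#'   biomass reaction.
#' @return An object of class `fba_result`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`), `objective_value`,
#'   `objective` (the reaction id) and `fluxes` (tibble `reaction`,
#'   `flux`; `NULL` unless optimal).
#' @export
#' @examples
#' m <- toy_chain_model()
#' fba_max(m)$objective_value  # 0.027
fba_max <- function(model, objective = model$biomass_reaction_id) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!objective %in% model$reactions$id) {
    abort(paste0("objective reaction '", objective, "' not in model"))
  }
  p <- model_lp_parts(model)
  obj <- as.numeric(p$ids == objective)
  sol <- solve_lp(p$S, p$lb, p$ub, obj)
  fluxes <- NULL
  if (sol$status == "optimal") {
    fluxes <- tibble(reaction = p$ids, flux = sol$v)
  }
  structure(list(status = sol$status,
                 objective = objective,
                 objective_value = if (sol$status == "optimal")
                   sol$objective else sol$objective,
                 fluxes = fluxes),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  max ", x$objective, " = ", format(x$objective_value), "\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname fba_max
#' @param x An `fba_result`.
#' @param ... Unused.
#' @export
tidy.fba_result <- function(x, ...) {
  if (is.null(x$fluxes)) return(tibble(reaction = character(),
                                       flux = numeric()))
  x$fluxes
}

#' @rdname fba_max
#' @export
glance.fba_result <- function(x, ...) {
  tibble(status = x$status, objective = x$objective,
         objective_value = x$objective_value)
}
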