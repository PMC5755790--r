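#' Construct a genome-scale metabolic model
#'
#' A `metabolic_model` bundles the metabolite and reaction tables of a
#' constraint-based metabolic network together with the identity of the
#' biomass (growth) pseudo-reaction and the set of exchange reactions.
#' The steady-state assumption constrains feasible flux vectors `v` to
#' `S v = 0` over the internal (non-boundary) metabolites, with each flux
#' boxed between its lower and upper bound (mmol per gram dry weight per
#' hour).
#'
#' @param metabolites A data frame with columns `id`, and optionally
#'   `name`, `compartment`, `kegg_id` and `boundary` (logical; boundary
#'   metabolites are excluded from the steady-state constraint).
#' @param reactions A data frame with columns `id`, `stoichiometry`
#'   (a list column of named numeric vectors, negative = consumed,
#'   positive = produced), and optionally `name`, `reversible`,
#'   `lower_bound`, `upper_bound` and `genes` (a list column of character
#'   vectors; any one listed gene suffices to catalyse the reaction).
#' @param biomass Reaction id of the biomass objective. If `NULL`, the
#'   first reaction whose id or name matches `biomass_pattern`
#'   (case-insensitive) is used; more than one match is an error.
#' @param biomass_pattern Regular expression used to resolve the biomass
#'   reaction when `biomass` is not given.
#' @param default_bound Magnitude used to fill missing bounds: reversible
#'   reactions get `(-default_bound, default_bound)`, irreversible
#'   `(0, default_bound)`.
#'
#' @return An object of class `metabolic_model`: a list with elements
#'   `metabolites` (tibble), `reactions` (tibble), `biomass_reaction_id`
#'   and `exchange_reaction_ids`.
#' @export
#' @examples
#' mets <- tibble::tibble(id = c("A", "B"))
#' rxns <- tibble::tibble(
#'   id = c("R_up", "R_conv", "R_bio"),
#'   stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
#'   upper_bound = c(0.081, 0.027, 0.135)
#' )
#' m <- metabolic_model(mets, rxns, biomass = "R_bio")
#' stoichiometric_matrix(m)
metabolic_model <- function(metabolites, reactions, biomass = NULL,
                            biomass_pattern = "biomass",
                            default_bound = 1000) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (!"id" %in% names(metabolites) || !"id" %in% names(reactions)) {
    abort("both `metabolites` and `reactions` need an `id` column")
  }
  if (anyDuplicated(metabolites$id)) {
    abort(paste0("duplicate metabolite id: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]),
                       collapse = ", ")))
  }
  if (anyDuplicated(reactions$id)) {
    abort(paste0("duplicate reaction id: ",
                 paste(unique(reactions$id[duplicated(reactions$id)]),
                       collapse = ", ")))
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"kegg_id" %in% names(metabolites)) metabolites$kegg_id <- NA_character_
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE

  if (!"stoichiometry" %in% names(reactions)) {
    abort("`reactions` needs a `stoichiometry` list column")
  }
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"reversible" %in% names(reactions)) reactions$reversible <- FALSE
  if (!"genes" %in% names(reactions)) {
    reactions$genes <- rep(list(character(0)), nrow(reactions))
  }
  if (!"lower_bound" %in% names(reactions)) {
    reactions$lower_bound <- NA_real_
  }
  if (!"upper_bound" %in% names(reactions)) {
    reactions$upper_bound <- NA_real_
  }
  reactions$upper_bound <- ifelse(is.na(reactions$upper_bound),
                                  default_bound, reactions$upper_bound)
  reactions$lower_bound <- ifelse(
    is.na(reactions$lower_bound),
    ifelse(reactions$reversible, -default_bound, 0),
    reactions$lower_bound
  )

  bad <- !map_lgl(reactions$stoichiometry, ~ length(.x) > 0 &&
                    !is.null(names(.x)))
  if (any(bad)) {
    abort(paste0("empty or unnamed stoichiometry in reaction: ",
                 paste(reactions$id[bad], collapse = ", ")))
  }
  unknown <- setdiff(unique(unlist(map(reactions$stoichiometry, names))),
                     metabolites$id)
  if (length(unknown)) {
    abort(paste0("stoichiometry references unknown metabolite: ",
                 paste(unknown, collapse = ", ")))
  }

  if (is.null(biomass)) {
    hit <- grepl(biomass_pattern, reactions$id, ignore.case = TRUE) |
      grepl(biomass_pattern, reactions$name, ignore.case = TRUE)
    if (sum(hit) == 0L) {
      abort(paste0("no biomass reaction matches pattern '",
                   biomass_pattern, "'"))
    }
    if (sum(hit) > 1L) {
      abort(paste0("ambiguous biomass reaction, candidates: ",
                   paste(reactions$id[hit], collapse = ", ")))
    }
    biomass <- reactions$id[hit]
  }
  if (!biomass %in% reactions$id) {
    abort(paste0("biomass reaction '", biomass, "' not in model"))
  }

  boundary_ids <- metabolites$id[metabolites$boundary]
  n_internal <- map_int(reactions$stoichiometry, function(s) {
    sum(!names(s) %in% boundary_ids)
  })
  exchange_ids <- reactions$id[n_internal == 1L & reactions$id != biomass]

  structure(
    list(metabolites = metabolites,
         reactions = reactions,
         biomass_reaction_id = biomass,
         exchange_reaction_ids = exchange_ids),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  biomass:  ", x$biomass_reaction_id, "\n", sep = "")
  cat("  exchange: ", length(x$exchange_reaction_ids), " reactions\n",
      sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' Returns the internal-metabolite-by-reaction matrix `S` of signed
#' stoichiometric coefficients (negative = consumed, positive =
#' produced). Boundary metabolites are not mass balanced and are
#' excluded as rows, so exchange reactions appear as columns with a
#' single nonzero entry.
#'
#' @param model A [metabolic_model()].
#' @return A dense numeric matrix with metabolite ids as row names and
#'   reaction ids as column names.
#' @export
stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  internal <- model$metabolites$id[!model$metabolites$boundary]
  S <- matrix(0, nrow = length(internal), ncol = nrow(model$reactions),
              dimnames = list(internal, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[j]]
    keep <- names(s) %in% internal
    if (any(keep)) S[names(s)[keep], j] <- s[keep]
  }
  S
}

#' Diagnose structural problems in a model
#'
#' Pure check: reports orphan metabolites (appearing in no reaction),
#' reactions without gene association, and bound inversions
#' (`lower_bound > upper_bound`). The model is never modified.
#'
#' @param model A [metabolic_model()].
#' @return A tibble with columns `type`, `id` and `message`; zero rows
#'   for a clean model.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  used <- unique(unlist(map(model$reactions$stoichiometry, names)))
  orphans <- setdiff(model$metabolites$id, used)
  inv <- model$reactions$id[model$reactions$lower_bound >
                              model$reactions$upper_bound]
  irrev_neg <- model$reactions$id[!model$reactions$reversible &
                                    model$reactions$lower_bound < 0]
  no_gene <- model$reactions$id[map_int(model$reactions$genes, length) == 0L]
  no_gene <- setdiff(no_gene,
                     c(model$biomass_reaction_id, model$exchange_reaction_ids))
  bind_rows(
    tibble(type = "orphan_metabolite", id = orphans,
           message = "metabolite appears in no reaction"),
    tibble(type = "bound_inversion", id = inv,
           message = "lower_bound exceeds upper_bound"),
    tibble(type = "negative_irreversible_bound", id = irrev_neg,
           message = "irreversible reaction with negative lower bound"),
    tibble(type = "no_gene_association", id = no_gene,
           message = "internal reaction without gene association")
  )
}

#' Export a compact JSON summary of a model
#'
#' Writes counts, the biomass reaction, exchange reactions, and the
#' per-reaction bounds/gene table, for downstream tooling and quick
#' inspection of constrained models.
#'
#' @param model A [metabolic_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  summary <- list(
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    biomass_reaction = model$biomass_reaction_id,
    exchange_reactions = model$exchange_reaction_ids,
    reactions = model$reactions |>
      mutate(genes = map(.data$genes, identity)) |>
      select("id", "reversible", "lower_bound", "upper_bound", "genes")
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# internal: replace bounds for a set of reactions, returning a copy
set_bounds <- function(model, ids, lower = NULL, upper = NULL) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    abort(paste0("unknown reaction id: ",
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  if (!is.null(lower)) model$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[idx] <- upper
  model
}
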