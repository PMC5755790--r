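# Synthetic desk-scale fixtures: toy metabolic networks with parallel
# pathways of unequal stoichiometric efficiency, expression profiles
# with a planted therapeutic window (a transporter expressed in healthy
# profiles but silent in cancer profiles), and a toy compound library
# with known analog pairs and EC annotations. Plus an exhaustive
# vertex-enumeration oracle used to validate the LP path.

#' Specification of a synthetic toy network
#'
#' Describes a network with one nutrient uptake, `n_pathways` parallel
#' conversion routes of unequal stoichiometric efficiency, an optional
#' direct transporter route for the product, and a biomass sink:
#'
#' \preformatted{ EX_A: -> A          (gene g_up)
#'   P_k:  e_k A -> C     (gene g_p<k>), e_k = pathway_efficiencies[k]
#'   EX_C: -> C           (gene g_tr, the plantable transporter)
#'   EX_D: -> D           (gene g_hk, housekeeping co-substrate)
#'   BIO:  C + D ->       (biomass, no gene)}
#'
#' Larger `e_k` means a less efficient route (more nutrient per unit
#' product). The transporter route is present in the network whenever
#' `transporter_bound` is not `NA`; profiles decide whether it carries
#' flux.
#'
#' @param n_pathways Number of parallel conversion routes (>= 1).
#' @param pathway_efficiencies Units of A consumed per unit of C, one
#'   per pathway.
#' @param pathway_bounds Upper bounds of the pathway reactions.
#' @param uptake_bound Upper bound of nutrient uptake `EX_A`.
#' @param transporter_bound Upper bound of the direct product uptake
#'   `EX_C`; `NA` omits the reaction entirely.
#' @param cosubstrate_bound Upper bound of `EX_D`; `NA` omits `EX_D`
#'   and drops D from the biomass reaction.
#' @param kegg_ids Named KEGG-style accessions for metabolites A, C, D
#'   (used by drug-target mapping fixtures).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pathways = 2,
                         pathway_efficiencies = c(1, 2),
                         pathway_bounds = c(0.05, 1000),
                         uptake_bound = 0.1,
                         transporter_bound = NA_real_,
                         cosubstrate_bound = NA_real_,
                         kegg_ids = c(A = "C90001", C = "C90003",
                                      D = "C90004")) {
  if (n_pathways < 1) abort("fixture needs at least one pathway")
  stopifnot(length(pathway_efficiencies) == n_pathways,
            length(pathway_bounds) == n_pathways,
            all(pathway_efficiencies > 0))
  structure(list(n_pathways = n_pathways,
                 pathway_efficiencies = pathway_efficiencies,
                 pathway_bounds = pathway_bounds,
                 uptake_bound = uptake_bound,
                 transporter_bound = transporter_bound,
                 cosubstrate_bound = cosubstrate_bound,
                 kegg_ids = kegg_ids),
            class = "fixture_spec")
}

#' Build the toy metabolic model described by a fixture spec
#'
#' @param spec A [fixture_spec()].
#' @return A [metabolic_model()] whose bounds are those stated in the
#'   spec (use [apply_expression_constraints()] to drive them from a
#'   profile instead).
#' @export
#' @examples
#' m <- make_toy_model(fixture_spec())
#' fba_max(m)$objective_value  # 0.075
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  has_tr <- !is.na(spec$transporter_bound)
  has_d <- !is.na(spec$cosubstrate_bound)
  met_ids <- c("A", "C", if (has_d) "D")
  mets <- tibble(id = met_ids,
                 kegg_id = unname(spec$kegg_ids[met_ids]))
  bio_stoich <- c(C = -1, if (has_d) c(D = -1))
  rxns <- bind_rows(
    tibble(id = "EX_A", stoichiometry = list(c(A = 1)),
           upper_bound = spec$uptake_bound, genes = list("g_up")),
    tibble(id = paste0("P", seq_len(spec$n_pathways)),
           stoichiometry = map(seq_len(spec$n_pathways), function(k) {
             c(A = -spec$pathway_efficiencies[k], C = 1)
           }),
           upper_bound = spec$pathway_bounds,
           genes = map(seq_len(spec$n_pathways), ~ paste0("g_p", .x))),
    if (has_tr)
      tibble(id = "EX_C", stoichiometry = list(c(C = 1)),
             upper_bound = spec$transporter_bound, genes = list("g_tr")),
    if (has_d)
      tibble(id = "EX_D", stoichiometry = list(c(D = 1)),
             upper_bound = spec$cosubstrate_bound, genes = list("g_hk")),
    tibble(id = "BIO", stoichiometry = list(bio_stoich),
           upper_bound = 1000, genes = list(character(0)))
  )
  rxns$reversible <- FALSE
  rxns$lower_bound <- 0
  metabolic_model(mets, rxns, biomass = "BIO")
}

#' Three-reaction linear chain fixture
#'
#' `R1: -> A` (ub 0.081), `R2: A -> B` (ub 0.027), `R3: B ->`
#' (biomass, ub 0.135). The unique optimum is 0.027 and there is no
#' alternative route, so inhibiting `R2` by a fraction `i` scales
#' growth by exactly `1 - i`.
#'
#' @return A [metabolic_model()].
#' @export
toy_chain_model <- function() {
  mets <- tibble(id = c("A", "B"), kegg_id = c("C90001", "C90002"))
  rxns <- tibble(
    id = c("R1", "R2", "R3"),
    stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    reversible = FALSE,
    lower_bound = 0,
    upper_bound = c(0.081, 0.027, 0.135),
    genes = list("g_up", "g_conv", character(0))
  )
  metabolic_model(mets, rxns, biomass = "R3")
}

#' Parallel-pathway fixture with an inefficient backup route
#'
#' Nutrient uptake 0.1; efficient route `P1: A -> C` capped at 0.05;
#' backup route `P2: 2A -> C` effectively uncapped. The optimum is
#' 0.075; inhibiting `P1` by 0.9 leaves 0.0525, i.e. relative growth
#' 0.70 — partial compensation through the less efficient pathway.
#'
#' @return A [metabolic_model()].
#' @export
toy_parallel_model <- function() {
  make_toy_model(fixture_spec())
}

#' Generate expression profiles with a planted therapeutic window
#'
#' Cancer-labeled profiles silence the transporter gene `g_tr`
#' (0 RPKM), making growth depend on the synthesis pathways; healthy
#' profiles express it at `transporter_rpkm`. All other genes are
#' jittered around `base_levels` with seeded Gaussian noise truncated
#' at zero, emulating biological and technical variability between
#' replicate transcriptomes.
#'
#' @param base_levels Named RPKM vector for all genes except the
#'   transporter.
#' @param n_cancer,n_healthy Number of profiles per group (>= 2 each
#'   for downstream group tests).
#' @param transporter_rpkm RPKM of `g_tr` in healthy profiles.
#' @param noise_sd Standard deviation of the RPKM jitter (>= 0).
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A list of [expression_profile()]s, cancer first.
#' @export
make_profiles <- function(base_levels = c(g_up = 40, g_p1 = 10,
                                          g_p2 = 10, g_hk = 10),
                          n_cancer = 4, n_healthy = 4,
                          transporter_rpkm = 20, noise_sd = 2,
                          seed = 1) {
  if (noise_sd < 0) abort("negative noise_sd")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  one <- function(label, group, transporter) {
    vals <- base_levels + rnorm(length(base_levels), 0, noise_sd)
    vals[vals < 0] <- 0
    vals <- c(vals, g_tr = transporter)
    expression_profile(vals, label = label, group = group)
  }
  c(
    map(seq_len(n_cancer),
        ~ one(paste0("cancer_", .x), "cancer", 0)),
    map(seq_len(n_healthy),
        ~ one(paste0("healthy_", .x), "healthy", transporter_rpkm))
  )
}

#' Toy compound library with planted analog pairs
#'
#' A small SMILES set designed around the shipped substructure-key
#' patterns: homolog pairs (same functional groups, different chain
#' length) score 1.0 and are genuine analogs; chemically unrelated
#' pairs score low; one drug is the same molecule as a metabolite
#' written in a different SMILES order, to exercise the
#' identical-structure exclusion. Metabolite ids double as the
#' KEGG-style accessions carried by the toy models, and EC annotations
#' plant known shared and unshared targets.
#'
#' @return A tibble with columns `id`, `role`, `smiles`, `ecs`
#'   (list column of EC strings; empty = unannotated).
#' @export
make_compound_library <- function() {
  tibble(
    id = c("C90001", "C90003", "C90004",
           "drug_syn", "drug_hk", "drug_far", "drug_same", "drug_noec"),
    role = c(rep("metabolite", 3), rep("drug", 5)),
    smiles = c(
      "CCCCCCCC(=O)O",    # metabolite A: octanoic acid
      "OCC(O)CO",         # metabolite C: glycerol (distinct scaffold)
      "CCCCCO",           # metabolite D: pentanol
      "CCCCCCCCC(=O)O",   # analog of the fatty-acid metabolites
      "CCCCCCO",          # analog of D (hexanol)
      "c1ccncc1",         # pyridine: unrelated scaffold
      "OC(=O)CCCCCCC",    # octanoic acid again, reordered SMILES
      "CCCCCCCO"          # heptanol analog, no EC annotation
    ),
    ecs = list(
      c("1.1.1.1", "2.7.1.1"),  # A
      c("1.1.1.1"),             # C
      c("3.1.1.3"),             # D
      c("1.1.1.1"),             # drug_syn shares 1.1.1.1 with A and C
      c("3.1.1.3"),             # drug_hk shares with D
      c("4.2.1.1"),             # drug_far: no shared target
      c("2.7.1.1"),             # drug_same (excluded as identical)
      character(0)              # unannotated
    )
  )
}

#' Enumerate all vertices of a model's flux polytope
#'
#' Independent brute-force oracle: enumerates every basic feasible
#' solution of `{S v = 0, lb <= v <= ub}` by fixing each choice of
#' non-basic reactions at a bound and solving the remaining square
#' system, then reports the exact optimum of `objective` and all
#' optimal vertices. Exponential in model size, hence guarded to small
#' models; never calls the package's LP solver.
#'
#' @param model A [metabolic_model()] with at most `max_reactions`
#'   reactions and finite bounds.
#' @param objective Reaction id to maximize.
#' @param max_reactions Safety guard (default 10).
#' @param tol Feasibility tolerance.
#' @return A list with `vertices` (matrix, one row per vertex, reaction
#'   ids as columns), `optimum` (max objective flux; `-Inf` when
#'   infeasible) and `optimal_vertices` (subset matrix of vertices
#'   attaining the optimum within `tol`).
#' @export
brute_force_lp <- function(model, objective = model$biomass_reaction_id,
                           max_reactions = 10, tol = 1e-8) {
  stopifnot(inherits(model, "metabolic_model"))
  n <- nrow(model$reactions)
  if (n > max_reactions) abort("model too large for exhaustive enumeration")
  p <- model_lp_parts(model)
  if (any(!is.finite(p$lb)) || any(!is.finite(p$ub))) {
    abort("vertex enumeration needs finite bounds")
  }
  S <- p$S
  r <- if (nrow(S)) qr(S)$rank else 0L
  # independent rows of S
  Si <- if (r > 0) S[qr(t(S))$pivot[seq_len(r)], , drop = FALSE]
        else matrix(0, 0, n)
  verts <- list()
  basis_sets <- if (r > 0) utils::combn(n, r, simplify = FALSE) else list(integer(0))
  for (B in basis_sets) {
    SB <- Si[, B, drop = FALSE]
    if (r > 0 && abs(det(SB)) < 1e-12) next
    N <- setdiff(seq_len(n), B)
    k <- length(N)
    for (mask in seq_len(max(1L, 2L^k)) - 1L) {
      at_ub <- as.logical(bitwAnd(mask, 2L^(seq_len(k) - 1L)) > 0)
      if (k == 0L && mask > 0L) break
      vN <- ifelse(at_ub, p$ub[N], p$lb[N])
      v <- numeric(n)
      v[N] <- vN
      if (r > 0) {
        rhs <- if (k > 0) -Si[, N, drop = FALSE] %*% vN else rep(0, r)
        v[B] <- solve(SB, rhs)
      }
      if (any(v < p$lb - tol) || any(v > p$ub + tol)) next
      if (nrow(S) && max(abs(S %*% v)) > tol) next
      verts[[length(verts) + 1L]] <- v
    }
  }
  if (length(verts) == 0L) {
    return(list(vertices = matrix(numeric(0), 0, n,
                                  dimnames = list(NULL, p$ids)),
                optimum = -Inf,
                optimal_vertices = matrix(numeric(0), 0, n,
                                          dimnames = list(NULL, p$ids))))
  }
  V <- do.call(rbind, verts)
  colnames(V) <- p$ids
  V <- V[!duplicated(round(V, 9)), , drop = FALSE]
  j <- match(objective, p$ids)
  opt <- max(V[, j])
  list(vertices = V, optimum = opt,
       optimal_vertices = V[V[, j] >= opt - tol, , drop = FALSE])
}
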