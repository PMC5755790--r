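# Compound fingerprints, Tanimoto analog pairing and shared-target
# enrichment. Fingerprints are substructure keys: a fixed, versioned
# table of SMARTS patterns shipped with the package (FP4-style
# functional-group keys); bit i is set when pattern i matches the
# structure at least once. Matching goes through OpenBabel
# (ChemmineOB), but the pattern set is pinned here so scores cannot
# drift with toolkit releases.

#' The pinned substructure-key pattern set
#'
#' @param path Path to a two-column TSV (`key`, `smarts`); defaults to
#'   the table shipped with the package.
#' @return A tibble with columns `key` and `smarts`; row order defines
#'   the bit index of each key.
#' @export
fp_patterns <- function(path = system.file("extdata",
                                           "substructure_keys.tsv",
                                           package = "fluxwindow")) {
  readr::read_tsv(path, col_types = "cc")
}

#' Read a compound library from a delimited file
#'
#' Expects columns `id`, `role` (`drug` or `metabolite`), `smiles` and
#' `ecs` (semicolon-separated EC numbers, empty = no target reported).
#'
#' @param path TSV or CSV file path (delimiter auto-detected).
#' @return A tibble with `ecs` as a list column.
#' @export
read_compound_library <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read library: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("id", "role", "smiles")
  if (!all(need %in% names(tbl))) {
    abort("compound library needs columns: id, role, smiles[, ecs]")
  }
  if (!"ecs" %in% names(tbl)) tbl$ecs <- ""
  tbl$ecs <- map(tbl$ecs, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, ";")[[1]])
  })
  as_tibble(tbl[, c("id", "role", "smiles", "ecs")])
}

# parse one SMILES into an SDFset, naming the offending record on error
smiles_to_sdf <- function(smiles, id) {
  out <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, id))),
    error = function(e) NULL
  )
  if (is.null(out)) {
    abort(paste0("cannot parse structure for record '", id, "': ", smiles))
  }
  out
}

#' Fingerprint the compounds of a library
#'
#' Adds two columns to a compound table: `fingerprint` (integer
#' indices of the matching substructure keys; possibly empty) and
#' `canonical_smiles` (OpenBabel canonical form, used by the
#' identical-structure exclusion). Deterministic given the pattern
#' table.
#'
#' @param compounds A tibble with columns `id` and `smiles`.
#' @param patterns A pattern table from [fp_patterns()].
#' @return The input with `fingerprint` and `canonical_smiles` added.
#' @export
fingerprint_compounds <- function(compounds, patterns = fp_patterns()) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  # parse individually first so failures name the offending record,
  # then build one SDFset for vectorized SMARTS matching
  invisible(map2(compounds$smiles, compounds$id, smiles_to_sdf))
  sdfset <- suppressWarnings(
    ChemmineR::smiles2sdf(setNames(compounds$smiles, compounds$id)))
  hits <- matrix(FALSE, nrow = nrow(compounds), ncol = nrow(patterns))
  for (k in seq_len(nrow(patterns))) {
    cnt <- ChemmineR::smartsSearchOB(sdfset, patterns$smarts[[k]],
                                     uniqueMatches = FALSE)
    hits[, k] <- cnt > 0
  }
  compounds$fingerprint <- map(seq_len(nrow(compounds)),
                               ~ which(hits[.x, ]))
  compounds$canonical_smiles <- map_chr(compounds$smiles, function(s) {
    trimws(ChemmineOB::convertFormat("SMI", "CAN", s))
  })
  compounds
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over substructure-key index sets.
#' Undefined (an error) when both sets are empty: no keys match either
#' structure, so similarity carries no information and a silent 0 or 1
#' would pollute analog pairing.
#'
#' @param a,b Integer vectors of key indices.
#' @return A number in `[0, 1]`; 1 iff the sets are equal.
#' @export
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))  # 0.5
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    abort("undefined similarity: both fingerprints are empty")
  }
  length(intersect(a, b)) / length(union(a, b))
}

# normalize an EC string to 4 dash-padded fields
ec_normalize <- function(ec) {
  parts <- strsplit(trimws(ec), ".", fixed = TRUE)[[1]]
  parts <- c(parts, rep("-", 4L))[1:4]
  parts[!nzchar(parts)] <- "-"
  parts
}

# TRUE if two EC strings match field-wise, "-" matching anything
ec_match <- function(x, y) {
  px <- ec_normalize(x); py <- ec_normalize(y)
  all(px == py | px == "-" | py == "-")
}

# number of ECs of `a` matching at least one EC of `b`
shared_ec_count <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(NA_integer_)
  sum(map_lgl(unique(a), function(x) any(map_lgl(b, ~ ec_match(x, .x)))))
}

#' Extract drug-metabolite analog pairs by Tanimoto score
#'
#' All drug x metabolite pairs with Tanimoto strictly above
#' `threshold`, excluding the trivial pairs whose canonical structures
#' are identical (a drug that *is* the metabolite cannot act as its
#' competitive analog). When both tables carry `ecs` annotations, the
#' number of shared enzyme targets is attached (`NA` when either side
#' reports no target).
#'
#' @param drugs,metabolites Fingerprinted compound tables
#'   ([fingerprint_compounds()]).
#' @param threshold Pairing threshold; strict inequality. Default 0.9.
#' @return A tibble `drug_id`, `metabolite_id`, `tanimoto`,
#'   `shared_targets`, sorted by descending score.
#' @export
find_analog_pairs <- function(drugs, metabolites, threshold = 0.9) {
  if (nrow(drugs) == 0L || nrow(metabolites) == 0L) {
    return(tibble(drug_id = character(), metabolite_id = character(),
                  tanimoto = numeric(), shared_targets = integer()))
  }
  stopifnot("fingerprint" %in% names(drugs),
            "fingerprint" %in% names(metabolites))
  has_ec <- "ecs" %in% names(drugs) && "ecs" %in% names(metabolites)
  grid <- tidyr::expand_grid(di = seq_len(nrow(drugs)),
                             mi = seq_len(nrow(metabolites)))
  res <- grid |>
    mutate(
      drug_id = drugs$id[.data$di],
      metabolite_id = metabolites$id[.data$mi],
      tanimoto = map2_dbl_safe(drugs$fingerprint[.data$di],
                               metabolites$fingerprint[.data$mi]),
      identical_structure =
        drugs$canonical_smiles[.data$di] ==
        metabolites$canonical_smiles[.data$mi]
    ) |>
    filter(.data$tanimoto > threshold, !.data$identical_structure)
  res$shared_targets <- if (has_ec) {
    map2(drugs$ecs[res$di], metabolites$ecs[res$mi], shared_ec_count) |>
      unlist() %||% integer(0)
  } else NA_integer_
  res |>
    arrange(desc(.data$tanimoto), .data$drug_id, .data$metabolite_id) |>
    select("drug_id", "metabolite_id", "tanimoto", "shared_targets")
}

# vectorized tanimoto over two lists; empty-vs-empty pairs score NA
# here (they can never exceed a positive threshold) instead of erroring
map2_dbl_safe <- function(fa, fb) {
  map2(fa, fb, function(a, b) {
    if (length(a) == 0L && length(b) == 0L) return(NA_real_)
    tanimoto(a, b)
  }) |> unlist()
}

#' Shared-target summary of a set of analog pairs
#'
#' Restricts to pairs where both the drug and the metabolite report at
#' least one enzyme target; unannotated pairs are excluded from the
#' denominator, not counted as non-sharing. The histogram bins shared
#' counts as 1, 2, 3 and "more".
#'
#' @param pairs Output of [find_analog_pairs()] (needs
#'   `shared_targets`).
#' @return A list with `n_pairs`, `n_annotated`, `n_shared`,
#'   `fraction` and `histogram` (tibble `bin`, `count`, `percent`).
#' @export
shared_target_stats <- function(pairs) {
  ann <- pairs[!is.na(pairs$shared_targets), ]
  shared <- ann$shared_targets[ann$shared_targets > 0L]
  hist <- tibble(
    bin = c("1", "2", "3", "more"),
    count = c(sum(shared == 1L), sum(shared == 2L), sum(shared == 3L),
              sum(shared > 3L))
  )
  hist$percent <- if (length(shared)) 100 * hist$count / length(shared)
                  else 0
  list(n_pairs = nrow(pairs),
       n_annotated = nrow(ann),
       n_shared = length(shared),
       fraction = if (nrow(ann)) length(shared) / nrow(ann) else NA_real_,
       histogram = hist)
}

#' Bootstrap null distribution of the shared-target fraction
#'
#' Draws `n_pairs` uniform random drug-metabolite pairs (with
#' replacement, no similarity restriction) and records the fraction of
#' annotated pairs sharing at least one target; repeated `reps` times.
#' This is the null against which the analog-pair sharing fraction is
#' compared.
#'
#' @param drugs,metabolites Compound tables with `ecs` list columns.
#' @param n_pairs Pairs per replicate (default 4000).
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed; same seed, same output.
#' @return Numeric vector of `reps` shared fractions in `[0, 1]`.
#' @export
bootstrap_null <- function(drugs, metabolites, n_pairs = 4000,
                           reps = 1000, seed = 1) {
  if (n_pairs < 1 || reps < 1) abort("n_pairs and reps must be >= 1")
  stopifnot("ecs" %in% names(drugs), "ecs" %in% names(metabolites))
  nd <- nrow(drugs); nm <- nrow(metabolites)
  share <- matrix(NA_integer_, nd, nm)
  for (i in seq_len(nd)) {
    for (j in seq_len(nm)) {
      share[i, j] <- shared_ec_count(drugs$ecs[[i]], metabolites$ecs[[j]])
    }
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(reps), function(r) {
    di <- sample.int(nd, n_pairs, replace = TRUE)
    mi <- sample.int(nm, n_pairs, replace = TRUE)
    s <- share[cbind(di, mi)]
    ann <- !is.na(s)
    if (!any(ann)) return(NA_real_)
    mean(s[ann] > 0L)
  }, numeric(1))
}

#' Fisher exact test of shared-target enrichment
#'
#' Two-by-two table `[[a, b], [c, d]]` = shared / not shared (rows
#' analog / random). Reports both the sample odds ratio `ad / bc` and
#' the conditional maximum-likelihood odds ratio, with the exact
#' two-sided p-value from the hypergeometric distribution.
#'
#' @param a,b Shared / not-shared counts among analog pairs.
#' @param c,d Shared / not-shared counts among random pairs.
#' @return An object of class `enrichment_result`.
#' @export
#' @examples
#' fisher_enrichment(644, 2173, 40, 3960)
fisher_enrichment <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) abort("negative count")
  tab <- matrix(c(a, c, b, d), nrow = 2,
                dimnames = list(pairing = c("analog", "random"),
                                target = c("shared", "not_shared")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: a row or column margin is zero")
  }
  ft <- fisher.test(tab)
  sample_or <- if (b * c > 0) (a * d) / (b * c)
               else if (a * d > 0) Inf else NaN
  structure(list(table = tab,
                 odds_ratio = unname(ft$estimate),
                 sample_odds_ratio = sample_or,
                 p_value = ft$p.value,
                 conf_int = unname(ft$conf.int)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$table)
  cat("sample OR: ", format(x$sample_odds_ratio, digits = 4),
      "   conditional MLE OR: ", format(x$odds_ratio, digits = 4),
      "   p: ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fisher_enrichment
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(estimate = x$odds_ratio,
         sample_odds_ratio = x$sample_odds_ratio,
         p.value = x$p_value,
         conf.low = x$conf_int[1],
         conf.high = x$conf_int[2])
}

#' @rdname fisher_enrichment
#' @export
glance.enrichment_result <- function(x, ...) tidy(x)
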