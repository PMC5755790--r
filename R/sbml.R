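#' Read a genome-scale metabolic model from SBML
#'
#' Parses SBML Level 3 with the `fbc` package (flux bounds as global
#' parameters referenced from `fbc:lowerFluxBound` /
#' `fbc:upperFluxBound`, gene associations as
#' `fbc:geneProductAssociation`). SBML Level 2 files are tolerated:
#' bounds are taken from `LOWER_BOUND` / `UPPER_BOUND` kinetic-law
#' parameters and gene associations from `GENE_ASSOCIATION:` notes.
#' Gene association logic is flattened to the plain set of genes; the
#' bound-setting rule only ever uses the most abundant associated
#' enzyme, so AND/OR structure is deliberately not retained.
#'
#' Reactions missing bound information receive
#' `(-default_bound, default_bound)` when reversible and
#' `(0, default_bound)` otherwise. KEGG compound accessions are read
#' from `identifiers.org/kegg.compound` resource annotations on
#' species.
#'
#' @param path Path to an SBML file.
#' @param biomass Explicit biomass reaction id; wins over pattern
#'   matching.
#' @param biomass_pattern Case-insensitive pattern used to resolve the
#'   biomass reaction when `biomass` is `NULL`.
#' @param default_bound Fill-in bound magnitude for reactions without
#'   bound attributes.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path, biomass = NULL,
                            biomass_pattern = "biomass",
                            default_bound = 1000) {
  if (!file.exists(path)) abort(paste0("cannot read SBML file: ", path))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) abort("no species found in SBML file")
  kegg_of <- function(node) {
    res <- xml2::xml_find_all(node, ".//*[@*[local-name()='resource']]")
    urls <- c(xml2::xml_attr(res, "resource"),
              xml2::xml_attr(res, "rdf:resource"))
    hit <- grep("kegg.compound[:/]", urls, value = TRUE)
    if (length(hit)) sub(".*kegg.compound[:/]", "", hit[[1]]) else NA_character_
  }
  metabolites <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    kegg_id = map_chr(sp_nodes, kegg_of),
    boundary = dplyr::coalesce(
      xml2::xml_attr(sp_nodes, "boundaryCondition"), "false") == "true"
  )
  if (anyDuplicated(metabolites$id)) {
    abort(paste0("duplicate species id: ",
                 paste(unique(metabolites$id[duplicated(metabolites$id)]),
                       collapse = ", ")))
  }

  # fbc flux-bound parameters (L3)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0L) abort("no reactions found in SBML file")
  rx_ids <- xml2::xml_attr(rx_nodes, "id")
  if (anyDuplicated(rx_ids)) {
    abort(paste0("duplicate reaction id: ",
                 paste(unique(rx_ids[duplicated(rx_ids)]), collapse = ", ")))
  }

  parse_reaction <- function(node) {
    side <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp)
      if (length(refs) == 0L) return(numeric(0))
      coef <- as.numeric(dplyr::coalesce(
        xml2::xml_attr(refs, "stoichiometry"), "1"))
      setNames(sign * coef, xml2::xml_attr(refs, "species"))
    }
    stoich <- c(side("./listOfReactants/speciesReference", -1),
                side("./listOfProducts/speciesReference", +1))
    stoich <- tapply(stoich, names(stoich), sum)  # merge duplicated species
    stoich <- setNames(as.numeric(stoich), names(stoich))

    rev <- dplyr::coalesce(xml2::xml_attr(node, "reversible"), "true") == "true"

    lb <- ub <- NA_real_
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_val)) lb <- par_val[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_val)) ub <- par_val[[ub_ref]]
    kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
    if (length(kl)) {
      kl_id <- xml2::xml_attr(kl, "id")
      kl_v <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lb) && "LOWER_BOUND" %in% kl_id)
        lb <- kl_v[match("LOWER_BOUND", kl_id)]
      if (is.na(ub) && "UPPER_BOUND" %in% kl_id)
        ub <- kl_v[match("UPPER_BOUND", kl_id)]
    }

    gpr <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    genes <- unique(dplyr::coalesce(xml2::xml_attr(gpr, "geneProduct"),
                                    xml2::xml_attr(gpr, "fbc:geneProduct")))
    if (length(genes) == 0L) {
      notes <- xml2::xml_text(xml2::xml_find_all(node, ".//notes"))
      ga <- regmatches(notes,
                       regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(ga)) {
        raw <- sub("GENE_ASSOCIATION:", "", ga[[1]])
        genes <- unique(trimws(strsplit(
          gsub("[()]|\\band\\b|\\bor\\b|\\bAND\\b|\\bOR\\b", " ", raw),
          "\\s+")[[1]]))
        genes <- genes[nzchar(genes)]
      }
    }
    list(stoichiometry = stoich, reversible = rev,
         lower_bound = lb, upper_bound = ub, genes = genes)
  }

  parsed <- map(rx_nodes, parse_reaction)
  reactions <- tibble(
    id = rx_ids,
    name = dplyr::coalesce(xml2::xml_attr(rx_nodes, "name"), rx_ids),
    stoichiometry = map(parsed, "stoichiometry"),
    reversible = map_lgl(parsed, "reversible"),
    lower_bound = map_dbl(parsed, "lower_bound"),
    upper_bound = map_dbl(parsed, "upper_bound"),
    genes = map(parsed, "genes")
  )

  # fbc objective, if declared, resolves biomass before pattern matching
  if (is.null(biomass)) {
    obj <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(obj, "xml_missing")) {
      cand <- dplyr::coalesce(xml2::xml_attr(obj, "reaction"),
                              xml2::xml_attr(obj, "fbc:reaction"))
      if (!is.na(cand) && cand %in% reactions$id) biomass <- cand
    }
  }

  metabolic_model(metabolites, reactions, biomass = biomass,
                  biomass_pattern = biomass_pattern,
                  default_bound = default_bound)
}

#' Write a model to SBML Level 3 with fbc bounds
#'
#' Emits the subset of SBML that [read_sbml_model()] consumes:
#' species with boundary flags and KEGG annotations, reactions with
#' stoichiometry, bound parameters, flattened gene associations and an
#' fbc objective naming the biomass reaction. Intended for fixture
#' generation and model exchange within this package, not for
#' annotation-faithful curation round trips.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) formatC(x, format = "g", digits = 17)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    '<model id="model" fbc:strict="true">',
    '<listOfCompartments>'
  )
  for (cmp in unique(model$metabolites$compartment)) {
    lines <- c(lines, paste0('<compartment id="', esc(cmp),
                             '" constant="true"/>'))
  }
  lines <- c(lines, '</listOfCompartments>', '<listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    ann <- ""
    if (!is.na(m$kegg_id)) {
      ann <- paste0(
        '><annotation><rdf:RDF ',
        'xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
        'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
        '<rdf:Description><bqbiol:is><rdf:Bag><rdf:li rdf:resource=',
        '"http://identifiers.org/kegg.compound/', esc(m$kegg_id),
        '"/></rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF>',
        '</annotation></species>')
    }
    lines <- c(lines, paste0(
      '<species id="', esc(m$id), '" name="', esc(m$name),
      '" compartment="', esc(m$compartment),
      '" boundaryCondition="', tolower(as.character(m$boundary)),
      '" hasOnlySubstanceUnits="false" constant="false"',
      if (nzchar(ann)) ann else "/>"))
  }
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lines <- c(lines,
               paste0('<parameter id="lb_', esc(r$id), '" value="',
                      num(r$lower_bound), '" constant="true"/>'),
               paste0('<parameter id="ub_', esc(r$id), '" value="',
                      num(r$upper_bound), '" constant="true"/>'))
  }
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    s <- r$stoichiometry[[1]]
    ref <- function(ids, coefs) {
      paste0('<speciesReference species="', esc(ids), '" stoichiometry="',
             num(coefs), '" constant="true"/>', collapse = "")
    }
    body <- ""
    cons <- s[s < 0]; prod <- s[s > 0]
    if (length(cons)) body <- paste0(body, '<listOfReactants>',
                                     ref(names(cons), -cons),
                                     '</listOfReactants>')
    if (length(prod)) body <- paste0(body, '<listOfProducts>',
                                     ref(names(prod), prod),
                                     '</listOfProducts>')
    g <- r$genes[[1]]
    if (length(g) == 1L) {
      body <- paste0(body, '<fbc:geneProductAssociation>',
                     '<fbc:geneProductRef fbc:geneProduct="', esc(g),
                     '"/></fbc:geneProductAssociation>')
    } else if (length(g) > 1L) {
      body <- paste0(body, '<fbc:geneProductAssociation><fbc:or>',
                     paste0('<fbc:geneProductRef fbc:geneProduct="',
                            esc(g), '"/>', collapse = ""),
                     '</fbc:or></fbc:geneProductAssociation>')
    }
    lines <- c(lines, paste0(
      '<reaction id="', esc(r$id), '" name="', esc(r$name),
      '" reversible="', tolower(as.character(r$reversible)),
      '" fast="false" fbc:lowerFluxBound="lb_', esc(r$id),
      '" fbc:upperFluxBound="ub_', esc(r$id), '">', body, '</reaction>'))
  }
  genes <- unique(unlist(model$reactions$genes))
  lines <- c(lines, '</listOfReactions>')
  if (length(genes)) {
    lines <- c(lines, '<fbc:listOfGeneProducts>',
               paste0('<fbc:geneProduct fbc:id="', esc(genes),
                      '" fbc:label="', esc(genes), '"/>'),
               '</fbc:listOfGeneProducts>')
  }
  lines <- c(lines,
             '<fbc:listOfObjectives fbc:activeObjective="obj">',
             '<fbc:objective fbc:id="obj" fbc:type="maximize">',
             '<fbc:listOfFluxObjectives>',
             paste0('<fbc:fluxObjective fbc:reaction="',
                    esc(model$biomass_reaction_id),
                    '" fbc:coefficient="1"/>'),
             '</fbc:listOfFluxObjectives>', '</fbc:objective>',
             '</fbc:listOfObjectives>',
             '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
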