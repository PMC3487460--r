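# SBML reading and writing on top of xml2.
#
# Writing targets SBML Level 3 Version 1 with the fbc (version 2) package:
# flux bounds as fbc parameters, charge/formula as fbc species attributes,
# GPRs as fbc geneProductAssociation trees (duplicated in notes for older
# tooling). Reading additionally tolerates the encodings found in legacy
# Level 2 models: kinetic-law LOWER_BOUND/UPPER_BOUND parameters,
# GENE_ASSOCIATION / FORMULA / CHARGE notes fields, and boundary-condition
# species (which are dropped from the stoichiometry, the usual COBRA
# convention). On conflicting bound encodings the fbc values win.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sanitize_sid <- function(id) {
  ok <- grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)
  out <- id
  if (any(!ok)) {
    fixed <- gsub("[^A-Za-z0-9_]", "_", id[!ok])
    first_digit <- grepl("^[0-9]", fixed)
    fixed[first_digit] <- paste0("_", fixed[first_digit])
    message("sanitised ", sum(!ok), " id(s) for SBML: ",
            paste(id[!ok], "->", fixed, collapse = ", "))
    out[!ok] <- fixed
  }
  out
}

#' Write a model as SBML Level 3 with fbc
#'
#' The output round-trips losslessly through [read_sbml()]: ids,
#' stoichiometry, bounds, compartments, formulas, charges, reaction kinds
#' and normalised GPR strings are all preserved. Ids that are not valid
#' SBML identifiers are sanitised (reported via `message()`).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  doc <- xml2::xml_new_root("sbml",
    "xmlns" = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                               "fbc:strict" = "false")
  if (length(model$biomass)) {
    notes <- xml2::xml_add_child(mnode, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
      paste0("BIOMASS_LABELS: ",
             paste(names(model$biomass), unname(model$biomass),
                   sep = "=", collapse = ";")))
  }

  comps <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in model$compartments)
    xml2::xml_add_child(comps, "compartment", id = sanitize_sid(cp),
                        constant = "true")

  mets <- model$metabolites
  sp <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(mets))) {
    node <- xml2::xml_add_child(sp, "species",
      id = sanitize_sid(mets$id[i]), name = mets$name[i],
      compartment = sanitize_sid(mets$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.na(mets$charge[i]))
      xml2::xml_set_attr(node, "fbc:charge", as.character(mets$charge[i]))
    if (!is.na(mets$formula[i]))
      xml2::xml_set_attr(node, "fbc:chemicalFormula", mets$formula[i])
  }

  rxns <- model$reactions
  bound_vals <- sort(unique(c(rxns$lower, rxns$upper)))
  bound_ids <- stats::setNames(
    sprintf("fb_%d", seq_along(bound_vals)),
    vapply(bound_vals, format, character(1), digits = 17))
  pars <- xml2::xml_add_child(mnode, "listOfParameters")
  for (v in bound_vals)
    xml2::xml_add_child(pars, "parameter",
                        id = bound_ids[[format(v, digits = 17)]],
                        value = format(v, digits = 17), constant = "true")

  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nrow(rxns))) {
    rn <- xml2::xml_add_child(rl, "reaction",
      id = sanitize_sid(rxns$id[j]), name = rxns$name[j],
      reversible = tolower(rxns$lower[j] < 0), fast = "false",
      "fbc:lowerFluxBound" = bound_ids[[format(rxns$lower[j], digits = 17)]],
      "fbc:upperFluxBound" = bound_ids[[format(rxns$upper[j], digits = 17)]])
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p", paste0("KIND: ", rxns$kind[j]))
    gpr_str <- format_gpr(model$gprs[[rxns$id[j]]])
    if (nzchar(gpr_str))
      xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", gpr_str))

    col <- model$stoich[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    if (length(reac)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(lr, "speciesReference",
                            species = sanitize_sid(mets$id[i]),
                            stoichiometry = format(-col[i], digits = 17),
                            constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(lp, "speciesReference",
                            species = sanitize_sid(mets$id[i]),
                            stoichiometry = format(col[i], digits = 17),
                            constant = "true")
    }
    gpa <- model$gprs[[rxns$id[j]]]
    if (!is.null(gpa)) {
      node <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpa(node, gpa)
    }
  }

  if (length(model$biomass)) {
    objs <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj1")
    obj <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj1",
                               "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = sanitize_sid(model$biomass[[1]]),
                        "fbc:coefficient" = "1")
  }

  genes <- model$genes
  has_unknown <- any(vapply(model$gprs, gpr_has_unknown, logical(1)))
  if (length(genes) || has_unknown) {
    gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sanitize_sid(g)),
                          "fbc:label" = g)
    if (has_unknown)
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = "G_unknown", "fbc:label" = "unknown")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

gpr_has_unknown <- function(expr) {
  if (is.null(expr)) return(FALSE)
  if (expr$type == "unknown") return(TRUE)
  if (expr$type == "gene") return(FALSE)
  any(vapply(expr$children, gpr_has_unknown, logical(1)))
}

write_gpa <- function(parent, expr) {
  switch(expr$type,
    gene = xml2::xml_add_child(parent, "fbc:geneProductRef",
      "fbc:geneProduct" = paste0("G_", sanitize_sid(expr$gene))),
    unknown = xml2::xml_add_child(parent, "fbc:geneProductRef",
      "fbc:geneProduct" = "G_unknown"),
    and = ,
    or = {
      node <- xml2::xml_add_child(parent, paste0("fbc:", expr$type))
      for (ch in expr$children) write_gpa(node, ch)
    })
  invisible(parent)
}

#' Read a genome-scale model from SBML
#'
#' Supports SBML Level 2 and Level 3, with flux bounds taken from fbc
#' constructs when present, else from kinetic-law `LOWER_BOUND` /
#' `UPPER_BOUND` parameters, else from the `reversible` flag (giving
#' `[-big, big]` or `[0, big]`). GPRs are read from
#' `fbc:geneProductAssociation` when present, else from
#' `GENE_ASSOCIATION` notes. Formulas and charges come from fbc species
#' attributes or `FORMULA:` / `CHARGE:` notes; metabolites without them
#' are marked unknown and skipped (with the reason) by the balance
#' checker. Boundary-condition species are dropped from the
#' stoichiometry.
#'
#' @param path SBML file path.
#' @param big big-M replacing infinite or missing bounds.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)           # parse errors name the line
  xml2::xml_ns_strip(doc)               # fbc attrs keep their prefix
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) stop("no <model> element in ", path)
  model_id <- xml2::xml_attr(mnode, "id")
  if (is.na(model_id)) model_id <- "model"

  comp_nodes <- xml2::xml_find_all(mnode, "./listOfCompartments/compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  sp_attr <- lapply(sp_nodes, xml2::xml_attrs)
  getat <- function(at, keys, default = NA_character_) {
    for (k in keys) if (k %in% names(at)) return(at[[k]])
    default
  }
  boundary <- vapply(sp_attr, getat, character(1),
                     keys = "boundaryCondition", default = "false") == "true"
  notes_field <- function(node, key) {
    leaves <- xml2::xml_find_all(node, "./notes//*[not(*)]")
    txt <- if (length(leaves)) vapply(leaves, xml2::xml_text, character(1))
           else xml2::xml_text(xml2::xml_find_first(node, "./notes"))
    txt <- unlist(strsplit(txt[!is.na(txt)], "\n"))
    hit <- grep(paste0("^\\s*", key, ":"), txt, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub(paste0("^\\s*", key, ":"), "", hit[1]))
  }
  mets <- data.frame(
    id = vapply(sp_attr, getat, character(1), keys = "id"),
    name = vapply(sp_attr, function(a) getat(a, "name", getat(a, "id")),
                  character(1)),
    compartment = vapply(sp_attr, getat, character(1), keys = "compartment"),
    formula = vapply(sp_attr, getat, character(1),
                     keys = c("fbc:chemicalFormula", "chemicalFormula")),
    charge = vapply(sp_attr, getat, character(1),
                    keys = c("fbc:charge", "charge")),
    stringsAsFactors = FALSE)
  for (i in which(is.na(mets$formula)))
    mets$formula[i] <- notes_field(sp_nodes[[i]], "FORMULA")
  for (i in which(is.na(mets$charge)))
    mets$charge[i] <- notes_field(sp_nodes[[i]], "CHARGE")
  mets$charge <- suppressWarnings(as.integer(mets$charge))
  mets <- mets[!boundary, , drop = FALSE]
  if (anyNA(mets$compartment)) mets$compartment[is.na(mets$compartment)] <- "c"

  # bound parameters (global and fbc)
  par_nodes <- xml2::xml_find_all(mnode, "./listOfParameters/parameter")
  par_vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  gp_nodes <- xml2::xml_find_all(mnode, ".//listOfGeneProducts/geneProduct")
  gp_label <- stats::setNames(
    vapply(lapply(gp_nodes, xml2::xml_attrs), getat, character(1),
           keys = c("fbc:label", "label", "fbc:id", "id")),
    vapply(lapply(gp_nodes, xml2::xml_attrs), getat, character(1),
           keys = c("fbc:id", "id")))

  rx_nodes <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  n <- length(rx_nodes)
  rid <- character(n); rname <- character(n)
  lower <- numeric(n); upper <- numeric(n)
  gpr <- character(n); kind <- rep(NA_character_, n)
  stoich_entries <- vector("list", n)
  big <- 1000

  for (j in seq_len(n)) {
    node <- rx_nodes[[j]]
    at <- xml2::xml_attrs(node)
    rid[j] <- at[["id"]]
    rname[j] <- getat(at, "name", rid[j])
    reversible <- !identical(getat(at, "reversible", "true"), "false")

    lo <- hi <- NA_real_
    lbref <- getat(at, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubref <- getat(at, c("fbc:upperFluxBound", "upperFluxBound"))
    if (!is.na(lbref) && lbref %in% names(par_vals)) lo <- par_vals[[lbref]]
    if (!is.na(ubref) && ubref %in% names(par_vals)) hi <- par_vals[[ubref]]
    if (is.na(lo) || is.na(hi)) {      # legacy kinetic-law encoding
      kl <- xml2::xml_find_all(node, ".//kineticLaw//parameter")
      kl_ids <- xml2::xml_attr(kl, "id")
      kl_vals <- as.numeric(xml2::xml_attr(kl, "value"))
      if (is.na(lo) && "LOWER_BOUND" %in% kl_ids)
        lo <- kl_vals[match("LOWER_BOUND", kl_ids)]
      if (is.na(hi) && "UPPER_BOUND" %in% kl_ids)
        hi <- kl_vals[match("UPPER_BOUND", kl_ids)]
    }
    if (is.na(lo)) lo <- if (reversible) -big else 0
    if (is.na(hi)) hi <- big
    lower[j] <- lo; upper[j] <- hi

    sref <- function(xpath, sign) {
      refs <- xml2::xml_find_all(node, xpath)
      if (!length(refs)) return(NULL)
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      data.frame(met = xml2::xml_attr(refs, "species"),
                 coef = sign * coef, stringsAsFactors = FALSE)
    }
    entries <- rbind(sref("./listOfReactants/speciesReference", -1),
                     sref("./listOfProducts/speciesReference", 1))
    if (is.null(entries) || !nrow(entries))
      stop("reaction '", rid[j], "' has no stoichiometry")
    stoich_entries[[j]] <- entries

    gpa <- xml2::xml_find_first(node, "./geneProductAssociation")
    if (!inherits(gpa, "xml_missing")) {
      gpr[j] <- gpa_to_string(xml2::xml_children(gpa)[[1]], gp_label)
    } else {
      txt <- notes_field(node, "GENE_ASSOCIATION")
      gpr[j] <- if (is.na(txt)) "" else txt
    }
    k <- notes_field(node, "KIND")
    if (!is.na(k)) kind[j] <- k
  }

  keep_met <- mets$id
  S <- matrix(0, length(keep_met), n, dimnames = list(keep_met, rid))
  for (j in seq_len(n)) {
    e <- stoich_entries[[j]]
    e <- e[e$met %in% keep_met, , drop = FALSE]   # boundary species dropped
    if (!nrow(e))
      stop("reaction '", rid[j],
           "' touches only boundary species; no stoichiometry left")
    agg <- tapply(e$coef, e$met, sum)
    S[names(agg), j] <- agg
  }

  rxns <- data.frame(id = rid, name = rname, lower = lower, upper = upper,
                     kind = kind, gpr = gpr, stringsAsFactors = FALSE)

  biomass <- character(0)
  bm_note <- notes_field(mnode, "BIOMASS_LABELS")
  if (!is.na(bm_note)) {
    kv <- strsplit(strsplit(bm_note, ";")[[1]], "=")
    biomass <- stats::setNames(vapply(kv, `[`, character(1), 2),
                               vapply(kv, `[`, character(1), 1))
  } else {
    fo <- xml2::xml_find_first(mnode, ".//listOfFluxObjectives/fluxObjective")
    if (!inherits(fo, "xml_missing")) {
      ref <- getat(xml2::xml_attrs(fo), c("fbc:reaction", "reaction"))
      if (!is.na(ref) && ref %in% rid) biomass <- c(objective = ref)
    }
  }

  metabolic_model(mets, rxns, S, biomass = biomass,
                  compartments = if (length(compartments)) compartments,
                  id = model_id, big = big)
}

# fbc association subtree -> GPR rule string
gpa_to_string <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- getat2(xml2::xml_attrs(node), c("fbc:geneProduct", "geneProduct"))
    lab <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(lab)
  }
  if (nm %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), gpa_to_string, character(1),
                    gp_label)
    return(paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")"))
  }
  stop("unsupported gene association element: ", nm)
}

getat2 <- function(at, keys, default = NA_character_) {
  for (k in keys) if (k %in% names(at)) return(at[[k]])
  default
}

#' Read a model from tabular reaction/metabolite sheets
#'
#' Mirrors the supplementary-spreadsheet layout: one TSV of reactions with
#' human-readable equation strings, one TSV of metabolites. Equations use
#' `->` (irreversible) or `<->`/`<=>` (reversible), coefficients as bare
#' numbers, e.g. `"2 A_c + B_c -> C_e"`.
#'
#' @param reactions_path TSV with columns `id`, `equation`, and optionally
#'   `lower`, `upper`, `gpr`, `kind`, `name`.
#' @param metabolites_path optional TSV with columns `id` and optionally
#'   `name`, `compartment`, `formula`, `charge`; metabolites missing from
#'   it are created bare.
#' @param big big-M default bound magnitude.
#' @return A `metabolic_model`.
#' @export
read_model_table <- function(reactions_path, metabolites_path = NULL,
                             big = 1000) {
  rx <- utils::read.delim(reactions_path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "equation") %in% names(rx)))
  parsed <- lapply(rx$equation, parse_equation)
  reversible <- vapply(parsed, `[[`, logical(1), "reversible")
  met_ids <- unique(unlist(lapply(parsed, function(p) names(p$coef))))

  mets <- data.frame(id = met_ids, stringsAsFactors = FALSE)
  if (!is.null(metabolites_path)) {
    mtab <- utils::read.delim(metabolites_path, stringsAsFactors = FALSE)
    mets <- merge(mets, mtab, by = "id", all.x = TRUE, sort = FALSE)
  }
  # infer missing compartments from the conventional _c/_p/_e suffix
  sfx <- sub("^.*_([a-z])$", "\\1", mets$id)
  inferred <- ifelse(nchar(sfx) == 1, sfx, "c")
  if (is.null(mets$compartment)) mets$compartment <- inferred
  else mets$compartment[is.na(mets$compartment)] <-
    inferred[is.na(mets$compartment)]

  rxns <- data.frame(
    id = rx$id,
    name = rx$name %||% rx$id,
    lower = rx$lower %||% ifelse(reversible, -big, 0),
    upper = rx$upper %||% big,
    kind = rx$kind %||% NA_character_,
    gpr = rx$gpr %||% "",
    stringsAsFactors = FALSE)

  S <- matrix(0, nrow(mets), nrow(rxns), dimnames = list(mets$id, rx$id))
  for (j in seq_along(parsed)) S[names(parsed[[j]]$coef), j] <- parsed[[j]]$coef
  metabolic_model(mets, rxns, S, big = big)
}

parse_equation <- function(eq) {
  arrow <- regmatches(eq, regexpr("<->|<=>|->|=>", eq))
  if (!length(arrow)) stop("no reaction arrow in equation: '", eq, "'")
  sides <- strsplit(eq, "<->|<=>|->|=>")[[1]]
  term <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    parts <- trimws(strsplit(side, "\\+")[[1]])
    coefs <- vapply(parts, function(p) {
      m <- regmatches(p, regexpr("^[0-9.]+ ", p))
      if (length(m)) as.numeric(m) else 1
    }, numeric(1))
    ids <- sub("^[0-9.]+ ", "", parts)
    stats::setNames(sign * coefs, ids)
  }
  lhs <- term(sides[1], -1)
  rhs <- if (length(sides) > 1) term(sides[2], 1) else numeric(0)
  coef <- c(lhs, rhs)
  tot <- tapply(coef, names(coef), sum)
  list(coef = stats::setNames(as.numeric(tot), names(tot)),
       reversible = arrow %in% c("<->", "<=>"))
}
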