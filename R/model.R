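#' Construct a compartmented stoichiometric model
#'
#' A `metabolic_model` holds the network used by every analysis in the
#' package: a metabolite table (with optional elemental formula and charge
#' for balance linting), a reaction table (bounds, kind, GPR string), the
#' stoichiometric matrix S (metabolites x reactions, negative = consumed),
#' and a mapping from growth-condition labels to biomass reaction ids.
#'
#' Infinite bounds are normalised to the conventional big-M value for
#' genome-scale models (+/- `big`, default 1000 flux units).
#'
#' @param metabolites data.frame with columns `id`, and optionally `name`,
#'   `compartment`, `formula` (Hill-style string, `NA` = unknown), `charge`
#'   (integer, `NA` = unknown).
#' @param reactions data.frame with columns `id`, `lower`, `upper`, and
#'   optionally `name`, `kind` (one of `"metabolic"`, `"transport"`,
#'   `"exchange"`, `"biomass"`) and `gpr` (Boolean rule string, `""` =
#'   spontaneous / not gene-associated).
#' @param stoich numeric matrix, rows named by metabolite id, columns by
#'   reaction id.
#' @param biomass named character vector mapping growth-condition labels to
#'   biomass reaction ids (may be empty for pure QC work).
#' @param compartments character vector of compartment codes; defaults to
#'   those seen in `metabolites`.
#' @param id model identifier used when serialising.
#' @param big big-M used to replace infinite bounds.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich,
                            biomass = character(), compartments = NULL,
                            id = "model", big = 1000) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  nm <- nrow(metabolites); nr <- nrow(reactions)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- rep("c", nm)
  if (is.null(metabolites$formula))
    metabolites$formula <- rep(NA_character_, nm)
  if (is.null(metabolites$charge))
    metabolites$charge <- rep(NA_integer_, nm)
  metabolites$charge <- as.integer(metabolites$charge)
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- rep("", nr)
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$kind)) reactions$kind <- rep(NA_character_, nr)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  stoich <- as.matrix(stoich)
  if (nrow(metabolites) && is.null(rownames(stoich)))
    rownames(stoich) <- metabolites$id
  if (nrow(reactions) && is.null(colnames(stoich)))
    colnames(stoich) <- reactions$id
  # align matrix to table order
  if (nrow(metabolites)) stoich <- stoich[metabolites$id, , drop = FALSE]
  if (nrow(reactions)) stoich <- stoich[, reactions$id, drop = FALSE]

  reactions$lower[is.infinite(reactions$lower)] <- -big
  reactions$upper[is.infinite(reactions$upper)] <- big
  kind_missing <- is.na(reactions$kind)
  if (any(kind_missing)) {
    reactions$kind[kind_missing] <-
      vapply(which(kind_missing), function(j)
        infer_reaction_kind(stoich[, j], metabolites$compartment,
                            reactions$id[j]), character(1))
  }

  gprs <- lapply(reactions$gpr, parse_gpr)
  names(gprs) <- reactions$id
  genes <- sort(unique(unlist(lapply(gprs, gpr_genes))))

  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoich = stoich,
    gprs = gprs,
    genes = genes,
    biomass = biomass,
    compartments = if (is.null(compartments))
      sort(unique(metabolites$compartment)) else compartments,
    big = big
  ), class = "metabolic_model")
  validate_model(model)
  model
}

# classify a reaction from its stoichiometry when no kind was given
infer_reaction_kind <- function(column, compartments, rxn_id) {
  touched <- which(column != 0)
  if (grepl("biomass|^BIO", rxn_id, ignore.case = TRUE)) return("biomass")
  if (length(touched) == 1) return("exchange")
  if (length(unique(compartments[touched])) > 1) return("transport")
  "metabolic"
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, matrix/table agreement, bound ordering, non-empty
#' stoichiometry per reaction, that exchange reactions touch exactly one
#' metabolite, and that every biomass label points at an existing reaction.
#' Stops with an informative error on the first violation.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites; rxn <- model$reactions; S <- model$stoich
  if (anyDuplicated(met$id))
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id))
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    stop("stoichiometric matrix is ", nrow(S), "x", ncol(S),
         " but model has ", nrow(met), " metabolites and ",
         nrow(rxn), " reactions")
  if (nrow(met) && !identical(rownames(S), met$id))
    stop("stoichiometric matrix rows do not match metabolite ids")
  if (nrow(rxn) && !identical(colnames(S), rxn$id))
    stop("stoichiometric matrix columns do not match reaction ids")
  bad <- rxn$lower > rxn$upper
  if (any(bad))
    stop("lower bound exceeds upper bound for: ",
         paste(rxn$id[bad], collapse = ", "))
  if (nrow(rxn)) {
    empty <- colSums(S != 0) == 0
    if (any(empty))
      stop("reactions with empty stoichiometry: ",
           paste(rxn$id[empty], collapse = ", "))
    ex <- rxn$kind == "exchange"
    multi <- ex & colSums(S != 0) != 1
    if (any(multi))
      stop("exchange reactions must touch exactly one metabolite: ",
           paste(rxn$id[multi], collapse = ", "))
  }
  if (length(model$biomass)) {
    missing <- setdiff(unname(model$biomass), rxn$id)
    if (length(missing))
      stop("biomass reactions not in model: ", paste(missing, collapse = ", "))
  }
  unknown_comp <- setdiff(unique(met$compartment), model$compartments)
  if (length(unknown_comp))
    stop("metabolite compartments not declared: ",
         paste(unknown_comp, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "  reactions: ", nrow(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  if (nrow(x$reactions)) {
    tab <- table(x$reactions$kind)
    cat("  kinds: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat("  compartments: ", paste(x$compartments, collapse = ", "), "\n",
      sep = "")
  if (length(x$biomass))
    cat("  biomass: ",
        paste(names(x$biomass), x$biomass, sep = " -> ", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Compare two models by shared and unique identifiers
#'
#' Reactions and metabolites are matched by exact id string (the two
#' cyanobacterial reconstructions this package targets use one consistent
#' naming convention, so no fuzzy matching is attempted).
#'
#' @param a,b `metabolic_model` objects.
#' @return A `model_comparison` list: for reactions and metabolites, the
#'   `shared`, `unique_to_a` and `unique_to_b` id sets plus a `counts`
#'   data.frame.
#' @export
compare_models <- function(a, b) {
  part <- function(ia, ib) {
    list(shared = sort(intersect(ia, ib)),
         unique_to_a = sort(setdiff(ia, ib)),
         unique_to_b = sort(setdiff(ib, ia)))
  }
  rxn <- part(a$reactions$id, b$reactions$id)
  met <- part(a$metabolites$id, b$metabolites$id)
  counts <- data.frame(
    entity = c("reactions", "metabolites"),
    shared = c(length(rxn$shared), length(met$shared)),
    unique_to_a = c(length(rxn$unique_to_a), length(met$unique_to_a)),
    unique_to_b = c(length(rxn$unique_to_b), length(met$unique_to_b)),
    stringsAsFactors = FALSE
  )
  structure(list(a = a$id, b = b$id, reactions = rxn, metabolites = met,
                 counts = counts),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> ", x$a, " vs ", x$b, "\n", sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Write a model comparison as TSV and JSON reports
#'
#' @param cmp a `model_comparison`.
#' @param path_prefix files `<path_prefix>.tsv` (counts) and
#'   `<path_prefix>.json` (full id sets) are written.
#' @return The two paths, invisibly.
#' @export
write_comparison <- function(cmp, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  utils::write.table(cmp$counts, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(a = cmp$a, b = cmp$b, reactions = cmp$reactions,
                            metabolites = cmp$metabolites),
                       json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv, json))
}

# working bounds as a 2-column matrix
model_bounds <- function(model) {
  cbind(lower = model$reactions$lower, upper = model$reactions$upper)
}

rxn_index <- function(model, ids, what = "reaction") {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx))
    stop("unknown ", what, " id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

met_index <- function(model, ids) {
  idx <- match(ids, model$metabolites$id)
  if (anyNA(idx))
    stop("unknown metabolite id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}
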