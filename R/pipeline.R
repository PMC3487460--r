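# End-to-end analyses: yield tables, FVA-vs-measurement comparison,
# essentiality screening, and the QC bundle. Every report carries a
# manifest attribute recording how it was produced.

run_manifest <- function(...) {
  list(package = "cyanoflux",
       version = as.character(utils::packageVersion("cyanoflux")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = list(...))
}

#' Compute a table of maximum theoretical yields
#'
#' Each task names a scenario, a product reaction and (optionally) a
#' denominator reaction; yields are computed with [compute_yield()].
#'
#' @param model a `metabolic_model`.
#' @param tasks list of lists with elements `scenario` (a [scenario()]),
#'   `product`, and optionally `denominator` and `fix_biomass`.
#' @param diurnal_sets passed to [build_problem()].
#' @return data.frame(model, scenario, product, yield, product_flux,
#'   denominator_flux) with a `"manifest"` attribute.
#' @export
run_yields <- function(model, tasks, diurnal_sets = NULL) {
  rows <- lapply(tasks, function(tk) {
    y <- compute_yield(model, tk$scenario, tk$product,
                       denominator = tk$denominator,
                       fix_biomass = tk$fix_biomass %||% TRUE,
                       diurnal_sets = diurnal_sets)
    data.frame(model = model$id, scenario = tk$scenario$label,
               product = tk$product, yield = as.numeric(y),
               product_flux = attr(y, "product_flux"),
               denominator_flux = attr(y, "denominator_flux"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "manifest") <- run_manifest(model = model$id,
                                        n_tasks = length(tasks))
  out
}

#' Classify how a predicted flux range relates to a measured one
#'
#' `"contained"`: the measured range lies within the predicted one;
#' `"under"`: the predicted range lies entirely below the measured one;
#' `"over"`: entirely above; `"partial"`: the ranges overlap without
#' containment.
#'
#' @param meas_lo,meas_hi measured interval.
#' @param mod_lo,mod_hi model-predicted interval.
#' @param tol comparison tolerance.
#' @return Character scalar.
#' @export
classify_range_overlap <- function(meas_lo, meas_hi, mod_lo, mod_hi,
                                   tol = 1e-9) {
  if (mod_lo <= meas_lo + tol && mod_hi >= meas_hi - tol) return("contained")
  if (mod_hi < meas_lo - tol) return("under")
  if (mod_lo > meas_hi + tol) return("over")
  "partial"
}

#' Read a table of measured flux ranges
#'
#' TSV with columns `reaction`, `meas_lb`, `meas_ub` (95% confidence
#' bounds of carbon-labelling flux estimates, on the same uptake basis as
#' the model scenario).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_mfa_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  stopifnot(all(c("reaction", "meas_lb", "meas_ub") %in% names(tab)))
  tab
}

#' Compare model-predicted flux ranges against measured ranges
#'
#' Runs flux variability at a max-biomass floor for every measured
#' reaction present in the model and classifies each predicted range
#' against the measurement with [classify_range_overlap()]. Measured
#' reactions that do not map to a model reaction are listed in the
#' `"unmapped"` attribute (and a message), never silently dropped.
#'
#' @param model a `metabolic_model`.
#' @param scen the growth [scenario()] used for the floor.
#' @param mfa data.frame from [read_mfa_table()].
#' @param id_map optional named character vector mapping measurement
#'   reaction names to model reaction ids (default: identity).
#' @param floor_fraction biomass floor as a fraction of the optimum.
#' @param diurnal_sets passed to [build_problem()].
#' @return data.frame(reaction, meas_lb, meas_ub, model_lb, model_ub,
#'   overlap) with `"unmapped"` and `"manifest"` attributes.
#' @export
run_fva_table <- function(model, scen, mfa, id_map = NULL,
                          floor_fraction = 1, diurnal_sets = NULL) {
  ids <- if (is.null(id_map)) stats::setNames(mfa$reaction, mfa$reaction)
         else id_map
  mapped <- mfa$reaction[ids[mfa$reaction] %in% model$reactions$id]
  unmapped <- setdiff(mfa$reaction, mapped)
  if (length(unmapped))
    message("measured reaction(s) not mapped to the model: ",
            paste(unmapped, collapse = ", "))
  problem <- build_problem(model, scen, diurnal_sets)
  fva <- flux_variability(problem, unname(ids[mapped]),
                          floor_fraction = floor_fraction)
  sub <- mfa[mfa$reaction %in% mapped, , drop = FALSE]
  out <- data.frame(reaction = sub$reaction,
                    meas_lb = sub$meas_lb, meas_ub = sub$meas_ub,
                    model_lb = fva$min[match(ids[sub$reaction],
                                             fva$reaction_id)],
                    model_ub = fva$max[match(ids[sub$reaction],
                                             fva$reaction_id)],
                    stringsAsFactors = FALSE)
  out$overlap <- mapply(classify_range_overlap, out$meas_lb, out$meas_ub,
                        out$model_lb, out$model_ub)
  attr(out, "unmapped") <- unmapped
  attr(out, "manifest") <- run_manifest(model = model$id,
                                        scenario = scen$label,
                                        floor_fraction = floor_fraction)
  out
}

#' Run the essentiality screen against an in vivo table
#'
#' @param model a `metabolic_model`.
#' @param scen the growth [scenario()] to screen under.
#' @param invivo a named character vector gene -> `"G"`/`"NG"`, or the
#'   path to a TSV for [read_viability_table()].
#' @param threshold_fraction viability cutoff.
#' @param diurnal_sets passed to [build_problem()].
#' @return list(calls, summary) with a `"manifest"` attribute.
#' @export
run_essentiality <- function(model, scen, invivo,
                             threshold_fraction = 0.10,
                             diurnal_sets = NULL) {
  if (is.character(invivo) && length(invivo) == 1 && is.null(names(invivo)))
    invivo <- read_viability_table(invivo)
  if (!length(invivo)) stop("empty in vivo gene table")
  calls <- single_gene_deletions(model, scen, genes = names(invivo),
                                 threshold_fraction = threshold_fraction,
                                 diurnal_sets = diurnal_sets)
  calls <- classify_essentiality(calls, invivo)
  out <- list(calls = calls, summary = summarize_screen(calls))
  attr(out, "manifest") <- run_manifest(model = model$id,
                                        scenario = scen$label,
                                        threshold = threshold_fraction,
                                        n_genes = length(invivo))
  out
}

#' Run the model QC bundle
#'
#' Balance linting, blocked-metabolite detection and infeasible-loop
#' detection in one pass.
#'
#' @param model a `metabolic_model`.
#' @param scen optional scenario for blocked-metabolite detection.
#' @return list(balance, blocked, loops) with a `"manifest"` attribute.
#' @export
run_qc <- function(model, scen = NULL) {
  out <- list(balance = check_balance(model),
              blocked = if (nrow(model$reactions))
                find_blocked_metabolites(model, scen) else character(0),
              loops = detect_infeasible_loops(model))
  attr(out, "manifest") <- run_manifest(model = model$id)
  out
}
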