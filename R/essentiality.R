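# In silico single-gene-deletion screening and comparison against in vivo
# viability, with the four-way GG/GNG/NGG/NGNG classification.

#' Single-gene-deletion screen
#'
#' For each gene, disables the reactions whose GPR evaluates false under
#' the knockout and re-maximises biomass. The in silico verdict is growth
#' (`"G"`) when the mutant optimum reaches at least `threshold_fraction`
#' (default 10%) of the wild-type optimum of the same scenario — the
#' standard cutoff for calling a deletion viable in silico. Genes
#' appearing in no GPR leave the network untouched and are `"G"` with
#' `mutant_growth == wild_type_growth`.
#'
#' @param model a `metabolic_model`.
#' @param scen the growth [scenario()] to screen under.
#' @param genes gene ids to delete; defaults to all genes in the model's
#'   GPRs.
#' @param threshold_fraction viability cutoff as a fraction of wild-type
#'   growth.
#' @param diurnal_sets passed to [build_problem()].
#' @return data.frame with columns `gene`, `wild_type_growth`,
#'   `mutant_growth`, `in_silico` (`"G"`/`"NG"`).
#' @export
single_gene_deletions <- function(model, scen, genes = NULL,
                                  threshold_fraction = 0.10,
                                  diurnal_sets = NULL) {
  genes <- genes %||% model$genes
  problem <- build_problem(model, scen, diurnal_sets)
  wt <- maximize_flux(problem)
  if (wt$status != "optimal" || wt$objective_value <= 1e-9)
    stop("wild-type problem under scenario '", scen$label, "' is ",
         if (wt$status == "optimal") "zero-growth" else wt$status,
         "; cannot screen")
  wt_growth <- wt$objective_value

  mutant <- vapply(genes, function(g) {
    off <- suppressWarnings(reactions_disabled_by(model, g))
    if (!length(off)) return(wt_growth)
    res <- maximize_flux(apply_knockout(problem, off))
    if (res$status != "optimal") 0 else res$objective_value
  }, numeric(1))

  data.frame(gene = genes,
             wild_type_growth = wt_growth,
             mutant_growth = unname(mutant),
             in_silico = ifelse(mutant >= threshold_fraction * wt_growth,
                                "G", "NG"),
             stringsAsFactors = FALSE)
}

#' Join in silico calls to in vivo viability
#'
#' Assigns the four-way category: first letter pair is the in silico
#' verdict, second the in vivo one (`G` growth, `NG` no growth). Genes
#' with no in vivo record are `"unclassified"` (mutants flagged with
#' incomplete segregation should be dropped upstream, e.g. by
#' [read_viability_table()]).
#'
#' @param calls data.frame from [single_gene_deletions()].
#' @param invivo named character vector gene -> `"G"`/`"NG"`.
#' @return `calls` with `in_vivo` and `category` columns added.
#' @export
classify_essentiality <- function(calls, invivo) {
  if (anyDuplicated(names(invivo)))
    stop("duplicate genes in the in vivo table: ",
         paste(unique(names(invivo)[duplicated(names(invivo))]),
               collapse = ", "))
  bad <- setdiff(unique(invivo), c("G", "NG"))
  if (length(bad))
    stop("in vivo verdicts must be 'G' or 'NG'; saw: ",
         paste(bad, collapse = ", "))
  calls$in_vivo <- ifelse(calls$gene %in% names(invivo),
                          unname(invivo[calls$gene]), "unknown")
  calls$category <- ifelse(calls$in_vivo == "unknown", "unclassified",
                           paste0(calls$in_silico, calls$in_vivo))
  calls
}

#' Summarise a classified essentiality screen
#'
#' Specificity is the fraction of in vivo viable mutants the model also
#' grows, `GG / (GG + NGG)`; sensitivity is the fraction of in vivo
#' lethal mutants the model also kills, `NGNG / (NGNG + GNG)`. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param calls classified data.frame from [classify_essentiality()].
#' @return list with `counts` (named GG/GNG/NGG/NGNG/unclassified),
#'   `specificity`, `sensitivity`.
#' @export
summarize_screen <- function(calls) {
  classified <- calls$category[calls$category != "unclassified"]
  if (!length(classified)) stop("no classified calls to summarise")
  counts <- vapply(c("GG", "GNG", "NGG", "NGNG", "unclassified"),
                   function(k) sum(calls$category == k), integer(1))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(counts = counts,
       specificity = ratio(counts[["GG"]], counts[["GG"]] + counts[["NGG"]]),
       sensitivity = ratio(counts[["NGNG"]],
                           counts[["NGNG"]] + counts[["GNG"]]))
}

#' Read an in vivo viability table
#'
#' Expects a TSV with columns `gene_id`, `viability` (`G`/`NG`) and
#' optionally `segregation_flag`; rows flagged `incomplete` are dropped
#' (mutants whose chromosome copies were not fully segregated carry no
#' reliable essentiality information).
#'
#' @param path TSV path.
#' @return Named character vector gene -> `"G"`/`"NG"`.
#' @export
read_viability_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "viability") %in% names(tab)))
  if ("segregation_flag" %in% names(tab))
    tab <- tab[!tab$segregation_flag %in% "incomplete", , drop = FALSE]
  stats::setNames(tab$viability, tab$gene_id)
}
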