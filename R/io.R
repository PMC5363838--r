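# Readers and writers for the package's plain-text formats: YAML reaction
# networks, two-column TSV media and conversion vectors, TSV count tables,
# and JSON/TSV fit reports.

#' Write a reaction network to a YAML file
#'
#' Stores the compound registry (id, formula, charge, dGf0') and every
#' reaction (catabolic/anabolic stoichiometry maps, lambda_cat, population,
#' scenario) so that [read_network()] reproduces the network exactly.
#'
#' @param network A [reaction_network].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  cps <- lapply(network$compounds, function(cp)
    list(formula = cp$formula, charge = cp$charge, dGf0 = cp$dGf0_prime,
         roles = as.list(cp$roles)))
  rxns <- lapply(network$reactions, function(r) {
    out <- list(population = r$population, scenario = r$scenario,
                lambda_cat = r$lambda_cat,
                catabolic = as.list(r$catabolic$stoich))
    if (!is.null(r$anabolic)) out$anabolic <- as.list(r$anabolic$stoich)
    out
  })
  yaml::write_yaml(list(compounds = cps, reactions = rxns), path,
                   precision = 15)
  invisible(path)
}

#' Read a reaction network from a YAML file
#'
#' @param path File written by [write_network()] (or hand-authored in the
#'   same layout).
#' @param validate If `TRUE` (default), unbalanced reactions are collected
#'   and reported via a warning naming them; loading still succeeds so the
#'   problems can be inspected.
#' @return A [reaction_network].
#' @export
read_network <- function(path, validate = TRUE) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$compounds) || is.null(doc$reactions))
    stop("network file must contain 'compounds' and 'reactions' blocks: ", path)
  cps <- lapply(names(doc$compounds), function(id) {
    d <- doc$compounds[[id]]
    compound(id, d$formula, charge = d$charge %||% 0,
             dGf0 = d$dGf0 %||% NA_real_,
             roles = unlist(d$roles) %||% character())
  })
  names(cps) <- names(doc$compounds)
  rxns <- lapply(names(doc$reactions), function(id) {
    d <- doc$reactions[[id]]
    cat_half <- half_reaction(unlist(d$catabolic), "catabolic", cps)
    an_half <- if (!is.null(d$anabolic))
      half_reaction(unlist(d$anabolic), "anabolic", cps) else NULL
    metabolic_reaction(id, cat_half, an_half,
                       lambda_cat = d$lambda_cat %||% 1,
                       population = d$population %||% NA_character_,
                       scenario = d$scenario %||% "both", compounds = cps,
                       check = FALSE)
  })
  net <- reaction_network(rxns, cps)
  if (validate) {
    bad <- Filter(function(r) nrow(check_balance(r, cps)) > 0, net$reactions)
    if (length(bad))
      warning("unbalanced reaction(s): ",
              paste(vapply(bad, `[[`, "", "id"), collapse = ", "))
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a medium as two-column TSV
#'
#' Format: a `# dilution_rate <value>` header comment followed by
#' `compound<TAB>mM` rows.
#'
#' @param med A [medium].
#' @param path File path.
#' @return `path` / the [medium].
#' @export
write_medium_tsv <- function(med, path) {
  stopifnot(inherits(med, "medium"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# dilution_rate %.15g", med$dilution_rate), con)
  writeLines("compound\tmM", con)
  writeLines(sprintf("%s\t%.15g", names(med$concentrations),
                     med$concentrations), con)
  invisible(path)
}

#' @rdname write_medium_tsv
#' @export
read_medium_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*dilution_rate\\s+([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2) stop("missing '# dilution_rate' header in ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("compound", "mM") %in% names(df)))
    stop("medium TSV needs columns 'compound' and 'mM': ", path)
  medium(setNames(df$mM, df$compound), as.numeric(m[2]))
}

#' Write / read a conversion vector as two-column TSV
#'
#' Format: optional `# biomass_rate <value>` header comment, then
#' `compound<TAB>rate` rows (mmol l^-1 day^-1).
#'
#' @param cv A [conversion_vector].
#' @param path File path.
#' @return `path` / the [conversion_vector].
#' @export
write_conversions_tsv <- function(cv, path) {
  stopifnot(inherits(cv, "conversion_vector"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.na(cv$biomass_rate))
    writeLines(sprintf("# biomass_rate %.15g", cv$biomass_rate), con)
  writeLines("compound\trate", con)
  writeLines(sprintf("%s\t%.15g", names(cv$rates), cv$rates), con)
  invisible(path)
}

#' @rdname write_conversions_tsv
#' @export
read_conversions_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*biomass_rate\\s+([0-9.eE+-]+)", first))[[1]]
  biomass <- if (length(m) >= 2) as.numeric(m[2]) else NA_real_
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("compound", "rate") %in% names(df)))
    stop("conversion TSV needs columns 'compound' and 'rate': ", path)
  conversion_vector(setNames(df$rate, df$compound), biomass)
}

#' Read a per-ORF count table from TSV
#'
#' Expects columns `orf_id`, `bin_id`, `length`, `count` and optionally
#' `family`; validation (positive lengths, unique ORFs) as in
#' [count_table()].
#'
#' @param path TSV file.
#' @return A [count_table].
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  count_table(df)
}

#' @rdname read_count_table
#' @param counts A [count_table].
#' @export
write_count_table <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fit report (JSON summary + TSV flux table)
#'
#' @param fit A `community_fit` from [fit_community()].
#' @param prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>_fluxes.tsv`.
#' @return Character vector of the files written, invisibly.
#' @export
write_fit_report <- function(fit, prefix) {
  stopifnot(inherits(fit, "community_fit"))
  json_path <- paste0(prefix, ".json")
  tsv_path <- paste0(prefix, "_fluxes.tsv")
  jsonlite::write_json(list(
    scenario = fit$scenario,
    residual_norm = fit$residual_norm,
    community_yield = fit$community_yield,
    rates = as.list(fit$rates),
    population_growth = as.list(fit$population_growth),
    abundances = as.list(fit$abundances),
    modeled = as.list(fit$modeled$rates),
    biomass_rate = fit$modeled$biomass_rate
  ), json_path, auto_unbox = TRUE, digits = NA)
  en <- yield_report(fit$network$reactions)
  en$rate <- fit$rates[en$id]
  utils::write.table(en, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
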