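#' Load a metabolic network model
#'
#' Reads SBML Level 3 (with FBC flux bounds), BIGG JSON, or the package's
#' plain TSV dialect into a [metabolic_network()]. Only internal
#' (non-boundary) metabolites become rows of the stoichiometric matrix;
#' exchange reactions are kept as columns. A reaction is reversible iff its
#' lower flux bound is negative (falling back to the SBML `reversible`
#' attribute when no FBC bounds are present). The biomass reaction is
#' detected by case-insensitive substring `"biomass"` unless `biomass`
#' overrides it.
#'
#' @param path Model file.
#' @param format `"auto"` (by extension: `.json`, `.xml`/`.sbml`, `.tsv`),
#'   `"sbml"`, `"bigg_json"`, or `"tsv"`.
#' @param biomass Optional biomass reaction id, overriding detection.
#' @return A [metabolic_network()].
#' @export
load_network <- function(path, format = c("auto", "sbml", "bigg_json", "tsv"),
                         biomass = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     json = "bigg_json",
                     xml = "sbml", sbml = "sbml",
                     tsv = "tsv", txt = "tsv",
                     stop("cannot infer model format from extension '.",
                          ext, "'", call. = FALSE))
  }
  net <- switch(format,
                bigg_json = read_bigg_json(path),
                sbml = read_sbml(path),
                tsv = read_network_tsv(path))
  if (!is.null(biomass)) {
    net$biomass <- biomass
    rxn_index(net, biomass)
  } else if (is.na(net$biomass)) {
    hit <- grep("biomass", net$reactions, ignore.case = TRUE, value = TRUE)
    if (length(hit)) net$biomass <- hit[1]
  }
  net
}

assemble_network <- function(met_ids, rxn_rows, reversible, boundary = NULL) {
  # rxn_rows: named list reaction -> named numeric of metabolite coefficients
  if (anyDuplicated(met_ids))
    stop("duplicate metabolite identifiers in model", call. = FALSE)
  if (anyDuplicated(names(rxn_rows)))
    stop("duplicate reaction identifiers in model", call. = FALSE)
  keep <- if (is.null(boundary)) met_ids else setdiff(met_ids, boundary)
  S <- matrix(0, length(keep), length(rxn_rows),
              dimnames = list(keep, names(rxn_rows)))
  for (j in seq_along(rxn_rows)) {
    coefs <- rxn_rows[[j]]
    coefs <- coefs[names(coefs) %in% keep]
    if (length(coefs)) S[names(coefs), j] <- S[names(coefs), j] + coefs
  }
  metabolic_network(S, reversible = reversible)
}

read_bigg_json <- function(path) {
  m <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e)
                  stop("failed to parse BIGG JSON: ", conditionMessage(e),
                       call. = FALSE))
  if (is.null(m$metabolites) || is.null(m$reactions))
    stop("not a BIGG JSON model: missing 'metabolites' or 'reactions'",
         call. = FALSE)
  met_ids <- vapply(m$metabolites, function(x) x$id, character(1))
  rxn_rows <- lapply(m$reactions, function(r)
    vapply(r$metabolites, as.numeric, numeric(1)))
  names(rxn_rows) <- vapply(m$reactions, function(x) x$id, character(1))
  reversible <- vapply(m$reactions, function(r)
    !is.null(r$lower_bound) && r$lower_bound < 0, logical(1))
  assemble_network(met_ids, rxn_rows, reversible)
}

xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop("failed to parse SBML: ", conditionMessage(e),
                         call. = FALSE))
  sp <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  if (length(sp) == 0L) stop("not an SBML model: no species found", call. = FALSE)
  met_ids <- vapply(sp, function(x) xattr(x, "id"), character(1))
  boundary <- met_ids[vapply(sp, function(x)
    identical(xattr(x, "boundaryCondition"), "true"), logical(1))]
  pars <- xml2::xml_find_all(doc, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  parval <- stats::setNames(
    vapply(pars, function(x) as.numeric(xattr(x, "value")), numeric(1)),
    vapply(pars, function(x) xattr(x, "id"), character(1)))
  rx <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxn_rows <- list(); reversible <- logical(length(rx))
  ids <- character(length(rx))
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    ids[j] <- xattr(r, "id")
    grab <- function(tag, sign) {
      refs <- xml2::xml_find_all(r, paste0("./*[local-name()='", tag,
                                           "']/*[local-name()='speciesReference']"))
      if (length(refs) == 0L) return(numeric())
      stats::setNames(
        sign * vapply(refs, function(x) {
          st <- xattr(x, "stoichiometry")
          if (is.na(st)) 1 else as.numeric(st)
        }, numeric(1)),
        vapply(refs, function(x) xattr(x, "species"), character(1)))
    }
    coefs <- c(grab("listOfReactants", -1), grab("listOfProducts", +1))
    agg <- tapply(coefs, names(coefs), sum)
    rxn_rows[[j]] <- stats::setNames(as.numeric(agg), names(agg))
    lbid <- xattr(r, "lowerFluxBound")
    reversible[j] <- if (!is.na(lbid) && lbid %in% names(parval))
      parval[[lbid]] < 0
    else identical(xattr(r, "reversible"), "true")
  }
  names(rxn_rows) <- ids
  assemble_network(met_ids, rxn_rows, reversible, boundary = boundary)
}

read_network_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, "", 1L)
  bad <- setdiff(unique(kind), c("reaction", "coef", "metabolite"))
  if (length(bad))
    stop("malformed network TSV: unknown record type '", bad[1], "'",
         call. = FALSE)
  rparts <- parts[kind == "reaction"]
  rxn_ids <- vapply(rparts, `[`, "", 2L)
  reversible <- vapply(rparts, `[`, "", 3L) == "1"
  biomass <- NULL
  flag <- vapply(rparts, function(p) length(p) >= 4 && p[4] == "biomass",
                 logical(1))
  if (any(flag)) biomass <- rxn_ids[which(flag)[1]]
  cparts <- parts[kind == "coef"]
  mets <- vapply(cparts, `[`, "", 2L)
  rxns <- vapply(cparts, `[`, "", 3L)
  vals <- as.numeric(vapply(cparts, `[`, "", 4L))
  if (anyNA(vals)) stop("malformed network TSV: non-numeric coefficient",
                        call. = FALSE)
  met_ids <- unique(c(vapply(parts[kind == "metabolite"], `[`, "", 2L), mets))
  if (anyDuplicated(rxn_ids))
    stop("duplicate reaction identifiers in TSV", call. = FALSE)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (i in seq_along(vals)) S[mets[i], rxns[i]] <- S[mets[i], rxns[i]] + vals[i]
  metabolic_network(S, reversible = reversible, biomass = biomass)
}

#' Write a metabolic network model
#'
#' Writes the TSV dialect (`reaction` rows carrying reversibility and the
#' biomass flag; `coef` rows carrying stoichiometry) or a minimal SBML
#' Level 3 document. Both round-trip exactly through [load_network()].
#'
#' @param net A [metabolic_network()].
#' @param path Output file.
#' @param format `"tsv"` or `"sbml"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "tsv", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "tsv"
  }
  if (format == "tsv") write_network_tsv(net, path) else write_sbml(net, path)
}

write_network_tsv <- function(net, path) {
  rl <- vapply(seq_along(net$reactions), function(j) {
    base <- paste("reaction", net$reactions[j],
                  as.integer(net$reversible[j]), sep = "\t")
    if (!is.na(net$biomass) && net$biomass == net$reactions[j])
      paste(base, "biomass", sep = "\t") else base
  }, character(1))
  ml <- paste("metabolite", net$metabolites, sep = "\t")
  idx <- which(net$S != 0, arr.ind = TRUE)
  cl <- paste("coef", net$metabolites[idx[, 1]], net$reactions[idx[, 2]],
              format(net$S[idx], trim = TRUE, digits = 15), sep = "\t")
  writeLines(c(rl, ml, cl), path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_sbml <- function(net, path) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
           '<model id="model">',
           '<listOfSpecies>')
  out <- c(out, sprintf(
    '<species id="%s" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>',
    xml_escape(net$metabolites)))
  out <- c(out, '</listOfSpecies>', '<listOfReactions>')
  for (j in seq_along(net$reactions)) {
    col <- net$S[, j]
    out <- c(out, sprintf('<reaction id="%s" reversible="%s" fast="false">',
                          xml_escape(net$reactions[j]),
                          tolower(as.character(net$reversible[j]))))
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs)) {
      out <- c(out, '<listOfReactants>',
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       xml_escape(net$metabolites[subs]),
                       format(-col[subs], trim = TRUE, digits = 15)),
               '</listOfReactants>')
    }
    if (length(prods)) {
      out <- c(out, '<listOfProducts>',
               sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       xml_escape(net$metabolites[prods]),
                       format(col[prods], trim = TRUE, digits = 15)),
               '</listOfProducts>')
    }
    out <- c(out, '</reaction>')
  }
  out <- c(out, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(out, path)
  invisible(path)
}
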