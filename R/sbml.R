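# SBML level 3 serialization ---------------------------------------------
#
# Every model in this package is a mass-action network with at most two
# reactants and two products, so the exported SBML uses exactly that
# subset: global parameters for the rate constants and kinetic laws of
# the form k * S1 [* S2].  The importer accepts only this subset and
# raises an explicit unsupported-feature error on anything else, which
# is enough for loss-free round trips of the package's own models.

.SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
.MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

#' Export a reaction network as SBML
#'
#' @param net a [mk_network()] network.
#' @param path output file; the document is also returned invisibly.
#' @param model_id SBML model id.
#' @export
sbml_export <- function(net, path, model_id = "ubithresh_model") {
  stopifnot(inherits(net, "reaction_network"))
  esc <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  sp_id <- stats::setNames(paste0("s_", esc(net$species)), net$species)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="3" version="2">', .SBML_NS),
    sprintf('<model id="%s">', model_id),
    '<listOfCompartments><compartment id="cell" size="1" constant="true"/></listOfCompartments>',
    '<listOfSpecies>')
  for (s in net$species) {
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" compartment="cell" initialAmount="%.17g" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
      sp_id[[s]], s, net$x0[[s]]))
  }
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>')
  for (k in names(net$rates)) {
    lines <- c(lines, sprintf(
      '<parameter id="%s" value="%.17g" constant="true"/>',
      paste0("k_", esc(k)), net$rates[[k]]))
  }
  lines <- c(lines, '</listOfParameters>', '<listOfReactions>')
  for (j in seq_along(net$reactions)) {
    rx <- net$reactions[[j]]
    ref <- function(sps, listtag) {
      if (!length(sps)) return(character(0))
      tab <- table(sps)
      c(sprintf('<%s>', listtag),
        sprintf('<speciesReference species="%s" stoichiometry="%d" constant="true"/>',
                sp_id[names(tab)], as.integer(tab)),
        sprintf('</%s>', listtag))
    }
    math_terms <- c(paste0("k_", esc(net$rate_name[j])),
                    sp_id[rx$reactants])
    math <- paste0("<apply><times/>",
                   paste0("<ci>", math_terms, "</ci>", collapse = ""),
                   "</apply>")
    if (length(math_terms) == 1L) {
      math <- paste0("<ci>", math_terms, "</ci>")
    }
    lines <- c(lines,
      sprintf('<reaction id="r_%d" reversible="false">', j),
      ref(rx$reactants, "listOfReactants"),
      ref(rx$products, "listOfProducts"),
      '<kineticLaw>',
      sprintf('<math xmlns="%s">%s</math>', .MATHML_NS, math),
      '</kineticLaw>',
      '</reaction>')
  }
  lines <- c(lines, '</listOfReactions>', '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

.sbml_unsupported <- function(what) {
  stop("unsupported SBML construct: ", what, call. = FALSE)
}

#' Import an SBML document written by [sbml_export()]
#'
#' @param path SBML file.
#' @return a \code{reaction_network}.  Documents using constructs
#'   outside the package's mass-action subset (function definitions,
#'   rules, events, non-product kinetic laws) raise an explicit error;
#'   malformed XML raises a parse error.
#' @export
sbml_import <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) .sbml_unsupported("document without <model>")
  for (bad in c("listOfFunctionDefinitions", "listOfRules", "listOfEvents",
                "listOfConstraints", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model, paste0(".//", bad)),
                  "xml_missing")) .sbml_unsupported(bad)
  }
  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp_nodes)) .sbml_unsupported("model without species")
  ids <- xml2::xml_attr(sp_nodes, "id")
  nms <- xml2::xml_attr(sp_nodes, "name")
  nms[is.na(nms)] <- ids[is.na(nms)]
  x0 <- stats::setNames(as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
                        nms)
  id2name <- stats::setNames(nms, ids)
  par_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  rates <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                           sub("^k_", "", xml2::xml_attr(par_nodes, "id")))
  par_ids <- xml2::xml_attr(par_nodes, "id")
  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(rx) {
    grab <- function(xp) {
      refs <- xml2::xml_find_all(rx, xp)
      sp <- xml2::xml_attr(refs, "species")
      st <- as.integer(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1L
      rep(unname(id2name[sp]), st)
    }
    cis <- xml2::xml_find_all(rx, ".//kineticLaw//ci")
    if (!length(cis)) .sbml_unsupported("kinetic law without <ci> terms")
    terms <- trimws(xml2::xml_text(cis))
    kterm <- terms[terms %in% par_ids]
    if (length(kterm) != 1L) {
      .sbml_unsupported("kinetic law that is not rate-constant times reactants")
    }
    reactants <- grab(".//listOfReactants/speciesReference")
    sterms <- sort(unname(id2name[terms[!terms %in% par_ids]]))
    if (!identical(sort(reactants), sterms)) {
      .sbml_unsupported("kinetic law inconsistent with mass action")
    }
    list(rate = sub("^k_", "", kterm),
         reactants = reactants,
         products = grab(".//listOfProducts/speciesReference"))
  })
  mk_network(nms, x0, reactions, rates)
}

#' Round-trip a network through SBML
#'
#' Exports, re-imports and checks that the network comes back with the
#' same species, reactions and simulated trajectories.
#'
#' @param net a \code{reaction_network}.
#' @param times simulation times used for the trajectory comparison.
#' @param tol maximum tolerated trajectory deviation.
#' @return list with the re-imported network and the maximum deviation.
#' @export
sbml_roundtrip <- function(net, times = seq(0, 2, length.out = 21L),
                           tol = 1e-8) {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  sbml_export(net, path)
  back <- sbml_import(path)
  if (!setequal(net$species, back$species)) {
    stop("round trip changed the species set")
  }
  if (length(net$reactions) != length(back$reactions)) {
    stop("round trip changed the reaction count")
  }
  a <- simulate_network(net, times)
  b <- simulate_network(back, times)
  dev <- max(abs(a[, net$species] - b[, net$species]))
  scale <- max(abs(a[, net$species]), 1)
  if (dev > tol * scale) {
    stop("round-trip trajectories deviate by ", signif(dev, 3))
  }
  list(network = back, max_deviation = dev)
}
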