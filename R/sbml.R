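#' Read a metabolic model from SBML
#'
#' Pragmatic reader for SBML Level 3 documents carrying the flux-balance
#' (`fbc`) extension: species, reactions with reactant/product
#' stoichiometries, flux bounds referenced through parameters (or inline
#' `fbc:lowerFluxBound`-style numeric attributes), gene associations as
#' nested `fbc:and` / `fbc:or` / `fbc:geneProductRef` elements, and the
#' active objective for the target reaction. Elements are matched by local
#' name, so namespace prefixes other than `fbc` are tolerated.
#'
#' @param path SBML file path.
#' @param target target reaction id; required when the file declares no flux
#'   objective.
#' @return a validated [metabolic_model()].
#' @export
read_sbml_model <- function(path, target = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse SBML file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) {
    stop("no <model> element in ", path, call. = FALSE)
  }
  id <- xml2::xml_attr(model_node, "id")
  if (is.na(id)) id <- basename(path)

  species <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- mets[!boundary]

  params <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx_nodes)) stop("no reactions in ", path, call. = FALSE)
  n <- length(rx_nodes)
  rxns <- xml2::xml_attr(rx_nodes, "id")
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)

  resolve_bound <- function(attr_val, default) {
    if (is.na(attr_val)) return(default)
    num <- suppressWarnings(as.numeric(attr_val))
    if (!is.na(num)) return(num)
    if (attr_val %in% names(pval)) return(pval[[attr_val]])
    stop("flux bound parameter '", attr_val, "' is undefined", call. = FALSE)
  }

  for (j in seq_len(n)) {
    nd <- rx_nodes[[j]]
    rev_attr <- xml2::xml_attr(nd, "reversible") %in% "true"
    lb[j] <- resolve_bound(xml_attr_any(nd, "lowerFluxBound"),
                           if (rev_attr) -1000 else 0)
    ub[j] <- resolve_bound(xml_attr_any(nd, "upperFluxBound"), 1000)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(nd, paste0("./*[local-name()='", side,
        "']/*[local-name()='speciesReference']"))
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      keep <- sp %in% mets
      sp <- sp[keep]
      if (!length(sp)) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))[keep]
      coef[is.na(coef)] <- 1
      trip_i <- c(trip_i, match(sp, mets))
      trip_j <- c(trip_j, rep(j, length(sp)))
      trip_x <- c(trip_x, sgn * coef)
    }
    ga <- xml2::xml_find_first(nd,
      "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(ga, "xml_missing")) "" else {
      kids <- xml2::xml_find_all(ga, "./*")
      if (!length(kids)) "" else
        tryCatch(sbml_assoc_to_rule(kids[[1]]),
                 error = function(e) {
                   stop("unparseable gene association on reaction '",
                        rxns[j], "': ", conditionMessage(e), call. = FALSE)
                 })
    }
  }
  S <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(mets), n))

  gp_nodes <- xml2::xml_find_all(model_node,
    ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  genes <- vapply(gp_nodes, xml_attr_any, character(1), name = "id")
  labels <- vapply(gp_nodes, xml_attr_any, character(1), name = "label")
  genes[!is.na(labels) & nzchar(labels)] <-
    labels[!is.na(labels) & nzchar(labels)]

  if (is.null(target)) {
    fo <- xml2::xml_find_first(model_node,
      ".//*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) target <- xml_attr_any(fo, "reaction")
  }
  if (is.null(target) || is.na(target)) {
    stop("SBML file ", path, " declares no flux objective; supply the ",
         "target reaction explicitly", call. = FALSE)
  }
  metabolic_model(mets, rxns, S, lb, ub, gpr,
                  genes = if (length(genes)) unique(genes) else NULL,
                  target = target, id = id)
}

## Attribute lookup tolerant of namespace prefixes ("fbc:id" vs "id").
xml_attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (!length(hit)) NA_character_ else unname(at[hit[1]])
}

## fbc association subtree -> rule string. geneProduct attributes may carry
## the raw gene id or a geneProduct SId resolved via label upstream.
sbml_assoc_to_rule <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml_attr_any(node, "geneProduct")
    if (is.na(g)) stop("geneProductRef without geneProduct attribute")
    return(g)
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_find_all(node, "./*")
    if (!length(kids)) stop("empty <", nm, "> association")
    parts <- vapply(kids, sbml_assoc_to_rule, character(1))
    return(paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")"))
  }
  stop("unsupported association element <", nm, ">")
}

#' Write a metabolic model to SBML (Level 3 + fbc)
#'
#' Inverse of [read_sbml_model()] for the subset this package uses; bounds
#' are emitted as shared parameters, GPRs as `fbc:geneProductAssociation`
#' trees, and the target reaction as the active flux objective.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  ln <- character(0)
  push <- function(...) ln <<- c(ln, paste0(...))
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
       'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
       'level="3" version="1" fbc:required="false">')
  push('  <model id="', esc(model$id), '" fbc:strict="true">')
  push('    <listOfCompartments>')
  push('      <compartment id="c" constant="true"/>')
  push('    </listOfCompartments>')
  push('    <listOfSpecies>')
  for (m in model$mets) {
    push('      <species id="', esc(m), '" compartment="c" ',
         'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
         'constant="false"/>')
  }
  push('    </listOfSpecies>')
  push('    <listOfParameters>')
  bounds <- sort(unique(c(model$lb, model$ub)))
  bid <- function(v) paste0("B_", gsub("[^0-9A-Za-z]", "_", format(v,
    scientific = FALSE, trim = TRUE)))
  for (v in bounds) {
    push('      <parameter id="', bid(v), '" value="',
         format(v, scientific = FALSE, trim = TRUE),
         '" constant="true"/>')
  }
  push('    </listOfParameters>')
  push('    <listOfReactions>')
  Sd <- as.matrix(model$S)
  for (j in seq_along(model$rxns)) {
    push('      <reaction id="', esc(model$rxns[j]), '" reversible="',
         tolower(model$lb[j] < 0), '" fast="false" fbc:lowerFluxBound="',
         bid(model$lb[j]), '" fbc:upperFluxBound="', bid(model$ub[j]), '">')
    reac <- which(Sd[, j] < 0); prod <- which(Sd[, j] > 0)
    if (length(reac)) {
      push('        <listOfReactants>')
      for (i in reac) {
        push('          <speciesReference species="', esc(model$mets[i]),
             '" stoichiometry="', format(-Sd[i, j], scientific = FALSE),
             '" constant="true"/>')
      }
      push('        </listOfReactants>')
    }
    if (length(prod)) {
      push('        <listOfProducts>')
      for (i in prod) {
        push('          <speciesReference species="', esc(model$mets[i]),
             '" stoichiometry="', format(Sd[i, j], scientific = FALSE),
             '" constant="true"/>')
      }
      push('        </listOfProducts>')
    }
    if (nzchar(model$gpr[j])) {
      push('        <fbc:geneProductAssociation>')
      push(rule_to_sbml_assoc(model$rules[[j]], indent = 10L))
      push('        </fbc:geneProductAssociation>')
    }
    push('      </reaction>')
  }
  push('    </listOfReactions>')
  if (length(model$genes)) {
    push('    <fbc:listOfGeneProducts>')
    for (g in model$genes) {
      push('      <fbc:geneProduct fbc:id="', esc(g), '" fbc:label="',
           esc(g), '"/>')
    }
    push('    </fbc:listOfGeneProducts>')
  }
  push('    <fbc:listOfObjectives fbc:activeObjective="obj">')
  push('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
  push('        <fbc:listOfFluxObjectives>')
  push('          <fbc:fluxObjective fbc:reaction="', esc(model$target),
       '" fbc:coefficient="1"/>')
  push('        </fbc:listOfFluxObjectives>')
  push('      </fbc:objective>')
  push('    </fbc:listOfObjectives>')
  push('  </model>')
  push('</sbml>')
  writeLines(ln, path)
  invisible(path)
}

rule_to_sbml_assoc <- function(expr, indent = 0L) {
  pad <- strrep(" ", indent)
  if (expr$op == "gene") {
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="', expr$id,
                  '"/>'))
  }
  inner <- vapply(expr$args, rule_to_sbml_assoc, character(1),
                  indent = indent + 2L)
  paste0(pad, "<fbc:", expr$op, ">\n",
         paste(inner, collapse = "\n"), "\n",
         pad, "</fbc:", expr$op, ">")
}
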