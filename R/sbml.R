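ns_uri <- c(
  l3core = "http://www.sbml.org/sbml/level3/version1/core",
  l2v4   = "http://www.sbml.org/sbml/level2/version4",
  fbc    = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  rdf    = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  bqbiol = "http://biomodels.net/biology-qualifiers/",
  xhtml  = "http://www.w3.org/1999/xhtml",
  mathml = "http://www.w3.org/1998/Math/MathML"
)

# attribute lookup tolerant of namespace prefixes ("fbc:lowerFluxBound" or
# "lowerFluxBound", whatever the serialiser chose)
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  if (!length(at)) return(NA_character_)
  hit <- which(names(at) == name |
                 endsWith(names(at), paste0(":", name)))
  if (length(hit)) unname(at[hit[1L]]) else NA_character_
}

xfind <- function(node, local) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", local))
}
xfind1 <- function(node, local) {
  xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", local))
}

#' Read a metabolic model from SBML
#'
#' Supports the two dialects distributed for the consensus yeast network: a
#' Level 3 file using the Flux Balance Constraints (FBC) package, and the
#' older Level 2 COBRA-compatible encoding (bounds in per-reaction
#' `kineticLaw` parameters, GPRs in a `GENE_ASSOCIATION` notes line). The
#' dialect is auto-detected from the document namespaces unless given.
#' MIRIAM-style controlled-vocabulary annotations (ChEBI, UniProt, PubMed
#' via `identifiers.org` or `urn:miriam:` resources) are parsed into
#' `external_refs`/`pubmed_refs`; parsing legacy PMID lists out of Notes
#' fields is off unless `notes_fallback = TRUE`, since the convention
#' followed here encodes annotations per the SBML specification rather than
#' in COBRA Notes fields.
#'
#' Species flagged `boundaryCondition="true"` are treated as outside the
#' system boundary and removed from stoichiometries (the usual COBRA
#' convention), which turns `A -> A_boundary` encodings into ordinary
#' single-metabolite exchange reactions.
#'
#' @param path SBML file.
#' @param dialect `NULL` to auto-detect, or one of `"fbc3"`, `"cobra_l2"`,
#'   `"reconstruction_only"`.
#' @param notes_fallback Also scavenge PubMed ids from Notes fields.
#' @return A `gem_model`.
#' @export
read_model <- function(path, dialect = NULL, notes_fallback = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse failure in '", path, "': ", conditionMessage(e)))
  root_ns <- unlist(xml2::xml_ns(doc))
  has_fbc <- any(root_ns == ns_uri[["fbc"]])
  is_l2 <- any(grepl("sbml/level2", root_ns))
  if (is.null(dialect))
    dialect <- if (has_fbc) "fbc3" else if (is_l2) "cobra_l2"
      else stop("cannot detect SBML dialect of '", path,
                "': neither the FBC namespace nor a level 2 namespace found")
  model_node <- xfind1(doc, "model")
  if (is.na(model_node) || inherits(model_node, "xml_missing"))
    stop("format error: no <model> element in '", path, "'")

  comp_nodes <- xfind(model_node, "compartment")
  compartments <- stats::setNames(
    vapply(comp_nodes, function(n) {
      nm <- xattr(n, "name"); if (is.na(nm)) xattr(n, "id") else nm
    }, character(1)),
    vapply(comp_nodes, function(n) xattr(n, "id"), character(1)))

  # --- species ---------------------------------------------------------
  sp_nodes <- xfind(model_node, "species")
  boundary_ids <- character(0)
  mets <- list()
  for (n in sp_nodes) {
    id <- xattr(n, "id")
    if (is.na(id)) stop("format error: species without id in '", path, "'")
    if (identical(xattr(n, "boundaryCondition"), "true")) {
      boundary_ids <- c(boundary_ids, id); next
    }
    nm <- xattr(n, "name"); if (is.na(nm)) nm <- id
    refs <- parse_cv_terms(n)
    mets[[length(mets) + 1L]] <- metabolite_row(
      id, nm, xattr(n, "compartment"),
      is_biomass = grepl("biomass", nm, ignore.case = TRUE) ||
        grepl("biomass", id, ignore.case = TRUE),
      external_refs = refs$refs)
  }
  metabolites <- if (length(mets)) do.call(rbind, mets)
    else empty_metabolite_table()

  # --- gene products (fbc) --------------------------------------------
  gp_map <- character(0)   # geneProduct SId -> gene label
  genes <- list()
  if (dialect != "cobra_l2") {
    for (n in xfind(model_node, "geneProduct")) {
      gpid <- xattr(n, "id"); label <- xattr(n, "label")
      if (is.na(label)) label <- gpid
      gp_map[gpid] <- label
      refs <- parse_cv_terms(n)
      genes[[length(genes) + 1L]] <-
        gene_row(label, standard_name = xattr(n, "name"),
                 external_refs = refs$refs)
    }
  }

  # --- global bound parameters (fbc) ----------------------------------
  par_nodes <- xml2::xml_find_all(model_node,
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    suppressWarnings(as.numeric(vapply(par_nodes, xattr, character(1),
                                       name = "value"))),
    vapply(par_nodes, xattr, character(1), name = "id"))

  # --- reactions ------------------------------------------------------
  rxns <- list()
  obj_from_l2 <- NA_character_
  for (n in xfind(model_node, "reaction")) {
    id <- xattr(n, "id")
    if (is.na(id)) stop("format error: reaction without id in '", path, "'")
    nm <- xattr(n, "name"); if (is.na(nm)) nm <- id
    stoich <- numeric(0)
    for (kind in c("listOfReactants", "listOfProducts")) {
      sgn <- if (kind == "listOfReactants") -1 else 1
      box <- xml2::xml_find_first(n, sprintf("./*[local-name()='%s']", kind))
      if (inherits(box, "xml_missing")) next
      for (sr in xml2::xml_find_all(box,
             "./*[local-name()='speciesReference']")) {
        sp <- xattr(sr, "species")
        co <- xattr(sr, "stoichiometry")
        co <- if (is.na(co)) 1 else as.numeric(co)
        if (sp %in% boundary_ids) next
        stoich[sp] <- (if (sp %in% names(stoich)) stoich[[sp]] else 0) +
          sgn * co
      }
    }
    stoich <- stoich[stoich != 0]
    if (!length(stoich))
      stop("format error: reaction '", id,
           "' has no (non-boundary) stoichiometry")

    rev_attr <- xattr(n, "reversible")
    if (dialect == "cobra_l2") {
      klaw <- xml2::xml_find_first(n, "./*[local-name()='kineticLaw']")
      lbv <- ubv <- NA_real_
      if (!inherits(klaw, "xml_missing")) {
        for (p in xml2::xml_find_all(klaw, ".//*[local-name()='parameter']")) {
          pid <- xattr(p, "id")
          pv <- suppressWarnings(as.numeric(xattr(p, "value")))
          if (identical(pid, "LOWER_BOUND")) lbv <- pv
          if (identical(pid, "UPPER_BOUND")) ubv <- pv
          if (identical(pid, "OBJECTIVE_COEFFICIENT") && !is.na(pv) &&
              pv != 0) obj_from_l2 <- id
        }
      }
      if (is.na(lbv) || is.na(ubv)) {
        rev <- if (is.na(rev_attr)) TRUE else identical(rev_attr, "true")
        if (is.na(lbv)) lbv <- if (rev) -Inf else 0
        if (is.na(ubv)) ubv <- Inf
      }
    } else {
      lb_ref <- xattr(n, "lowerFluxBound")
      ub_ref <- xattr(n, "upperFluxBound")
      lbv <- if (!is.na(lb_ref) && lb_ref %in% names(par_val))
        par_val[[lb_ref]] else NA_real_
      ubv <- if (!is.na(ub_ref) && ub_ref %in% names(par_val))
        par_val[[ub_ref]] else NA_real_
      if (is.na(lbv) || is.na(ubv)) {
        if (is.na(rev_attr))
          stop("bound missing and not inferable for reaction '", id, "'")
        rev <- identical(rev_attr, "true")
        if (is.na(lbv)) lbv <- if (rev) -Inf else 0
        if (is.na(ubv)) ubv <- Inf
      }
    }

    # GPR
    g <- gpr_empty()
    if (dialect == "cobra_l2") {
      txt <- notes_text(n)
      ga <- regmatches(txt,
        regexpr("GENE[ _]ASSOCIATION:[^\n<]*", txt))
      if (length(ga)) {
        expr <- trimws(sub("GENE[ _]ASSOCIATION:", "", ga[1L]))
        g <- parse_gpr(expr)
      }
    } else {
      gpa <- xml2::xml_find_first(n,
        "./*[local-name()='geneProductAssociation']")
      if (!inherits(gpa, "xml_missing")) {
        kids <- xml2::xml_find_all(gpa, "./*")
        if (length(kids)) g <- parse_fbc_association(kids[[1L]], gp_map)
      }
    }

    refs <- parse_cv_terms(n)
    pm <- refs$pubmed
    if (notes_fallback) {
      txt <- notes_text(n)
      hits <- regmatches(txt, gregexpr("PMID:? ?([0-9]+)", txt))[[1L]]
      if (length(hits)) pm <- unique(c(pm, gsub("[^0-9]", "", hits)))
    }

    rxns[[length(rxns) + 1L]] <- reaction_row(
      id, nm, stoich, lbv, ubv, gpr = g, pubmed_refs = pm,
      is_exchange = length(stoich) == 1L)
  }
  reactions <- if (length(rxns)) do.call(rbind, rxns)
    else empty_reaction_table()

  # genes for L2 files: implied by the GPR strings
  if (dialect == "cobra_l2") {
    ids <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
    genes <- lapply(ids, gene_row)
  }
  gene_tab <- if (length(genes)) do.call(rbind, genes) else empty_gene_table()
  unknown <- setdiff(unique(unlist(lapply(reactions$gpr, gpr_genes))),
                     gene_tab$id)
  if (length(unknown))
    stop("GPR references unknown gene identifier(s): ",
         paste(unknown, collapse = ", "))

  # --- objective ------------------------------------------------------
  obj_id <- NA_character_; sense <- "maximize"
  if (dialect == "cobra_l2") {
    obj_id <- obj_from_l2
  } else {
    fo <- xfind1(model_node, "fluxObjective")
    if (!inherits(fo, "xml_missing")) {
      obj_id <- xattr(fo, "reaction")
      on2 <- xfind1(model_node, "objective")
      ty <- xattr(on2, "type")
      if (!is.na(ty) && ty == "minimize") sense <- "minimize"
    }
  }
  if (dialect == "fbc3" && is.na(obj_id)) dialect <- "reconstruction_only"

  gem_model(
    id = { i <- xattr(model_node, "id"); if (is.na(i)) "model" else i },
    name = { nmm <- xattr(model_node, "name")
             if (is.na(nmm)) "" else nmm },
    compartments = compartments,
    metabolites = metabolites, reactions = reactions, genes = gene_tab,
    objective_reaction_id = obj_id, objective_sense = sense,
    dialect = dialect)
}

# MIRIAM controlled-vocabulary terms on one element: returns pubmed ids and
# a (database, accession) table for everything else.
parse_cv_terms <- function(node) {
  lis <- xml2::xml_find_all(node,
    ".//*[local-name()='annotation']//*[local-name()='li']")
  pubmed <- character(0)
  db <- character(0); acc <- character(0)
  for (li in lis) {
    res <- xattr(li, "resource")
    if (is.na(res)) next
    m <- regmatches(res,
      regexec("identifiers\\.org/([^/]+)/(.+)$", res))[[1L]]
    if (length(m) != 3L) {
      m <- regmatches(res, regexec("urn:miriam:([^:]+):(.+)$", res))[[1L]]
      if (length(m) == 3L) m[3L] <- utils::URLdecode(m[3L])
    }
    if (length(m) != 3L) next
    d <- tolower(m[2L]); a <- m[3L]
    if (d == "pubmed") pubmed <- c(pubmed, a)
    else { db <- c(db, d); acc <- c(acc, a) }
  }
  list(pubmed = unique(pubmed),
       refs = data.frame(database = db, accession = acc,
                         stringsAsFactors = FALSE))
}

notes_text <- function(node) {
  nts <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(nts, "xml_missing")) return("")
  paste(xml2::xml_text(xml2::xml_find_all(nts, ".//text()")), collapse = "\n")
}

parse_fbc_association <- function(node, gp_map) {
  loc <- xml2::xml_name(node)
  if (loc == "geneProductRef") {
    gp <- xattr(node, "geneProduct")
    lbl <- if (gp %in% names(gp_map)) gp_map[[gp]] else gp
    return(gpr_leaf(lbl))
  }
  kids <- lapply(xml2::xml_find_all(node, "./*"),
                 parse_fbc_association, gp_map = gp_map)
  if (loc == "and") gpr_and(kids)
  else if (loc == "or") gpr_or(kids)
  else stop("format error: unexpected element <", loc,
            "> inside geneProductAssociation")
}

#' Write a metabolic model to SBML
#'
#' Emits either the Level 3 + FBC dialect (`"fbc3"`), the Level 2
#' COBRA-compatible dialect (`"cobra_l2"`; bounds as kineticLaw parameters,
#' GPR as a `GENE_ASSOCIATION` notes line), or a `"reconstruction_only"`
#' Level 3 file that refuses to carry an objective. Infinite bounds are
#' written as +/- `cap`, the de-facto interchange convention; annotations
#' are written as MIRIAM controlled-vocabulary RDF terms.
#'
#' @param model A valid `gem_model`.
#' @param path Output file.
#' @param dialect Target dialect (defaults to the model's own).
#' @param cap Magnitude substituted for infinite bounds on write.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = model$dialect, cap = 1000) {
  dialect <- match.arg(dialect, c("fbc3", "cobra_l2", "reconstruction_only"))
  validate_model(model)
  if (dialect == "reconstruction_only" && !is.na(model$objective_reaction_id))
    stop("capability error: the reconstruction_only dialect cannot carry ",
         "an objective (reaction '", model$objective_reaction_id, "')")
  if (dialect == "cobra_l2") write_model_l2(model, path, cap)
  else write_model_fbc(model, path, cap,
                       with_objective = dialect == "fbc3")
  invisible(path)
}

fin <- function(x, cap) {
  x[x == -Inf] <- -cap; x[x == Inf] <- cap; x
}

num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

add_cv <- function(parent, metaid, pubmed = character(0), refs = no_refs()) {
  if (!length(pubmed) && !nrow(refs)) return(invisible(NULL))
  ann <- xml2::xml_add_child(parent, "annotation")
  rdf <- xml2::xml_add_child(ann, "rdf:RDF")
  desc <- xml2::xml_add_child(rdf, "rdf:Description",
                              "rdf:about" = paste0("#", metaid))
  if (nrow(refs)) {
    q <- xml2::xml_add_child(desc, "bqbiol:is")
    bag <- xml2::xml_add_child(q, "rdf:Bag")
    for (k in seq_len(nrow(refs)))
      xml2::xml_add_child(bag, "rdf:li",
        "rdf:resource" = paste0("http://identifiers.org/",
                                refs$database[k], "/", refs$accession[k]))
  }
  if (length(pubmed)) {
    q <- xml2::xml_add_child(desc, "bqbiol:isDescribedBy")
    bag <- xml2::xml_add_child(q, "rdf:Bag")
    for (p in pubmed)
      xml2::xml_add_child(bag, "rdf:li",
        "rdf:resource" = paste0("http://identifiers.org/pubmed/", p))
  }
  invisible(NULL)
}

write_model_fbc <- function(model, path, cap, with_objective = TRUE) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = ns_uri[["l3core"]],
    "xmlns:fbc" = ns_uri[["fbc"]],
    "xmlns:rdf" = ns_uri[["rdf"]],
    "xmlns:bqbiol" = ns_uri[["bqbiol"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, name = model$name,
                             "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$compartments))
    xml2::xml_add_child(lc, "compartment", id = cid,
                        name = model$compartments[[cid]],
                        constant = "true")

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = mt$id,
      metaid = paste0("meta_", mt$id), name = mt$name,
      compartment = mt$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    add_cv(sp, paste0("meta_", mt$id), refs = mt$external_refs[[1L]])
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  rxn <- model$reactions
  for (i in seq_len(nrow(rxn))) {
    xml2::xml_add_child(lp, "parameter", id = paste0(rxn$id[i], "_lb"),
      value = num(fin(rxn$lower_bound[i], cap)), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(rxn$id[i], "_ub"),
      value = num(fin(rxn$upper_bound[i], cap)), constant = "true")
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(rxn))) {
    r <- xml2::xml_add_child(lr, "reaction", id = rxn$id[i],
      metaid = paste0("meta_", rxn$id[i]), name = rxn$name[i],
      reversible = if (fin(rxn$lower_bound[i], cap) < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = paste0(rxn$id[i], "_lb"),
      "fbc:upperFluxBound" = paste0(rxn$id[i], "_ub"))
    add_cv(r, paste0("meta_", rxn$id[i]), pubmed = rxn$pubmed_refs[[i]])
    s <- rxn$stoichiometry[[i]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      box <- xml2::xml_add_child(r, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(box, "speciesReference",
          species = names(reac)[k], stoichiometry = num(-reac[[k]]),
          constant = "true")
    }
    if (length(prod)) {
      box <- xml2::xml_add_child(r, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(box, "speciesReference",
          species = names(prod)[k], stoichiometry = num(prod[[k]]),
          constant = "true")
    }
    g <- rxn$gpr[[i]]
    if (g$type != "empty") {
      gpa <- xml2::xml_add_child(r, "fbc:geneProductAssociation")
      write_fbc_association(gpa, g)
    }
  }

  if (with_objective && !is.na(model$objective_reaction_id)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = model$objective_sense)
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = model$objective_reaction_id,
                        "fbc:coefficient" = "1")
  }

  if (nrow(model$genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (i in seq_len(nrow(model$genes))) {
      gn <- model$genes[i, ]
      gp <- xml2::xml_add_child(lg, "fbc:geneProduct",
        metaid = paste0("meta_G_", gn$id),
        "fbc:id" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", gn$id)),
        "fbc:label" = gn$id)
      if (!is.na(gn$standard_name))
        xml2::xml_set_attr(gp, "fbc:name", gn$standard_name)
      add_cv(gp, paste0("meta_G_", gn$id), refs = gn$external_refs[[1L]])
    }
  }

  xml2::write_xml(doc, path)
}

write_fbc_association <- function(parent, g) {
  if (g$type == "leaf") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
      "fbc:geneProduct" = paste0("G_", gsub("[^A-Za-z0-9_]", "_", g$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", g$type))
    for (k in g$children) write_fbc_association(node, k)
  }
  invisible(NULL)
}

write_model_l2 <- function(model, path, cap) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = ns_uri[["l2v4"]],
    "xmlns:rdf" = ns_uri[["rdf"]],
    "xmlns:bqbiol" = ns_uri[["bqbiol"]],
    level = "2", version = "4")
  mdl <- xml2::xml_add_child(doc, "model", id = model$id, name = model$name)

  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$compartments))
    xml2::xml_add_child(lc, "compartment", id = cid,
                        name = model$compartments[[cid]])

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    mt <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species", id = mt$id,
      metaid = paste0("meta_", mt$id), name = mt$name,
      compartment = mt$compartment, boundaryCondition = "false")
    add_cv(sp, paste0("meta_", mt$id), refs = mt$external_refs[[1L]])
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  rxn <- model$reactions
  for (i in seq_len(nrow(rxn))) {
    lbv <- fin(rxn$lower_bound[i], cap); ubv <- fin(rxn$upper_bound[i], cap)
    r <- xml2::xml_add_child(lr, "reaction", id = rxn$id[i],
      metaid = paste0("meta_", rxn$id[i]), name = rxn$name[i],
      reversible = if (lbv < 0) "true" else "false")
    g <- rxn$gpr[[i]]
    nts <- xml2::xml_add_child(r, "notes")
    body <- xml2::xml_add_child(nts, "body", xmlns = ns_uri[["xhtml"]])
    xml2::xml_add_child(body, "p",
      paste0("GENE_ASSOCIATION: ", gpr_to_string(g)))
    add_cv(r, paste0("meta_", rxn$id[i]), pubmed = rxn$pubmed_refs[[i]])
    s <- rxn$stoichiometry[[i]]
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) {
      box <- xml2::xml_add_child(r, "listOfReactants")
      for (k in seq_along(reac))
        xml2::xml_add_child(box, "speciesReference",
          species = names(reac)[k], stoichiometry = num(-reac[[k]]))
    }
    if (length(prod)) {
      box <- xml2::xml_add_child(r, "listOfProducts")
      for (k in seq_along(prod))
        xml2::xml_add_child(box, "speciesReference",
          species = names(prod)[k], stoichiometry = num(prod[[k]]))
    }
    klaw <- xml2::xml_add_child(r, "kineticLaw")
    math <- xml2::xml_add_child(klaw, "math", xmlns = ns_uri[["mathml"]])
    xml2::xml_add_child(math, "ci", " FLUX_VALUE ")
    lpars <- xml2::xml_add_child(klaw, "listOfParameters")
    xml2::xml_add_child(lpars, "parameter", id = "LOWER_BOUND",
                        value = num(lbv),
                        units = "mmol_per_gDW_per_hr")
    xml2::xml_add_child(lpars, "parameter", id = "UPPER_BOUND",
                        value = num(ubv),
                        units = "mmol_per_gDW_per_hr")
    xml2::xml_add_child(lpars, "parameter", id = "OBJECTIVE_COEFFICIENT",
      value = if (!is.na(model$objective_reaction_id) &&
                  rxn$id[i] == model$objective_reaction_id) "1" else "0")
  }
  xml2::write_xml(doc, path)
}

#' PubMed annotation coverage of a model's reactions
#'
#' The fraction of reactions carrying at least one PubMed reference, plus a
#' per-reaction reference-count table — the "reactions with PMID
#' references" summary statistic used when comparing reconstruction
#' versions.
#'
#' @param model A `gem_model`.
#' @return List with `fraction` (in `[0, 1]`; `NaN` for an empty model) and
#'   `table` (data frame `reaction_id`, `n_pubmed_refs`).
#' @export
annotation_coverage <- function(model) {
  cnt <- vapply(model$reactions$pubmed_refs, length, integer(1))
  list(fraction = if (length(cnt)) mean(cnt > 0) else NaN,
       table = data.frame(reaction_id = reaction_ids(model),
                          n_pubmed_refs = cnt, stringsAsFactors = FALSE))
}
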