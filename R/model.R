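#' Constraint-based metabolic model container
#'
#' A `gem_model` holds the computable subset of a genome-scale metabolic
#' reconstruction: compartments, metabolites, reactions with flux bounds and
#' GPR trees, genes, and an optional linear objective. Flux bounds are in
#' mmol per gram dry weight per hour; unbounded directions are stored as
#' `-Inf`/`Inf` internally and capped only on serialisation or when an LP is
#' built (see `exchange_cap`). Exchange reactions are written
#' `metabolite -> (nothing)` with coefficient -1, so positive flux means
#' secretion into the medium and negative flux means uptake.
#'
#' @param id,name Model identifier and human-readable name.
#' @param compartments Named character vector: compartment id -> name.
#' @param metabolites Data frame with columns `id`, `name`, `compartment`,
#'   `is_biomass` and list-column `external_refs` (each element a data frame
#'   with columns `database`, `accession`).
#' @param reactions Data frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `is_exchange` and list-columns `stoichiometry` (named
#'   numeric: metabolite id -> signed coefficient, negative = consumed),
#'   `gpr` (a [gpr] tree) and `pubmed_refs` (character vector of PubMed ids).
#' @param genes Data frame with columns `id`, `standard_name` and list-column
#'   `external_refs`.
#' @param objective_reaction_id Reaction id of the objective (usually the
#'   biomass drain), or `NA` for a reconstruction without modelling additions.
#' @param objective_sense `"maximize"` or `"minimize"`.
#' @param dialect Which SBML dialect the model came from / should go to:
#'   `"fbc3"`, `"cobra_l2"` or `"reconstruction_only"`.
#' @return A validated `gem_model` object.
#' @seealso [read_model()], [write_model()], [make_toy_model()]
#' @export
gem_model <- function(id, name = id, compartments = character(0),
                      metabolites = empty_metabolite_table(),
                      reactions = empty_reaction_table(),
                      genes = empty_gene_table(),
                      objective_reaction_id = NA_character_,
                      objective_sense = c("maximize", "minimize"),
                      dialect = c("fbc3", "cobra_l2", "reconstruction_only")) {
  objective_sense <- match.arg(objective_sense)
  dialect <- match.arg(dialect)
  m <- structure(list(
    id = as.character(id), name = as.character(name),
    compartments = compartments,
    metabolites = metabolites, reactions = reactions, genes = genes,
    objective_reaction_id = as.character(objective_reaction_id),
    objective_sense = objective_sense,
    dialect = dialect
  ), class = "gem_model")
  validate_model(m)
  m
}

#' @export
empty_metabolite_table <- function() {
  data.frame(id = character(0), name = character(0),
             compartment = character(0), is_biomass = logical(0),
             external_refs = I(list()), stringsAsFactors = FALSE)
}

#' @export
empty_reaction_table <- function() {
  data.frame(id = character(0), name = character(0),
             lower_bound = numeric(0), upper_bound = numeric(0),
             is_exchange = logical(0),
             stoichiometry = I(list()), gpr = I(list()),
             pubmed_refs = I(list()), stringsAsFactors = FALSE)
}

#' @export
empty_gene_table <- function() {
  data.frame(id = character(0), standard_name = character(0),
             external_refs = I(list()), stringsAsFactors = FALSE)
}

# Row builders used by the reader and the fixture generator ------------------

metabolite_row <- function(id, name = id, compartment, is_biomass = FALSE,
                           external_refs = no_refs()) {
  data.frame(id = id, name = name, compartment = compartment,
             is_biomass = is_biomass, external_refs = I(list(external_refs)),
             stringsAsFactors = FALSE)
}

reaction_row <- function(id, name = id, stoichiometry, lower_bound, upper_bound,
                         gpr = gpr_empty(), pubmed_refs = character(0),
                         is_exchange = NA) {
  if (is.na(is_exchange)) is_exchange <- length(stoichiometry) == 1L
  data.frame(id = id, name = name,
             lower_bound = lower_bound, upper_bound = upper_bound,
             is_exchange = is_exchange,
             stoichiometry = I(list(stoichiometry)), gpr = I(list(gpr)),
             pubmed_refs = I(list(pubmed_refs)), stringsAsFactors = FALSE)
}

gene_row <- function(id, standard_name = NA_character_,
                     external_refs = no_refs()) {
  data.frame(id = id, standard_name = standard_name,
             external_refs = I(list(external_refs)), stringsAsFactors = FALSE)
}

no_refs <- function() {
  data.frame(database = character(0), accession = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a model's structural invariants
#'
#' Checks identifier uniqueness, compartment and gene references, bound
#' ordering, stoichiometry sanity (nonempty, finite, nonzero), the
#' single-metabolite property of exchange reactions, and that the objective
#' names an existing reaction.
#'
#' @param model A `gem_model`.
#' @return The model, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gem_model"))
  met <- model$metabolites; rxn <- model$reactions; gen <- model$genes
  if (anyDuplicated(met$id))
    stop("duplicate metabolite ids: ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "))
  if (anyDuplicated(rxn$id))
    stop("duplicate reaction ids: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (anyDuplicated(gen$id))
    stop("duplicate gene ids: ",
         paste(unique(gen$id[duplicated(gen$id)]), collapse = ", "))
  bad_comp <- setdiff(met$compartment, names(model$compartments))
  if (length(bad_comp))
    stop("metabolites reference unknown compartments: ",
         paste(bad_comp, collapse = ", "))
  if (nrow(rxn)) {
    if (any(rxn$lower_bound > rxn$upper_bound)) {
      off <- rxn$id[rxn$lower_bound > rxn$upper_bound]
      stop("lower_bound > upper_bound for reaction(s): ",
           paste(off, collapse = ", "))
    }
    for (i in seq_len(nrow(rxn))) {
      s <- rxn$stoichiometry[[i]]
      if (!length(s))
        stop("reaction ", rxn$id[i], " has empty stoichiometry")
      if (any(!is.finite(s)) || any(s == 0))
        stop("reaction ", rxn$id[i],
             " has non-finite or zero stoichiometric coefficients")
      missing_met <- setdiff(names(s), met$id)
      if (length(missing_met))
        stop("reaction ", rxn$id[i], " references unknown metabolites: ",
             paste(missing_met, collapse = ", "))
      if (rxn$is_exchange[i] && length(s) != 1L)
        stop("exchange reaction ", rxn$id[i],
             " must touch exactly one metabolite")
      g <- rxn$gpr[[i]]
      if (!is_gpr(g)) stop("reaction ", rxn$id[i], " has a malformed GPR")
      unknown <- setdiff(gpr_genes(g), gen$id)
      if (length(unknown))
        stop("reaction ", rxn$id[i], " GPR references unknown gene(s): ",
             paste(unknown, collapse = ", "))
    }
  }
  if (!is.na(model$objective_reaction_id) &&
      !(model$objective_reaction_id %in% rxn$id))
    stop("objective reaction '", model$objective_reaction_id,
         "' is not in the model")
  invisible(model)
}

# Accessors -------------------------------------------------------------------

#' Entity counts and identifier accessors
#' @param model A `gem_model`.
#' @return Integer count or character vector of ids.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
n_metabolites <- function(model) nrow(model$metabolites)

#' @rdname model-accessors
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' @rdname model-accessors
#' @export
n_genes <- function(model) nrow(model$genes)

#' @rdname model-accessors
#' @export
metabolite_ids <- function(model) model$metabolites$id

#' @rdname model-accessors
#' @export
reaction_ids <- function(model) model$reactions$id

#' @rdname model-accessors
#' @export
gene_ids <- function(model) model$genes$id

reaction_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (anyNA(i))
    stop("unknown reaction id(s): ",
         paste(reaction_id[is.na(i)], collapse = ", "))
  i
}

#' Replace a reaction's flux bounds
#'
#' Returns a copy of the model with one reaction's `(lower_bound,
#' upper_bound)` replaced. This is the mechanism for condition-dependent
#' manual restrictions (for instance limiting ATP synthase flux when
#' simulating anaerobic fermentation).
#'
#' @param model A `gem_model`.
#' @param reaction_id Reaction to constrain.
#' @param bounds Numeric length-2 vector `c(lower, upper)`.
#' @return The modified model (the input is untouched).
#' @export
constrain_reaction <- function(model, reaction_id, bounds) {
  stopifnot(is.numeric(bounds), length(bounds) == 2L)
  if (bounds[1] > bounds[2])
    stop("lower bound ", bounds[1], " exceeds upper bound ", bounds[2])
  i <- reaction_index(model, reaction_id)
  model$reactions$lower_bound[i] <- bounds[1]
  model$reactions$upper_bound[i] <- bounds[2]
  model
}

#' @export
print.gem_model <- function(x, ...) {
  cat("<gem_model> ", x$id, if (nzchar(x$name) && x$name != x$id)
    paste0(" (", x$name, ")") else "", "\n", sep = "")
  cat("  dialect:     ", x$dialect, "\n", sep = "")
  cat("  metabolites: ", n_metabolites(x), "\n", sep = "")
  cat("  reactions:   ", n_reactions(x), " (",
      sum(x$reactions$is_exchange), " exchange)\n", sep = "")
  cat("  genes:       ", n_genes(x), "\n", sep = "")
  cat("  objective:   ",
      if (is.na(x$objective_reaction_id)) "none"
      else paste(x$objective_sense, x$objective_reaction_id), "\n", sep = "")
  invisible(x)
}

# Deep structural equality used by round-trip tests. Bounds at or beyond
# +/- cap are treated as unbounded, so the +/-1000 interchange encoding and
# true infinities compare equal.
model_equal <- function(a, b, check_annotations = TRUE, tol = 1e-9,
                        cap = 1000) {
  same_ids <- identical(a$metabolites$id, b$metabolites$id) &&
    identical(a$reactions$id, b$reactions$id) &&
    setequal(a$genes$id, b$genes$id) &&
    identical(sort(names(a$compartments)), sort(names(b$compartments)))
  if (!same_ids) return(FALSE)
  for (i in seq_len(nrow(a$reactions))) {
    sa <- a$reactions$stoichiometry[[i]]; sb <- b$reactions$stoichiometry[[i]]
    if (!setequal(names(sa), names(sb))) return(FALSE)
    if (max(abs(sa - sb[names(sa)])) > tol) return(FALSE)
    if (!gpr_equal(a$reactions$gpr[[i]], b$reactions$gpr[[i]])) return(FALSE)
    if (check_annotations &&
        !setequal(a$reactions$pubmed_refs[[i]], b$reactions$pubmed_refs[[i]]))
      return(FALSE)
  }
  normb <- function(x) { x[x <= -cap] <- -Inf; x[x >= cap] <- Inf; x }
  ba <- normb(cbind(a$reactions$lower_bound, a$reactions$upper_bound))
  bb <- normb(cbind(b$reactions$lower_bound, b$reactions$upper_bound))
  if (!all((ba == bb) | (abs(ba - bb) <= tol), na.rm = TRUE)) return(FALSE)
  if (!identical(is.na(a$objective_reaction_id),
                 is.na(b$objective_reaction_id))) return(FALSE)
  if (!is.na(a$objective_reaction_id) &&
      a$objective_reaction_id != b$objective_reaction_id) return(FALSE)
  TRUE
}
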