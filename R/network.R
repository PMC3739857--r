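#' Build the sparse stoichiometric matrix of a model
#'
#' Rows are metabolites, columns reactions, entries the signed stoichiometric
#' coefficients (negative = consumed, positive = produced). This is the `S`
#' of the steady-state FBA constraint `S v = 0`.
#'
#' @param model A `gem_model`.
#' @return A `dgCMatrix` with `dimnames` set to metabolite and reaction ids.
#' @export
build_stoich_matrix <- function(model) {
  m <- n_metabolites(model); n <- n_reactions(model)
  if (m == 0L || n == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(m, n),
                                dimnames = list(metabolite_ids(model),
                                                reaction_ids(model))))
  ii <- jj <- integer(0); xx <- numeric(0)
  row_of <- stats::setNames(seq_len(m), metabolite_ids(model))
  for (j in seq_len(n)) {
    s <- model$reactions$stoichiometry[[j]]
    ii <- c(ii, row_of[names(s)])
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                       dimnames = list(metabolite_ids(model),
                                       reaction_ids(model)))
}

#' Identify exchange reactions
#'
#' Returns reactions flagged `is_exchange`; when no reaction in the model
#' carries the flag (older files), falls back to the structural definition:
#' a reaction touching exactly one metabolite.
#'
#' @param model A `gem_model`.
#' @return Character vector of reaction ids.
#' @export
find_exchange_reactions <- function(model) {
  rxn <- model$reactions
  if (any(rxn$is_exchange)) return(rxn$id[rxn$is_exchange])
  n_mets <- vapply(rxn$stoichiometry, length, integer(1))
  rxn$id[n_mets == 1L]
}

#' Knock out genes and propagate through GPR logic
#'
#' Every reaction whose GPR evaluates to `FALSE` under the deletion set has
#' both bounds set to zero; all other reactions are untouched. Gene ids not
#' present in the model are reported via a warning (benchmark lists routinely
#' contain ORFs outside the model) and otherwise ignored.
#'
#' @param model A `gem_model`.
#' @param deleted Character vector of gene ids to delete.
#' @param warn_unknown Warn about ids absent from the model (default `TRUE`).
#' @return A new model with closed reactions; the input is not modified.
#' @export
apply_deletion <- function(model, deleted, warn_unknown = TRUE) {
  deleted <- unique(as.character(deleted))
  unknown <- setdiff(deleted, gene_ids(model))
  if (length(unknown) && warn_unknown)
    warning("gene id(s) not in model, ignored: ",
            paste(unknown, collapse = ", "))
  if (!length(deleted)) return(model)
  closed <- !vapply(model$reactions$gpr, evaluate_gpr, logical(1),
                    deleted = deleted)
  if (any(closed)) {
    model$reactions$lower_bound[closed] <- 0
    model$reactions$upper_bound[closed] <- 0
  }
  model
}

#' Growth media
#'
#' A medium is a named set of bounds for exchange reactions, defining one
#' growth condition. Applying a medium sets the listed exchange reactions to
#' the given bounds and every *unlisted* exchange reaction to `(0, Inf)` —
#' secretion allowed, uptake forbidden. Internal reactions are never touched.
#' Under the sign convention used here, uptake is negative flux, so a
#' nutrient is made available with a strictly negative lower bound.
#'
#' @param bounds Data frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`.
#' @param name Medium name, embedded in reports.
#' @return A `gem_medium` object.
#' @export
medium <- function(bounds, name = "unnamed") {
  stopifnot(is.data.frame(bounds),
            all(c("reaction_id", "lower_bound", "upper_bound") %in%
                  names(bounds)))
  bounds$reaction_id <- as.character(bounds$reaction_id)
  bounds$lower_bound <- as.numeric(bounds$lower_bound)
  bounds$upper_bound <- as.numeric(bounds$upper_bound)
  if (any(bounds$lower_bound > bounds$upper_bound))
    stop("medium '", name, "': lower_bound > upper_bound for ",
         paste(bounds$reaction_id[bounds$lower_bound > bounds$upper_bound],
               collapse = ", "))
  structure(list(name = name, bounds = bounds), class = "gem_medium")
}

#' @rdname medium
#' @param path TSV file with columns `reaction_id`, `lower_bound`,
#'   `upper_bound`; lines starting with `#` are comments.
#' @export
read_medium <- function(path, name = sub("\\.tsv$", "", basename(path))) {
  if (!file.exists(path)) stop("medium file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  medium(df, name = name)
}

#' @rdname medium
#' @param med A `gem_medium`.
#' @export
write_medium <- function(med, path) {
  stopifnot(inherits(med, "gem_medium"))
  utils::write.table(med$bounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname medium
#' @param model A `gem_model`.
#' @export
apply_medium <- function(model, med) {
  stopifnot(inherits(med, "gem_medium"))
  exch <- find_exchange_reactions(model)
  stray <- setdiff(med$bounds$reaction_id, exch)
  in_model <- intersect(stray, reaction_ids(model))
  if (length(in_model))
    stop("medium '", med$name, "' references non-exchange reaction(s): ",
         paste(in_model, collapse = ", "))
  missing <- setdiff(stray, in_model)
  if (length(missing))
    stop("medium '", med$name, "' references unknown reaction(s): ",
         paste(missing, collapse = ", "))
  i_exch <- match(exch, model$reactions$id)
  model$reactions$lower_bound[i_exch] <- 0
  model$reactions$upper_bound[i_exch] <- Inf
  i_med <- match(med$bounds$reaction_id, model$reactions$id)
  model$reactions$lower_bound[i_med] <- med$bounds$lower_bound
  model$reactions$upper_bound[i_med] <- med$bounds$upper_bound
  model
}

#' Relax reaction reversibility
#'
#' Sets each listed reaction's lower bound to minus its upper bound, making
#' it reversible. This supports the reported experiment that relaxing the
#' reversibility of nucleotide-cofactor reactions reduces the number of
#' blocked reactions.
#'
#' @param model A `gem_model`.
#' @param reaction_ids Reactions to relax.
#' @return The modified model.
#' @export
relax_reversibility <- function(model, reaction_ids) {
  i <- reaction_index(model, reaction_ids)
  model$reactions$lower_bound[i] <-
    pmin(model$reactions$lower_bound[i], -model$reactions$upper_bound[i])
  model
}

#' @export
print.gem_medium <- function(x, ...) {
  cat("<gem_medium> ", x$name, " (", nrow(x$bounds), " exchange bounds)\n",
      sep = "")
  invisible(x)
}

#' The model's own exchange bounds as a medium
#'
#' Captures the exchange bounds a model file shipped with, so they can be
#' re-applied (or reported) like any other medium.
#'
#' @param model A `gem_model`.
#' @return A `gem_medium` named `"model_default"`.
#' @export
model_default_medium <- function(model) {
  exch <- find_exchange_reactions(model)
  i <- match(exch, model$reactions$id)
  medium(data.frame(reaction_id = exch,
                    lower_bound = model$reactions$lower_bound[i],
                    upper_bound = model$reactions$upper_bound[i],
                    stringsAsFactors = FALSE),
         name = "model_default")
}

#' Shipped media presets
#'
#' Best-effort reconstructions of the growth conditions used when
#' benchmarking the consensus yeast network (the exact supplementary media
#' are unpublished): `minimal_aerobic_glucose`, `anaerobic_minimal`, and
#' `anaerobic_sterol_supplemented`. Reaction ids follow the consensus
#' `r_####` exchange identifiers and should be overridden for other models.
#'
#' @param which Preset name.
#' @return A `gem_medium`.
#' @export
medium_preset <- function(which = c("minimal_aerobic_glucose",
                                    "anaerobic_minimal",
                                    "anaerobic_sterol_supplemented")) {
  which <- match.arg(which)
  path <- system.file("extdata", "media", paste0(which, ".tsv"),
                      package = "gemqc", mustWork = TRUE)
  read_medium(path, name = which)
}
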