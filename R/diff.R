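#' Structured diff of two model versions
#'
#' Consensus-network releases keep `r_####`/`s_####` identifiers stable
#' across versions, so the intended comparison semantics are purely
#' identifier-based: entity sets are partitioned into only-in-A, only-in-B
#' and shared, and shared reactions are additionally checked for changed
#' `(lower_bound, upper_bound)` constraints. Two reactions with equal
#' stoichiometry but different ids are different entities by design.
#'
#' @param a,b `gem_model` objects.
#' @param tol Bounds differing by no more than this compare equal.
#' @param normalize_caps Treat bounds at or beyond +/- `cap` as infinite
#'   before comparing, so a `+/-1000`-encoded file and a true-infinity
#'   model do not produce spurious constraint diffs.
#' @param cap Cap magnitude used when `normalize_caps` is `TRUE`.
#' @return A `diff_report`: per-entity-class id sets (`*_only_a`,
#'   `*_only_b`, `*_shared`), `constraint_diffs` (data frame `reaction_id`,
#'   `lb_a`, `ub_a`, `lb_b`, `ub_b`) and a `summary` count list.
#' @export
diff_models <- function(a, b, tol = 1e-9, normalize_caps = TRUE,
                        cap = 1000) {
  split3 <- function(ia, ib)
    list(only_a = setdiff(ia, ib), only_b = setdiff(ib, ia),
         shared = intersect(ia, ib))
  mets <- split3(metabolite_ids(a), metabolite_ids(b))
  rxns <- split3(reaction_ids(a), reaction_ids(b))
  gens <- split3(gene_ids(a), gene_ids(b))

  normb <- function(x) {
    if (normalize_caps) { x[x <= -cap] <- -Inf; x[x >= cap] <- Inf }
    x
  }
  ia <- match(rxns$shared, a$reactions$id)
  ib <- match(rxns$shared, b$reactions$id)
  lb_a <- normb(a$reactions$lower_bound[ia])
  ub_a <- normb(a$reactions$upper_bound[ia])
  lb_b <- normb(b$reactions$lower_bound[ib])
  ub_b <- normb(b$reactions$upper_bound[ib])
  neq <- function(x, y) !((x == y) | (abs(x - y) <= tol)) | xor(is.finite(x), is.finite(y))
  changed <- neq(lb_a, lb_b) | neq(ub_a, ub_b)
  changed[is.na(changed)] <- FALSE
  constraint_diffs <- data.frame(
    reaction_id = rxns$shared[changed],
    lb_a = lb_a[changed], ub_a = ub_a[changed],
    lb_b = lb_b[changed], ub_b = ub_b[changed],
    stringsAsFactors = FALSE)

  structure(list(
    metabolites_only_a = mets$only_a, metabolites_only_b = mets$only_b,
    metabolites_shared = mets$shared,
    reactions_only_a = rxns$only_a, reactions_only_b = rxns$only_b,
    reactions_shared = rxns$shared,
    genes_only_a = gens$only_a, genes_only_b = gens$only_b,
    genes_shared = gens$shared,
    constraint_diffs = constraint_diffs,
    summary = list(
      model_a = a$id, model_b = b$id,
      metabolites_only_a = length(mets$only_a),
      metabolites_only_b = length(mets$only_b),
      metabolites_shared = length(mets$shared),
      reactions_only_a = length(rxns$only_a),
      reactions_only_b = length(rxns$only_b),
      reactions_shared = length(rxns$shared),
      genes_only_a = length(gens$only_a),
      genes_only_b = length(gens$only_b),
      genes_shared = length(gens$shared),
      constraint_diffs = nrow(constraint_diffs))
  ), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  s <- x$summary
  cat("<diff_report> ", s$model_a, " vs ", s$model_b, "\n", sep = "")
  cat(sprintf("  metabolites: %d shared, %d only A, %d only B\n",
              s$metabolites_shared, s$metabolites_only_a,
              s$metabolites_only_b))
  cat(sprintf("  reactions:   %d shared, %d only A, %d only B\n",
              s$reactions_shared, s$reactions_only_a, s$reactions_only_b))
  cat(sprintf("  genes:       %d shared, %d only A, %d only B\n",
              s$genes_shared, s$genes_only_a, s$genes_only_b))
  cat(sprintf("  constraint differences on shared reactions: %d\n",
              s$constraint_diffs))
  invisible(x)
}

#' Summary statistics of a model
#'
#' Entity counts plus PubMed annotation coverage — the per-version summary
#' row used when comparing reconstruction releases — and optionally the
#' blocked-reaction count (an FVA sweep, so off by default).
#'
#' @param model A `gem_model`.
#' @param count_blocked Also run [blocked_reactions()].
#' @inheritParams fba
#' @return Named list of summary statistics.
#' @export
summarize_model <- function(model, count_blocked = FALSE,
                            exchange_cap = 1000) {
  cov <- annotation_coverage(model)
  out <- list(id = model$id, name = model$name,
              genes = n_genes(model),
              metabolites = n_metabolites(model),
              reactions = n_reactions(model),
              exchange_reactions = length(find_exchange_reactions(model)),
              pmid_coverage = cov$fraction)
  if (count_blocked) {
    bl <- blocked_reactions(model, exchange_cap = exchange_cap)
    out$blocked_reactions <- length(bl)
    out$blocked_fraction <- if (n_reactions(model))
      length(bl) / n_reactions(model) else NaN
  }
  out
}
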