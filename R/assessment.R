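#' Contingency table for essentiality prediction
#'
#' Orientation follows the convention used when benchmarking gene
#' essentiality: the positive class is *predicted growth* (mutant viable).
#' A true positive is a gene predicted viable that is not in the essential
#' list; a true negative is a gene predicted lethal that is essential.
#' MCC is orientation-invariant but sensitivity/specificity are not, so the
#' orientation is recorded in the object.
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), total = sum(counts),
            positive_class = "predicted viable (growth)",
            class = "contingency_table")
}

#' Build a contingency table from predictions and truth sets
#'
#' @param predicted_viable Genes predicted to grow after deletion.
#' @param truth_essential Genes observed essential (must be within
#'   `universe`).
#' @param universe All evaluated genes.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(predicted_viable, truth_essential, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  predicted_viable <- unique(as.character(predicted_viable))
  truth_essential <- unique(as.character(truth_essential))
  stray <- setdiff(predicted_viable, universe)
  if (length(stray))
    stop("predicted set contains genes outside the universe: ",
         paste(stray, collapse = ", "))
  stray <- setdiff(truth_essential, universe)
  if (length(stray))
    stop("essential set contains genes outside the universe: ",
         paste(stray, collapse = ", "))
  viable_truth <- setdiff(universe, truth_essential)
  pred_lethal <- setdiff(universe, predicted_viable)
  contingency_table(
    TP = length(intersect(predicted_viable, viable_truth)),
    FP = length(intersect(predicted_viable, truth_essential)),
    TN = length(intersect(pred_lethal, truth_essential)),
    FN = length(intersect(pred_lethal, viable_truth)))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> positive =", attr(x, "positive_class"), "\n")
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d  (n = %d)\n",
              x$TP, x$FP, x$TN, x$FN, attr(x, "total")))
  invisible(x)
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Contingency-derived classifier metrics
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `ppv = TP/(TP+FP)`, `npv = TN/(TN+FN)`. A zero denominator yields `NA`
#' (undefined), never a silent 0. [mcc()] is
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the
#' documented convention that any zero factor gives 0 (the limiting value
#' of the binary-vector Pearson correlation).
#' [geometric_mean_accuracy()] is `sqrt(sensitivity * specificity)` and is
#' `NA` whenever a component is undefined.
#'
#' @param t A [contingency_table()].
#' @return Numeric scalar (possibly `NA` for the ratio metrics).
#' @name contingency-metrics
NULL

#' @rdname contingency-metrics
#' @export
sensitivity <- function(t) ratio_or_na(t$TP, t$TP + t$FN)

#' @rdname contingency-metrics
#' @export
specificity <- function(t) ratio_or_na(t$TN, t$TN + t$FP)

#' @rdname contingency-metrics
#' @export
ppv <- function(t) ratio_or_na(t$TP, t$TP + t$FP)

#' @rdname contingency-metrics
#' @export
npv <- function(t) ratio_or_na(t$TN, t$TN + t$FN)

#' @rdname contingency-metrics
#' @export
mcc <- function(t) {
  f <- c(t$TP + t$FP, t$TP + t$FN, t$TN + t$FP, t$TN + t$FN)
  if (any(f == 0)) return(0)
  # products can overflow integer range on large tables; go via double
  (as.numeric(t$TP) * t$TN - as.numeric(t$FP) * t$FN) /
    sqrt(prod(as.numeric(f)))
}

#' @rdname contingency-metrics
#' @export
geometric_mean_accuracy <- function(t) {
  se <- sensitivity(t); sp <- specificity(t)
  if (is.na(se) || is.na(sp)) return(NA_real_)
  sqrt(se * sp)
}

#' All metrics as a named list
#' @param t A [contingency_table()].
#' @export
contingency_metrics <- function(t) {
  list(TP = t$TP, FP = t$FP, TN = t$TN, FN = t$FN,
       sensitivity = sensitivity(t), specificity = specificity(t),
       ppv = ppv(t), npv = npv(t), mcc = mcc(t),
       geometric_mean_accuracy = geometric_mean_accuracy(t))
}

#' Gene-essentiality benchmark
#'
#' Compares the model's single-gene-deletion growth predictions on a medium
#' against a curated essential-gene list. The evaluation universe is the
#' intersection of the model's genes with the supplied verified-ORF list;
#' genes on the lists but absent from the model cannot change FBA outcomes
#' and are reported separately, not silently dropped.
#'
#' @param model A `gem_model`.
#' @param med Growth [medium()].
#' @param essential_genes Curated essential gene ids.
#' @param verified_orfs Verified ORF ids defining the candidate universe
#'   (default: all model genes).
#' @param threshold Lethality growth cutoff.
#' @inheritParams fba
#' @return List with `table` (the [contingency_table()]), `metrics`,
#'   `per_gene` (data frame), `universe`, `excluded_from_model` and the
#'   resolved settings.
#' @export
essentiality_benchmark <- function(model, med, essential_genes,
                                   verified_orfs = gene_ids(model),
                                   threshold = 1e-6, exchange_cap = 1000,
                                   tol = 1e-9) {
  m <- apply_medium(model, med)
  universe <- intersect(gene_ids(model), unique(as.character(verified_orfs)))
  if (!length(universe)) stop("empty universe: no verified ORF is in the model")
  excluded <- setdiff(unique(c(verified_orfs, essential_genes)), gene_ids(model))
  sgd <- single_gene_deletions(m, genes = universe, threshold = threshold,
                               exchange_cap = exchange_cap, tol = tol)
  predicted_viable <- sgd$gene[sgd$classification == "viable"]
  truth_essential <- intersect(unique(as.character(essential_genes)), universe)
  tab <- build_contingency(predicted_viable, truth_essential, universe)
  per_gene <- data.frame(
    gene = sgd$gene, growth = sgd$growth,
    predicted = sgd$classification,
    observed = ifelse(sgd$gene %in% truth_essential, "essential",
                      "inessential"),
    stringsAsFactors = FALSE)
  list(table = tab, metrics = contingency_metrics(tab), per_gene = per_gene,
       universe = universe, excluded_from_model = excluded,
       settings = list(medium = med$name, threshold = threshold,
                       exchange_cap = exchange_cap, solver_tol = tol))
}

#' Auxotrophy benchmark
#'
#' For each gene reported to induce auxotrophy upon deletion, the mutant is
#' simulated on the minimal medium and on a supplemented medium. The
#' prediction is *correct* when the mutant fails to grow on minimal medium
#' but grows on its supplement (the two-condition definition);
#' *incorrectly viable in minimal* when it still grows on minimal medium;
#' *incorrectly inviable in supplemented* when it grows on neither.
#'
#' @param model A `gem_model`.
#' @param auxotroph_genes Genes whose deletion should cause auxotrophy.
#' @param minimal Minimal [medium()].
#' @param supplemented Either a single [medium()] used for every gene or a
#'   named list gene -> medium; a gene without an entry is an error. When
#'   `NULL`, a default supplement is derived from the minimal medium by
#'   additionally allowing uptake (lower bound -1) through every exchange
#'   reaction not already open in the minimal medium.
#' @param threshold Growth cutoff.
#' @inheritParams fba
#' @return List with the per-gene table and the aggregate counts
#'   `n_genes`, `n_correct`, `n_incorrect_viable_minimal`,
#'   `n_incorrect_inviable_supplemented`, `n_not_in_model`.
#' @export
auxotrophy_benchmark <- function(model, auxotroph_genes, minimal,
                                 supplemented = NULL, threshold = 1e-6,
                                 exchange_cap = 1000, tol = 1e-9) {
  auxotroph_genes <- unique(as.character(auxotroph_genes))
  wt <- check_growth(model, minimal, threshold = threshold,
                     exchange_cap = exchange_cap, tol = tol)
  if (!wt$grows)
    stop("wild type does not grow on the minimal medium; ",
         "auxotrophy benchmark is meaningless")
  if (is.null(supplemented)) supplemented <- default_supplement(model, minimal)

  get_supp <- function(g) {
    if (inherits(supplemented, "gem_medium")) return(supplemented)
    if (!g %in% names(supplemented))
      stop("no supplemented medium supplied for gene ", g)
    supplemented[[g]]
  }

  rows <- lapply(auxotroph_genes, function(g) {
    if (!g %in% gene_ids(model))
      return(data.frame(gene = g, grows_minimal = NA, grows_supplemented = NA,
                        class = "not_in_model", stringsAsFactors = FALSE))
    mut <- apply_deletion(model, g)
    gm <- check_growth(mut, minimal, threshold = threshold,
                       exchange_cap = exchange_cap, tol = tol)$grows
    gs <- check_growth(mut, get_supp(g), threshold = threshold,
                       exchange_cap = exchange_cap, tol = tol)$grows
    cls <- if (gm) "incorrect_viable_minimal"
      else if (gs) "correct"
      else "incorrect_inviable_supplemented"
    data.frame(gene = g, grows_minimal = gm, grows_supplemented = gs,
               class = cls, stringsAsFactors = FALSE)
  })
  per_gene <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), grows_minimal = logical(0),
               grows_supplemented = logical(0), class = character(0),
               stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       n_genes = length(auxotroph_genes),
       n_correct = sum(per_gene$class == "correct"),
       n_incorrect_viable_minimal =
         sum(per_gene$class == "incorrect_viable_minimal"),
       n_incorrect_inviable_supplemented =
         sum(per_gene$class == "incorrect_inviable_supplemented"),
       n_not_in_model = sum(per_gene$class == "not_in_model"),
       settings = list(minimal = minimal$name, threshold = threshold,
                       exchange_cap = exchange_cap, solver_tol = tol))
}

# Default per-gene supplement: minimal medium plus uptake (-1) through every
# exchange it leaves closed — a generic "rich" rescue condition used when no
# gene-specific supplement is available.
default_supplement <- function(model, minimal, uptake = -1) {
  exch <- find_exchange_reactions(model)
  extra <- setdiff(exch, minimal$bounds$reaction_id)
  b <- rbind(minimal$bounds,
             data.frame(reaction_id = extra, lower_bound = uptake,
                        upper_bound = Inf, stringsAsFactors = FALSE))
  medium(b, name = paste0(minimal$name, "+all_supplements"))
}
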