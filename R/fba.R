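#' Flux balance analysis
#'
#' Maximises (or minimises, per the model's `objective_sense`) flux through
#' the objective reaction subject to the steady-state constraint `S v = 0`
#' and the flux bounds. Unbounded directions are capped at `exchange_cap`
#' before the LP is built, the de-facto convention in constraint-based
#' modelling. The optimum is deterministic for a fixed model; the flux
#' vector itself may be one of several degenerate optima and is advisory.
#'
#' @param model A `gem_model` with an objective reaction set.
#' @param exchange_cap Cap substituted for infinite bounds (default 1000
#'   mmol/gDW/h).
#' @param tol Solver pivot tolerance.
#' @return A `flux_result`: list with `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`), `objective_value` and named `fluxes`.
#' @examples
#' toy <- make_toy_model(toy_model_spec(chain_length = 3))
#' fba(toy$model)$objective_value
#' @export
fba <- function(model, exchange_cap = 1000, tol = 1e-9) {
  if (is.na(model$objective_reaction_id))
    stop("model has no objective reaction; set objective_reaction_id")
  S <- as.matrix(build_stoich_matrix(model))
  bounds <- cap_bounds(model$reactions$lower_bound,
                       model$reactions$upper_bound, cap = exchange_cap)
  obj <- as.numeric(reaction_ids(model) == model$objective_reaction_id)
  res <- lp_solve(obj, Aeq = S, beq = rep(0, nrow(S)),
                  lb = bounds$lb, ub = bounds$ub,
                  maximize = model$objective_sense == "maximize", tol = tol)
  fluxes <- stats::setNames(res$solution, reaction_ids(model))
  structure(list(status = res$status,
                 objective_value = res$objective,
                 fluxes = fluxes),
            class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> status: ", x$status,
      if (x$status == "optimal")
        paste0(", objective: ", format(x$objective_value, digits = 8)),
      "\n", sep = "")
  invisible(x)
}

#' Single-gene deletion screen
#'
#' Deletes each requested gene in turn (propagating through GPR logic with
#' [apply_deletion()]), re-solves the FBA problem, and classifies the mutant
#' as `"lethal"` when the optimum falls below `threshold` (or the problem
#' becomes infeasible) and `"viable"` otherwise. Genes absent from the model
#' cannot change any GPR and are reported viable at wild-type growth with
#' `in_model = FALSE`.
#'
#' @param model A `gem_model`; its wild type must grow at or above
#'   `threshold`.
#' @param genes Gene ids to screen (default: all model genes).
#' @param threshold Growth cutoff separating lethal from viable, in flux
#'   units (default `1e-6`).
#' @inheritParams fba
#' @return Data frame with columns `gene`, `growth`, `classification`,
#'   `in_model`, plus attributes `wild_type_growth` and `threshold`.
#' @export
single_gene_deletions <- function(model, genes = gene_ids(model),
                                  threshold = 1e-6, exchange_cap = 1000,
                                  tol = 1e-9) {
  genes <- as.character(genes)
  wt <- fba(model, exchange_cap = exchange_cap, tol = tol)
  # the screen needs a growing wild type; the classification threshold may
  # still sit above wild-type growth (degenerate, but well defined)
  if (wt$status != "optimal" || wt$objective_value <= 1e-12)
    stop("wild-type model does not grow (status ", wt$status,
         ", objective ", format(wt$objective_value),
         "); the deletion screen is meaningless")

  S <- as.matrix(build_stoich_matrix(model))
  bounds <- cap_bounds(model$reactions$lower_bound,
                       model$reactions$upper_bound, cap = exchange_cap)
  obj <- as.numeric(reaction_ids(model) == model$objective_reaction_id)
  maximize <- model$objective_sense == "maximize"

  growth <- numeric(length(genes))
  status <- character(length(genes))
  in_model <- genes %in% gene_ids(model)
  for (k in seq_along(genes)) {
    if (!in_model[k]) { growth[k] <- wt$objective_value; status[k] <- "optimal"; next }
    closed <- !vapply(model$reactions$gpr, evaluate_gpr, logical(1),
                      deleted = genes[k])
    if (!any(closed)) { growth[k] <- wt$objective_value; status[k] <- "optimal"; next }
    lb <- bounds$lb; ub <- bounds$ub
    lb[closed] <- 0; ub[closed] <- 0
    res <- lp_solve(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                    maximize = maximize, tol = tol)
    status[k] <- res$status
    growth[k] <- if (res$status == "optimal") res$objective else 0
  }
  out <- data.frame(
    gene = genes, growth = growth,
    classification = ifelse(status == "optimal" & growth >= threshold,
                            "viable", "lethal"),
    in_model = in_model, stringsAsFactors = FALSE)
  attr(out, "wild_type_growth") <- wt$objective_value
  attr(out, "threshold") <- threshold
  out
}

#' Flux variability analysis
#'
#' For every reaction, computes the minimum and maximum flux it can carry
#' subject to `S v = 0`, the bounds, and (optionally) the requirement that
#' the objective stays at or above `objective_fraction` times the wild-type
#' optimum. Reactions are processed in column order so logs are reproducible.
#'
#' @inheritParams fba
#' @param objective_fraction `NULL` for unconstrained variability, or a
#'   fraction in `[0, 1]` of the FBA optimum that must be maintained.
#' @return Data frame with columns `reaction_id`, `v_min`, `v_max`; attribute
#'   `objective_fraction` records the setting.
#' @export
flux_variability <- function(model, objective_fraction = NULL,
                             exchange_cap = 1000, tol = 1e-9) {
  S <- as.matrix(build_stoich_matrix(model))
  bounds <- cap_bounds(model$reactions$lower_bound,
                       model$reactions$upper_bound, cap = exchange_cap)
  n <- n_reactions(model)
  Ageq <- NULL; bgeq <- NULL
  if (!is.null(objective_fraction)) {
    stopifnot(objective_fraction >= 0, objective_fraction <= 1)
    wt <- fba(model, exchange_cap = exchange_cap, tol = tol)
    if (wt$status != "optimal")
      stop("base FBA problem is ", wt$status,
           "; cannot impose an objective fraction")
    crow <- matrix(as.numeric(reaction_ids(model) ==
                                model$objective_reaction_id), 1L)
    if (model$objective_sense == "maximize") {
      Ageq <- crow; bgeq <- objective_fraction * wt$objective_value
    } else {
      Ageq <- -crow; bgeq <- -objective_fraction * wt$objective_value
    }
  }
  v_min <- v_max <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    lo <- lp_solve(obj, S, rep(0, nrow(S)), Ageq, bgeq,
                   bounds$lb, bounds$ub, maximize = FALSE, tol = tol)
    hi <- lp_solve(obj, S, rep(0, nrow(S)), Ageq, bgeq,
                   bounds$lb, bounds$ub, maximize = TRUE, tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for reaction ", reaction_ids(model)[j],
           " is ", lo$status, "/", hi$status)
    v_min[j] <- lo$objective; v_max[j] <- hi$objective
  }
  out <- data.frame(reaction_id = reaction_ids(model),
                    v_min = v_min, v_max = v_max, stringsAsFactors = FALSE)
  attr(out, "objective_fraction") <- objective_fraction
  out
}

#' Detect blocked reactions
#'
#' A reaction is blocked when its flux is identically zero over the whole
#' feasible region. Following the convention documented in the package
#' vignette, the test is run with every exchange reaction opened to
#' `(-exchange_cap, exchange_cap)` and no objective constraint, so a
#' reaction is blocked only for structural reasons (dead ends, disconnected
#' subnetworks, irreversibility conflicts), not because of the medium.
#'
#' @inheritParams fba
#' @param zero_tol Classification tolerance on the FVA extrema.
#' @return Character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, exchange_cap = 1000, zero_tol = 1e-6,
                              tol = 1e-9) {
  exch <- find_exchange_reactions(model)
  i <- match(exch, model$reactions$id)
  model$reactions$lower_bound[i] <- -exchange_cap
  model$reactions$upper_bound[i] <- exchange_cap
  fva <- flux_variability(model, objective_fraction = NULL,
                          exchange_cap = exchange_cap, tol = tol)
  fva$reaction_id[abs(fva$v_min) <= zero_tol & abs(fva$v_max) <= zero_tol]
}

#' Growth check under a defined medium
#'
#' Applies the medium, runs FBA, and reports whether the model grows at or
#' above the threshold — the operation behind qualitative statements such as
#' "no growth on minimal medium under strict anaerobiosis unless sterols are
#' supplied".
#'
#' @inheritParams fba
#' @param med A [medium()].
#' @param threshold Growth cutoff (default `1e-6`).
#' @return List with `grows` (logical), `growth_rate` and `status`.
#' @export
check_growth <- function(model, med, threshold = 1e-6, exchange_cap = 1000,
                         tol = 1e-9) {
  res <- fba(apply_medium(model, med), exchange_cap = exchange_cap, tol = tol)
  grows <- res$status == "optimal" && res$objective_value >= threshold
  list(grows = grows,
       growth_rate = if (res$status == "optimal") res$objective_value else 0,
       status = res$status)
}
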