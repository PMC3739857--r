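#' @title Dense two-phase simplex with variable bounds
#' @description
#' Linear-programming core used by the FBA engine. Solves
#' `max/min c'v  s.t.  Aeq v = beq,  Ageq v >= bgeq,  lb <= v <= ub`.
#' No LP solver library is assumed; this is a full-tableau two-phase simplex
#' with Bland's anti-cycling rule, adequate for the model sizes this package
#' targets (fixtures and small-to-mid reconstructions). Variables are shifted
#' to `x = v - lb >= 0`; finite upper bounds become explicit slack rows;
#' infinite bounds are capped at `cap` beforehand by the caller.
#'
#' @param obj Numeric objective coefficients, length n.
#' @param Aeq Numeric matrix (meq x n) of equality constraints (may have 0 rows).
#' @param beq Numeric right-hand side, length meq.
#' @param Ageq Optional matrix of >= constraints.
#' @param bgeq Right-hand side for `Ageq`.
#' @param lb,ub Numeric bounds, length n, all finite.
#' @param maximize Logical.
#' @param tol Pivot/feasibility tolerance.
#' @return List with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and `solution` (length n, on the original `v` scale).
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, Ageq = NULL, bgeq = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  Aeq <- as.matrix(Aeq)
  if (is.null(dim(Aeq)) || ncol(Aeq) != n)
    stop("Aeq must have ", n, " columns")
  if (!is.null(Ageq)) {
    Ageq <- as.matrix(Ageq)
    stopifnot(ncol(Ageq) == n, nrow(Ageq) == length(bgeq))
  }

  # shift: x = v - lb
  b_eq2 <- beq - drop(Aeq %*% lb)
  rng <- ub - lb

  # >= rows get surplus variables s >= 0 (bounded below only; cap generously)
  n_geq <- if (is.null(Ageq)) 0L else nrow(Ageq)
  b_geq2 <- if (n_geq) bgeq - drop(Ageq %*% lb) else numeric(0)

  # columns: x (n) | surplus (n_geq) | upper-bound slacks (n)
  ncol_tot <- n + n_geq + n
  mk <- function(nr) matrix(0, nr, ncol_tot)

  rows <- list(); rhs <- numeric(0)
  if (nrow(Aeq)) {
    R <- mk(nrow(Aeq)); R[, seq_len(n)] <- Aeq
    rows <- c(rows, list(R)); rhs <- c(rhs, b_eq2)
  }
  if (n_geq) {
    R <- mk(n_geq); R[, seq_len(n)] <- Ageq
    R[cbind(seq_len(n_geq), n + seq_len(n_geq))] <- -1
    rows <- c(rows, list(R)); rhs <- c(rhs, b_geq2)
  }
  # x_j + w_j = rng_j
  R <- mk(n)
  R[cbind(seq_len(n), seq_len(n))] <- 1
  R[cbind(seq_len(n), n + n_geq + seq_len(n))] <- 1
  rows <- c(rows, list(R)); rhs <- c(rhs, rng)

  A <- do.call(rbind, rows)
  b <- rhs
  neg <- b < 0
  A[neg, ] <- -A[neg, ]
  b[neg] <- -b[neg]

  cvec <- c(if (maximize) obj else -obj, rep(0, n_geq + n))
  res <- simplex_tableau(A, b, cvec, tol = tol)

  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_,
                solution = rep(NA_real_, n)))
  v <- res$x[seq_len(n)] + lb
  objv <- sum(obj * v)
  list(status = "optimal", objective = objv, solution = v)
}

# max c'x s.t. Ax = b (b >= 0), x >= 0 — two-phase full tableau, Bland's rule.
simplex_tableau <- function(A, b, cvec, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 50L * (m + n) + 2000L
  # artificial start basis
  Tb <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  nt <- n + m

  run_phase <- function(Tb, basis, cost, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      cb <- cost[basis]
      # reduced costs r_j = c_j - cb' T[,j]
      r <- cost[seq_len(nt)] - drop(cb %*% Tb[, seq_len(nt), drop = FALSE])
      cand <- which(allowed & r > tol)
      if (!length(cand)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- cand[1L]                       # Bland: smallest index enters
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, nt + 1L] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      i <- ties[which.min(basis[ties])]   # Bland: smallest basis index leaves
      # pivot on (i, j)
      Tb[i, ] <- Tb[i, ] / Tb[i, j]
      other <- setdiff(seq_len(nrow(Tb)), i)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
      basis[i] <- j
    }
  }

  # phase 1: maximise -(sum of artificials)
  cost1 <- c(rep(0, n), rep(-1, m))
  allowed1 <- rep(TRUE, nt)
  p1 <- run_phase(Tb, basis, cost1, allowed1)
  if (p1$status != "optimal") return(list(status = "infeasible", x = NULL))
  art_level <- sum(p1$Tb[p1$basis > n, nt + 1L])
  if (art_level > 1e-7) return(list(status = "infeasible", x = NULL))

  # drive remaining zero-level artificials out of the basis so they cannot
  # drift during phase 2; rows where no structural pivot exists are redundant
  Tb <- p1$Tb; basis <- p1$basis
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    j <- which(abs(Tb[i, seq_len(n)]) > tol)[1L]
    if (is.na(j)) { drop_rows <- c(drop_rows, i); next }
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    other <- setdiff(seq_len(nrow(Tb)), i)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
    basis[i] <- j
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  # phase 2: original costs; artificial columns may not re-enter
  cost2 <- c(cvec, rep(0, nt - n))
  allowed2 <- c(rep(TRUE, n), rep(FALSE, nt - n))
  p2 <- run_phase(Tb, basis, cost2, allowed2)
  if (p2$status != "optimal") return(list(status = p2$status, x = NULL))

  x <- numeric(n)
  inb <- p2$basis <= n
  x[p2$basis[inb]] <- p2$Tb[inb, nt + 1L]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}

# Cap infinite bounds for LP construction.
cap_bounds <- function(lb, ub, cap = 1000) {
  lb[!is.finite(lb)] <- -cap
  ub[!is.finite(ub)] <- cap
  list(lb = lb, ub = ub)
}
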