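# Linear programming backend.
#
# All LPs in the package (flux balance analysis, feasibility checks, the
# two-stage diet optimizer) go through one bounded-variable wrapper over a
# dense two-phase primal simplex with Bland's anti-cycling rule. Steady-
# state flux problems are heavily degenerate (many equality rows with zero
# right-hand side), so anti-cycling pivoting is required for reliable
# termination. Problems here are small (at most a few hundred variables),
# where a dense tableau is entirely adequate.

# Largest magnitude used to stand in for an unbounded flux.
DEFAULT_FLUX_BOUND <- 1e4

# Two-phase tableau simplex for
#   minimize cost' x  s.t.  A x = b, x >= 0,  with b >= 0.
# Bland's rule (first eligible entering column, lowest-index leaving basis
# variable on ratio ties) guarantees termination under degeneracy.
# Returns list(status = "optimal"|"infeasible"|"unbounded", x).
simplex_standard <- function(cost, A, b, eps = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cost) == n, all(b >= 0))
  max_iter <- max_iter %||% (500 + 50 * (n + m))

  run_phase <- function(T_, basis, cvec, n_cols) {
    for (it in seq_len(max_iter)) {
      cb <- cvec[basis]
      # reduced costs over structural columns
      rc <- cvec[seq_len(n_cols)] -
        as.numeric(crossprod(cb, T_[, seq_len(n_cols), drop = FALSE]))
      enter <- which(rc < -eps)
      if (length(enter) == 0) return(list(T_ = T_, basis = basis, status = "optimal"))
      j <- enter[1]                                    # Bland: first eligible
      col <- T_[, j]
      pos <- which(col > eps)
      if (length(pos) == 0) return(list(T_ = T_, basis = basis, status = "unbounded"))
      ratios <- T_[pos, n_cols + 1] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + eps]
      r <- cand[which.min(basis[cand])]                # Bland: lowest basis index
      # pivot on (r, j)
      T_[r, ] <- T_[r, ] / T_[r, j]
      other <- setdiff(seq_len(m), r)
      T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[r, ])
      basis[r] <- j
      if (it == max_iter) return(list(T_ = T_, basis = basis, status = "iteration_limit"))
    }
    list(T_ = T_, basis = basis, status = "iteration_limit")
  }

  # Phase 1: artificial basis
  n_all <- n + m
  T_ <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(T_, basis, cost1, n_all)
  if (ph1$status != "optimal") return(list(status = ph1$status, x = NULL))
  T_ <- ph1$T_; basis <- ph1$basis
  val1 <- sum(cost1[basis] * T_[, n_all + 1])
  if (val1 > 1e-7) return(list(status = "infeasible", x = NULL))
  # drive residual artificials out of the (degenerate) basis
  drop_rows <- integer(0)
  for (r in which(basis > n)) {
    piv <- which(abs(T_[r, seq_len(n)]) > eps)
    piv <- setdiff(piv, basis)
    if (length(piv) == 0) { drop_rows <- c(drop_rows, r); next }  # redundant row
    j <- piv[1]
    T_[r, ] <- T_[r, ] / T_[r, j]
    other <- setdiff(seq_len(m), r)
    T_[other, ] <- T_[other, ] - outer(T_[other, j], T_[r, ])
    basis[r] <- j
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    T_ <- T_[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- length(keep)
  }
  # Phase 2 on structural columns only
  T2 <- T_[, c(seq_len(n), n_all + 1), drop = FALSE]
  ph2 <- run_phase(T2, basis, cost, n)
  if (ph2$status != "optimal") return(list(status = ph2$status, x = NULL))
  x <- numeric(n)
  x[ph2$basis] <- ph2$T_[, n + 1]
  list(status = "optimal", x = x)
}

#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `mat %*% x (dir) rhs` and
#' `lb <= x <= ub`. Variables fixed by `lb == ub` are eliminated, the rest
#' shifted to `x >= 0`; inequality rows and upper bounds get slack columns,
#' and the resulting standard-form problem is solved by a two-phase simplex.
#' Infinite bounds are clamped to `+/- 1e4` (ample for mmol/day dietary
#' fluxes).
#'
#' @param obj numeric objective coefficients.
#' @param mat constraint matrix (dense or `Matrix` sparse), may have 0 rows.
#' @param dir character vector of `"<="`, `">="`, `"=="` per row.
#' @param rhs numeric right-hand sides.
#' @param lb,ub numeric variable bounds, recycled to length of `obj`.
#' @param maximize logical; maximize when `TRUE`.
#' @return list with `status` ("optimal", "infeasible", "unbounded", or
#'   "iteration_limit"), `value` (objective at the optimum or `NA`), and
#'   `solution` (the optimum on the original variable scale, or `NULL`).
#' @keywords internal
solve_lp <- function(obj, mat, dir, rhs, lb, ub, maximize = TRUE) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  lb[!is.finite(lb)] <- -DEFAULT_FLUX_BOUND
  ub[!is.finite(ub)] <- DEFAULT_FLUX_BOUND
  assert_that(all(lb <= ub), "lower bound exceeds upper bound")
  mat <- as.matrix(mat)
  if (nrow(mat) > 0) assert_that(ncol(mat) == n, "constraint matrix width mismatch")
  assert_that(length(dir) == nrow(mat) && length(rhs) == nrow(mat),
              "constraint dimensions disagree")

  # eliminate variables fixed by lb == ub: fold them into the rhs
  fixed <- lb == ub
  x_fixed <- lb
  free <- which(!fixed)
  if (nrow(mat) > 0 && any(fixed)) {
    rhs <- rhs - as.numeric(mat[, fixed, drop = FALSE] %*% lb[fixed])
  }
  obj_const <- sum(obj[fixed] * lb[fixed])
  if (length(free) == 0) {
    tol <- 1e-9
    ok <- nrow(mat) == 0 || all(
      (dir == "<=" & rhs >= -tol) | (dir == ">=" & rhs <= tol) |
      (dir == "==" & abs(rhs) <= tol))
    return(if (ok)
      list(status = "optimal", value = obj_const, solution = x_fixed)
      else list(status = "infeasible", value = NA_real_, solution = NULL))
  }
  matf <- mat[, free, drop = FALSE]
  lbf <- lb[free]; ubf <- ub[free]
  nf <- length(free)

  # shift x = v - lb (x >= 0); all rows become equalities with slacks:
  # general rows first, then the upper-bound rows x_i + s = ub - lb
  shift_rhs <- rhs - if (nrow(matf) > 0) as.numeric(matf %*% lbf) else numeric(0)
  n_gen <- nrow(matf)
  n_slack_gen <- sum(dir != "==")
  n_cols <- nf + n_slack_gen + nf           # x, general slacks, bound slacks
  A <- matrix(0, n_gen + nf, n_cols)
  b <- numeric(n_gen + nf)
  if (n_gen > 0) {
    A[seq_len(n_gen), seq_len(nf)] <- matf
    b[seq_len(n_gen)] <- shift_rhs
    sc <- nf
    for (i in seq_len(n_gen)) {
      if (dir[i] == "==") next
      sc <- sc + 1
      A[i, sc] <- if (dir[i] == "<=") 1 else -1
    }
  }
  brow <- n_gen + seq_len(nf)
  A[cbind(brow, seq_len(nf))] <- 1
  A[cbind(brow, nf + n_slack_gen + seq_len(nf))] <- 1
  b[brow] <- ubf - lbf
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  cost <- c(if (maximize) -obj[free] else obj[free], rep(0, n_cols - nf))
  res <- simplex_standard(cost, A, b)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_, solution = NULL))
  }
  x <- numeric(n)
  x[fixed] <- x_fixed[fixed]
  x[free] <- res$x[seq_len(nf)] + lbf
  list(status = "optimal", value = sum(obj * x), solution = x)
}
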