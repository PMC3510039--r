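# Linear-programming backend.
#
# The per-step optimizations are small dense LPs (tens of variables), solved
# by a two-phase tableau simplex with Bland's anti-cycling rule. Absolute
# values are linearized by splitting every flux V into nonnegative
# forward/reverse parts, V = f - r; reactions whose current lower bound is
# >= 0 get no reverse part.

# Standard-form simplex: min c'x s.t. A x = b (b >= 0), x >= 0.
# Two phases with artificial variables; Bland's rule guarantees
# termination. Returns list(x, value, status) with status "optimal",
# "infeasible" or "unbounded".
simplex_standard <- function(c_obj, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, all(b >= -tol))
  b <- pmax(b, 0)
  # scale rows for numerical stability
  rs <- pmax(apply(abs(A), 1, max), 1)
  A <- A / rs
  b <- b / rs
  Tb <- cbind(A, diag(m), b)          # tableau with artificials
  basis <- n + seq_len(m)
  run_phase <- function(Tb, basis, cost, tol) {
    m <- nrow(Tb); ncols <- ncol(Tb) - 1L
    repeat {
      cb <- cost[basis]
      # reduced costs: c_j - cb' B^{-1} A_j ; tableau rows are B^{-1}A
      red <- cost[seq_len(ncols)] - as.numeric(crossprod(cb, Tb[, seq_len(ncols), drop = FALSE]))
      enter <- which(red < -tol)
      if (length(enter) == 0) return(list(Tb = Tb, basis = basis,
                                          status = "optimal"))
      j <- min(enter)                  # Bland: smallest index enters
      col <- Tb[, j]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(Tb = Tb, basis = basis,
                                        status = "unbounded"))
      ratios <- Tb[pos, ncols + 1L] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])]  # Bland: smallest basic index leaves
      # pivot on (i, j)
      Tb[i, ] <- Tb[i, ] / Tb[i, j]
      other <- setdiff(seq_len(m), i)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
      basis[i] <- j
      Tb[, basis] <- 0; Tb[cbind(seq_len(m), basis)] <- 1
    }
  }
  # phase 1: drive artificials out
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tb, basis, cost1, tol)
  art_val <- sum(ph1$Tb[ph1$basis > n, n + m + 1L])
  if (ph1$status != "optimal" || art_val > 1e-7) {
    return(list(x = rep(NA_real_, n), value = NA_real_,
                status = "infeasible"))
  }
  Tb <- ph1$Tb; basis <- ph1$basis
  # pivot any lingering (degenerate) artificials out of the basis
  for (i in which(basis > n)) {
    row <- Tb[i, seq_len(n)]
    j <- which(abs(row) > tol)
    if (length(j) == 0) next            # redundant row
    j <- j[1]
    Tb[i, ] <- Tb[i, ] / Tb[i, j]
    other <- setdiff(seq_len(nrow(Tb)), i)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[i, ])
    basis[i] <- j
  }
  # drop redundant rows still carrying an artificial, then the artificial
  # columns, for phase 2
  redundant <- basis > n
  if (any(redundant)) {
    Tb <- Tb[!redundant, , drop = FALSE]
    basis <- basis[!redundant]
  }
  Tb2 <- Tb[, c(seq_len(n), n + m + 1L), drop = FALSE]
  ph2 <- run_phase(Tb2, basis, c_obj, tol)
  if (ph2$status == "unbounded") {
    return(list(x = rep(NA_real_, n), value = NA_real_,
                status = "unbounded"))
  }
  x <- numeric(n)
  rhs <- ph2$Tb[, ncol(ph2$Tb)]
  inb <- ph2$basis <= n
  x[ph2$basis[inb]] <- rhs[inb]
  x <- pmax(x, 0)
  list(x = x, value = sum(c_obj * x), status = "optimal")
}

# Solve: min/max obj'x s.t. Aeq x = beq, Ale x <= ble, lb <= x <= ub
# (finite bounds). Returns list(x, value, status).
lp_solve <- function(obj, lb, ub, Aeq = NULL, beq = NULL,
                     Ale = NULL, ble = NULL, maximize = FALSE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub + 1e-12))
  ub <- pmax(ub, lb)
  # shift x = lb + y (y >= 0); add slack s for y <= ub - lb, t for Ale rows
  n_ineq <- if (is.null(Ale)) 0L else nrow(matrix(Ale, ncol = n))
  # y + s = ub - lb
  Abox <- cbind(diag(n), diag(n),
                matrix(0, n, n_ineq))
  bbox <- ub - lb
  A_all <- Abox; b_all <- bbox
  if (n_ineq > 0) {
    Ale <- matrix(Ale, ncol = n)
    Aineq <- cbind(Ale, matrix(0, n_ineq, n), diag(n_ineq))
    bineq <- as.numeric(ble - Ale %*% lb)
    A_all <- rbind(A_all, Aineq); b_all <- c(b_all, bineq)
  }
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = n)
    Aeq_all <- cbind(Aeq, matrix(0, nrow(Aeq), n + n_ineq))
    beq_all <- as.numeric(beq - Aeq %*% lb)
    A_all <- rbind(A_all, Aeq_all); b_all <- c(b_all, beq_all)
  }
  neg <- b_all < 0
  if (any(neg)) {
    A_all[neg, ] <- -A_all[neg, , drop = FALSE]
    b_all <- abs(b_all)
  }
  c_full <- c(if (maximize) -obj else obj, rep(0, n + n_ineq))
  res <- simplex_standard(c_full, A_all, b_all)
  if (res$status != "optimal") {
    return(list(x = rep(NA_real_, n), value = NA_real_,
                status = res$status))
  }
  x <- lb + res$x[seq_len(n)]
  list(x = x, value = sum(obj * x), status = "optimal")
}

# Solve a flux program over a stoichiometric matrix with current total-flux
# bounds. Objective: minimize abs_w'(|V|) + lin_w'V (either part optional);
# optional extra constraint lock_w'|V| <= lock_rhs. Returns V, objective
# parts, and status.
solve_flux_lp <- function(S, lb, ub, abs_w = NULL, lin_w = NULL,
                          lock_w = NULL, lock_rhs = NULL, maximize = FALSE) {
  n <- ncol(S)
  if (is.null(abs_w)) abs_w <- numeric(n)
  if (is.null(lin_w)) lin_w <- numeric(n)
  rev_idx <- which(lb < 0)
  m <- length(rev_idx)
  # boxes: f in [max(0,lb), max(0,ub)], r in [max(0,-ub), max(0,-lb)]
  vlb <- c(pmax(0, lb), pmax(0, -ub[rev_idx]))
  vub <- c(pmax(0, ub), pmax(0, -lb[rev_idx]))
  Aeq <- cbind(S, -S[, rev_idx, drop = FALSE])
  beq <- numeric(nrow(S))
  obj <- c(abs_w + lin_w, abs_w[rev_idx] - lin_w[rev_idx])
  Ale <- NULL; ble <- NULL
  if (!is.null(lock_w)) {
    Ale <- matrix(c(lock_w, lock_w[rev_idx]), nrow = 1)
    ble <- lock_rhs
  }
  res <- lp_solve(obj, vlb, vub, Aeq = Aeq, beq = beq,
                  Ale = Ale, ble = ble, maximize = maximize)
  if (res$status != "optimal") {
    return(list(V = rep(NA_real_, n), status = res$status,
                abs_value = NA_real_, lin_value = NA_real_))
  }
  V <- res$x[seq_len(n)]
  if (m > 0) V[rev_idx] <- V[rev_idx] - res$x[n + seq_len(m)]
  list(V = V, status = "optimal",
       abs_value = sum(abs_w * abs(V)), lin_value = sum(lin_w * V))
}

# Maximum achievable flux through one reaction under the given bounds
# (plain FBA). Returns the optimum value, or NA if infeasible.
fba_max_flux <- function(S, lb, ub, reaction_index) {
  w <- numeric(ncol(S))
  w[reaction_index] <- 1
  res <- solve_flux_lp(S, lb, ub, lin_w = w, maximize = TRUE)
  if (res$status != "optimal") return(NA_real_)
  res$V[reaction_index]
}
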