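## ---------------------------------------------------------------------------
## A small exact solver for 0/1 / bounded-integer linear programs in
## inequality form:  minimize c'v  subject to  A v <= b,  v_j in {0,1} or
## {0..ub_j}.  Branch-and-bound over binary variables with interval
## propagation; auxiliary integer variables (zero objective coefficient,
## at most one positive-coefficient integer per constraint, as in the
## paralog model) are resolved by bound propagation.  The model container
## is environment-based with preallocated storage so that construction of
## instances with tens of thousands of rows stays linear.
## ---------------------------------------------------------------------------

milp_new <- function(nvar_hint = 64L, ncon_hint = 64L) {
  m <- new.env(parent = emptyenv())
  m$nvar <- 0L
  m$names <- character(nvar_hint)
  m$obj <- numeric(nvar_hint)
  m$vtype <- character(nvar_hint)
  m$ub <- numeric(nvar_hint)
  m$ix <- new.env(parent = emptyenv())   # name -> index
  m$ncon <- 0L
  ## constraints accumulate in a small buffer flushed into chunks, so that
  ## appending stays linear (R copies an environment-bound list on each
  ## element assignment, which would make direct appends quadratic)
  m$bufsize <- 512L
  m$buf_Ai <- vector("list", m$bufsize)
  m$buf_Av <- vector("list", m$bufsize)
  m$buf_rhs <- numeric(m$bufsize)
  m$buf_n <- 0L
  m$chunks <- list()
  m$Ai <- NULL; m$Av <- NULL; m$rhs <- NULL
  m
}

milp_flush <- function(m) {
  if (m$buf_n > 0L) {
    m$chunks[[length(m$chunks) + 1L]] <-
      list(Ai = m$buf_Ai[seq_len(m$buf_n)], Av = m$buf_Av[seq_len(m$buf_n)],
           rhs = m$buf_rhs[seq_len(m$buf_n)])
    m$buf_Ai <- vector("list", m$bufsize)
    m$buf_Av <- vector("list", m$bufsize)
    m$buf_rhs <- numeric(m$bufsize)
    m$buf_n <- 0L
  }
  invisible(m)
}

milp_finalize <- function(m) {
  milp_flush(m)
  if (is.null(m$Ai) || length(m$Ai) != m$ncon) {
    m$Ai <- unlist(lapply(m$chunks, `[[`, "Ai"), recursive = FALSE)
    m$Av <- unlist(lapply(m$chunks, `[[`, "Av"), recursive = FALSE)
    m$rhs <- unlist(lapply(m$chunks, `[[`, "rhs"))
  }
  invisible(m)
}

milp_add_var <- function(m, name, obj = 0, vtype = "B", ub = 1) {
  n <- m$nvar + 1L
  if (n > length(m$names)) {
    grow <- function(x) { length(x) <- 2L * length(x); x }
    m$names <- grow(m$names); m$obj <- grow(m$obj)
    m$vtype <- grow(m$vtype); m$ub <- grow(m$ub)
  }
  m$nvar <- n
  m$names[n] <- name; m$obj[n] <- obj; m$vtype[n] <- vtype; m$ub[n] <- ub
  assign(name, n, envir = m$ix)
  invisible(n)
}

milp_var <- function(m, name) get(name, envir = m$ix, inherits = FALSE)

milp_add_con <- function(m, idx, coef, rhs) {
  if (is.character(idx)) idx <- vapply(idx, milp_var, 1L, m = m)
  if (m$buf_n >= m$bufsize) milp_flush(m)
  j <- m$buf_n + 1L
  m$buf_n <- j
  m$buf_Ai[[j]] <- as.integer(idx)
  m$buf_Av[[j]] <- as.numeric(coef)
  m$buf_rhs[j] <- rhs
  m$ncon <- m$ncon + 1L
  invisible(m$ncon)
}

milp_sizes <- function(m) c(variables = m$nvar, constraints = m$ncon)

## interval propagation to a fixpoint; NULL when infeasible
milp_propagate <- function(m, lo, hi) {
  milp_finalize(m)
  ncon <- m$ncon
  changed <- TRUE; rounds <- 0L
  while (changed && rounds < 60L) {
    changed <- FALSE
    rounds <- rounds + 1L
    for (k in seq_len(ncon)) {
      ix <- m$Ai[[k]]; av <- m$Av[[k]]
      mins <- ifelse(av > 0, av * lo[ix], av * hi[ix])
      smin <- sum(mins)
      if (smin > m$rhs[k] + 1e-9) return(NULL)
      for (t in seq_along(ix)) {
        j <- ix[t]
        cap <- m$rhs[k] - (smin - mins[t])
        if (av[t] > 0) {
          nb <- floor(cap / av[t] + 1e-9)
          if (nb < hi[j]) { hi[j] <- nb; changed <- TRUE }
        } else {
          nb <- ceiling(cap / av[t] - 1e-9)
          if (nb > lo[j]) { lo[j] <- nb; changed <- TRUE }
        }
        if (lo[j] > hi[j]) return(NULL)
      }
    }
  }
  list(lo = lo, hi = hi)
}

## exact solve; branch_order: variable indices to branch on first
milp_solve <- function(m, branch_order = NULL) {
  milp_finalize(m)
  nvar <- m$nvar
  lo0 <- rep(0, nvar); hi0 <- m$ub[seq_len(nvar)]
  best <- new.env(parent = emptyenv())
  best$obj <- Inf; best$sol <- NULL
  obj <- m$obj[seq_len(nvar)]
  bins <- which(m$vtype[seq_len(nvar)] == "B")
  if (!is.null(branch_order)) bins <- c(branch_order, setdiff(bins, branch_order))

  rec <- function(lo, hi) {
    p <- milp_propagate(m, lo, hi)
    if (is.null(p)) return(invisible(NULL))
    lo <- p$lo; hi <- p$hi
    bound <- sum(ifelse(obj > 0, obj * lo, obj * hi))
    if (bound >= best$obj - 1e-9) return(invisible(NULL))
    free <- bins[lo[bins] < hi[bins]]
    if (!length(free)) {
      ## all binaries fixed; every auxiliary integer interval is feasible
      sol <- ifelse(obj > 0, lo, hi)
      best$obj <- bound
      best$sol <- sol
      return(invisible(NULL))
    }
    j <- free[1]
    for (v in if (obj[j] >= 0) c(0, 1) else c(1, 0)) {
      lo2 <- lo; hi2 <- hi
      lo2[j] <- v; hi2[j] <- v
      rec(lo2, hi2)
    }
    invisible(NULL)
  }
  rec(lo0, hi0)
  if (!is.finite(best$obj)) return(list(status = "infeasible"))
  sol <- best$sol
  names(sol) <- m$names[seq_len(nvar)]
  list(status = "optimal", objective = best$obj, solution = sol)
}
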