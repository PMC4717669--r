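## ---------------------------------------------------------------------------
## Paralog assignment by integer linear programming.  For two circular
## structures compared under equal standard-operation weights, the distance
## equals B + S1 - S2, where B is the number of blocks (special nodes) of
## the common graph, S1 the sum of integer parts of half-lengths of maximal
## conventional-edge regions, and S2 the number of circles made of
## conventional edges only.  The construction introduces matching variables
## z[k,i,j], block-border variables x, alternation variables y and circle
## indicators u/p whose optimal values realize those three summands.
## ---------------------------------------------------------------------------

## decompose gene ids into family/paralog (absent index counts as paralog 1)
par_index <- function(ids) {
  p <- gene_paralog(ids)
  ifelse(is.na(p), 1L, p)
}

## adjacent pairs of a structure: one row per adjacency with the two member
## gene occurrences (family, paralog, end)
adjacent_pairs <- function(s) {
  ad <- structure_adjacencies(s)
  if (!length(ad))
    return(data.frame(key = character(0), f1 = character(0), p1 = integer(0),
                      e1 = integer(0), f2 = character(0), p2 = integer(0),
                      e2 = integer(0), stringsAsFactors = FALSE))
  pp <- do.call(rbind, split_adj(ad))
  g1 <- ext_gene(pp[, 1]); g2 <- ext_gene(pp[, 2])
  data.frame(key = ad,
             f1 = gene_family(g1), p1 = par_index(g1),
             e1 = as.integer(sub("^.*:", "", pp[, 1])),
             f2 = gene_family(g2), p2 = par_index(g2),
             e2 = as.integer(sub("^.*:", "", pp[, 2])),
             stringsAsFactors = FALSE)
}

#' Build the paralog-matching ILP for two circular structures
#'
#' @param a,b `chrom_structure` objects whose chromosomes are all circular.
#' @param sim optional similarity table: data.frame with columns `family`,
#'   `pa`, `pb`, `sim` (values in `[0,1]`); pairs absent from the table
#'   default to similarity 1.  When supplied, the objective gains the
#'   penalty `sum z * (1 - sim)`, pairs with zero similarity are excluded
#'   and positive-similarity pairs may not leave two free paralogs.
#' @return a `paralog_ilp` object: the model plus per-family bookkeeping.
#' @export
build_matching_ilp <- function(a, b, sim = NULL) {
  if (any(vapply(a$chrs, function(ch) !ch$circular, TRUE)) ||
      any(vapply(b$chrs, function(ch) !ch$circular, TRUE)))
    stop("all chromosomes must be circular; use distance_with_paths() for mixed structures")
  ga <- structure_genes(a); gb <- structure_genes(b)
  Pa <- split(par_index(ga), gene_family(ga))
  Pb <- split(par_index(gb), gene_family(gb))
  fams <- intersect(names(Pa), names(Pb))
  pa_pairs <- adjacent_pairs(a)
  pb_pairs <- adjacent_pairs(b)
  nz <- sum(vapply(fams, function(k) length(Pa[[k]]) * length(Pb[[k]]), 1))
  npair <- nrow(pa_pairs) + nrow(pb_pairs)
  m <- milp_new(nvar_hint = max(64L, as.integer(nz + 4L * npair)),
                ncon_hint = max(64L, as.integer(8L * (nz + npair))))
  cnt <- c(z_vars = 0L, z_cons = 0L, x_vars = 0L, x_cons = 0L,
           y_vars = 0L, y_cons = 0L, up_vars = 0L, up_cons = 0L)
  simval <- function(k, i, j) {
    if (is.null(sim)) return(1)
    r <- sim[sim$family == k & sim$pa == i & sim$pb == j, "sim"]
    if (length(r)) r[1] else 1
  }
  zname <- function(k, i, j) paste0("z.", k, ".", i, ".", j)
  for (k in fams) {
    for (i in Pa[[k]]) for (j in Pb[[k]]) {
      s <- simval(k, i, j)
      milp_add_var(m, zname(k, i, j), obj = if (is.null(sim)) 0 else 1 - s,
                   vtype = "B", ub = if (!is.null(sim) && s == 0) 0 else 1)
      cnt["z_vars"] <- cnt["z_vars"] + 1L
    }
    for (i in Pa[[k]]) {
      milp_add_con(m, vapply(Pb[[k]], function(j) zname(k, i, j), ""),
                   rep(1, length(Pb[[k]])), 1)
      cnt["z_cons"] <- cnt["z_cons"] + 1L
    }
    for (j in Pb[[k]]) {
      milp_add_con(m, vapply(Pa[[k]], function(i) zname(k, i, j), ""),
                   rep(1, length(Pa[[k]])), 1)
      cnt["z_cons"] <- cnt["z_cons"] + 1L
    }
  }
  ## chromosomes whose families are all absent from the other structure are
  ## whole blocks (one deletion or insertion each); chromosomes that do have
  ## shared families must keep at least one matched gene, otherwise the
  ## block-border device would miss a block that spans the entire circle
  const_blocks <- 0L
  cover_cons <- 0L
  zcache <- new.env(parent = emptyenv())
  zsum_idx <- function(side, k, i) {
    if (!k %in% fams) return(integer(0))
    key <- paste0(side, "|", k, "|", i)
    if (!is.null(v <- zcache[[key]])) return(v)
    v <- if (side == "a")
      vapply(Pb[[k]], function(j) milp_var(m, zname(k, i, j)), 1L)
    else vapply(Pa[[k]], function(ii) milp_var(m, zname(k, ii, i)), 1L)
    zcache[[key]] <- v
    v
  }
  for (side in c("a", "b")) {
    s <- if (side == "a") a else b
    chrom_z <- list()
    for (ch in s$chrs) {
      fam <- gene_family(ch$id); pix <- par_index(ch$id)
      zi <- integer(0)
      for (t in seq_along(fam))
        zi <- c(zi, zsum_idx(side, fam[t], pix[t]))
      zi <- unique(zi)
      if (!length(zi)) const_blocks <- const_blocks + 1L
      else chrom_z[[length(chrom_z) + 1L]] <- zi
    }
    if (length(chrom_z) == 1L) {
      ## a single chromosome with shared families always keeps a match
      milp_add_con(m, chrom_z[[1]], rep(-1, length(chrom_z[[1]])), -1)
      cover_cons <- cover_cons + 1L
    } else if (length(chrom_z) > 1L) {
      ## soft indicators: a fully unmatched chromosome is one whole block
      for (q in seq_along(chrom_z)) {
        wv <- milp_add_var(m, paste0("w", side, ".", q), obj = 1)
        milp_add_con(m, c(wv, chrom_z[[q]]), rep(-1, 1 + length(chrom_z[[q]])), -1)
        cover_cons <- cover_cons + 1L
      }
    }
  }
  ## m_s: pairwise-distinct values 1..N (N = total number of adjacent
  ## pairs, so every value lies in the stated range).  Distinctness makes
  ## "exactly one u reaches its maximum on each circle of conventional
  ## edges" hold: the u variables are equal around such a circle, so only
  ## the pair with the smallest m_s can attain its own bound.
  msv <- list(a = seq_len(nrow(pa_pairs)),
              b = nrow(pa_pairs) + seq_len(nrow(pb_pairs)))
  uidx <- list(a = integer(0), b = integer(0))
  yidx <- list(a = integer(0), b = integer(0))
  for (side in c("a", "b")) {
    pr <- if (side == "a") pa_pairs else pb_pairs
    f1 <- pr$f1; p1 <- pr$p1; f2 <- pr$f2; p2 <- pr$p2
    nr <- nrow(pr)
    if (nr) { yidx[[side]] <- integer(nr); uidx[[side]] <- integer(nr) }
    for (r in seq_len(nr)) {
      ms <- msv[[side]][r]
      xi <- milp_add_var(m, paste0("x", side, ".", r), obj = 0.5)
      cnt["x_vars"] <- cnt["x_vars"] + 1L
      i1 <- zsum_idx(side, f1[r], p1[r])
      i2 <- zsum_idx(side, f2[r], p2[r])
      milp_add_con(m, c(i1, i2, xi), c(rep(1, length(i1)), rep(-1, length(i2)), -1), 0)
      milp_add_con(m, c(i2, i1, xi), c(rep(1, length(i2)), rep(-1, length(i1)), -1), 0)
      cnt["x_cons"] <- cnt["x_cons"] + 2L
      yidx[[side]][r] <- milp_add_var(m, paste0("y", side, ".", r), obj = 1)
      ui <- milp_add_var(m, paste0("u", side, ".", r), obj = 0, vtype = "I", ub = ms)
      uidx[[side]][r] <- ui
      pi <- milp_add_var(m, paste0("p", side, ".", r), obj = -1)
      cnt["y_vars"] <- cnt["y_vars"] + 1L
      cnt["up_vars"] <- cnt["up_vars"] + 2L
      milp_add_con(m, c(pi, ui), c(ms, -1), 0)              # p*ms <= u
      cnt["up_cons"] <- cnt["up_cons"] + 1L
      for (gix in 1:2) {
        k <- if (gix == 1) f1[r] else f2[r]
        i <- if (gix == 1) p1[r] else p2[r]
        zi <- zsum_idx(side, k, i)
        milp_add_con(m, c(ui, zi), c(1, rep(-ms, length(zi))), 0)
        cnt["up_cons"] <- cnt["up_cons"] + 1L
      }
    }
  }
  ## potential neighbours: a-pair s1 and b-pair s2 sharing the same
  ## extremity type (family, end) through paralogs i (in s1), j (in s2)
  occ <- function(pr) {
    if (!nrow(pr)) return(NULL)
    rbind(data.frame(r = seq_len(nrow(pr)), f = pr$f1, p = pr$p1, e = pr$e1,
                     of = pr$f2, op = pr$p2, stringsAsFactors = FALSE),
          data.frame(r = seq_len(nrow(pr)), f = pr$f2, p = pr$p2, e = pr$e2,
                     of = pr$f1, op = pr$p1, stringsAsFactors = FALSE))
  }
  oa <- occ(pa_pairs); ob <- occ(pb_pairs)
  if (!is.null(oa) && !is.null(ob)) {
    key_a <- paste(oa$f, oa$e); key_b <- paste(ob$f, ob$e)
    grp_b <- split(seq_len(nrow(ob)), key_b)
    oa_f <- oa$f; oa_p <- oa$p; oa_of <- oa$of; oa_op <- oa$op; oa_r <- oa$r
    ob_p <- ob$p; ob_of <- ob$of; ob_op <- ob$op; ob_r <- ob$r
    ya <- yidx$a; yb <- yidx$b; ua <- uidx$a; ub <- uidx$b
    ycons <- 0L; ucons <- 0L
    for (u1 in seq_len(nrow(oa))) {
      fam <- oa_f[u1]
      if (!fam %in% fams) next
      ib <- grp_b[[key_a[u1]]]
      if (is.null(ib)) next
      za <- zsum_idx("a", oa_of[u1], oa_op[u1])
      y1 <- ya[oa_r[u1]]
      u1i <- ua[oa_r[u1]]
      for (u2 in ib) {
        z0 <- milp_var(m, zname(fam, oa_p[u1], ob_p[u2]))
        zb <- zsum_idx("b", ob_of[u2], ob_op[u2])
        y2 <- yb[ob_r[u2]]
        milp_add_con(m, c(y1, y2, z0, za, zb),
                     c(1, 1, 1, rep(1, length(za)), rep(1, length(zb))), 4)
        milp_add_con(m, c(z0, za, zb, y1, y2),
                     c(1, rep(1, length(za)), rep(1, length(zb)), -1, -1), 2)
        ycons <- ycons + 2L
        u2i <- ub[ob_r[u2]]
        ms1 <- msv$a[oa_r[u1]]; ms2 <- msv$b[ob_r[u2]]
        milp_add_con(m, c(u1i, u2i, z0), c(1, -1, ms1), ms1)
        milp_add_con(m, c(u2i, u1i, z0), c(1, -1, ms2), ms2)
        ucons <- ucons + 2L
      }
    }
    cnt["y_cons"] <- cnt["y_cons"] + ycons
    cnt["up_cons"] <- cnt["up_cons"] + ucons
  }
  if (!is.null(sim)) {
    for (k in fams) for (i in Pa[[k]]) for (j in Pb[[k]]) {
      if (simval(k, i, j) > 0) {
        zi <- unique(c(zsum_idx("a", k, i), zsum_idx("b", k, j)))
        milp_add_con(m, zi, rep(-1, length(zi)), -1)
      }
    }
  }
  cnt2 <- as.list(cnt)
  cnt2$x_vars_a <- nrow(pa_pairs)
  cnt2$x_vars_b <- nrow(pb_pairs)
  cnt2$cover_cons <- cover_cons
  structure(list(model = m, counts = cnt2, fams = fams, Pa = Pa, Pb = Pb,
                 pa_pairs = pa_pairs, pb_pairs = pb_pairs, ms = msv,
                 const_blocks = const_blocks, a = a, b = b, sim = sim),
            class = "paralog_ilp")
}

#' @export
print.paralog_ilp <- function(x, ...) {
  cat("paralog-matching ILP:", x$model$nvar, "variables,",
      x$model$ncon, "constraints\n")
  str(ilp_size(x), give.attr = FALSE)
  invisible(x)
}

#' Variable and constraint counts of the matching ILP
#'
#' @param ilp a `paralog_ilp`.
#' @return named list: per-family counts plus totals.
#' @export
ilp_size <- function(ilp) {
  c(ilp$counts, list(total_vars = ilp$model$nvar, total_cons = ilp$model$ncon))
}

#' Solve the paralog matching and return bijections and distance
#'
#' @param a,b circular `chrom_structure` objects.
#' @param sim optional similarity table (see [build_matching_ilp()]).
#' @return list with `bijections` (per family data.frame pa -> pb),
#'   `distance` (B + S1 - S2 at the optimum), `relabelled` structures with
#'   matched paralogs sharing indices, and the components `B`, `S1`, `S2`.
#' @export
solve_paralog_matching <- function(a, b, sim = NULL) {
  ilp <- build_matching_ilp(a, b, sim)
  m <- ilp$model
  res <- milp_solve(m, branch_order = which(startsWith(m$names[seq_len(m$nvar)], "z.")))
  if (!identical(res$status, "optimal")) stop("ILP solve failed: ", res$status)
  sol <- res$solution
  B <- 0.5 * sum(sol[startsWith(names(sol), "xa.") | startsWith(names(sol), "xb.")]) +
    sum(sol[startsWith(names(sol), "wa.") | startsWith(names(sol), "wb.")]) +
    ilp$const_blocks
  S1 <- sum(sol[startsWith(names(sol), "ya.") | startsWith(names(sol), "yb.")])
  S2 <- sum(sol[startsWith(names(sol), "pa.") | startsWith(names(sol), "pb.")])
  bij <- list()
  for (k in ilp$fams) {
    rows <- data.frame(pa = integer(0), pb = integer(0))
    for (i in ilp$Pa[[k]]) for (j in ilp$Pb[[k]])
      if (sol[[paste0("z.", k, ".", i, ".", j)]] > 0.5)
        rows <- rbind(rows, data.frame(pa = i, pb = j))
    bij[[k]] <- rows
  }
  rel <- relabel_matched(a, b, bij)
  list(bijections = bij, distance = B + S1 - S2, B = B, S1 = S1, S2 = S2,
       relabelled = rel, objective = res$objective)
}

## rewrite paralog indices so that matched paralogs share an index and
## unmatched paralogs get fresh, distinct indices
relabel_matched <- function(a, b, bij) {
  map_side <- function(s, side) {
    ids <- structure_genes(s)
    fam <- gene_family(ids); pix <- par_index(ids)
    newid <- ids
    for (k in unique(fam)) {
      rows <- bij[[k]]
      nxt <- if (!is.null(rows)) nrow(rows) else 0L
      for (t in which(fam == k)) {
        p <- pix[t]
        hit <- if (!is.null(rows) && nrow(rows)) {
          if (side == "a") match(p, rows$pa) else match(p, rows$pb)
        } else NA_integer_
        if (!is.na(hit)) newid[t] <- paste0(k, ".", hit)
        else {
          nxt <- nxt + 1L
          newid[t] <- paste0(k, ".", nxt, if (side == "b") "00" else "0")
        }
      }
    }
    lk <- stats::setNames(newid, ids)
    s$chrs <- lapply(s$chrs, function(ch) { ch$id <- unname(lk[ch$id]); ch })
    s
  }
  list(a = map_side(a, "a"), b = map_side(b, "b"))
}

#' Close all linear chromosomes of a structure into circles
#'
#' @param a a `chrom_structure`.
#' @return list with `closed` (all-circular structure) and `n_paths`.
#' @export
close_paths <- function(a) {
  n <- 0L
  chrs <- lapply(a$chrs, function(ch) {
    if (!ch$circular) { n <<- n + 1L; ch$circular <- TRUE }
    ch
  })
  list(closed = chrom_structure(chrs, a$name), n_paths = n)
}

#' Biological distance for mixed linear/circular structures with paralogs
#'
#' Closes all paths into circles, solves the circular paralog ILP on the
#' closures and adds the number of closed paths.  The result differs from
#' the true minimum by at most `2 * (n1 + n2)`.
#'
#' @param a,b `chrom_structure` objects.
#' @param sim optional similarity table.
#' @return list with `value`, `error_bound`, `n1`, `n2`, `matching`.
#' @export
distance_with_paths <- function(a, b, sim = NULL) {
  ca <- close_paths(a); cb <- close_paths(b)
  r <- solve_paralog_matching(ca$closed, cb$closed, sim)
  list(value = r$distance + ca$n_paths + cb$n_paths,
       error_bound = 2 * (ca$n_paths + cb$n_paths),
       n1 = ca$n_paths, n2 = cb$n_paths, matching = r)
}

#' Breakpoint distance minimized over paralog assignments
#'
#' A 0/1 program couples gene-matching variables with adjacency-preservation
#' indicators; its optimum equals the exhaustive minimum of the breakpoint
#' distance over all paralog bijections.
#'
#' @param a,b `chrom_structure` objects.
#' @return list with `bijections` and `distance`.
#' @export
breakpoint_matching <- function(a, b) {
  ga <- structure_genes(a); gb <- structure_genes(b)
  Pa <- split(par_index(ga), gene_family(ga))
  Pb <- split(par_index(gb), gene_family(gb))
  fams <- intersect(names(Pa), names(Pb))
  m <- milp_new()
  zname <- function(k, i, j) paste0("z.", k, ".", i, ".", j)
  for (k in fams) {
    for (i in Pa[[k]]) for (j in Pb[[k]])
      milp_add_var(m, zname(k, i, j), obj = -2)
    for (i in Pa[[k]])
      milp_add_con(m, vapply(Pb[[k]], function(j) zname(k, i, j), ""),
                   rep(1, length(Pb[[k]])), 1)
    for (j in Pb[[k]])
      milp_add_con(m, vapply(Pa[[k]], function(i) zname(k, i, j), ""),
                   rep(1, length(Pa[[k]])), 1)
  }
  pa_pairs <- adjacent_pairs(a); pb_pairs <- adjacent_pairs(b)
  tvars <- character(0)
  if (nrow(pa_pairs) && nrow(pb_pairs)) {
    for (r1 in seq_len(nrow(pa_pairs))) for (r2 in seq_len(nrow(pb_pairs))) {
      s1 <- pa_pairs[r1, ]; s2 <- pb_pairs[r2, ]
      for (al in 1:2) {
        m1 <- if (al == 1) list(s2$f1, s2$p1, s2$e1) else list(s2$f2, s2$p2, s2$e2)
        m2 <- if (al == 1) list(s2$f2, s2$p2, s2$e2) else list(s2$f1, s2$p1, s2$e1)
        ok <- s1$f1 == m1[[1]] && s1$e1 == m1[[3]] && s1$f1 %in% fams &&
          s1$f2 == m2[[1]] && s1$e2 == m2[[3]] && s1$f2 %in% fams
        if (!ok) next
        tn <- paste0("t.", r1, ".", r2, ".", al)
        milp_add_var(m, tn, obj = -2)
        tvars <- c(tvars, tn)
        milp_add_con(m, c(tn, zname(s1$f1, s1$p1, m1[[2]])), c(1, -1), 0)
        milp_add_con(m, c(tn, zname(s1$f2, s1$p2, m2[[2]])), c(1, -1), 0)
      }
    }
    for (r1 in seq_len(nrow(pa_pairs))) {
      tv <- tvars[startsWith(tvars, paste0("t.", r1, "."))]
      if (length(tv)) milp_add_con(m, tv, rep(1, length(tv)), 1)
    }
    for (r2 in seq_len(nrow(pb_pairs))) {
      tv <- tvars[grepl(paste0("^t\\.[0-9]+\\.", r2, "\\.[12]$"), tvars)]
      if (length(tv)) milp_add_con(m, tv, rep(1, length(tv)), 1)
    }
  }
  res <- milp_solve(m, branch_order = which(startsWith(m$names[seq_len(m$nvar)], "z.")))
  if (!identical(res$status, "optimal")) stop("ILP solve failed")
  const <- nrow(pa_pairs) + nrow(pb_pairs) + length(ga) + length(gb)
  sol <- res$solution
  bij <- list()
  for (k in fams) {
    rows <- data.frame(pa = integer(0), pb = integer(0))
    for (i in Pa[[k]]) for (j in Pb[[k]])
      if (sol[[zname(k, i, j)]] > 0.5) rows <- rbind(rows, data.frame(pa = i, pb = j))
    bij[[k]] <- rows
  }
  list(bijections = bij, distance = const + res$objective)
}
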