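#' Algebraic null-space basis of an (S0 | -D) matrix
#'
#' For a stoichiometric matrix with the growth-dilution block structure
#' \eqn{S = (S_0 | -D)}, the columns of
#' \eqn{G = (I_r ; D^{-1} S_0)} form a basis of the null space:
#' \eqn{S G = S_0 - D D^{-1} S_0 = 0}.  Each column is the flux pattern
#' obtained by running one non-dilution reaction at unit rate and letting
#' the dilution pseudo-reactions absorb the net production.
#'
#' @param S a `bp_smatrix` with the (S0 | -D) structure.
#' @return an n x r matrix with rows named by reaction id.
#' @export
build_null_basis_G <- function(S) {
  M <- S$matrix
  r <- S$r
  n <- ncol(M)
  dil_cols <- seq.int(r + 1L, n)
  D <- M[, dil_cols, drop = FALSE]
  offdiag <- D; diag(offdiag) <- 0
  if (any(offdiag != 0) || any(diag(D) >= 0))
    stop("dilution block is not diagonal with strictly negative diagonal")
  d <- -diag(D)
  S0 <- M[, seq_len(r), drop = FALSE]
  G <- rbind(diag(1, r), S0 / d)  # rows of S0 divided by d elementwise
  dimnames(G) <- list(S$reaction_index, S$reaction_index[seq_len(r)])
  G
}

# nonnegative least squares with column equilibration (Lawson-Hanson is
# sensitive to column scaling); returns NULL when the solver fails
nnls_scaled <- function(A, b) {
  cs <- sqrt(colSums(A^2)); cs[cs == 0] <- 1
  fit <- tryCatch(pracma::lsqnonneg(sweep(A, 2, cs, "/"), b),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(x = fit$x / cs, resid = sqrt(fit$resid.norm))
}

# one nonnegative null vector through reaction j via nonnegative least
# squares on the remaining columns; returns NULL on failure
nn_column_nnls <- function(M, j, tol = 1e-8) {
  fit <- nnls_scaled(M[, -j, drop = FALSE], -M[, j])
  if (is.null(fit)) return(NULL)
  scale <- max(1, sqrt(sum(M[, j]^2)))
  if (fit$resid > tol * scale) return(NULL)
  w <- numeric(ncol(M))
  w[j] <- 1
  w[-j] <- fit$x
  w
}

#' Nonnegative flux decomposition
#'
#' Decomposes a nonnegative steady-state rate vector into nonnegative
#' null-space components with positive weights, by greedy support
#' shrinking: repeatedly extract a flux-cone vertex supported inside the
#' remaining flux and subtract the largest multiple that keeps the
#' remainder nonnegative (which zeroes at least one reaction, so the
#' procedure terminates).  By the conic Caratheodory argument such a
#' decomposition always exists for a flux in the cone.
#'
#' @param S a `bp_smatrix`.
#' @param R nonnegative steady rate vector (`S R = 0`).
#' @param tol relative activity threshold.
#' @return list with `components` (matrix, one nonnegative null vector
#'   per column) and `weights` (positive), with
#'   `components %*% weights = R`.
#' @export
decompose_flux <- function(S, R, tol = 1e-10) {
  M <- S$matrix
  R <- R[S$reaction_index]
  scale <- max(R)
  if (max(abs(M %*% R)) > 1e-8 * max(1, scale))
    stop("R is not a steady-state flux")
  Rw <- R
  comps <- list(); lam <- numeric(0)
  for (it in seq_len(2L * length(R))) {
    if (max(Rw) <= tol * scale) break
    supp <- which(Rw > tol * scale)
    w <- NULL
    for (j in supp[order(Rw[supp])]) {
      oth <- supp[supp != j]
      fit <- nnls_scaled(M[, oth, drop = FALSE], -M[, j])
      if (!is.null(fit) &&
          fit$resid < 1e-8 * max(1, sqrt(sum(M[, j]^2)))) {
        w <- numeric(length(R)); w[j] <- 1; w[oth] <- fit$x
        break
      }
    }
    if (is.null(w)) w <- Rw / max(Rw)  # remainder is itself a component
    act <- which(w > 1e-12)
    ratio <- Rw[act] / w[act]
    l <- min(ratio)
    comps[[length(comps) + 1L]] <- w
    lam <- c(lam, l)
    Rw <- Rw - l * w
    Rw[act[ratio < l * (1 + 1e-12)]] <- 0
    Rw[Rw < 0] <- 0
  }
  W <- do.call(cbind, comps)
  rownames(W) <- S$reaction_index
  list(components = W, weights = lam)
}

# numerical column rank on unit-max-scaled columns
num_col_rank <- function(A, tol = 1e-10) {
  cs <- apply(abs(A), 2, max); cs[cs == 0] <- 1
  qr(sweep(A, 2, cs, "/"), tol = tol)$rank
}

# greedy selection of k independent columns, in the given order
greedy_independent_columns <- function(A, k, row_names = NULL) {
  keep <- integer(0)
  for (jc in seq_len(ncol(A))) {
    if (num_col_rank(A[, c(keep, jc), drop = FALSE]) == length(keep) + 1L)
      keep <- c(keep, jc)
    if (length(keep) == k) break
  }
  out <- A[, keep, drop = FALSE]
  if (!is.null(row_names)) rownames(out) <- row_names
  out
}

# Monotone multi-pass sweep turning G into nonnegative columns.  Only
# columns that are already entirely nonnegative may serve as pivots:
# adding a positive multiple of a nonnegative column removes the targeted
# negative entry and can never create a new one, so each column converges
# in at most one step per negative row.  Columns whose producers have not
# converged yet are deferred to a later pass (e.g. a metallation step
# whose apo substrate comes from a biosynthesis column further down the
# reaction list).  Columns the sweep cannot clear (mutually dependent
# loops with no nonnegative producer path) are rebuilt as flux-cone
# vertices by nonnegative least squares.
sweep_nonnegative <- function(G, S, tol = 1e-9) {
  W <- G
  r <- ncol(W)
  done <- vapply(seq_len(r), function(j) min(W[, j]) >= -tol, TRUE)
  repeat {
    progress <- FALSE
    for (j in which(!done)) {
      repeat {
        k <- which.min(W[, j])
        if (W[k, j] >= -tol) { done[j] <- TRUE; progress <- TRUE; break }
        cand <- setdiff(which(done & W[k, ] > tol), j)
        if (!length(cand)) break  # defer to next pass
        p <- cand[[1]]
        W[, j] <- W[, j] + (-W[k, j] / W[k, p]) * W[, p]
        W[k, j] <- 0
      }
    }
    if (all(done) || !progress) break
  }
  for (j in which(!done)) {
    w <- nn_column_nnls(S$matrix, j)
    if (is.null(w))
      stop("could not build a nonnegative basis column through reaction ",
           S$reaction_index[j],
           "; no nonnegative steady flux uses this reaction")
    W[, j] <- w
  }
  W[W < 0 & W > -tol] <- 0
  if (any(W < 0))
    stop("nonnegative transformation failed for column(s): ",
         paste(which(apply(W, 2, min) < 0), collapse = ", "))
  W
}

#' Transform a null-space basis into a nonnegative Basic-Pathways basis
#'
#' Negative entries of `G` (reactions that net-consume a component, so
#' that its dilution would have to run backwards) are eliminated by
#' repeatedly adding positive multiples of other columns that produce the
#' offending component, a Gaussian-elimination-like sweep that preserves
#' the column span.  Columns that resist elimination are rebuilt
#' individually by nonnegative least squares on the full matrix.  The
#' result is checked against the contract: all entries nonnegative,
#' `S %*% W = 0`, rank r, every row and column carrying at least one
#' nonzero.  Columns are scaled so that the entry of their first singleton
#' row equals 1 (singleton-deficient columns are scaled to unit maximum).
#'
#' @param G null-space basis from [build_null_basis_G()].
#' @param S the `bp_smatrix` the basis belongs to.
#' @param tol numerical tolerance for zero/negativity decisions.
#' @param anchor optional nonnegative steady-state rate vector; when
#'   given, the basis is built around its [decompose_flux()] components
#'   so that the anchor flux has an exactly nonnegative weight vector.
#' @return an object of class `bp_basis`: list with the nonnegative matrix
#'   `W`, `reaction_index`, `singleton_rows` (row index -> column index),
#'   `deficient_columns`, `sparsity` and `provenance`.
#' @export
make_nonnegative_basis <- function(G, S, tol = 1e-9, anchor = NULL) {
  n <- nrow(G); r <- ncol(G)
  W <- sweep_nonnegative(G, S, tol)
  if (!is.null(anchor)) {
    # Anchored construction: decompose the reference flux into
    # nonnegative components with positive weights and prefer those as
    # basis columns, completing the span from the swept columns.  The
    # anchor then has an exactly nonnegative weight vector in the
    # resulting basis - mirroring a basis built around the wild-type
    # state - which a generic basis cannot guarantee (an r-generator
    # simplicial cone is a strict subcone of the full flux cone).
    dec <- decompose_flux(S, anchor)
    W <- greedy_independent_columns(
      cbind(dec$components, W), r, S$reaction_index)
  }
  W <- sweep(W, 2, apply(W, 2, max), "/")
  resid <- max(abs(S$matrix %*% W))
  if (resid > 1e-8 * max(1, max(abs(W))))
    stop("null-space residual too large after transformation: ", resid)
  if (num_col_rank(W) != r) {
    # A rebuilt vertex can land inside the span of the other columns
    # (extreme rays need not be in general position).  Because every
    # reaction carries flux in some cone element, the cone spans the full
    # null space, so the span can always be completed by perturbing a
    # strictly positive interior flux along a complementary null
    # direction: w = x* + eps g stays nonnegative and adds the missing
    # dimension.
    pool <- lapply(seq_len(r), function(j) nn_column_nnls(S$matrix, j))
    if (any(vapply(pool, is.null, TRUE)))
      stop("reaction(s) ",
           paste(S$reaction_index[vapply(pool, is.null, TRUE)],
                 collapse = ", "),
           " carry no nonnegative steady flux; the cone does not span ",
           "the null space and no nonnegative basis of size r exists")
    xstar <- rowSums(vapply(pool, function(w) w / max(w), numeric(n)))
    keep <- integer(0)
    for (jc in seq_len(ncol(W))) {
      trial <- W[, c(keep, jc), drop = FALSE]
      if (num_col_rank(trial) == length(keep) + 1L)
        keep <- c(keep, jc)
    }
    Wk <- W[, keep, drop = FALSE]
    while (ncol(Wk) < r) {
      Q <- qr.Q(qr(Wk))
      # complementary null direction: column of G with the largest
      # residual after projecting onto the current span
      Gres <- G - Q %*% (t(Q) %*% G)
      gnorm <- sqrt(colSums(Gres^2))
      g <- Gres[, which.max(gnorm)]
      g <- g / sqrt(sum(g^2))
      neg <- g < 0
      eps <- if (any(neg)) 0.5 * min(xstar[neg] / (-g[neg])) else 1
      w_new <- xstar + eps * g
      w_new[w_new < 0] <- 0   # roundoff at the binding entries
      Wk <- cbind(Wk, w_new / max(w_new))
    }
    W <- Wk
    resid <- max(abs(S$matrix %*% W))
    if (resid > 1e-8 * max(1, max(abs(W))))
      stop("null-space residual too large after span completion: ", resid)
    if (num_col_rank(W) != r)
      stop("could not complete a nonnegative basis of rank ", r)
  }
  zero_rows <- which(rowSums(W != 0) == 0)
  if (length(zero_rows))
    stop("reaction(s) used by no basic pathway: ",
         paste(S$reaction_index[zero_rows], collapse = ", "))

  basis <- normalize_basis(W, S$reaction_index, provenance = "constructed")
  basis
}

normalize_basis <- function(W, reaction_index, provenance) {
  stats_ <- singleton_stats(W)
  for (j in seq_len(ncol(W))) {
    srows <- which(stats_$singleton_map == j)
    scale <- if (length(srows)) W[min(srows), j] else max(W[, j])
    W[, j] <- W[, j] / scale
  }
  stats_ <- singleton_stats(W)
  structure(list(W = W, reaction_index = reaction_index,
                 singleton_rows = stats_$singleton_map,
                 deficient_columns = stats_$deficient_columns,
                 sparsity = stats_$sparsity,
                 provenance = provenance),
            class = "bp_basis")
}

#' @export
print.bp_basis <- function(x, ...) {
  s <- singleton_stats(x$W)
  cat("Basic-pathway basis:", ncol(x$W), "pathways over", nrow(x$W),
      "reactions\n  sparsity", round(s$sparsity, 3), "|",
      s$singleton_row_count, "singleton rows |",
      s$deficient_column_count, "deficient columns\n")
  invisible(x)
}

#' Singleton structure of a nonnegative basis
#'
#' A singleton row has exactly one nonzero entry; its pathway weight can
#' be read directly from one reaction rate.  A singleton-deficient column
#' has no singleton element and its weight requires solving a small linear
#' system.
#'
#' @param W nonnegative basis matrix (or a `bp_basis`).
#' @return list with `sparsity`, `singleton_row_count`,
#'   `singleton_row_rank`, `deficient_column_count`, `deficient_columns`
#'   and `singleton_map` (per-row column index, NA for non-singleton rows).
#' @export
singleton_stats <- function(W) {
  if (inherits(W, "bp_basis")) W <- W$W
  nz <- W != 0
  rn <- rowSums(nz)
  singleton <- rn == 1L
  map <- rep(NA_integer_, nrow(W))
  map[singleton] <- apply(nz[singleton, , drop = FALSE], 1, which)
  deficient <- setdiff(seq_len(ncol(W)), unique(map[!is.na(map)]))
  list(sparsity = mean(!nz),
       singleton_row_count = sum(singleton),
       singleton_row_rank = sum(singleton) / nrow(W),
       deficient_column_count = length(deficient),
       deficient_columns = deficient,
       singleton_map = map)
}

#' Rate assignment for the steady-state solve
#'
#' @param independent named numeric vector: reaction id -> assigned rate
#'   (uM/min, cytosol-referenced), all nonnegative.
#' @param zero_set reaction ids fixed at rate 0 (merged into the
#'   independent set).
#' @return an object of class `bp_assignment`.
#' @export
rate_assignment <- function(independent, zero_set = character(0)) {
  if (length(zero_set)) {
    zero_set <- setdiff(zero_set, names(independent))
    independent <- c(independent, stats::setNames(rep(0, length(zero_set)),
                                                  zero_set))
  }
  if (any(independent < 0)) stop("assigned rates must be >= 0")
  if (anyDuplicated(names(independent)))
    stop("duplicate reaction ids in assignment")
  structure(list(independent = independent), class = "bp_assignment")
}

#' Select an independent reaction set
#'
#' Chooses r reactions whose rows of W form an invertible system, greedily
#' preferring the supplied candidates in order (typically all dilution
#' reactions first, mirroring that dilution rates are directly measurable
#' as growth rate times steady-state concentration, then any reactions
#' with justifiably known rates).
#'
#' @param basis a `bp_basis`.
#' @param prefer reaction ids to prefer, in priority order; defaults to
#'   the dilution reactions (ids after position r).
#' @return character vector of r reaction ids.
#' @export
select_independent_set <- function(basis, prefer = NULL) {
  W <- basis$W
  ids <- basis$reaction_index
  r <- ncol(W)
  n <- nrow(W)
  if (is.null(prefer)) prefer <- ids[seq.int(r + 1L, n)]  # the dilutions
  pref_idx <- match(intersect(prefer, ids), ids)
  ord <- c(pref_idx, setdiff(seq_len(n), pref_idx))
  # greedy Gram-Schmidt over candidate rows, honoring the preference
  # order: a row is taken iff it adds a new dimension
  Q <- matrix(0, r, 0)
  picked <- integer(0)
  for (i in ord) {
    v <- W[i, ]
    nv <- sqrt(sum(v^2))
    if (nv == 0) next
    res <- v - Q %*% (t(Q) %*% v)
    if (sqrt(sum(res^2)) > 1e-8 * nv) {
      Q <- cbind(Q, res / sqrt(sum(res^2)))
      picked <- c(picked, i)
    }
    if (length(picked) == r) break
  }
  if (length(picked) < r)
    stop("W rows span only ", length(picked), " of ", r,
         " dimensions; no independent set exists")
  ids[sort(picked)]
}

#' Solve for pathway weights from assigned independent rates
#'
#' Weights of columns owning a singleton row among the independent
#' reactions are read off directly as `c_j = R_i / w_ij` (ties broken by
#' lowest row index).  The remaining weights are found from the reduced
#' linear system over the independent rows, with the already-solved
#' contributions subtracted.  The full system restricted to independent
#' rows must close with residual below `tol`; weights in `[-1e-10, 0)` are
#' clamped to zero and larger negatives raise an infeasibility error.
#'
#' @param basis a `bp_basis`.
#' @param assignment a [rate_assignment()] with r independent rates.
#' @param tol residual tolerance.
#' @return nonnegative weight vector `C_BP` of length r, named `BP01`...
#' @export
solve_weights <- function(basis, assignment, tol = 1e-8) {
  W <- basis$W
  ids <- basis$reaction_index
  r <- ncol(W)
  R_ind <- assignment$independent
  unknown <- setdiff(names(R_ind), ids)
  if (length(unknown))
    stop("assignment names unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  if (length(R_ind) != r)
    stop("need exactly r = ", r, " independent rates, got ", length(R_ind))
  I <- match(names(R_ind), ids)

  cvec <- rep(NA_real_, r)
  smap <- basis$singleton_rows
  used_rows <- integer(0)
  for (i in sort(intersect(which(!is.na(smap)), I))) {
    j <- smap[i]
    if (is.na(cvec[j])) {
      cvec[j] <- R_ind[[match(i, I)]] / W[i, j]
      used_rows <- c(used_rows, i)
    }
  }
  J2 <- which(is.na(cvec))
  if (length(J2)) {
    I2 <- setdiff(I, used_rows)
    b <- R_ind[match(I2, I)] -
      W[I2, -J2, drop = FALSE] %*% ifelse(is.na(cvec[-J2]), 0, cvec[-J2])
    A <- W[I2, J2, drop = FALSE]
    # equilibrate: pathway fluxes span many orders of magnitude and an
    # unscaled decomposition would misjudge the rank
    rs <- apply(abs(A), 1, max); rs[rs == 0] <- 1
    As <- A / rs
    cs <- apply(abs(As), 2, max); cs[cs == 0] <- 1
    As <- sweep(As, 2, cs, "/")
    qrA <- qr(As, tol = 1e-10)
    if (qrA$rank < length(J2))
      stop("independent set insufficient; unresolvable column(s): ",
           paste(J2, collapse = ", "))
    cJ2 <- qr.coef(qrA, as.numeric(b) / rs) / cs
    cvec[J2] <- cJ2
  }
  # full-system consistency over all independent rows
  resid <- max(abs(W[I, , drop = FALSE] %*% cvec - R_ind))
  scale <- max(1, max(abs(R_ind)))
  if (resid > tol * scale)
    stop("assigned rates are inconsistent with the basis (residual ",
         format(resid), ")")
  cvec[cvec < 0 & cvec >= -1e-10] <- 0
  if (any(cvec < 0))
    stop("infeasible assignment: negative weight for column(s) ",
         paste(which(cvec < 0), collapse = ", "))
  stats::setNames(cvec, sprintf("BP%02d", seq_len(r)))
}

#' Compose a full rate vector from pathway weights
#'
#' @param basis a `bp_basis`.
#' @param C_BP nonnegative weights, length r.
#' @return nonnegative rate vector over all n reactions, named by id.
#' @export
compose_rates <- function(basis, C_BP) {
  if (length(C_BP) != ncol(basis$W))
    stop("C_BP must have length r = ", ncol(basis$W))
  if (any(C_BP < 0)) stop("pathway weights must be >= 0")
  stats::setNames(as.numeric(basis$W %*% C_BP), basis$reaction_index)
}

#' Decompose a rate vector onto the basic-pathway basis
#'
#' Least-squares projection; the decomposition is exact (residual ~ 0)
#' whenever `R` lies in the span of W, in particular for any steady-state
#' rate vector of the network.
#'
#' @param basis a `bp_basis`.
#' @param R rate vector of length n (nonnegative).
#' @return list with `C_BP` and `residual` (Euclidean norm).
#' @export
decompose_rates <- function(basis, R) {
  if (any(R < 0)) stop("rates must be >= 0")
  fit <- qr.coef(qr(basis$W, LAPACK = TRUE), R)
  fit[is.na(fit)] <- 0
  resid <- sqrt(sum((basis$W %*% fit - R)^2))
  list(C_BP = stats::setNames(as.numeric(fit),
                              sprintf("BP%02d", seq_len(ncol(basis$W)))),
       residual = resid)
}

#' Chemical reading of one basic pathway
#'
#' Components whose dilution reaction is active in the pathway are being
#' made in excess; those among them that no active reaction consumes are
#' the pathway's destinations, the others are co-diluted intermediates.
#' Nutrients consumed by active import reactions are the sources.  A
#' pathway consuming no nutrient and diluting nothing is a cycle.
#'
#' @param w one column of W (named by reaction id, or unnamed with the
#'   basis order), or a column index together with `basis`.
#' @param network the `bp_network` the basis was built from.
#' @param basis optional `bp_basis` when `w` is a column index.
#' @param tol activity threshold.
#' @return list with `nutrients_consumed`, `destinations`,
#'   `intermediates_diluted`, `active_reactions` and `cyclic`.
#' @export
classify_pathway <- function(w, network, basis = NULL, tol = 1e-10) {
  if (length(w) == 1 && !is.null(basis)) {
    w <- stats::setNames(basis$W[, w], basis$reaction_index)
  }
  ids <- names(w)
  active <- ids[abs(w) > tol]
  comp <- network$components
  nutrients <- character(0)
  diluted <- character(0)
  consumed <- character(0)
  for (id in active) {
    rxn <- network_reaction(network, id)
    if (is_dilution(rxn)) {
      diluted <- c(diluted, names(rxn$reactants))
    } else {
      rs <- names(rxn$reactants)
      roles <- comp$role[match(rs, comp$name)]
      nutrients <- c(nutrients, rs[roles == "nutrient"])
      consumed <- c(consumed, rs[roles != "nutrient"])
    }
  }
  nutrients <- unique(nutrients)
  destinations <- setdiff(diluted, consumed)
  list(nutrients_consumed = nutrients,
       destinations = destinations,
       intermediates_diluted = intersect(diluted, consumed),
       active_reactions = active,
       cyclic = length(nutrients) == 0 && length(diluted) == 0)
}

#' Build a complete steady state
#'
#' Solves the pathway weights from the assignment, composes the full rate
#' vector and attaches the steady-state concentrations; the result is
#' verified against `S R = 0` and `R >= 0`.
#'
#' @param network a `bp_network`.
#' @param basis a `bp_basis` built from the network's S matrix.
#' @param assignment a [rate_assignment()].  Dilution rates must be
#'   consistent with `U_ss` (alpha_cell times the cellular concentration
#'   over f_c, i.e. the cytosol-referenced dilution rate).
#' @param U_ss named cellular concentrations (uM); defaults to the
#'   component table's `conc_uM`.
#' @param S optional `bp_smatrix` (rebuilt when missing) for verification.
#' @return object of class `bp_steady_state` with `R_cell`, `C_BP`,
#'   `U_ss`.
#' @export
build_steady_state <- function(network, basis, assignment, U_ss = NULL,
                               S = NULL) {
  if (is.null(S)) S <- build_smatrix(network)
  if (is.null(U_ss)) {
    comp <- network$components
    int <- internal_components(network)
    U_ss <- stats::setNames(comp$conc_uM[match(int, comp$name)], int)
  }
  C_BP <- solve_weights(basis, assignment)
  R_cell <- compose_rates(basis, C_BP)
  resid <- max(abs(S$matrix %*% R_cell))
  if (resid > 1e-8 * max(1, max(abs(R_cell))))
    stop("steady-state rates violate S R = 0 (residual ", format(resid), ")")
  structure(list(R_cell = R_cell, C_BP = C_BP, U_ss = U_ss),
            class = "bp_steady_state")
}

#' @export
print.bp_steady_state <- function(x, ...) {
  cat("Steady state:", length(x$R_cell), "rates,",
      sum(x$R_cell > 0), "nonzero;",
      length(x$C_BP), "pathway weights\n")
  invisible(x)
}

#' Cytosol-referenced dilution rates implied by concentrations
#'
#' The dilution pseudo-reaction of component i removes it at
#' `alpha_cell * [C_i]_local` in its home compartment; expressed in the
#' cytosol-referenced frame shared by all rates this is
#' `alpha_cell * [C_i]_local * f_k / f_c = alpha_cell * [C_i]_cellular / f_c`.
#'
#' @param network a `bp_network`.
#' @param U_ss named cellular concentrations (uM); defaults to the
#'   component table.
#' @return named vector over dilution reaction ids (`D<name>`).
#' @export
dilution_rate_assignment <- function(network, U_ss = NULL) {
  comp <- network$components
  int <- internal_components(network)
  if (is.null(U_ss))
    U_ss <- stats::setNames(comp$conc_uM[match(int, comp$name)], int)
  f_c <- network$morphology$fractions[["c"]]
  alpha <- network$morphology$alpha_cell
  dil_ids <- vapply(Filter(is_dilution, network$reactions), `[[`, "", "id")
  targets <- sub("^D", "", dil_ids)
  # map via the actual reactant, not the name convention
  targets <- vapply(Filter(is_dilution, network$reactions),
                    function(r) names(r$reactants), "")
  stats::setNames(alpha * U_ss[targets] / f_c, dil_ids)
}
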