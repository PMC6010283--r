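#' Default distance cutoffs
#'
#' Cutoff for spring placement: 7.5 A for C-alpha networks and 3.5 A for
#' heavy-atom (all-atom) networks.
#'
#' @param mode `"calpha"` or `"heavy_atom"`.
#' @return cutoff in Angstrom.
#' @export
defaultCutoff <- function(mode = c("calpha", "heavy_atom")) {
    switch(match.arg(mode), calpha = 7.5, heavy_atom = 3.5)
}

#' Mode-subset sizes used throughout the package
#'
#' The low-frequency mode grid \{5, 10, 20, 30, 50\}, clipped to the
#' number of available nonzero modes with a warning for small systems.
#'
#' @param nNonzero number of nonzero modes available (N - 1 for a
#'   connected network); `Inf` returns the grid unclipped.
#' @return integer vector of subset sizes.
#' @export
modeSubsets <- function(nNonzero = Inf) {
    grid <- c(5L, 10L, 20L, 30L, 50L)
    if (is.finite(nNonzero) && any(grid > nNonzero)) {
        keep <- unique(pmin(grid, as.integer(nNonzero)))
        warning("mode subsets clipped to ", nNonzero,
                " available nonzero modes")
        return(keep)
    }
    grid
}

#' Build the GNM Kirchhoff matrix
#'
#' Connects every node pair within `rc` (inclusive) by a spring of
#' stiffness `gamma`: entry (i, j) is -gamma iff i != j and
#' ||x_i - x_j|| <= rc, and each diagonal entry is minus the sum of its
#' row's off-diagonals.
#'
#' @param m a [CoarseModel-class].
#' @param rc distance cutoff in Angstrom; default depends on the model's
#'   selection mode (see [defaultCutoff()]).
#' @param gamma spring stiffness; it cancels in normalized correlations.
#' @return a [KirchhoffMatrix-class].
#' @examples
#' chain <- new("CoarseModel",
#'              coords = cbind(c(0, 5, 10), 0, 0),
#'              resKeys = c("A|1|", "A|2|", "A|3|"),
#'              atomNames = rep("CA", 3), selectionMode = "calpha")
#' as.matrix(buildKirchhoff(chain, rc = 7.5))
#' @export
buildKirchhoff <- function(m, rc = defaultCutoff(m@selectionMode),
                           gamma = 1) {
    stopifnot(is(m, "CoarseModel"), rc > 0, gamma > 0)
    d <- as.matrix(stats::dist(m@coords))
    k <- ifelse(d <= rc, -gamma, 0)
    diag(k) <- 0
    diag(k) <- -rowSums(k)
    dimnames(k) <- NULL
    new("KirchhoffMatrix", matrix = k, rc = rc, gamma = gamma)
}

#' Diagonalize a Kirchhoff matrix
#'
#' Computes the full eigensystem with eigenvalues ascending, counting
#' eigenvalues below `zeroTol * lambda_max` as zero modes. A connected
#' contact network has exactly one zero mode; more than one means the
#' network is disconnected at the chosen cutoff, which is an error.
#'
#' @param k a [KirchhoffMatrix-class].
#' @param zeroTol relative tolerance separating zero modes.
#' @return a [ModeSet-class].
#' @export
decomposeModes <- function(k, zeroTol = 1e-10) {
    stopifnot(is(k, "KirchhoffMatrix"))
    ## decompose the unit-stiffness matrix so the eigenbasis (and hence
    ## any mode subset) is bitwise independent of gamma; its entries are
    ## integers (-1, 0, node degree), so rounding removes the division's
    ## last-ulp noise. Eigenvalues are rescaled afterwards.
    e <- eigen(round(k@matrix / k@gamma), symmetric = TRUE)
    ord <- order(e$values)
    values <- e$values[ord] * k@gamma
    vectors <- e$vectors[, ord, drop = FALSE]
    scale <- max(values)
    if (scale <= 0)
        stop("contact network is disconnected at rc = ", k@rc,
             " A (no contacts at all); raise rc")
    values[abs(values) < zeroTol * scale] <- 0
    nZero <- sum(values < zeroTol * scale)
    if (nZero > 1L)
        stop("contact network is disconnected at rc = ", k@rc,
             " A (", nZero, " zero modes); raise rc or analyse the ",
             "largest connected component")
    new("ModeSet", values = values, vectors = vectors,
        nZero = as.integer(nZero))
}

.checkModeCount <- function(ms, nModes) {
    avail <- length(ms@values) - ms@nZero
    if (nModes < 1L || nModes > avail)
        stop("nModes must be in 1..", avail,
             " (nonzero modes available), got ", nModes)
    avail
}

#' Mode-subset pseudo-inverse of the Kirchhoff matrix
#'
#' Sums lambda_i^-1 V_i V_i' over the `nModes` lowest-frequency nonzero
#' modes. With all N-1 nonzero modes this equals the Moore-Penrose
#' pseudo-inverse of the Kirchhoff matrix.
#'
#' @param ms a [ModeSet-class].
#' @param nModes number of nonzero modes to use.
#' @return symmetric positive-semidefinite N x N matrix.
#' @export
modePseudoInverse <- function(ms, nModes) {
    stopifnot(is(ms, "ModeSet"))
    nModes <- as.integer(nModes)
    .checkModeCount(ms, nModes)
    idx <- ms@nZero + seq_len(nModes)
    v <- ms@vectors[, idx, drop = FALSE]
    g <- v %*% (t(v) / ms@values[idx])
    (g + t(g)) / 2
}

#' GNM dynamic cross-correlation matrix
#'
#' Normalizes the mode-subset pseudo-inverse G:
#' DCC(i, j) = G(i, j) / sqrt(G(i, i) G(j, j)), with the diagonal set to
#' exactly 1. A node whose diagonal entry vanishes is invisible to the
#' chosen modes (it sits on a node of every selected mode shape) and is
#' reported as an error; adding modes resolves it.
#'
#' @param ms a [ModeSet-class].
#' @param nModes number of nonzero modes to use.
#' @param resKeys optional residue keys carried into the result.
#' @return a [CorrelationMatrix-class] with `source = "gnm"`.
#' @export
dccGNM <- function(ms, nModes, resKeys = character()) {
    g <- modePseudoInverse(ms, nModes)
    dg <- diag(g)
    dead <- which(dg <= 1e-12 * max(dg))
    if (length(dead))
        stop("node(s) ", paste(dead, collapse = ", "),
             " have zero fluctuation in the chosen ", nModes,
             " mode(s); use more modes")
    dcc <- g / sqrt(outer(dg, dg))
    dcc <- pmin(pmax(dcc, -1), 1)
    dcc <- (dcc + t(dcc)) / 2
    diag(dcc) <- 1
    new("CorrelationMatrix", matrix = dcc, source = "gnm",
        nModes = as.integer(nModes), resKeys = resKeys)
}

#' GNM cross-correlations straight from a coarse model
#'
#' Convenience wrapper: Kirchhoff matrix, eigendecomposition and
#' normalized correlations in one call.
#'
#' @param m a [CoarseModel-class].
#' @param nModes number of nonzero modes (default 20, the subset at
#'   which agreement with trajectory-derived correlations converges).
#' @param rc distance cutoff in Angstrom.
#' @param gamma spring stiffness.
#' @return a [CorrelationMatrix-class].
#' @export
gnmCorrelations <- function(m, nModes = 20L,
                            rc = defaultCutoff(m@selectionMode),
                            gamma = 1) {
    ms <- decomposeModes(buildKirchhoff(m, rc = rc, gamma = gamma))
    nModes <- min(as.integer(nModes), length(ms@values) - ms@nZero)
    dccGNM(ms, nModes, resKeys = m@resKeys)
}
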