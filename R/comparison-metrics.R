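.labelsOf <- function(p) {
    if (is(p, "CommunityPartition")) p@labels else as.integer(p)
}

## Exact maximum-trace assignment over label permutations, by dynamic
## programming over column subsets: O(k^2 2^k), exact for the k <= 10
## community counts used here. Ties in the trace are broken by
## maximizing the product of matched marginals (the chance-agreement
## term), which depends only on the confusion-matrix content, so the
## outcome -- and any kappa computed from it -- is invariant to how
## either partition happened to number its labels.
.bestPermutation <- function(confusion) {
    k <- nrow(confusion)
    stopifnot(ncol(confusion) == k)
    rowS <- rowSums(confusion)
    colS <- colSums(confusion)
    nS <- bitwShiftL(1L, k)
    best <- rep(-Inf, nS)
    best2 <- rep(-Inf, nS)
    choice <- integer(nS)
    from <- integer(nS)
    best[1L] <- 0; best2[1L] <- 0
    for (S in 0:(nS - 1L)) {
        if (!is.finite(best[S + 1L])) next
        row <- sum(bitwAnd(S, bitwShiftL(1L, 0:(k - 1L))) != 0L) + 1L
        if (row > k) next
        for (col in seq_len(k)) {
            bit <- bitwShiftL(1L, col - 1L)
            if (bitwAnd(S, bit) != 0L) next
            S2 <- bitwOr(S, bit)
            val <- best[S + 1L] + confusion[row, col]
            val2 <- best2[S + 1L] + rowS[row] * colS[col]
            if (val > best[S2 + 1L] ||
                (val == best[S2 + 1L] && val2 > best2[S2 + 1L])) {
                best[S2 + 1L] <- val
                best2[S2 + 1L] <- val2
                choice[S2 + 1L] <- col
                from[S2 + 1L] <- S
            }
        }
    }
    perm <- integer(k)
    S <- nS - 1L
    for (row in rev(seq_len(k))) {
        perm[row] <- choice[S + 1L]
        S <- from[S + 1L]
    }
    perm                            # perm[row of a] = matched label of b
}

#' Align the labels of one partition to another
#'
#' Community labels from independent clusterings are arbitrary, so
#' before computing agreement the labels of `b` are permuted to
#' maximize the trace of the a-vs-b confusion matrix (an exact optimal
#' assignment). Both partitions must cover the same nodes with the same
#' community count.
#'
#' @param a reference [CommunityPartition-class].
#' @param b partition to relabel.
#' @return `b` with permuted labels.
#' @export
alignLabels <- function(a, b) {
    stopifnot(is(a, "CommunityPartition"), is(b, "CommunityPartition"))
    if (length(a@labels) != length(b@labels))
        stop("partitions cover different node sets (",
             length(a@labels), " vs ", length(b@labels), " nodes)")
    if (length(a@resKeys) && length(b@resKeys) &&
        !identical(a@resKeys, b@resKeys))
        stop("partitions cover different node sets (residue keys differ)")
    if (a@nc != b@nc)
        stop("partitions have different community counts")
    conf <- table(factor(a@labels, levels = seq_len(a@nc)),
                  factor(b@labels, levels = seq_len(b@nc)))
    perm <- .bestPermutation(unclass(conf))
    relabel <- integer(a@nc)
    relabel[perm] <- seq_len(a@nc)  # b label perm[r] becomes a label r
    newLabels <- relabel[b@labels]
    new("CommunityPartition", labels = newLabels, nc = b@nc,
        resKeys = b@resKeys)
}

#' Cohen's kappa between two partitions
#'
#' Chance-corrected agreement K = (p_o - p_e) / (1 - p_e), with p_o the
#' fraction of nodes assigned the same label and p_e the agreement
#' expected from the marginal label frequencies. Labels must already be
#' matched (see [alignLabels()]); otherwise K is meaningless. In the
#' degenerate case where both partitions put everything in one class
#' (p_e = 1, p_o = 1), K is 1.
#'
#' @param a,b partitions (or plain integer label vectors) over the same
#'   nodes.
#' @return kappa in \[-1, 1\].
#' @examples
#' cohensKappa(c(1, 1, 2, 2), c(1, 2, 2, 2))   # 0.5
#' @export
cohensKappa <- function(a, b) {
    la <- .labelsOf(a); lb <- .labelsOf(b)
    if (length(la) != length(lb))
        stop("label vectors differ in length")
    n <- length(la)
    po <- mean(la == lb)
    labs <- union(la, lb)
    pe <- sum(vapply(labs, function(k)
        (sum(la == k) / n) * (sum(lb == k) / n), numeric(1)))
    if (abs(1 - pe) < 1e-15)
        return(if (po >= 1 - 1e-15) 1 else 0)
    (po - pe) / (1 - pe)
}

#' Kappa profile across community counts
#'
#' For each community count in `ncRange` (clipped to the node count),
#' detects communities from both correlation matrices, aligns the
#' labels, and computes Cohen's kappa. Also reports the maximum kappa
#' (Kappa_max) and the community count achieving it, taking the
#' smallest count on ties.
#'
#' @param c1,c2 [CorrelationMatrix-class] objects over the same nodes.
#' @param ncRange community counts to evaluate (default 2:10).
#' @return list with `kappaByNc` (named numeric), `kappaMax`,
#'   `kappaMaxNc`.
#' @export
kappaProfile <- function(c1, c2, ncRange = 2:10) {
    stopifnot(is(c1, "CorrelationMatrix"), is(c2, "CorrelationMatrix"))
    n <- nrow(c1@matrix)
    if (nrow(c2@matrix) != n)
        stop("correlation matrices cover different node counts: ",
             n, " vs ", nrow(c2@matrix))
    ## harmonize node naming: a matrix without residue keys inherits the
    ## other's, so partitions over the same nodes are comparable
    if (!length(c1@resKeys) && length(c2@resKeys))
        c1@resKeys <- c2@resKeys
    if (!length(c2@resKeys) && length(c1@resKeys))
        c2@resKeys <- c1@resKeys
    if (length(c1@resKeys) && !identical(c1@resKeys, c2@resKeys))
        stop("correlation matrices cover different node sets ",
             "(residue keys differ)")
    ncRange <- ncRange[ncRange >= 2L & ncRange <= min(10L, n)]
    d1 <- wpgmaLinkage(distanceTransform(c1))
    d2 <- wpgmaLinkage(distanceTransform(c2))
    kap <- vapply(ncRange, function(nc) {
        p1 <- cutCommunities(d1, nc)
        p2 <- alignLabels(p1, cutCommunities(d2, nc))
        cohensKappa(p1, p2)
    }, numeric(1))
    names(kap) <- ncRange
    imax <- which.max(kap)          # which.max takes the first maximum
    list(kappaByNc = kap, kappaMax = unname(kap[imax]),
         kappaMaxNc = as.integer(ncRange[imax]))
}

#' Weighted closeness centrality of the residue network
#'
#' Builds the complete graph whose edge weights are the
#' distance-transformed correlations, computes all-pairs shortest paths,
#' and returns 1 / farness for each node, where farness is the sum of
#' shortest-path lengths to every other node. A node at distance zero
#' from all others has infinite centrality and is flagged with a
#' warning.
#'
#' @param d a [DistanceCorrelationMatrix-class] or plain symmetric
#'   nonnegative matrix.
#' @return numeric vector of closeness centralities.
#' @export
closenessCentrality <- function(d) {
    m <- if (is(d, "DistanceCorrelationMatrix")) d@matrix else d
    stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2L)
    if (any(m < 0)) {
        warning("negative edge weights clipped to 0")
        m[m < 0] <- 0
    }
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ## zero-weight pairs are dropped by weighted = TRUE; restore them as
    ## explicit zero-weight edges so shortest paths can use them
    full <- which(upper.tri(m), arr.ind = TRUE)
    have <- igraph::as_edgelist(g, names = FALSE)
    haveKey <- paste(pmin(have[, 1], have[, 2]),
                     pmax(have[, 1], have[, 2]))
    missing <- full[!paste(full[, 1], full[, 2]) %in% haveKey, ,
                    drop = FALSE]
    if (nrow(missing))
        g <- igraph::add_edges(g, t(missing), weight = 0)
    sp <- igraph::distances(g, weights = igraph::E(g)$weight,
                            algorithm = "dijkstra")
    farness <- rowSums(sp)
    if (any(farness == 0))
        warning("node(s) ", paste(which(farness == 0), collapse = ", "),
                " are at distance 0 from all others; centrality is Inf")
    1 / farness
}

#' Correlation of two centrality vectors
#'
#' Pearson by default; Spearman available as an option.
#'
#' @param x,y numeric vectors of equal length (>= 3), not constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation coefficient.
#' @export
centralityCorrelation <- function(x, y,
                                  method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (length(x) != length(y) || length(x) < 3L)
        stop("need two vectors of equal length >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("centrality vector is constant; correlation undefined")
    stats::cor(x, y, method = method)
}

#' Root-mean-square inner product of principal eigenvector sets
#'
#' Singular value decomposition of each correlation matrix; the `n`
#' singular vectors of largest singular value form the subspaces U and
#' V, and RMSIP = sqrt( (1/n) sum_ij (V_i . U_j)^2 ). 1 means identical
#' subspaces, 0 orthogonal ones; the value is invariant to rotations of
#' either basis within its own span.
#'
#' @param A,B [CorrelationMatrix-class] objects (or plain symmetric
#'   matrices) over the same nodes.
#' @param n number of principal vectors to compare.
#' @return RMSIP in \[0, 1\].
#' @export
rmsip <- function(A, B, n) {
    ma <- if (is(A, "CorrelationMatrix")) A@matrix else A
    mb <- if (is(B, "CorrelationMatrix")) B@matrix else B
    stopifnot(nrow(ma) == nrow(mb))
    n <- as.integer(n)
    if (n < 1L || n > nrow(ma))
        stop("n must be in 1..", nrow(ma), ", got ", n)
    U <- svd(ma, nu = n, nv = 0)$u
    V <- svd(mb, nu = n, nv = 0)$u
    sqrt(sum(crossprod(U, V)^2) / n)
}

#' Full GNM-vs-MD comparison report
#'
#' Runs the three agreement metrics between two correlation matrices of
#' the same nodes: the kappa profile over community counts with
#' Kappa_max, the correlation of weighted closeness centralities, and
#' the RMSIP of the `nModes` leading singular vectors.
#'
#' @param cGNM,cMD [CorrelationMatrix-class] objects over the same
#'   nodes (any two sources are accepted; names reflect the typical
#'   use).
#' @param nModes number of singular vectors for RMSIP; defaults to the
#'   GNM matrix's mode-subset size, clipped to the node count.
#' @param ncRange community counts for the kappa profile.
#' @param centralityMethod `"pearson"` (default) or `"spearman"`.
#' @return a [ComparisonReport-class].
#' @export
compareCorrelations <- function(cGNM, cMD, nModes = cGNM@nModes,
                                ncRange = 2:10,
                                centralityMethod = c("pearson",
                                                     "spearman")) {
    centralityMethod <- match.arg(centralityMethod)
    if (is.na(nModes)) nModes <- 10L
    nModes <- min(as.integer(nModes), nrow(cGNM@matrix))
    prof <- kappaProfile(cGNM, cMD, ncRange)
    cc <- centralityCorrelation(
        closenessCentrality(distanceTransform(cGNM)),
        closenessCentrality(distanceTransform(cMD)),
        method = centralityMethod)
    ov <- rmsip(cGNM, cMD, nModes)
    new("ComparisonReport", kappaByNc = prof$kappaByNc,
        kappaMax = prof$kappaMax, kappaMaxNc = prof$kappaMaxNc,
        centralityCorrelation = cc, centralityMethod = centralityMethod,
        rmsip = ov, nModes = nModes)
}
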