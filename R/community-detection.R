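#' Distance transform of a correlation matrix
#'
#' Entrywise 1 - DCC with the diagonal forced to exact zero. Perfectly
#' correlated pairs are at distance 0, uncorrelated pairs at 1 and
#' perfectly anticorrelated pairs at 2.
#'
#' @param c a [CorrelationMatrix-class].
#' @return a [DistanceCorrelationMatrix-class].
#' @export
distanceTransform <- function(c) {
    stopifnot(is(c, "CorrelationMatrix"))
    m <- 1 - c@matrix
    diag(m) <- 0
    m[m < 0] <- 0
    new("DistanceCorrelationMatrix", matrix = m, source = c@source,
        resKeys = c@resKeys)
}

## WPGMA agglomeration. At each step the pair of clusters at minimum
## distance is merged and the merged cluster's distance to any other
## cluster C is the unweighted mean of its two children's distances:
## d(AB, C) = (d(A, C) + d(B, C)) / 2. Ties are broken deterministically
## by the lexicographically smallest (smaller min leaf index, then the
## other min leaf index) among the tied pairs.

#' WPGMA hierarchical clustering of a distance matrix
#'
#' Classic weighted pair-group agglomeration. The merge list follows the
#' hclust convention (negative entries are leaves, positive entries are
#' earlier merges). Because 1 - DCC need not be ultrametric, merge
#' heights can decrease occasionally; this is reported as a warning but
#' the tree is still returned.
#'
#' @param d a [DistanceCorrelationMatrix-class], or a plain symmetric
#'   matrix of dissimilarities.
#' @return a [Dendrogram-class].
#' @export
wpgmaLinkage <- function(d) {
    if (is(d, "DistanceCorrelationMatrix")) {
        keys <- if (length(d@resKeys)) d@resKeys else
            as.character(seq_len(nrow(d@matrix)))
        m <- d@matrix
    } else {
        stopifnot(is.matrix(d), nrow(d) == ncol(d))
        keys <- as.character(seq_len(nrow(d)))
        m <- d
    }
    n <- nrow(m)
    stopifnot(n >= 2L)
    D <- m
    diag(D) <- Inf
    active <- rep(TRUE, n)
    minLeaf <- seq_len(n)          # smallest leaf index in each cluster
    nodeId <- -seq_len(n)          # hclust id: -leaf or +merge step
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        sub <- D[idx, idx, drop = FALSE]
        best <- min(sub)
        ## candidate tied pairs (a small tolerance absorbs last-ulp
        ## asymmetries of equivalent entries), then the deterministic
        ## tie rule
        w <- which(sub <= best + 1e-12, arr.ind = TRUE)
        w <- w[w[, 1] < w[, 2], , drop = FALSE]
        a <- idx[w[, 1]]; b <- idx[w[, 2]]
        lo <- pmin(minLeaf[a], minLeaf[b])
        hi <- pmax(minLeaf[a], minLeaf[b])
        pick <- order(lo, hi)[1]
        i <- a[pick]; j <- b[pick]
        if (minLeaf[j] < minLeaf[i]) { tmp <- i; i <- j; j <- tmp }
        merge[step, ] <- c(nodeId[i], nodeId[j])
        height[step] <- D[i, j]
        ## WPGMA update: unweighted mean of the two children
        newd <- (D[i, ] + D[j, ]) / 2
        D[i, ] <- newd
        D[, i] <- newd
        D[i, i] <- Inf
        active[j] <- FALSE
        D[j, ] <- Inf
        D[, j] <- Inf
        nodeId[i] <- step
        minLeaf[i] <- min(minLeaf[i], minLeaf[j])
    }
    if (any(diff(height) < -1e-12))
        warning("non-monotone merge heights: the dissimilarity is not ",
                "ultrametric; the dendrogram is still valid for cutting ",
                "by cluster count")
    new("Dendrogram", merge = merge, height = height, labels = keys)
}

#' Convert a Dendrogram to an hclust object
#'
#' Useful for plotting with base graphics. The agglomeration order is
#' preserved exactly.
#'
#' @param x a [Dendrogram-class].
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.Dendrogram <- function(x, ...) {
    n <- nrow(x@merge) + 1L
    ## leaf order: in-order traversal of the merge tree
    expand <- function(id) {
        if (id < 0) return(-id)
        c(expand(x@merge[id, 1]), expand(x@merge[id, 2]))
    }
    structure(list(merge = x@merge, height = x@height,
                   order = expand(n - 1L), labels = x@labels,
                   method = "mcquitty", call = match.call(),
                   dist.method = "1-DCC"),
              class = "hclust")
}

.canonicalLabels <- function(raw) {
    as.integer(match(raw, unique(raw)))
}

#' Cut a dendrogram into a fixed number of communities
#'
#' Undoes the last `nc - 1` merges, i.e. replays the first N - nc merge
#' steps, which yields exactly `nc` clusters regardless of height
#' monotonicity. Communities are relabeled canonically: community 1
#' contains the lowest-index node, and so on.
#'
#' @param dg a [Dendrogram-class].
#' @param nc requested number of communities, 2..min(10, N).
#' @return a [CommunityPartition-class].
#' @export
cutCommunities <- function(dg, nc) {
    stopifnot(is(dg, "Dendrogram"))
    n <- nrow(dg@merge) + 1L
    nc <- as.integer(nc)
    if (nc < 2L || nc > min(10L, n))
        stop("nc must be in 2..", min(10L, n), ", got ", nc)
    comp <- seq_len(n)             # leaf -> component representative
    clusterOf <- integer(n - 1L)   # merge step -> representative
    for (step in seq_len(n - nc)) {
        kids <- dg@merge[step, ]
        reps <- ifelse(kids < 0, -kids, clusterOf[pmax(kids, 1L)])
        ## point every member of the second child at the first child
        repA <- comp[reps[1]]; repB <- comp[reps[2]]
        comp[comp == repB] <- repA
        clusterOf[step] <- repA
    }
    labels <- .canonicalLabels(comp)
    new("CommunityPartition", labels = labels, nc = nc,
        resKeys = dg@labels)
}

#' Detect dynamic communities from a correlation matrix
#'
#' The full community pipeline: distance transform (1 - DCC), WPGMA
#' linkage, and a cut into `nc` communities.
#'
#' @param c a [CorrelationMatrix-class].
#' @param nc requested number of communities.
#' @return a [CommunityPartition-class].
#' @examples
#' fx <- makeBeadProtein(fixtureSpec(seed = 1), tempfile(fileext = ".pdb"))
#' dcc <- gnmCorrelations(fx$model, nModes = 5)
#' detectCommunities(dcc, nc = 2)
#' @export
detectCommunities <- function(c, nc) {
    cutCommunities(wpgmaLinkage(distanceTransform(c)), nc)
}
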