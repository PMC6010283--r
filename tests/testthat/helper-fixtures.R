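## Handcrafted PDB fixtures and independent brute-force oracles used
## across the test files. Oracles are deliberately written as plain,
## slow re-derivations so they share no code with the package.

pdbLine <- function(serial, name, resid, chain, resno, xyz,
                    element, altloc = " ", record = "ATOM  ") {
    name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name)
             else sprintf("%-4s", name)
    sprintf("%s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name4, altloc, resid, chain, resno,
            xyz[1], xyz[2], xyz[3], 1, 0, element)
}

## Three residues with full heavy-atom topologies: GLY (4), ALA (5),
## SER (6); 15 heavy atoms total, CA atoms 3.8 A apart along x.
threeResidueLines <- function() {
    res <- list(
        list(resid = "GLY", x0 = 0,
             atoms = list(c("N", "N"), c("CA", "C"), c("C", "C"),
                          c("O", "O"))),
        list(resid = "ALA", x0 = 3.8,
             atoms = list(c("N", "N"), c("CA", "C"), c("C", "C"),
                          c("O", "O"), c("CB", "C"))),
        list(resid = "SER", x0 = 7.6,
             atoms = list(c("N", "N"), c("CA", "C"), c("C", "C"),
                          c("O", "O"), c("CB", "C"), c("OG", "O"))))
    lines <- character(0)
    serial <- 0L
    for (i in seq_along(res)) {
        r <- res[[i]]
        for (j in seq_along(r$atoms)) {
            serial <- serial + 1L
            a <- r$atoms[[j]]
            xyz <- c(r$x0 + 0.3 * (j - 1), 0.5 * j, 0.2 * i)
            if (a[1] == "CA") xyz <- c(r$x0, 0, 0)
            lines <- c(lines, pdbLine(serial, a[1], r$resid, "A", i,
                                      xyz, a[2]))
        }
    }
    lines
}

writeThreeResiduePDB <- function(path = tempfile(fileext = ".pdb")) {
    writeLines(c(threeResidueLines(), "END"), path)
    path
}

## CA-only chain model at given x positions
chainModel <- function(x) {
    n <- length(x)
    new("CoarseModel", coords = cbind(x, 0, 0),
        resKeys = paste("A", seq_len(n), "", sep = "|"),
        atomNames = rep("CA", n), selectionMode = "calpha")
}

## Random coordinates guaranteed connected at the given cutoff: a
## jittered chain with spacing below the cutoff.
randomConnectedModel <- function(n, rc = 7.5, seed = 1) {
    set.seed(seed)
    base <- cbind(cumsum(runif(n, 3, 4)), 0, 0)
    coords <- base + matrix(runif(3 * n, -1, 1), n)
    new("CoarseModel", coords = coords,
        resKeys = paste("A", seq_len(n), "", sep = "|"),
        atomNames = rep("CA", n), selectionMode = "calpha")
}

## Independent WPGMA oracle: list-of-clusters agglomeration recording
## the height of every merge and the full partition after each step.
## Same tie rule as documented (smallest min-leaf pair).
naiveWPGMA <- function(m) {
    n <- nrow(m)
    clusters <- lapply(seq_len(n), identity)
    D <- m
    diag(D) <- NA
    heights <- numeric(0)
    partitions <- list()
    while (length(clusters) > 1L) {
        k <- length(clusters)
        best <- Inf; bi <- bj <- NA
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
            dij <- D[i, j]
            better <- dij < best - 1e-12
            if (!better && abs(dij - best) <= 1e-12) {
                lo <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
                cur <- sort(c(min(clusters[[bi]]), min(clusters[[bj]])))
                better <- lo[1] < cur[1] ||
                    (lo[1] == cur[1] && lo[2] < cur[2])
            }
            if (better) { best <- dij; bi <- i; bj <- j }
        }
        heights <- c(heights, best)
        newd <- (D[bi, ] + D[bj, ]) / 2
        merged <- c(clusters[[bi]], clusters[[bj]])
        keep <- setdiff(seq_len(k), c(bi, bj))
        D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                   c(newd[keep], NA))
        clusters <- c(clusters[keep], list(merged))
        lab <- integer(n)
        for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
        partitions[[length(partitions) + 1L]] <- lab
    }
    list(heights = heights, partitions = partitions)
}

canonical <- function(lab) as.integer(match(lab, unique(lab)))

## Floyd-Warshall all-pairs shortest paths on a complete weighted graph
floydWarshall <- function(w) {
    n <- nrow(w)
    d <- w
    diag(d) <- 0
    for (k in seq_len(n))
        for (i in seq_len(n))
            for (j in seq_len(n))
                if (d[i, k] + d[k, j] < d[i, j])
                    d[i, j] <- d[i, k] + d[k, j]
    d
}

## Naive one-pass DCC straight from the printed formula
naiveDCC <- function(frames) {
    F <- dim(frames)[1]; N <- dim(frames)[2]
    mu <- apply(frames, c(2, 3), mean)
    cov <- matrix(0, N, N)
    for (i in seq_len(N)) for (j in seq_len(N)) {
        s <- 0
        for (t in seq_len(F))
            s <- s + sum((frames[t, i, ] - mu[i, ]) *
                         (frames[t, j, ] - mu[j, ]))
        cov[i, j] <- s / F
    }
    cov / sqrt(outer(diag(cov), diag(cov)))
}

## random symmetric matrix with zero diagonal, entries in (0, 2)
randomDistanceMatrix <- function(n, seed) {
    set.seed(seed)
    m <- matrix(runif(n * n, 0.01, 2), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    m
}
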