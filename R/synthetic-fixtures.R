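#' Specification of a synthetic bead protein
#'
#' Describes a toy multi-domain structure: `nDomains` compact clusters
#' of `beadsPerDomain` beads each, with near-neighbour spacing
#' `intraSpacing` inside a domain and a gap of `linkerLength` between
#' the closest beads of adjacent domains. With the defaults
#' (3.8 A spacing, the C-alpha virtual bond length, and a 7.0 A gap,
#' just inside the 7.5 A cutoff) each domain is densely connected while
#' adjacent domains touch through a single contact pair, giving two
#' loosely coupled dynamic communities by construction.
#'
#' @param nDomains number of domains (>= 1).
#' @param beadsPerDomain beads in each domain.
#' @param intraSpacing lattice spacing within a domain, Angstrom.
#' @param linkerLength gap between adjacent domains' closest beads,
#'   Angstrom.
#' @param jitter amplitude of the seeded coordinate jitter, Angstrom;
#'   breaks lattice degeneracies. The default 0.2 A keeps the bridging
#'   bead pair within the 7.5 A cutoff for the default linker, so the
#'   contact graph is connected by construction.
#' @param seed integer seed making the fixture reproducible.
#' @return a list with class `"FixtureSpec"`.
#' @export
fixtureSpec <- function(nDomains = 2L, beadsPerDomain = 10L,
                        intraSpacing = 3.8, linkerLength = 7.0,
                        jitter = 0.2, seed = 1L) {
    stopifnot(nDomains >= 1L, beadsPerDomain >= 2L,
              nDomains * beadsPerDomain >= 4L,
              intraSpacing > 1, linkerLength > 0, jitter >= 0)
    structure(list(nDomains = as.integer(nDomains),
                   beadsPerDomain = as.integer(beadsPerDomain),
                   intraSpacing = intraSpacing,
                   linkerLength = linkerLength,
                   jitter = jitter, seed = as.integer(seed)),
              class = "FixtureSpec")
}

## Compact cubic-lattice blob: the first n lattice points sorted by
## distance from the blob centre.
.domainBlob <- function(n, spacing) {
    k <- ceiling(n^(1 / 3)) + 1L
    g <- as.matrix(expand.grid(x = 0:k, y = 0:k, z = 0:k)) * spacing
    ctr <- colMeans(g)
    d <- rowSums(sweep(g, 2L, ctr)^2)
    g[order(d, g[, 1], g[, 2], g[, 3])[seq_len(n)], , drop = FALSE]
}

#' Generate a synthetic multi-domain bead protein
#'
#' Builds the structure described by a [fixtureSpec()], writes it as a
#' valid single-model PDB (one CA bead per residue, chain A, sequential
#' residue numbers), and returns the coarse model together with the
#' ground-truth domain label of every bead. Output is deterministic for
#' a fixed seed, byte-identical across runs.
#'
#' @param spec a `"FixtureSpec"`.
#' @param path output PDB path; `NULL` skips writing.
#' @param labelPath optional path for a two-column sidecar
#'   (bead index, true domain); `NULL` skips writing.
#' @return list with `model` ([CoarseModel-class]), `domains`
#'   (integer ground-truth labels), `path`.
#' @export
makeBeadProtein <- function(spec, path = NULL, labelPath = NULL) {
    stopifnot(inherits(spec, "FixtureSpec"))
    set.seed(spec$seed)
    blob <- .domainBlob(spec$beadsPerDomain, spec$intraSpacing)
    coords <- NULL
    domains <- integer(0)
    offset <- 0
    for (d in seq_len(spec$nDomains)) {
        b <- blob
        b[, 1] <- b[, 1] + offset
        coords <- rbind(coords, b)
        domains <- c(domains, rep(d, nrow(b)))
        offset <- offset + diff(range(blob[, 1])) + spec$linkerLength
    }
    coords <- coords +
        matrix(stats::runif(length(coords), -spec$jitter, spec$jitter),
               ncol = 3)
    if (min(stats::dist(coords)) < 1)
        stop("fixture spec produces beads closer than 1 A")
    n <- nrow(coords)
    model <- new("CoarseModel",
                 coords = unname(round(coords, 3)),
                 resKeys = .resKey("A", seq_len(n), ""),
                 atomNames = rep("CA", n), selectionMode = "calpha")
    if (!is.null(path)) writeCoarsePDB(model, path)
    if (!is.null(labelPath))
        utils::write.table(data.frame(bead = seq_len(n),
                                      domain = domains),
                           labelPath, quote = FALSE, row.names = FALSE)
    list(model = model, domains = domains, path = path)
}

#' Sample a trajectory from the GNM fluctuation covariance
#'
#' Draws `nFrames` independent frames around `meanCoords`: each
#' Cartesian axis of the displacement field is an independent zero-mean
#' Gaussian with covariance `amplitude` times the full nonzero-mode
#' pseudo-inverse of the Kirchhoff matrix. Cross-correlations estimated
#' from such a trajectory converge to the all-mode GNM correlations as
#' the frame count grows, which is what makes the fixture useful:
#' MD-style and GNM-style analyses provably agree on it. The default
#' amplitude scales the per-node root-mean-square fluctuation to about
#' 1 A.
#'
#' @param ms a [ModeSet-class] from a connected network.
#' @param meanCoords N x 3 matrix of mean positions.
#' @param nFrames number of frames (>= 2).
#' @param amplitude covariance scale; `NULL` picks the 1 A RMSF default.
#' @param seed integer seed.
#' @param resKeys optional residue keys for the trajectory.
#' @return a [Trajectory-class].
#' @export
sampleGNMTrajectory <- function(ms, meanCoords, nFrames,
                                amplitude = NULL, seed = 1L,
                                resKeys = character()) {
    stopifnot(is(ms, "ModeSet"), nFrames >= 2L)
    n <- length(ms@values)
    stopifnot(nrow(meanCoords) == n, ncol(meanCoords) == 3L)
    g <- modePseudoInverse(ms, n - ms@nZero)
    if (is.null(amplitude))
        amplitude <- 1 / (3 * mean(diag(g)))
    if (amplitude <= 0)
        stop("amplitude must be positive")
    idx <- ms@nZero + seq_len(n - ms@nZero)
    ## L L' = amplitude * pseudo-inverse
    L <- ms@vectors[, idx, drop = FALSE] %*%
        diag(sqrt(amplitude / ms@values[idx]), length(idx))
    if (length(resKeys) == 0L)
        resKeys <- .resKey("A", seq_len(n), "")
    set.seed(seed)
    frames <- array(NA_real_, c(nFrames, n, 3))
    for (ax in 1:3) {
        z <- matrix(stats::rnorm(nFrames * length(idx)), nFrames)
        frames[, , ax] <- sweep(z %*% t(L), 2L, meanCoords[, ax], `+`)
    }
    new("Trajectory", frames = frames, resKeys = resKeys)
}

#' Apply deterministic coordinate edits to a bead model
#'
#' Moves selected beads to new positions, creating or removing specific
#' contacts; used to construct synthetic "mutants" with known community
#' consequences. Edits that bring any two beads closer than 1 A are
#' rejected.
#'
#' @param m a [CoarseModel-class].
#' @param edits list of `list(bead = index, to = c(x, y, z))` moves (an
#'   empty list returns the model unchanged).
#' @return the edited [CoarseModel-class].
#' @export
perturbContacts <- function(m, edits = list()) {
    stopifnot(is(m, "CoarseModel"))
    coords <- m@coords
    for (e in edits) {
        stopifnot(is.list(e), !is.null(e$bead), length(e$to) == 3L)
        coords[e$bead, ] <- e$to
    }
    if (length(edits) && min(stats::dist(coords)) < 1)
        stop("edit produces a clash: beads closer than 1 A")
    new("CoarseModel", coords = coords, resKeys = m@resKeys,
        atomNames = m@atomNames, selectionMode = m@selectionMode)
}

#' Synthetic block-structured correlation matrix
#'
#' A correlation matrix with known community structure: within-block
#' correlation `within`, between-block correlation `between`, plus
#' independent Gaussian noise of standard deviation `noiseSd` on the
#' off-diagonal entries (symmetrized, clipped to \[-1, 1\], diagonal 1).
#' Used to test that clustering at the true block count recovers the
#' blocks.
#'
#' @param sizes integer block sizes.
#' @param within within-block correlation.
#' @param between between-block correlation.
#' @param noiseSd standard deviation of the added noise.
#' @param seed integer seed.
#' @param source tag for the resulting matrix.
#' @return list with `dcc` ([CorrelationMatrix-class]) and `blocks`
#'   (ground-truth labels).
#' @export
makeBlockDCC <- function(sizes, within = 0.9, between = 0.1,
                         noiseSd = 0.05, seed = 1L, source = "md") {
    stopifnot(all(sizes >= 1L), within > between)
    labels <- rep(seq_along(sizes), sizes)
    n <- length(labels)
    m <- ifelse(outer(labels, labels, `==`), within, between)
    set.seed(seed)
    noise <- matrix(stats::rnorm(n * n, sd = noiseSd), n)
    noise <- (noise + t(noise)) / 2
    m <- pmin(pmax(m + noise, -1), 1)
    diag(m) <- 1
    list(dcc = new("CorrelationMatrix", matrix = m, source = source,
                   nModes = NA_integer_,
                   resKeys = .resKey("A", seq_len(n), "")),
         blocks = labels)
}
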