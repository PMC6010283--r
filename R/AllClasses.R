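#' @import methods
NULL

.checkSymmetric <- function(m, tol = 1e-8) {
    is.matrix(m) && nrow(m) == ncol(m) &&
        all(is.finite(m)) && max(abs(m - t(m))) <= tol
}

#' Parsed protein structure
#'
#' Holds the ATOM records of one model of a PDB file as a data frame with
#' columns `chain`, `resno`, `insert`, `resid`, `elety` (atom name),
#' `elesy` (element symbol) and coordinates `x`, `y`, `z` in Angstrom.
#' Waters, heteroatoms, hydrogens and alternate locations other than
#' blank/'A' are removed at parse time, so every retained atom is a
#' candidate elastic-network node.
#'
#' @slot atoms data.frame of retained ATOM records, in file order.
#' @slot modelIndex 1-based index of the model these records came from.
#' @export
setClass("PDBStructure",
    representation(atoms = "data.frame", modelIndex = "integer"),
    validity = function(object) {
        need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                  "x", "y", "z")
        if (!all(need %in% names(object@atoms)))
            return(paste("atoms must have columns:",
                         paste(need, collapse = ", ")))
        if (nrow(object@atoms) < 1L)
            return("structure contains no atoms")
        xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
        if (!all(is.finite(xyz)))
            return("non-finite atom coordinates")
        key <- with(object@atoms, paste(chain, resno, insert, elety))
        if (anyDuplicated(key))
            return("duplicate (chain, resno, insert, atom name) records")
        TRUE
    })

#' Elastic-network node set
#'
#' A coarse-grained view of a structure: one node per C-alpha (mode
#' `"calpha"`) or one node per heavy atom (mode `"heavy_atom"`), with an
#' explicit node-to-residue map. Node order is PDB file order.
#'
#' @slot coords N x 3 matrix of node coordinates (Angstrom).
#' @slot resKeys length-N residue keys `"chain|resno|insert"`.
#' @slot atomNames length-N PDB atom names (all `"CA"` in calpha mode).
#' @slot selectionMode `"calpha"` or `"heavy_atom"`.
#' @export
setClass("CoarseModel",
    representation(coords = "matrix", resKeys = "character",
                   atomNames = "character", selectionMode = "character"),
    validity = function(object) {
        n <- nrow(object@coords)
        if (n < 2L) return("need at least 2 nodes")
        if (ncol(object@coords) != 3L) return("coords must be N x 3")
        if (!all(is.finite(object@coords))) return("non-finite coordinates")
        if (length(object@resKeys) != n || length(object@atomNames) != n)
            return("resKeys/atomNames length must match node count")
        if (!object@selectionMode %in% c("calpha", "heavy_atom"))
            return("selectionMode must be 'calpha' or 'heavy_atom'")
        if (object@selectionMode == "calpha" &&
            anyDuplicated(object@resKeys))
            return("calpha mode requires exactly one node per residue")
        TRUE
    })

#' C-alpha trajectory
#'
#' Frame-wise node coordinates, F x N x 3, with the same node-to-residue
#' map as a [CoarseModel]. Frames are used as given: no superposition is
#' applied, so correlations computed from it include any rigid-body
#' motion present in the input.
#'
#' @slot frames numeric array F x N x 3 (Angstrom).
#' @slot resKeys length-N residue keys.
#' @export
setClass("Trajectory",
    representation(frames = "array", resKeys = "character"),
    validity = function(object) {
        d <- dim(object@frames)
        if (length(d) != 3L || d[3] != 3L)
            return("frames must be an F x N x 3 array")
        if (d[1] < 2L) return("need at least 2 frames")
        if (length(object@resKeys) != d[2])
            return("resKeys length must match node count")
        if (!all(is.finite(object@frames)))
            return("non-finite trajectory coordinates")
        TRUE
    })

#' GNM Kirchhoff (contact Laplacian) matrix
#'
#' Off-diagonal entries are -gamma for node pairs within the cutoff
#' (inclusive), 0 otherwise; each diagonal entry is minus the sum of its
#' row's off-diagonals, so all row sums are exactly zero.
#'
#' @slot matrix N x N Kirchhoff matrix.
#' @slot rc distance cutoff in Angstrom.
#' @slot gamma spring stiffness (cancels in normalized correlations).
#' @export
setClass("KirchhoffMatrix",
    representation(matrix = "matrix", rc = "numeric", gamma = "numeric"),
    validity = function(object) {
        m <- object@matrix
        if (!.checkSymmetric(m)) return("matrix must be symmetric")
        off <- m[row(m) != col(m)]
        if (!all(abs(off) < 1e-12 | abs(off + object@gamma) < 1e-12))
            return("off-diagonal entries must be 0 or -gamma")
        if (max(abs(rowSums(m))) > 1e-9) return("row sums must be zero")
        if (object@rc <= 0) return("rc must be positive")
        TRUE
    })

#' GNM mode set
#'
#' Full eigensystem of a Kirchhoff matrix with eigenvalues in ascending
#' order and the count of numerically-zero modes. A connected contact
#' graph has exactly one zero mode (the uniform vector).
#'
#' @slot values ascending eigenvalues, length N.
#' @slot vectors N x N matrix with orthonormal eigenvector columns.
#' @slot nZero number of numerically zero eigenvalues.
#' @export
setClass("ModeSet",
    representation(values = "numeric", vectors = "matrix",
                   nZero = "integer"),
    validity = function(object) {
        n <- length(object@values)
        if (!identical(dim(object@vectors), c(n, n)))
            return("vectors must be N x N")
        if (is.unsorted(object@values, strictly = FALSE))
            return("eigenvalues must be ascending")
        if (min(object@values) < -1e-8 * max(abs(object@values)))
            return("eigenvalues must be nonnegative within tolerance")
        g <- crossprod(object@vectors)
        if (max(abs(g - diag(n))) > 1e-8)
            return("eigenvectors must be orthonormal")
        if (object@nZero < 1L) return("a Laplacian has at least one zero mode")
        TRUE
    })

#' Dynamic cross-correlation matrix
#'
#' Normalized covariance of node fluctuations: symmetric, unit diagonal,
#' entries in [-1, 1]. `source` records whether it came from the GNM
#' pseudo-inverse or from a trajectory time average; `nModes` is the
#' mode-subset size for GNM matrices (NA for trajectory-derived ones).
#'
#' @slot matrix N x N correlation matrix.
#' @slot source `"gnm"` or `"md"`.
#' @slot nModes integer mode count used, or NA.
#' @slot resKeys residue keys for the nodes (may be empty).
#' @export
setClass("CorrelationMatrix",
    representation(matrix = "matrix", source = "character",
                   nModes = "integer", resKeys = "character"),
    validity = function(object) {
        m <- object@matrix
        if (!.checkSymmetric(m)) return("matrix must be symmetric")
        if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal must be 1")
        if (max(abs(m)) > 1 + 1e-8) return("entries must lie in [-1, 1]")
        if (!object@source %in% c("gnm", "md"))
            return("source must be 'gnm' or 'md'")
        if (length(object@resKeys) &&
            length(object@resKeys) != nrow(m))
            return("resKeys length must match matrix dimension")
        TRUE
    })

#' Distance-transformed correlation matrix
#'
#' Entrywise 1 - DCC with the diagonal forced to exact zero; entries lie
#' in [0, 2]. This is the dissimilarity clustered by WPGMA and the edge
#' weight of the residue network used for closeness centrality.
#'
#' @slot matrix N x N distance matrix.
#' @slot source `"gnm"` or `"md"`.
#' @slot resKeys residue keys for the nodes (may be empty).
#' @export
setClass("DistanceCorrelationMatrix",
    representation(matrix = "matrix", source = "character",
                   resKeys = "character"),
    validity = function(object) {
        m <- object@matrix
        if (!.checkSymmetric(m)) return("matrix must be symmetric")
        if (max(abs(diag(m))) > 0) return("diagonal must be exactly 0")
        if (min(m) < -1e-8 || max(m) > 2 + 1e-8)
            return("entries must lie in [0, 2]")
        TRUE
    })

#' WPGMA dendrogram
#'
#' Merge list in hclust convention: row i of `merge` gives the two
#' clusters joined at step i (negative = leaf index, positive = earlier
#' merge), `height` the merge distances. Heights can be non-monotone when
#' the dissimilarity is not ultrametric; that is reported as a warning
#' when the tree is built, never an error.
#'
#' @slot merge (N-1) x 2 integer merge matrix.
#' @slot height length N-1 merge heights.
#' @slot labels leaf labels (residue keys).
#' @export
setClass("Dendrogram",
    representation(merge = "matrix", height = "numeric",
                   labels = "character"),
    validity = function(object) {
        n <- nrow(object@merge) + 1L
        if (length(object@height) != n - 1L)
            return("height length must be N-1")
        leaves <- -object@merge[object@merge < 0]
        if (!setequal(leaves, seq_len(n)) || length(leaves) != n)
            return("every leaf must appear exactly once")
        TRUE
    })

#' Community partition
#'
#' Per-node community labels at a requested community count. Partitions
#' built by [cutCommunities()] are canonically numbered (community 1
#' contains the lowest-index node, community 2 the lowest-index node not
#' in community 1, and so on) so they are comparable across runs;
#' [alignLabels()] deliberately renumbers one partition to match
#' another, so aligned labels need not be canonical.
#'
#' @slot labels integer labels in 1..nc, one per node.
#' @slot nc requested number of communities.
#' @slot resKeys residue keys aligned with `labels` (may be empty).
#' @export
setClass("CommunityPartition",
    representation(labels = "integer", nc = "integer",
                   resKeys = "character"),
    validity = function(object) {
        u <- unique(object@labels)
        if (!setequal(u, seq_len(object@nc)))
            return("labels must cover exactly 1..nc")
        if (length(object@resKeys) &&
            length(object@resKeys) != length(object@labels))
            return("resKeys length must match labels")
        TRUE
    })

#' GNM-vs-MD comparison report
#'
#' Agreement metrics between two correlation analyses of the same nodes:
#' Cohen's kappa per community count with its maximum, the correlation of
#' weighted closeness centralities, and the RMSIP of the leading singular
#' vector sets.
#'
#' @slot kappaByNc named numeric, kappa at each community count.
#' @slot kappaMax maximum kappa over the community counts.
#' @slot kappaMaxNc community count achieving it (smallest on ties).
#' @slot centralityCorrelation correlation of closeness centralities.
#' @slot centralityMethod `"pearson"` or `"spearman"`.
#' @slot rmsip subspace overlap of the leading singular vectors.
#' @slot nModes number of singular vectors compared.
#' @export
setClass("ComparisonReport",
    representation(kappaByNc = "numeric", kappaMax = "numeric",
                   kappaMaxNc = "integer",
                   centralityCorrelation = "numeric",
                   centralityMethod = "character",
                   rmsip = "numeric", nModes = "integer"),
    validity = function(object) {
        if (any(object@kappaByNc < -1 - 1e-8 | object@kappaByNc > 1 + 1e-8))
            return("kappa values must lie in [-1, 1]")
        if (abs(object@kappaMax - max(object@kappaByNc)) > 1e-12)
            return("kappaMax must equal the maximum of kappaByNc")
        if (object@rmsip < -1e-8 || object@rmsip > 1 + 1e-8)
            return("rmsip must lie in [0, 1]")
        TRUE
    })

#' Mutant community-shift report
#'
#' Per-mutant kappa-vs-wild-type curves for every (mode subset, community
#' count) pair, plus the median curve per stability class.
#'
#' @slot perMutant data.frame: id, stability, nModes, nc, kappa.
#' @slot medians data.frame: stability, nModes, nc, kappa (class median).
#' @slot rc cutoff used for the all-atom networks.
#' @export
setClass("MutantReport",
    representation(perMutant = "data.frame", medians = "data.frame",
                   rc = "numeric"),
    validity = function(object) {
        if (nrow(object@perMutant) &&
            any(abs(object@perMutant$kappa) > 1 + 1e-8))
            return("kappa values must lie in [-1, 1]")
        TRUE
    })
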