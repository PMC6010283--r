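#' Reduce an all-atom correlation matrix to residue level
#'
#' The all-atom GNM yields an atom-by-atom correlation matrix; community
#' analysis needs one node per residue. The default reduction extracts
#' the C-alpha rows/columns of the normalized matrix (a residue
#' represented by a single atom contributes that atom). The
#' `"average"` alternative averages the correlations over all atom
#' pairs of each residue pair and renormalizes.
#'
#' @param allatomDCC a [CorrelationMatrix-class] over atoms.
#' @param model the [CoarseModel-class] (heavy-atom mode) the matrix
#'   was computed from; supplies the atom-to-residue map.
#' @param method `"calpha"` (default) or `"average"`.
#' @return a residue-level [CorrelationMatrix-class].
#' @export
residueLevelDCC <- function(allatomDCC, model,
                            method = c("calpha", "average")) {
    stopifnot(is(allatomDCC, "CorrelationMatrix"), is(model, "CoarseModel"))
    method <- match.arg(method)
    m <- allatomDCC@matrix
    keys <- model@resKeys
    stopifnot(nrow(m) == length(keys))
    resOrder <- unique(keys)
    if (method == "calpha") {
        pick <- vapply(resOrder, function(k) {
            idx <- which(keys == k)
            if (length(idx) == 1L) return(idx)
            ca <- idx[model@atomNames[idx] == "CA"]
            if (length(ca) == 0L)
                stop("residue ", k, " has no CA atom in the heavy-atom ",
                     "model; cannot reduce to residue level")
            ca[1]
        }, integer(1))
        red <- m[pick, pick, drop = FALSE]
    } else {
        groups <- lapply(resOrder, function(k) which(keys == k))
        nr <- length(resOrder)
        red <- matrix(0, nr, nr)
        for (i in seq_len(nr))
            for (j in i:nr)
                red[i, j] <- red[j, i] <-
                    mean(m[groups[[i]], groups[[j]]])
        d <- diag(red)
        red <- red / sqrt(outer(d, d))
        red <- pmin(pmax(red, -1), 1)
    }
    dimnames(red) <- NULL
    diag(red) <- 1
    new("CorrelationMatrix", matrix = (red + t(red)) / 2,
        source = allatomDCC@source, nModes = allatomDCC@nModes,
        resKeys = resOrder)
}

#' Stability class from a ddG value
#'
#' Mutants with ddG (mutant minus wild-type folding free energy,
#' kcal/mol) below the threshold are "unstable", above it "stable". The
#' boundary value itself is ambiguous -- in the T4 lysozyme reference
#' set, -2.6 kcal/mol mutants appear in both classes -- so exactly at
#' the threshold the class must be supplied by the data source and this
#' function returns `NA`.
#'
#' @param ddG numeric ddG values, kcal/mol.
#' @param threshold class boundary (default -2.6).
#' @return character vector: `"unstable"`, `"stable"`, or `NA` at the
#'   boundary.
#' @export
classifyStability <- function(ddG, threshold = -2.6) {
    out <- ifelse(ddG < threshold, "unstable",
                  ifelse(ddG > threshold, "stable", NA_character_))
    out
}

#' The T4 lysozyme mutant set
#'
#' The packaged table of 16 Arg96-region T4 lysozyme mutant structures
#' with their ddG (pH 5.35, kcal/mol) relative to the 4s0w wild-type and
#' the stability class used to group them. The boundary mutants at
#' -2.6 kcal/mol carry their class explicitly, as the value alone does
#' not determine it.
#'
#' @return data.frame with columns `pdb_id`, `mutations`, `ddG`,
#'   `stability`.
#' @export
t4MutantTable <- function() {
    path <- system.file("extdata", "t4_lysozyme_mutants.csv",
                        package = "dyncomm", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
}

## One structure -> residue-level correlation matrices for each mode
## subset, restricted to the given residue keys.
.residueDCCSet <- function(struct, keys, subsets, rc, mode, reduction) {
    at <- struct@atoms
    keep <- .resKey(at$chain, at$resno, at$insert) %in% keys
    sub <- new("PDBStructure", atoms = at[keep, , drop = FALSE],
               modelIndex = struct@modelIndex)
    model <- selectNodes(sub, mode)
    ms <- decomposeModes(buildKirchhoff(model, rc = rc))
    avail <- length(ms@values) - ms@nZero
    subsets <- unique(pmin(subsets, avail))
    out <- lapply(subsets, function(nm) {
        dcc <- dccGNM(ms, nm, resKeys = model@resKeys)
        if (model@selectionMode == "heavy_atom")
            residueLevelDCC(dcc, model, method = reduction)
        else dcc
    })
    names(out) <- subsets
    out
}

#' Screen mutant structures for community shifts
#'
#' For every mutant, builds the all-atom GNM (default 3.5 A cutoff) of
#' both wild-type and mutant on their common residues, reduces the
#' correlations to residue level, detects communities at each
#' (mode subset, community count) pair, and records the aligned Cohen's
#' kappa against the wild-type communities. Medians are reported per
#' stability class; a destabilizing mutation is expected to reshape the
#' low community levels more than a neutral one.
#'
#' @param wildtype a [PDBStructure-class].
#' @param mutants list of entries `list(id =, structure =, stability =)`
#'   where `structure` is a [PDBStructure-class] and `stability` is
#'   `"stable"` or `"unstable"`.
#' @param subsets mode-subset sizes (default `modeSubsets()`), clipped
#'   per structure to the available nonzero modes.
#' @param ncRange community counts to evaluate.
#' @param rc distance cutoff, Angstrom (3.5 for heavy-atom networks).
#' @param mode node selection: `"heavy_atom"` (default) or `"calpha"`
#'   (used by the synthetic bead fixtures, where every residue is one
#'   bead).
#' @param reduction atom-to-residue reduction method, see
#'   [residueLevelDCC()].
#' @return a [MutantReport-class].
#' @export
screenMutants <- function(wildtype, mutants, subsets = modeSubsets(),
                          ncRange = 2:10, rc = NULL,
                          mode = c("heavy_atom", "calpha"),
                          reduction = c("calpha", "average")) {
    stopifnot(is(wildtype, "PDBStructure"), length(mutants) >= 1L)
    mode <- match.arg(mode)
    reduction <- match.arg(reduction)
    if (is.null(rc)) rc <- defaultCutoff(mode)
    wtAt <- wildtype@atoms
    wtKeys <- unique(.resKey(wtAt$chain, wtAt$resno, wtAt$insert))
    rows <- list()
    for (mut in mutants) {
        stopifnot(!is.null(mut$id), is(mut$structure, "PDBStructure"),
                  mut$stability %in% c("stable", "unstable"))
        mAt <- mut$structure@atoms
        mKeys <- unique(.resKey(mAt$chain, mAt$resno, mAt$insert))
        common <- intersect(wtKeys, mKeys)
        if (length(common) < 0.5 * max(length(wtKeys), length(mKeys)))
            stop("mutant ", mut$id, " shares fewer than 50% of residues ",
                 "with the wild-type (", length(common), " common)")
        wtDCC <- .residueDCCSet(wildtype, common, subsets, rc, mode,
                                reduction)
        muDCC <- .residueDCCSet(mut$structure, common, subsets, rc, mode,
                                reduction)
        for (nm in names(wtDCC)) {
            if (!nm %in% names(muDCC)) next
            dWT <- wpgmaLinkage(distanceTransform(wtDCC[[nm]]))
            dMU <- wpgmaLinkage(distanceTransform(muDCC[[nm]]))
            nHere <- length(dWT@labels)
            for (nc in ncRange[ncRange <= min(10L, nHere)]) {
                pWT <- cutCommunities(dWT, nc)
                pMU <- alignLabels(pWT, cutCommunities(dMU, nc))
                rows[[length(rows) + 1L]] <-
                    data.frame(id = mut$id, stability = mut$stability,
                               nModes = as.integer(nm), nc = nc,
                               kappa = cohensKappa(pWT, pMU))
            }
        }
    }
    perMutant <- do.call(rbind, rows)
    ## class medians are order-invariant: aggregate over sorted keys
    medians <- stats::aggregate(kappa ~ stability + nModes + nc,
                                data = perMutant, FUN = stats::median)
    medians <- medians[order(medians$stability, medians$nModes,
                             medians$nc), ]
    rownames(medians) <- NULL
    new("MutantReport", perMutant = perMutant, medians = medians,
        rc = rc)
}

#' Read a mutant manifest
#'
#' CSV with columns `pdb_id`, `path`, `mutations`, `ddG`,
#' `stability_class`; each `path` must point to a readable PDB file.
#' Missing files are reported together in one error.
#'
#' @param path manifest CSV path.
#' @param baseDir directory against which relative structure paths are
#'   resolved (defaults to the manifest's directory).
#' @return list of mutant entries suitable for [screenMutants()].
#' @export
readMutantManifest <- function(path, baseDir = dirname(path)) {
    man <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("pdb_id", "path", "ddG", "stability_class")
    if (!all(need %in% names(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    full <- ifelse(file.exists(man$path), man$path,
                   file.path(baseDir, man$path))
    missing <- man$pdb_id[!file.exists(full)]
    if (length(missing))
        stop("structure file(s) missing for: ",
             paste(missing, collapse = ", "),
             "; download or generate them and update the manifest paths")
    lapply(seq_len(nrow(man)), function(i)
        list(id = man$pdb_id[i], structure = readPDB(full[i]),
             stability = tolower(man$stability_class[i]),
             ddG = man$ddG[i]))
}
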