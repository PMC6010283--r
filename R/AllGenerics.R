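#' Node coordinates
#' @param x a CoarseModel
#' @return N x 3 numeric matrix in Angstrom
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Residue keys of the nodes
#' @param x an object carrying a node-to-residue map
#' @return character vector of `"chain|resno|insert"` keys
#' @export
setGeneric("resKeys", function(x) standardGeneric("resKeys"))

#' Number of elastic-network nodes
#' @param x an object with nodes
#' @return integer node count
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))

#' Community labels of a partition
#' @param x a CommunityPartition
#' @return integer vector of labels in 1..nc
#' @export
setGeneric("communityLabels", function(x) standardGeneric("communityLabels"))

#' Kappa profile of a comparison report
#' @param x a ComparisonReport
#' @return named numeric vector, kappa per community count
#' @export
setGeneric("kappaByNc", function(x) standardGeneric("kappaByNc"))

#' @describeIn coords coordinates of the nodes
#' @export
setMethod("coords", "CoarseModel", function(x) x@coords)

#' @describeIn resKeys node-to-residue map of a coarse model
#' @export
setMethod("resKeys", "CoarseModel", function(x) x@resKeys)
#' @describeIn resKeys node-to-residue map of a trajectory
#' @export
setMethod("resKeys", "Trajectory", function(x) x@resKeys)
#' @describeIn resKeys residue keys of a correlation matrix
#' @export
setMethod("resKeys", "CorrelationMatrix", function(x) x@resKeys)
#' @describeIn resKeys residue keys of a partition
#' @export
setMethod("resKeys", "CommunityPartition", function(x) x@resKeys)

#' @describeIn nodeCount nodes of a coarse model
#' @export
setMethod("nodeCount", "CoarseModel", function(x) nrow(x@coords))
#' @describeIn nodeCount nodes of a trajectory
#' @export
setMethod("nodeCount", "Trajectory", function(x) dim(x@frames)[2])
#' @describeIn nodeCount nodes of a correlation matrix
#' @export
setMethod("nodeCount", "CorrelationMatrix", function(x) nrow(x@matrix))

#' @describeIn communityLabels labels of a partition
#' @export
setMethod("communityLabels", "CommunityPartition", function(x) x@labels)

#' @describeIn kappaByNc kappa per community count
#' @export
setMethod("kappaByNc", "ComparisonReport", function(x) x@kappaByNc)

#' @rdname CorrelationMatrix-class
#' @param x a CorrelationMatrix or DistanceCorrelationMatrix
#' @param ... unused
#' @export
setMethod("as.matrix", "CorrelationMatrix", function(x, ...) x@matrix)

#' @rdname DistanceCorrelationMatrix-class
#' @export
setMethod("as.matrix", "DistanceCorrelationMatrix", function(x, ...) x@matrix)

#' @rdname KirchhoffMatrix-class
#' @param x a KirchhoffMatrix
#' @param ... unused
#' @export
setMethod("as.matrix", "KirchhoffMatrix", function(x, ...) x@matrix)

setMethod("show", "PDBStructure", function(object) {
    cat(sprintf("PDBStructure: %d atoms, %d residues, model %d\n",
                nrow(object@atoms),
                length(unique(with(object@atoms,
                                   paste(chain, resno, insert, sep = "|")))),
                object@modelIndex))
})

setMethod("show", "CoarseModel", function(object) {
    cat(sprintf("CoarseModel (%s): %d nodes, %d residues\n",
                object@selectionMode, nrow(object@coords),
                length(unique(object@resKeys))))
})

setMethod("show", "Trajectory", function(object) {
    d <- dim(object@frames)
    cat(sprintf("Trajectory: %d frames x %d nodes\n", d[1], d[2]))
})

setMethod("show", "KirchhoffMatrix", function(object) {
    cat(sprintf("KirchhoffMatrix: %d nodes, rc = %g A, gamma = %g\n",
                nrow(object@matrix), object@rc, object@gamma))
})

setMethod("show", "ModeSet", function(object) {
    n <- length(object@values)
    cat(sprintf("ModeSet: %d modes (%d zero), lambda_max = %.4g\n",
                n, object@nZero, object@values[n]))
})

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix (%s%s): %d x %d\n", object@source,
                if (is.na(object@nModes)) ""
                else sprintf(", %d modes", object@nModes),
                nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "DistanceCorrelationMatrix", function(object) {
    cat(sprintf("DistanceCorrelationMatrix (%s): %d x %d\n",
                object@source, nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "Dendrogram", function(object) {
    cat(sprintf("Dendrogram (WPGMA): %d leaves, %d merges\n",
                nrow(object@merge) + 1L, nrow(object@merge)))
})

setMethod("show", "CommunityPartition", function(object) {
    cat(sprintf("CommunityPartition: %d nodes in %d communities (sizes %s)\n",
                length(object@labels), object@nc,
                paste(tabulate(object@labels, object@nc), collapse = ", ")))
})

setMethod("show", "ComparisonReport", function(object) {
    cat(sprintf(paste0("ComparisonReport (%d modes): Kappa_max = %.3f at ",
                       "Nc = %d; centrality r = %.3f (%s); RMSIP = %.3f\n"),
                object@nModes, object@kappaMax, object@kappaMaxNc,
                object@centralityCorrelation, object@centralityMethod,
                object@rmsip))
})

setMethod("show", "MutantReport", function(object) {
    cat(sprintf("MutantReport: %d mutants, rc = %g A\n",
                length(unique(object@perMutant$id)), object@rc))
})
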