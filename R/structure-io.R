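## PDB reading is delegated to bio3d; this layer adds model selection,
## per-model consistency checks, and the fixed filtering policy (ATOM
## records only, no waters/heteroatoms, no hydrogens, altloc blank/'A').

.WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

.resKey <- function(chain, resno, insert) {
    paste(chain, resno, insert, sep = "|")
}

## Split raw PDB lines into per-model blocks of ATOM/HETATM lines.
## Files without MODEL records are a single model.
.pdbModelBlocks <- function(lines) {
    starts <- grep("^MODEL", lines)
    if (length(starts) == 0L)
        return(list(lines))
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
        ends <- c(ends, length(lines))
    lapply(seq_along(starts), function(i) {
        lines[(starts[i] + 1L):(ends[i] - 1L)]
    })
}

.countAtomRecords <- function(block) sum(grepl("^ATOM  ", block))

## Parse one model's lines through bio3d and apply the filtering policy.
.parseModelLines <- function(block, modelIndex) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(block, "END"), tmp)
    pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE))
    at <- pdb$atom
    at <- at[at$type == "ATOM", , drop = FALSE]
    if (nrow(at) == 0L)
        stop("model ", modelIndex, " contains no ATOM records")
    at$chain[is.na(at$chain)] <- ""
    at$insert[is.na(at$insert)] <- ""
    ## bio3d's rm.alt already kept only blank/'A' alternate locations
    ele <- at$elesy
    guess <- toupper(substr(gsub("^[0-9]+", "", at$elety), 1L, 1L))
    ele[is.na(ele) | ele == ""] <- guess[is.na(ele) | ele == ""]
    at$elesy <- ele
    keep <- !(at$elesy %in% c("H", "D")) & !(at$resid %in% .WATER_RESIDUES)
    at <- at[keep, , drop = FALSE]
    if (nrow(at) == 0L)
        stop("model ", modelIndex, " has no atoms left after filtering")
    rownames(at) <- NULL
    at[, c("chain", "resno", "insert", "resid", "elety", "elesy",
           "x", "y", "z")]
}

#' Read one model of a PDB file
#'
#' Returns the ATOM records of the requested model (1-based). HETATM
#' records, waters, hydrogens and alternate locations other than
#' blank/'A' are excluded, so the result holds exactly the atoms
#' eligible as elastic-network nodes, in file order.
#'
#' @param path path to a PDB file.
#' @param modelIndex 1-based model number (files without MODEL records
#'   have a single model).
#' @return a [PDBStructure-class] object.
#' @examples
#' pdb <- makeBeadProtein(fixtureSpec(seed = 1), tempfile(fileext = ".pdb"))
#' readPDB(pdb$path)
#' @export
readPDB <- function(path, modelIndex = 1L) {
    if (!file.exists(path))
        stop("PDB file not found: ", path)
    modelIndex <- as.integer(modelIndex)
    lines <- readLines(path, warn = FALSE)
    blocks <- .pdbModelBlocks(lines)
    if (modelIndex < 1L || modelIndex > length(blocks))
        stop("model index ", modelIndex, " out of range: file has ",
             length(blocks), " model(s)")
    atoms <- .parseModelLines(blocks[[modelIndex]], modelIndex)
    new("PDBStructure", atoms = atoms, modelIndex = modelIndex)
}

#' Select elastic-network nodes from a structure
#'
#' In `"calpha"` mode every residue contributes its C-alpha atom as one
#' node; a residue without a CA is an error. In `"heavy_atom"` mode all
#' non-hydrogen atoms become nodes, each mapped to its residue key.
#' Node order is PDB file order in both modes.
#'
#' @param s a [PDBStructure-class].
#' @param mode `"calpha"` or `"heavy_atom"`.
#' @return a [CoarseModel-class].
#' @export
selectNodes <- function(s, mode = c("calpha", "heavy_atom")) {
    stopifnot(is(s, "PDBStructure"))
    mode <- match.arg(mode)
    at <- s@atoms
    keys <- .resKey(at$chain, at$resno, at$insert)
    if (mode == "calpha") {
        isCA <- at$elety == "CA"
        resOrder <- unique(keys)
        missing <- setdiff(resOrder, unique(keys[isCA]))
        if (length(missing))
            stop("residue(s) missing a CA atom: ",
                 paste(missing, collapse = ", "))
        at <- at[isCA, , drop = FALSE]
        keys <- keys[isCA]
    }
    if (nrow(at) < 2L)
        stop("need at least 2 nodes, got ", nrow(at))
    new("CoarseModel",
        coords = as.matrix(at[, c("x", "y", "z")]),
        resKeys = keys, atomNames = at$elety, selectionMode = mode)
}

#' Read a C-alpha trajectory
#'
#' Two plain-text formats are supported. `"multi_model_pdb"`: a PDB file
#' with one MODEL per frame; the C-alpha atoms of each model become the
#' nodes, and every model must contain the same atoms in the same order.
#' `"frames_table"`: a delimited table with header `frame,node,x,y,z`
#' (1-based frames, 0-based nodes). Frames are used exactly as given; no
#' superposition is applied.
#'
#' @param path path to the trajectory file.
#' @param format `"multi_model_pdb"` or `"frames_table"`.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("multi_model_pdb",
                                            "frames_table")) {
    if (!file.exists(path))
        stop("trajectory file not found: ", path)
    format <- match.arg(format)
    if (format == "multi_model_pdb") .readTrajectoryPDB(path)
    else .readFramesTable(path)
}

.readTrajectoryPDB <- function(path) {
    lines <- readLines(path, warn = FALSE)
    blocks <- .pdbModelBlocks(lines)
    if (length(blocks) < 2L)
        stop("a trajectory needs at least 2 frames, found ",
             length(blocks))
    counts <- vapply(blocks, .countAtomRecords, integer(1))
    bad <- which(counts != counts[1])
    if (length(bad))
        stop("inconsistent atom count across frames: frame ", bad[1],
             " has ", counts[bad[1]], " ATOM records, frame 1 has ",
             counts[1])
    models <- lapply(seq_along(blocks), function(i)
        .parseModelLines(blocks[[i]], i))
    ref <- models[[1]]
    refCA <- ref$elety == "CA"
    if (!any(refCA))
        stop("no CA atoms found in trajectory frames")
    keys <- .resKey(ref$chain, ref$resno, ref$insert)[refCA]
    F <- length(models)
    N <- sum(refCA)
    frames <- array(NA_real_, c(F, N, 3))
    for (i in seq_len(F)) {
        m <- models[[i]]
        if (nrow(m) != nrow(ref) || !all(m$elety == ref$elety))
            stop("frame ", i, " atoms do not match frame 1")
        frames[i, , ] <- as.matrix(m[refCA, c("x", "y", "z")])
    }
    new("Trajectory", frames = frames, resKeys = keys)
}

.readFramesTable <- function(path) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first)) "," else ""
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             comment.char = "#",
                             strip.white = TRUE)
    need <- c("frame", "node", "x", "y", "z")
    if (!all(need %in% names(tab)))
        stop("frames table must have columns: ",
             paste(need, collapse = ", "))
    frames <- sort(unique(tab$frame))
    if (length(frames) < 2L)
        stop("a trajectory needs at least 2 frames, found ",
             length(frames))
    nodes <- sort(unique(tab$node))
    N <- length(nodes)
    arr <- array(NA_real_, c(length(frames), N, 3))
    for (i in seq_along(frames)) {
        sub <- tab[tab$frame == frames[i], , drop = FALSE]
        if (nrow(sub) != N || !setequal(sub$node, nodes))
            stop("frame ", frames[i], " has an inconsistent node set")
        sub <- sub[order(sub$node), , drop = FALSE]
        arr[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
    }
    new("Trajectory", frames = arr,
        resKeys = .resKey("", nodes + 1L, ""))
}

.formatAtomLine <- function(serial, name, resid, chain, resno, insert,
                            xyz, element) {
    ## PDB columns: atom names shorter than 4 chars start in column 14
    name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name)
             else sprintf("%-4s", name)
    sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name4, resid, chain, resno, insert,
            xyz[1], xyz[2], xyz[3], 1, 0, element)
}

.splitKey <- function(keys) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(chain = vapply(parts, `[`, "", 1L),
               resno = as.integer(vapply(parts, `[`, "", 2L)),
               insert = vapply(parts, function(p)
                   if (length(p) >= 3L) p[3] else "", ""))
}

#' Write a coarse model as a single-model PDB file
#'
#' Coordinates are written at the PDB fixed-width precision of 0.001 A,
#' so a read/write round trip reproduces them to that precision.
#'
#' @param m a [CoarseModel-class].
#' @param path output path.
#' @param resid residue name written for every node.
#' @return `path`, invisibly.
#' @export
writeCoarsePDB <- function(m, path, resid = "GLY") {
    stopifnot(is(m, "CoarseModel"))
    rk <- .splitKey(m@resKeys)
    ele <- toupper(substr(gsub("^[0-9]+", "", m@atomNames), 1L, 1L))
    lines <- vapply(seq_len(nrow(m@coords)), function(i)
        .formatAtomLine(i, m@atomNames[i], resid,
                        ifelse(rk$chain[i] == "", "A", rk$chain[i]),
                        rk$resno[i], rk$insert[i], m@coords[i, ], ele[i]),
        character(1))
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL block per frame, CA atoms only.
#'
#' @param t a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMultiModelPDB <- function(t, path) {
    stopifnot(is(t, "Trajectory"))
    rk <- .splitKey(t@resKeys)
    d <- dim(t@frames)
    con <- file(path, "w")
    on.exit(close(con))
    for (f in seq_len(d[1])) {
        writeLines(sprintf("MODEL     %4d", f), con)
        lines <- vapply(seq_len(d[2]), function(i)
            .formatAtomLine(i, "CA", "GLY",
                            ifelse(rk$chain[i] == "", "A", rk$chain[i]),
                            rk$resno[i], rk$insert[i],
                            t@frames[f, i, ], "C"), character(1))
        writeLines(lines, con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Write a trajectory as a plain frames table
#'
#' Whitespace-delimited text with header `frame node x y z`; frames are
#' 1-based and nodes 0-based, matching what [readTrajectory()] expects.
#'
#' @param t a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFramesTable <- function(t, path) {
    stopifnot(is(t, "Trajectory"))
    d <- dim(t@frames)
    frame <- rep(seq_len(d[1]), each = d[2])
    node <- rep(seq_len(d[2]) - 1L, times = d[1])
    xyz <- matrix(aperm(t@frames, c(3, 2, 1)), ncol = 3, byrow = TRUE)
    tab <- data.frame(frame = frame, node = node,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    utils::write.table(format(tab, scientific = FALSE, trim = TRUE),
                       path, quote = FALSE, row.names = FALSE)
    invisible(path)
}
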