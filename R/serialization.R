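## Plain-text exchange formats: square whitespace-delimited matrices
## with a '#' comment header, two-column partition files, JSON reports.

#' Write a correlation (or distance) matrix as plain text
#'
#' One row per line, whitespace-delimited, full double precision, with
#' a comment header recording source, cutoff and mode count.
#'
#' @param c a [CorrelationMatrix-class] or
#'   [DistanceCorrelationMatrix-class].
#' @param path output path.
#' @param rc optional cutoff recorded in the header.
#' @return `path`, invisibly.
#' @export
writeCorrelationMatrix <- function(c, path, rc = NA) {
    m <- as.matrix(c)
    header <- c(sprintf("# source: %s", c@source),
                sprintf("# rc: %s", format(rc)),
                sprintf("# n_modes: %s",
                        if (is(c, "CorrelationMatrix"))
                            format(c@nModes) else "NA"))
    body <- apply(m, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = " "))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a correlation matrix written by [writeCorrelationMatrix()]
#'
#' @param path input path.
#' @return a [CorrelationMatrix-class].
#' @export
readCorrelationMatrix <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("^#", lines, value = TRUE)
    src <- sub("^# source:\\s*", "", grep("^# source:", hdr, value = TRUE))
    nm <- sub("^# n_modes:\\s*", "",
              grep("^# n_modes:", hdr, value = TRUE))
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                               as.numeric))
    m <- (m + t(m)) / 2
    diag(m) <- 1
    new("CorrelationMatrix", matrix = m,
        source = if (length(src)) src else "md",
        nModes = if (length(nm) && nm != "NA") as.integer(nm)
                 else NA_integer_,
        resKeys = character())
}

#' Write a community partition as two-column text
#'
#' Columns: residue key, community label.
#'
#' @param p a [CommunityPartition-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePartition <- function(p, path) {
    keys <- if (length(p@resKeys)) p@resKeys
            else as.character(seq_along(p@labels))
    utils::write.table(data.frame(residue = keys, community = p@labels),
                       path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a dendrogram merge list as text
#'
#' Columns: step, child a, child b (hclust convention), merge height.
#'
#' @param dg a [Dendrogram-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDendrogram <- function(dg, path) {
    tab <- data.frame(step = seq_along(dg@height),
                      a = dg@merge[, 1], b = dg@merge[, 2],
                      height = sprintf("%.12g", dg@height))
    utils::write.table(tab, path, quote = FALSE, row.names = FALSE)
    invisible(path)
}

.reportAsList <- function(r) {
    list(n_modes = r@nModes,
         kappa_by_nc = as.list(r@kappaByNc),
         kappa_max = r@kappaMax,
         kappa_max_nc = r@kappaMaxNc,
         centrality_correlation = r@centralityCorrelation,
         centrality_method = r@centralityMethod,
         rmsip = r@rmsip,
         notes = paste("labels aligned by optimal assignment before",
                       "kappa; centrality correlation is",
                       r@centralityMethod))
}

#' Write a comparison report as JSON
#'
#' @param r a [ComparisonReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeComparisonReport <- function(r, path) {
    jsonlite::write_json(.reportAsList(r), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
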