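#' Dynamic cross-correlations from a trajectory
#'
#' Time-averaged normalized fluctuation correlations:
#' DCC(i, j) = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>), where
#' dr_i(t) = r_i(t) - <r_i> and the dot product runs over the three
#' Cartesian axes. The average is a plain time average over frames with
#' no mass weighting and no superposition, so permuting frame order
#' leaves the result unchanged. Computed in two passes (means, then
#' cross-products accumulated per axis) so memory stays proportional to
#' one frame set per axis.
#'
#' @param t a [Trajectory-class].
#' @return a [CorrelationMatrix-class] with `source = "md"`.
#' @examples
#' spec <- fixtureSpec(seed = 7)
#' fx <- makeBeadProtein(spec, tempfile(fileext = ".pdb"))
#' ms <- decomposeModes(buildKirchhoff(fx$model))
#' traj <- sampleGNMTrajectory(ms, coords(fx$model), nFrames = 200,
#'                             seed = 7)
#' dccMD(traj)
#' @export
dccMD <- function(t) {
    stopifnot(is(t, "Trajectory"))
    d <- dim(t@frames)
    F <- d[1]; N <- d[2]
    cov <- matrix(0, N, N)
    for (ax in 1:3) {
        x <- t@frames[, , ax]
        x <- sweep(x, 2L, colMeans(x))
        cov <- cov + crossprod(x) / F
    }
    v <- diag(cov)
    zero <- which(v <= .Machine$double.eps * max(v, 1))
    if (length(zero))
        stop("node(s) ", paste(zero, collapse = ", "),
             " have zero fluctuation across frames; correlations are ",
             "undefined for constant nodes")
    dcc <- cov / sqrt(outer(v, v))
    dcc <- pmin(pmax((dcc + t(dcc)) / 2, -1), 1)
    diag(dcc) <- 1
    new("CorrelationMatrix", matrix = dcc, source = "md",
        nModes = NA_integer_, resKeys = t@resKeys)
}
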