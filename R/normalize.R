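#' Median-shift normalization within experiment blocks
#'
#' Centres each gene's expression profile around zero separately within
#' each experiment: for every (gene, experiment) block the median of the
#' gene's non-missing values across that experiment's conditions is
#' subtracted from each of those values. This gives profiles from
#' "reference-less" experiments (single-channel intensities, global
#' reference designs) a common zero point so that multi-experiment
#' profiles become comparable. Example: values (11, 4, 6) within a
#' three-condition experiment normalize to (5, -2, 0).
#'
#' Conventions: the median of an even number of values is the midpoint
#' of the two central order statistics; the median is taken over
#' non-missing values only (a single observed value normalizes to 0);
#' missing entries stay missing; a gene with no observed value in an
#' experiment is left untouched there. The operation is idempotent and
#' invariant to adding a constant to a gene's values within one
#' experiment.
#'
#' @param x An \linkS4class{ExprMatrix}.
#' @param experiments Experiments to shift; \code{"all"} (default) or a
#'   character vector of experiment ids. Which experiments need shifting
#'   depends on their technology and is deliberately user configuration.
#' @return A normalized \linkS4class{ExprMatrix}; conditions of
#'   experiments not listed are unchanged.
#' @examples
#' v <- matrix(c(11, 4, 6), 1, dimnames = list("g1", c("c1", "c2", "c3")))
#' em <- ExprMatrix(v, c(c1 = "e1", c2 = "e1", c3 = "e1"))
#' exprValues(medianShift(em))  # 5 -2 0
#' @export
medianShift <- function(x, experiments = "all") {
    stopifnot(methods::is(x, "ExprMatrix"))
    v <- exprValues(x)
    ex <- experimentOf(x)
    shift <- if (identical(experiments, "all")) unique(ex) else experiments
    unknown <- setdiff(shift, ex)
    if (length(unknown))
        stop("unknown experiment(s): ", paste(unknown, collapse = ", "))
    for (e in shift) {
        cols <- which(ex == e)
        block <- v[, cols, drop = FALSE]
        med <- apply(block, 1L, stats::median, na.rm = TRUE)
        med[is.na(med)] <- 0  # gene unobserved in this experiment: no shift
        v[, cols] <- block - med
    }
    ExprMatrix(v, ex)
}
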