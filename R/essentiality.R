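## The core statistic: a two-mode model of the bimodal per-gene
## insertion-index distribution. The low mode (essential genes, indices near
## zero) is an exponential; the high mode (non-essential genes, indices
## around the genome-wide insertion density) is a gamma. A gene's log2
## likelihood ratio between the two densities decides its call.

#' Numerical guards for the likelihood ratio
#'
#' Densities are floored at \code{DENSITY_FLOOR} before taking the ratio and
#' the log2 ratio is clamped to +/- \code{LLR_CAP}, so an index of 0 under a
#' shape > 1 gamma (density exactly 0) yields the maximally essential-like
#' score instead of infinity.
#' @export
DENSITY_FLOOR <- 1e-300

#' @rdname DENSITY_FLOOR
#' @export
LLR_CAP <- 1000

#' Fit the exponential and gamma insertion-index modes
#'
#' The index distribution is split at two manually established cut-offs
#' (defaults 0.006 and 0.03) to minimise overlap between modes. The section
#' at or below the low cut-off is fitted with an exponential by closed-form
#' maximum likelihood (rate = 1 / mean); the section at or above the high
#' cut-off is fitted with a gamma by numerical maximum likelihood seeded by
#' method of moments (convergence tolerance 1e-9), using the conditional
#' likelihood of a gamma left-truncated at the cut-off, since the section is
#' by construction restricted to indices above it. Genes strictly between
#' the cut-offs are excluded from fitting but still classified downstream.
#'
#' When every low-section index is zero (a fully insertion-free essential
#' mode) the exponential rate is set by a zero-inflation rule: one
#' pseudo-insertion spread over the section's total gene length, with a
#' warning.
#'
#' @param stats Per-gene statistics from \code{\link{geneInsertionStats}}
#'   (needs insertion_index and length_bp).
#' @param cutoff_low,cutoff_high Section cut-offs on the insertion index.
#' @return An \code{\link{EssentialityFit}}.
#' @export
fitInsertionModes <- function(stats, cutoff_low = 0.006, cutoff_high = 0.03) {
    stopifnot(cutoff_low < cutoff_high)
    ii <- stats$insertion_index
    low <- ii[ii <= cutoff_low]
    high <- ii[ii >= cutoff_high]
    if (length(low) < 2L)
        stop("cannot fit mode: fewer than 2 genes at or below cutoff_low")
    if (length(high) < 2L)
        stop("cannot fit mode: fewer than 2 genes at or above cutoff_high")

    zero_inflated <- FALSE
    m <- mean(low)
    if (m == 0) {
        total_len <- sum(stats$length_bp[ii <= cutoff_low])
        m <- 1 / total_len
        zero_inflated <- TRUE
        warning("low section is all zeros; exponential rate set by the ",
                "one-pseudo-insertion rule (rate = ", format(total_len), ")")
    }
    lambda <- 1 / m

    gpar <- .fitTruncatedGamma(high, cutoff_high)
    shape <- gpar[["shape"]]
    scale <- gpar[["scale"]]

    EssentialityFit(cutoff_low = cutoff_low, cutoff_high = cutoff_high,
                    exp_rate = lambda, gamma_shape = shape,
                    gamma_scale = scale,
                    n_low = sum(ii <= cutoff_low),
                    n_high = sum(ii >= cutoff_high),
                    n_between = sum(ii > cutoff_low & ii < cutoff_high),
                    zero_inflated = zero_inflated)
}

## Conditional (left-truncated) gamma MLE. The high section is the
## non-essential mode restricted to indices >= the cut-off, so the correct
## likelihood renormalises the density by its mass above the cut-off; a
## plain gamma fit on the section overestimates the shape. Method-of-moments
## start, quasi-Newton optimisation on log-parameters, tolerance 1e-9.
.fitTruncatedGamma <- function(x, cutoff) {
    m <- mean(x)
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0)
        stop("cannot fit mode: high section has no spread")
    start <- c(log(m^2 / v), log(v / m))
    nll <- function(p) {
        shape <- exp(p[1]); scale <- exp(p[2])
        tail_mass <- stats::pgamma(cutoff, shape = shape, scale = scale,
                                   lower.tail = FALSE)
        if (tail_mass <= 0) return(.Machine$double.xmax)
        -sum(stats::dgamma(x, shape = shape, scale = scale, log = TRUE)) +
            length(x) * log(tail_mass)
    }
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(reltol = 1e-9, maxit = 500))
    c(shape = exp(opt$par[1]), scale = exp(opt$par[2]))
}

#' Log2 likelihood ratio of the essential over the non-essential mode
#'
#' llr = log2( f_exp(ii; rate) / f_gamma(ii; shape, scale) ), with both
#' densities floored at \code{DENSITY_FLOOR} and the result clamped to
#' +/- \code{LLR_CAP}. Positive values favour the essential (exponential)
#' mode.
#'
#' @param ii Insertion index (vectorised).
#' @param fit An \code{\link{EssentialityFit}}.
#' @return Numeric vector of clamped log2 likelihood ratios.
#' @export
logLikRatio <- function(ii, fit) {
    fe <- pmax(stats::dexp(ii, rate = expRate(fit)), DENSITY_FLOOR)
    fg <- pmax(stats::dgamma(ii, shape = gammaShape(fit),
                             scale = gammaScale(fit)), DENSITY_FLOOR)
    pmin(pmax(log2(fe / fg), -LLR_CAP), LLR_CAP)
}

#' Trichotomous essentiality call from a log2 likelihood ratio
#'
#' A gene is essential when it is more than \code{threshold_fold} times more
#' likely under the essential mode (llr > log2(fold)), non-essential when
#' the non-essential mode is favoured by the same factor
#' (llr < -log2(fold)), and unclear in between.
#'
#' @param llr Log2 likelihood ratio (vectorised).
#' @param threshold_fold Fold threshold (default 12).
#' @return Character vector: "essential", "non_essential" or "unclear".
#' @export
classifyCall <- function(llr, threshold_fold = 12) {
    stopifnot(threshold_fold > 1)
    thr <- log2(threshold_fold)
    ifelse(llr > thr, "essential",
           ifelse(llr < -thr, "non_essential", "unclear"))
}

#' Classify every gene of a genome
#'
#' Fits the two insertion-index modes, scores every gene (including RNA
#' genes and pseudogenes, and including genes between the fitting cut-offs)
#' by its log2 likelihood ratio and assigns the trichotomous call.
#'
#' @param stats Per-gene statistics from \code{\link{geneInsertionStats}}.
#' @param cutoff_low,cutoff_high Section cut-offs for fitting.
#' @param threshold_fold Fold threshold for the call (default 12).
#' @return A \code{\link{GeneCallSet}}.
#' @export
callGenome <- function(stats, cutoff_low = 0.006, cutoff_high = 0.03,
                       threshold_fold = 12) {
    fit <- fitInsertionModes(stats, cutoff_low, cutoff_high)
    llr <- logLikRatio(stats$insertion_index, fit)
    call <- classifyCall(llr, threshold_fold)
    d <- S4Vectors::DataFrame(
        gene_id = stats$gene_id,
        feature_class = stats$feature_class,
        length_bp = stats$length_bp,
        unique_insertions = stats$unique_insertions,
        insertion_index = stats$insertion_index,
        llr = llr,
        call = call,
        domain_flag = FALSE)
    methods::new("GeneCallSet", calls = d, fit = fit,
                 threshold_fold = threshold_fold)
}

#' Summarise call counts as rounded percentages
#'
#' Percentages are count / denominator x 100 rounded to the nearest integer.
#' The denominator defaults to the number of classified entries; a genome
#' report conventionally quotes percentages of annotated genes, excluding
#' pseudogenes from the denominator while keeping them in the counts, so an
#' explicit denominator can be supplied.
#'
#' @param counts Named integer vector with entries essential, non_essential,
#'   unclear.
#' @param denominator Denominator for the percentages (default: sum of
#'   counts).
#' @return A list with counts, total (sum of counts), denominator and
#'   percent (named, rounded to integers).
#' @export
summarizeCalls <- function(counts, denominator = sum(counts)) {
    counts <- counts[CALL_LEVELS]
    counts[is.na(counts)] <- 0L
    names(counts) <- CALL_LEVELS
    list(counts = as.integer(counts) |> stats::setNames(CALL_LEVELS),
         total = as.integer(sum(counts)),
         denominator = as.integer(denominator),
         percent = round(counts / denominator * 100) |>
             as.integer() |> stats::setNames(CALL_LEVELS))
}

#' @describeIn callGenome Summary of a \code{GeneCallSet}: counts and
#'   percentages under two denominators, all classified entries
#'   (\code{percent_all}) and genes excluding pseudogenes (\code{percent},
#'   the genome-report convention).
#' @param object A \code{GeneCallSet}.
#' @export
setMethod("callSummary", "GeneCallSet", function(x, ...) {
    d <- x@calls
    counts <- table(factor(d$call, levels = CALL_LEVELS))
    counts <- stats::setNames(as.integer(counts), CALL_LEVELS)
    n_genes <- sum(d$feature_class != "pseudogene")
    s <- summarizeCalls(counts, denominator = n_genes)
    s$percent_all <- summarizeCalls(counts)$percent
    s$n_domain_flagged <- sum(d$domain_flag)
    s
})
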