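make_stats <- function(ii, len = 900L) {
    data.frame(gene_id = sprintf("g%04d", seq_along(ii)),
               feature_class = "CDS", length_bp = len,
               unique_insertions = as.integer(round(ii * len)),
               insertion_index = ii, stringsAsFactors = FALSE)
}

test_that("the exponential mode has its closed-form MLE", {
    ii <- c(0.001, 0.002, 0.003, rep(0.08, 50), rep(0.09, 50))
    fit <- fitInsertionModes(make_stats(ii))
    expect_equal(expRate(fit), 500)           # 1 / mean(0.001, 0.002, 0.003)
    expect_equal(unname(sectionCounts(fit)), c(3L, 0L, 100L))
})

test_that("gamma parameters are recovered from seeded draws", {
    withr::local_seed(101)
    high <- rgamma(5000, shape = 5, scale = 0.016)
    high <- high[high >= 0.03]   # the section view of the mode
    ii <- c(rep(0.001, 50), high)
    fit <- fitInsertionModes(make_stats(ii))
    expect_lt(abs(gammaShape(fit) - 5) / 5, 0.10)
    expect_lt(abs(gammaScale(fit) - 0.016) / 0.016, 0.10)
})

test_that("the section fit agrees with an unconstrained gamma MLE when the
           cut-off truncates nothing", {
    withr::local_seed(103)
    x <- rgamma(3000, shape = 5, scale = 0.16)  # mass below 0.03 ~ 2e-6
    ii <- c(rep(0.001, 50), x[x >= 0.03])
    fit <- fitInsertionModes(make_stats(ii))
    ref <- fitdistrplus::fitdist(x[x >= 0.03], "gamma", method = "mle")
    expect_equal(gammaShape(fit), unname(ref$estimate["shape"]),
                 tolerance = 0.01)
    expect_equal(gammaScale(fit), 1 / unname(ref$estimate["rate"]),
                 tolerance = 0.01)
})

test_that("degenerate sections fail loudly, all-zero lows use the pseudo rule", {
    expect_error(fitInsertionModes(make_stats(rep(0.08, 100))), "cannot fit")
    expect_error(fitInsertionModes(make_stats(rep(0.001, 100))), "cannot fit")
    withr::local_seed(5)
    ii <- c(rep(0, 40), rgamma(100, 5, scale = 0.016) + 0.03)
    expect_warning(fit <- fitInsertionModes(make_stats(ii, len = 900L)),
                   "pseudo-insertion")
    expect_equal(expRate(fit), 40 * 900)  # one insertion per total low length
    expect_true(fit@zero_inflated)
})

test_that("the log likelihood ratio matches closed-form densities", {
    fit <- TraDISect:::EssentialityFit(0.006, 0.03, exp_rate = 500,
                                       gamma_shape = 5, gamma_scale = 0.016,
                                       n_low = 10, n_high = 10, n_between = 0)
    x <- 0.01
    f_exp <- 500 * exp(-500 * x)
    f_gam <- x^4 * exp(-x / 0.016) / (0.016^5 * gamma(5))
    expect_equal(logLikRatio(x, fit), log2(f_exp / f_gam))
    # zero index under a shape>1 gamma: density 0 -> maximally essential-like
    expect_equal(logLikRatio(0, fit), LLR_CAP)
    # crossing point: equal densities give llr 0
    root <- uniroot(function(z) log(500) - 500 * z -
                        (4 * log(z) - z / 0.016 - 5 * log(0.016) -
                             lgamma(5)), c(1e-6, 0.05), tol = 1e-12)$root
    expect_equal(logLikRatio(root, fit), 0, tolerance = 1e-6)
})

test_that("classification is a strict trichotomy around log2(12)", {
    thr <- log2(12)
    expect_equal(classifyCall(thr + 1), "essential")
    expect_equal(classifyCall(thr), "unclear")       # strict inequality
    expect_equal(classifyCall(0), "unclear")
    expect_equal(classifyCall(-4), "non_essential")  # -4 < -3.585
    # monotone in threshold: raising it only moves genes into "unclear"
    withr::local_seed(7)
    llr <- runif(500, -20, 20)
    c1 <- classifyCall(llr, 12)
    c2 <- classifyCall(llr, 50)
    moved <- c1 != c2
    expect_true(all(c2[moved] == "unclear"))
    expect_true(all(c1[c1 == "unclear"] == c2[c1 == "unclear"]))
})

test_that("genome calls are exhaustive, deterministic and summarised", {
    b <- simulateBundle(simulationConfig(seed = 21, n_genes = 400))
    st <- geneInsertionStats(b$sites, b$annotation)
    cs1 <- suppressWarnings(callGenome(st))
    cs2 <- suppressWarnings(callGenome(st))
    expect_identical(geneCalls(cs1), geneCalls(cs2))
    d <- geneCalls(cs1)
    expect_equal(nrow(d), 400L)
    s <- callSummary(cs1)
    expect_equal(sum(s$counts), s$total)
    expect_equal(s$total, 400L)
    # genes between the cut-offs are classified, not auto-unclear
    fit <- essentialityFit(cs1)
    between <- d$insertion_index > cutoffs(fit)["low"] &
        d$insertion_index < cutoffs(fit)["high"]
    expect_true(all(d$call[between] %in%
                    c("essential", "non_essential", "unclear")))
})

test_that("summary percentages follow integer rounding per denominator", {
    s <- summarizeCalls(c(essential = 300, non_essential = 650, unclear = 50))
    expect_equal(unname(s$percent), c(30L, 65L, 5L))
    s2 <- summarizeCalls(c(essential = 300, non_essential = 650,
                           unclear = 50), denominator = 990)
    expect_equal(unname(s2$percent), c(30L, 66L, 5L))
})

test_that("well-separated synthetic modes are recovered almost perfectly", {
    # essential mode insertion-free, non-essential mean well above the gap;
    # the window scan can over-promote a sparsely inserted tolerant gene
    # (~0.2% here), which is a known property of the correction
    b <- simulateBundle(simulationConfig(seed = 31, n_genes = 500))
    st <- geneInsertionStats(b$sites, b$annotation)
    dc <- domainCorrection(suppressWarnings(callGenome(st)),
                           b$annotation, b$sites)
    d <- geneCalls(dc$calls)
    pred <- as.character(d$call)
    truth <- ifelse(b$manifest$genes$class == "non_essential",
                    "non_essential", "essential")
    expect_gte(mean(pred == truth), 0.99)
    # every truly essential (insertion-free) gene is recovered
    expect_true(all(pred[truth == "essential" & d$unique_insertions == 0] ==
                    "essential"))
})
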