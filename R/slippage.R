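# Reversion-frequency statistics for the replication-slippage assay.

#' Reversion frequency from plate counts
#'
#' Per experiment, the two plates of each medium are averaged and the
#' frequency is the dilution-corrected ratio
#' \code{(mean selective count * selective dilution) /
#' (mean non-selective count * non-selective dilution)}. Frequencies are
#' aggregated to mean and SD within each (strain, condition).
#'
#' @param exp a [SlippageExperiment-class].
#' @return A list with \code{perExperiment} (the count table plus a
#'   \code{frequency} column) and \code{summary} (per strain and
#'   condition: \code{mean_frequency}, \code{sd_frequency},
#'   \code{n_experiments}).
#' @examples
#' exp <- SlippageExperiment(data.frame(
#'   strain = "s", condition = "barrier_on", experiment = 1,
#'   selective1 = 50, selective2 = 50,
#'   nonselective1 = 200, nonselective2 = 200,
#'   dilutionSelective = 10, dilutionNonselective = 1e4))
#' reversionFrequency(exp)$perExperiment$frequency  # 2.5e-4
#' @export
reversionFrequency <- function(exp) {
  stopifnot(is(exp, "SlippageExperiment"))
  df <- plateCounts(exp)
  selMean <- (df$selective1 + df$selective2) / 2
  nonMean <- (df$nonselective1 + df$nonselective2) / 2
  if (any(nonMean == 0))
    stop("zero viable (non-selective) count: failed plating in ",
      "experiment(s) ",
      paste(df$experiment[nonMean == 0], collapse = ", "))
  df$frequency <- (selMean * df$dilutionSelective) /
    (nonMean * df$dilutionNonselective)
  summ <- aggregate(frequency ~ strain + condition, data = df,
    FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  summ <- cbind(summ[, c("strain", "condition"), drop = FALSE],
    mean_frequency = summ$frequency[, "mean"],
    sd_frequency = summ$frequency[, "sd"],
    n_experiments = as.integer(summ$frequency[, "n"]))
  list(perExperiment = df, summary = summ)
}

#' Two-tailed Student's t comparison of reversion frequencies
#'
#' Classical equal-variance two-sample t test on the raw frequency
#' scale. With zero pooled variance and equal means the result is
#' \code{t = 0, p = 1}; with zero pooled variance and unequal means the
#' comparison is degenerate and reported as \code{p = 0} with
#' \code{degenerate = TRUE}.
#'
#' @param groupA,groupB numeric vectors of per-experiment frequencies
#'   (at least 2 each).
#' @return A list with \code{t}, \code{df}, \code{p_two_tailed},
#'   \code{degenerate}.
#' @examples
#' compareFrequencies(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.021
#' @export
compareFrequencies <- function(groupA, groupB) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2L || nB < 2L)
    stop("need at least 2 experiments per group")
  dfree <- nA + nB - 2L
  pooled <- ((nA - 1) * var(groupA) + (nB - 1) * var(groupB)) / dfree
  if (pooled == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = dfree, p_two_tailed = 1, degenerate = FALSE))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf, df = dfree,
      p_two_tailed = 0, degenerate = TRUE))
  }
  tt <- t.test(groupA, groupB, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
    p_two_tailed = tt$p.value, degenerate = FALSE)
}
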