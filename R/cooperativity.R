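#' @title Cooperativity scoring of membrane-binding data
#' @description The cooperativity score alpha is the slope of
#'   `log10(membrane)` on `log10(cytoplasm)` across a graded-depletion
#'   (rundown) series: alpha = 1 for linear (mass-action) binding, alpha > 1
#'   for positive cooperativity. If the on/off-rate ratio scales as
#'   `m^lambda`, then alpha = 1/(1 - lambda); lambda is reported alongside.
#'   Uncertainty is estimated by bootstrap resampling of embryos.
#' @name cooperativity
NULL

#' Assemble a rundown dataset
#'
#' Validates and normalizes a per-embryo table of paired cytoplasmic and
#' membrane concentration measurements.
#'
#' @param cyt,mem Positive concentrations (raw AU or molar), one per embryo.
#' @param embryo_id Optional identifiers (default sequential).
#' @param genotype,condition Optional labels (recycled).
#' @param units `"au"` or `"molar"`.
#' @return A data frame of class `"rundown_dataset"` with columns
#'   `embryo_id`, `genotype`, `condition`, `cyt`, `mem`, `units`.
#' @export
rundown_dataset <- function(cyt, mem, embryo_id = seq_along(cyt),
                            genotype = "wt", condition = "polarized",
                            units = c("au", "molar")) {
  units <- match.arg(units)
  stopifnot(length(cyt) == length(mem))
  bad <- which(!(cyt > 0 & mem > 0) | !is.finite(cyt) | !is.finite(mem))
  if (length(bad)) {
    stop("nonpositive or non-finite concentrations at records: ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(embryo_id = embryo_id, genotype = genotype,
                    condition = condition, cyt = cyt, mem = mem,
                    units = units, stringsAsFactors = FALSE)
  class(out) <- c("rundown_dataset", "data.frame")
  out
}

#' Cooperativity score of a rundown dataset
#'
#' Ordinary least squares of `log10(mem)` on `log10(cyt)`. The slope is
#' scale-invariant: rescaling either channel by a constant shifts only the
#' intercept.
#'
#' @param data A [rundown_dataset()] (or data frame with `cyt`, `mem`).
#' @param pool Pool all conditions/genotypes into one regression
#'   (default TRUE, matching the pooling of polarized and uniform embryos).
#' @return A list of class `"cooperativity_result"`: `alpha` (slope), `beta`
#'   (intercept, log10 units), `lambda` (= 1 - 1/alpha), `n`, and the `lm`
#'   fit.
#' @examples
#' d <- rundown_dataset(cyt = c(1, 2, 4, 8), mem = 10 * c(1, 2, 4, 8)^2)
#' coop_score(d)$alpha # exactly 2
#' @export
coop_score <- function(data, pool = TRUE) {
  stopifnot(is.data.frame(data), all(c("cyt", "mem") %in% names(data)))
  if (!pool && "condition" %in% names(data)) {
    data <- data[data$condition == data$condition[1], , drop = FALSE]
  }
  if (nrow(data) < 3) stop("need at least 3 records to score cooperativity")
  bad <- which(!(data$cyt > 0 & data$mem > 0))
  if (length(bad)) {
    stop("nonpositive concentrations at records: ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(log10(mem) ~ log10(cyt), data = data)
  alpha <- unname(stats::coef(fit)[2])
  structure(
    list(alpha = alpha, beta = unname(stats::coef(fit)[1]),
         lambda = 1 - 1 / alpha, n = nrow(data), fit = fit),
    class = "cooperativity_result"
  )
}

#' Bootstrap confidence interval for the cooperativity score
#'
#' Resamples embryos (records) with replacement, rescoring each replicate;
#' the 95% CI is the 2.5th/97.5th percentile of the bootstrap distribution.
#' Replicates in which all resampled cytoplasmic values coincide (slope
#' undefined) are skipped and counted.
#'
#' @inheritParams coop_score
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; required, for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return A `"cooperativity_result"` augmented with `boot_alpha` (the
#'   replicate slopes), `ci` (named lower/upper), `n_boot`, `n_skipped`,
#'   `seed`.
#' @export
coop_bootstrap <- function(data, n_boot = 10000, seed, conf = 0.95,
                           pool = TRUE) {
  if (missing(seed)) stop("seed is required")
  res <- coop_score(data, pool = pool)
  lx <- log10(data$cyt)
  ly <- log10(data$mem)
  n <- length(lx)
  boot <- numeric(n_boot)
  skipped <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    x <- lx[idx]
    if (max(x) - min(x) < 1e-12) {
      boot[b] <- NA_real_
      skipped <- skipped + 1L
      next
    }
    y <- ly[idx]
    # slope of the simple regression, without lm() overhead
    boot[b] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  if (skipped) {
    message(skipped, " degenerate bootstrap replicates skipped")
  }
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  res$boot_alpha <- boot
  res$ci <- c(lower = qs[1], upper = qs[2])
  res$n_boot <- n_boot
  res$n_skipped <- skipped
  res$seed <- seed
  res
}

#' @export
print.cooperativity_result <- function(x, ...) {
  cat(sprintf("Cooperativity score: alpha = %.3f (beta = %.3f, n = %d)\n",
              x$alpha, x$beta, x$n))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% bootstrap CI [%.3f, %.3f] (%d replicates, seed %d)\n",
                x$ci["lower"], x$ci["upper"], x$n_boot, x$seed))
  }
  invisible(x)
}
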