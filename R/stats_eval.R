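#' Exact Shapiro-Wilk normality test for n = 3
#'
#' At sample size three the Shapiro-Wilk statistic reduces to
#' `W = 0.5 * (x(3) - x(1))^2 / sum((x - mean(x))^2)` and its p-value has
#' the closed form `p = (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))`,
#' where 0.75 is the minimum attainable W at n = 3. This is the exact
#' distribution, preferable to the large-n approximation when checking
#' normality of replicate triples.
#'
#' @param x Numeric vector of exactly three finite values, not all equal.
#' @return An object of class `normality_result`: list with `W`, `p_value`,
#'   `n`, `method`.
#' @examples
#' shapiro_wilk_n3(c(0.864, 0.857, 0.854))
#' @export
shapiro_wilk_n3 <- function(x) {
  if (length(x) != 3) stop("shapiro_wilk_n3 requires exactly 3 values; ",
                           "use shapiro_wilk() for general n")
  if (any(!is.finite(x))) stop("values must be finite")
  ss <- sum((x - mean(x))^2)
  if (ss == 0) stop("zero variance: all three values are equal")
  xs <- sort(x)
  W <- 0.5 * (xs[3] - xs[1])^2 / ss
  p <- (6 / pi) * (asin(sqrt(W)) - asin(sqrt(0.75)))
  p <- min(max(p, 0), 1)
  structure(list(W = W, p_value = p, n = 3L, method = "exact n = 3"),
            class = "normality_result")
}

#' Shapiro-Wilk normality test
#'
#' Dispatches to the exact n = 3 form for triples and to the standard
#' Royston approximation ([stats::shapiro.test()]) otherwise.
#'
#' @param x Numeric vector (3 <= n <= 5000).
#' @return A `normality_result`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) == 3) return(shapiro_wilk_n3(x))
  st <- stats::shapiro.test(x)
  structure(list(W = unname(st$statistic), p_value = st$p.value,
                 n = length(x), method = "Royston approximation"),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk (%s): W = %.4f, p = %.4f (n = %d)\n",
              x$method, x$W, x$p_value, x$n))
  invisible(x)
}

#' Paired two-sided Student's t-test
#'
#' Replicates are paired by index: `d = b - a`,
#' `t = mean(d) / (sd(d) / sqrt(n))` with the n - 1 denominator in `sd`,
#' `df = n - 1`, and a two-sided p from the t distribution. For the common
#' three-replicate case (df = 2) the p-value also has the closed form
#' `p = 1 - |t| / sqrt(t^2 + 2)`.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @return An object of class `paired_t_result`: list with `t`, `df`,
#'   `p_value`, `mean_diff`, `n`.
#' @examples
#' paired_t_test(c(0.693, 0.725, 0.701), c(0.735, 0.742, 0.731))
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("samples must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("values must be finite")
  d <- b - a
  s <- sd(d)
  if (s == 0) stop("zero variance of the pairwise differences")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- 2 * pt(-abs(t), df)
  structure(list(t = t, df = df, p_value = p, mean_diff = mean(d), n = n),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, p = %.4f (mean diff %.4f)\n",
              x$t, x$df, x$p_value, x$mean_diff))
  invisible(x)
}

#' Load a replicate AP table
#'
#' Tab-separated table with one row per training method: columns `method`,
#' `val` (validation AP@0.5) and `test_1 .. test_3` (three test replicates).
#' The bundled default holds the benchmark comparison of training methods
#' for a generalist worm detector: a base dataset (bd), the same with
#' standard data augmentation (bd_augmented), plus style transfer (st),
#' mask-conditioned synthetic worms (p2p) and supervised self-labeling
#' (ssl) additions.
#'
#' @param path Table path; default is the bundled fixture.
#' @return An object of class `replicate_table`: data frame with a
#'   `replicates()`-style accessor via `[`, rows keyed by `method`.
#' @export
load_replicate_table <- function(path = system.file("extdata", "ap_replicates.tsv",
                                                    package = "wormsynth")) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("method", "val", "test_1", "test_2", "test_3")
  if (!all(need %in% names(df)))
    stop("replicate table must have columns: ", paste(need, collapse = ", "))
  vals <- as.matrix(df[, c("test_1", "test_2", "test_3")])
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("replicate AP values must lie in [0, 1]")
  structure(df, class = c("replicate_table", "data.frame"))
}

replicate_triple <- function(table, method) {
  i <- match(method, table$method)
  if (is.na(i)) stop("unknown method in replicate table: ", method)
  as.numeric(table[i, c("test_1", "test_2", "test_3")])
}

#' Load a method-comparison plan
#'
#' Tab-separated with columns `label`, `baseline`, `treatment` naming rows
#' of the replicate table. The bundled default compares each augmentation
#' method against the strongest pipeline not containing it: style transfer
#' and synthetic worms each against the augmented base dataset, and
#' self-labeling against the combined style-transfer + synthetic pipeline.
#'
#' @param path Plan path; default is the bundled fixture.
#' @return Data frame `(label, baseline, treatment)`.
#' @export
load_comparison_plan <- function(path = system.file("extdata", "comparison_plan.tsv",
                                                    package = "wormsynth")) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("label", "baseline", "treatment") %in% names(df)))
    stop("comparison plan must have columns label, baseline, treatment")
  df
}

#' Compare training methods from replicate APs
#'
#' For each planned baseline/treatment pair, checks normality of both
#' replicate triples with the exact n = 3 Shapiro-Wilk test, then runs the
#' paired two-sided Student's t-test on the index-paired replicates. The
#' result is the per-method significance table for the question "does this
#' augmentation method improve AP@0.5?".
#'
#' @param table A [load_replicate_table()] table.
#' @param plan A [load_comparison_plan()] plan.
#' @return An object of class `method_comparison`: data frame with one row
#'   per comparison: `method`, `t`, `df`, `p_value`,
#'   `shapiro_p_baseline`, `shapiro_p_treatment`, `mean_improvement`.
#' @examples
#' compare_methods(load_replicate_table(), load_comparison_plan())
#' @export
compare_methods <- function(table = load_replicate_table(),
                            plan = load_comparison_plan()) {
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    a <- replicate_triple(table, plan$baseline[i])
    b <- replicate_triple(table, plan$treatment[i])
    swa <- shapiro_wilk_n3(a)
    swb <- shapiro_wilk_n3(b)
    tt <- paired_t_test(a, b)
    data.frame(method = plan$label[i], t = tt$t, df = tt$df,
               p_value = tt$p_value,
               shapiro_p_baseline = swa$p_value,
               shapiro_p_treatment = swb$p_value,
               mean_improvement = tt$mean_diff)
  })
  structure(do.call(rbind, rows),
            class = c("method_comparison", "data.frame"))
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison (paired t-test on AP@0.5 replicates)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-16s p = %.4f  (t = %.2f, df = %d, mean gain %+.3f)\n",
                x$method[i], x$p_value[i], x$t[i], x$df[i],
                x$mean_improvement[i]))
  invisible(x)
}

#' Relative AP drop in percent
#'
#' Percentage drop from a reference AP to a degraded AP,
#' `100 * (reference - value) / reference`; used for robustness-to-strain
#' analyses (e.g. AP on a familiar morphology vs an unfamiliar one).
#'
#' @param reference Reference AP.
#' @param value Degraded AP.
#' @return Drop in percent.
#' @examples
#' ap_drop_pct(0.995, 0.814)  # about 18 percent
#' @export
ap_drop_pct <- function(reference, value) {
  if (reference <= 0) stop("reference AP must be positive")
  100 * (reference - value) / reference
}
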