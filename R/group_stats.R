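#' Two-group comparison of a per-fly metric
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, tie-
#' corrected normal approximation otherwise) plus group summaries and the
#' percent change of the mutant group relative to control. The percent
#' change is computed on group means of per-fly values by default
#' (`basis = "median"` available), the main reproduction-sensitive choice
#' when comparing against published single-percentage effects.
#'
#' @param control,mutant Numeric vectors of per-fly metric values (n >= 3
#'   each).
#' @param metric Metric name carried into the result.
#' @param groups Length-2 character, group labels.
#' @param basis `"mean"` or `"median"`: basis of the percent change.
#' @return Object of class `comparison_result`: summaries per group (n,
#'   mean, median, IQR), `percent_change` (signed; positive = increase in
#'   mutant), `direction`, `statistic` (U), `p_value`, `test`.
#' @export
compare_groups <- function(control, mutant, metric = "metric",
                           groups = c("control", "mutant"),
                           basis = c("mean", "median")) {
  basis <- match.arg(basis)
  control <- as.numeric(control); mutant <- as.numeric(mutant)
  if (length(control) < 3L || length(mutant) < 3L)
    stop("both samples need n >= 3", call. = FALSE)
  summ <- function(x) list(n = length(x), mean = mean(x),
                           median = stats::median(x), iqr = stats::IQR(x))
  base_c <- if (basis == "mean") mean(control) else stats::median(control)
  base_m <- if (basis == "mean") mean(mutant) else stats::median(mutant)
  pc <- if (base_c != 0) 100 * (base_m - base_c) / base_c else {
    warning("control summary is 0; percent change undefined", call. = FALSE)
    NA_real_
  }
  degenerate <- stats::var(c(control, mutant)) == 0
  if (degenerate) {
    warning("all values tied; p = 1", call. = FALSE)
    w <- list(statistic = c(W = length(mutant) * length(control) / 2),
              p.value = 1)
  } else {
    w <- suppressWarnings(stats::wilcox.test(mutant, control,
                                             alternative = "two.sided"))
  }
  structure(list(metric = metric, groups = groups,
                 control = summ(control), mutant = summ(mutant),
                 percent_change = pc,
                 direction = if (is.na(pc) || pc == 0) "none"
                             else if (pc > 0) "increase" else "decrease",
                 statistic = unname(w$statistic), p_value = w$p.value,
                 test = "two-sided Mann-Whitney U", basis = basis),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s vs %s: %.2f%% %s, U = %.1f, p = %.4g\n",
              x$metric, x$groups[2], x$groups[1],
              abs(x$percent_change), x$direction, x$statistic, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(metric = x$metric, control = x$groups[1], mutant = x$groups[2],
             n_control = x$control$n, n_mutant = x$mutant$n,
             mean_control = x$control$mean, mean_mutant = x$mutant$mean,
             median_control = x$control$median, median_mutant = x$mutant$median,
             percent_change = x$percent_change, direction = x$direction,
             statistic = x$statistic, p_value = x$p_value, test = x$test)
}

#' Permutation test for dispersion differences
#'
#' Statistic: `|log(var(A) / var(B))|` after centering each group at its
#' median (so location shifts between groups do not masquerade as
#' dispersion differences). The p-value is estimated by random relabeling
#' of the pooled centered values with the add-one correction
#' `p = (1 + #[permuted >= observed]) / (n_perm + 1)`, which keeps the test
#' valid (conservative) at any permutation count.
#'
#' @param a,b Numeric samples (n >= 3 each).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List of class `dispersion_test`: `statistic`, `p_value`,
#'   `var_ratio`, `n_perm`, `seed`.
#' @export
dispersion_permutation_test <- function(a, b, n_perm = 10000L, seed = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3L || length(b) < 3L)
    stop("both groups need n >= 3", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    warning("zero variance in both groups; p = 1", call. = FALSE)
    return(structure(list(statistic = 0, p_value = 1, var_ratio = NaN,
                          n_perm = n_perm, seed = seed),
                     class = "dispersion_test"))
  }
  obs <- abs(log(va / vb))
  z <- c(a - stats::median(a), b - stats::median(b))
  n1 <- length(a); n2 <- length(b); n <- length(z)
  set_seed_if(seed)
  idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                integer(n1))
  zm <- matrix(z[idx], nrow = n1)
  s1 <- colSums(zm); q1 <- colSums(zm^2)
  S <- sum(z); S2 <- sum(z^2)
  v1 <- (q1 - s1^2 / n1) / (n1 - 1)
  v2 <- ((S2 - q1) - (S - s1)^2 / n2) / (n2 - 1)
  stat <- abs(log(v1 / v2))
  hits <- sum(stat >= obs, na.rm = TRUE)
  structure(list(statistic = obs, p_value = (1 + hits) / (n_perm + 1),
                 var_ratio = va / vb, n_perm = n_perm, seed = seed),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat(sprintf("<dispersion_test> |log var ratio| = %.3f (ratio %.2f), p = %.4g (%d permutations)\n",
              x$statistic, x$var_ratio, x$p_value, x$n_perm))
  invisible(x)
}

#' Age-trend analysis of response proportions
#'
#' Two-way ANOVA (genotype x age group, with interaction) on per-fly
#' response proportions -- reasonably robust to the non-normality of
#' proportions -- backed by per-genotype Kruskal-Wallis tests for the age
#' main effect, and Mann-Whitney post-hoc comparisons between adjacent age
#' groups. Post-hoc p values are reported uncorrected; the result carries
#' the note that they are meant to be interpreted at p = 0.01.
#'
#' @param data data.frame with columns `genotype`, `age` (age-group factor
#'   or values; level order defines adjacency), and the response metric.
#' @param value Name of the metric column (default `"value"`).
#' @return Object of class `age_trend_result`: `anova` (data.frame: term,
#'   df, F, p for age, genotype, interaction), `kruskal` (per-genotype age
#'   p values), `posthoc` (adjacent-age Mann-Whitney p values, pooled
#'   across genotypes), `note`.
#' @export
age_trend_analysis <- function(data, value = "value") {
  stopifnot(all(c("genotype", "age", value) %in% names(data)))
  d <- data.frame(genotype = factor(data$genotype),
                  age = if (is.factor(data$age)) factor(data$age,
                                                        levels = levels(data$age))
                        else factor(data$age),
                  value = as.numeric(data[[value]]))
  if (nlevels(d$genotype) < 2L)
    stop("two-way design requires >= 2 genotypes", call. = FALSE)
  if (nlevels(d$age) < 2L)
    stop("two-way design requires >= 2 age groups", call. = FALSE)
  tab <- table(d$genotype, d$age)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: genotype %s x age %s",
                 rownames(tab)[bad[1]], colnames(tab)[bad[2]]), call. = FALSE)
  }
  if (any(tab < 3))
    warning("design cells with fewer than 3 flies", call. = FALSE)
  if (stats::var(d$value) == 0) {
    warning("response constant across all cells; F = 0, p = 1", call. = FALSE)
    an <- data.frame(term = c("age", "genotype", "genotype:age"),
                     df = NA_integer_, F = 0, p = 1)
  } else {
    fit <- stats::aov(value ~ genotype * age, data = d)
    s <- summary(fit)[[1]]
    rn <- trimws(rownames(s))
    pick <- function(term) {
      i <- match(term, rn)
      data.frame(term = term, df = s[i, "Df"], F = s[i, "F value"],
                 p = s[i, "Pr(>F)"])
    }
    an <- rbind(pick("age"), pick("genotype"), pick("genotype:age"))
  }
  kr <- vapply(levels(d$genotype), function(g) {
    dd <- d[d$genotype == g, ]
    if (stats::var(dd$value) == 0 || nlevels(droplevels(dd$age)) < 2L)
      return(1)
    stats::kruskal.test(value ~ age, data = dd)$p.value
  }, numeric(1))
  ages <- levels(d$age)
  ph <- if (length(ages) > 1L) {
    vapply(seq_len(length(ages) - 1L), function(i) {
      x <- d$value[d$age == ages[i]]
      y <- d$value[d$age == ages[i + 1L]]
      if (stats::var(c(x, y)) == 0) return(1)
      suppressWarnings(stats::wilcox.test(x, y)$p.value)
    }, numeric(1))
  } else numeric(0)
  names(ph) <- paste(ages[-length(ages)], ages[-1], sep = " vs ")
  structure(list(anova = an, kruskal = kr, posthoc = ph,
                 note = "post-hoc p values are uncorrected; interpret at p = 0.01"),
            class = "age_trend_result")
}

#' @export
print.age_trend_result <- function(x, ...) {
  cat("<age_trend_result> two-way ANOVA:\n")
  print(x$anova, row.names = FALSE)
  cat("Kruskal-Wallis age effect per genotype:\n")
  print(signif(x$kruskal, 3))
  cat("Adjacent-age Mann-Whitney post-hocs (", x$note, "):\n", sep = "")
  print(signif(x$posthoc, 3))
  invisible(x)
}
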