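#' Empirical speed-conditioned response curve (outer model)
#'
#' Per speed-bin label frequencies over all supplied classified trials --
#' the probability of each response type as a function of the pre-stimulus
#' speed, pooled across the supplied trials (the grand average across a
#' genotype or the whole dataset). Empty bins are flagged (`NA`
#' probabilities), never imputed.
#'
#' @param classified data.frame from [classify_trials()] (valid trials with
#'   `label` and `v_pre` are used).
#' @param edges Speed-bin edges from [speed_bins()].
#' @return Object of class `speed_response_curve`: `edges`, `n` (trials per
#'   bin), `counts` (bins x 4), `prob` (bins x 4, rows summing to 1 where
#'   populated).
#' @export
build_curve <- function(classified, edges = speed_bins()) {
  v <- classified[!is.na(classified$label) & classified$valid, , drop = FALSE]
  if (!nrow(v)) stop("no valid classified trials", call. = FALSE)
  labs <- response_labels()
  nb <- length(edges) - 1L
  bin <- findInterval(v$v_pre, edges)
  counts <- matrix(0L, nb, length(labs), dimnames = list(NULL, labs))
  for (j in seq_along(labs))
    counts[, j] <- tabulate(bin[v$label == labs[j]], nbins = nb)
  n <- rowSums(counts)
  prob <- counts / ifelse(n > 0, n, NA_real_)
  structure(list(edges = edges, n = n, counts = counts, prob = prob),
            class = "speed_response_curve")
}

#' @export
print.speed_response_curve <- function(x, ...) {
  cat(sprintf("<speed_response_curve> %d bins (%d populated), %d trials\n",
              length(x$n), sum(x$n > 0), sum(x$n)))
  invisible(x)
}

#' @export
as.data.frame.speed_response_curve <- function(x, ...) {
  nb <- length(x$n)
  data.frame(bin_lo = x$edges[seq_len(nb)], bin_hi = x$edges[-1],
             n = x$n,
             p_stop = x$prob[, "stop"], p_slow = x$prob[, "slow_down"],
             p_speedup = x$prob[, "speed_up"], p_none = x$prob[, "no_reaction"])
}

#' Simulate a virtual-fly cohort (inner model)
#'
#' Draws `n_virtual` independent virtual flies: each gets a pre-stimulus
#' speed resampled with replacement from the genotype's empirical `v_pre`
#' values, then a response label drawn from the curve's probabilities at
#' that speed's bin. Together with [test_prediction()] this asks whether a
#' genotype's response distribution is explained by its baseline speed
#' distribution alone.
#'
#' @param v_pre Numeric vector of the genotype's empirical pre-stimulus
#'   speeds (mm/s); must be non-empty.
#' @param curve A [build_curve()] result (typically pooled across
#'   genotypes).
#' @param n_virtual Number of virtual flies (default 3000).
#' @param seed Optional seed.
#' @param genotype Label stored in the result.
#' @return Object of class `virtual_cohort_result`: `predicted` (label
#'   counts summing to `n_virtual`), `n_virtual`, `n_remapped` (draws whose
#'   speed bin was unpopulated and was remapped to the nearest populated
#'   bin), `genotype`, `seed`.
#' @export
simulate_virtual_cohort <- function(v_pre, curve, n_virtual = 3000L,
                                    seed = NULL, genotype = "") {
  if (!length(v_pre)) stop("empty speed sample", call. = FALSE)
  stopifnot(inherits(curve, "speed_response_curve"), n_virtual >= 1)
  set_seed_if(seed)
  labs <- response_labels()
  draws <- sample(as.numeric(v_pre), n_virtual, replace = TRUE)
  bin <- findInterval(draws, curve$edges)
  pop <- which(curve$n > 0)
  n_remap <- 0L
  off <- which(!(bin %in% pop))
  if (length(off)) {
    n_remap <- length(off)
    bin[off] <- vapply(bin[off], function(b) pop[which.min(abs(pop - b))],
                       integer(1))
    message(sprintf("%d virtual draws fell in unpopulated speed bins; remapped to nearest populated bin",
                    n_remap))
  }
  predicted <- stats::setNames(numeric(length(labs)), labs)
  for (b in unique(bin)) {
    m <- sum(bin == b)
    predicted <- predicted +
      as.numeric(stats::rmultinom(1, m, prob = curve$prob[b, ]))
  }
  structure(list(predicted = predicted, n_virtual = n_virtual,
                 n_remapped = n_remap, genotype = genotype, seed = seed),
            class = "virtual_cohort_result")
}

#' @export
print.virtual_cohort_result <- function(x, ...) {
  cat(sprintf("<virtual_cohort_result> %s: n = %d\n", x$genotype, x$n_virtual))
  print(round(x$predicted / x$n_virtual, 3))
  invisible(x)
}

#' Chi-square comparison of observed and virtual response counts
#'
#' Default (`method = "expected"`): Pearson goodness-of-fit chi-square of
#' the observed counts against the virtual-cohort proportions scaled to the
#' observed total. Treating the finite virtual cohort as exact expectation
#' is mildly anti-conservative, but because the virtual flies are
#' speed-matched to the very trials being tested (which positively
#' correlates observed and expected counts, a conservative effect), the two
#' biases nearly cancel and the test is close to nominal at the default
#' `n_virtual = 3000`. `method = "sample"` is the 2 x k homogeneity
#' chi-square treating both count vectors as samples; it is conservative
#' under speed matching. Both have `df = k - 1`. Labels unobserved in
#' both vectors are dropped; labels with zero virtual count but non-zero
#' observed count are merged into the nearest virtual-supported label (and
#' reported).
#'
#' @param observed Named counts over the four labels (experimental trials).
#' @param predicted Named counts over the four labels (virtual cohort), or a
#'   `virtual_cohort_result`.
#' @param method `"sample"` or `"expected"`.
#' @return List of class `prediction_test`: `statistic`, `df`, `p_value`,
#'   `method`, `observed`, `predicted`, `merged` (labels merged away).
#' @export
test_prediction <- function(observed, predicted,
                            method = c("expected", "sample")) {
  method <- match.arg(method)
  if (inherits(predicted, "virtual_cohort_result"))
    predicted <- predicted$predicted
  labs <- response_labels()
  o <- stats::setNames(as.numeric(observed[labs]), labs)
  e <- stats::setNames(as.numeric(predicted[labs]), labs)
  if (anyNA(o) || anyNA(e))
    stop("observed and predicted must cover the four response labels",
         call. = FALSE)
  if (sum(o) == 0) stop("all-zero observed counts", call. = FALSE)
  merged <- character(0)
  bad <- which(e == 0 & o > 0)
  if (length(bad)) {
    ok <- which(e > 0)
    for (b in bad) {
      tgt <- ok[which.min(abs(ok - b))]
      o[tgt] <- o[tgt] + o[b]
      merged <- c(merged, labs[b])
    }
    message("categories with zero virtual count merged: ",
            paste(merged, collapse = ", "))
  }
  keep <- which(e > 0 | o > 0)
  keep <- setdiff(keep, bad)
  o <- o[keep]; e <- e[keep]
  k <- length(keep)
  if (k < 2L) stop("fewer than 2 usable categories", call. = FALSE)
  if (method == "sample") {
    ct <- suppressWarnings(stats::chisq.test(rbind(o, e), correct = FALSE))
    stat <- unname(ct$statistic); df <- unname(ct$parameter)
    p <- unname(ct$p.value)
  } else {
    exp_cnt <- sum(o) * e / sum(e)
    stat <- sum((o - exp_cnt)^2 / exp_cnt)
    df <- k - 1
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df = df, p_value = p, method = method,
                 observed = o, predicted = e, merged = merged),
            class = "prediction_test")
}

#' @export
print.prediction_test <- function(x, ...) {
  cat(sprintf("<prediction_test> chi-square (%s) = %.3f, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}
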