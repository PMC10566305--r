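# Nonparametric comparison layer: rank-sum, signed-rank,
# Kruskal-Wallis, and Dunn-type pairwise follow-up with Fisher's LSD
# protection (unadjusted pairwise p gated on the omnibus test).

new_swd_test <- function(method, statistic, p_value, group_sizes,
                         medians = NULL, notes = "") {
  structure(list(method = method, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 group_sizes = as.integer(group_sizes),
                 medians = medians, notes = notes),
            class = "swd_test")
}

#' @export
print.swd_test <- function(x, ...) {
  cat(sprintf("<%s: statistic = %.4g, p = %.4g (n = %s)%s>\n", x$method,
              x$statistic, x$p_value, paste(x$group_sizes, collapse = ", "),
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' @export
tidy.swd_test <- function(x, ...) {
  out <- tibble(method = x$method, statistic = x$statistic,
                p_value = x$p_value,
                n = list(x$group_sizes), notes = x$notes)
  if (!is.null(x$medians)) {
    out$median_1 <- x$medians[[1L]]
    out$median_2 <- if (length(x$medians) > 1L) x$medians[[2L]] else NA_real_
  }
  out
}

#' @export
glance.swd_test <- function(x, ...) tidy(x, ...)

has_ties <- function(v) anyDuplicated(v) > 0L

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. The exact null distribution is used for small samples
#' without ties (`n_x + n_y <= 12`); otherwise the normal approximation
#' with tie and continuity corrections. Identical degenerate samples
#' yield p = 1 with a note rather than an error.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return An object of class `swd_test` ([tidy()]-able).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty.")
  if (diff(range(c(x, y))) == 0) {
    return(new_swd_test("rank_sum", length(x) * length(y) / 2, 1,
                        c(length(x), length(y)),
                        medians = c(median(x), median(y)),
                        notes = "degenerate: all values identical"))
  }
  exact <- switch(mode,
                  exact = TRUE, normal = FALSE,
                  auto = length(x) + length(y) <= 12L && !has_ties(c(x, y)))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  new_swd_test("rank_sum", ht$statistic, ht$p.value,
               c(length(x), length(y)),
               medians = c(median(x), median(y)),
               notes = if (exact) "exact" else
                 "normal approximation, tie and continuity corrected")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank on the paired differences `before - after`.
#' Zero differences are dropped (the Wilcoxon convention); the exact
#' null is used for up to 15 nonzero differences without ties in their
#' magnitudes, otherwise the normal approximation with corrections.
#'
#' @param before,after Paired numeric samples of equal length.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return An object of class `swd_test`.
#' @export
signed_rank_test <- function(before, after, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(before) != length(after)) {
    abort("paired samples must have equal length.")
  }
  d <- before - after
  d <- d[d != 0]
  if (length(d) == 0L) {
    abort("all paired differences are zero; the signed-rank test is undefined.")
  }
  exact <- switch(mode,
                  exact = TRUE, normal = FALSE,
                  auto = length(d) <= 15L && !has_ties(abs(d)))
  ht <- suppressWarnings(wilcox.test(d, exact = exact, correct = TRUE))
  new_swd_test("signed_rank", ht$statistic, ht$p.value,
               length(d),
               medians = c(median(before), median(after)),
               notes = if (exact) "exact" else
                 "normal approximation, tie and continuity corrected")
}

#' Kruskal-Wallis rank test
#'
#' Omnibus H test on joint ranks with tie correction; p from the
#' chi-square approximation with k - 1 degrees of freedom.
#'
#' @param groups List of two or more numeric samples.
#' @return An object of class `swd_test`.
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort("`groups` must be a list of at least two samples.")
  }
  if (any(lengths(groups) == 0L)) abort("each group must be non-empty.")
  if (diff(range(unlist(groups))) == 0) {
    return(new_swd_test("kruskal_wallis", 0, 1, lengths(groups),
                        medians = vapply(groups, median, numeric(1)),
                        notes = "degenerate: all values identical"))
  }
  ht <- kruskal.test(groups)
  new_swd_test("kruskal_wallis", ht$statistic, ht$p.value, lengths(groups),
               medians = vapply(groups, median, numeric(1)),
               notes = sprintf("df = %d, tie corrected",
                               as.integer(ht$parameter)))
}

#' Dunn-type pairwise follow-up with Fisher's LSD protection
#'
#' Pairwise z statistics on joint mean ranks with the tie-corrected
#' pooled variance. In the Fisher's-LSD spirit the pairwise p values
#' are unadjusted and are meant to be read only when the accompanying
#' omnibus Kruskal-Wallis test rejects.
#'
#' @param groups Named or unnamed list of numeric samples.
#' @return A tibble with one row per pair (`group_1`, `group_2`, `z`,
#'   `p_value`, group sizes); the omnibus `swd_test` is attached as the
#'   `omnibus` attribute.
#' @export
pairwise_lsd <- function(groups) {
  omnibus <- kruskal_wallis(groups)
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  nm[nm == ""] <- as.character(seq_len(k))[nm == ""]
  pooled <- unlist(groups)
  n_tot <- length(pooled)
  rks <- rank(pooled)
  gidx <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(rks, gidx, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  v0 <- n_tot * (n_tot + 1) / 12 - tie_term
  pairs <- utils::combn(k, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1L, c0]; j <- pairs[2L, c0]
    se <- sqrt(v0 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    tibble(group_1 = nm[[i]], group_2 = nm[[j]], z = z,
           p_value = 2 * pnorm(-abs(z)),
           n_1 = length(groups[[i]]), n_2 = length(groups[[j]]))
  })
  attr(out, "omnibus") <- omnibus
  out
}

#' Compare two conditions on a per-event or per-session metric
#'
#' Dispatches to the rank-sum test (independent design) or the
#' signed-rank test (paired design) and reports the group medians
#' alongside, since group medians are the headline summary of each
#' condition.
#'
#' @param values_a,values_b Numeric metric values (e.g. event
#'   durations pooled within a group).
#' @param design `"independent"` or `"paired"`.
#' @return An object of class `swd_test` carrying both medians.
#' @export
compare_conditions <- function(values_a, values_b,
                               design = c("independent", "paired")) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(values_a) != length(values_b)) {
      abort("paired design requires equal-length samples.")
    }
    signed_rank_test(values_a, values_b)
  } else {
    rank_sum_test(values_a, values_b)
  }
}
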