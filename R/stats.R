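## Comparative statistics: chi-square contingency tests, pairwise chi-square
## partitioning with compact letter displays, Welch t-tests, coefficient of
## variation and Pearson correlation. Thin, validated wrappers over base R
## plus a hand-rolled insert-absorb letter display.

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction; df = (r-1)(k-1).
#'
#' @param table r x k matrix of non-negative counts; all margins must be
#'   positive.
#' @return list: `statistic`, `df`, `p`.
#' @export
chisq_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("chisq_contingency: negative cell count")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) stop("chisq_contingency: zero row margin (row ",
                         paste(which(rs == 0), collapse = ","), ")")
  if (any(cs == 0)) stop("chisq_contingency: zero column margin (column ",
                         paste(which(cs == 0), collapse = ","), ")")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Pairwise chi-square partitioning with a compact letter display
#'
#' The overall m x k test plus every 2 x k pairwise sub-table test; groups are
#' then assigned lowercase letters from the pairwise significance graph at
#' `alpha` (groups sharing no letter differ; groups sharing a letter do not).
#' No multiplicity correction by default (single-alpha letters); set
#' `bonferroni = TRUE` to divide alpha by the number of pairs.
#'
#' @param table m x k matrix of counts, one row per group; rownames label the
#'   groups.
#' @param alpha significance level for the letters (default 0.05).
#' @param bonferroni apply Bonferroni correction across pairs (default FALSE).
#' @return list: `overall` ([chisq_contingency()] result), `pairwise`
#'   (data.frame: group1, group2, statistic, df, p, significant), `letters`
#'   (named character vector per group), `alpha`.
#' @export
chisq_partition_pairwise <- function(table, alpha = 0.05, bonferroni = FALSE) {
  m <- as.matrix(table)
  if (nrow(m) < 2) stop("chisq_partition_pairwise: need at least 2 groups")
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  overall <- chisq_contingency(m)
  pairs <- utils::combn(rownames(m), 2)
  thr <- if (bonferroni) alpha / ncol(pairs) else alpha
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g <- pairs[, i]
    r <- chisq_contingency(m[g, , drop = FALSE])
    data.frame(group1 = g[1], group2 = g[2], statistic = r$statistic,
               df = r$df, p = r$p, significant = r$p < thr,
               row.names = NULL)
  }))
  list(overall = overall, pairwise = pw,
       letters = letter_display(rownames(m), pw),
       alpha = alpha)
}

#' Compact letter display by insert-and-absorb
#'
#' Deterministic: groups are processed in their given (label) order, and the
#' significant pairs in that same order.
#'
#' @param groups character vector of group labels.
#' @param pairwise data.frame with columns group1, group2, significant.
#' @return named character vector: letters per group (e.g. `"a"`, `"ab"`).
#' @export
letter_display <- function(groups, pairwise) {
  cols <- list(groups)                      # start: one column with everybody
  sig <- pairwise[pairwise$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by first member for stable letter assignment
  first <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first)]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  }
  out
}

#' Welch two-sample t-test
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return list: `kind = "t-test"`, `statistic`, `df`, `p`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("two_sample_ttest: each sample needs at least 2 values")
  }
  r <- stats::t.test(a, b, var.equal = FALSE)
  list(kind = "t-test", statistic = unname(r$statistic),
       df = unname(r$parameter), p = unname(r$p.value))
}

#' Coefficient of variation (sample sd over mean)
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return list: `kind = "CV"`, `value` (`NA` with a warning on zero mean).
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("coefficient_of_variation: need n >= 2")
  m <- mean(values)
  if (m == 0) {
    warning("coefficient_of_variation: zero mean, CV undefined")
    return(list(kind = "CV", value = NA_real_))
  }
  list(kind = "CV", value = stats::sd(values) / m)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `kind = "Pearson"`, `r`, `p` (both `NA` with a warning for a
#'   constant vector).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_correlation: unequal lengths")
  if (length(x) < 3) stop("pearson_correlation: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pearson_correlation: constant vector, correlation undefined")
    return(list(kind = "Pearson", r = NA_real_, p = NA_real_))
  }
  r <- stats::cor.test(x, y, method = "pearson")
  list(kind = "Pearson", r = unname(r$estimate), p = unname(r$p.value))
}
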