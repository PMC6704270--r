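#' Labelled sample of measurements for group comparison
#'
#' The unit of analysis matters: parametric comparisons (Welch t, ANOVA) are
#' conventionally run on per-brain means, while the rank-sum comparison of
#' node lengths is run on the individual node measurements pooled across
#' brains.
#'
#' @param label group label.
#' @param values numeric measurements.
#' @param unit `"brain"` (per-animal means) or `"object"` (individual
#'   measurements); recorded, not enforced.
#' @return An object of class `group_sample`.
#' @export
group_sample <- function(label, values, unit = c("object", "brain")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    myelin_error("values must be non-missing and non-empty", "myelin_bad_sample")
  }
  structure(list(label = label, values = values, n = length(values), unit = unit),
            class = "group_sample")
}

as_group <- function(x, label = deparse(substitute(x))) {
  if (inherits(x, "group_sample")) x else group_sample(label, x)
}

new_test_result <- function(statistic, df, p_value, method, n, estimate = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, n = n, estimate = estimate),
            class = "myelin_test")
}

#' @export
print.myelin_test <- function(x, ...) {
  cat(sprintf("<myelin_test> %s\n", x$method))
  cat(sprintf("  statistic = %.4f%s, p = %.4g (n = %s)\n",
              x$statistic,
              if (!is.null(x$df) && !anyNA(x$df))
                paste0(", df = ", paste(signif(x$df, 5), collapse = ", ")) else "",
              x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Unpaired two-tailed t-test with unequal variances:
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with sample variances and the
#' Welch–Satterthwaite degrees of freedom; two-sided p from the t
#' distribution.
#'
#' @param a,b numeric vectors or [group_sample()]s with >= 2 values each.
#' @return A `myelin_test` with fields `statistic` (t), `df` (non-integer in
#'   general), `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- as_group(a); b <- as_group(b)
  if (a$n < 2L || b$n < 2L) {
    myelin_error("Welch's t-test needs n >= 2 per group", "myelin_bad_sample")
  }
  v1 <- stats::var(a$values); v2 <- stats::var(b$values)
  n1 <- a$n; n2 <- b$n
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (mean(a$values) == mean(b$values)) {
      myelin_error("both groups constant with equal means: t undefined",
                   "myelin_stats_degenerate")
    }
    return(new_test_result(statistic = sign(mean(a$values) - mean(b$values)) * Inf,
                           df = NA_real_, p_value = 0,
                           method = "Welch two-sample t-test (two-sided)",
                           n = c(n1, n2), estimate = c(mean(a$values), mean(b$values))))
  }
  t <- (mean(a$values) - mean(b$values)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  new_test_result(statistic = t, df = df, p_value = 2 * pt(-abs(t), df),
                  method = "Welch two-sample t-test (two-sided)",
                  n = c(n1, n2), estimate = c(mean(a$values), mean(b$values)))
}

#' Mann–Whitney rank sum test
#'
#' U statistic from midranks. Two-sided p-value either by exact enumeration of
#' all assignments of the observed ranks to the two groups
#' (`2 * min(P(U <= u), P(U >= u))`, capped at 1) or by the normal
#' approximation with tie correction and a 0.5 continuity correction. By
#' default the exact computation is used when `n1 + n2 <= 16` and there are no
#' ties; `mode` overrides (exact enumeration with ties conditions on the
#' observed midranks).
#'
#' @param a,b numeric vectors or [group_sample()]s (>= 1 value each).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A `myelin_test` with fields `statistic` (U for the first group),
#'   `df = NULL`, `p_value`.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  a <- as_group(a); b <- as_group(b)
  n1 <- a$n; n2 <- b$n
  N <- n1 + n2
  r <- rank(c(a$values, b$values))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a$values, b$values)))
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = N <= 16 && !ties)
  if (use_exact) {
    if (choose(N, n1) > 5e6) {
      myelin_error("exact enumeration infeasible at this sample size", "myelin_bad_sample")
    }
    combs <- combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "Mann-Whitney rank sum test (exact, two-sided)"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "Mann-Whitney rank sum test (normal approximation, two-sided)"
  }
  new_test_result(statistic = U, df = NULL, p_value = p, method = method,
                  n = c(n1, n2))
}

#' One-way ANOVA with Bonferroni-corrected pairwise post-hoc tests
#'
#' Classic equal-variance one-way F test over all groups, followed by all
#' pairwise Welch comparisons with each p-value multiplied by the number of
#' pairs (capped at 1).
#'
#' @param groups list of numeric vectors or [group_sample()]s (>= 2 groups,
#'   each n >= 2). Unnamed numeric groups are labelled by position.
#' @return An object of class `myelin_anova`: `overall` (a `myelin_test` for
#'   the F statistic) and `pairwise` (data.frame with `group1`, `group2`, `t`,
#'   `df`, `p`, `p_bonferroni`, `family_size`).
#' @export
anova_bonferroni <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  labels <- names(groups) %||% rep(NA_character_, length(groups))
  groups <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    lab <- if (!is.na(labels[i]) && nzchar(labels[i])) labels[i] else paste0("group", i)
    if (inherits(g, "group_sample")) g else group_sample(lab, g)
  })
  if (any(vapply(groups, function(g) g$n, 0L) < 2L)) {
    myelin_error("ANOVA needs n >= 2 per group", "myelin_bad_sample")
  }
  values <- unlist(lapply(groups, `[[`, "values"))
  if (length(unique(values)) == 1L) {
    myelin_error("all values identical across all groups: F undefined",
                 "myelin_stats_degenerate")
  }
  g <- factor(rep(vapply(groups, `[[`, "", "label"),
                  vapply(groups, `[[`, 0L, "n")))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  overall <- new_test_result(statistic = unname(ow$statistic),
                             df = unname(ow$parameter),
                             p_value = unname(ow$p.value),
                             method = "one-way ANOVA (equal variances)",
                             n = vapply(groups, `[[`, 0L, "n"))
  pairs <- combn(length(groups), 2)
  family <- ncol(pairs)
  pw <- apply(pairs, 2, function(ij) {
    res <- welch_t(groups[[ij[1]]], groups[[ij[2]]])
    data.frame(group1 = groups[[ij[1]]]$label, group2 = groups[[ij[2]]]$label,
               t = res$statistic, df = res$df %||% NA_real_, p = res$p_value,
               p_bonferroni = min(1, res$p_value * family),
               family_size = family)
  })
  structure(list(overall = overall, pairwise = do.call(rbind, pw)),
            class = "myelin_anova")
}

#' @export
print.myelin_anova <- function(x, ...) {
  print(x$overall)
  cat("  pairwise Welch comparisons (Bonferroni-adjusted):\n")
  print.data.frame(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
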