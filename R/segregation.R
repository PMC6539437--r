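#' Chi-square goodness-of-fit for a Mendelian segregation ratio
#'
#' For two phenotypic classes (df = 1) the statistic carries the Yates
#' continuity correction, `sum((|O - E| - 0.5)^2 / E)`, with the corrected
#' deviation squared as-is — it is deliberately not floored at zero, so
#' observations closer than 0.5 to expectation give a small positive
#' statistic rather than exactly 0. With more than two classes the
#' ordinary uncorrected statistic is returned.
#'
#' @param observed Non-negative integer counts, one per class.
#' @param ratio Positive expected ratio terms, e.g. `c(3, 1)` or `c(1, 2)`.
#' @return The chi-square statistic (numeric scalar).
#' @examples
#' yates_chisq(c(310, 90), c(3, 1)) # 1.20 to 2 dp
#' @export
yates_chisq <- function(observed, ratio) {
  if (length(observed) != length(ratio) || length(observed) < 2) {
    abort("`observed` and `ratio` must have equal length >= 2.")
  }
  if (any(observed < 0) || sum(observed) <= 0) {
    abort("counts must be non-negative with a positive total.")
  }
  if (any(ratio <= 0)) abort("ratio terms must be positive.")
  expected <- sum(observed) * ratio / sum(ratio)
  if (any(expected == 0)) abort("an expected count is zero.")
  if (length(observed) == 2) {
    sum((abs(observed - expected) - 0.5)^2 / expected)
  } else {
    sum((observed - expected)^2 / expected)
  }
}

#' Upper-tail chi-square probability
#'
#' @param statistic Chi-square statistic, `>= 0`.
#' @param df Degrees of freedom, `>= 1`.
#' @return `P(X >= statistic)` for `X ~ chi-square(df)`.
#' @examples
#' chisq_pvalue(3.8415, 1) # ~0.05
#' @export
chisq_pvalue <- function(statistic, df) {
  if (any(statistic < 0)) abort("`statistic` must be non-negative.")
  if (any(df < 1)) abort("`df` must be >= 1.")
  pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Chi-square critical value
#'
#' @param alpha Significance level.
#' @param df Degrees of freedom.
#' @return The value `x` with `P(X >= x) = alpha`.
#' @examples
#' chisq_critical(0.05, 1) # 3.84
#' @export
chisq_critical <- function(alpha, df = 1) {
  qchisq(1 - alpha, df = df)
}

#' Test observed segregation counts against an expected ratio
#'
#' Composes [yates_chisq()] and [chisq_pvalue()]; the observation "fits"
#' the ratio iff `p >= alpha`.
#'
#' @param observed Class counts.
#' @param ratio Expected ratio terms.
#' @param alpha Significance level (default 0.05).
#' @param classes Optional class labels.
#' @return An object of class `seg_test` with `tidy()` and `glance()`
#'   methods; printed values are rounded to 2 decimals, raw values are
#'   kept in the object.
#' @examples
#' segregation_test(c(310, 90), c(3, 1))
#' @export
segregation_test <- function(observed, ratio, alpha = 0.05, classes = NULL) {
  stat <- yates_chisq(observed, ratio)
  df <- length(observed) - 1L
  p <- chisq_pvalue(stat, df)
  structure(
    list(
      observed = observed, ratio = ratio, alpha = alpha,
      classes = classes %||% paste0("class", seq_along(observed)),
      statistic = stat, df = df, p_value = p,
      decision = if (p >= alpha) "fits" else "rejects"
    ),
    class = "seg_test"
  )
}

#' @export
print.seg_test <- function(x, ...) {
  cat("Segregation goodness-of-fit (", paste(x$ratio, collapse = ":"),
      " expected)\n", sep = "")
  cat("  observed: ", paste(x$observed, collapse = ", "),
      "  (n = ", sum(x$observed), ")\n", sep = "")
  cat(sprintf("  chi-square = %.2f, df = %d, p = %.2f -> %s at alpha = %g\n",
              x$statistic, x$df, x$p_value, x$decision, x$alpha))
  invisible(x)
}

#' @method tidy seg_test
#' @export
tidy.seg_test <- function(x, ...) {
  tibble(
    class = x$classes, observed = x$observed,
    expected = sum(x$observed) * x$ratio / sum(x$ratio)
  )
}

#' @method glance seg_test
#' @export
glance.seg_test <- function(x, ...) {
  tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n = sum(x$observed), ratio = paste(x$ratio, collapse = ":"),
    decision = x$decision
  )
}

#' Run segregation tests over a table of observations
#'
#' Data-frame-first companion to [segregation_test()]: one row per
#' cross/generation with two count columns and a ratio string such as
#' `"3:1"`.
#'
#' @param data A data frame.
#' @param counts Character vector naming the count columns, in class order.
#' @param ratio Name of the column holding the expected ratio (`"a:b"`),
#'   or a single ratio string applied to all rows.
#' @param alpha Significance level.
#' @return `data` with `statistic`, `p_value` and `decision` appended.
#' @examples
#' tbl <- tibble::tibble(wild = c(310, 609), mutant = c(90, 184))
#' segregation_table(tbl, c("wild", "mutant"), ratio = "3:1")
#' @export
segregation_table <- function(data, counts, ratio, alpha = 0.05) {
  ratios <- if (ratio %in% names(data)) data[[ratio]] else rep(ratio, nrow(data))
  res <- purrr::map2(seq_len(nrow(data)), ratios, function(i, r) {
    obs <- as.numeric(unlist(data[i, counts]))
    rt <- as.numeric(strsplit(r, ":", fixed = TRUE)[[1]])
    st <- segregation_test(obs, rt, alpha = alpha)
    tibble(statistic = st$statistic, p_value = st$p_value,
           decision = st$decision)
  })
  dplyr::bind_cols(as_tibble(data), bind_rows(res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
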