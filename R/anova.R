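#' Reads per million mapped
#'
#' @param te_reads Reads assigned to the element (vectorized).
#' @param total_mapped Total reads mapped to the reference (> 0).
#' @return `1e6 * te_reads / total_mapped`.
#' @export
rpm <- function(te_reads, total_mapped) {
  stopifnot(all(te_reads >= 0), all(te_reads <= total_mapped))
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  1e6 * te_reads / total_mapped
}

#' Upper tail of the F distribution
#'
#' @param statistic F statistic (>= 0, vectorized).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @return `P(F >= statistic)`.
#' @export
f_tail <- function(statistic, df1, df2) {
  stopifnot(all(statistic >= 0))
  if (any(df1 <= 0) || any(df2 <= 0)) stop("degrees of freedom must be positive")
  stats::pf(statistic, df1, df2, lower.tail = FALSE)
}

finish_anova_table <- function(tab, response, n, fit = NULL) {
  df_resid <- tab$df[tab$term == "Residuals"]
  resid_ms <- tab$sum_sq[tab$term == "Residuals"] / df_resid
  tab$mean_sq <- tab$sum_sq / tab$df
  tab$statistic <- NA_real_
  tab$p_value <- NA_real_
  idx <- which(tab$term != "Residuals")
  degenerate <- tab$sum_sq[idx] == 0 & resid_ms == 0
  tab$statistic[idx] <- ifelse(degenerate, 0, tab$mean_sq[idx] / resid_ms)
  tab$p_value[idx] <- ifelse(degenerate, 1,
                             f_tail(tab$statistic[idx], tab$df[idx], df_resid))
  structure(
    list(table = tab, fit = fit, response = response, n = n),
    class = "te_anova"
  )
}

#' Sequential (Type I) ANOVA on expression observations
#'
#' Fits the fixed-effect factorial model used for reciprocal-cross RPM
#' comparisons -- by default treatment, then age class, then barcode, then
#' the treatment x age interaction -- with sequential sums of squares (each
#' term adjusted for all preceding terms), F against the residual mean
#' square, and upper-tail F p-values. Technical replicates (lanes) enter as
#' observations; no lane term is fit. Backed by `stats::aov`.
#'
#' @param data A tibble of observations (e.g. [simulate_expression()]
#'   output) with the response and factor columns.
#' @param response Name of the response column (reads per million mapped).
#' @param terms Character vector of model terms, in the order in which their
#'   sums of squares are taken.
#' @return An object of class `te_anova` whose `table` has rows `term`,
#'   `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value` (plus a Residuals
#'   row). Use [generics::tidy()] / [generics::glance()] to extract tibbles.
#' @export
sequential_anova <- function(data, response = "rpm",
                             terms = c("treatment", "age_class", "barcode",
                                       "treatment:age_class")) {
  stopifnot(response %in% names(data), nrow(data) > 1)
  base_terms <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_cols <- setdiff(base_terms, names(data))
  if (length(missing_cols) > 0) {
    stop("missing factor column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (tm in base_terms) {
    if (length(unique(data[[tm]])) < 2) {
      stop("factor '", tm, "' has fewer than 2 levels")
    }
  }
  fml <- stats::as.formula(
    paste(response, "~", paste(terms, collapse = " + "))
  )
  fit <- stats::aov(fml, data = data)
  s <- summary(fit)[[1]]
  tab <- tibble::tibble(
    term = trimws(rownames(s)),
    df = s[["Df"]],
    sum_sq = s[["Sum Sq"]]
  )
  # canonicalize interaction labels (R orders them by main-effect position)
  canon <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                              function(p) paste(sort(p), collapse = ":"),
                              character(1))
  if (fit$rank < ncol(stats::model.matrix(fit)) ||
      !all(canon(terms) %in% canon(tab$term))) {
    bad <- terms[!canon(terms) %in% canon(tab$term)]
    stop("singular (confounded) design; offending term(s): ",
         paste(if (length(bad) > 0) bad else "(aliased contrasts)",
               collapse = ", "))
  }
  finish_anova_table(tab, response, nrow(data), fit = fit)
}

#' Rebuild an ANOVA table from printed sums of squares
#'
#' Recomputes mean squares, F statistics and p-values from a published
#' table's `term`, `df` and `sum_sq` columns (one row must be named
#' `"Residuals"`), exactly as `mean_sq = sum_sq/df` and
#' `F = mean_sq / mean_sq(Residuals)`. Useful for checking or re-deriving
#' published ANOVA arithmetic when the raw observations are unavailable.
#'
#' @param summary_table A data frame with columns `term`, `df`, `sum_sq`.
#' @return A `te_anova` object (with `fit = NULL`).
#' @export
anova_from_summary <- function(summary_table) {
  stopifnot(all(c("term", "df", "sum_sq") %in% names(summary_table)),
            "Residuals" %in% summary_table$term)
  tab <- tibble::as_tibble(summary_table[, c("term", "df", "sum_sq")])
  finish_anova_table(tab, response = NA_character_,
                     n = sum(tab$df) + 1L)
}

#' @export
print.te_anova <- function(x, ...) {
  cat("Sequential ANOVA",
      if (!is.na(x$response)) paste0(" on '", x$response, "'"),
      " (n = ", x$n, ")\n", sep = "")
  print(as.data.frame(x$table), digits = 6)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sequential ANOVA
#'
#' @param x A `te_anova` object.
#' @param ... Unused.
#' @return The term-level tibble (`term`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic`, `p_value`).
#' @export
tidy.te_anova <- function(x, ...) x$table

#' One-row summary of a sequential ANOVA
#'
#' @param x A `te_anova` object.
#' @param ... Unused.
#' @return A tibble with `n`, `df_residual`, `total_sum_sq`, `r_squared`.
#' @export
glance.te_anova <- function(x, ...) {
  ssr <- x$table$sum_sq[x$table$term == "Residuals"]
  sst <- sum(x$table$sum_sq)
  tibble::tibble(
    n = x$n,
    df_residual = x$table$df[x$table$term == "Residuals"],
    total_sum_sq = sst,
    r_squared = if (sst > 0) 1 - ssr / sst else NA_real_
  )
}

#' Combined expression report over multiple elements
#'
#' Flags significant terms per element at level `alpha` and, when the raw
#' observations are supplied, emits per-group mean RPM with a technical
#' replicate error bar (SE over the libraries/lanes of each treatment x age
#' group) for plotting.
#'
#' @param anovas Named list of `te_anova` objects (names = element ids).
#' @param data Optional named list of the corresponding observation tibbles.
#' @param alpha Significance level for the flags.
#' @return A list of class `te_expression_report`: `flags` (tibble: `te`,
#'   `term`, `statistic`, `p_value`, `significant`) and `group_means`
#'   (tibble or NULL).
#' @export
expression_report <- function(anovas, data = NULL, alpha = 0.05) {
  stopifnot(length(anovas) >= 1)
  if (is.null(names(anovas))) names(anovas) <- paste0("TE", seq_along(anovas))
  flags <- purrr::imap_dfr(anovas, function(a, nm) {
    tab <- a$table[a$table$term != "Residuals", ]
    tibble::tibble(
      te = nm, term = tab$term, statistic = tab$statistic,
      p_value = tab$p_value,
      significant = !is.na(tab$p_value) & tab$p_value < alpha
    )
  })
  group_means <- NULL
  if (!is.null(data)) {
    group_means <- purrr::imap_dfr(data, function(d, nm) {
      d |>
        dplyr::group_by(.data$treatment, .data$age_class) |>
        dplyr::summarise(
          mean_rpm = mean(.data$rpm),
          se_rpm = stats::sd(.data$rpm) / sqrt(dplyr::n()),
          n = dplyr::n(), .groups = "drop"
        ) |>
        dplyr::mutate(te = nm, .before = 1)
    })
  }
  structure(
    list(flags = flags, group_means = group_means, alpha = alpha),
    class = "te_expression_report"
  )
}
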