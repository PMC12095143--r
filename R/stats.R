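# Batch statistics over prescription ensembles: median splits, Wilcoxon
# rank-sum comparisons between groups, and Pearson correlations among the
# indicators.

#' Split observations at the median of a variable
#'
#' Items strictly above the sample median of `split_var` get the second
#' label, items at or below it the first (so with all-equal values
#' everything is labeled low). The median uses the midpoint convention for
#' even n.
#'
#' @param data A data frame.
#' @param split_var Unquoted column to split on.
#' @param labels Two-element character vector, low then high; e.g.
#'   `c("low", "high")` or `c("less", "more")`.
#'
#' @return `data` with an added factor column `group`; the cutoff is
#'   attached as attribute `split_value`.
#' @export
#' @examples
#' median_split(tibble::tibble(x = 1:4), x)
median_split <- function(data, split_var, labels = c("low", "high")) {
  v <- dplyr::pull(data, {{ split_var }})
  if (length(v) < 2) {
    abort_validation("median split needs at least two observations")
  }
  if (length(labels) != 2) {
    abort_validation("labels must have exactly two elements")
  }
  cut <- stats::median(v)
  out <- dplyr::mutate(
    data,
    group = factor(ifelse(v > cut, labels[2], labels[1]), levels = labels)
  )
  attr(out, "split_value") <- cut
  out
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum test with midranks for ties. The exact permutation
#' distribution is used when the combined sample size is at most
#' `exact_limit` and there are no ties; otherwise the normal approximation
#' with tie and continuity correction. The default switch point (12) keeps
#' the exact branch cheap and deterministic.
#'
#' @param a,b Numeric vectors, both nonempty.
#' @param exact_limit Combined-n threshold for the exact branch.
#' @param correct Apply the continuity correction in the approximate
#'   branch (default `TRUE`).
#'
#' @return One-row tibble: `statistic` (Mann-Whitney U for the first
#'   group), `p_value`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # exact two-sided p = 0.1
rank_sum_test <- function(a, b, exact_limit = 12, correct = TRUE) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    abort_validation("both groups must be nonempty")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= exact_limit && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = correct)
  )
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation",
    n_a = length(a),
    n_b = length(b)
  )
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the t
#' transform with n - 2 degrees of freedom. Constant input is an error
#' (the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#'
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p_value`,
#'   `n`.
#' @export
pearson_cor_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort_validation("x and y must have the same length")
  }
  if (length(x) < 3) {
    abort_validation("correlation needs at least three observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_validation("constant input: correlation undefined")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(
    estimate = unname(ht$estimate),
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = length(x)
  )
}

#' Indicator panels for a list of prescription bundles
#'
#' Runs [compare_prescription()] on every bundle and stacks the results
#' into the batch table consumed by [batch_stats()].
#'
#' @param bundles List of prescription bundles (see [generate_ensemble()],
#'   [chong_he_fixture()], [read_bundle()]).
#' @param p_cutoff,min_genes,adjust,average,propagate Passed through to
#'   [compare_prescription()].
#' @param use_gene_sets Run the pathway stage (default `TRUE` when bundles
#'   carry gene sets).
#'
#' @return Tibble with one row per prescription: `prescription_id`,
#'   `n_drugs` and the six indicator columns.
#' @export
batch_indicators <- function(bundles, p_cutoff = 0.05, min_genes = 10,
                             adjust = "none", average = "targets",
                             propagate = "sum", use_gene_sets = TRUE) {
  purrr::map_dfr(bundles, function(b) {
    cmp <- compare_prescription(
      b$records, b$maps, b$disease_targets,
      gene_sets = if (use_gene_sets) b$gene_sets else NULL,
      p_cutoff = p_cutoff, min_genes = min_genes, adjust = adjust,
      average = average, propagate = propagate
    )
    dplyr::bind_cols(
      tibble::tibble(
        prescription_id = b$prescription_id %||% NA_character_,
        n_drugs = nrow(b$records)
      ),
      cmp$panel
    )
  })
}

group_comparison_row <- function(panels, outcome, input, labels) {
  split <- median_split(panels, !!rlang::sym(outcome), labels = labels)
  lo <- split[[input]][split$group == labels[1]]
  hi <- split[[input]][split$group == labels[2]]
  lo <- lo[!is.na(lo)]
  hi <- hi[!is.na(hi)]
  base <- tibble::tibble(
    grouping = outcome, variable = input,
    cutoff = attr(split, "split_value"),
    n_low = length(lo), n_high = length(hi)
  )
  if (length(lo) == 0 || length(hi) == 0) {
    rlang::warn(sprintf(
      "degenerate %s grouping (all observations on one side); test skipped",
      outcome
    ))
    return(dplyr::bind_cols(
      base,
      tibble::tibble(statistic = NA_real_, p_value = NA_real_)
    ))
  }
  ht <- rank_sum_test(lo, hi)
  dplyr::bind_cols(
    base,
    tibble::tibble(statistic = ht$statistic, p_value = ht$p_value)
  )
}

#' Ensemble-level statistics on an indicator table
#'
#' Reproduces the grouping analyses of the method at batch level:
#' prescriptions are split at the median of each output indicator (DeDT,
#' DePy; labels low/high) and the input indicators (Dedis, DeSD and their
#' metabolite-level variants) are compared between groups with the
#' Wilcoxon rank-sum test. Prescriptions are additionally split by drug
#' count (labels less/more) and DeSD compared between the groups. Pearson
#' correlations are computed for (Dedis, DeSD) and (drug count, DeSD).
#' Degenerate splits (all observations on one side) and constant
#' correlation inputs are skipped with a warning and reported as `NA`.
#'
#' @param panels Indicator table from [batch_indicators()].
#'
#' @return A `batch_stats` object: list with tibbles `group_tests` and
#'   `correlations`; has a [tidy()] method.
#' @export
batch_stats <- function(panels) {
  assert_columns(panels, c("n_drugs", "dedis", "desd", "dedt"),
    what = "indicator table"
  )
  outcomes <- intersect(c("dedt", "depy"), names(panels))
  outcomes <- outcomes[vapply(
    outcomes, function(o) !all(is.na(panels[[o]])), logical(1)
  )]
  inputs <- intersect(
    c("dedis", "desd", "compound_dedis", "compound_desd"), names(panels)
  )
  group_tests <- purrr::map_dfr(outcomes, function(o) {
    purrr::map_dfr(inputs, function(i) {
      group_comparison_row(panels, o, i, labels = c("low", "high"))
    })
  })
  group_tests <- dplyr::bind_rows(
    group_tests,
    group_comparison_row(panels, "n_drugs", "desd",
      labels = c("less", "more")
    )
  )

  cor_pairs <- list(c("dedis", "desd"), c("n_drugs", "desd"))
  correlations <- purrr::map_dfr(cor_pairs, function(p) {
    res <- tryCatch(
      pearson_cor_test(panels[[p[1]]], panels[[p[2]]]),
      dosenet_validation_error = function(e) {
        rlang::warn(sprintf(
          "correlation (%s, %s) skipped: %s",
          p[1], p[2], conditionMessage(e)
        ))
        tibble::tibble(
          estimate = NA_real_, statistic = NA_real_,
          p_value = NA_real_, n = nrow(panels)
        )
      }
    )
    dplyr::bind_cols(tibble::tibble(x = p[1], y = p[2]), res)
  })

  structure(
    list(group_tests = group_tests, correlations = correlations),
    class = "batch_stats"
  )
}

#' @export
print.batch_stats <- function(x, ...) {
  cat("<batch_stats>\n$group_tests\n")
  print(x$group_tests)
  cat("$correlations\n")
  print(x$correlations)
  invisible(x)
}

#' Tidy batch statistics into one long table
#'
#' @param x A `batch_stats` object.
#' @param ... Unused.
#' @return Tibble stacking the grouped comparisons and correlations with a
#'   `type` column.
#' @export
tidy.batch_stats <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$group_tests, type = "group_test"),
    dplyr::mutate(
      tibble::tibble(
        grouping = NA_character_,
        variable = paste(x$correlations$x, x$correlations$y, sep = ","),
        cutoff = NA_real_, n_low = NA_integer_, n_high = NA_integer_,
        statistic = x$correlations$estimate,
        p_value = x$correlations$p_value
      ),
      type = "correlation"
    )
  )
}
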