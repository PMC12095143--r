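# Input/output difference indicators between the non-dosage and
# dosage-weighted network variants of the same prescription:
#   Dedis  - Euclidean distance between the standardized dosage vector and
#            the all-ones vector (input difference, drug level)
#   DeSD   - sample standard deviation of the standardized dosage vector
#            (the all-ones vector's SD being identically 0)
#   DeDT   - 1 - Jaccard similarity of the two predicted drug-target sets
#   DePy   - 1 - Jaccard similarity of the two enriched-pathway sets
# plus metabolite-level variants compound_Dedis / compound_DeSD.

#' Euclidean input-difference indicator (Dedis)
#'
#' Euclidean distance between two dosage vectors over the same drugs in
#' the same order; with the default `y = NULL` the comparison is against
#' the all-ones vector of the non-dosage network, which is the Dedis
#' indicator.
#'
#' @param x A `dosage_vector`, data frame with a `value` column, or bare
#'   numeric vector.
#' @param y Same, defaulting to all ones of matching length.
#'
#' @return Nonnegative scalar; 0 iff `x == y` componentwise.
#' @export
#' @examples
#' dedis(c(1, 1, 10)) # 9
dedis <- function(x, y = NULL) {
  xv <- dosage_values(x)
  yv <- if (is.null(y)) rep(1, length(xv)) else dosage_values(y)
  if (length(xv) != length(yv)) {
    abort_validation("dosage vectors must have the same length")
  }
  if (is.data.frame(x) && is.data.frame(y) &&
    "drug_id" %in% names(x) && "drug_id" %in% names(y) &&
    !identical(x$drug_id, y$drug_id)) {
    abort_validation("dosage vectors must cover the same drugs in order")
  }
  sqrt(sum((xv - yv)^2))
}

#' Standard-deviation input-difference indicator (DeSD)
#'
#' Sample standard deviation (n - 1 denominator, as in R's `sd()`) of the
#' standardized dosage vector. Because the non-dosage vector is constant
#' its SD is identically zero, so this difference equals the SD of the
#' weighted vector itself.
#'
#' @inheritParams dedis
#' @return Nonnegative scalar; 0 for any constant vector.
#' @export
#' @examples
#' desd(c(1, 1, 10)) # sqrt(27)
desd <- function(x) {
  xv <- dosage_values(x)
  if (length(xv) < 2) {
    abort_validation("DeSD needs at least two components")
  }
  stats::sd(xv)
}

#' Set-difference indicator (1 - Jaccard similarity)
#'
#' `1 - |S1 n S2| / |S1 u S2|`, the output-difference measure behind DeDT
#' (drug-target sets) and DePy (enriched-pathway sets). Two empty sets are
#' defined as identical (difference 0); a disjoint nonempty pair scores 1.
#'
#' @param s1,s2 Vectors treated as sets (duplicates ignored).
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' set_difference(c("A", "B", "C"), c("B", "C", "D")) # 0.5
set_difference <- function(s1, s2) {
  s1 <- unique(s1)
  s2 <- unique(s2)
  u <- union(s1, s2)
  if (length(u) == 0) {
    return(0)
  }
  1 - length(intersect(s1, s2)) / length(u)
}

#' Metabolite-level dosage vector
#'
#' Expands a per-drug standardized dosage vector to the metabolite level:
#' one component per distinct metabolite, equal to the summed standardized
#' dosages of its parent drugs, in lexicographic metabolite order (fixed so
#' the compound indicators are reproducible).
#'
#' @param dosage A `dosage_vector`.
#' @param maps A [component_map()] covering every drug in `dosage`.
#'
#' @return Tibble with columns `metabolite_id`, `value`.
#' @export
metabolite_dosage_vector <- function(dosage, maps) {
  drugs <- dosage$drug_id
  unmapped <- setdiff(drugs, unique(maps$drug_metabolite$drug_id))
  if (length(unmapped) > 0) {
    abort_validation(sprintf(
      "no metabolite data for drug(s): %s",
      paste(unmapped, collapse = ", ")
    ))
  }
  dm <- dplyr::filter(maps$drug_metabolite, .data$drug_id %in% drugs)
  dm <- dplyr::left_join(dm, tibble::as_tibble(dosage)[c("drug_id", "value")],
    by = "drug_id"
  )
  out <- dplyr::summarise(
    dplyr::group_by(dm, .data$metabolite_id),
    value = sum(.data$value), .groups = "drop"
  )
  dplyr::arrange(out, .data$metabolite_id)
}

#' Compare the non-dosage and dosage-weighted pipelines end to end
#'
#' Runs the full pipeline twice for one prescription -- once with the
#' all-ones dosage vector (non-dosage variant) and once with the
#' standardized dosage vector -- and quantifies the differences: Dedis and
#' DeSD on the inputs, compound_Dedis / compound_DeSD on the
#' metabolite-level inputs, DeDT on the predicted drug-target sets, and
#' DePy on the enriched-pathway sets. With all-equal dosages the two
#' variants are identical and every indicator is exactly zero. When
#' `gene_sets` is `NULL` the pathway stage is skipped and DePy is `NA`.
#'
#' @inheritParams convert_to_grams
#' @param maps A [component_map()].
#' @param disease_targets Character vector of disease-associated genes.
#' @param gene_sets Optional [gene_set_collection()] for the pathway stage.
#' @param p_cutoff,min_genes,adjust Passed to [enrich()].
#' @param average,propagate Passed to [select_key_targets()] /
#'   [build_network()].
#'
#' @return A `dose_comparison` object with elements `dosage`, `networks`,
#'   `predictions`, `enrichment` (each a `nondosage` / `weighted` pair) and
#'   `panel`, a one-row tibble of the six indicators. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' fx <- chong_he_fixture()
#' cmp <- compare_prescription(fx$records, fx$maps, fx$disease_targets,
#'   fx$gene_sets,
#'   min_genes = 2
#' )
#' glance(cmp)
compare_prescription <- function(records, maps, disease_targets,
                                 gene_sets = NULL, p_cutoff = 0.05,
                                 min_genes = 10, adjust = "none",
                                 average = "targets", propagate = "sum",
                                 conversion = unit_conversion_table()) {
  report <- validate_prescription(records, maps, conversion)
  if (!is_valid(report)) {
    reasons <- c(
      attr(report, "issues"),
      stats::na.omit(report$reason)
    )
    abort_validation(paste0(
      "prescription failed validation: ",
      paste(unique(reasons), collapse = "; ")
    ))
  }
  x <- standardize_dosage(records, conversion)
  y <- ones_vector(drug_ids = x$drug_id)

  net_u <- build_network(y, maps, disease_targets, propagate = propagate)
  net_w <- build_network(x, maps, disease_targets, propagate = propagate)
  pred_u <- intersect_disease_targets(
    select_key_targets(net_u, average = average), disease_targets
  )
  pred_w <- intersect_disease_targets(
    select_key_targets(net_w, average = average), disease_targets
  )
  s1 <- pred_u$drug_targets
  s2 <- pred_w$drug_targets
  dedt <- set_difference(s1, s2)

  enr_u <- enr_w <- NULL
  depy <- NA_real_
  if (!is.null(gene_sets)) {
    enr_u <- enrich(s1, gene_sets,
      p_cutoff = p_cutoff,
      min_genes = min_genes, adjust = adjust
    )
    enr_w <- enrich(s2, gene_sets,
      p_cutoff = p_cutoff,
      min_genes = min_genes, adjust = adjust
    )
    depy <- set_difference(enr_u$pathway_id, enr_w$pathway_id)
  }

  mv_w <- metabolite_dosage_vector(x, maps)
  mv_u <- metabolite_dosage_vector(y, maps)
  compound_dedis <- sqrt(sum((mv_w$value - mv_u$value)^2))
  compound_desd <- if (nrow(mv_w) >= 2) {
    stats::sd(mv_w$value) - stats::sd(mv_u$value)
  } else {
    NA_real_
  }

  panel <- tibble::tibble(
    dedis = dedis(x, y),
    desd = if (nrow(x) >= 2) desd(x) else NA_real_,
    compound_dedis = compound_dedis,
    compound_desd = compound_desd,
    dedt = dedt,
    depy = depy
  )

  structure(
    list(
      dosage = x,
      networks = list(nondosage = net_u, weighted = net_w),
      predictions = list(nondosage = pred_u, weighted = pred_w),
      enrichment = list(nondosage = enr_u, weighted = enr_w),
      panel = panel
    ),
    class = "dose_comparison"
  )
}

#' @export
print.dose_comparison <- function(x, ...) {
  cat(sprintf(
    "<dose_comparison: %d drugs; drug targets %d (non-dosage) vs %d (weighted)>\n",
    nrow(x$dosage),
    length(x$predictions$nondosage$drug_targets),
    length(x$predictions$weighted$drug_targets)
  ))
  print(x$panel)
  invisible(x)
}

#' Tidy a dose comparison into long indicator form
#'
#' @param x A `dose_comparison`.
#' @param ... Unused.
#' @return Tibble with columns `indicator`, `level`, `value`.
#' @export
tidy.dose_comparison <- function(x, ...) {
  tibble::tibble(
    indicator = c(
      "dedis", "desd", "compound_dedis", "compound_desd", "dedt", "depy"
    ),
    level = c(
      "drug", "drug", "metabolite", "metabolite", "target", "pathway"
    ),
    value = unlist(x$panel[1, ], use.names = FALSE)
  )
}

#' One-row summary of a dose comparison
#'
#' @param x A `dose_comparison`.
#' @param ... Unused.
#' @return One-row tibble: sizes of each layer and prediction plus the six
#'   indicators.
#' @export
glance.dose_comparison <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_drugs = nrow(x$dosage),
      n_metabolites = sum(x$networks$weighted$nodes$layer == "metabolite"),
      n_targets = sum(x$networks$weighted$nodes$layer == "target"),
      n_drug_targets_nondosage =
        length(x$predictions$nondosage$drug_targets),
      n_drug_targets_weighted = length(x$predictions$weighted$drug_targets)
    ),
    x$panel
  )
}

#' Write indicator panels as a batch TSV
#'
#' @param panels Tibble of indicator rows, e.g. from [batch_indicators()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_indicator_panels <- function(panels, path) {
  readr::write_tsv(panels, path)
  invisible(path)
}
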