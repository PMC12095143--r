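# Synthetic fixtures and randomized prescription ensembles.
#
# Every stage of the pipeline is testable without any database access: the
# generator emulates the shapes of curated prescription data (drug counts,
# dosage ratio ranges, metabolite/target map sizes, disease target lists,
# pathway collections) with fully synthetic identifiers (G0001..., M...),
# reproducibly under a single seed.

#' Configuration for the synthetic ensemble generator
#'
#' Defaults emulate a realistically sized curated prescription corpus:
#' 94 prescriptions spanning 3-9 botanical drugs (median 6), dosage ratios
#' up to 99, and a disease gene list covering a substantial fraction of
#' the target universe.
#'
#' @param n_prescriptions Number of prescriptions to generate.
#' @param drugs_per_prescription Integer range `c(lo, hi)` of drugs per
#'   prescription.
#' @param metabolites_per_drug Integer range of bioactive metabolites per
#'   drug.
#' @param targets_per_metabolite Integer range of targets per metabolite.
#' @param dosage_ratio_max Maximum standardized dosage ratio; dosages are
#'   sampled on a log-uniform grid of `[1, dosage_ratio_max]` so extreme
#'   and near-null prescriptions both occur.
#' @param disease_target_fraction Fraction of the gene universe flagged as
#'   disease-associated, in (0, 1).
#' @param n_pathways Number of gene sets in the pathway collection.
#' @param pathway_size Integer range of genes per pathway.
#' @param n_genes Size of the synthetic gene universe.
#' @param null_fraction Fraction of prescriptions generated with all-equal
#'   dosages (exact count `round(n * null_fraction)`), the null cases of
#'   the comparison.
#' @param dosage_design `"log_uniform"` (default): independent per-drug
#'   ratios on the log-uniform grid, so input spread and input distance
#'   co-vary; or `"constant_spread"`: a single high-dosage drug with ratio
#'   `1 + c * sqrt(k)` for `k` drugs, which holds the sample SD of the
#'   dosage vector near `c` while the Euclidean distance still varies --
#'   an ensemble in which SD-based grouping carries no output signal.
#' @param seed Integer seed; all randomness in [generate_ensemble()] flows
#'   from it.
#'
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_prescriptions = 94,
                             drugs_per_prescription = c(3, 9),
                             metabolites_per_drug = c(2, 6),
                             targets_per_metabolite = c(2, 10),
                             dosage_ratio_max = 99,
                             disease_target_fraction = 0.3,
                             n_pathways = 25,
                             pathway_size = c(10, 30),
                             n_genes = 400,
                             null_fraction = 0.1,
                             dosage_design = c(
                               "log_uniform", "constant_spread"
                             ),
                             seed = 1L) {
  dosage_design <- match.arg(dosage_design)
  check_range <- function(r, name, lo_min = 1) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
      r[1] < lo_min || any(r != round(r))) {
      abort_validation(sprintf("%s must be an integer range c(lo, hi)", name))
    }
  }
  check_range(drugs_per_prescription, "drugs_per_prescription", lo_min = 2)
  check_range(metabolites_per_drug, "metabolites_per_drug")
  check_range(targets_per_metabolite, "targets_per_metabolite")
  check_range(pathway_size, "pathway_size")
  if (n_prescriptions < 1) abort_validation("n_prescriptions must be >= 1")
  if (!is.finite(dosage_ratio_max) || dosage_ratio_max <= 1) {
    abort_validation("dosage_ratio_max must exceed 1")
  }
  if (disease_target_fraction <= 0 || disease_target_fraction >= 1) {
    abort_validation("disease_target_fraction must lie in (0, 1)")
  }
  if (null_fraction < 0 || null_fraction > 1) {
    abort_validation("null_fraction must lie in [0, 1]")
  }
  if (n_genes < pathway_size[2]) {
    abort_validation("n_genes must be at least the maximum pathway size")
  }
  structure(
    list(
      n_prescriptions = as.integer(n_prescriptions),
      drugs_per_prescription = as.integer(drugs_per_prescription),
      metabolites_per_drug = as.integer(metabolites_per_drug),
      targets_per_metabolite = as.integer(targets_per_metabolite),
      dosage_ratio_max = dosage_ratio_max,
      disease_target_fraction = disease_target_fraction,
      n_pathways = as.integer(n_pathways),
      pathway_size = as.integer(pathway_size),
      n_genes = as.integer(n_genes),
      null_fraction = null_fraction,
      dosage_design = dosage_design,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
}

#' Hand-built worked-example fixture (Chong He powder)
#'
#' The classic three-drug prescription recorded as one Fen of Bai Yao Zi,
#' one Fen of Gan Cao and one Qian of Xiong Huang (realgar) in Song-Yuan
#' units, which converts to \[0.4, 0.4, 4\] g and standardizes to
#' \[1, 1, 10\]. (A later source records the same formula as 1 Qian / 1
#' Qian / 1 Liang, the same 1:1:10 ratio.) The accompanying component map,
#' disease list and pathway collection are synthetic and hand-sized so
#' that the dosage-weighted network predicts a strict superset of the
#' non-dosage drug targets, the gained targets belonging to the
#' ten-fold-dosed drug -- the qualitative behaviour the method is designed
#' to expose. Use `min_genes = 2` for the pathway stage: the fixture
#' universe holds only 20 genes.
#'
#' @return A prescription bundle: list with `prescription_id`, `records`,
#'   `maps`, `disease_targets`, `gene_sets`.
#' @export
#' @examples
#' fx <- chong_he_fixture()
#' standardize_dosage(fx$records)$value # 1 1 10
chong_he_fixture <- function() {
  records <- tibble::tibble(
    drug_id = c("BaiYaoZi", "GanCao", "XiongHuang"),
    quantity = c(1, 1, 1),
    unit = c("Fen", "Fen", "Qian"),
    dynasty = "SongYuan"
  )
  maps <- component_map(
    tibble::tibble(
      drug_id = c(
        "BaiYaoZi", "GanCao", "XiongHuang", "XiongHuang"
      ),
      metabolite_id = c("M.BYZ.1", "M.GC.1", "M.XH.1", "M.XH.2")
    ),
    tibble::tibble(
      metabolite_id = c(
        rep("M.BYZ.1", 3), rep("M.GC.1", 3), rep("M.XH.1", 2),
        rep("M.XH.2", 3)
      ),
      gene_symbol = c(
        "G01", "G02", "G05",
        "G01", "G02", "G06",
        "G01", "G03",
        "G02", "G04", "G07"
      )
    )
  )
  gene_sets <- gene_set_collection(
    list(
      P.SHARED = c("G01", "G02"),
      P.XH = c("G03", "G04"),
      P.BG = sprintf("G%02d", 5:20)
    ),
    names = c(
      "shared inflammatory response",
      "high-dose drug response",
      "background"
    )
  )
  list(
    prescription_id = "ChongHe",
    records = records,
    maps = maps,
    disease_targets = c("G01", "G02", "G03", "G04"),
    gene_sets = gene_sets
  )
}

generate_bundle <- function(i, cfg, genes, disease, gene_sets, is_null) {
  k <- sample_range(cfg$drugs_per_prescription)
  drug_ids <- sprintf("P%03d_D%02d", i, seq_len(k))

  m_counts <- vapply(
    seq_len(k), function(j) sample_range(cfg$metabolites_per_drug),
    integer(1)
  )
  pool_size <- max(max(m_counts), ceiling(0.8 * sum(m_counts)))
  pool <- sprintf("P%03d_M%03d", i, seq_len(pool_size))
  dm <- purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(
      drug_id = drug_ids[j],
      metabolite_id = sort(sample(pool, m_counts[j]))
    )
  })
  used <- sort(unique(dm$metabolite_id))
  mt <- purrr::map_dfr(used, function(m) {
    t <- sample_range(cfg$targets_per_metabolite)
    tibble::tibble(metabolite_id = m, gene_symbol = sample(genes, t))
  })

  grid <- exp(seq(log(1), log(cfg$dosage_ratio_max), length.out = 200))
  if (is_null) {
    quantity <- rep(sample(grid, 1), k)
  } else if (cfg$dosage_design == "log_uniform") {
    quantity <- sample(grid, k, replace = TRUE)
    if (length(unique(quantity)) == 1) {
      # keep the configured null fraction exact
      alt <- setdiff(grid, quantity[1])
      quantity[1] <- sample(alt, 1)
    }
  } else { # constant_spread
    r <- 1 + 3 * stats::runif(1, 0.9, 1.1) * sqrt(k)
    quantity <- sample(c(rep(1, k - 1), r))
  }

  records <- tibble::tibble(
    drug_id = drug_ids,
    quantity = quantity,
    unit = "gram",
    dynasty = "SongYuan"
  )
  list(
    prescription_id = sprintf("P%03d", i),
    records = records,
    maps = component_map(dm, mt),
    disease_targets = disease,
    gene_sets = gene_sets
  )
}

#' Generate a reproducible synthetic prescription ensemble
#'
#' Draws `n_prescriptions` self-contained bundles (prescription records,
#' component maps, a shared disease gene list and a shared pathway
#' collection) from the configured distributions. A fixed fraction of the
#' bundles has all-equal dosages, the exact null cases of the
#' non-dosage/dosage-weighted comparison. Pathway gene sets are sampled
#' with controlled overlap to the disease list so enrichment is
#' non-degenerate. Output is fully deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#'
#' @return List of prescription bundles (see [chong_he_fixture()] for the
#'   bundle shape); the configuration is attached as attribute `config`.
#' @export
generate_ensemble <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validation("config must be a synthetic_config")
  }
  cfg <- config
  set.seed(cfg$seed)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  disease <- sort(sample(
    genes, max(1, round(cfg$disease_target_fraction * cfg$n_genes))
  ))
  background <- setdiff(genes, disease)
  sets <- lapply(seq_len(cfg$n_pathways), function(j) {
    size <- sample_range(cfg$pathway_size)
    n_dis <- min(round(0.4 * size), length(disease))
    sort(c(
      sample(disease, n_dis),
      sample(background, size - n_dis)
    ))
  })
  names(sets) <- sprintf("PW%04d", seq_len(cfg$n_pathways))
  # catch-all background set pinning the universe; its over-representation
  # p is identically 1, so it can never be reported as enriched, and it
  # lets the GMT file carry the full universe through write/read cycles
  sets <- c(list(PW0000 = genes), sets)
  gene_sets <- gene_set_collection(
    sets,
    names = c("background universe", sprintf("pathway %d", seq_len(cfg$n_pathways)))
  )

  n <- cfg$n_prescriptions
  n_null <- round(n * cfg$null_fraction)
  null_idx <- if (n_null > 0) sample(seq_len(n), n_null) else integer()

  bundles <- lapply(seq_len(n), function(i) {
    generate_bundle(i, cfg, genes, disease, gene_sets, i %in% null_idx)
  })
  attr(bundles, "config") <- cfg
  bundles
}

#' Write a prescription bundle to a directory
#'
#' Emits the exact file dialects the package readers accept:
#' `prescription.csv`, `drug_metabolite.tsv`, `metabolite_target.tsv`
#' (metabolites without targets keep a row with an empty gene field),
#' `disease_targets.txt` (one symbol per line) and `gene_sets.gmt`.
#'
#' @param bundle A prescription bundle.
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    rlang::abort(sprintf("cannot create directory: %s", directory))
  }
  readr::write_csv(
    bundle$records, file.path(directory, "prescription.csv")
  )
  readr::write_tsv(
    bundle$maps$drug_metabolite,
    file.path(directory, "drug_metabolite.tsv")
  )
  mt <- bundle$maps$metabolite_target
  bare <- setdiff(bundle$maps$metabolites, unique(mt$metabolite_id))
  if (length(bare) > 0) {
    mt <- dplyr::bind_rows(
      mt, tibble::tibble(metabolite_id = bare, gene_symbol = "")
    )
  }
  readr::write_tsv(
    dplyr::arrange(mt, .data$metabolite_id),
    file.path(directory, "metabolite_target.tsv"), na = ""
  )
  writeLines(
    bundle$disease_targets, file.path(directory, "disease_targets.txt")
  )
  write_gmt(bundle$gene_sets, file.path(directory, "gene_sets.gmt"))
  invisible(directory)
}

#' Read a prescription bundle written by [write_bundle()]
#'
#' @param directory Bundle directory.
#' @return A prescription bundle; `prescription_id` is the directory
#'   basename.
#' @export
read_bundle <- function(directory) {
  need <- c(
    "prescription.csv", "drug_metabolite.tsv", "metabolite_target.tsv",
    "disease_targets.txt", "gene_sets.gmt"
  )
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "bundle directory %s is missing: %s",
      directory, paste(missing, collapse = ", ")
    ))
  }
  list(
    prescription_id = basename(normalizePath(directory)),
    records = read_prescriptions(file.path(directory, "prescription.csv")),
    maps = read_component_map(
      file.path(directory, "drug_metabolite.tsv"),
      file.path(directory, "metabolite_target.tsv")
    ),
    disease_targets = read_disease_targets(
      file.path(directory, "disease_targets.txt")
    ),
    gene_sets = read_gmt(file.path(directory, "gene_sets.gmt"))
  )
}
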