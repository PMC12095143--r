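# Layered prescription networks.
#
# The analysis graph is a four-layer multipartite network
# drug -> metabolite -> target -> disease. The non-dosage variant assigns
# weight 1 to every edge; the dosage-weighted variant propagates each
# drug's standardized dosage along its edges.

#' Build a component map from edge tables
#'
#' A component map holds the drug -> bioactive-metabolite and
#' metabolite -> target relations retrieved upstream (e.g. from a TCM
#' network-pharmacology database export). Gene symbols are case-normalized
#' and duplicate edges collapsed. A metabolite may legitimately have no
#' known targets; it stays in the map with an empty target set.
#'
#' @param drug_metabolite Data frame with columns `drug_id`,
#'   `metabolite_id`.
#' @param metabolite_target Data frame with columns `metabolite_id`,
#'   `gene_symbol`. Rows with an empty/`NA` gene symbol declare a
#'   metabolite with no known targets.
#'
#' @return A `component_map` object.
#' @export
#' @examples
#' component_map(
#'   tibble::tibble(drug_id = "d1", metabolite_id = "m1"),
#'   tibble::tibble(metabolite_id = "m1", gene_symbol = c("tp53", "IL6"))
#' )
component_map <- function(drug_metabolite, metabolite_target) {
  assert_columns(drug_metabolite, c("drug_id", "metabolite_id"),
    what = "drug_metabolite table"
  )
  assert_columns(metabolite_target, c("metabolite_id", "gene_symbol"),
    what = "metabolite_target table"
  )
  dm <- tibble::tibble(
    drug_id = as.character(drug_metabolite$drug_id),
    metabolite_id = as.character(drug_metabolite$metabolite_id)
  )
  dm <- dplyr::distinct(dm)
  mt <- tibble::tibble(
    metabolite_id = as.character(metabolite_target$metabolite_id),
    gene_symbol = toupper(trimws(as.character(metabolite_target$gene_symbol)))
  )
  mt$gene_symbol[is.na(mt$gene_symbol) | !nzchar(mt$gene_symbol) |
    mt$gene_symbol == "NA"] <- NA_character_
  declared <- unique(mt$metabolite_id)
  mt <- dplyr::distinct(mt[!is.na(mt$gene_symbol), ])
  structure(
    list(
      drug_metabolite = dm,
      metabolite_target = mt,
      metabolites = sort(unique(c(dm$metabolite_id, declared)))
    ),
    class = "component_map"
  )
}

#' @export
print.component_map <- function(x, ...) {
  cat(sprintf(
    "<component_map: %d drugs, %d metabolites, %d targets>\n",
    length(unique(x$drug_metabolite$drug_id)),
    length(x$metabolites),
    length(unique(x$metabolite_target$gene_symbol))
  ))
  invisible(x)
}

#' Read a component map from two TSV edge lists
#'
#' @param drug_metabolite_path TSV with header `drug_id`, `metabolite_id`.
#' @param metabolite_target_path TSV with header `metabolite_id`,
#'   `gene_symbol` (empty gene field = metabolite with no targets).
#'
#' @return A `component_map`.
#' @export
read_component_map <- function(drug_metabolite_path, metabolite_target_path) {
  dm <- readr::read_tsv(drug_metabolite_path,
    col_types = readr::cols(.default = readr::col_character())
  )
  mt <- readr::read_tsv(metabolite_target_path,
    col_types = readr::cols(.default = readr::col_character())
  )
  component_map(dm, mt)
}

#' Read a disease target list (one gene symbol per line)
#'
#' @param path Text file, one symbol per line; blank lines ignored.
#' @return Character vector of unique, case-normalized symbols.
#' @export
read_disease_targets <- function(path) {
  unique(norm_symbols(readLines(path, warn = FALSE)))
}

#' Construct a prescription network from node and edge tables
#'
#' Low-level constructor validating the layer structure: edges may only
#' connect adjacent layers (drug-metabolite, metabolite-target,
#' target-disease) and weights must be positive.
#'
#' @param nodes Tibble with columns `node`, `layer` (one of `"drug"`,
#'   `"metabolite"`, `"target"`, `"disease"`).
#' @param edges Tibble with columns `from`, `to`, `layer_pair`, `weight`.
#' @param dosage Optional `dosage_vector` the network was built from.
#' @param disease_targets Optional character vector of disease genes.
#'
#' @return A `prescription_network` object.
#' @export
prescription_network <- function(nodes, edges, dosage = NULL,
                                 disease_targets = NULL) {
  assert_columns(nodes, c("node", "layer"), what = "nodes")
  assert_columns(edges, c("from", "to", "layer_pair", "weight"),
    what = "edges"
  )
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (anyDuplicated(nodes$node) > 0) {
    abort_validation("duplicated node identifiers across layers")
  }
  allowed <- c("drug-metabolite", "metabolite-target", "target-disease")
  if (!all(edges$layer_pair %in% allowed)) {
    abort_validation("edges must connect adjacent layers only")
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    abort_validation("edge weights must be positive")
  }
  layer_of <- stats::setNames(nodes$layer, nodes$node)
  pair <- paste(layer_of[edges$from], layer_of[edges$to], sep = "-")
  if (!all(pair == edges$layer_pair)) {
    abort_validation("edge layer_pair inconsistent with node layers")
  }
  structure(
    list(
      nodes = nodes, edges = edges,
      dosage = dosage, disease_targets = disease_targets
    ),
    class = "prescription_network"
  )
}

#' Build the layered prescription network
#'
#' Builds the drug-metabolite-target-disease network for one prescription.
#' Drug-metabolite edges carry the drug's standardized dosage component;
#' each metabolite-target edge carries the dosages of all prescription
#' drugs containing that metabolite, combined by `propagate` (summed by
#' default, so a metabolite contributed by two drugs counts both sources);
#' target-disease edges (weight 1) link targets found in the disease gene
#' list to a single disease node. With an all-ones dosage vector and
#' unshared metabolites every edge weight is 1, i.e. the classical
#' non-dosage network.
#'
#' @param dosage A `dosage_vector` (see [standardize_dosage()],
#'   [ones_vector()]).
#' @param maps A [component_map()] covering every drug in `dosage`.
#' @param disease_targets Character vector of disease-associated gene
#'   symbols (may be empty).
#' @param propagate How a shared metabolite combines its parent drugs'
#'   dosages on its target edges: `"sum"` (default) or `"max"`.
#'
#' @return A `prescription_network`.
#' @export
#' @examples
#' fx <- chong_he_fixture()
#' x <- standardize_dosage(fx$records)
#' build_network(x, fx$maps, fx$disease_targets)
build_network <- function(dosage, maps, disease_targets = character(),
                          propagate = c("sum", "max")) {
  propagate <- match.arg(propagate)
  if (!inherits(maps, "component_map")) {
    abort_validation("maps must be a component_map")
  }
  drugs <- dosage$drug_id
  unmapped <- setdiff(drugs, unique(maps$drug_metabolite$drug_id))
  if (length(unmapped) > 0) {
    abort_validation(sprintf(
      "no metabolite/target data for drug(s): %s",
      paste(unmapped, collapse = ", ")
    ))
  }
  disease_targets <- unique(norm_symbols(disease_targets))

  dm <- dplyr::filter(maps$drug_metabolite, .data$drug_id %in% drugs)
  dm <- dplyr::left_join(dm, tibble::as_tibble(dosage)[c("drug_id", "value")],
    by = "drug_id"
  )

  met_weight <- dplyr::summarise(
    dplyr::group_by(dm, .data$metabolite_id),
    weight = if (propagate == "sum") sum(.data$value) else max(.data$value),
    .groups = "drop"
  )

  mt <- dplyr::filter(
    maps$metabolite_target,
    .data$metabolite_id %in% dm$metabolite_id
  )
  mt <- dplyr::left_join(mt, met_weight, by = "metabolite_id")

  targets <- sort(unique(mt$gene_symbol))
  hit <- intersect(targets, disease_targets)

  edges <- dplyr::bind_rows(
    tibble::tibble(
      from = dm$drug_id, to = dm$metabolite_id,
      layer_pair = "drug-metabolite", weight = dm$value
    ),
    tibble::tibble(
      from = mt$metabolite_id, to = mt$gene_symbol,
      layer_pair = "metabolite-target", weight = mt$weight
    ),
    tibble::tibble(
      from = hit, to = rep("disease", length(hit)),
      layer_pair = "target-disease", weight = rep(1, length(hit))
    )
  )
  edges <- dplyr::arrange(edges, .data$layer_pair, .data$from, .data$to)

  nodes <- dplyr::bind_rows(
    tibble::tibble(node = drugs, layer = "drug"),
    tibble::tibble(
      node = sort(unique(dm$metabolite_id)), layer = "metabolite"
    ),
    tibble::tibble(node = targets, layer = "target"),
    if (length(hit) > 0) tibble::tibble(node = "disease", layer = "disease")
  )

  prescription_network(nodes, edges,
    dosage = dosage, disease_targets = disease_targets
  )
}

#' @export
print.prescription_network <- function(x, ...) {
  counts <- table(factor(x$nodes$layer,
    levels = c("drug", "metabolite", "target", "disease")
  ))
  cat(sprintf(
    "<prescription_network: %d drugs, %d metabolites, %d targets%s; %d edges>\n",
    counts[["drug"]], counts[["metabolite"]], counts[["target"]],
    if (counts[["disease"]] > 0) " + disease node" else "",
    nrow(x$edges)
  ))
  invisible(x)
}

#' Weighted degree of network nodes
#'
#' The weighted degree of a node is the sum of the weights of its incident
#' edges; with unit weights this is the ordinary graph-theoretic degree.
#'
#' @param network A `prescription_network`.
#' @param nodes Optional character vector of node ids; default all nodes.
#'   Unknown ids are an error. Nodes with no incident edges have degree 0.
#'
#' @return A tibble with columns `node`, `layer`, `degree` (in the order of
#'   `nodes` when given).
#' @export
weighted_degree <- function(network, nodes = NULL) {
  incident <- dplyr::bind_rows(
    tibble::tibble(node = network$edges$from, w = network$edges$weight),
    tibble::tibble(node = network$edges$to, w = network$edges$weight)
  )
  deg <- dplyr::summarise(
    dplyr::group_by(incident, .data$node),
    degree = sum(.data$w), .groups = "drop"
  )
  out <- dplyr::left_join(network$nodes, deg, by = "node")
  out$degree[is.na(out$degree)] <- 0
  if (!is.null(nodes)) {
    unknown <- setdiff(nodes, out$node)
    if (length(unknown) > 0) {
      abort_validation(sprintf(
        "unknown node(s): %s", paste(unknown, collapse = ", ")
      ))
    }
    out <- out[match(nodes, out$node), ]
  }
  out
}

#' Select key targets by above-average weighted degree
#'
#' Target-layer nodes whose weighted degree strictly exceeds the average
#' weighted degree are the prescription's key targets. The averaging
#' population defaults to the target layer (key targets are selected among
#' targets); `average = "all"` uses every node in the network instead, as a
#' sensitivity check. Ties at the mean are excluded.
#'
#' @param network A `prescription_network` with at least one target node.
#' @param average `"targets"` (default) or `"all"`: population over which
#'   the mean degree is taken.
#'
#' @return A `target_prediction` object with elements `key_targets`
#'   (sorted character), `drug_targets` (`NULL` until
#'   [intersect_disease_targets()] is applied), `degree_table`,
#'   `mean_degree` and `average`.
#' @export
select_key_targets <- function(network, average = c("targets", "all")) {
  average <- match.arg(average)
  deg <- weighted_degree(network)
  tdeg <- deg[deg$layer == "target", c("node", "degree")]
  if (nrow(tdeg) == 0) {
    abort_validation("network has no target nodes")
  }
  mu <- if (average == "targets") mean(tdeg$degree) else mean(deg$degree)
  structure(
    list(
      key_targets = sort(tdeg$node[tdeg$degree > mu]),
      drug_targets = NULL,
      degree_table = tibble::as_tibble(tdeg),
      mean_degree = mu,
      average = average
    ),
    class = "target_prediction"
  )
}

#' Intersect key targets with disease targets
#'
#' The prescription's drug targets are the key targets that also appear in
#' the disease-associated gene list.
#'
#' @param prediction A `target_prediction` from [select_key_targets()].
#' @param disease_targets Character vector of disease gene symbols.
#'
#' @return The prediction with `drug_targets` populated (sorted).
#' @export
intersect_disease_targets <- function(prediction, disease_targets) {
  stopifnot(inherits(prediction, "target_prediction"))
  prediction$drug_targets <- sort(intersect(
    prediction$key_targets, unique(norm_symbols(disease_targets))
  ))
  prediction
}

#' @export
print.target_prediction <- function(x, ...) {
  cat(sprintf(
    "<target_prediction: %d key targets (mean degree %.3f over %s)%s>\n",
    length(x$key_targets), x$mean_degree, x$average,
    if (is.null(x$drug_targets)) {
      ""
    } else {
      sprintf(", %d drug targets", length(x$drug_targets))
    }
  ))
  invisible(x)
}

#' Tidy a target prediction into a degree table
#'
#' @param x A `target_prediction`.
#' @param ... Unused.
#' @return Tibble with columns `node`, `degree`, `is_key` (and
#'   `is_drug_target` once disease intersection has been applied), sorted
#'   by descending degree.
#' @export
tidy.target_prediction <- function(x, ...) {
  out <- dplyr::arrange(x$degree_table, dplyr::desc(.data$degree), .data$node)
  out$is_key <- out$node %in% x$key_targets
  if (!is.null(x$drug_targets)) {
    out$is_drug_target <- out$node %in% x$drug_targets
  }
  out
}

#' Write a network as a weighted edge-list TSV
#'
#' Columns `source`, `target`, `layer_pair`, `weight`; the dialect is
#' directly importable into Cytoscape and re-readable by [read_network()].
#'
#' @param network A `prescription_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  out <- tibble::tibble(
    source = network$edges$from,
    target = network$edges$to,
    layer_pair = network$edges$layer_pair,
    weight = network$edges$weight
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a network edge-list TSV written by [write_network()]
#'
#' @param path Edge-list TSV path.
#' @return A `prescription_network` (node layers inferred from
#'   `layer_pair`).
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path, col_types = "cccd")
  from_layer <- sub("-.*$", "", edges$layer_pair)
  to_layer <- sub("^.*-", "", edges$layer_pair)
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(node = edges$source, layer = from_layer),
    tibble::tibble(node = edges$target, layer = to_layer)
  ))
  nodes <- dplyr::arrange(nodes,
    factor(.data$layer, levels = c("drug", "metabolite", "target", "disease")),
    .data$node
  )
  prescription_network(
    nodes,
    tibble::tibble(
      from = edges$source, to = edges$target,
      layer_pair = edges$layer_pair, weight = edges$weight
    )
  )
}
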