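#' Read a stage-resolved abundance table
#'
#' Reads a compound-by-sample abundance table from CSV/TSV in either the
#' canonical long dialect (columns `compound`, `stage`, `replicate`, `value`,
#' optionally `class`, `fw_mg`, `istd`, `age_days`) or a wide dialect where
#' the first column is `compound` (optionally followed by `class`) and the
#' remaining columns are samples named `<stage>_<replicate>`, e.g. `S9_1`.
#' Long is the canonical internal form; wide input is pivoted on read.
#'
#' Missing cells are preserved as `NA`, never coerced to zero: an absent
#' measurement and a true zero are different observations.
#'
#' @param path Path to a delimited text file; delimiter is sniffed from the
#'   extension (`.tsv`/`.txt` are tab, everything else comma).
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @return A validated long tibble of abundances.
#' @export
read_profile_table <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (format == "auto") {
    format <- if (all(c("stage", "replicate", "value") %in% names(raw))) "long" else "wide"
  }
  if (format == "wide") {
    if (!"compound" %in% names(raw)) {
      abort("Malformed header: missing column `compound`.")
    }
    id_cols <- intersect(c("compound", "class"), names(raw))
    sample_cols <- setdiff(names(raw), id_cols)
    bad <- sample_cols[!grepl("^[^_]+_[0-9]+$", sample_cols)]
    if (length(bad)) {
      abort(sprintf("Wide sample columns must be <stage>_<replicate>; offending: %s.",
                    paste(bad, collapse = ", ")))
    }
    raw <- tidyr::pivot_longer(raw, cols = dplyr::all_of(sample_cols),
                               names_to = c("stage", "replicate"),
                               names_sep = "_", values_to = "value")
    raw$replicate <- as.integer(raw$replicate)
  }
  validate_profile_table(raw)
}

#' Validate a long profile table
#'
#' Enforces the structural invariants of a stage-resolved abundance table:
#' required columns present, no duplicated (compound, stage, replicate) cell,
#' abundances non-negative or missing, and positive fresh weight and internal
#' standard where supplied.
#'
#' @param data A long data frame of abundances.
#' @return The data as a tibble, invisibly validated.
#' @export
validate_profile_table <- function(data) {
  required <- c("compound", "stage", "replicate", "value")
  miss <- setdiff(required, names(data))
  if (length(miss)) {
    abort(sprintf("Malformed header: missing column `%s`.", miss[1]))
  }
  neg <- which(!is.na(data$value) & data$value < 0)
  if (length(neg)) {
    abort(sprintf("Negative abundance at row %d.", neg[1]))
  }
  dup <- duplicated(data[, c("compound", "stage", "replicate")])
  if (any(dup)) {
    abort(sprintf("Duplicated (compound, stage, replicate) cell at row %d.",
                  which(dup)[1]))
  }
  if ("fw_mg" %in% names(data) && any(data$fw_mg <= 0, na.rm = TRUE)) {
    abort("`fw_mg` must be positive.")
  }
  if ("istd" %in% names(data) && any(data$istd <= 0, na.rm = TRUE)) {
    abort("`istd` must be positive.")
  }
  tibble::as_tibble(data)
}

#' Write a profile table to CSV
#'
#' @param data A long profile table.
#' @param path Output file path.
#' @param format `"long"` (canonical) or `"wide"`.
#' @return The path, invisibly.
#' @export
write_profile_table <- function(data, path, format = c("long", "wide")) {
  format <- match.arg(format)
  data <- validate_profile_table(data)
  if (format == "wide") {
    data <- data |>
      dplyr::mutate(sample = paste(.data$stage, .data$replicate, sep = "_")) |>
      dplyr::select(dplyr::any_of(c("compound", "class")), "sample", "value") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "value")
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Write a correlation network to GraphML or edge-list CSV
#'
#' GraphML output carries node attributes (`id`, `class`, `degree`,
#' `betweenness`) and the edge attribute `r`; the edge CSV has columns
#' `source`, `target`, `r`, `p`. GraphML is preferred over GML because it
#' types its attributes; the CSV is for spreadsheet users. Both formats are
#' readable by standard graph tools.
#'
#' @param network A `correlation_network`, as built by [build_network()].
#' @param path Output file path.
#' @param format `"graphml"` or `"edge_csv"`.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_csv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "correlation_network"))
  if (format == "edge_csv") {
    readr::write_csv(network$edges[, c("source", "target", "r", "p")], path,
                     progress = FALSE)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydefs <- list(
    c("d_class", "node", "class", "string"),
    c("d_degree", "node", "degree", "int"),
    c("d_betweenness", "node", "betweenness", "double"),
    c("d_r", "edge", "r", "double"),
    c("d_p", "edge", "p", "double")
  )
  for (k in keydefs) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[3], attr.type = k[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- network$nodes[i, ]
    node <- xml2::xml_add_child(graph, "node", id = nd$id)
    d1 <- xml2::xml_add_child(node, "data", key = "d_class")
    xml2::xml_set_text(d1, as.character(nd$class %||% ""))
    d2 <- xml2::xml_add_child(node, "data", key = "d_degree")
    xml2::xml_set_text(d2, format(nd$degree))
    d3 <- xml2::xml_add_child(node, "data", key = "d_betweenness")
    xml2::xml_set_text(d3, format(nd$betweenness, digits = 17))
  }
  for (i in seq_len(nrow(network$edges))) {
    ed <- network$edges[i, ]
    edge <- xml2::xml_add_child(graph, "edge", source = ed$source, target = ed$target)
    d1 <- xml2::xml_add_child(edge, "data", key = "d_r")
    xml2::xml_set_text(d1, format(ed$r, digits = 17))
    d2 <- xml2::xml_add_child(edge, "data", key = "d_p")
    xml2::xml_set_text(d2, format(ed$p, digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GraphML correlation network written by [write_network()]
#'
#' @param path Path to a GraphML file.
#' @return A `correlation_network` with `nodes` and `edges` tibbles.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keymap <- setNames(xml2::xml_attr(keys, "attr.name"), xml2::xml_attr(keys, "id"))
  get_data <- function(node) {
    d <- xml2::xml_find_all(node, "./g:data", ns)
    setNames(xml2::xml_text(d), keymap[xml2::xml_attr(d, "key")])
  }
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- purrr::map_dfr(node_els, function(n) {
    dat <- get_data(n)
    tibble::tibble(
      id = xml2::xml_attr(n, "id"),
      class = dat[["class"]] %||% NA_character_,
      degree = as.integer(dat[["degree"]] %||% NA),
      betweenness = as.numeric(dat[["betweenness"]] %||% NA)
    )
  })
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- purrr::map_dfr(edge_els, function(e) {
    dat <- get_data(e)
    tibble::tibble(
      source = xml2::xml_attr(e, "source"),
      target = xml2::xml_attr(e, "target"),
      r = as.numeric(dat[["r"]] %||% NA),
      p = as.numeric(dat[["p"]] %||% NA)
    )
  })
  if (!nrow(nodes)) {
    nodes <- tibble::tibble(id = character(), class = character(),
                            degree = integer(), betweenness = numeric())
  }
  if (!nrow(edges)) {
    edges <- tibble::tibble(source = character(), target = character(),
                            r = numeric(), p = numeric())
  }
  new_correlation_network(nodes, edges)
}
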