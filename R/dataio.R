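#' @importFrom igraph graph_from_data_frame simplify V E ecount vcount
#'   as_data_frame make_empty_graph read_graph vertex_attr edge_attr
#'   delete_vertices degree neighbors distances add_vertices
#' @importFrom stats var cor sd pf pnorm p.adjust quantile setNames
#' @importFrom utils read.delim write.table combn adist head
NULL

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' Construct an expression dataset
#'
#' Bundles a genes-by-samples numeric matrix with a two-condition sample
#' annotation. Expression values are assumed to be already normalized
#' (typically log scale); the package performs no normalization itself.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param condition character vector named by sample id with values
#'   `"disease"` or `"control"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values` (matrix) and `condition` (named character vector aligned to
#'   the matrix columns).
#' @export
expression_dataset <- function(values, condition) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in `values`; collapse before construction")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  if (is.null(names(condition)))
    stop("`condition` must be named by sample id")
  missing_ann <- setdiff(colnames(values), names(condition))
  if (length(missing_ann) > 0)
    stop("samples missing from annotation: ", paste(missing_ann, collapse = ", "))
  condition <- as.character(condition[colnames(values)])
  names(condition) <- colnames(values)
  bad <- setdiff(unique(condition), c("disease", "control"))
  if (length(bad) > 0)
    stop("condition labels must be 'disease' or 'control'; found: ",
         paste(bad, collapse = ", "))
  if (length(unique(condition)) != 2)
    stop("exactly two condition labels required, found ",
         length(unique(condition)))
  if (min(table(condition)) < 2)
    stop("at least 2 samples per condition required")
  if (anyNA(values))
    stop("missing values in expression matrix; drop incomplete rows first")
  structure(list(values = values, condition = condition),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("expression_dataset: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is TSV (or CSV for a `.csv` extension) with a header row
#' of sample ids and gene symbols in the first column. The annotation file
#' maps sample id to condition (`disease`/`control`) in two columns, with or
#' without a header. Rows with missing values are dropped; duplicate gene
#' symbols are collapsed by keeping the row with the highest variance.
#' Both events are reported via [message()].
#'
#' @param path path to the expression matrix (TSV/CSV).
#' @param annotation_path path to the two-column sample annotation.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, annotation_path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes

  n_na <- sum(!stats::complete.cases(m))
  if (n_na > 0) {
    message(sprintf("read_expression: dropped %d row(s) with missing values", n_na))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }

  if (anyDuplicated(rownames(m))) {
    v <- apply(m, 1, var)
    ord <- order(rownames(m), -v)
    m2 <- m[ord, , drop = FALSE]
    keep <- !duplicated(rownames(m2))
    n_dup <- sum(!keep)
    message(sprintf("read_expression: collapsed %d duplicate gene row(s) keeping max variance", n_dup))
    m <- m2[keep, , drop = FALSE]
    m <- m[order(match(rownames(m), genes)), , drop = FALSE]
  }

  ann <- read.delim(annotation_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (tolower(ann[1, 2]) %in% c("condition", "group", "label"))
    ann <- ann[-1, , drop = FALSE]
  cond <- setNames(as.character(ann[[2]]), as.character(ann[[1]]))

  unmatched <- setdiff(colnames(m), names(cond))
  if (length(unmatched) > 0)
    stop("samples absent from annotation: ", paste(unmatched, collapse = ", "))
  expression_dataset(m, cond)
}

# ---------------------------------------------------------------------------
# GeneNetwork (igraph-backed)
# ---------------------------------------------------------------------------

#' Build a gene network from an edge table
#'
#' Networks are undirected igraph objects over gene symbols with an edge
#' `weight` attribute in \[0, 1\] (1 for unweighted input). Self-loops are
#' dropped and duplicate edges keep the maximum weight.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to include.
#' @param rescale if `TRUE`, weights outside \[0, 1\] are min-max rescaled
#'   instead of raising an error.
#' @return An undirected `igraph` graph.
#' @export
gene_network <- function(edges, nodes = NULL, rescale = FALSE) {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- make_empty_graph(n = 0, directed = FALSE)
    if (!is.null(nodes) && length(nodes) > 0)
      g <- add_vertices(g, length(nodes), name = as.character(nodes))
    return(g)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$weight)) edges$weight <- 1
  edges$weight <- as.numeric(edges$weight)

  n_loops <- sum(edges$from == edges$to)
  if (n_loops > 0) {
    message(sprintf("gene_network: removed %d self-loop(s)", n_loops))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
  }
  if (any(edges$weight < 0 | edges$weight > 1)) {
    if (!rescale)
      stop("edge weights outside [0,1]; pass rescale = TRUE to min-max rescale")
    rng <- range(edges$weight)
    edges$weight <- if (diff(rng) == 0) rep(1, nrow(edges)) else
      (edges$weight - rng[1]) / diff(rng)
  }
  all_nodes <- unique(c(edges$from, edges$to, as.character(nodes)))
  if (nrow(edges) == 0) return(gene_network(NULL, nodes = all_nodes))
  g <- graph_from_data_frame(edges[, c("from", "to", "weight")],
                             directed = FALSE, vertices = all_nodes)
  simplify(g, remove.loops = TRUE, remove.multiple = TRUE,
           edge.attr.comb = list(weight = "max"))
}

#' Canonical edge table of a network
#'
#' @param g an igraph gene network.
#' @return data.frame `from`, `to`, `weight` with `from < to` per row,
#'   sorted lexicographically (deterministic, diffable).
#' @export
network_edges <- function(g) {
  if (ecount(g) == 0)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  df <- igraph::as_data_frame(g, what = "edges")
  if (is.null(df$weight)) df$weight <- 1
  a <- pmin(df$from, df$to); b <- pmax(df$from, df$to)
  out <- data.frame(from = a, to = b, weight = df$weight,
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Read a network from an edge-list TSV or GraphML file
#'
#' Edge lists have 2 or 3 columns (`node_a`, `node_b`, optional weight), no
#' header required. Files ending in `.graphml` or `.xml` are parsed as
#' GraphML (read-only support).
#'
#' @inheritParams gene_network
#' @param path input file.
#' @return An undirected `igraph` graph with weights in \[0, 1\].
#' @export
read_network <- function(path, rescale = FALSE) {
  if (grepl("\\.(graphml|xml)$", path, ignore.case = TRUE)) {
    g <- read_graph(path, format = "graphml")
    df <- igraph::as_data_frame(g, what = "edges")
    nodes <- vertex_attr(g, "name")
    if (is.null(nodes)) nodes <- as.character(seq_len(vcount(g)))
    return(gene_network(df, nodes = nodes, rescale = rescale))
  }
  first <- readLines(path, n = 50)
  first <- first[!grepl("^#", first) & nzchar(first)]
  has_header <- length(first) > 0 &&
    grepl("^(from|node_a|source)\\b", first[1], ignore.case = TRUE)
  df <- read.delim(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("edge list needs at least 2 columns")
  names(df)[1:2] <- c("from", "to")
  if (ncol(df) >= 3) names(df)[3] <- "weight"
  gene_network(df[, seq_len(min(3, ncol(df))), drop = FALSE], rescale = rescale)
}

#' Write a network as a canonical edge-list TSV
#'
#' @param g igraph network.
#' @param path output path.
#' @param config optional named list echoed as `# key=value` header lines.
#' @export
write_network <- function(g, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_config_header(con, config)
  writeLines("from\tto\tweight", con)
  df <- network_edges(g)
  if (nrow(df) > 0)
    writeLines(sprintf("%s\t%s\t%.17g", df$from, df$to, df$weight), con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Drug library
# ---------------------------------------------------------------------------

#' Construct a drug record
#'
#' @param drug_id unique identifier.
#' @param smiles SMILES string or `NA` when the structure is unknown.
#' @param targets character vector of target gene symbols (may be empty).
#' @param network optional perturbational gene network (igraph).
#' @return list of class `drug_record`.
#' @export
drug_record <- function(drug_id, smiles = NA_character_, targets = character(0),
                        network = NULL) {
  stopifnot(is.character(drug_id), length(drug_id) == 1, nzchar(drug_id))
  structure(list(drug_id = drug_id,
                 smiles = if (is.na(smiles) || !nzchar(smiles)) NA_character_ else smiles,
                 targets = unique(as.character(targets)),
                 network = network),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat(sprintf("drug_record %s: smiles=%s, %d target(s), network=%s\n",
              x$drug_id, ifelse(is.na(x$smiles), "<absent>", x$smiles),
              length(x$targets),
              if (is.null(x$network)) "none" else
                sprintf("%d nodes/%d edges", vcount(x$network), ecount(x$network))))
  invisible(x)
}

#' Read a drug library TSV
#'
#' Expects columns `drug_id`, `smiles`, `targets` (semicolon-separated gene
#' symbols; empty allowed). SMILES that fail to parse are kept with an
#' absent structure and a warning; duplicate drug ids are a hard error.
#'
#' @param path drug library TSV.
#' @param validate_smiles if `TRUE` (default) each SMILES is parsed and
#'   unparseable ones are blanked with a warning.
#' @return named list of [drug_record()]s, class `drug_library`.
#' @export
read_drug_library <- function(path, validate_smiles = TRUE) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  need <- c("drug_id", "smiles", "targets")
  if (!all(need %in% names(df)))
    stop("drug library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug_id: ",
         paste(unique(df$drug_id[duplicated(df$drug_id)]), collapse = ", "))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    smi <- df$smiles[i]
    if (validate_smiles && !is.na(smi) && nzchar(smi)) {
      can <- tryCatch(canonical_smiles(smi), error = function(e) NA_character_)
      if (is.na(can)) {
        warning(sprintf("drug %s: unparseable SMILES '%s' dropped",
                        df$drug_id[i], smi), call. = FALSE)
        smi <- NA_character_
      }
    }
    tg <- df$targets[i]
    tg <- if (is.na(tg) || !nzchar(tg)) character(0) else
      strsplit(tg, ";", fixed = TRUE)[[1]]
    drug_record(df$drug_id[i], smiles = smi, targets = trimws(tg))
  })
  names(recs) <- df$drug_id
  structure(recs, class = "drug_library")
}

#' Write a drug library TSV
#' @param drugs `drug_library` list.
#' @param path output path.
#' @param config optional header config.
#' @export
write_drug_library <- function(drugs, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_config_header(con, config)
  writeLines("drug_id\tsmiles\ttargets", con)
  for (d in drugs)
    writeLines(sprintf("%s\t%s\t%s", d$drug_id,
                       ifelse(is.na(d$smiles), "", d$smiles),
                       paste(d$targets, collapse = ";")), con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Distance matrices and Pareto fronts
# ---------------------------------------------------------------------------

#' Write a labeled symmetric matrix as TSV
#'
#' Rows and columns are sorted lexicographically by label so output is
#' canonical and diffable; the round trip through [read_matrix()] is exact
#' to better than 1e-12.
#'
#' @param m square symmetric numeric matrix with identical row/col labels.
#' @param path output path.
#' @param config optional named list echoed as `# key=value` header lines.
#' @export
write_matrix <- function(m, path, config = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("`m` must be a square matrix")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("`m` must carry identical row and column labels")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix is not symmetric")
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  write_config_header(con, config)
  writeLines(paste(c("id", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])),
                     collapse = "\t"), con)
  invisible(NULL)
}

#' Read a labeled matrix written by [write_matrix()]
#' @param path input TSV.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a Pareto front as TSV
#'
#' One row per solution: the member drug ids (semicolon-separated,
#' sorted) and the five objective values.
#'
#' @param solutions list of `pareto_solution` objects from [run_ga()] /
#'   [pareto_front()].
#' @param path output path.
#' @param config optional header config.
#' @export
write_front <- function(solutions, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_config_header(con, config)
  writeLines("subset\tf1_size\tf2_moa\tf3_structure\tf4_coverage\tf5_target_dist",
             con)
  for (s in solutions)
    writeLines(paste(c(paste(sort(s$subset), collapse = ";"),
                       sprintf("%.17g", s$objectives)), collapse = "\t"), con)
  invisible(NULL)
}

#' Read a Pareto front TSV written by [write_front()]
#' @param path input TSV.
#' @return list of solutions (subset + objective vector).
#' @export
read_front <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  lapply(seq_len(nrow(df)), function(i) {
    obj <- as.numeric(df[i, 2:6])
    names(obj) <- c("f1_size", "f2_moa", "f3_structure", "f4_coverage",
                    "f5_target_dist")
    structure(list(subset = strsplit(df$subset[i], ";", fixed = TRUE)[[1]],
                   objectives = obj),
              class = "pareto_solution")
  })
}

# internal: "# key=value" provenance header
write_config_header <- function(con, config) {
  if (is.null(config) || length(config) == 0) return(invisible(NULL))
  keys <- sort(names(config))
  for (k in keys)
    writeLines(sprintf("# %s=%s", k, paste(format(config[[k]]), collapse = ",")),
               con)
  invisible(NULL)
}
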