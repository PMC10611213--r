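# Tissue-expression atlases: loading, prediction refinement, clustering
#
# Atlases are gene x tissue matrices of log2(TPM+1) values per species.
# Predictions whose target gene is expressed (>= theta) in at least one
# tissue of interest are retained; genes absent from the atlas are kept and
# flagged (absence of data is not evidence of absence).

#' Construct an expression atlas from a matrix
#'
#' @param mat numeric gene x tissue matrix (rownames = gene symbols,
#'   colnames = tissue labels), values log2(TPM+1), non-negative.
#' @param species species tag.
#' @param provenance free-text provenance string.
#' @return An `expression_atlas`.
#' @export
expression_atlas <- function(mat, species, provenance = "unspecified") {
  if (any(mat < 0)) {
    stop_offtarget("expression values must be non-negative", "offtarget_value_error")
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))]
    stop_offtarget(sprintf("duplicate gene row(s): %s",
                           paste(unique(dup), collapse = ", ")),
                   "offtarget_schema_error")
  }
  if (anyDuplicated(colnames(mat)) || any(!nzchar(colnames(mat)))) {
    stop_offtarget("tissue labels must be unique and non-empty",
                   "offtarget_schema_error")
  }
  structure(list(mat = mat, species = species, provenance = provenance),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas (%s): %d genes x %d tissues>\n",
              x$species, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Load an expression atlas from TSV
#'
#' Header row = tissue labels; first column = gene symbols. Duplicate genes,
#' empty tissue headers, ragged rows and negative values are format errors.
#'
#' @param path TSV path.
#' @param species species tag.
#' @return An `expression_atlas`.
#' @export
load_atlas <- function(path, species) {
  if (!file.exists(path)) {
    stop_offtarget(sprintf("file not found: %s", path), "offtarget_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- vapply(fields, length, 1L)
  if (length(unique(widths)) != 1) {
    stop_offtarget(sprintf("ragged TSV: rows have %s fields",
                           paste(unique(widths), collapse = "/")),
                   "offtarget_schema_error")
  }
  header <- fields[[1]]
  tissues <- header[-1]
  if (any(!nzchar(tissues))) {
    stop_offtarget("empty tissue column header", "offtarget_schema_error")
  }
  body <- fields[-1]
  genes <- vapply(body, `[[`, "", 1)
  vals <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(length(tissues))))
  if (any(is.na(vals))) {
    stop_offtarget("non-numeric expression values", "offtarget_schema_error")
  }
  rownames(vals) <- genes
  colnames(vals) <- tissues
  expression_atlas(vals, species, provenance = path)
}

#' Annotate predictions with tissue expression
#'
#' Each prediction's target gene is looked up in the atlas; the prediction
#' is retained for the tissue program when its maximum over the requested
#' tissues reaches `theta`. Genes absent from the atlas get status
#' `no_data` and are retained with a warning flag, never dropped.
#'
#' @param predictions tibble with at least `target_id`; the gene symbol
#'   defaults to `target_id` unless a `gene` column is present.
#' @param atlas an `expression_atlas`.
#' @param tissues tissue labels to consider (subset of the atlas's).
#' @param theta expression threshold in log2(TPM+1) (default 1.0).
#' @return `predictions` plus `gene`, `max_expression`, `expressed`
#'   (logical; `NA` for no-data), `expression_status`
#'   (`expressed` / `not_expressed` / `no_data`).
#' @export
filter_by_expression <- function(predictions, atlas, tissues = NULL,
                                 theta = 1.0) {
  if (theta < 0) stop_offtarget("theta must be >= 0", "offtarget_config_error")
  tissues <- tissues %||% colnames(atlas$mat)
  unknown <- setdiff(tissues, colnames(atlas$mat))
  if (length(unknown) > 0) {
    stop_offtarget(sprintf("unknown tissue label(s): %s",
                           paste(unknown, collapse = ", ")),
                   "offtarget_value_error")
  }
  gene <- if ("gene" %in% names(predictions)) predictions$gene
          else predictions$target_id
  idx <- match(gene, rownames(atlas$mat))
  mx <- rep(NA_real_, length(gene))
  has <- !is.na(idx)
  if (any(has)) {
    sub <- atlas$mat[idx[has], tissues, drop = FALSE]
    mx[has] <- apply(sub, 1, max)
  }
  status <- ifelse(!has, "no_data",
                   ifelse(mx >= theta, "expressed", "not_expressed"))
  if (any(!has)) {
    warn(sprintf("%d prediction(s) have no atlas data; retained and flagged",
                 sum(!has)))
  }
  predictions %>%
    mutate(gene = gene,
           max_expression = mx,
           expressed = ifelse(has, mx >= theta, NA),
           expression_status = status)
}

#' Flag relatively high expression per gene
#'
#' A tissue counts as "relatively high" for a gene when its value reaches
#' the gene's 75th percentile across all atlas tissues. Used for report
#' annotation only.
#'
#' @param atlas an `expression_atlas`.
#' @param genes gene symbols (default: all atlas genes).
#' @return Long tibble `gene`, `tissue`, `value`, `relatively_high`.
#' @export
relative_expression <- function(atlas, genes = NULL) {
  genes <- genes %||% rownames(atlas$mat)
  genes <- intersect(genes, rownames(atlas$mat))
  purrr::map(genes, function(g) {
    v <- atlas$mat[g, ]
    q75 <- quantile(v, 0.75, names = FALSE)
    tibble(gene = g, tissue = colnames(atlas$mat), value = unname(v),
           relatively_high = unname(v) >= q75)
  }) %>% bind_rows()
}

#' Hierarchically cluster atlas rows
#'
#' Agglomerative clustering with average linkage on 1 - Pearson correlation
#' across tissues. Rows are pre-sorted lexicographically by gene symbol so
#' the result is invariant to input row order; constant (zero-variance) rows
#' get the maximum distance (2) to every other row and are logged.
#'
#' @param mat numeric matrix with gene rownames (or an `expression_atlas`).
#' @return List `order` (gene symbols in dendrogram order) and `hclust`.
#' @export
cluster_rows <- function(mat) {
  if (inherits(mat, "expression_atlas")) mat <- mat$mat
  if (nrow(mat) < 2) {
    stop_offtarget("clustering needs at least 2 rows", "offtarget_value_error")
  }
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    inform(sprintf("constant row(s) assigned maximal distance: %s",
                   paste(rownames(mat)[sds == 0], collapse = ", ")))
  }
  cc <- suppressWarnings(cor(t(mat)))
  cc[!is.finite(cc)] <- -1 # constant rows: distance 2 to everything
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  list(order = rownames(mat)[hc$order], hclust = hc)
}

#' Export a clustered heatmap and its ordered matrix
#'
#' Writes the image (PNG) via pheatmap with the supplied row ordering, plus
#' a TSV of the row-ordered, row-z-scored matrix so downstream checks never
#' read pixels.
#'
#' @param mat numeric matrix (or an `expression_atlas`).
#' @param ordering row ordering from [cluster_rows()] (list or character).
#' @param path output PNG path; the TSV lands next to it (`.tsv`).
#' @return Invisible list with `png` and `tsv` paths.
#' @export
export_heatmap <- function(mat, ordering, path) {
  if (inherits(mat, "expression_atlas")) mat <- mat$mat
  ord <- if (is.list(ordering)) ordering$order else ordering
  m <- mat[ord, , drop = FALSE]
  sds <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  tsv <- sub("\\.png$", ".tsv", path)
  if (identical(tsv, path)) tsv <- paste0(path, ".tsv")
  df <- data.frame(gene = rownames(z), z, check.names = FALSE)
  write_descriptor_table(df, tsv)
  grDevices::png(path, width = 900, height = 200 + 18 * nrow(z), res = 110)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(z, cluster_rows = FALSE, cluster_cols = FALSE,
                     border_color = NA, main = "tissue expression (row z-score)")
  invisible(list(png = path, tsv = tsv))
}

#' Map human gene symbols to another species
#'
#' @param genes human gene symbols.
#' @param ortholog_map tibble `human_symbol`, `species`, `species_symbol`
#'   (at most one row per (species, human symbol)).
#' @param species target species tag.
#' @return List `mapped` (tibble `human_symbol`, `species_symbol` in input
#'   order) and `unmapped` (character vector).
#' @export
map_orthologs <- function(genes, ortholog_map, species) {
  sub <- ortholog_map[ortholog_map$species == species, , drop = FALSE]
  if (anyDuplicated(sub$human_symbol)) {
    stop_offtarget("ortholog map has multiple rows for one human symbol",
                   "offtarget_schema_error")
  }
  idx <- match(genes, sub$human_symbol)
  mapped <- tibble(human_symbol = genes[!is.na(idx)],
                   species_symbol = sub$species_symbol[idx[!is.na(idx)]])
  list(mapped = mapped, unmapped = genes[is.na(idx)])
}
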