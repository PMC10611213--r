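write_atlas_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("atlas TSVs load with full validation", {
  path <- write_atlas_tsv(c(
    "gene\tbrain\tliver\theart\tkidney",
    "G1\t5.2\t0.1\t0.2\t0.3",
    "G2\t0.1\t4.0\t0.0\t0.2",
    "G3\t1.0\t1.0\t1.0\t1.0"))
  atlas <- load_atlas(path, "human")
  expect_equal(dim(atlas$mat), c(3, 4))
  expect_equal(atlas$species, "human")

  dup <- write_atlas_tsv(c("gene\ta\tb", "G1\t1\t2", "G1\t3\t4"))
  err <- expect_error(load_atlas(dup, "human"), class = "offtarget_schema_error")
  expect_match(conditionMessage(err), "G1")

  noheader <- write_atlas_tsv(c("gene\ta\t", "G1\t1\t2"))
  expect_error(load_atlas(noheader, "human"), class = "offtarget_schema_error")

  ragged <- write_atlas_tsv(c("gene\ta\tb", "G1\t1"))
  expect_error(load_atlas(ragged, "human"), class = "offtarget_schema_error")

  neg <- write_atlas_tsv(c("gene\ta\tb", "G1\t-1\t2"))
  expect_error(load_atlas(neg, "human"), class = "offtarget_value_error")
})

test_that("expression filtering annotates, retains no-data, and conserves rows", {
  mat <- rbind(G1 = c(brain = 5.2, liver = 0.1),
               G2 = c(brain = 0.3, liver = 0.2))
  atlas <- expression_atlas(mat, "human")
  preds <- tibble::tibble(drug_id = "d",
                          target_id = c("G1", "G2", "GHOST"))
  expect_warning(
    ann <- filter_by_expression(preds, atlas, tissues = "brain", theta = 1.0),
    "no atlas data")
  expect_equal(ann$expression_status, c("expressed", "not_expressed", "no_data"))
  expect_equal(ann$expressed, c(TRUE, FALSE, NA))
  expect_equal(nrow(ann), nrow(preds)) # conservation
  counts <- table(ann$expression_status)
  expect_equal(sum(counts), nrow(preds))
  expect_error(filter_by_expression(preds, atlas, tissues = "spleen"),
               class = "offtarget_value_error")
  expect_error(filter_by_expression(preds, atlas, theta = -1),
               class = "offtarget_config_error")
})

test_that("clustering is deterministic, order-invariant, and groups duplicates", {
  set.seed(101)
  mat <- matrix(runif(5 * 6), nrow = 5,
                dimnames = list(paste0("G", 1:5), paste0("t", 1:6)))
  mat["G4", ] <- mat["G1", ] # identical pair must end up adjacent
  cl <- cluster_rows(mat)
  pos <- match(c("G1", "G4"), cl$order)
  expect_equal(abs(diff(pos)), 1)
  expect_equal(min(cl$hclust$height), 0)
  # permuting input rows changes nothing
  perm <- mat[sample(nrow(mat)), ]
  expect_identical(cluster_rows(perm)$order, cl$order)
  # constant rows are tolerated and logged
  mat2 <- rbind(mat, G6 = rep(1, 6))
  expect_message(cl2 <- cluster_rows(mat2), "constant")
  expect_equal(length(cl2$order), 6)
  expect_error(cluster_rows(mat[1, , drop = FALSE]),
               class = "offtarget_value_error")
})

test_that("planted expression blocks cluster contiguously across seeds", {
  hits <- vapply(1:20, function(s) {
    spec <- synthetic_spec(seed = 100 + s)
    atl <- gen_expression_atlas(spec)
    cl <- cluster_rows(atl$atlases[[1]])
    ord <- match(atl$blocks$gene, cl$order)
    all(vapply(split(ord, atl$blocks$block), function(ix) {
      max(ix) - min(ix) == length(ix) - 1
    }, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("heatmap export writes an ordered TSV next to the image", {
  mat <- matrix(abs(rnorm(40)), nrow = 8,
                dimnames = list(paste0("G", 1:8), paste0("t", 1:5)))
  cl <- cluster_rows(mat)
  png_path <- withr::local_tempfile(fileext = ".png")
  out <- export_heatmap(mat, cl, png_path)
  expect_true(file.exists(out$png))
  expect_true(file.exists(out$tsv))
  tsv <- utils::read.delim(out$tsv)
  expect_equal(tsv$gene, cl$order)
})

test_that("ortholog mapping preserves order and reports the unmapped", {
  map <- tibble::tibble(
    human_symbol = c("A", "B", "C"), species = "rat",
    species_symbol = c("A_rat", "B_rat", "C_rat"))
  res <- map_orthologs(c("B", "A", "Z"), map, "rat")
  expect_equal(res$mapped$species_symbol, c("B_rat", "A_rat"))
  expect_equal(res$unmapped, "Z")
  # human -> human identity via the synthetic generator's map
  spec <- synthetic_spec(seed = 1, n_targets = 3)
  atl <- gen_expression_atlas(spec)
  hu <- map_orthologs(c("GENE01", "GENE02"), atl$ortholog_map, "human")
  expect_equal(hu$mapped$species_symbol, c("GENE01", "GENE02"))
  expect_length(hu$unmapped, 0)
  full <- map_orthologs(paste0("GENE0", 1:3), atl$ortholog_map, "rat")
  expect_equal(nrow(full$mapped), 3)
  expect_length(full$unmapped, 0)
})
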