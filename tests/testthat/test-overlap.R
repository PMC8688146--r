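mini_table <- function(...) {
  de_table(data.frame(..., stringsAsFactors = FALSE))
}

test_that("prefilter keeps protein-coding genes with TPM >= 1", {
  tab <- mini_table(gene_id = c("a", "b", "c", "d"),
                    biotype = c("protein_coding", "lncRNA",
                                "protein_coding", "protein_coding"),
                    mean_tpm = c(1.0, 50, 0.99, 5),
                    log2fc = 0, padj = 0.5)
  out <- prefilter(tab)
  expect_setequal(out$gene_id, c("a", "d")) # boundary TPM = 1 retained
  empty <- prefilter(tab[0, ])
  expect_equal(nrow(empty), 0L)
  expect_error(prefilter(data.frame(gene_id = "x")), "lacks column")
})

test_that("the enrichment gate uses padj <= 0.05 and log2fc > 0", {
  tab <- mini_table(gene_id = c("a", "b", "c", "d", "e"),
                    biotype = "protein_coding", mean_tpm = 10,
                    log2fc = c(0.1, -1, 2, 0.5, 0),
                    padj = c(0.05, 0.01, 0.2, NA, 0.01))
  expect_equal(tanycyte_enriched(tab), "a") # inclusive boundary, sign gate
})

test_that("common DEGs require significance in both with concordant sign", {
  a <- mini_table(gene_id = c("up", "disc", "onlyA", "down", "zero"),
                  biotype = "protein_coding", mean_tpm = 10,
                  log2fc = c(1, 1, 1, -2, 0),
                  padj = c(0.01, 0.01, 0.01, 0.04, 0.001))
  b <- mini_table(gene_id = c("up", "disc", "onlyA", "down", "zero"),
                  biotype = "protein_coding", mean_tpm = 10,
                  log2fc = c(2, -1, 1, -1, 0),
                  padj = c(0.04, 0.01, 0.5, 0.01, 0.001))
  cd <- common_degs(a, b)
  expect_equal(cd$up, "up")
  expect_equal(cd$down, "down")
  # padj = 0.05 is NOT significant here (strict inequality)
  a$padj[1] <- 0.05
  expect_length(common_degs(a, b)$up, 0L)
})

test_that("restrict_to intersects and counts", {
  sets <- list(up = c("a", "b", "c"), down = c("d", "e"))
  res <- restrict_to(sets, c("a", "c", "e", "zzz"))
  expect_equal(res$up, c("a", "c"))
  expect_equal(res$down, "e")
  expect_equal(unlist(res$counts), c(n_up = 3, n_down = 2,
                                     n_up_in_set = 2, n_down_in_set = 1))
  ident <- restrict_to(sets, c(sets$up, sets$down))
  expect_equal(ident$up, sets$up)
  none <- restrict_to(sets, character(0))
  expect_length(none$up, 0L)
  expect_length(none$down, 0L)
})

test_that("the pipeline reproduces planted counts exactly", {
  tabs <- simulate_de_tables(n_up = 74L, n_down = 50L, n_up_in_set = 60L,
                             n_down_in_set = 28L, seed = 3)
  res <- overlap_pipeline(tabs$ip_vs_input, tabs$table_a, tabs$table_b)
  expect_equal(unlist(res$counts),
               c(n_up = 74, n_down = 50, n_up_in_set = 60,
                 n_down_in_set = 28))
  expect_setequal(res$common$up, tabs$truth$up)
  expect_setequal(res$common$down, tabs$truth$down)
})

test_that("zero planted genes yield empty sets; infeasible specs error", {
  tabs <- simulate_de_tables(n_up = 0L, n_down = 0L, n_up_in_set = 0L,
                             n_down_in_set = 0L, seed = 1)
  res <- overlap_pipeline(tabs$ip_vs_input, tabs$table_a, tabs$table_b)
  expect_equal(res$counts$n_up, 0L)
  expect_equal(res$counts$n_down, 0L)
  expect_error(simulate_de_tables(n_up = 50L, n_up_in_set = 60L), "exceed")
})

test_that("generated tables are seeded and deterministic", {
  expect_identical(simulate_de_tables(seed = 5)$table_a$padj,
                   simulate_de_tables(seed = 5)$table_a$padj)
  expect_false(identical(simulate_de_tables(seed = 5)$table_a$padj,
                         simulate_de_tables(seed = 6)$table_a$padj))
})

test_that("results are invariant to row order", {
  tabs <- simulate_de_tables(seed = 7)
  shuffle <- function(tab) tab[sample.int(nrow(tab)), ]
  set.seed(1)
  res1 <- overlap_pipeline(tabs$ip_vs_input, tabs$table_a, tabs$table_b)
  res2 <- overlap_pipeline(shuffle(tabs$ip_vs_input), shuffle(tabs$table_a),
                           shuffle(tabs$table_b))
  expect_equal(res1$common, res2$common)
  expect_equal(sort(res1$enriched), sort(res2$enriched))
})

test_that("relaxing thresholds never shrinks the returned sets", {
  tabs <- simulate_de_tables(noise = TRUE, seed = 9)
  a <- prefilter(tabs$table_a)
  b <- prefilter(tabs$table_b)
  strict <- common_degs(a, b)
  # relax by doubling every padj threshold via direct recomputation
  relax <- function(tab) { tab$padj <- tab$padj / 2; tab }
  loose <- common_degs(relax(a), relax(b)) # halving padj = doubling cutoff
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))
})

test_that("DE tables round-trip through TSV and CSV", {
  tabs <- simulate_de_tables(n_genes = 500L, n_set_extra = 50L, seed = 2)
  for (ext in c(".tsv", ".csv")) {
    tf <- tempfile(fileext = ext)
    write_de_table(tabs$table_a, tf)
    back <- read_de_table(tf)
    expect_equal(back$gene_id, tabs$table_a$gene_id)
    expect_equal(back$padj, tabs$table_a$padj, tolerance = 1e-12)
  }
})
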