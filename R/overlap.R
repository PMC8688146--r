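#' Differential-expression table schema
#'
#' The overlap filter chain consumes any DE result table with columns
#' `gene_id` (unique), `biotype`, `mean_tpm`, `log2fc`, `padj`
#' (`padj` in \[0, 1\] or `NA`; `NA` is treated as not significant, as in
#' DESeq2 output). DE statistics themselves are not computed here.
#'
#' @param table A data frame.
#' @return The validated table (invisibly classed `de_table`).
#' @export
de_table <- function(table) {
  need <- c("gene_id", "biotype", "mean_tpm", "log2fc", "padj")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("DE table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(table$gene_id))
    stop("gene_id must be unique")
  p <- table$padj
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("padj must lie in [0, 1] or be NA")
  class(table) <- unique(c("de_table", class(table)))
  table
}

#' Expression pre-filter
#'
#' Retains protein-coding genes with a mean TPM of at least 1 (boundary
#' inclusive).
#'
#' @param table A [de_table()].
#' @return The filtered table.
#' @export
prefilter <- function(table) {
  table <- de_table(table)
  keep <- table$biotype == "protein_coding" &
    !is.na(table$mean_tpm) & table$mean_tpm >= 1
  table[keep, , drop = FALSE]
}

#' Tanycyte-enrichment gate
#'
#' Genes upregulated in the ribosomal pulldown (IP) relative to the input:
#' adjusted p <= 0.05 AND log2 fold change > 0. Note the inclusive 0.05
#' boundary here, versus the strict `< 0.05` in [common_degs()]; both follow
#' the conventions as printed.
#'
#' @param ip_vs_input A prefiltered [de_table()] of IP vs input.
#' @return Character vector of gene ids (a gene set).
#' @export
tanycyte_enriched <- function(ip_vs_input) {
  tab <- de_table(ip_vs_input)
  sel <- !is.na(tab$padj) & tab$padj <= 0.05 & tab$log2fc > 0
  tab$gene_id[sel]
}

#' Commonly regulated genes across two comparisons
#'
#' Genes significant (adjusted p < 0.05) in both tables with the same
#' (nonzero) fold-change sign, partitioned into concordant-up and
#' concordant-down sets. The concordant-sign requirement is what makes the
#' up/down partition sum to the common total.
#'
#' @param table_a,table_b [de_table()]s over a shared gene universe.
#' @return List with character vectors `up` and `down`.
#' @export
common_degs <- function(table_a, table_b) {
  a <- de_table(table_a); b <- de_table(table_b)
  m <- merge(a[, c("gene_id", "log2fc", "padj")],
             b[, c("gene_id", "log2fc", "padj")],
             by = "gene_id", suffixes = c("_a", "_b"))
  sig <- !is.na(m$padj_a) & m$padj_a < 0.05 &
    !is.na(m$padj_b) & m$padj_b < 0.05
  up <- sig & m$log2fc_a > 0 & m$log2fc_b > 0
  down <- sig & m$log2fc_a < 0 & m$log2fc_b < 0
  list(up = sort(m$gene_id[up]), down = sort(m$gene_id[down]))
}

#' Restrict common DEG sets to a gene set
#'
#' Intersects the concordant up/down sets with (for example) the
#' tanycyte-enriched set and reports the counts.
#'
#' @param sets List with `up` and `down` (from [common_degs()]).
#' @param gene_set Character vector of gene ids.
#' @return List with `up`, `down` (intersections) and `counts`
#'   (`n_up`, `n_down`, `n_up_in_set`, `n_down_in_set`).
#' @export
restrict_to <- function(sets, gene_set) {
  up <- intersect(sets$up, gene_set)
  down <- intersect(sets$down, gene_set)
  list(up = sort(up), down = sort(down),
       counts = list(n_up = length(sets$up), n_down = length(sets$down),
                     n_up_in_set = length(up),
                     n_down_in_set = length(down)))
}

#' Synthetic DE tables with planted overlap structure
#'
#' Generates three DE tables (IP vs input, comparison A, comparison B) whose
#' filter-chain outcomes equal the planted truth exactly when `noise` is
#' off: `n_up` genes concordantly up and `n_down` concordantly down in both
#' comparisons, of which `n_up_in_set` and `n_down_in_set` lie inside the
#' enriched gene set. Defaults mirror a 74/50/60/28 overlap structure.
#'
#' @param n_genes Universe size.
#' @param n_up,n_down Planted concordant counts.
#' @param n_up_in_set,n_down_in_set Planted counts inside the enriched set
#'   (must not exceed `n_up` / `n_down`).
#' @param n_set_extra Additional enriched genes that are not common DEGs.
#' @param noise If `TRUE`, adjusted p-values of non-planted genes are drawn
#'   uniformly (so spurious overlaps can occur); if `FALSE` the planted
#'   counts are reproduced exactly.
#' @param seed Integer seed.
#' @return List with `ip_vs_input`, `table_a`, `table_b` (all [de_table()])
#'   and `truth` (the planted gene sets).
#' @export
simulate_de_tables <- function(n_genes = 4000L, n_up = 74L, n_down = 50L,
                               n_up_in_set = 60L, n_down_in_set = 28L,
                               n_set_extra = 300L, noise = FALSE,
                               seed = 1L) {
  if (n_up_in_set > n_up || n_down_in_set > n_down)
    stop("planted in-set counts cannot exceed the planted common counts")
  n_planted <- n_up + n_down
  if (n_genes < n_planted + n_set_extra + 100L)
    stop("gene universe too small for the planted structure")
  with_seed_(seed, {
    gene_id <- sprintf("gene_%05d", seq_len(n_genes))
    up_ids <- gene_id[seq_len(n_up)]
    down_ids <- gene_id[n_up + seq_len(n_down)]
    set_ids <- c(up_ids[seq_len(n_up_in_set)],
                 down_ids[seq_len(n_down_in_set)],
                 gene_id[n_planted + seq_len(n_set_extra)])
    planted <- gene_id %in% c(up_ids, down_ids)
    in_set <- gene_id %in% set_ids

    biotype <- ifelse(planted | in_set, "protein_coding",
                      sample(c("protein_coding", "lncRNA", "pseudogene"),
                             n_genes, TRUE, prob = c(0.75, 0.15, 0.10)))
    mean_tpm <- exp(stats::rnorm(n_genes, 2, 1.5))
    mean_tpm[planted | in_set] <- pmax(mean_tpm[planted | in_set], 1)

    null_p <- function() if (noise) stats::runif(n_genes)
      else stats::runif(n_genes, 0.1, 1)
    mk <- function(sig, lfc_sign) {
      padj <- null_p()
      lfc <- stats::rnorm(n_genes, 0, 0.4)
      padj[sig] <- stats::runif(sum(sig), 0, 0.049)
      lfc[sig] <- lfc_sign[sig] * stats::runif(sum(sig), 0.5, 3)
      # DESeq2-style missing padj, only among non-planted genes
      na_pool <- which(!sig)
      padj[sample(na_pool, max(1L, n_genes %/% 50))] <- NA
      list(padj = padj, lfc = lfc)
    }
    sgn <- ifelse(gene_id %in% up_ids, 1, ifelse(gene_id %in% down_ids, -1, 0))
    # comparisons A and B: planted genes significant with concordant sign;
    # a slice of non-planted genes is significant in A only (and some with
    # discordant sign in B) so the concordance logic is exercised
    a <- mk(planted, sgn)
    b <- mk(planted, sgn)
    only_a <- !planted & seq_len(n_genes) %% 7L == 0L
    a$padj[only_a] <- stats::runif(sum(only_a), 0, 0.049)
    a$lfc[only_a] <- stats::runif(sum(only_a), 0.5, 2)
    if (!noise) b$padj[only_a] <- stats::runif(sum(only_a), 0.1, 1)
    disc <- !planted & seq_len(n_genes) %% 11L == 0L & !only_a
    a$padj[disc] <- stats::runif(sum(disc), 0, 0.049)
    b$padj[disc] <- stats::runif(sum(disc), 0, 0.049)
    a$lfc[disc] <- abs(a$lfc[disc]) + 0.5
    b$lfc[disc] <- -(abs(b$lfc[disc]) + 0.5)

    ip <- mk(in_set, rep(1, n_genes))
    # exercise the inclusive gate boundary with one exact padj = 0.05
    ip$padj[match(set_ids[1], gene_id)] <- 0.05
    if (!noise) {
      out_set <- !in_set
      ip$padj[out_set & !is.na(ip$padj) & ip$padj <= 0.05] <- 0.2
    }

    tab <- function(x) de_table(data.frame(
      gene_id = gene_id, biotype = biotype, mean_tpm = mean_tpm,
      log2fc = x$lfc, padj = x$padj, stringsAsFactors = FALSE))
    list(ip_vs_input = tab(ip), table_a = tab(a), table_b = tab(b),
         truth = list(up = sort(up_ids), down = sort(down_ids),
                      enriched = sort(set_ids)))
  })
}

#' Full overlap filter chain
#'
#' Prefilters the three tables, applies the enrichment gate to IP vs input,
#' intersects the concordant common DEGs of the two comparisons with the
#' enriched set, and returns the counts report.
#'
#' @param ip_vs_input,table_a,table_b [de_table()]s.
#' @return List with `enriched`, `common` (up/down), `restricted`, and
#'   `counts`.
#' @export
overlap_pipeline <- function(ip_vs_input, table_a, table_b) {
  enriched <- tanycyte_enriched(prefilter(ip_vs_input))
  common <- common_degs(prefilter(table_a), prefilter(table_b))
  res <- restrict_to(common, enriched)
  list(enriched = enriched, common = common, restricted = res,
       counts = res$counts)
}

#' Read / write DE tables
#'
#' Tab- or comma-separated by file extension, with the [de_table()] header.
#' @param path File path (`.tsv`/`.txt` tab, `.csv` comma).
#' @export
read_de_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  de_table(utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE))
}

#' @rdname read_de_table
#' @param table A [de_table()].
#' @export
write_de_table <- function(table, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
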