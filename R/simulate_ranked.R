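#' Simulate a ranked gene list with a planted enriched set
#'
#' Draws per-gene differential statistics from Normal(0, 1), except for the
#' members of a planted gene set, which are drawn from Normal(`shift`, 1).
#' The list is returned sorted by statistic, descending, with ties broken by
#' gene id, mimicking a Wald-statistic ranking from a differential-expression
#' fit. With `shift = 0` the set is null by construction.
#'
#' @param n_genes total number of genes.
#' @param set_size number of genes in the planted set (`< n_genes`).
#' @param shift mean shift of the set members' statistics (effect size).
#' @param seed integer seed; output is deterministic per seed.
#' @param set_name name given to the planted gene set.
#' @return A list with elements `ranked` (a [ranked_gene_list()]) and
#'   `gene_set` (a [gene_set()] of the planted members).
#' @examples
#' sim <- simulate_ranked_list(100, 5, shift = 10, seed = 1)
#' head(sim$ranked$gene, 5)  # the planted members dominate the top ranks
#' @export
simulate_ranked_list <- function(n_genes, set_size, shift = 0, seed = 1L,
                                 set_name = "planted_set") {
  if (!is_count(n_genes, min = 2L)) stopf("`n_genes` must be an integer >= 2")
  if (!is_count(set_size) || set_size >= n_genes) {
    stopf("`set_size` must satisfy 1 <= set_size < n_genes")
  }
  if (!is_number(shift)) stopf("`shift` must be a finite number")
  width <- max(4L, nchar(as.character(n_genes)))
  ids <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))
  with_seed(seed, {
    members <- sort(sample(ids, set_size))
    stat <- stats::rnorm(n_genes)
    stat[ids %in% members] <- stats::rnorm(set_size, mean = shift)
    list(ranked = ranked_gene_list(ids, stat),
         gene_set = gene_set(set_name, members))
  })
}
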