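#' Ranked gene lists and gene sets
#'
#' A `ranked_gene_list` stores unique gene ids with their ranking statistics
#' (e.g. Wald statistics from a differential-expression fit), sorted by
#' statistic descending; ties are broken by gene id so the ranking — and
#' every enrichment score computed from it — is deterministic. A `gene_set`
#' is a named, non-empty collection of unique gene ids.
#'
#' @param gene character vector of gene ids (unique).
#' @param stat numeric vector of ranking statistics, same length.
#' @return `ranked_gene_list()` returns a data frame of class
#'   `ranked_gene_list` with columns `gene` and `stat`, sorted.
#' @export
ranked_gene_list <- function(gene, stat) {
  gene <- as.character(gene)
  stat <- as.numeric(stat)
  if (length(gene) != length(stat)) stopf("`gene` and `stat` lengths differ")
  if (length(gene) < 2L) stopf("a ranked list needs at least 2 genes")
  if (anyDuplicated(gene)) {
    stopf("duplicate gene ids: %s",
          paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  if (!all(is.finite(stat))) stopf("all statistics must be finite")
  o <- order(-stat, gene)
  structure(data.frame(gene = gene[o], stat = stat[o],
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' @param name gene-set name.
#' @param members character vector of member gene ids (unique, non-empty).
#' @rdname ranked_gene_list
#' @export
gene_set <- function(name, members) {
  members <- as.character(members)
  if (!length(members)) stopf("gene set '%s' is empty", name)
  if (anyDuplicated(members)) members <- unique(members)
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s (%d genes)\n", x$name, length(x$members)))
  invisible(x)
}

#' Read and write RNK and GMT files
#'
#' RNK files are two-column, tab-delimited `gene<TAB>statistic` lists;
#' GMT files hold one gene set per line:
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return `read_rnk()` returns a [ranked_gene_list()]; `read_gmt()` a named
#'   list of [gene_set()] objects.
#' @export
read_rnk <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene", "stat"),
                          colClasses = c("character", "numeric"),
                          quote = "", comment.char = "#")
  ranked_gene_list(df$gene, df$stat)
}

#' @param ranked a [ranked_gene_list()].
#' @rdname read_rnk
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_gene_list"))
  utils::write.table(ranked[c("gene", "stat")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_rnk
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stopf("GMT line with fewer than 3 fields: '%s'", l)
    gene_set(f[1L], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' @param sets a list of [gene_set()] objects.
#' @param descriptions optional character vector of set descriptions.
#' @rdname read_rnk
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(s, d) {
    paste(c(s$name, d, s$members), collapse = "\t")
  }, sets, descriptions)
  writeLines(lines, path)
  invisible(path)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing a running sum at
#' each gene-set member ("hit") by `|stat|^weight / sum_set |stat|^weight`
#' and decrementing at each non-member ("miss") by `1 / (N - N_hit)`. The
#' enrichment score is the running sum's signed maximum deviation from zero;
#' set members clustered at the top of the list give a score near +1, at the
#' bottom near -1. `weight = 1` (default) is the conventional weighted
#' statistic; `weight = 0` gives the classic unweighted Kolmogorov-Smirnov-like
#' form. Set members absent from the ranked list are dropped (with a message);
#' the running sum always ends at zero.
#'
#' @param ranked a [ranked_gene_list()].
#' @param gs a [gene_set()] with at least one member in `ranked` and not
#'   covering the whole list.
#' @param weight exponent applied to `|stat|` at hit positions; default 1.
#' @return A list with `es` (the enrichment score), `running` (the running
#'   sum, one value per rank), and `leading_edge` (the member ids at or
#'   before the extremum for positive scores, at or after it for negative
#'   ones). The extremum position itself is attached as `which_extreme`.
#' @examples
#' rl <- ranked_gene_list(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))
#' enrichment_score(rl, gene_set("demo", c("g1", "g3")))$es  # 0.75
#' @export
enrichment_score <- function(ranked, gs, weight = 1) {
  stopifnot(inherits(ranked, "ranked_gene_list"), inherits(gs, "gene_set"))
  if (!is_number(weight) || weight < 0) stopf("`weight` must be >= 0")
  hit <- ranked$gene %in% gs$members
  n_absent <- length(setdiff(gs$members, ranked$gene))
  if (n_absent > 0) {
    message(sprintf("%d member(s) of '%s' absent from the ranked list dropped",
                    n_absent, gs$name))
  }
  es_from_hits(ranked$stat, hit, weight, set_name = gs$name,
               genes = ranked$gene)
}

# Core running-sum computation on a precomputed hit mask; shared by the
# observed score and the permutation null (where only the mask changes).
es_from_hits <- function(stat, hit, weight, set_name = "gene set",
                         genes = NULL) {
  n <- length(stat)
  n_hit <- sum(hit)
  if (n_hit == 0L) stopf("no member of '%s' occurs in the ranked list", set_name)
  if (n_hit == n) {
    stopf("'%s' covers the entire ranked list; the miss decrement is undefined",
          set_name)
  }
  w <- if (weight == 0) rep(1, n) else abs(stat)^weight
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  es <- running[i_max]
  leading <- if (is.null(genes)) {
    NULL
  } else if (es >= 0) {
    genes[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    genes[i_max:n][hit[i_max:n]]
  }
  list(es = es, running = running, leading_edge = leading,
       which_extreme = i_max)
}

#' Permutation significance of an enrichment score
#'
#' Builds a null distribution of enrichment scores from random gene sets of
#' the same (overlap) size drawn without replacement from the ranked list,
#' and reports
#' `p = (1 + #\{null ES at least as extreme, same sign\}) / (n same-sign nulls + 1)`
#' together with `nes = es / mean(|null ES| of the same sign)`. Conditioning
#' on the sign follows the usual pre-ranked GSEA convention: positive and
#' negative scores are judged against their own half of the null. When
#' `exact = TRUE` (or `exact = NULL` and `choose(N, n_hit) <= 20000`) every
#' possible placement of the set is enumerated instead, and `p` is the exact
#' fraction of same-sign placements whose score is at least as extreme.
#'
#' @inheritParams enrichment_score
#' @param n_perm number of random sets (>= 100); ignored in exact mode.
#' @param seed integer seed; the null draw is deterministic per seed.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` (default) enumerates when feasible (`choose(N, n_hit) <= 20000`).
#' @return An object of class `enrichment_result`: a list with `set`, `size`
#'   (overlap with the ranked list), `es`, `nes`, `p_perm`, `q_bh`
#'   (`NA` here; filled by [gsea_preranked()] across a set family),
#'   `leading_edge`, `n_perm` (number of null scores used), `n_same_sign`
#'   (null scores sharing the observed sign), `exact`, `seed`.
#' @examples
#' rl <- ranked_gene_list(paste0("g", 1:6), c(3, 2, 1, -1, -2, -3))
#' permutation_significance(rl, gene_set("demo", c("g1", "g3")), seed = 1)
#' @export
permutation_significance <- function(ranked, gs, n_perm = 1000L, seed = 1L,
                                     weight = 1, exact = NULL) {
  stopifnot(inherits(ranked, "ranked_gene_list"), inherits(gs, "gene_set"))
  obs <- enrichment_score(ranked, gs, weight)
  n <- nrow(ranked)
  n_hit <- sum(ranked$gene %in% gs$members)
  do_exact <- if (is.null(exact)) choose(n, n_hit) <= 20000 else isTRUE(exact)
  if (do_exact && choose(n, n_hit) > 20000) {
    stopf("exact enumeration infeasible: choose(%d, %d) placements", n, n_hit)
  }
  if (do_exact) {
    placements <- utils::combn(n, n_hit)
    null_es <- apply(placements, 2L, function(pos) {
      hit <- logical(n)
      hit[pos] <- TRUE
      es_from_hits(ranked$stat, hit, weight)$es
    })
    same_sign <- if (obs$es >= 0) null_es >= 0 else null_es < 0
    if (!any(same_sign)) {
      stopf("no enumerated placement shares the observed sign")
    }
    extreme <- same_sign & abs(null_es) >= abs(obs$es)
    # conditional on sign, as in the Monte-Carlo branch, so the two modes
    # estimate the same quantity
    p <- sum(extreme) / sum(same_sign)
    n_used <- length(null_es)
    n_same <- sum(same_sign)
  } else {
    if (!is_count(n_perm, min = 100L)) stopf("`n_perm` must be an integer >= 100")
    null_es <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        hit <- logical(n)
        hit[sample.int(n, n_hit)] <- TRUE
        es_from_hits(ranked$stat, hit, weight)$es
      }, 0)
    })
    same_sign <- if (obs$es >= 0) null_es >= 0 else null_es < 0
    if (!any(same_sign)) {
      stopf("no null enrichment score shares the observed sign; increase n_perm")
    }
    extreme <- same_sign & abs(null_es) >= abs(obs$es)
    p <- (1 + sum(extreme)) / (sum(same_sign) + 1)
    n_used <- as.integer(n_perm)
    n_same <- sum(same_sign)
  }
  mean_abs_same <- mean(abs(null_es[same_sign]))
  nes <- if (mean_abs_same > 0) obs$es / mean_abs_same else NA_real_
  structure(
    list(set = gs$name, size = n_hit, es = obs$es, nes = nes, p_perm = p,
         q_bh = NA_real_, leading_edge = obs$leading_edge,
         n_perm = n_used, n_same_sign = n_same, exact = do_exact,
         seed = as.integer(seed)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s (n = %d): ES = %.4f, NES = %.3f, p = %.4g%s\n",
              x$set, x$size, x$es, x$nes, x$p_perm,
              if (x$exact) " (exact)" else sprintf(" (%d permutations)", x$n_perm)))
  cat(sprintf("  leading edge (%d): %s\n", length(x$leading_edge),
              paste(x$leading_edge, collapse = ", ")))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values, with
#' monotonicity enforced; input order is preserved.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || !length(pvals)) stopf("`pvals` must be numeric")
  if (anyNA(pvals) || any(pvals <= 0 | pvals > 1)) {
    stopf("all p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Pre-ranked gene-set enrichment over a family of sets
#'
#' Scores every gene set against the ranked list with
#' [permutation_significance()] and adjusts the permutation p-values across
#' the family with [bh_adjust()].
#'
#' @inheritParams permutation_significance
#' @param sets a list of [gene_set()] objects (e.g. from [read_gmt()]), or a
#'   single `gene_set`.
#' @return A data frame of class `gsea_prerank` with one row per set:
#'   `set, size, es, nes, p, q, leading_edge` (comma-separated). The full
#'   per-set `enrichment_result` objects are attached as attribute
#'   `"results"`.
#' @examples
#' sim <- simulate_ranked_list(200, 10, shift = 2, seed = 4)
#' gsea_preranked(sim$ranked, sim$gene_set, n_perm = 500, seed = 4)
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           weight = 1, exact = FALSE) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, TRUE, "gene_set")))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(sets)))
  results <- mapply(function(gs, s) {
    permutation_significance(ranked, gs, n_perm = n_perm, seed = s,
                             weight = weight, exact = exact)
  }, sets, seeds, SIMPLIFY = FALSE)
  p <- vapply(results, `[[`, 0, "p_perm")
  q <- bh_adjust(p)
  for (i in seq_along(results)) results[[i]]$q_bh <- q[i]
  out <- data.frame(
    set = vapply(results, `[[`, "", "set"),
    size = vapply(results, `[[`, 0L, "size"),
    es = vapply(results, `[[`, 0, "es"),
    nes = vapply(results, `[[`, 0, "nes"),
    p = p, q = q,
    leading_edge = vapply(results, function(r)
      paste(r$leading_edge, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "results") <- results
  class(out) <- c("gsea_prerank", "data.frame")
  out
}

#' @export
print.gsea_prerank <- function(x, ...) {
  cat(sprintf("Pre-ranked enrichment: %d set(s)\n", nrow(x)))
  df <- as.data.frame(x)[c("set", "size", "es", "nes", "p", "q")]
  df$es <- round(df$es, 4); df$nes <- round(df$nes, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an enrichment results table
#'
#' @param res a `gsea_prerank` result.
#' @param path output path for a tab-delimited table
#'   `set, size, es, nes, p, q, leading_edge`.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(res, path) {
  stopifnot(inherits(res, "gsea_prerank"))
  utils::write.table(as.data.frame(res), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
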