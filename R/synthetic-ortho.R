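#' Build fly-human ortholog and disease-catalog fixtures with known overlap
#'
#' Constructs an ortholog pair table (fly gene, human gene, integer
#' confidence score) and a human disease-gene catalog such that a designated
#' query gene set has exactly `planted_overlap` pairs whose human member is
#' in the catalog at score >= 3. Pairs may be many-to-many. All remaining
#' pairs are built so that they cannot contribute to the query count (fly
#' gene outside the query, score below 3, or human gene outside the
#' catalog).
#'
#' @param n_fly_genes Size of the fly gene universe.
#' @param n_pairs Total number of ortholog pairs.
#' @param n_ad_genes Number of human genes in the disease catalog.
#' @param planted_overlap Exact number of qualifying query pairs to plant
#'   (<= `n_pairs`; requires `n_ad_genes >= 1` when positive).
#' @param query_size Size of the designated query set (default covers the
#'   planted pairs, minimum 3).
#' @param seed Integer seed.
#' @return A list with `pairs` (`data.frame`: `fly_gene`, `human_gene`,
#'   `score`), `catalog` (character vector), `query` (character vector) and
#'   `universe` (all fly gene ids).
#' @export
#' @examples
#' fx <- make_ortholog_fixture(10, 12, 4, planted_overlap = 2)
#' count_ad_orthologs(fx$query, fx$pairs, fx$catalog, mode = "pairs")
make_ortholog_fixture <- function(n_fly_genes, n_pairs, n_ad_genes,
                                  planted_overlap, query_size = NULL,
                                  seed = 1L) {
  stopifnot(is_count(n_fly_genes), is_count(n_pairs), is_count(n_ad_genes, 0L),
            is_count(planted_overlap, 0L))
  if (planted_overlap > n_pairs) {
    stop("planted_overlap cannot exceed n_pairs", call. = FALSE)
  }
  if (planted_overlap > 0 && n_ad_genes < 1) {
    stop("a positive planted_overlap requires a non-empty catalog", call. = FALSE)
  }
  universe <- sprintf("Fgene%03d", seq_len(n_fly_genes))
  n_human <- max(n_ad_genes + 5L, 10L)
  humans <- sprintf("HGENE%03d", seq_len(n_human))
  catalog <- humans[seq_len(n_ad_genes)]
  off_catalog <- setdiff(humans, catalog)
  if (is.null(query_size)) {
    query_size <- max(3L, min(planted_overlap, n_fly_genes))
  }
  stopifnot(query_size >= 1, query_size <= n_fly_genes)
  query <- universe[seq_len(query_size)]
  non_query <- setdiff(universe, query)

  pairs <- with_seed(seed, {
    fly <- character(n_pairs); hum <- character(n_pairs); sc <- integer(n_pairs)
    k <- planted_overlap
    if (k > 0) {
      fly[seq_len(k)] <- sample(query, k, replace = TRUE)
      hum[seq_len(k)] <- sample(catalog, k, replace = TRUE)
      sc[seq_len(k)] <- sample(3:15, k, replace = TRUE)
    }
    rest <- setdiff(seq_len(n_pairs), seq_len(k))
    for (i in rest) {
      if (length(non_query) > 0 && stats::runif(1) < 0.7) {
        # fly gene outside the query: any human gene, any score
        fly[i] <- sample(non_query, 1)
        hum[i] <- sample(humans, 1)
        sc[i] <- sample(1:15, 1)
      } else if (length(off_catalog) > 0) {
        # query fly gene but human gene not in the catalog
        fly[i] <- sample(query, 1)
        hum[i] <- sample(off_catalog, 1)
        sc[i] <- sample(1:15, 1)
      } else {
        # last resort: query pair with sub-threshold score
        fly[i] <- sample(query, 1)
        hum[i] <- sample(humans, 1)
        sc[i] <- sample(1:2, 1)
      }
    }
    data.frame(fly_gene = fly, human_gene = hum, score = sc,
               stringsAsFactors = FALSE)
  })
  list(pairs = pairs, catalog = catalog, query = query, universe = universe)
}

#' Build a synthetic gene annotation tiling a set of chromosomes
#'
#' Lays `n_genes` non-overlapping genes (1-based inclusive intervals) across
#' the chromosome arms, alternating strand, so that simulated variants can
#' be mapped to genes and enrichment universes defined.
#'
#' @param n_genes Number of genes.
#' @param chroms Chromosome names to tile.
#' @param gene_length,gap Interval length and inter-gene gap in bp.
#' @return `data.frame` with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
make_annotation_fixture <- function(n_genes, chroms = c("2L", "2R", "3L", "3R", "X"),
                                    gene_length = 4000L, gap = 1000L) {
  stopifnot(is_count(n_genes))
  chrom <- sort(rep(chroms, length.out = n_genes))
  idx <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  start <- (idx - 1L) * (gene_length + gap) + 1L
  data.frame(gene_id = sprintf("FBgn%07d", seq_len(n_genes)),
             symbol = sprintf("gene%03d", seq_len(n_genes)),
             chrom = chrom, start = as.integer(start),
             end = as.integer(start + gene_length - 1L),
             strand = rep(c("+", "-"), length.out = n_genes),
             stringsAsFactors = FALSE)
}
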