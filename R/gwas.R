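# -- variant filtering -------------------------------------------------------

#' Filter variants on missingness and minor-allele frequency
#'
#' Discards variants with missing-call rate > `max_missing` or minor-allele
#' frequency < `min_maf` (MAF over non-missing calls only). The retained /
#' discarded counts are reported as a message.
#'
#' @param g A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing fraction (default 0.2).
#' @param min_maf Minimum minor-allele frequency (default 0.05).
#' @return A filtered [genotype_matrix()] (possibly with zero variants, with
#'   a warning).
#' @export
filter_variants <- function(g, max_missing = 0.2, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  miss <- variant_missing_rate(g)
  maf <- variant_maf(g)
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf
  message(sprintf("filter_variants: %d of %d variants retained (missing <= %.2g, MAF >= %.2g)",
                  sum(keep), length(keep), max_missing, min_maf))
  if (!any(keep)) warning("no variants passed the filters")
  subset_variants(g, keep)
}

# -- population-structure covariates ----------------------------------------

#' Principal-component decomposition of a genotype matrix
#'
#' Variants are mean-imputed (missing calls replaced by the variant mean),
#' standardised to zero mean and unit variance, and decomposed by SVD.
#' Eigenvalues are those of the line-by-line covariance of the
#' standardised matrix.
#'
#' @param g A filtered [genotype_matrix()].
#' @return An object of class `genotype_pca`: `scores` (lines x PCs,
#'   orthogonal columns), `eigenvalues` (non-increasing), `n_lines`,
#'   `n_variants_used`.
#' @export
pca_covariates <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- g$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  na <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na) > 0) x[na] <- mu[na[, 2]]
  sdv <- apply(x, 2, stats::sd)
  use <- sdv > 0
  if (!any(use)) stop("zero-variance genotype matrix: PCA undefined", call. = FALSE)
  xs <- scale(x[, use, drop = FALSE], center = mu[use], scale = sdv[use])
  sv <- svd(xs)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- g$lines
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(scores = scores,
                 eigenvalues = sv$d^2 / (nrow(xs) - 1),
                 n_lines = nrow(xs), n_variants_used = sum(use)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d lines, %d variants; leading eigenvalues: %s\n",
              x$n_lines, x$n_variants_used,
              paste(signif(utils::head(x$eigenvalues, 4), 3), collapse = ", ")))
  invisible(x)
}

# Tracy-Widom (TW1) critical values at the supported significance levels
# (Patterson-style eigenanalysis tables).
tw_critical_value <- function(alpha) {
  if (alpha >= 1) return(-Inf)
  tab <- c(`0.05` = 0.9793, `0.01` = 2.0234, `0.001` = 3.2724)
  key <- names(tab)[vapply(as.numeric(names(tab)), function(a) {
    isTRUE(all.equal(a, alpha))
  }, logical(1))]
  if (length(key) == 0) {
    stop("alpha must be one of 0.05, 0.01, 0.001 (or >= 1 to retain all PCs)",
         call. = FALSE)
  }
  tab[[key]]
}

#' Select principal components by the Tracy-Widom eigenvalue test
#'
#' Patterson-style test of leading eigenvalues: for each candidate PC the
#' remaining spectrum is used to estimate the effective number of markers,
#' the leading eigenvalue is normalised to a Tracy-Widom statistic, and the
#' PC is retained if the statistic exceeds the critical value at `alpha`.
#' Testing stops at the first non-significant eigenvalue.
#'
#' @param eigenvalues Non-increasing eigenvalue spectrum (from
#'   [pca_covariates()]).
#' @param alpha Significance level; supported values 0.05 (critical value
#'   0.9793), 0.01 and 0.001; any `alpha >= 1` retains all tested PCs.
#' @param max_pcs Number of leading eigenvalues to test (must leave at
#'   least 2 eigenvalues in each remaining spectrum).
#' @return Integer: number of retained PCs, with the per-PC statistics as
#'   `attr(, "tw_stats")`.
#' @export
tracy_widom_select <- function(eigenvalues, alpha = 0.05, max_pcs = 10L) {
  ev <- as.numeric(eigenvalues)
  stopifnot(length(ev) >= 2, all(diff(ev) <= 1e-8))
  ev <- pmax(ev, 0)
  if (max_pcs > length(ev) - 2L) {
    stop("fewer eigenvalues than requested tests (need max_pcs <= length - 2)",
         call. = FALSE)
  }
  crit <- tw_critical_value(alpha)
  stats_out <- numeric(0)
  n_keep <- 0L
  for (i in seq_len(max_pcs)) {
    evi <- ev[i:length(ev)]
    evi <- evi[evi > 1e-12]
    m <- length(evi)
    if (m < 3) break
    s1 <- sum(evi); s2 <- sum(evi^2)
    # effective number of markers from the spectrum (Patterson-style)
    s2n <- m^2 * s2 / s1^2
    n_eff <- m * (m + 2) / (s2n - m)
    if (!is.finite(n_eff) || n_eff <= 1) break
    l <- m * evi[1] / s1
    mu <- (sqrt(n_eff - 1) + sqrt(m))^2 / n_eff
    sig <- (sqrt(n_eff - 1) + sqrt(m)) / n_eff *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(m))^(1 / 3)
    tw <- (l - mu) / sig
    stats_out <- c(stats_out, tw)
    if (tw > crit) n_keep <- n_keep + 1L else break
  }
  structure(n_keep, tw_stats = stats_out)
}

#' Assemble the covariate set for association
#'
#' @param pca A `genotype_pca`.
#' @param n_pcs Number of leading PCs to include (e.g. the
#'   [tracy_widom_select()] result).
#' @param wolbachia Optional named 0/1 vector of infection status per line.
#' @return An object of class `covariate_set`: numeric matrix (lines x
#'   covariates) with `n_pcs_retained` as an attribute.
#' @export
make_covariates <- function(pca, n_pcs, wolbachia = NULL) {
  stopifnot(inherits(pca, "genotype_pca"), n_pcs >= 0,
            n_pcs <= ncol(pca$scores))
  cov <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  if (!is.null(wolbachia)) {
    stopifnot(!is.null(names(wolbachia)))
    w <- wolbachia[rownames(pca$scores)]
    stopifnot(!anyNA(w), all(w %in% 0:1))
    cov <- cbind(cov, wolbachia = as.numeric(w))
  }
  structure(cov, n_pcs_retained = as.integer(n_pcs), class = c("covariate_set", class(cov)))
}

# -- per-variant association -------------------------------------------------

# Single-variant OLS with covariates via QR; returns beta, se, p, n.
ols_single <- function(y, gcall, covs) {
  ok <- !is.na(gcall)
  y <- y[ok]; gv <- gcall[ok]
  X <- cbind(1, gv, if (!is.null(covs)) covs[ok, , drop = FALSE])
  n <- length(y); p <- ncol(X)
  if (n <= p || stats::var(gv) == 0) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = n, tested = 0))
  }
  qq <- qr(X)
  if (qq$rank < p) {
    return(c(beta = NA_real_, se = NA_real_, p = NA_real_, n = n, tested = 0))
  }
  beta <- qr.coef(qq, y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (n - p)
  xtx_inv <- chol2inv(qr.R(qq))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- beta[2] / se
  c(beta = beta[2], se = se, p = 2 * stats::pt(-abs(tval), df = n - p),
    n = n, tested = 1)
}

#' Per-variant linear additive association scan
#'
#' Ordinary least squares of the per-line trait BLUPs on the minor-allele
#' class (0/1 inbred coding) with optional covariates, one regression per
#' variant, with a two-sided t test on the allele coefficient. Lines with a
#' missing call are dropped from that variant's regression only (case-wise
#' deletion); variants with too few usable lines or no allelic variation
#' are flagged untested (`tested = FALSE`, P and beta `NA`). Complete
#' variants share the covariate projection (Frisch-Waugh residualisation),
#' which is algebraically identical to the full per-variant OLS.
#'
#' @param trait_blups Named numeric vector of per-line values (names = line
#'   ids, matching `g$lines`).
#' @param g A filtered [genotype_matrix()].
#' @param covariates Optional [make_covariates()] matrix (or any numeric
#'   matrix with rows in line order).
#' @return `data.frame` of class `association_scan`: `variant`, `chrom`,
#'   `pos`, `beta`, `se`, `p_raw`, `n_used`, `tested`.
#' @export
associate <- function(trait_blups, g, covariates = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(names(trait_blups)))
  y <- trait_blups[g$lines]
  if (anyNA(y)) stop("trait_blups must cover every line in the genotype matrix", call. = FALSE)
  covs <- if (!is.null(covariates)) {
    m <- unclass(covariates)
    attr(m, "n_pcs_retained") <- NULL
    stopifnot(nrow(m) == length(y))
    m
  } else NULL
  calls <- g$calls
  m <- ncol(calls)
  out <- matrix(NA_real_, m, 5,
                dimnames = list(NULL, c("beta", "se", "p", "n", "tested")))

  complete <- which(colSums(is.na(calls)) == 0)
  incomplete <- setdiff(seq_len(m), complete)

  if (length(complete) > 0) {
    n <- length(y)
    Z <- cbind(matrix(1, n, 1), covs)
    p_full <- ncol(Z) + 1L
    qz <- qr(Z)
    yr <- stats::resid(stats::lm.fit(Z, y))
    G <- calls[, complete, drop = FALSE]
    storage.mode(G) <- "double"
    Gr <- G - Z %*% qr.coef(qz, G)
    gg <- colSums(Gr^2)
    gy <- as.numeric(crossprod(Gr, yr))
    df <- n - p_full
    beta <- ifelse(gg > 1e-12, gy / gg, NA_real_)
    rss <- sum(yr^2) - beta^2 * gg
    se <- sqrt(pmax(rss, 0) / df / gg)
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df = df)
    tested <- as.numeric(gg > 1e-12 & n > p_full)
    out[complete, ] <- cbind(beta, se, ifelse(tested == 1, pval, NA_real_),
                             n, tested)
    out[complete, "beta"][tested == 0] <- NA_real_
    out[complete, "se"][tested == 0] <- NA_real_
  }
  for (j in incomplete) {
    out[j, ] <- ols_single(y, calls[, j], covs)
  }
  res <- data.frame(variant = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos, beta = out[, "beta"],
                    se = out[, "se"], p_raw = out[, "p"],
                    n_used = as.integer(out[, "n"]),
                    tested = out[, "tested"] == 1,
                    stringsAsFactors = FALSE)
  class(res) <- c("association_scan", "data.frame")
  res
}

# -- multiple testing and hit classification ---------------------------------

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted P values (monotone, capped at 1), via
#' `stats::p.adjust`.
#'
#' @param p Numeric vector of raw P values in `(0, 1]` (NA allowed for
#'   untested records).
#' @return Adjusted P values, same length.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Association scans across traits with per-trait BH adjustment
#'
#' Runs [associate()] for each trait and BH-adjusts within trait (the
#' default, matching per-trait reporting), or across the pooled scan when
#' `adjust_within_trait = FALSE`.
#'
#' @param blups_by_trait Named list of per-line BLUP vectors, one per trait.
#' @param g A filtered [genotype_matrix()].
#' @param covariates Optional covariate matrix.
#' @param adjust_within_trait Logical (default `TRUE`).
#' @return `data.frame` with a `trait` column, the [associate()] columns and
#'   `p_adjust`.
#' @export
associate_traits <- function(blups_by_trait, g, covariates = NULL,
                             adjust_within_trait = TRUE) {
  stopifnot(is.list(blups_by_trait), !is.null(names(blups_by_trait)))
  res <- lapply(names(blups_by_trait), function(tr) {
    scan <- associate(blups_by_trait[[tr]], g, covariates)
    scan$trait <- tr
    if (adjust_within_trait) scan$p_adjust <- bh_adjust(scan$p_raw)
    scan
  })
  out <- do.call(rbind, res)
  if (!adjust_within_trait) out$p_adjust <- bh_adjust(out$p_raw)
  out[, c("trait", setdiff(names(out), "trait"))]
}

#' Classify significant and suggestive associations
#'
#' Significant: BH-adjusted P < `alpha` (default 0.05). Suggestive: raw
#' P < `suggestive` (default 1e-5). The two sets are defined independently
#' on their own thresholds. Per-variant counts of the traits in which a
#' variant is suggestive are tallied across the scan.
#'
#' @param records Association records with columns `variant`, `p_raw`,
#'   `p_adjust` and optionally `trait`.
#' @param alpha Adjusted-P threshold for significance.
#' @param suggestive Raw-P threshold for suggestive associations.
#' @return An object of class `hit_set`: `significant` and `suggestive`
#'   record subsets, `trait_counts` (`data.frame`: `variant`,
#'   `n_traits_suggestive`), and unique-variant tallies
#'   `n_unique_significant`, `n_unique_suggestive`.
#' @export
classify_hits <- function(records, alpha = 0.05, suggestive = 1e-5) {
  stopifnot(is.data.frame(records),
            all(c("variant", "p_raw", "p_adjust") %in% names(records)))
  sig <- records[!is.na(records$p_adjust) & records$p_adjust < alpha, , drop = FALSE]
  sug <- records[!is.na(records$p_raw) & records$p_raw < suggestive, , drop = FALSE]
  counts <- if ("trait" %in% names(sug) && nrow(sug) > 0) {
    tc <- stats::aggregate(trait ~ variant, data = sug,
                           FUN = function(x) length(unique(x)))
    names(tc)[2] <- "n_traits_suggestive"
    tc
  } else {
    data.frame(variant = unique(sug$variant),
               n_traits_suggestive = rep(1L, length(unique(sug$variant))))
  }
  structure(list(significant = sig, suggestive = sug, trait_counts = counts,
                 n_unique_significant = length(unique(sig$variant)),
                 n_unique_suggestive = length(unique(sug$variant)),
                 alpha = alpha, suggestive_threshold = suggestive),
            class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("hit_set: %d significant (unique %d, P.adjust < %g), %d suggestive (unique %d, P < %g)\n",
              nrow(x$significant), x$n_unique_significant, x$alpha,
              nrow(x$suggestive), x$n_unique_suggestive, x$suggestive_threshold))
  invisible(x)
}

# -- SNP-to-gene mapping -----------------------------------------------------

#' Map variants to overlapping annotated genes
#'
#' Each variant is assigned every gene whose (1-based, inclusive) interval,
#' extended by `window` bp on both sides, contains the variant position.
#' The primary gene is chosen deterministically: smallest start coordinate,
#' then lexicographic `gene_id`. Variants overlapping no gene are flagged
#' intergenic.
#'
#' @param variants `data.frame` with columns `variant` (or `id`), `chrom`,
#'   `pos`; e.g. the `significant` or `suggestive` component of a
#'   [classify_hits()] result.
#' @param annotation `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (and optionally `symbol`, `strand`).
#' @param window Basepair extension on each side (default 0).
#' @return `data.frame`: `variant`, `chrom`, `pos`, `genes`
#'   (comma-separated), `primary_gene`, `intergenic`.
#' @export
map_snps_to_genes <- function(variants, annotation, window = 0) {
  if (!"variant" %in% names(variants) && "id" %in% names(variants)) {
    variants$variant <- variants$id
  }
  stopifnot(all(c("variant", "chrom", "pos") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(annotation)))
  if (any(annotation$start > annotation$end)) {
    stop("malformed annotation intervals (start > end)", call. = FALSE)
  }
  variants <- variants[!duplicated(variants$variant), , drop = FALSE]
  nv <- nrow(variants)
  out <- data.frame(variant = variants$variant, chrom = variants$chrom,
                    pos = variants$pos, genes = rep("", nv),
                    primary_gene = rep(NA_character_, nv),
                    intergenic = rep(TRUE, nv), stringsAsFactors = FALSE)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    ai <- which(annotation$chrom == ch)
    if (length(ai) == 0) next
    q <- IRanges::IRanges(start = variants$pos[vi], width = 1L)
    s <- IRanges::IRanges(start = pmax(annotation$start[ai] - window, 1L),
                          end = annotation$end[ai] + window)
    ov <- IRanges::findOverlaps(q, s)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in unique(qh)) {
      genes_k <- ai[sh[qh == k]]
      ord <- order(annotation$start[genes_k], annotation$gene_id[genes_k])
      ids <- annotation$gene_id[genes_k][ord]
      out$genes[vi[k]] <- paste(ids, collapse = ",")
      out$primary_gene[vi[k]] <- ids[1]
      out$intergenic[vi[k]] <- FALSE
    }
  }
  out
}
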