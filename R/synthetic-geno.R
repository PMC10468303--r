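#' Specify a synthetic inbred-line genotype panel
#'
#' Emulates a reference panel of fully sequenced, homozygous inbred lines:
#' biallelic variants with minor-allele frequencies drawn from `maf_range`,
#' optional missing calls, optional population structure produced by a
#' Balding-Nichols-style allele-frequency shift between subpopulations, and
#' optional planted causal variants with additive effects on a trait.
#'
#' @param n_lines,n_variants Panel dimensions.
#' @param maf_range Interval in `(0, 0.5]` for ancestral minor-allele
#'   frequencies.
#' @param missing_rate Per-call missingness probability.
#' @param n_subpops Number of subpopulations (1 = unstructured).
#' @param fst_like_divergence Divergence proportion `F` of the
#'   Balding-Nichols frequency shift; `0` disables structure.
#' @param causal_indices Variant indices carrying a phenotype effect.
#' @param causal_effects Additive effect per minor-allele class for each
#'   causal variant (same length as `causal_indices`).
#' @param seed Integer seed.
#' @return An object of class `geno_sim_spec`.
#' @export
geno_sim_spec <- function(n_lines = 162L, n_variants = 5000L,
                          maf_range = c(0.05, 0.5), missing_rate = 0,
                          n_subpops = 1L, fst_like_divergence = 0,
                          causal_indices = integer(0),
                          causal_effects = numeric(0), seed = 1L) {
  stopifnot(is_count(n_lines, 2L), is_count(n_variants),
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            is_prob(missing_rate), is_count(n_subpops),
            fst_like_divergence >= 0, fst_like_divergence < 1,
            length(causal_indices) == length(causal_effects),
            all(causal_indices >= 1), all(causal_indices <= n_variants))
  structure(list(n_lines = as.integer(n_lines),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, missing_rate = missing_rate,
                 n_subpops = as.integer(n_subpops),
                 fst_like_divergence = fst_like_divergence,
                 causal_indices = as.integer(causal_indices),
                 causal_effects = causal_effects, seed = as.integer(seed)),
            class = "geno_sim_spec")
}

#' Simulate a homozygous genotype panel with known ground truth
#'
#' @param spec A [geno_sim_spec()].
#' @return A list with elements `geno` (a [genotype_matrix()]),
#'   `true_effects` (numeric vector, one per variant, zero except at the
#'   planted causal indices) and `subpop` (integer subpopulation label per
#'   line).
#' @export
#' @examples
#' sim <- simulate_genotypes(geno_sim_spec(n_lines = 20, n_variants = 50))
#' sim$geno
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "geno_sim_spec"))
  n <- spec$n_lines; m <- spec$n_variants
  subpop <- rep(seq_len(spec$n_subpops), length.out = n)

  res <- with_seed(spec$seed, {
    p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    freq <- matrix(p, nrow = spec$n_subpops, ncol = m, byrow = TRUE)
    f <- spec$fst_like_divergence
    if (spec$n_subpops > 1 && f > 0) {
      a <- p * (1 - f) / f
      b <- (1 - p) * (1 - f) / f
      for (s in seq_len(spec$n_subpops)) {
        freq[s, ] <- stats::rbeta(m, a, b)
      }
    }
    calls <- matrix(stats::rbinom(n * m, 1L, freq[subpop, ]), nrow = n)
    if (spec$missing_rate > 0) {
      calls[stats::runif(n * m) < spec$missing_rate] <- NA_integer_
    }
    calls
  })

  chroms <- c("2L", "2R", "3L", "3R", "X")
  chrom <- sort(rep(chroms, length.out = m))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  variants <- data.frame(id = paste0(chrom, "_", pos, "_SNP"),
                         chrom = chrom, pos = as.integer(pos), type = "SNP",
                         stringsAsFactors = FALSE)
  true_effects <- numeric(m)
  true_effects[spec$causal_indices] <- spec$causal_effects
  list(geno = genotype_matrix(res, variants),
       true_effects = true_effects, subpop = subpop)
}

#' Additive genetic values of lines given per-variant effects
#'
#' Sums `calls * effect` over variants with non-zero effect; missing calls
#' contribute the variant's mean call (mean imputation), so a line's genetic
#' value is always defined.
#'
#' @param g A [genotype_matrix()].
#' @param effects Numeric vector of per-variant additive effects.
#' @return Named numeric vector of line genetic values.
#' @export
genetic_values <- function(g, effects) {
  stopifnot(inherits(g, "genotype_matrix"), length(effects) == ncol(g$calls))
  idx <- which(effects != 0)
  gv <- numeric(nrow(g$calls))
  for (j in idx) {
    cj <- g$calls[, j]
    cj[is.na(cj)] <- mean(cj, na.rm = TRUE)
    gv <- gv + cj * effects[j]
  }
  stats::setNames(gv, g$lines)
}
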