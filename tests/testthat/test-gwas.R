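make_toy_geno <- function(calls, chrom = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("2L", m)
  variants <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = seq_len(m) * 100L, type = "SNP",
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants)
}

test_that("variant filtering applies the missingness and MAF thresholds", {
  calls <- matrix(0L, 100, 3)
  calls[1:4, 1] <- 1L                      # MAF 0.04 -> discarded
  calls[1:30, 2] <- 1L; calls[1:25, 3] <- NA  # missing 0.25 -> discarded
  calls[26:55, 3] <- 1L
  g <- make_toy_geno(calls)
  expect_message(kept <- filter_variants(g), "1 of 3")
  expect_equal(kept$variants$id, "v2")

  # boundary cases: missing rate exactly 0.2 and MAF exactly 0.05 are retained
  calls2 <- matrix(0L, 100, 2)
  calls2[1:20, 1] <- NA; calls2[21:60, 1] <- 1L
  calls2[1:5, 2] <- 1L
  g2 <- make_toy_geno(calls2)
  expect_message(kept2 <- filter_variants(g2), "2 of 2")
  expect_equal(ncol(kept2$calls), 2L)
  expect_warning(expect_message(filter_variants(g2, min_maf = 0.9)), "no variants")
})

test_that("PCA gives identical scores for duplicated lines and a sorted spectrum", {
  sim <- simulate_genotypes(geno_sim_spec(n_lines = 30, n_variants = 300, seed = 6))
  g <- sim$geno
  g$calls[2, ] <- g$calls[1, ]             # duplicate line 1 into line 2
  p <- pca_covariates(g)
  expect_equal(p$scores[1, ], p$scores[2, ], tolerance = 1e-8)
  expect_true(all(diff(p$eigenvalues) <= 1e-8))
  expect_true(all(p$eigenvalues >= -1e-8))
  expect_lt(max(abs(crossprod(p$scores[, 1], p$scores[, 2]))), 1e-6)
})

test_that("Tracy-Widom selection is null-calibrated, detects structure, honours edges", {
  nret <- sapply(1:30, function(s) {
    gn <- simulate_genotypes(geno_sim_spec(n_lines = 80, n_variants = 800, seed = s))
    as.integer(tracy_widom_select(pca_covariates(gn$geno)$eigenvalues, 0.05, 5))
  })
  expect_gte(mean(nret == 0), 0.9)

  gs <- simulate_genotypes(geno_sim_spec(n_lines = 80, n_variants = 800,
                                         n_subpops = 2, fst_like_divergence = 0.2,
                                         seed = 3))
  ev <- pca_covariates(gs$geno)$eigenvalues
  expect_gte(as.integer(tracy_widom_select(ev, 0.05, 5)), 1L)
  expect_equal(as.integer(tracy_widom_select(ev, 1, 5)), 5L)
  expect_error(tracy_widom_select(ev[1:4], 0.05, 5), "fewer eigenvalues")
  expect_error(tracy_widom_select(ev, 0.07, 3), "alpha")
})

test_that("association matches the normal-equations oracle on a 10-line toy", {
  set.seed(41)
  calls <- matrix(rbinom(10 * 4, 1, 0.4), 10, 4)
  g <- make_toy_geno(calls)
  covs <- matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "PC1"))
  y <- setNames(rnorm(10), g$lines)
  scan <- associate(y, g, covs)
  for (j in 1:4) {
    X <- cbind(1, calls[, j], covs)
    oracle <- ols_oracle(unname(y), X, 2)
    expect_equal(scan$beta[j], oracle$beta[2], tolerance = 1e-10)
    expect_equal(scan$p_raw[j], oracle$p, tolerance = 1e-10)
  }
  # case-wise deletion path agrees with the oracle on the reduced rows
  calls_na <- calls; calls_na[c(2, 5), 2] <- NA
  g_na <- make_toy_geno(calls_na)
  scan_na <- associate(y, g_na, covs)
  keep <- setdiff(1:10, c(2, 5))
  oracle_na <- ols_oracle(unname(y)[keep], cbind(1, calls[keep, 2], covs[keep, ]), 2)
  expect_equal(scan_na$beta[2], oracle_na$beta[2], tolerance = 1e-10)
  expect_equal(scan_na$p_raw[2], oracle_na$p, tolerance = 1e-10)
  expect_equal(scan_na$n_used[2], 8L)
  # monomorphic variant flagged untested
  calls_mono <- calls; calls_mono[, 3] <- 0L
  expect_false(associate(y, make_toy_geno(calls_mono), covs)$tested[3])
})

test_that("BH adjustment equals the step-up formula and preserves discovery monotonicity", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  p <- runif(200)^1.5
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-15)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  # lowering one p-value never loses discoveries
  adj1 <- bh_adjust(p)
  p2 <- p; p2[7] <- p2[7] / 10
  adj2 <- bh_adjust(p2)
  expect_gte(sum(adj2 < 0.1), sum(adj1 < 0.1))
})

test_that("hit classification applies both thresholds and counts traits per variant", {
  rec <- data.frame(variant = c("a", "b", "c"),
                    p_raw = c(2e-6, 2e-5, 0.01),
                    p_adjust = c(0.049, 0.2, 0.5),
                    trait = "t1", stringsAsFactors = FALSE)
  hs <- classify_hits(rec)
  expect_equal(hs$significant$variant, "a")
  expect_equal(hs$suggestive$variant, "a")   # 2e-5 is not < 1e-5

  # one variant suggestive in exactly 12 of 14 traits
  traits <- paste0("trait", 1:14)
  rec14 <- do.call(rbind, lapply(seq_along(traits), function(i) {
    data.frame(variant = "hot", trait = traits[i],
               p_raw = if (i <= 12) 1e-7 else 1e-3,
               p_adjust = 0.5, stringsAsFactors = FALSE)
  }))
  hs14 <- classify_hits(rec14)
  expect_equal(hs14$trait_counts$n_traits_suggestive[hs14$trait_counts$variant == "hot"],
               12L)
  expect_equal(hs14$n_unique_suggestive, 1L)
})

test_that("SNP-to-gene mapping handles overlaps, windows and intergenic variants", {
  ann <- data.frame(gene_id = c("FBgn2", "FBgn1", "FBgn3"),
                    symbol = c("bi", "lncRNA", "far"),
                    chrom = c("X", "X", "X"),
                    start = c(4359000L, 4359500L, 4500000L),
                    end = c(4362000L, 4360500L, 4501000L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  v <- data.frame(variant = c("X_4359702_SNP", "X_4359100_SNP", "X_4480000_SNP"),
                  chrom = "X", pos = c(4359702L, 4359100L, 4480000L),
                  stringsAsFactors = FALSE)
  gm <- map_snps_to_genes(v, ann, window = 0)
  # inside two overlapping genes on opposite strands: both reported,
  # primary = smallest start then lexicographic id
  expect_equal(gm$genes[1], "FBgn2,FBgn1")
  expect_equal(gm$primary_gene[1], "FBgn2")
  expect_equal(gm$primary_gene[2], "FBgn2")
  expect_true(gm$intergenic[3])            # 10 kb away, window too small
  gm_w <- map_snps_to_genes(v, ann, window = 25000)
  expect_false(gm_w$intergenic[3])
  bad <- ann; bad$end[1] <- bad$start[1] - 1L
  expect_error(map_snps_to_genes(v, bad), "malformed")
})

test_that("planted causal variants are recovered and permutation destroys the signal", {
  sim <- simulate_genotypes(geno_sim_spec(n_lines = 162, n_variants = 800,
                                          causal_indices = 400L,
                                          causal_effects = 1, seed = 8))
  y <- genetic_values(sim$geno, sim$true_effects)
  set.seed(80)
  y <- y + rnorm(162, 0, 1)
  scan <- associate(y, sim$geno)
  expect_equal(which.min(scan$p_raw), 400L)

  y_perm <- setNames(sample(y), names(y))
  scan_perm <- associate(y_perm, sim$geno)
  expect_gt(scan_perm$p_raw[400], 1e-4)
})

test_that("genotype TSV and VCF round-trips preserve calls", {
  sim <- simulate_genotypes(geno_sim_spec(n_lines = 8, n_variants = 12,
                                          missing_rate = 0.1, seed = 10))
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(sim$geno, path)
  back <- read_genotype_tsv(path)
  expect_identical(unname(back$calls), unname(sim$geno$calls))
  expect_identical(back$variants$id, sim$geno$variants$id)

  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "lineA", "lineB", "lineC"), collapse = "\t"))
  rows <- c(paste(c("2L", "100", ".", "A", "T", ".", ".", ".", "GT",
                    "0/0", "1/1", "0/0"), collapse = "\t"),
            paste(c("2L", "200", "rs1", "A", "ATT", ".", ".", ".", "GT",
                    "1", "0", "./."), collapse = "\t"))
  writeLines(c(hdr, rows), vcf)
  gv <- read_genotype_vcf(vcf)
  expect_equal(dim(gv$calls), c(3L, 2L))
  expect_equal(unname(gv$calls[, 1]), c(0L, 1L, 0L))
  expect_equal(unname(gv$calls[, 2]), c(1L, 0L, NA))
  expect_equal(gv$variants$type, c("SNP", "INS"))
})
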