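# -- configuration -----------------------------------------------------------

#' Default end-to-end run configuration
#'
#' Every stage parameter with its default, serialised into each run's
#' provenance record. Seeds are explicit for every stochastic stage.
#'
#' @return Nested named list (schema version 1).
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    image = list(structuring_radius = 8, detect_method = "otsu",
                 detect_quantile = 0.95, prune_q = 0.8, conf_level = 0.95,
                 min_cluster_size = 5L, connectivity = 8,
                 exclude_boundary = FALSE),
    simulate = list(
      n_lines = 162L, reps_per_line = 5L, n_variants = 2000L,
      maf_range = c(0.05, 0.5), missing_rate = 0.02, n_subpops = 2L,
      fst_like_divergence = 0.05,
      causal_index = 1000L, causal_effect = 1,
      var_line = 0.3, var_residual = 1, seed = 1L,
      n_genes = 400L),
    gwas = list(max_missing = 0.2, min_maf = 0.05, tw_alpha = 0.05,
                max_pcs = 10L, alpha = 0.05, suggestive = 1e-5,
                adjust_within_trait = TRUE, gene_window = 1000L),
    heritability = list(n_boot = 200L, seed = 1L),
    enrich = list(mode = "pairs", n_iter = 10000L, seed = 1L, min_score = 3,
                  n_pairs = 600L, n_ad_genes = 40L)
  )
}

check_config_keys <- function(config, reference = default_config(), path = "") {
  extra <- setdiff(names(config), names(reference))
  if (length(extra) > 0) {
    stop("unknown config keys: ", paste0(path, extra, collapse = ", "), call. = FALSE)
  }
  for (k in names(config)) {
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]]))) {
      if (!is.list(config[[k]])) stop("config key ", path, k, " must be a list", call. = FALSE)
      check_config_keys(config[[k]], reference[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a run configuration file
#'
#' YAML or JSON by extension. Unknown keys are rejected; missing keys fall
#' back to [default_config()].
#'
#' @param path Config file path.
#' @return Full validated configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be YAML or JSON", call. = FALSE))
  check_config_keys(cfg)
  utils::modifyList(default_config(), cfg)
}

# -- image batch -------------------------------------------------------------

#' Quantify a batch of eye images
#'
#' Runs [quantify_image()] over a directory (or explicit file list) with
#' per-image metadata, producing one metrics row per successfully processed
#' image. A failing image is logged with its stage and reason and the batch
#' continues.
#'
#' @param images Directory containing PNG/TIFF images, or a character
#'   vector of file paths.
#' @param metadata `data.frame` with columns `image_id` (file name without
#'   directory), `line`, `group`, `batch`. Images without metadata get NA.
#' @param config Image-stage options as in [quantify_image()].
#' @return `data.frame`: `image_id`, `line`, `group`, `batch`,
#'   `n_ommatidia`, then the 16 metrics in canonical order; failures (if
#'   any) in `attr(, "failures")`.
#' @export
run_image_batch <- function(images, metadata = NULL, config = list()) {
  files <- if (length(images) == 1 && dir.exists(images)) {
    list.files(images, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
               full.names = TRUE)
  } else as.character(images)
  files <- files[file.exists(files)]
  if (length(files) == 0) stop("no readable images found", call. = FALSE)
  rows <- list(); fails <- list()
  for (f in files) {
    id <- basename(f)
    res <- tryCatch(quantify_image(f, config), error = function(e) e)
    if (inherits(res, "error")) {
      fails[[id]] <- conditionMessage(res)
      next
    }
    meta <- if (!is.null(metadata) && id %in% metadata$image_id) {
      metadata[match(id, metadata$image_id), c("line", "group", "batch")]
    } else data.frame(line = NA_character_, group = NA_character_,
                      batch = NA_character_)
    rows[[id]] <- cbind(data.frame(image_id = id, stringsAsFactors = FALSE),
                        meta, n_ommatidia = res$n_ommatidia,
                        res[, metric_names()], row.names = NULL)
  }
  if (length(rows) == 0) stop("no images could be processed", call. = FALSE)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (length(fails) > 0) {
    attr(out, "failures") <- data.frame(image_id = names(fails),
                                        reason = unlist(fails),
                                        row.names = NULL)
  }
  out
}

#' Write an image-metrics table as TSV
#' @param metrics Result of [run_image_batch()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- full synthetic pipeline -------------------------------------------------

#' Run the full synthetic screen end to end
#'
#' Executes the downstream stages in order on a synthetic bundle with
#' known ground truth: simulate a structured genotype panel with a planted
#' causal variant, derive line genetic values, simulate replicated
#' phenotypes, fit the line mixed model and extract BLUPs, estimate
#' heritability, filter variants, build PC covariates with Tracy-Widom
#' selection, run the association scan with BH correction, classify hits,
#' map them to a synthetic gene annotation, and test the suggestive genes
#' for ortholog enrichment against fixture tables. Each stage's outputs are
#' written under `out_dir` together with a provenance JSON (config, seeds,
#' row counts, config file hash).
#'
#' @param config Configuration list (see [default_config()]) or a YAML/JSON
#'   path.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the stage results: `geno`, `pheno`, `model`,
#'   `h2`, `pca`, `n_pcs`, `scan`, `hits`, `gene_map`, `enrichment`,
#'   `provenance`.
#' @export
run_full <- function(config = default_config(), out_dir = tempfile("rougheye_run_")) {
  if (is.character(config)) config <- read_run_config(config)
  check_config_keys(config)
  config <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$simulate
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stop_stage(name, conditionMessage(e)))
  }

  gs <- stage("simulate_genotypes", {
    spec <- geno_sim_spec(n_lines = sim$n_lines, n_variants = sim$n_variants,
                          maf_range = sim$maf_range,
                          missing_rate = sim$missing_rate,
                          n_subpops = sim$n_subpops,
                          fst_like_divergence = sim$fst_like_divergence,
                          causal_indices = sim$causal_index,
                          causal_effects = sim$causal_effect,
                          seed = sim$seed)
    simulate_genotypes(spec)
  })
  pheno <- stage("simulate_phenotypes", {
    gv <- genetic_values(gs$geno, gs$true_effects)
    gv <- gv - mean(gv)
    spec <- pheno_sim_spec(n_lines = sim$n_lines,
                           reps_per_line = sim$reps_per_line,
                           var_line = sim$var_line,
                           var_residual = sim$var_residual,
                           seed = sim$seed + 1L)
    line_noise <- with_seed(sim$seed + 2L,
                            stats::rnorm(sim$n_lines, 0, sqrt(sim$var_line)))
    simulate_line_phenotypes(spec, line_effects = gv + line_noise)
  })
  model <- stage("fit_line_model", fit_line_model(pheno))
  h2 <- stage("heritability",
              heritability(model, n_boot = config$heritability$n_boot,
                           seed = config$heritability$seed))
  gflt <- stage("filter_variants",
                suppressMessages(suppressWarnings(
                  filter_variants(gs$geno, config$gwas$max_missing,
                                  config$gwas$min_maf))))
  if (ncol(gflt$calls) == 0) {
    warning("no variants passed the filters: association scan is empty")
    pca <- NULL
    n_pcs <- 0L
    scan <- data.frame(trait = character(0), variant = character(0),
                       chrom = character(0), pos = integer(0),
                       beta = numeric(0), se = numeric(0),
                       p_raw = numeric(0), n_used = integer(0),
                       tested = logical(0), p_adjust = numeric(0),
                       stringsAsFactors = FALSE)
  } else {
    pca <- stage("pca_covariates", pca_covariates(gflt))
    n_pcs <- stage("tracy_widom_select",
                   as.integer(tracy_widom_select(pca$eigenvalues,
                                                 alpha = config$gwas$tw_alpha,
                                                 max_pcs = min(config$gwas$max_pcs,
                                                               length(pca$eigenvalues) - 2L))))
    covs <- if (n_pcs > 0) make_covariates(pca, n_pcs) else NULL
    bl <- blups(model)
    scan <- stage("associate", {
      s <- associate(bl, gflt, covs)
      s$trait <- "synthetic_trait"
      s$p_adjust <- bh_adjust(s$p_raw)
      s
    })
  }
  hits <- stage("classify_hits",
                classify_hits(scan, alpha = config$gwas$alpha,
                              suggestive = config$gwas$suggestive))
  annotation <- stage("annotation",
                      make_annotation_fixture(sim$n_genes))
  gene_map <- stage("map_snps_to_genes", {
    src <- if (nrow(hits$suggestive) > 0) hits$suggestive else
      scan[order(scan$p_raw), ][seq_len(min(10, nrow(scan))), ]
    map_snps_to_genes(src, annotation, window = config$gwas$gene_window)
  })
  enr <- stage("enrichment", {
    genes <- unique(stats::na.omit(gene_map$primary_gene))
    if (length(genes) == 0) genes <- annotation$gene_id[1]
    fx <- make_ortholog_fixture(n_fly_genes = sim$n_genes,
                                n_pairs = config$enrich$n_pairs,
                                n_ad_genes = config$enrich$n_ad_genes,
                                planted_overlap = 0,
                                seed = config$enrich$seed)
    # universe = all annotated genes; pairs table re-keyed to annotation ids
    fx$pairs$fly_gene <- annotation$gene_id[match(fx$pairs$fly_gene, fx$universe)]
    permutation_enrichment(genes, annotation$gene_id, fx$pairs, fx$catalog,
                           mode = config$enrich$mode,
                           n_iter = config$enrich$n_iter,
                           seed = config$enrich$seed,
                           min_score = config$enrich$min_score)
  })

  # outputs + provenance
  write_genotype_tsv(gflt, file.path(out_dir, "genotypes_filtered.tsv"))
  utils::write.table(pheno, file.path(out_dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model$blups, file.path(out_dir, "blups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scan, file.path(out_dir, "association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gene_map, file.path(out_dir, "gene_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_permutation_json(enr, file.path(out_dir, "enrichment.json"))
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  provenance <- list(
    schema_version = config$schema_version,
    config_hash = unname(tools::md5sum(cfg_path)),
    seeds = list(simulate = sim$seed,
                 heritability = config$heritability$seed,
                 enrich = config$enrich$seed),
    counts = list(n_lines = sim$n_lines,
                  n_variants_filtered = ncol(gflt$calls),
                  n_pcs_retained = n_pcs,
                  n_significant = hits$n_unique_significant,
                  n_suggestive = hits$n_unique_suggestive),
    package_version = as.character(utils::packageVersion("rougheye")))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(geno = gs, pheno = pheno, model = model, h2 = h2, pca = pca,
                 n_pcs = n_pcs, scan = scan, hits = hits,
                 gene_map = gene_map, enrichment = enr,
                 provenance = provenance, out_dir = out_dir))
}
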