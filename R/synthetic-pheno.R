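#' Specify a replicated line-phenotype simulation
#'
#' Generative counterpart of the screening design: replicate trait values
#' for inbred lines measured in image groups and experimental batches,
#' `y = mu + group + batch + line + error`, with the line effect random
#' (`N(0, var_line)`) and the residual `N(0, var_residual)`. Group and batch
#' are fixed offsets. Defaults give broad-sense heritability
#' `var_line / (var_line + var_residual) = 0.25`.
#'
#' @param n_lines Number of lines (>= 2).
#' @param reps_per_line Replicates per line (>= 2).
#' @param var_line,var_residual Variance components (>= 0).
#' @param group_effects Named numeric vector of fixed group offsets, or
#'   `NULL` for a single unnamed group. Lines are assigned to groups
#'   round-robin (each line is imaged within one group, as in the screen).
#' @param batch_effects Named numeric vector of fixed batch offsets, or
#'   `NULL`; replicates within a line cycle through batches.
#' @param mu General mean.
#' @param seed Integer seed.
#' @return An object of class `pheno_sim_spec`.
#' @export
pheno_sim_spec <- function(n_lines = 100L, reps_per_line = 10L,
                           var_line = 1, var_residual = 3,
                           group_effects = NULL, batch_effects = NULL,
                           mu = 0, seed = 1L) {
  stopifnot(is_count(n_lines, 2L), is_count(reps_per_line, 2L),
            var_line >= 0, var_residual >= 0)
  if (!is.null(group_effects)) stopifnot(!is.null(names(group_effects)))
  if (!is.null(batch_effects)) stopifnot(!is.null(names(batch_effects)))
  structure(list(n_lines = as.integer(n_lines),
                 reps_per_line = as.integer(reps_per_line),
                 var_line = var_line, var_residual = var_residual,
                 group_effects = group_effects, batch_effects = batch_effects,
                 mu = mu, seed = as.integer(seed)),
            class = "pheno_sim_spec")
}

#' Simulate replicated line phenotypes with known variance components
#'
#' @param spec A [pheno_sim_spec()].
#' @param line_effects Optional numeric vector of length `n_lines` to use as
#'   the true line effects (e.g. genetic values from a simulated genotype
#'   panel); when supplied it replaces the `N(0, var_line)` draw.
#' @return A `data.frame` (class `trait_table`) with columns `line`, `group`,
#'   `batch`, `rep`, `value`; the true line effects are attached as
#'   `attr(, "line_effects")` (named by line) for recovery tests.
#' @export
#' @examples
#' ph <- simulate_line_phenotypes(pheno_sim_spec(n_lines = 10, seed = 3))
#' head(ph)
simulate_line_phenotypes <- function(spec, line_effects = NULL) {
  stopifnot(inherits(spec, "pheno_sim_spec"))
  n <- spec$n_lines; r <- spec$reps_per_line
  lines <- sprintf("line_%03d", seq_len(n))
  groups <- if (is.null(spec$group_effects)) {
    stats::setNames(0, "g1")
  } else spec$group_effects
  batches <- if (is.null(spec$batch_effects)) {
    stats::setNames(0, "b1")
  } else spec$batch_effects
  line_group <- rep(names(groups), length.out = n)
  rep_batch <- rep(names(batches), length.out = r)

  out <- with_seed(spec$seed, {
    le <- if (is.null(line_effects)) {
      stats::rnorm(n, 0, sqrt(spec$var_line))
    } else {
      stopifnot(length(line_effects) == n)
      as.numeric(line_effects)
    }
    names(le) <- lines
    eps <- stats::rnorm(n * r, 0, sqrt(spec$var_residual))
    d <- data.frame(line = rep(lines, each = r),
                    group = rep(line_group, each = r),
                    batch = rep(rep_batch, times = n),
                    rep = rep(seq_len(r), times = n),
                    stringsAsFactors = FALSE)
    d$value <- spec$mu + groups[d$group] + batches[d$batch] + le[d$line] + eps
    attr(d, "line_effects") <- le
    d
  })
  class(out) <- c("trait_table", "data.frame")
  out
}
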