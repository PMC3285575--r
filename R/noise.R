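#' Summarize replicated experiments into means and standard errors
#'
#' For every base experiment with at least `min_reps` replicate columns,
#' computes per gene the arithmetic mean and the standard error (sample
#' standard deviation over replicates divided by sqrt of the replicate
#' count). Base experiments with fewer replicates are dropped.
#'
#' @param expr Expression matrix whose columns are replicate measurements.
#' @param reps Named list: base experiment id -> replicate column ids.
#' @param min_reps Minimum replicate count to retain a base experiment
#'   (default 3).
#' @return A `noise_model`: list with `gene_ids`, `base_ids`, `mean` and
#'   `se` (genes x base experiments matrices), `n_reps`.
#' @export
replicate_summary <- function(expr, reps, min_reps = 3L) {
  stopifnot(is.matrix(expr), is.list(reps))
  missing_cols <- setdiff(unlist(reps, use.names = FALSE), colnames(expr))
  if (length(missing_cols) > 0L) {
    stop_format("replicate map references unknown column '%s'", missing_cols[[1L]])
  }
  keep <- names(reps)[lengths(reps) >= min_reps]
  if (length(keep) == 0L) {
    stop_format("no base experiment has at least %d replicates", min_reps)
  }
  gene_ids <- rownames(expr)
  mean_m <- matrix(NA_real_, nrow(expr), length(keep),
                   dimnames = list(gene_ids, keep))
  se_m <- mean_m
  n_reps <- stats::setNames(lengths(reps)[keep], keep)
  for (b in keep) {
    cols <- expr[, reps[[b]], drop = FALSE]
    r <- ncol(cols)
    mean_m[, b] <- rowMeans(cols)
    se_m[, b] <- apply(cols, 1L, stats::sd) / sqrt(r)
  }
  structure(list(gene_ids = gene_ids, base_ids = keep,
                 mean = mean_m, se = se_m, n_reps = n_reps),
            class = "noise_model")
}

#' Draw an artificial dataset from a noise model
#'
#' Each cell (gene, base experiment) is drawn independently from
#' `Normal(mean, c * se)`. At `c = 0` the mean matrix is returned exactly
#' (no draw is made), recreating the original data set. The artificial
#' dataset has one column per base experiment.
#'
#' @param model A `noise_model` from [replicate_summary()].
#' @param c Non-negative noise scale.
#' @param seed Integer seed; draws are reproducible from it.
#' @return Expression matrix, genes x base experiments.
#' @export
perturb_expression <- function(model, c, seed = 1L) {
  stopifnot(inherits(model, "noise_model"), c >= 0)
  if (c == 0) return(model$mean)
  noise <- with_seed(seed, matrix(stats::rnorm(length(model$mean)),
                                  nrow(model$mean), ncol(model$mean)))
  out <- model$mean + c * model$se * noise
  dimnames(out) <- dimnames(model$mean)
  out
}

#' Noise sweep: community structure of artificial noisy datasets
#'
#' For each noise scale `c` in `c_grid`, generates `datasets_per_c`
#' artificial datasets from the noise model, runs the CLR pipeline on each
#' (MI, relatedness, threshold at `z0`), partitions each resulting network
#' `runs_per_dataset` times, and pools all `datasets_per_c *
#' runs_per_dataset` partitionings into a single co-classification matrix
#' from which core communities are extracted. Seeds are derived
#' hierarchically (c index, dataset index, run index) so any subset is
#' independently reproducible.
#'
#' @param model A `noise_model`.
#' @param c_grid Distinct ascending noise scales.
#' @param datasets_per_c Artificial datasets per noise scale (default 20).
#' @param runs_per_dataset Partitionings per dataset (default 10).
#' @param z0 Relatedness threshold for network construction (default 2).
#' @param bins,spline_order Binning options for the CLR step.
#' @param tau Core extraction threshold (default 1).
#' @param seed Integer master seed.
#' @return A `noise_sweep`: list with `c_grid`, `per_c` (list per scale:
#'   `c`, `coclassification`, `cores`), and `summary` (data frame: c,
#'   n_cores, mean_core_size, max_core_size).
#' @export
noise_sweep <- function(model, c_grid, datasets_per_c = 20L,
                        runs_per_dataset = 10L, z0 = 2,
                        bins = 10L, spline_order = 3L, tau = 1,
                        seed = 1L) {
  stopifnot(inherits(model, "noise_model"))
  if (anyDuplicated(c_grid) || is.unsorted(c_grid)) {
    stop_format("c_grid must be distinct and ascending")
  }
  per_c <- vector("list", length(c_grid))
  for (ci in seq_along(c_grid)) {
    cval <- c_grid[[ci]]
    parts <- list()
    for (ds in seq_len(datasets_per_c)) {
      seed_ds <- derive_seed(seed, ci * 100000L + ds)
      x <- perturb_expression(model, cval, seed = seed_ds)
      mi <- mi_matrix(x, bins = bins, spline_order = spline_order)
      rel <- clr_relatedness(mi)
      net <- threshold_network(rel, z0)
      for (run in seq_len(runs_per_dataset)) {
        seed_run <- derive_seed(seed_ds, run)
        parts[[length(parts) + 1L]] <- partition_network(net, seed = seed_run)
      }
    }
    C <- coclassification(parts)
    cores <- core_communities(C, tau = tau)
    per_c[[ci]] <- list(c = cval, coclassification = C, cores = cores)
  }
  summary <- data.frame(
    c = c_grid,
    n_cores = vapply(per_c, function(p) length(p$cores$sets), integer(1)),
    mean_core_size = vapply(per_c, function(p) mean(p$cores$sizes), numeric(1)),
    max_core_size = vapply(per_c, function(p) max(p$cores$sizes), numeric(1)))
  structure(list(c_grid = c_grid, per_c = per_c, summary = summary,
                 z0 = z0, tau = tau),
            class = "noise_sweep")
}

#' Persistence of baseline core communities under noise
#'
#' For each noise scale of a sweep, the proportion of genes that belong to
#' a non-singleton baseline (c = 0) core and, at that scale, still sit in a
#' non-singleton core. Under the default `"subset"` rule the gene's noisy
#' core must consist entirely of genes from its own baseline core (the
#' noisy core is a sub-community of the baseline one); under `"any"` it
#' must merely retain at least one baseline co-member.
#'
#' @param baseline `core_communities` at c = 0.
#' @param swept A `noise_sweep` over the same gene universe.
#' @param rule `"subset"` (default) or `"any"`.
#' @return Data frame with columns `c` and `persistence`.
#' @export
core_persistence <- function(baseline, swept, rule = c("subset", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(baseline, "core_communities"), inherits(swept, "noise_sweep"))
  base_lab <- baseline$labels
  base_sizes <- baseline$sizes[base_lab]
  eligible <- names(base_lab)[base_sizes >= 2L]
  if (length(eligible) == 0L) {
    stop_format("baseline has no non-singleton core community")
  }
  persist <- vapply(swept$per_c, function(p) {
    lab <- p$cores$labels
    ok <- vapply(eligible, function(g) {
      core <- p$cores$sets[[lab[[g]]]]
      if (length(core) < 2L) return(FALSE)
      if (rule == "subset") {
        all(base_lab[core] == base_lab[[g]])
      } else {
        any(base_lab[setdiff(core, g)] == base_lab[[g]])
      }
    }, logical(1))
    mean(ok)
  }, numeric(1))
  data.frame(c = swept$c_grid, persistence = persist)
}
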