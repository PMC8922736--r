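#' Build an experiment configuration
#'
#' Four experiment shapes are supported, mirroring the benchmark designs:
#' \describe{
#'   \item{`permutation-null`}{run methods on the original data and on `B`
#'     label-permuted copies; summarize discovery counts and per-gene
#'     identification frequencies.}
#'   \item{`semi-synthetic`}{build `R` semi-synthetic replicates with known
#'     truth from a parent dataset; evaluate FDR and power across a nominal
#'     threshold grid.}
#'   \item{`sample-size-sweep`}{as `semi-synthetic`, additionally
#'     down-sampling every replicate to each per-condition size in `n_grid`.}
#'   \item{`deg-proportion-sweep`}{as `semi-synthetic` with a simulated parent
#'     per DEG proportion in `pi_grid`.}
#' }
#'
#' @param experiment one of the four shapes above.
#' @param methods subset of `c("wilcoxon", "nbwald")` plus named external
#'   result paths.
#' @param seed top-level integer seed; every random draw derives from it.
#' @param outdir output directory (created; intermediate tables and a
#'   `manifest.txt` of key=value provenance lines are written there).
#' @param B permutations (permutation-null).
#' @param R semi-synthetic replicates.
#' @param select_fraction fraction of true DEGs preserved per replicate.
#' @param thresholds nominal FDR grid for evaluation.
#' @param threshold single FDR threshold defining a discovery
#'   (permutation-null).
#' @param n_grid per-condition sizes for the sample-size sweep.
#' @param pi_grid DEG proportions for the proportion sweep.
#' @param sim `"sim_config"` describing the simulated parent; alternatively
#'   supply `counts` and `labels` (objects or file paths) and, for
#'   semi-synthetic shapes, `truth` (id vector).
#' @param counts,labels,truth parent data when not simulated.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(experiment = c("permutation-null", "semi-synthetic",
                                             "sample-size-sweep", "deg-proportion-sweep"),
                              methods = "wilcoxon", seed, outdir,
                              B = 1000L, R = 50L, select_fraction = 0.5,
                              thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.05),
                              threshold = 0.05,
                              n_grid = c(2L, 4L, 8L, 16L, 32L, 64L, 100L),
                              pi_grid = c(0.01, 0.03, 0.05, 0.09, 0.20),
                              sim = NULL, counts = NULL, labels = NULL,
                              truth = NULL) {
  experiment <- match.arg(experiment)
  if (missing(seed)) stop("a seed is mandatory")
  if (missing(outdir)) stop("an output directory is required")
  stopifnot(length(methods) >= 1L, length(thresholds) >= 1L,
            length(n_grid) >= 1L, length(pi_grid) >= 1L)
  if (is.null(sim) && (is.null(counts) || is.null(labels))) {
    stop("supply either 'sim' or 'counts' + 'labels'")
  }
  structure(as.list(environment()), class = "experiment_config")
}

.run_method <- function(method, m, labels, fdr) {
  switch(method,
         wilcoxon = run_wilcoxon_pipeline(m, labels, fdr_threshold = fdr),
         nbwald = nb_wald_pipeline(m, labels, fdr_threshold = fdr),
         load_external_result(method))
}

.load_parent <- function(config) {
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim)
    list(counts = ds$counts, labels = ds$labels,
         truth = ds$truth$true_deg_ids, sim = ds)
  } else {
    m <- if (is.character(config$counts)) read_count_matrix(config$counts) else config$counts
    lab <- if (is.character(config$labels)) read_labels(config$labels) else config$labels
    list(counts = validate_count_matrix(m), labels = lab, truth = config$truth,
         sim = NULL)
  }
}

.write_manifest <- function(path, entries) {
  writeLines(sprintf("%s=%s", names(entries), vapply(entries, format, "")), path)
}

#' Run a configured benchmark experiment end to end
#'
#' Executes the staged pipeline (ingest or simulate, resample, run DE methods,
#' evaluate), writing every summary table plus a manifest sufficient to re-run
#' the experiment bit-identically. Stage failures abort with the failing stage
#' named; tables already written are retained.
#'
#' @param config `"experiment_config"` object.
#' @return the experiment's summary object (a `"permutation_summary"` list by
#'   method, an `"evaluation_summary"`, or a named list of them), invisibly
#'   augmented with `outdir`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "ingest"
  result <- tryCatch({
    parent <- .load_parent(config)
    man <- list(experiment = config$experiment, seed = config$seed,
                genes = nrow(parent$counts), samples = ncol(parent$counts),
                methods = paste(config$methods, collapse = ","))
    out <- switch(config$experiment,
      "permutation-null" = {
        stage <- "permute"
        perms <- permute_labels(parent$labels, config$B,
                                derive_seed(config$seed, 100L))
        stage <- "run-methods"
        summaries <- list()
        for (meth in config$methods) {
          orig <- .run_method(meth, parent$counts, parent$labels, config$threshold)
          permres <- lapply(perms$permuted_labels, function(pl)
            .run_method(meth, parent$counts, pl, config$threshold))
          stage <- "summarize"
          ps <- permutation_summary(orig, permres, config$threshold)
          write_tsv_meta(data.frame(permutation = seq_along(ps$perm_counts),
                                    discoveries = ps$perm_counts),
                         file.path(config$outdir, paste0("perm_counts_", meth, ".tsv")),
                         meta = list(method = meth, B = ps$B,
                                     threshold = ps$threshold,
                                     original_count = ps$original_count,
                                     exceed_fraction = ps$exceed_fraction,
                                     seed = config$seed))
          write_tsv_meta(data.frame(gene_id = names(ps$gene_freq),
                                    frequency = unname(ps$gene_freq)),
                         file.path(config$outdir, paste0("gene_freq_", meth, ".tsv")),
                         meta = list(method = meth, seed = config$seed))
          summaries[[meth]] <- ps
        }
        man$B <- config$B
        summaries
      },
      "semi-synthetic" = {
        stage <- "resample"
        out <- .run_semisynthetic(parent, config, config$seed)
        man$R <- config$R
        out
      },
      "sample-size-sweep" = {
        stage <- "resample"
        sweeps <- list()
        for (n in config$n_grid) {
          sweeps[[as.character(n)]] <-
            .run_semisynthetic(parent, config, config$seed, n = n)
        }
        man$R <- config$R
        man$n_grid <- paste(config$n_grid, collapse = ",")
        sweeps
      },
      "deg-proportion-sweep" = {
        stage <- "simulate"
        if (is.null(config$sim)) stop("proportion sweep requires a simulated parent")
        sweeps <- list()
        for (p in config$pi_grid) {
          cf <- config$sim
          cf$pi <- p
          cf$seed <- derive_seed(config$seed, 200L, round(p * 1e4))
          ds <- simulate_dataset(cf)
          par_p <- list(counts = ds$counts, labels = ds$labels,
                        truth = ds$truth$true_deg_ids)
          sweeps[[format(p)]] <-
            .run_semisynthetic(par_p, config, cf$seed)
        }
        man$pi_grid <- paste(config$pi_grid, collapse = ",")
        sweeps
      })
    .write_manifest(file.path(config$outdir, "manifest.txt"), man)
    out
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(structure(result, outdir = config$outdir))
}

.run_semisynthetic <- function(parent, config, seed, n = NULL) {
  if (is.null(parent$truth) || length(parent$truth) == 0L) {
    stop("semi-synthetic construction needs a non-empty truth set")
  }
  sp <- split_by_condition(parent$counts, parent$labels)
  reps <- generate_replicates(sp$X, sp$Y, parent$truth, R = config$R,
                              select_fraction = config$select_fraction,
                              seed = seed)
  if (!is.null(n)) {
    reps <- lapply(reps, function(ds)
      downsample(ds, n, seed = derive_seed(seed, 6L, ds$replicate_index, n)))
  }
  truths <- lapply(reps, `[[`, "selected_true_degs")
  results_by_method <- lapply(structure(config$methods, names = config$methods),
                              function(meth) {
    lapply(reps, function(ds) {
      d <- semisynthetic_to_dataset(ds, level_names = levels(parent$labels))
      .run_method(meth, d$counts, d$labels, max(config$thresholds))
    })
  })
  ev <- evaluate_methods(results_by_method, truths, thresholds = config$thresholds)
  tag <- if (is.null(n)) "evaluation" else paste0("evaluation_n", n)
  write_tsv_meta(ev$summary, file.path(config$outdir, paste0(tag, ".tsv")),
                 meta = list(R = config$R, seed = seed,
                             select_fraction = config$select_fraction,
                             n = if (is.null(n)) "full" else n))
  ev
}
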