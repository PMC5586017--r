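# End-to-end orchestration with a validated configuration, deterministic
# outputs, and a machine-readable run manifest.

.config_schema <- list(
  gtf = "character", fasta = "character",
  reads_dir = "character", events = "character",
  expression = "character", raw_counts = "character",
  samples = "character", event_counts = "character",
  allele_counts = "character", evidence = "character",
  effectors = "character",
  threshold_nt = "numeric", required_mapq = "numeric",
  mapq_exact = "logical", min_overhang_nt = "numeric",
  clean_window_nt = "numeric", min_event_reads = "numeric",
  min_allele_depth = "numeric", allele_scope = "character",
  min_support = "numeric", min_low_reads = "numeric",
  alpha = "numeric", pseudocount = "numeric",
  shared_events_only = "logical", zero_method = "character",
  effector_mode = "character", seed = "numeric", out_dir = "character")

#' Validate a run configuration
#'
#' Checks a configuration list (or YAML file) against the published schema
#' before any work is done: unknown keys are rejected, values must have the
#' declared type, and numeric thresholds must be non-negative
#' (`alpha` in (0,1)).
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated config list with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.config_schema))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(config)) {
    want <- .config_schema[[k]]
    v <- config[[k]]
    ok <- switch(want, character = is.character(v),
                 numeric = is.numeric(v), logical = is.logical(v))
    if (!ok) stop("config key '", k, "' must be ", want)
  }
  num_keys <- c("threshold_nt", "required_mapq", "min_overhang_nt",
                "clean_window_nt", "min_event_reads", "min_allele_depth",
                "min_support", "min_low_reads", "pseudocount", "seed")
  for (k in intersect(num_keys, names(config))) {
    if (config[[k]] < 0) stop("config key '", k, "' must be non-negative")
  }
  if (!is.null(config$alpha) && (config$alpha <= 0 || config$alpha >= 1)) {
    stop("config key 'alpha' must be in (0, 1)")
  }
  defaults <- list(threshold_nt = 50, required_mapq = 50, mapq_exact = FALSE,
                   min_overhang_nt = 6, clean_window_nt = 12,
                   min_event_reads = 10, min_allele_depth = 5,
                   allele_scope = "per_tissue", min_support = 3,
                   min_low_reads = 10, alpha = 0.05, pseudocount = 0,
                   shared_events_only = FALSE, zero_method = "wilcox",
                   effector_mode = "per_sample", seed = 1)
  modifyList(defaults, config)
}

.read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Discover events from configured annotation (pipeline stage)
#'
#' Wraps [load_gene_models()] and [discover_nmd_events()]; writes the event
#' table (and JSON sidecar) into `out_dir`.
#'
#' @param config Run configuration (list or YAML path) with `gtf`, `fasta`,
#'   `out_dir`.
#' @return The event data.frame, invisibly; written to
#'   `<out_dir>/events.tsv`.
#' @export
run_find_events <- function(config) {
  config <- validate_run_config(config)
  stopifnot(!is.null(config$gtf), !is.null(config$fasta),
            !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  models <- load_gene_models(config$gtf, config$fasta)
  events <- discover_nmd_events(models, threshold_nt = config$threshold_nt)
  write_events(events, file.path(config$out_dir, "events.tsv"))
  invisible(events)
}

#' Count junction reads for all configured samples (pipeline stage)
#'
#' For each sample in the metadata, reads `reads_<sample>.sam` (or `.bam`)
#' from `config$reads_dir` and counts splice-form support for every event.
#'
#' @param config Run configuration with `reads_dir`, `events`, `samples`,
#'   `out_dir`.
#' @return Combined counts data.frame, invisibly; written to
#'   `<out_dir>/event_counts.tsv`.
#' @export
run_quant <- function(config) {
  config <- validate_run_config(config)
  stopifnot(!is.null(config$reads_dir), !is.null(config$events),
            !is.null(config$samples), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- read_events(config$events)
  samples <- read.delim(config$samples, stringsAsFactors = FALSE)
  params <- junction_filter_params(config$required_mapq,
                                   config$min_overhang_nt,
                                   config$clean_window_nt, config$mapq_exact)
  out <- list()
  for (s in samples$sample_id) {
    f <- file.path(config$reads_dir, paste0("reads_", s, ".sam"))
    if (!file.exists(f)) f <- sub("\\.sam$", ".bam", f)
    if (!file.exists(f)) stop("no reads file for sample ", s)
    reads <- read_alignments(f)
    out[[s]] <- count_events(reads, events, s, params)
  }
  counts <- do.call(rbind, c(out, make.row.names = FALSE))
  write.table(counts, file.path(config$out_dir, "event_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' Run the full assessment pipeline
#'
#' Loads every configured input (expression + evidence for R_mRNA, events +
#' counts for R_isoform, allele counts for R_allele), runs [nmd_assess()],
#' and writes per-metric value tables, the per-patient comparison table,
#' correlation tables, and a machine-readable manifest with versions,
#' config hash and exclusion counters into `config$out_dir`.
#'
#' @param config Run configuration (list or YAML path); `samples` and
#'   `out_dir` are required, plus the inputs of at least one metric.
#' @return The `nmd_assessment`, invisibly.
#' @export
run_assess <- function(config) {
  config <- validate_run_config(config)
  stopifnot(!is.null(config$samples), !is.null(config$out_dir))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))

  samples <- read.delim(config$samples, stringsAsFactors = FALSE)

  expression <- raw_counts <- target_set <- NULL
  if (!is.null(config$expression) && !is.null(config$evidence)) {
    expression <- .read_matrix_tsv(config$expression)
    if (!is.null(config$raw_counts)) raw_counts <- .read_matrix_tsv(config$raw_counts)
    classified <- classify_genes(read_evidence(config$evidence))
    target_set <- select_target_set(classified, config$min_support)
  }
  events <- event_counts <- NULL
  if (!is.null(config$event_counts)) {
    event_counts <- read.delim(config$event_counts, stringsAsFactors = FALSE)
    events <- if (!is.null(config$events)) read_events(config$events) else
      stop("event_counts given without an events table")
  }
  allele_counts <- NULL
  if (!is.null(config$allele_counts)) {
    allele_counts <- read.delim(config$allele_counts, stringsAsFactors = FALSE)
  }
  effector_expr <- NULL
  if (!is.null(config$effectors) && !is.null(expression)) {
    eff <- intersect(config$effectors, rownames(expression))
    if (length(eff)) effector_expr <- expression[eff, , drop = FALSE]
  }

  res <- nmd_assess(samples, expression = expression, raw_counts = raw_counts,
                    target_set = target_set, event_counts = event_counts,
                    events = events, allele_counts = allele_counts,
                    effector_expr = effector_expr,
                    alpha = config$alpha,
                    min_event_reads = config$min_event_reads,
                    min_allele_depth = config$min_allele_depth,
                    allele_scope = config$allele_scope,
                    min_low_reads = config$min_low_reads,
                    shared_events_only = config$shared_events_only,
                    pseudocount = config$pseudocount,
                    zero_method = config$zero_method,
                    effector_mode = config$effector_mode)

  wt <- function(x, f) write.table(x, file.path(config$out_dir, f),
                                   sep = "\t", quote = FALSE, row.names = FALSE)
  for (m in names(res$metrics)) wt(res$metrics[[m]], paste0("metric_", m, ".tsv"))
  comp <- do.call(rbind, c(lapply(res$comparisons, as.data.frame),
                           make.row.names = FALSE))
  wt(comp, "comparisons.tsv")
  if (!is.null(res$cross_metric)) wt(res$cross_metric, "cross_metric.tsv")
  if (!is.null(res$effectors)) wt(res$effectors, "effector_correlations.tsv")

  manifest <- list(
    package = "nmdactivity",
    version = as.character(packageVersion("nmdactivity")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[order(names(config))],
    config_hash = .hash_config(config),
    seed = config$seed,
    n_patients = length(unique(samples$patient_id)),
    metrics = names(res$metrics),
    exclusions = res$exclusions,
    input_rows = list(
      event_counts = if (!is.null(event_counts)) nrow(event_counts) else 0L,
      allele_counts = if (!is.null(allele_counts)) nrow(allele_counts) else 0L))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

.hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}
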