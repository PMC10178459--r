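#' Pipeline configuration
#'
#' Builds the configuration for an end-to-end run: model thresholds, merge
#' policy overrides, run QC inputs and the case manifest. Unknown keys are
#' rejected fail-fast. Configuration may also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param model_name model to run (see [model_config()]).
#' @param manifest path to a tab-separated manifest with columns `case_id`,
#'   `target`, `table_path` (paths relative to the manifest's directory), or
#'   a data frame of the same shape.
#' @param q30_fraction run-level fraction of bases at or above Q30.
#' @param negative_control,positive_control paths to the control clonotype
#'   tables (or `clonotype_table` objects).
#' @param positive_control_target assay target of the positive control.
#' @param q30_threshold minimum acceptable Q30 fraction.
#' @param model_overrides named list of [model_config()] threshold
#'   overrides.
#' @param merge_overrides named list of [merge_policy()] overrides
#'   (`top_n`, `pool_n`, `max_mismatch`, `length_mode`).
#' @param out_dir directory for JSON case reports (`NULL` = no files).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(model_name = "roswell_park",
                            manifest = NULL,
                            q30_fraction = NULL,
                            negative_control = NULL,
                            positive_control = NULL,
                            positive_control_target = NULL,
                            q30_threshold = 0.75,
                            model_overrides = list(),
                            merge_overrides = list(),
                            out_dir = NULL) {
  structure(list(
    model_name = model_name,
    manifest = manifest,
    q30_fraction = q30_fraction,
    negative_control = negative_control,
    positive_control = positive_control,
    positive_control_target = positive_control_target,
    q30_threshold = q30_threshold,
    model_overrides = model_overrides,
    merge_overrides = merge_overrides,
    out_dir = out_dir
  ), class = "pipeline_config")
}

.PIPELINE_KEYS <- names(formals(pipeline_config))

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys abort before any processing.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

.resolve_model <- function(config) {
  cfg <- do.call(model_config,
                 c(list(model_name = config$model_name), config$model_overrides))
  if (length(config$merge_overrides)) {
    mp <- cfg$merge_policy
    mp_args <- utils::modifyList(
      list(top_n = mp$top_n, pool_n = mp$pool_n,
           max_mismatch = mp$max_mismatch, length_mode = mp$length_mode),
      config$merge_overrides)
    cfg$merge_policy <- do.call(merge_policy, mp_args)
  }
  cfg
}

.load_table <- function(x, target = NULL, base_dir = ".") {
  if (inherits(x, "clonotype_table")) return(x)
  path <- if (file.exists(x)) x else file.path(base_dir, x)
  read_clonotype_table(path, target = target)
}

.assay_call_fields <- function(ac) {
  list(
    sample_id = ac$sample_id,
    target = ac$target,
    call = ac$call,
    dominant_pcts = ac$dominant_pcts,
    background_pct = ac$background_pct,
    fired_rule = ac$fired_rule,
    model_name = ac$model_name
  )
}

.case_report <- function(case_id, b_call, t_call, assay_calls, run_qc, cfg) {
  list(
    schema_version = "1.0",
    case_id = case_id,
    b_cell_call = b_call,
    t_cell_call = t_call,
    assay_calls = lapply(assay_calls, .assay_call_fields),
    run_qc = list(
      run_pass = run_qc$run_pass, q30_pass = run_qc$q30_pass,
      negative_pass = run_qc$negative_pass, positive_pass = run_qc$positive_pass,
      messages = run_qc$messages
    ),
    model_name = cfg$model_name,
    software = list(
      package = "clonocall",
      version = as.character(utils::packageVersion("clonocall"))
    )
  )
}

#' Run the end-to-end clonality pipeline
#'
#' Evaluates the run-level quality gate first; a failing run blocks all
#' sample calling and every case is reported invalid with the run-level
#' failure reasons. On a passing run, each assay table in the manifest is
#' merged under the model's merge policy, called, and aggregated to
#' case-level lineage results. Output is a pure function of inputs and
#' configuration; when `out_dir` is set, one JSON report per case is
#' written (no timestamps, so reruns are byte-identical).
#'
#' @param config a [pipeline_config()] or path to a YAML config file.
#' @return a named list of case reports (see the JSON schema shipped at
#'   `system.file("schema/case_report.schema.json", package = "clonocall")`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- .resolve_model(config)

  if (is.null(config$manifest)) stop("pipeline config has no manifest")
  if (is.character(config$manifest)) {
    base_dir <- dirname(config$manifest)
    manifest <- utils::read.delim(config$manifest, stringsAsFactors = FALSE)
  } else {
    base_dir <- "."
    manifest <- as.data.frame(config$manifest)
  }
  need <- c("case_id", "target", "table_path")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_targets <- setdiff(unique(manifest$target), ASSAY_TARGETS)
  if (length(bad_targets)) stop("manifest has unknown target(s): ",
                                paste(bad_targets, collapse = ", "))

  if (is.null(config$q30_fraction) || is.null(config$negative_control) ||
      is.null(config$positive_control)) {
    stop("run QC inputs (q30_fraction, negative_control, positive_control) are required")
  }
  neg <- merge_top_clones(.load_table(config$negative_control,
                                      base_dir = base_dir), cfg$merge_policy)
  pos <- merge_top_clones(.load_table(config$positive_control,
                                      target = config$positive_control_target,
                                      base_dir = base_dir), cfg$merge_policy)
  qc <- evaluate_run(config$q30_fraction, neg, pos,
                     positive_control_target = pos$target,
                     q30_threshold = config$q30_threshold, cfg = cfg)

  case_ids <- unique(manifest$case_id)
  reports <- list()
  for (cid in case_ids) {
    rows <- manifest[manifest$case_id == cid, , drop = FALSE]
    if (!qc$run_pass) {
      calls <- lapply(seq_len(nrow(rows)), function(i) {
        structure(list(sample_id = cid, target = rows$target[i],
                       call = "INVALID", dominant_pcts = numeric(0),
                       background_pct = NA_real_,
                       fired_rule = paste0("run_qc_failed: ",
                                           paste(qc$messages, collapse = "; ")),
                       model_name = cfg$model_name),
                  class = "assay_call")
      })
      agg <- aggregate_case(calls, cid)
    } else {
      calls <- lapply(seq_len(nrow(rows)), function(i) {
        tbl <- .load_table(rows$table_path[i], target = rows$target[i],
                           base_dir = base_dir)
        tbl$sample_id <- cid
        call_clonality(merge_top_clones(tbl, cfg$merge_policy), cfg)
      })
      agg <- aggregate_case(calls, cid)
    }
    reports[[cid]] <- .case_report(cid, agg$b_cell_call, agg$t_cell_call,
                                   calls, qc, cfg)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cid in names(reports)) {
      jsonlite::write_json(reports[[cid]],
                           file.path(config$out_dir, paste0(cid, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           na = "null")
    }
  }
  reports
}

#' Validate a case report against the shipped schema contract
#'
#' Structural validation of the JSON case report: required fields present
#' with the expected types, every input assay reported exactly once, and
#' calls drawn from the allowed categories. (The formal JSON-schema document
#' is shipped under `inst/schema/` for external validators.)
#'
#' @param report one element of the [run_pipeline()] return value (or the
#'   same structure re-read from JSON).
#' @return `TRUE`, invisibly; aborts with a message on violation.
#' @export
validate_case_report <- function(report) {
  need <- c("schema_version", "case_id", "b_cell_call", "t_cell_call",
            "assay_calls", "run_qc", "model_name", "software")
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("case report missing field(s): ",
                         paste(miss, collapse = ", "))
  ok_call <- function(x) is.na(x) || x %in% c("CLONAL", "NEC", "INVALID")
  if (!ok_call(report$b_cell_call) || !ok_call(report$t_cell_call)) {
    stop("lineage calls must be CLONAL, NEC, INVALID or NA")
  }
  for (ac in report$assay_calls) {
    amiss <- setdiff(c("sample_id", "target", "call", "fired_rule", "model_name"),
                     names(ac))
    if (length(amiss)) stop("assay call missing field(s): ",
                            paste(amiss, collapse = ", "))
    if (!ac$call %in% CALL_LEVELS) stop("unknown assay call: ", ac$call)
  }
  targets <- vapply(report$assay_calls, `[[`, character(1), "target")
  if (anyDuplicated(targets)) stop("assay reported more than once: ",
                                   paste(unique(targets[duplicated(targets)]),
                                         collapse = ", "))
  qmiss <- setdiff(c("run_pass", "q30_pass", "negative_pass", "positive_pass"),
                   names(report$run_qc))
  if (length(qmiss)) stop("run_qc missing field(s): ",
                          paste(qmiss, collapse = ", "))
  invisible(TRUE)
}
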