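#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: input location and dialect,
#' attribute selection, discretization spec (an object or the name of a
#' bundled preset), class attribute, mining thresholds, antecedent cap and
#' output directory. When `spec` is `"dataset1"` or `"dataset2"` the matching
#' bundled selection (column names, retained subset, rename map, class
#' attribute) fills any field left `NULL`.
#'
#' @param input path to the input table.
#' @param dialect input dialect for [read_table()].
#' @param spec a [disc_spec()], or `"dataset1"` / `"dataset2"`.
#' @param class_attr class attribute name (canonical, i.e. after renaming).
#' @param col_names,select,rename see [read_table()] / [select_attributes()];
#'   `select = NULL` keeps all columns.
#' @param min_support,min_confidence mining thresholds (study defaults 0.6
#'   and 0.9).
#' @param max_antecedent cap on antecedent size (default unlimited).
#' @param out_of_range see [encode_transactions()].
#' @param metric_tolerance see [mutual_rules()].
#' @param out_dir directory for artifacts (`NULL`: in-memory only).
#' @param dataset_label provenance label; defaults to the input file name.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(input, dialect = "csv", spec, class_attr = NULL,
                            col_names = NULL, select = NULL, rename = NULL,
                            min_support = 0.6, min_confidence = 0.9,
                            max_antecedent = Inf,
                            out_of_range = "error", metric_tolerance = 0,
                            out_dir = NULL, dataset_label = NULL) {
  if (is.character(spec)) {
    preset <- match.arg(spec, c("dataset1", "dataset2"))
    sel <- switch(preset, dataset1 = dataset1_selection(),
                  dataset2 = dataset2_selection())
    spec <- switch(preset, dataset1 = spec_dataset1(), dataset2 = spec_dataset2())
    if (is.null(col_names)) col_names <- sel$col_names
    if (is.null(select)) select <- sel$names
    if (is.null(rename)) rename <- sel$rename
    if (is.null(class_attr)) class_attr <- sel$class_attr
  }
  stopifnot(inherits(spec, "disc_spec"), !is.null(class_attr),
            min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  structure(
    list(input = input, dialect = dialect, spec = spec,
         class_attr = class_attr, col_names = col_names, select = select,
         rename = rename, min_support = min_support,
         min_confidence = min_confidence, max_antecedent = max_antecedent,
         out_of_range = out_of_range, metric_tolerance = metric_tolerance,
         out_dir = out_dir,
         dataset_label = dataset_label %||% basename(input)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full knowledge-extraction pipeline
#'
#' Ingest, select, clean, discretize, stratify by class, mine each group with
#' both algorithms, generate class-targeted rules, and intersect the two rule
#' sets -- logging record counts at every stage. Both miners always run: the
#' consensus stage is the pipeline's integrity mechanism, and any rule found
#' by one miner only signals a bug, not a finding.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `db` (the encoded [transaction_db()]),
#'   `groups` (per class level: `apriori`, `fpgrowth` rule sets and
#'   `consensus` report), `stage_log` (character lines), `config`. If
#'   `config$out_dir` is set, artifacts are also written there (per group:
#'   `rules_<group>_<algorithm>.csv/.json`, `consensus_<group>.csv/.json`;
#'   plus `stage_log.txt`), each atomically via a temp-file rename.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  push <- function(...) log_lines[length(log_lines) + 1L] <<- sprintf(...)

  raw <- stage("read", read_table(config$input, config$dialect,
                                  col_names = config$col_names,
                                  source_label = config$dataset_label))
  push("read: %d records, %d attributes", nrow(raw), ncol(raw))

  if (!is.null(config$select)) {
    raw <- stage("select", select_attributes(raw, config$select, config$rename))
    push("select: %d records, %d attributes retained", nrow(raw), ncol(raw))
  }
  cleaned <- stage("clean", drop_incomplete(raw))
  push("clean: %d records remain (%d incomplete removed)",
       nrow(cleaned), nrow(raw) - nrow(cleaned))

  db <- stage("discretize", encode_transactions(
    cleaned, config$spec, config$class_attr,
    out_of_range = config$out_of_range))
  oor <- attr(db, "n_out_of_range") %||% 0L
  push("encode: %d transactions, %d distinct items (%d out-of-range dropped)",
       db$N, length(db$items), oor)

  groups <- stage("stratify", split_by_class(db, config$class_attr))
  for (g in names(groups)) push("group %s: %d transactions", g, groups[[g]]$N)

  th <- thresholds(config$min_support, config$min_confidence)
  mine_len <- if (is.finite(config$max_antecedent)) {
    config$max_antecedent + 1
  } else Inf

  results <- list()
  for (g in names(groups)) {
    gdb <- groups[[g]]
    class_item <- make_item(config$class_attr, g)
    fa <- stage("apriori", apriori_mine(gdb, th$min_support, max_len = mine_len))
    ff <- stage("fpgrowth", fpgrowth_mine(gdb, th$min_support, max_len = mine_len))
    ra <- stage("rules", generate_class_rules(gdb, class_item, fa, th,
                                              config$max_antecedent))
    rf <- stage("rules", generate_class_rules(gdb, class_item, ff, th,
                                              config$max_antecedent))
    cons <- stage("consensus", mutual_rules(ra, rf, config$metric_tolerance))
    push("group %s: %d frequent itemsets, %d mutual rules (%d apriori-only, %d fpgrowth-only)",
         g, nrow(fa), nrow(cons$mutual), nrow(cons$only_first),
         nrow(cons$only_second))
    results[[g]] <- list(apriori = ra, fpgrowth = rf, consensus = cons)
  }

  if (!is.null(config$out_dir)) {
    stage("write", write_artifacts(results, log_lines, config$out_dir))
  }
  invisible(list(db = db, groups = results, stage_log = log_lines,
                 config = config))
}

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
}

write_artifacts <- function(results, log_lines, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- function(x) tolower(gsub("[^A-Za-z0-9]+", "_", x))
  for (g in names(results)) {
    r <- results[[g]]
    for (alg in c("apriori", "fpgrowth")) {
      base <- file.path(out_dir, sprintf("rules_%s_%s", safe(g), alg))
      write_atomic(paste0(base, ".csv"),
                   function(p) write_rule_set(r[[alg]], csv = p))
      write_atomic(paste0(base, ".json"),
                   function(p) write_rule_set(r[[alg]], json = p))
    }
    base <- file.path(out_dir, sprintf("consensus_%s", safe(g)))
    write_atomic(paste0(base, ".csv"),
                 function(p) write_consensus(r$consensus, csv = p))
    write_atomic(paste0(base, ".json"),
                 function(p) write_consensus(r$consensus, json = p))
  }
  write_atomic(file.path(out_dir, "stage_log.txt"),
               function(p) writeLines(log_lines, p))
  invisible(NULL)
}

#' Generate a synthetic table and run the pipeline on it
#'
#' Writes the generated table to CSV (the dialect [read_table()] reads),
#' then runs [run_pipeline()] with the matching bundled discretization spec.
#'
#' @param preset `"dataset1"` or `"dataset2"`.
#' @param seed generator seed.
#' @param out_dir artifact directory (`NULL`: in-memory only).
#' @param min_support,min_confidence mining thresholds.
#' @param n optional record-count override.
#' @param keep_table path to keep the generated CSV at (default: a temp file
#'   removed afterwards).
#' @return The [run_pipeline()] result plus `truth` (generator ground truth)
#'   and `syn_config`.
#' @export
simulate_pipeline <- function(preset = c("dataset1", "dataset2"), seed = 1L,
                              out_dir = NULL, min_support = 0.6,
                              min_confidence = 0.9, n = NULL,
                              keep_table = NULL) {
  preset <- match.arg(preset)
  syn_cfg <- if (preset == "dataset1") {
    if (is.null(n)) preset_dataset1_like(seed) else preset_dataset1_like(seed, n = n)
  } else {
    if (is.null(n)) preset_dataset2_like(seed) else preset_dataset2_like(seed, n = n)
  }
  gen <- generate_transactions(syn_cfg)
  path <- keep_table %||% tempfile(fileext = ".csv")
  readr::write_csv(gen$table, path, na = "", progress = FALSE)
  on.exit(if (is.null(keep_table)) unlink(path), add = TRUE)

  cfg <- pipeline_config(
    input = path, dialect = "csv",
    spec = if (preset == "dataset1") spec_dataset1() else spec_dataset2(),
    class_attr = syn_cfg$class_attr,
    select = colnames(gen$table),
    min_support = min_support, min_confidence = min_confidence,
    out_dir = out_dir,
    dataset_label = paste0("synthetic-", preset)
  )
  res <- run_pipeline(cfg)
  res$truth <- gen$truth
  res$syn_config <- syn_cfg
  res
}

#' Read a pipeline configuration from JSON
#'
#' The file mirrors [pipeline_config()] fields. `spec` is either the name of
#' a bundled preset (`"dataset1"` / `"dataset2"`) or a map
#' `attribute -> {type, ...}` with types `categorical` (optional `recode`,
#' `strip`), `boolean`, `normal_range` (`lo`, `hi`), `bins` (`breaks`,
#' optional `labels`), `threshold` (`cut`, optional `labels`).
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("input", "spec", "class_attr")
  if (is.character(cfg$spec) && length(cfg$spec) == 1) required <- c("input", "spec")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0) {
    stop("missing config key(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  spec <- if (is.character(cfg$spec)) cfg$spec else spec_from_list(cfg$spec)
  pipeline_config(
    input = cfg$input,
    dialect = cfg$dialect %||% "csv",
    spec = spec,
    class_attr = cfg$class_attr,
    col_names = cfg$col_names,
    select = cfg$select,
    rename = if (!is.null(cfg$rename)) unlist(cfg$rename),
    min_support = cfg$min_support %||% 0.6,
    min_confidence = cfg$min_confidence %||% 0.9,
    max_antecedent = cfg$max_antecedent %||% Inf,
    out_of_range = cfg$out_of_range %||% "error",
    metric_tolerance = cfg$metric_tolerance %||% 0,
    out_dir = cfg$out_dir,
    dataset_label = cfg$dataset_label
  )
}

spec_from_list <- function(x) {
  rules <- lapply(names(x), function(a) {
    r <- x[[a]]
    switch(r$type,
      categorical = rule_categorical(recode = if (!is.null(r$recode)) unlist(r$recode),
                                     strip = r$strip),
      boolean = rule_boolean(),
      normal_range = rule_normal_range(r$lo, r$hi),
      bins = rule_bins(unlist(r$breaks), if (!is.null(r$labels)) unlist(r$labels)),
      threshold = rule_threshold(r$cut, if (!is.null(r$labels)) unlist(r$labels)),
      stop("unknown rule type in config: ", r$type, call. = FALSE)
    )
  })
  names(rules) <- names(x)
  disc_spec(rules)
}
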