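## End-to-end orchestration: cohort build (or synthetic generation), SPFA
## training, subphenotyping, topic triage and trait screening, with all
## artifacts written to disk and a machine-readable summary. One master
## seed fans out to fixed per-stage sub-seeds so stages are independently
## reproducible.

#' Validate pipeline input files
#'
#' Checks that the event table (and optional mapping tables) parse:
#' schema, ISO dates, flag domains, known code systems. Returns an
#' itemized findings table; fatal findings mean the pipeline would fail.
#'
#' @param events_path path to the event table.
#' @param diagnosis_map_path,drug_map_path optional mapping-table paths.
#' @return data.frame with columns `level` ("fatal"/"warning"), `item`,
#'   `message`; zero rows when everything is well-formed.
#' @export
validate_inputs <- function(events_path, diagnosis_map_path = NULL,
                            drug_map_path = NULL) {
  findings <- list()
  note <- function(level, item, msg)
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, item = item, message = msg)
  if (!file.exists(events_path)) {
    note("fatal", "events", paste("unreadable file:", events_path))
  } else {
    ev <- tryCatch(read_events(events_path), error = function(e) e,
                   warning = function(w) w)
    if (inherits(ev, "error"))
      note("fatal", "events", conditionMessage(ev))
    else if (inherits(ev, "warning"))
      note("warning", "events", conditionMessage(ev))
  }
  for (p in list(c("diagnosis_map", diagnosis_map_path %||% NA),
                 c("drug_map", drug_map_path %||% NA))) {
    if (is.na(p[2])) next
    if (!file.exists(p[2])) { note("fatal", p[1], "unreadable file"); next }
    m <- tryCatch(read_code_map(p[2]), error = function(e) e)
    if (inherits(m, "error")) note("fatal", p[1], conditionMessage(m))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(), item = character(),
                  message = character())
}

#' Run the full subphenotyping pipeline
#'
#' Executes cohort building (from an event file) or synthetic cohort
#' generation, SPFA training, k-means subphenotyping, topic triage and
#' trait screening, writing every artifact under `out_dir`: the feature
#' matrix (matrix-market + sidecars), the training trace CSV, cluster
#' assignments CSV, the silhouette table, the per-topic report CSV, 2-D
#' embedding coordinates, and `summary.json` with group sizes, purities,
#' active topics and the chosen cluster count. Stage failures propagate
#' with the stage named.
#'
#' @param out_dir output directory.
#' @param events_path optional event-table path; when `NULL` a synthetic
#'   cohort ([simulate_cohort()]) is generated instead.
#' @param cohort optional [cohort_config()] (required with
#'   `events_path`).
#' @param diagnosis_map_path,drug_map_path optional mapping tables.
#' @param sim arguments for [simulate_cohort()] when synthetic.
#' @param train arguments for [spfa()] (e.g. `K`, `epochs`).
#' @param analysis list of analysis settings: `C` or `C_grid`, `alpha`,
#'   `top_m`, `M`.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return the summary list, invisibly (also written as JSON).
#' @export
run_pipeline <- function(out_dir, events_path = NULL, cohort = NULL,
                         diagnosis_map_path = NULL, drug_map_path = NULL,
                         sim = list(), train = list(),
                         analysis = list(), seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## --- cohort ---
  if (!is.null(events_path)) {
    co <- stage("cohort", {
      if (is.null(cohort)) stop("a cohort_config is required")
      ev <- read_events(events_path)
      dxm <- if (!is.null(diagnosis_map_path)) read_code_map(diagnosis_map_path)
      rxm <- if (!is.null(drug_map_path)) read_code_map(drug_map_path)
      build_cohort(ev, cohort, dxm, rxm)
    })
    X <- co$X; y <- co$y
    stage("cohort-io", write_cohort(co, file.path(out_dir, "cohort")))
  } else {
    simres <- stage("simulate", do.call(simulate_cohort,
      modifyList(list(seed = derive_seed(seed, "pipeline-sim")), sim)))
    X <- simres$X; y <- simres$y
    co <- list(X = X, y = y, patient_ids = colnames(X),
               feature_names = rownames(X))
    stage("cohort-io", {
      dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE)
      Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE),
                      file.path(out_dir, "cohort", "matrix.mtx"))
      writeLines(rownames(X), file.path(out_dir, "cohort", "features.txt"))
      writeLines(colnames(X), file.path(out_dir, "cohort", "patients.txt"))
      write.csv(data.frame(patient_id = colnames(X), y = y),
                file.path(out_dir, "cohort", "labels.csv"),
                row.names = FALSE)
    })
  }
  ## --- train ---
  fit <- stage("train", do.call(spfa, modifyList(
    list(X = X, y = y, K = 10, seed = derive_seed(seed, "pipeline-train")),
    train)))
  write.csv(fit$trace, file.path(out_dir, "training_trace.csv"),
            row.names = FALSE)
  prop <- predict(fit, type = "proportions")
  act <- active_topics(prop)
  ## --- subphenotype ---
  st <- stage("subphenotype", do.call(subphenotype, modifyList(
    list(object = fit, y = y, seed = derive_seed(seed, "pipeline-cluster")),
    analysis[intersect(names(analysis), c("C", "C_grid", "restarts"))])))
  write.csv(data.frame(patient_id = co$patient_ids, cluster = st$cluster,
                       subgroup = st$subgroup, y = y),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  if (!is.null(st$silhouette))
    write.csv(st$silhouette, file.path(out_dir, "silhouette.csv"),
              row.names = FALSE)
  emb <- stage("embed", embed_2d(t(prop),
                                 seed = derive_seed(seed, "pipeline-embed")))
  write.csv(data.frame(patient_id = co$patient_ids, emb,
                       cluster = st$cluster, y = y),
            file.path(out_dir, "embedding.csv"), row.names = FALSE)
  ## --- topics ---
  ts <- stage("topics", topic_stats(fit, st$subgroup, X = X,
                alpha = analysis$alpha %||% 0.05,
                top_m = analysis$top_m %||% 3,
                M = analysis$M %||% 5))
  write.csv(ts, file.path(out_dir, "topic_report.csv"), row.names = FALSE)
  ## --- baseline screening on the most prevalent features ---
  bs <- stage("baseline", {
    keep <- order(-rowMeans(X))[seq_len(min(20, nrow(X)))]
    cohort_summary(X[keep, , drop = FALSE], y)
  })
  write.csv(as.data.frame(bs), file.path(out_dir, "trait_screen.csv"),
            row.names = FALSE)
  ## --- summary ---
  gp <- st$group_purity
  sae_row <- gp[gp$group == "SAE", ]
  non_row <- gp[gp$group == "non-SAE", ]
  summary <- list(
    seed = seed,
    n_patients = ncol(X), n_features = nrow(X),
    sae_prevalence = mean(y),
    K = fit$config$K, n_active_topics = act$n_active,
    C = st$C,
    training_auc = fit$trace$auc[nrow(fit$trace)],
    sae_group = list(n = if (nrow(sae_row)) sae_row$n else 0,
                     n_sae = if (nrow(sae_row)) sae_row$n_sae else 0,
                     purity = if (nrow(sae_row)) sae_row$frac_sae else NA),
    nonsae_group = list(n = if (nrow(non_row)) non_row$n else 0,
                        n_without_sae = if (nrow(non_row))
                          non_row$n - non_row$n_sae else 0,
                        purity = if (nrow(non_row)) non_row$frac_nonsae
                        else NA),
    topic_categories = as.list(table(ts$category)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
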