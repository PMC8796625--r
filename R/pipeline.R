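#' Pipeline configuration with study defaults
#'
#' Collects every stage parameter with its study default: 30 fps, 20-minute
#' sessions, 15 principal components, 15 ARHMM states, 8 ensemble fits,
#' 44 consensus syllables, 200-550 Hz order-2 Butterworth detection band,
#' 4 oscillations at 3x a 250 ms baseline SD, alpha 0.05 and a 0.01% edge
#' threshold. Any subset can be overridden; unknown names are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fps = 30, minutes = 20,
    n_components = 15, K = 15, L = 1L, R = 8L,
    max_iter = 200L, tol = 1e-4,
    n_clusters = 44, linkage = "mcquitty", count_weighted = FALSE,
    alpha = 0.05, p_adjust = "none", gate_on_omnibus = TRUE,
    edge_threshold = 0.01,
    eeg_fs = 4000, band = c(200, 550), filter_order = 2, zero_phase = TRUE,
    min_oscillations = 4, amplitude_ratio = 3, baseline_ms = 250,
    merge_gap_ms = 10,
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

study_defaults <- function() unclass(pipeline_config())

#' Validate a pipeline configuration
#'
#' Range-checks every field against the module invariants and notes
#' departures from the study defaults. Invalid values are enumerated, never
#' silently corrected.
#'
#' @param config a [pipeline_config] (or plain named list; missing fields are
#'   filled with study defaults and reported).
#' @return list of class `config_report`: `config` (completed), `errors`,
#'   `warnings`, `filled`, and `ok`.
#' @export
validate_config <- function(config) {
  defaults <- study_defaults()
  filled <- setdiff(names(defaults), names(config))
  full <- defaults
  full[names(config)[names(config) %in% names(defaults)]] <-
    config[names(config) %in% names(defaults)]
  errors <- character(0)
  warn <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(full$fps > 0, "fps must be positive")
  chk(full$minutes > 0, "minutes must be positive")
  chk(full$K >= 1, "K must be >= 1")
  chk(full$n_components >= 1, "n_components must be >= 1")
  chk(full$L >= 1, "L must be >= 1")
  chk(full$R >= 1, "R must be >= 1")
  chk(full$tol > 0, "tol must be positive")
  chk(full$n_clusters >= 1, "n_clusters must be >= 1")
  chk(full$alpha > 0 && full$alpha < 1, "alpha must be in (0, 1)")
  chk(full$edge_threshold >= 0, "edge_threshold must be non-negative")
  chk(length(full$band) == 2 && full$band[1] > 0 &&
        full$band[1] < full$band[2], "band must be an increasing pair")
  chk(full$band[2] < full$eeg_fs / 2,
      "band top must be below the EEG Nyquist frequency (fs/2)")
  chk(full$min_oscillations >= 1, "min_oscillations must be >= 1")
  chk(full$amplitude_ratio > 0, "amplitude_ratio must be positive")
  chk(full$baseline_ms > 0, "baseline_ms must be positive")
  for (f in setdiff(names(defaults), c("seed"))) {
    if (is.character(defaults[[f]]) || is.logical(defaults[[f]])) next
    if (!identical(as.numeric(unlist(full[[f]])),
                   as.numeric(unlist(defaults[[f]]))))
      warn <- c(warn, sprintf("%s departs from the study default", f))
  }
  structure(list(config = structure(full, class = "pipeline_config"),
                 errors = errors, warnings = warn, filled = filled,
                 ok = length(errors) == 0L),
            class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  cat(sprintf("config report: %s\n", if (x$ok) "OK" else "INVALID"))
  if (length(x$errors)) cat("errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  if (length(x$filled))
    cat("filled with study defaults:", paste(x$filled, collapse = ", "), "\n")
  if (length(x$warnings))
    cat("notes:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config].
#' @return `read_config` returns a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rep <- validate_config(raw)
  if (!rep$ok) stop("invalid config: ", paste(rep$errors, collapse = "; "))
  rep$config
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize a fitted ARHMM as JSON
#'
#' @param model an [arhmm_model].
#' @param path output file.
#' @export
write_arhmm_json <- function(model, path) {
  obj <- list(K = model$K, P = model$P, L = model$L,
              trans = model$trans, init = model$init,
              A = model$A, b = model$b, Q = model$Q)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_arhmm_json
#' @export
read_arhmm_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  arhmm_model(trans = o$trans,
              A = lapply(seq_len(o$K), function(k) matrix_from_json(o$A, k)),
              b = lapply(seq_len(o$K), function(k) as.numeric(o$b[[k]])),
              Q = lapply(seq_len(o$K), function(k) matrix_from_json(o$Q, k)),
              init = as.numeric(o$init), L = o$L)
}

matrix_from_json <- function(x, k) {
  # equal-shaped per-state matrices simplify to a K x P x P array on read
  if (is.array(x) && length(dim(x)) == 3L)
    return(matrix(as.numeric(x[k, , ]), dim(x)[2], dim(x)[3]))
  m <- x[[k]]
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  as.matrix(m)
}

#' Export the consensus dendrogram
#'
#' Writes the WPGMA linkage tree as Newick text and its merge table (pair
#' indices and heights) as CSV, for review of the syllable split.
#'
#' @param map a `syllable_map` from [cluster_signatures].
#' @param newick_path,merges_path output files (`NULL` to skip either).
#' @export
export_dendrogram <- function(map, newick_path = NULL, merges_path = NULL) {
  tree <- map$tree
  if (is.null(tree)) {                # degenerate single-signature map
    if (!is.null(merges_path))
      write.csv(data.frame(left = integer(), right = integer(),
                           height = numeric()), merges_path,
                row.names = FALSE)
    if (!is.null(newick_path)) writeLines("();", newick_path)
    return(invisible(map))
  }
  if (!is.null(merges_path)) {
    mg <- data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
                     height = tree$height)
    write.csv(mg, merges_path, row.names = FALSE)
  }
  if (!is.null(newick_path)) {
    phy <- ape::as.phylo(tree)
    ape::write.tree(phy, file = newick_path)
  }
  invisible(map)
}

write_label_csv <- function(labels_list, info, path) {
  rows <- lapply(seq_along(labels_list), function(i) {
    l <- labels_list[[i]]
    data.frame(animal_id = info$animal_id[i], genotype = info$genotype[i],
               frame = seq_along(l), syllable = as.integer(l))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

read_label_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$animal_id)
  lapply(ids, function(a) {
    sub <- d[d$animal_id == a, ]
    list(animal_id = a, genotype = sub$genotype[1],
         labels = sub$syllable, valid_mask = !is.na(sub$syllable))
  })
}

#' Run the behavioral pipeline end to end
#'
#' Stages: PCA embedding of the merged cohort, ensemble ARHMM fitting,
#' consensus syllable clustering, per-animal metrics, genotype comparison,
#' and per-genotype transition networks. Every artifact is written under
#' `out_dir` together with a manifest recording the configuration and
#' per-stage status; with `resume = TRUE`, stages whose artifacts already
#' exist under an identical configuration are reloaded instead of recomputed,
#' so deleting an intermediate regenerates only the downstream stages.
#'
#' @param cohort list of `list(session, truth)` pairs or `pose_session`s.
#' @param config a [pipeline_config].
#' @param out_dir output directory (created if needed).
#' @param resume reuse on-disk artifacts when the configuration matches.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = "moseq_run", resume = FALSE) {
  rep <- validate_config(config)
  if (!rep$ok)
    stop("invalid config: ", paste(rep$errors, collapse = "; "))
  config <- rep$config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg_plain <- lapply(unclass(config), function(v) unname(v))
  prev <- if (resume && file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else NULL
  cfg_match <- !is.null(prev) &&
    identical(jsonlite::toJSON(cfg_plain, digits = NA, auto_unbox = TRUE),
              jsonlite::toJSON(prev$config, digits = NA, auto_unbox = TRUE))
  reuse <- function(files) {
    cfg_match && all(file.exists(file.path(out_dir, files)))
  }
  stages <- character(0)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    stages[[name]] <<- sprintf("%.2fs", proc.time()[["elapsed"]] - t0)
    message(sprintf("[moseqr] stage %-10s %s", name, stages[[name]]))
    res
  }

  sessions <- lapply(cohort, as_pose_session)

  # embed
  pca <- t_stage("embed", fit_pca(sessions, config$n_components))
  scores <- embed_sessions(pca, sessions)

  # ensemble fit
  ens_file <- "ensemble_labels.csv"
  if (reuse(ens_file)) {
    ens_df <- read.csv(file.path(out_dir, ens_file))
    ensemble <- rebuild_ensemble(ens_df, config)
    stages[["fit"]] <- "resumed"
  } else {
    ensemble <- t_stage("fit", run_ensemble(
      scores, K = config$K, L = config$L, R = config$R,
      master_seed = config$seed, max_iter = config$max_iter,
      tol = config$tol))
    ens_rows <- do.call(rbind, lapply(seq_along(scores), function(si) {
      m <- vapply(ensemble$fits, function(f)
        as.integer(f$state_seqs[[si]]),
        integer(length(scores[[si]]$valid_mask)))
      colnames(m) <- sprintf("fit_%d", seq_len(config$R))
      cbind(data.frame(animal_id = scores[[si]]$animal_id,
                       genotype = scores[[si]]$genotype,
                       frame = seq_len(nrow(m))), m)
    }))
    write.csv(ens_rows, file.path(out_dir, ens_file), row.names = FALSE)
    for (r in seq_len(config$R))
      write_arhmm_json(ensemble$fits[[r]]$model,
                       file.path(out_dir, sprintf("model_fit%d.json", r)))
  }

  # consensus
  cons_files <- c("syllable_labels.csv", "signature_map.csv",
                  "dendrogram_merges.csv", "dendrogram.nwk")
  if (reuse(cons_files)) {
    lab_sessions <- read_label_csv(file.path(out_dir, "syllable_labels.csv"))
    for (i in seq_along(lab_sessions)) {
      lab_sessions[[i]]$fps <- config$fps
    }
    assignment <- NULL
    stages[["consensus"]] <- "resumed"
  } else {
    assignment <- t_stage("consensus", {
      sigs <- build_signatures(ensemble)
      nc <- min(config$n_clusters, length(sigs$catalog$key))
      map <- cluster_signatures(sigs$catalog, n_clusters = nc,
                                linkage = config$linkage,
                                count_weighted = config$count_weighted)
      structure(list(labels = assign_syllables(sigs$signatures, map),
                     map = map, catalog = sigs$catalog,
                     session_info = ensemble$session_info,
                     n_clusters = nc),
                class = "syllable_assignment")
    })
    write_label_csv(assignment$labels, assignment$session_info,
                    file.path(out_dir, "syllable_labels.csv"))
    write.csv(assignment$map$map, file.path(out_dir, "signature_map.csv"),
              row.names = FALSE)
    export_dendrogram(assignment$map,
                      newick_path = file.path(out_dir, "dendrogram.nwk"),
                      merges_path = file.path(out_dir, "dendrogram_merges.csv"))
    lab_sessions <- as_label_sessions(assignment)
  }

  # metrics
  metrics <- t_stage("metrics", cohort_metrics(lab_sessions))
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  # compare
  comparison <- t_stage("compare", compare_groups(
    metrics, alpha = config$alpha, p_adjust = config$p_adjust,
    gate_on_omnibus = config$gate_on_omnibus))
  write.csv(comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)

  # network
  graphs <- t_stage("network", {
    genos <- unique(vapply(lab_sessions, `[[`, "", "genotype"))
    S <- max(unlist(lapply(lab_sessions, function(s)
      max(s$labels, na.rm = TRUE))))
    gl <- lapply(genos, function(g) {
      tg <- build_transition_graph(
        Filter(function(s) s$genotype == g, lab_sessions),
        n_syllables = S, edge_threshold = config$edge_threshold)
      export_transition_graph(
        tg, graphml_path = file.path(out_dir, sprintf("graph_%s.graphml", g)),
        edges_path = file.path(out_dir, sprintf("edges_%s.csv", g)))
      tg
    })
    names(gl) <- genos
    gl
  })

  manifest <- list(config = cfg_plain, stages = as.list(stages),
                   sessions = vapply(sessions, `[[`, "", "animal_id"),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(pca = pca, ensemble = ensemble,
                 assignment = assignment, metrics = metrics,
                 comparison = comparison, graphs = graphs,
                 manifest = manifest, out_dir = out_dir))
}

# Reconstruct the minimal ensemble surface (labels only) from its CSV.
rebuild_ensemble <- function(df, config) {
  ids <- unique(df$animal_id)
  fit_cols <- grep("^fit_", names(df), value = TRUE)
  fits <- lapply(seq_along(fit_cols), function(r) {
    seqs <- lapply(ids, function(a) df[df$animal_id == a, fit_cols[r]])
    list(state_seqs = seqs, fit_id = r)
  })
  structure(list(fits = fits, R = length(fit_cols), K = config$K,
                 L = config$L,
                 session_info = data.frame(
                   animal_id = ids,
                   genotype = vapply(ids, function(a)
                     df$genotype[df$animal_id == a][1], ""),
                   fps = config$fps)),
            class = "ensemble_result")
}
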