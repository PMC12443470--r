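# Orchestration of the full workflow: ensemble + experimental curve ->
# per-frame chi2 -> best model -> descriptor panel -> cross-species PCA;
# ensemble -> RMSF/DCCM/clusters/region correlation.

saxs_config_keys <- c("species", "selection", "chain_a", "chain_b",
                      "marker1", "marker2", "q_unit", "normalization",
                      "fit_background", "pca_standardize", "out_dir", "seed")
dyn_config_keys <- c("ensemble", "structure", "selection", "cutoff",
                     "region_1", "region_2", "chain_1", "chain_2",
                     "out_dir", "seed")

#' Read a run configuration
#'
#' Accepts JSON (file starting with `{`) or plain-text `key = value` lines
#' (`#` comments allowed; dotted keys such as `species.WT.ensemble` nest).
#' Unknown keys are rejected.
#'
#' @param path configuration file.
#' @param kind `"saxs"` or `"dynamics"`, selecting the allowed key set.
#' @return named list.
#' @export
read_run_config <- function(path, kind = c("saxs", "dynamics")) {
  kind <- match.arg(kind)
  txt <- readLines(path, warn = FALSE)
  cfg <- if (grepl("^\\s*\\{", paste(txt, collapse = ""))) {
    jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else {
    cfg <- list()
    for (ln in txt) {
      ln <- sub("#.*$", "", ln)
      if (!grepl("=", ln)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
      if (!nzchar(key)) next
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
      if (identical(val, "true")) val <- TRUE
      if (identical(val, "false")) val <- FALSE
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      cfg <- nested_assign(cfg, parts, val)
    }
    cfg
  }
  allowed <- if (kind == "saxs") saxs_config_keys else dyn_config_keys
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

nested_assign <- function(lst, parts, val) {
  if (length(parts) == 1L) {
    lst[[parts]] <- val
    return(lst)
  }
  sub <- lst[[parts[1L]]]
  if (is.null(sub)) sub <- list()
  lst[[parts[1L]]] <- nested_assign(sub, parts[-1L], val)
  lst
}

cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

check_readable <- function(path, stage) {
  if (!file.exists(path))
    stop("[", stage, "] input file not found: ", path)
  path
}

#' Run the SAXS model-selection pipeline
#'
#' For every species in the configuration: read the conformer ensemble and
#' the experimental curve, screen each frame by chi-square, write the
#' per-frame chi-square table and the best-fitting model, and compute the
#' 13-variable descriptor panel per frame. The combined labeled table is then
#' compared across species by PCA. All outputs are TSV/JSON with fixed
#' filenames; the resolved configuration is serialized into the output
#' directory, and identical configurations give byte-identical outputs.
#'
#' @param config path to a configuration file or an equivalent named list.
#'   Required keys: `species` (named list with `ensemble` and `exp` paths)
#'   and `out_dir`. Optional: `selection` (default "CA"), `chain_a`,
#'   `chain_b`, `marker1`, `marker2`, `q_unit`, `normalization`,
#'   `fit_background`, `pca_standardize`, `seed`.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_saxs_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config, "saxs") else config
  unknown <- setdiff(names(cfg), saxs_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$species) || !length(cfg$species))
    stop("[config] no species defined")
  out_dir <- cfg_get(cfg, "out_dir", stop("[config] out_dir is required"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  selection <- cfg_get(cfg, "selection", "CA")
  chain_a <- cfg_get(cfg, "chain_a", "A"); chain_b <- cfg_get(cfg, "chain_b", "B")
  marker1 <- as.integer(cfg_get(cfg, "marker1", 173L))
  marker2 <- as.integer(cfg_get(cfg, "marker2", 470L))
  q_unit <- cfg_get(cfg, "q_unit", "inverse-A")
  normalization <- cfg_get(cfg, "normalization", "n-p")
  fit_background <- isTRUE(cfg_get(cfg, "fit_background", FALSE))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  panels <- list(); summary <- list()
  for (sp in names(cfg$species)) {
    entry <- cfg$species[[sp]]
    ens <- read_ensemble(check_readable(entry$ensemble, paste0("read:", sp)))
    exp_curve <- read_saxs_curve(check_readable(entry$exp, paste0("read:", sp)),
                                 q_unit = q_unit)
    scr <- tryCatch(
      screen_ensemble(ens, exp_curve, selection = selection,
                      fit_background = fit_background,
                      normalization = normalization),
      error = function(e) stop("[screen:", sp, "] ", conditionMessage(e)))
    write_tsv(scr$table, file.path(out_dir, paste0("chi2_", sp, ".tsv")))
    best <- ensemble_frame(ens, scr$best_frame)
    write_structure(best, file.path(out_dir, paste0("best_", sp, ".pdb")))
    pan <- tryCatch(
      descriptor_table(ens, chain_a, chain_b, marker1, marker2,
                       label_prefix = sp),
      error = function(e) stop("[descriptors:", sp, "] ", conditionMessage(e)))
    pan$species <- sp
    panels[[sp]] <- pan
    best_panel <- pan[scr$best_frame, ]
    summary[[sp]] <- list(
      best_frame = scr$best_frame,
      chi2 = scr$chi2_per_frame[scr$best_frame],
      descriptors = as.list(best_panel[setdiff(names(best_panel),
                                               c("model_label", "species"))]))
  }
  all_pan <- do.call(rbind, panels)
  write_tsv(all_pan, file.path(out_dir, "descriptors.tsv"))
  pca_tab <- all_pan[, c("model_label", descriptor_names())]
  pca_tab$model_label <- all_pan$species
  pca <- tryCatch(
    run_pca(pca_tab, standardize = isTRUE(cfg_get(cfg, "pca_standardize", TRUE))),
    error = function(e) stop("[pca] ", conditionMessage(e)))
  write_tsv(data.frame(species = pca$model_labels, round(pca$scores, 6)),
            file.path(out_dir, "pca_scores.tsv"))
  write_tsv(data.frame(variable = rownames(pca$loadings),
                       round(pca$loadings, 6)),
            file.path(out_dir, "pca_loadings.tsv"))
  write_tsv(data.frame(component = seq_along(pca$explained_variance_ratio),
                       evr = round(pca$explained_variance_ratio, 6)),
            file.path(out_dir, "pca_variance.tsv"))
  out <- list(species = summary,
              pca_explained_variance = pca$explained_variance_ratio,
              tool = "dimerhinge", version = "0.1.0")
  jsonlite::write_json(out, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  invisible(out)
}

#' Run the ensemble-dynamics pipeline
#'
#' Computes the RMSF/B-factor table (with experimental B-factors when a
#' crystal structure is supplied), the DCCM (matrix and flat triplet list),
#' the gromos cluster table, and a region-vs-region correlation summary.
#'
#' @param config path to a configuration file or an equivalent named list.
#'   Required: `ensemble`, `cutoff`, `out_dir`. Optional: `structure`,
#'   `selection`, `region_1`, `region_2`, `chain_1`, `chain_2`, `seed`.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_dynamics_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config, "dynamics") else config
  unknown <- setdiff(names(cfg), dyn_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out_dir <- cfg_get(cfg, "out_dir", stop("[config] out_dir is required"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  selection <- cfg_get(cfg, "selection", "CA")
  ens <- read_ensemble(check_readable(cfg$ensemble, "read"))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  prof <- rmsf_profile(ens, selection = selection)
  if (all(prof$rmsf == 0)) warning("static ensemble: all RMSF values are zero")
  if (!is.null(cfg$structure)) {
    xt <- read_structure(check_readable(cfg$structure, "read"))
    idx <- resolve_selection(xt, selection)
    at <- xt$atoms[idx, ]
    hit <- match(paste(prof$chain, prof$res_id), paste(at$chain, at$res_seq))
    prof$b_exp <- at$b[hit]
  }
  write_tsv(prof, file.path(out_dir, "rmsf.tsv"))
  cc <- dccm(ens, selection = selection)
  mat <- as.data.frame(round(cc$matrix, 6))
  names(mat) <- paste0(cc$chain, cc$res_ids)
  write_tsv(cbind(res = paste0(cc$chain, cc$res_ids), mat),
            file.path(out_dir, "dccm.tsv"))
  if (is.null(cfg$cutoff)) stop("[config] clustering cutoff is required")
  cl <- gromos_cluster(ens, cutoff = as.numeric(cfg$cutoff),
                       selection = selection)
  write_tsv(data.frame(frame = seq_along(cl$assignments),
                       cluster = cl$assignments),
            file.path(out_dir, "clusters.tsv"))
  summary <- list(n_frames = n_frames(ens),
                  n_clusters = length(cl$centers),
                  cluster_centers = cl$centers,
                  rmsf_mean = mean(prof$rmsf),
                  tool = "dimerhinge", version = "0.1.0")
  if (!is.null(cfg$region_1) && !is.null(cfg$region_2)) {
    rc <- region_cross_correlation(cc, as.integer(cfg$region_1),
                                   as.integer(cfg$region_2),
                                   cfg$chain_1, cfg$chain_2)
    summary$region_correlation <- rc
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  invisible(summary)
}
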