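# Matrix I/O and workflow orchestration. Matrices are serialized samples in
# rows (n x p), first column = sample IDs, header row = feature IDs — note
# this is the transpose of the features-in-rows convention of much omics
# tooling.

#' Read a samples-by-features matrix with IDs from CSV/TSV
#'
#' @param path file path; delimiter inferred from the extension unless given.
#' @param delimiter field separator, or `NULL` to auto-detect (`.tsv`/`.txt`
#'   use tab, otherwise comma).
#' @param weight layer weight passed to [omics_layer()].
#' @param name optional layer name (defaults to the file name).
#' @return an [omics_layer()].
#' @export
read_matrix <- function(path, delimiter = NULL, weight = 1, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("no feature columns in ", path)
  ids <- dt[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(dt[, -1])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals), arr.ind = TRUE)
    coord <- if (nrow(bad) > 0) {
      sprintf(" (row %d, column %d)", bad[1, 1], bad[1, 2] + 1L)
    } else ""
    stop("non-numeric cell in ", path, coord)
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("missing value in ", path,
         sprintf(" (row %d, column %d)", bad[1, 1], bad[1, 2] + 1L))
  }
  if (is.null(name)) name <- basename(path)
  omics_layer(vals, sample_ids = ids, feature_ids = colnames(vals),
              weight = weight, name = name)
}

#' Write a samples-by-features matrix with IDs to CSV/TSV
#'
#' @param x an [omics_layer()] or a matrix with dimnames.
#' @param path output path; delimiter inferred from the extension unless
#'   given.
#' @param delimiter field separator, or `NULL` to auto-detect.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = NULL) {
  if (inherits(x, "omics_layer")) x <- x$values
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  dt <- data.table::data.table(sample_id = rownames(x))
  for (j in seq_len(ncol(x))) dt[[colnames(x)[j]]] <- x[, j]
  data.table::fwrite(dt, path, sep = delimiter)
  invisible(path)
}

write_labels <- function(sample_ids, labels, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = sample_ids, cluster = labels),
    path, sep = "\t")
  invisible(path)
}

#' Load a run configuration from JSON (with optional overrides)
#'
#' The configuration names the input layers and run parameters:
#' \preformatted{
#' {
#'   "layers": [{"path": "expr.csv", "sd_min": 1.5,
#'               "max_zero_prop": null, "weight": "auto"}, ...],
#'   "k": 3,            # or "k_range": [2, 8] for select-k
#'   "n_init": 30, "tol": 1e-4, "stability_count": 50, "max_iter": 200,
#'   "seed": 1, "out_dir": "results",
#'   "measures": ["cpi", "silhouette"]
#' }
#' }
#'
#' @param path JSON file path.
#' @param overrides named list replacing top-level keys.
#' @return the configuration list.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

load_layers <- function(cfg) {
  if (is.null(cfg$layers) || length(cfg$layers) == 0)
    stop("config must name at least one layer")
  layers <- lapply(cfg$layers, function(ls) {
    l <- read_matrix(ls$path, name = ls$name)
    sd_min <- ls$sd_min
    mzp <- ls$max_zero_prop
    if (!is.null(sd_min) || !is.null(mzp))
      l <- filter_features(l, sd_min = sd_min, max_zero_prop = mzp)
    l
  })
  coll <- multi_omics(layers)
  coll <- prepare_collection(coll)
  user_w <- vapply(cfg$layers, function(ls) {
    if (is.null(ls$weight)) "auto" else as.character(ls$weight)
  }, character(1))
  if (all(user_w == "auto")) {
    coll <- set_weights(coll, "auto")
  } else {
    w_auto <- compute_weights(coll)
    w <- ifelse(user_w == "auto", w_auto, suppressWarnings(as.numeric(user_w)))
    if (anyNA(w)) stop("layer weight must be a number or \"auto\"")
    coll <- set_weights(coll, w)
  }
  coll
}

default_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Fit the joint factorization at fixed k from a configuration
#'
#' Preprocesses the configured layers (feature filters, non-negative shift,
#' unit-max rescale, weights), runs the multi-start fit, and writes to
#' `out_dir`: `labels.tsv` (sample_id, cluster), `W.csv`, `H_<i>.csv`,
#' `consensus.csv`, and `run_metadata.json` (seed, k, weights, iterations,
#' final objective, convergence reason). Partial outputs are removed on error.
#'
#' @param config a configuration list (see [read_config()]) or a JSON path.
#' @return the fitted `nmf_fit`, invisibly, with `$paths` of written files.
#' @export
run_fit <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (is.null(cfg$k)) stop("config must set a fixed k for fit")
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_error <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    coll <- load_layers(cfg)
    fit <- run_multistart(
      coll, k = as.integer(cfg$k),
      n_init = as.integer(default_num(cfg$n_init, 30)),
      base_seed = as.integer(default_num(cfg$seed, 0)),
      tol = default_num(cfg$tol, 1e-4),
      stability_count = as.integer(default_num(cfg$stability_count, 50)),
      max_iter = as.integer(default_num(cfg$max_iter, 200)))
    paths <- c(labels = file.path(out_dir, "labels.tsv"),
               W = file.path(out_dir, "W.csv"),
               consensus = file.path(out_dir, "consensus.csv"),
               metadata = file.path(out_dir, "run_metadata.json"))
    written <- paths
    write_labels(fit$sample_ids, fit$labels, paths["labels"])
    W <- fit$W
    dimnames(W) <- list(fit$sample_ids, paste0("basis", seq_len(fit$k)))
    write_matrix(W, paths["W"])
    cons <- fit$consensus
    dimnames(cons) <- list(fit$sample_ids, fit$sample_ids)
    write_matrix(cons, paths["consensus"])
    for (i in seq_along(fit$H)) {
      hp <- file.path(out_dir, sprintf("H_%d.csv", i))
      written <- c(written, hp)
      Hi <- fit$H[[i]]
      dimnames(Hi) <- list(paste0("basis", seq_len(fit$k)),
                           coll$layers[[i]]$feature_ids)
      # H is k x p; serialize as-is with basis rows labelled in column 1
      data.table::fwrite(data.table::data.table(basis = rownames(Hi),
                                                as.data.frame(Hi)),
                         hp, sep = ",")
      paths[paste0("H_", i)] <- hp
    }
    meta <- list(k = fit$k, seed = default_num(cfg$seed, 0),
                 n_init = default_num(cfg$n_init, 30),
                 weights = fit$theta, n_iter = fit$n_iter,
                 final_Q = tail_value(fit$objective_trace),
                 convergence_reason = fit$convergence_reason,
                 best_run = fit$best_run,
                 objective_trace = fit$objective_trace,
                 reconstruction_error_trace = fit$reconstruction_error_trace)
    jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    fit$paths <- paths
    invisible(fit)
  }, error = on_error)
}

#' Scan k and write the selection profile from a configuration
#'
#' Runs [scan_k()] over the configured `k_range` and writes to `out_dir`:
#' `k_profile.tsv` (tidy: measure, k, repetition, value) and
#' `k_selection.json` (chosen k per measure plus per-k means).
#'
#' @param config a configuration list or JSON path; must set `k_range`
#'   (two-element min/max or an explicit vector) and optionally `measures`.
#' @return the `k_profile`, invisibly, with `$paths`.
#' @export
run_select_k <- function(config) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (is.null(cfg$k_range)) stop("config must set k_range for select-k")
  kr <- as.integer(cfg$k_range)
  k_range <- if (length(kr) == 2) seq(kr[1], kr[2]) else kr
  measures <- if (is.null(cfg$measures)) {
    c("silhouette", "cophenetic", "dispersion", "rss", "cpi")
  } else unlist(cfg$measures)
  if ("rss" %in% measures && length(k_range) < 3)
    stop("RSS elbow needs a k_range of width >= 3")
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tryCatch({
    coll <- load_layers(cfg)
    cpi_cfg <- cpi_config(
      n_repeats = as.integer(default_num(cfg$n_repeats, 20)),
      train_fraction = default_num(cfg$train_frac, 2 / 3),
      n_init_train = as.integer(default_num(cfg$n_init_cpi, 10)),
      n_init_test = as.integer(default_num(cfg$n_init_cpi, 10)))
    prof <- scan_k(
      coll, k_range = k_range,
      n_init = as.integer(default_num(cfg$n_init, 30)),
      measures = measures,
      base_seed = as.integer(default_num(cfg$seed, 0)),
      cpi = cpi_cfg,
      tol = default_num(cfg$tol, 1e-4),
      stability_count = as.integer(default_num(cfg$stability_count, 50)),
      max_iter = as.integer(default_num(cfg$max_iter, 200)))
    paths <- c(profile = file.path(out_dir, "k_profile.tsv"),
               summary = file.path(out_dir, "k_selection.json"))
    written <- paths
    tidy <- do.call(rbind, lapply(names(prof$values), function(msr) {
      v <- prof$values[[msr]]
      data.frame(measure = msr,
                 k = rep(prof$k_range, each = nrow(v)),
                 repetition = rep(seq_len(nrow(v)), times = ncol(v)),
                 value = as.vector(v))
    }))
    tidy <- tidy[!is.na(tidy$value), ]
    data.table::fwrite(tidy, paths["profile"], sep = "\t")
    jsonlite::write_json(
      list(k_range = prof$k_range,
           selected = as.list(prof$selected),
           means = prof$mean),
      paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prof$paths <- paths
    invisible(prof)
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  })
}

#' Generate and write a synthetic dataset from CLI-style parameters
#'
#' Writes one CSV per layer, `truth.tsv` and `spec.json` into `out_dir`.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory.
#' @return the [simulate_multiomics()] result, invisibly, with `$paths`.
#' @export
run_simulate <- function(spec, out_dir) {
  sim <- simulate_multiomics(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_len(sim$collection$m)) {
    p <- file.path(out_dir, sprintf("layer%d.csv", i))
    write_matrix(sim$collection$layers[[i]], p)
    paths[sprintf("layer%d", i)] <- p
  }
  paths["truth"] <- file.path(out_dir, "truth.tsv")
  write_labels(sim$collection$sample_ids, sim$truth, paths["truth"])
  paths["spec"] <- file.path(out_dir, "spec.json")
  jsonlite::write_json(unclass(sim$spec), paths["spec"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  sim$paths <- paths
  invisible(sim)
}
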