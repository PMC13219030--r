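# File formats: a graph family is a directory with a manifest CSV
# (sample_id, path) plus one file per sample, either a dense CSV with node
# names as header row/column, or a TSV edge list with columns
# effect_id, cause_id, weight ('#'-prefixed comment lines allowed; edges
# not listed are zero, node universes come from nodes.csv). Indicators are
# a CSV with a sample_id column plus one column per indicator, with a YAML
# sidecar naming mechanism groupings and task type.

#' Write a graph family to a directory
#'
#' @param family A [graph_family()].
#' @param dir Output directory (created if missing).
#' @param digits Significant digits to keep; the default round-trips
#'   doubles losslessly for practical purposes.
#' @return `dir`, invisibly.
#' @export
write_family <- function(family, dir, digits = 15) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  W1 <- family$graphs[[1]]
  rn <- rownames(W1)
  cn <- colnames(W1)
  if (is.null(rn)) rn <- sprintf(if (family$bipartite) "e%03d" else "n%03d",
                                 seq_len(nrow(W1)))
  if (is.null(cn)) cn <- if (family$bipartite)
    sprintf("c%03d", seq_len(ncol(W1))) else rn
  nodes <- data.frame(role = c(rep("effect", length(rn)),
                               rep("cause", length(cn))),
                      id = c(rn, cn))
  utils::write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  paths <- sprintf("%s.csv", family$ids)
  for (k in seq_along(family$graphs)) {
    W <- signif(family$graphs[[k]], digits)
    df <- as.data.frame(W)
    colnames(df) <- cn
    df <- cbind(node = rn, df)
    utils::write.csv(df, file.path(dir, paths[k]), row.names = FALSE)
  }
  manifest <- data.frame(sample_id = family$ids, path = paths)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

read_graph_file <- function(path, effect_ids, cause_ids) {
  if (grepl("\\.tsv$", path)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(matrix(0, length(effect_ids), length(cause_ids),
                    dimnames = list(effect_ids, cause_ids)))
    }
    df <- utils::read.table(text = lines, sep = "\t",
                            col.names = c("effect_id", "cause_id", "weight"),
                            colClasses = c("character", "character",
                                           "numeric"))
    W <- matrix(0, length(effect_ids), length(cause_ids),
                dimnames = list(effect_ids, cause_ids))
    ri <- match(df$effect_id, effect_ids)
    ci <- match(df$cause_id, cause_ids)
    if (anyNA(ri)) {
      stop("unknown effect node id '", df$effect_id[which(is.na(ri))[1]],
           "' in ", basename(path))
    }
    if (anyNA(ci)) {
      stop("unknown cause node id '", df$cause_id[which(is.na(ci))[1]],
           "' in ", basename(path))
    }
    W[cbind(ri, ci)] <- df$weight
    W
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    rn <- as.character(df[[1]])
    W <- as.matrix(df[, -1, drop = FALSE])
    rownames(W) <- rn
    storage.mode(W) <- "double"
    W
  }
}

#' Read a graph family from a directory
#'
#' Sample order follows the manifest. Dense-CSV and edge-list-TSV dialects
#' may be mixed; edge lists require a `nodes.csv` file declaring the node
#' universe, and any edge naming an unknown node is an error.
#'
#' @param dir Directory containing `manifest.csv` (or a path to the
#'   manifest itself).
#' @param bipartite Logical; mark the family as effect-by-cause.
#' @return A [graph_family()].
#' @export
read_family <- function(dir, bipartite = FALSE) {
  manifest_path <- if (grepl("\\.csv$", dir)) dir else
    file.path(dir, "manifest.csv")
  base <- dirname(manifest_path)
  manifest <- utils::read.csv(manifest_path, colClasses = "character")
  if (!all(c("sample_id", "path") %in% names(manifest))) {
    stop("manifest must have sample_id and path columns")
  }
  nodes_path <- file.path(base, "nodes.csv")
  effect_ids <- cause_ids <- NULL
  if (file.exists(nodes_path)) {
    nodes <- utils::read.csv(nodes_path, colClasses = "character")
    effect_ids <- nodes$id[nodes$role == "effect"]
    cause_ids <- nodes$id[nodes$role == "cause"]
  }
  graphs <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    path <- file.path(base, manifest$path[k])
    if (grepl("\\.tsv$", path) && is.null(effect_ids)) {
      stop("edge-list files need a nodes.csv declaring the node universe")
    }
    W <- read_graph_file(path, effect_ids, cause_ids)
    graphs[[k]] <- W
  }
  dims <- vapply(graphs, function(g) paste(dim(g), collapse = "x"),
                 character(1))
  if (length(unique(dims)) > 1) {
    bad <- which(dims != dims[1])[1]
    stop("graph dimensions are inconsistent across the family; file '",
         manifest$path[bad], "' is ", dims[bad], " but expected ", dims[1])
  }
  graph_family(graphs, ids = manifest$sample_id, bipartite = bipartite)
}

#' Write an indicator table with its sidecar config
#'
#' @param indicators An [indicator_table()].
#' @param path CSV output path; a YAML sidecar `<path>.yml` records the
#'   mechanism groupings and task types.
#' @param ids Optional sample identifiers for the first column.
#' @return `path`, invisibly.
#' @export
write_indicators <- function(indicators, path, ids = NULL) {
  V <- indicators$values
  if (is.null(colnames(V))) colnames(V) <- sprintf("y%d", seq_len(ncol(V)))
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(nrow(V)))
  df <- cbind(data.frame(sample_id = ids), as.data.frame(V))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(groups = lapply(indicators$groups, function(g) colnames(V)[g]),
               task = as.list(stats::setNames(indicators$task,
                                              names(indicators$groups))))
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Read an indicator table
#'
#' @param path CSV with a `sample_id` column; mechanism groupings come from
#'   the YAML sidecar `<path>.yml` when present (otherwise all columns form
#'   one regression group).
#' @return An [indicator_table()]; sample ids are kept as the attribute
#'   `"sample_id"`.
#' @export
read_indicators <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("indicator CSV needs a sample_id column")
  ids <- as.character(df$sample_id)
  V <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(V) <- "double"
  side_path <- paste0(path, ".yml")
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    groups <- lapply(side$groups, function(g) match(g, colnames(V)))
    task <- unlist(side$task)[names(groups)]
    tab <- indicator_table(V, groups, task)
  } else {
    tab <- indicator_table(V)
  }
  attr(tab, "sample_id") <- ids
  tab
}

#' Serialize a fitted model to a directory
#'
#' Bases go to CSV, predictor parameters to a shape-tagged JSON file, and
#' the fitting configuration and objective history are echoed alongside.
#'
#' @param model A fitted `trip_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trip_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  C <- orthonormalize(model$Z)
  cols <- basis_columns(model$J)
  for (s in seq_along(model$J)) {
    utils::write.csv(C[, cols[[s]], drop = FALSE],
                     file.path(dir, sprintf("basis_%d.csv", s)),
                     row.names = FALSE)
  }
  utils::write.csv(model$Z, file.path(dir, "Z.csv"), row.names = FALSE)
  pred <- lapply(model$predictors, function(p) {
    list(spec = unclass(p$spec),
         layers = lapply(p$params, function(l) {
           list(W = list(dim = dim(l$W), data = as.numeric(l$W)),
                b = as.numeric(l$b))
         }))
  })
  jsonlite::write_json(pred, file.path(dir, "predictors.json"),
                       auto_unbox = TRUE, digits = NA)
  meta <- list(J = model$J, beta = model$beta, bipartite = model$bipartite,
               tasks = model$tasks,
               groups = model$groups,
               input_scale = model$input_scale,
               restart = model$restart,
               config = unclass(model$config))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    utils::write.csv(data.frame(epoch = seq_along(model$history) - 1,
                                objective = model$history),
                     file.path(dir, "history.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Load a serialized model
#'
#' @param dir Directory written by [write_trip_model()].
#' @return A `trip_model`.
#' @export
read_trip_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  Z <- as.matrix(utils::read.csv(file.path(dir, "Z.csv")))
  pred_raw <- jsonlite::read_json(file.path(dir, "predictors.json"),
                                  simplifyVector = FALSE)
  predictors <- lapply(pred_raw, function(p) {
    spec <- predictor_spec(p$spec$input_dim,
                           hidden = unlist(p$spec$hidden),
                           output_dim = p$spec$output_dim,
                           loss = p$spec$loss)
    params <- lapply(p$layers, function(l) {
      list(W = matrix(unlist(l$W$data), unlist(l$W$dim)[1],
                      unlist(l$W$dim)[2]),
           b = as.numeric(unlist(l$b)))
    })
    list(spec = spec, params = params)
  })
  groups <- meta$groups
  if (is.null(names(groups))) names(groups) <- sprintf("m%d",
                                                       seq_along(groups))
  hist <- NULL
  hp <- file.path(dir, "history.csv")
  if (file.exists(hp)) hist <- utils::read.csv(hp)$objective
  structure(list(Z = unname(Z), J = as.integer(meta$J), predictors = predictors,
                 beta = meta$beta, bipartite = isTRUE(meta$bipartite),
                 groups = lapply(groups, as.integer),
                 tasks = as.character(meta$tasks),
                 input_scale = if (is.null(meta$input_scale)) NULL else
                   as.numeric(meta$input_scale),
                 history = hist, restart = meta$restart),
            class = "trip_model")
}

#' Consolidated JSON report of a model run
#'
#' Gathers the objective history, evaluation metrics, and (when planted
#' ground truth is supplied) the subspace similarity of each fitted basis,
#' into one JSON-serializable summary.
#'
#' @param model Fitted `trip_model`.
#' @param family Graph family to score.
#' @param indicators Matching indicator table.
#' @param truth_bases Optional list of ground-truth bases to compare
#'   against.
#' @param path Optional file to write the JSON report to.
#' @return The report list, invisibly when `path` is given.
#' @export
run_report <- function(model, family, indicators, truth_bases = NULL,
                       path = NULL) {
  ev <- trip_evaluate(model, family, indicators)
  metrics <- lapply(ev$mechanisms, function(m) {
    m[intersect(names(m), c("task", "rmse", "accuracy"))]
  })
  rep <- list(
    objective_history = as.numeric(model$history),
    final_objective = utils::tail(as.numeric(model$history), 1),
    restart = model$restart,
    metrics = metrics,
    mean_reconstruction_gap = ev$mean_reconstruction_gap)
  if (!is.null(truth_bases)) {
    if (is.matrix(truth_bases)) truth_bases <- list(truth_bases)
    rep$subspace_similarity <- vapply(seq_along(model$J), function(s) {
      if (s > length(truth_bases)) return(NA_real_)
      subspace_similarity(truth_bases[[s]], trip_basis(model, s))
    }, numeric(1))
  }
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
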