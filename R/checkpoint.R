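## Portable checkpoints: a directory with config.json (architecture) and
## params.csv.gz (flattened parameter values in leaf order).

serialize_encoder <- function(enc) {
  list(p = enc$p,
       channel_cells = lapply(enc$channel_cells, function(cl)
         list(kernels = cl$kernels, filters = cl$filters, pool = cl$pool)),
       global_cells = lapply(enc$global_cells, function(cl)
         list(kernels = cl$kernels, filters = cl$filters, pool = cl$pool)))
}

deserialize_encoder <- function(x) {
  encoder_config(
    channel_cells = lapply(x$channel_cells, function(cl)
      cell_config(unlist(cl$kernels), cl$filters, unlist(cl$pool))),
    global_cells = lapply(x$global_cells, function(cl)
      cell_config(lapply(cl$kernels, unlist), cl$filters,
                  vapply(cl$pool, function(v) if (is.null(v)) NA_real_ else v, 1))),
    p = x$p)
}

#' Save a model checkpoint
#'
#' Writes `config.json` (architecture and dimensions) and `params.csv.gz`
#' (every parameter value with its tree path) so the model can be restored
#' bit-for-bit on any platform.
#'
#' @param model A `fusionatt_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(C = model$C, n = model$n, n_classes = model$n_classes,
              p = model$p, r = model$r, kind = model$kind,
              vector_gate = model$vector_gate, dropout = model$dropout,
              per_channel_encoder = model$per_channel_encoder,
              seed = model$seed, encoder = serialize_encoder(model$enc))
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  paths <- param_paths(model$params)
  rows <- lapply(paths, function(p) {
    v <- get_leaf(model$params, p)
    # full %.17g precision so the round trip is exact
    data.frame(path = path_key(p), index = seq_along(v),
               value = sprintf("%.17g", as.numeric(v)))
  })
  con <- gzfile(file.path(dir, "params.csv.gz"), "w")
  utils::write.csv(do.call(rbind, rows), con, row.names = FALSE)
  close(con)
  if (!is.null(model$history))
    utils::write.csv(model$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' @param dir Directory written by [save_model()].
#' @return A `fusionatt_model` with the stored parameters.
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  enc <- deserialize_encoder(jsonlite::read_json(file.path(dir, "config.json"))$encoder)
  model <- fusionatt_model(cfg$C, cfg$n, cfg$n_classes, encoder = enc,
                           r = cfg$r, kind = cfg$kind,
                           vector_gate = isTRUE(cfg$vector_gate),
                           dropout = cfg$dropout,
                           per_channel_encoder = isTRUE(cfg$per_channel_encoder),
                           seed = cfg$seed)
  tab <- utils::read.csv(gzfile(file.path(dir, "params.csv.gz")),
                         colClasses = c("character", "integer", "character"))
  for (p in param_paths(model$params)) {
    key <- path_key(p)
    vals <- as.numeric(tab$value[tab$path == key])
    leaf <- get_leaf(model$params, p)
    if (length(vals) != length(leaf))
      stop("checkpoint parameter '", key, "' has ", length(vals),
           " values, expected ", length(leaf))
    leaf[] <- vals
    model$params <- set_leaf(model$params, p, leaf)
  }
  model
}
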