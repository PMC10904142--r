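# On-disk serialization: checkpoints as JSON (named arrays keyed by their
# position in the parameter tree), configurations as YAML. Both formats
# are plain text so checkpoints can be inspected and diffed.

#' Save a checkpoint to JSON
#'
#' @param checkpoint A `gcpnet_checkpoint` from [train_model()] (or any
#'   list with `params`, `config`, `widths`, `kind`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
checkpoint_save <- function(checkpoint, path) {
  payload <- list(params = strip_classes(checkpoint$params),
                  config = strip_classes(checkpoint$config),
                  widths = checkpoint$widths,
                  kind = checkpoint$kind,
                  seed = checkpoint$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Load a checkpoint saved by [checkpoint_save()]
#'
#' @param path JSON path.
#' @return A `gcpnet_checkpoint`.
#' @export
checkpoint_load <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  params <- rebuild_params(raw$params)
  cfg <- raw$config
  gcp <- do.call(gcp_config, cfg$gcp[c("lambda", "omega", "use_frames",
                                       "use_scalars", "use_vectors",
                                       "use_residual", "eps")])
  config <- gcpnet_config(hidden_node = cfg$hidden_node,
                          hidden_edge = cfg$hidden_edge,
                          out_node = cfg$out_node, n_layers = cfg$n_layers,
                          k = cfg$k, update_positions = cfg$update_positions,
                          gcp = gcp)
  structure(list(params = params, config = config,
                 widths = lapply(raw$widths, as.integer),
                 kind = raw$kind, seed = raw$seed),
            class = "gcpnet_checkpoint")
}

rebuild_params <- function(x) {
  if (is.list(x) && !is.null(x$w_s)) {
    for (nm in c("w_dz", "w_ds", "w_s", "w_uz", "w_g")) {
      if (!is.null(x[[nm]])) x[[nm]] <- as.matrix(x[[nm]])
    }
    for (nm in c("b_s", "b_g")) {
      if (!is.null(x[[nm]])) x[[nm]] <- as.numeric(x[[nm]])
    }
    for (nm in c("t_in", "r_in", "t_out", "r_out", "rz")) {
      x[[nm]] <- as.integer(x[[nm]])
    }
    # degenerate matrix shapes: a stored 1 x k or k x 1 map must keep the
    # orientation recorded by the width fields
    fix_shape <- function(m, nr, nc) {
      if (is.null(m)) return(NULL)
      matrix(as.numeric(m), nr, nc)
    }
    rz <- x$rz
    if (!is.null(x$w_dz)) x$w_dz <- fix_shape(x$w_dz, x$r_in, rz)
    if (!is.null(x$w_ds)) x$w_ds <- fix_shape(x$w_ds, x$r_in, 3L)
    x$w_s <- fix_shape(x$w_s, length(x$w_s) / x$t_out, x$t_out)
    if (!is.null(x$w_uz)) x$w_uz <- fix_shape(x$w_uz, rz, x$r_out)
    if (!is.null(x$w_g)) x$w_g <- fix_shape(x$w_g, x$t_out, x$r_out)
    class(x) <- "gcp_params"
    return(x)
  }
  if (is.list(x)) return(lapply(x, rebuild_params))
  x
}

#' Write a network configuration as YAML
#'
#' @param config A [gcpnet_config()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
config_save_yaml <- function(config, path) {
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

#' Read a network configuration written by [config_save_yaml()]
#'
#' @param path YAML path.
#' @return A [gcpnet_config()].
#' @export
config_load_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  gcp <- do.call(gcp_config, cfg$gcp[c("lambda", "omega", "use_frames",
                                       "use_scalars", "use_vectors",
                                       "use_residual", "eps")])
  gcpnet_config(hidden_node = unlist(cfg$hidden_node),
                hidden_edge = unlist(cfg$hidden_edge),
                out_node = unlist(cfg$out_node), n_layers = cfg$n_layers,
                k = cfg$k, update_positions = cfg$update_positions,
                gcp = gcp)
}
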