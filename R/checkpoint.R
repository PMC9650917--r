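# Checkpoints: a single serialized archive with a version tag and the
# encoder config embedded; loading verifies the version and (optionally)
# config compatibility.

CKPT_VERSION <- "usvid-checkpoint-1"

#' Save a pretraining or model checkpoint
#'
#' @param object For `type = "encoder"`: a list with `encoder`, `head`,
#'   `history`, `epochs_done` (as returned by [pretrain()]). For
#'   `type = "model"`: a `usv_model`.
#' @param path Destination file.
#' @param type Checkpoint flavour.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path, type = c("encoder", "model")) {
  type <- match.arg(type)
  config <- if (type == "encoder") object$encoder$config else
    object$encoder$config
  saveRDS(list(version = CKPT_VERSION, type = type, config = config,
               payload = object), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @param type Expected flavour (`NULL` accepts either).
#' @param config If given, an [encoder_config()] that must match the one
#'   embedded in the archive.
#' @return The stored payload.
#' @export
load_checkpoint <- function(path, type = NULL, config = NULL) {
  if (!file.exists(path)) stop("load_checkpoint: no such file: ", path)
  ck <- readRDS(path)
  if (!identical(ck$version, CKPT_VERSION)) {
    stop("load_checkpoint: unsupported checkpoint version: ",
         ck$version %||% "<missing>")
  }
  if (!is.null(type) && !identical(ck$type, type)) {
    stop("load_checkpoint: expected a ", type, " checkpoint, found ", ck$type)
  }
  if (!is.null(config) && !identical(unclass(config), unclass(ck$config))) {
    stop("load_checkpoint: encoder config in checkpoint is incompatible ",
         "with the requested config")
  }
  ck$payload
}

`%||%` <- function(a, b) if (is.null(a)) b else a
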