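# Versioned checkpoint I/O: weights and the network spec travel together.

CHECKPOINT_FORMAT <- "skanet-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' @param model a `skanet_model`.
#' @param path destination file (RDS).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "skanet_model"))
  saveRDS(list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
               spec = model$spec, params = model$params, msl = model$msl),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return the restored `skanet_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, CHECKPOINT_FORMAT))
    stop("not a model checkpoint: ", path)
  if (obj$version > CHECKPOINT_VERSION)
    stop("checkpoint version ", obj$version, " is newer than this package supports")
  m <- list(spec = obj$spec, params = obj$params)
  if (!is.null(obj$msl)) m$msl <- obj$msl
  structure(m, class = "skanet_model")
}
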