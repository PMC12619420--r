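## Plain-text model persistence: weights and configuration as JSON, so a
## trained estimator can be shipped, inspected and reloaded without binary
## artefacts.

.mat_enc <- function(m) list(dim = dim(m), data = as.vector(m))
.mat_dec <- function(x) matrix(unlist(x$data), x$dim[1], x$dim[2])

.net_enc <- function(net) list(sizes = net$sizes,
                               W = lapply(net$W, .mat_enc),
                               b = net$b)
.net_dec <- function(x) list(W = lapply(x$W, .mat_dec),
                             b = lapply(x$b, as.numeric),
                             sizes = as.integer(x$sizes))

.flow_enc <- function(fl) list(context_dim = fl$context_dim,
                               depth = fl$depth, layers = fl$layers)
.flow_dec <- function(x) {
  layers <- lapply(x$layers, function(p)
    list(Ws = as.numeric(p$Ws), bs = as.numeric(p$bs),
         Wt = as.numeric(p$Wt), bt = as.numeric(p$bt),
         Wg = as.numeric(p$Wg), bg = as.numeric(p$bg)))
  structure(list(layers = layers, context_dim = as.integer(x$context_dim),
                 depth = as.integer(x$depth)), class = "cond_flow")
}

#' Save a fitted estimator as a JSON model directory
#'
#' Writes \code{model.json} (all weights, full precision) and
#' \code{manifest.json} (configuration, feature names, training
#' summaries) under \code{path}.
#'
#' @param model a fitted \code{\link{cfrflow}}.
#' @param path directory to create.
#' @return \code{path}, invisibly.
#' @export
save_cfrflow <- function(model, path) {
  stopifnot(inherits(model, "cfrflow"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  weights <- list(
    encoder = .net_enc(model$stage0$encoder),
    head0 = .net_enc(model$stage0$head0),
    head1 = .net_enc(model$stage0$head1),
    center = model$stage0$center,
    scale = model$stage0$scale,
    stage1_flow = .flow_enc(model$stage1$flow),
    score_spread = model$stage1$score_spread,
    stage2_flow = .flow_enc(model$stage2$flow))
  jsonlite::write_json(weights, file.path(path, "model.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest <- list(
    package = "flowcfr",
    config = unclass(model$config),
    feature_names = model$feature_names,
    stage0_best_epoch = model$stage0$best_epoch,
    stage0_val_loss = model$stage0$best_val_loss)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an estimator saved with \code{\link{save_cfrflow}}
#'
#' @param path model directory.
#' @return a \code{cfrflow} model.
#' @export
load_cfrflow <- function(path) {
  w <- jsonlite::fromJSON(file.path(path, "model.json"),
                          simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  mf <- jsonlite::fromJSON(file.path(path, "manifest.json"),
                           simplifyVector = TRUE)
  cfgl <- mf$config
  cfg <- do.call(cfrflow_config,
                 cfgl[intersect(names(cfgl), names(formals(cfrflow_config)))])
  s0 <- structure(list(encoder = .net_dec(w$encoder),
                       head0 = .net_dec(w$head0),
                       head1 = .net_dec(w$head1),
                       center = unlist(w$center), scale = unlist(w$scale),
                       config = cfg,
                       best_epoch = mf$stage0_best_epoch,
                       best_val_loss = mf$stage0_val_loss),
                  class = "cfr_stage0")
  structure(list(
    stage0 = s0,
    stage1 = structure(list(flow = .flow_dec(w$stage1_flow),
                            score_spread = as.numeric(w$score_spread)),
                       class = "cfr_stage1"),
    stage2 = structure(list(flow = .flow_dec(w$stage2_flow)),
                       class = "cfr_stage2"),
    config = cfg,
    feature_names = mf$feature_names), class = "cfrflow")
}
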