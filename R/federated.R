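## Federated averaging and local personalisation.

#' Sample-weighted federated average of client parameters
#'
#' The aggregation rule \eqn{w_{t+1} = \sum_k (n_k / n) w_t^k} with
#' \eqn{n = \sum_k n_k}: a convex combination of the client parameter
#' vectors weighted by local sample counts.
#'
#' @param weights list of equal-length numeric client parameter vectors
#'   \eqn{w_t^k}
#' @param nSamples numeric vector of client sample counts \eqn{n_k}
#' @return the aggregated parameter vector
#' @examples
#' fedavgAggregate(list(0, 1), c(1, 3))   # 0.75
#' @export
fedavgAggregate <- function(weights, nSamples) {
  .stopIfNot(length(weights) >= 1, "need >= 1 client update")
  .stopIfNot(length(weights) == length(nSamples),
             "weights and nSamples must have equal length")
  .stopIfNot(all(nSamples > 0), "all n_k must be positive")
  len <- vapply(weights, length, 0L)
  .stopIfNot(all(len == len[1]),
             "client parameter vectors differ in length: ",
             paste(unique(len), collapse = " vs "))
  w <- nSamples / sum(nSamples)
  out <- 0
  for (k in seq_along(weights)) out <- out + w[k] * weights[[k]]
  out
}

#' Locally fine-tune the global model on one client's data
#'
#' Runs \code{rounds} local training passes of the global
#' \linkS4class{HarModel} on the client's windows and returns only the
#' parameter increment \eqn{\Delta = w_{local} - w_{global}} with the
#' local sample count -- raw client windows are never part of the update
#' object.
#'
#' @param global a trained \linkS4class{HarModel}
#' @param clientData the client's \linkS4class{FeatureWindows}
#' @param clientId id string
#' @param rounds local training passes (default 10)
#' @param lr local learning rate
#' @param round federation round index recorded in the update
#' @return a \linkS4class{ClientUpdate}
#' @export
localFinetune <- function(global, clientData, clientId = "client",
                          rounds = 10, lr = 0.005, round = 1) {
  stopifnot(is(global, "HarModel"))
  .stopIfNot(nWindows(clientData) > 0, "client data must be non-empty")
  .stopIfNot(all(levels(windowLabels(clientData)) %in% global@classes),
             "client labels outside the global class set")
  w0 <- .flattenParams(global@params)
  if (rounds == 0)
    return(clientUpdate(clientId, 0 * w0, nWindows(clientData), round))
  nodes <- graphNodes(global@graph)
  feats <- .windowNodeFeatures(clientData, nodes,
                               global@config$subFrames)
  Ahat <- buildNormalizedAdjacency(global@graph)
  y <- as.integer(factor(as.character(windowLabels(clientData)),
                         levels = global@classes))
  B <- nWindows(clientData)
  p <- global@params
  mv <- 0 * w0; vv <- mv
  for (it in seq_len(rounds)) {
    fwp <- .harForward(p, feats, Ahat, global@config, B)
    bk <- .harBackward(p, feats, Ahat, global@config, B, fwp, y)
    gv <- .flattenParams(bk$grad)
    mv <- 0.9 * mv + 0.1 * gv
    vv <- 0.999 * vv + 0.001 * gv^2
    pv <- .flattenParams(p) -
      lr * (mv / (1 - 0.9^it)) / (sqrt(vv / (1 - 0.999^it)) + 1e-8)
    p <- .unflattenParams(p, pv)
  }
  clientUpdate(clientId, .flattenParams(p) - w0, B, round)
}

#' Apply a parameter vector to a model
#'
#' @param model a \linkS4class{HarModel}
#' @param flat flattened parameter vector (same layout as
#'   \code{.flattenParams} of the model's params)
#' @return the model with parameters replaced
#' @export
setModelParams <- function(model, flat) {
  model@params <- .unflattenParams(model@params, flat)
  model
}

#' Flatten a model's parameters
#'
#' @param model a \linkS4class{HarModel}
#' @return numeric vector
#' @export
getModelParams <- function(model) .flattenParams(modelParams(model))

#' Run one federation round
#'
#' Each client fine-tunes the current global model locally
#' (\code{\link{localFinetune}}); the server reconstructs
#' \eqn{w^k = w_{global} + \Delta_k} and aggregates by
#' \code{\link{fedavgAggregate}}. The per-client sample counts are
#' retained in the server log.
#'
#' @param server list(model = \linkS4class{HarModel}, round = integer,
#'   log = data.frame) -- create with
#'   \code{list(model = m, round = 0L, log = NULL)}
#' @param clients named list of \linkS4class{FeatureWindows}
#' @param rounds local passes per client
#' @param lr local learning rate
#' @param seed integer seed (reserved for client subsampling; the local
#'   training itself is deterministic)
#' @return the updated server list
#' @export
runRound <- function(server, clients, rounds = 10, lr = 0.005,
                     seed = 1) {
  .stopIfNot(length(clients) >= 1, "need >= 1 client")
  w0 <- getModelParams(server$model)
  updates <- lapply(names(clients), function(id)
    localFinetune(server$model, clients[[id]], clientId = id,
                  rounds = rounds, lr = lr, round = server$round + 1L))
  ws <- lapply(updates, function(u) w0 + updateDelta(u))
  ns <- vapply(updates, sampleCount, 0)
  wNew <- fedavgAggregate(ws, ns)
  server$model <- setModelParams(server$model, wNew)
  server$round <- server$round + 1L
  server$log <- rbind(server$log, data.frame(
    round = server$round, client = names(clients), n = ns))
  server
}

#' Serialise a client update to its transport schema
#'
#' The mechanical privacy contract: the serialised update contains the
#' parameter increment, sample count, client id, round and vector length
#' -- and nothing else (asserted by schema in the tests).
#'
#' @param update a \linkS4class{ClientUpdate}
#' @return a list ready for JSON serialisation
#' @export
updateManifest <- function(update) {
  list(client_id = update@clientId,
       n_k = as.integer(update@nSamples),
       round = as.integer(update@round),
       vector_length = length(update@delta),
       delta = update@delta)
}
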