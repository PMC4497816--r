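#' Connection state returned by the four models
#'
#' A weight matrix `W` (RGC x SC neuron; integer terminal/synapse counts for
#' the Gierer and Koulakov models, continuous weights for the Whitelaw and
#' Willshaw models) plus model-specific auxiliary state and per-epoch logs.
#'
#' @param W weight matrix (base or `Matrix`).
#' @param model model name.
#' @param params named list of parameters used.
#' @param log per-epoch log (data frame).
#' @param aux model-specific auxiliary state.
#' @param seed seed used for the run.
#' @param w_min analysis threshold for continuous weights (`NULL` for
#'   integer-weight models).
#' @return an object of class `connection_state`.
#' @export
connection_state <- function(W, model, params = list(), log = NULL,
                             aux = list(), seed = NULL, w_min = NULL) {
  structure(list(W = W, model = model, params = params, log = log,
                 aux = aux, seed = seed, w_min = w_min),
            class = "connection_state")
}

#' @export
print.connection_state <- function(x, ...) {
  cat(sprintf("<connection_state> %s: %d x %d, total weight %g\n",
              x$model, nrow(x$W), ncol(x$W), sum(x$W)))
  invisible(x)
}

#' Zero out sub-threshold weights of a continuous-weight model
#'
#' The Whitelaw and Willshaw models use continuous weights; some analysis
#' measures require entries below the model's `w_min` to be set to zero.
#'
#' @param state a `connection_state`.
#' @return the state with thresholded `W`.
#' @export
threshold_weights <- function(state) {
  stopifnot(inherits(state, "connection_state"))
  if (!is.null(state$w_min)) {
    W <- state$W
    W[W < state$w_min] <- 0
    state$W <- W
  }
  state
}

#' Serialize a connection state to a directory (CSV + JSON)
#' @param state a `connection_state`.
#' @param path directory to create.
#' @export
write_connection_state <- function(state, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  W <- state$W
  idx <- which(as.matrix(W != 0), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], w = as.numeric(W[idx]))
  write.csv(df, file.path(path, "weights.csv"), row.names = FALSE)
  if (!is.null(state$log))
    write.csv(state$log, file.path(path, "log.csv"), row.names = FALSE)
  meta <- list(model = state$model, n_r = nrow(W), n_sc = ncol(W),
               seed = state$seed, w_min = state$w_min,
               params = state$params[!vapply(state$params, is.null, TRUE)])
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a connection state written by [write_connection_state()]
#' @param path directory.
#' @return a `connection_state` (sparse weight matrix; no auxiliary state).
#' @export
read_connection_state <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  df <- read.csv(file.path(path, "weights.csv"))
  W <- Matrix::sparseMatrix(i = df$i, j = df$j, x = df$w,
                            dims = c(meta$n_r, meta$n_sc))
  log <- NULL
  lp <- file.path(path, "log.csv")
  if (file.exists(lp)) log <- read.csv(lp)
  connection_state(W, meta$model, params = as.list(meta$params), log = log,
                   seed = meta$seed, w_min = meta$w_min)
}

# CSR (0-based) adjacency from a Delaunay edge matrix, for the C++ cores
.adjacency_csr <- function(edges, n) {
  adj <- .adjacency(edges, n)
  deg <- vapply(adj, length, integer(1))
  ptr <- c(0L, cumsum(deg))
  idx <- unlist(adj, use.names = FALSE)
  if (is.null(idx)) idx <- integer(0)
  list(ptr = as.integer(ptr), idx = as.integer(idx) - 1L)
}
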