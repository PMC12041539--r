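# Internal numerical helpers shared across modules.

# numerically stable elementwise sigmoid, kept strictly inside (0, 1)
sigmoid <- function(x) {
  p <- stats::plogis(x)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# names of per-layer entries that are state, not trainable parameters
.buffer_names <- c("running_mean", "running_var", "eps_self")

# indices of a (possibly unnamed) list that hold trainable content
.trainable_idx <- function(node) {
  nms <- names(node)
  keep <- vapply(seq_along(node), function(i) {
    nm <- if (is.null(nms)) "" else nms[i]
    !(nm %in% .buffer_names) &&
      (is.numeric(node[[i]]) || is.list(node[[i]]))
  }, logical(1))
  which(keep)
}

# zero-filled structure mirroring the trainable leaves of `params`
param_zeros <- function(params) {
  if (is.numeric(params)) {
    return(array(0, dim = if (is.null(dim(params))) length(params) else dim(params)))
  }
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (i in .trainable_idx(params)) out[[i]] <- param_zeros(params[[i]])
  out
}

# elementwise combination a + b over mirrored grad structures
grad_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  for (i in seq_along(a)) {
    if (!is.null(a[[i]]) && !is.null(b[[i]])) a[[i]] <- grad_add(a[[i]], b[[i]])
  }
  a
}

grad_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  for (i in seq_along(a)) if (!is.null(a[[i]])) a[[i]] <- grad_scale(a[[i]], s)
  a
}

# count trainable scalars in a nested parameter structure
n_param_leaves <- function(params) {
  if (is.numeric(params)) return(length(params))
  if (!is.list(params)) return(0L)
  total <- 0L
  for (i in .trainable_idx(params)) total <- total + n_param_leaves(params[[i]])
  total
}

#' Adam optimiser state
#'
#' Creates first/second-moment accumulators mirroring the trainable leaves of
#' a nested parameter list.
#'
#' @param params nested list of numeric parameter arrays.
#' @return an optimiser state list.
#' @keywords internal
adam_init <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0L)
}

# One Adam update. Returns list(params, state). Hyper-parameters follow the
# calling stage: pre-training uses beta1 = 0.5, classification beta1 = 0.9.
adam_step <- function(params, grads, state, lr = 2e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(node_p, node_g, node_m, node_v) {
    if (is.numeric(node_p)) {
      node_m <- beta1 * node_m + (1 - beta1) * node_g
      node_v <- beta2 * node_v + (1 - beta2) * node_g^2
      mhat <- node_m / (1 - beta1^t)
      vhat <- node_v / (1 - beta2^t)
      node_p <- node_p - lr * mhat / (sqrt(vhat) + eps)
      return(list(p = node_p, m = node_m, v = node_v))
    }
    nms <- names(node_p)
    for (i in .trainable_idx(node_p)) {
      # grads may omit buffer slots, so match named entries by name
      gi <- if (!is.null(nms) && nzchar(nms[i]) && !is.null(names(node_g))) {
        node_g[[nms[i]]]
      } else if (i <= length(node_g)) node_g[[i]] else NULL
      if (is.null(gi)) next
      r <- upd(node_p[[i]], gi, node_m[[i]], node_v[[i]])
      node_p[[i]] <- r$p
      node_m[[i]] <- r$m
      node_v[[i]] <- r$v
    }
    list(p = node_p, m = node_m, v = node_v)
  }
  r <- upd(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}
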