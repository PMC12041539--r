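# White-box edge-dropping attack. The contrastive loss of the pre-trained
# backbone is differentiated with respect to the reconstructed adjacency
# matrices A = z z^T, A1 = z1 z1^T, A2 = z2 z2^T; the combined, symmetrized
# gradient scores edge sensitivity, and edges whose gradient falls below the
# mean over edges are dropped. Attacks fire at random intervals governed by
# uniform draws from a sine wave on [0, pi].

#' Create an attack schedule
#'
#' @param threshold sine-value threshold above which an attack fires
#'   (fixed at 0.5 in the reference design).
#' @return an `attack_schedule` object.
#' @export
attack_schedule <- function(threshold = 0.5) {
  structure(list(threshold = threshold), class = "attack_schedule")
}

#' Decide whether to attack
#'
#' Draws `theta ~ Uniform[0, pi]` and fires iff `sin(theta) >= threshold`.
#' With the default threshold 0.5 the long-run attack frequency is exactly
#' 2/3 (the measure of `[pi/6, 5 pi/6]` relative to `[0, pi]`).
#'
#' Uses the session RNG; seed with [set.seed()].
#'
#' @param schedule an [attack_schedule()].
#' @return logical.
#' @export
should_attack <- function(schedule = attack_schedule()) {
  theta <- stats::runif(1, 0, pi)
  sin(theta) >= schedule$threshold
}

#' Edge-sensitivity gradients of the contrastive loss
#'
#' Encodes the graph with the (white-box) backbone, regenerates contrastive
#' perturbations `z1`, `z2`, forms the reconstructed adjacencies and computes
#' the composite loss (reconstruction + 0.4 x information) against the true
#' adjacency, with 1:1 negative sampling. Returns the symmetrized combined
#' gradient `dL/dA + dL/dA1 + dL/dA2` and its mean `mu_g` over existing-edge
#' entries (`mean_over = "edges"`) or over all entries.
#'
#' Uses the session RNG for the perturbation and negative draws; seed with
#' [set.seed()].
#'
#' @param graph a [molecular_graph()] with at least one edge.
#' @param backbone an encoder (pre-trained, or the spectral branch of a
#'   trained dual-branch model via [model_backbone()]).
#' @param penalty_lambda information-loss weight.
#' @param mean_over `"edges"` or `"all_entries"`.
#' @return list with `combined` (symmetric n x n gradient), `mu_g`, and the
#'   loss components (class `edge_gradient`).
#' @export
attack_gradients <- function(graph, backbone, penalty_lambda = 0.4,
                             mean_over = c("edges", "all_entries")) {
  mean_over <- match.arg(mean_over)
  z <- encode(graph, backbone)
  draw <- perturb_embedding(z)
  x <- adjacency_matrix(graph)
  positives <- undirected_edges(graph)
  if (nrow(positives) == 0) {
    stop("Cannot attack an edgeless graph.", call. = FALSE)
  }
  negatives <- negative_sample(graph, nrow(positives))
  res <- contrastive_loss_dz(z, draw, x, positives, negatives,
                             penalty_lambda = penalty_lambda)
  rec <- reconstruction_loss_grads(res$A, positives, negatives)
  inf <- information_loss_grads(x, res$A, res$A1, res$A2)
  combined <- (rec$dA + penalty_lambda * inf$dA) +
    penalty_lambda * inf$dA1 + penalty_lambda * inf$dA2
  combined <- (combined + t(combined)) / 2
  if (!all(is.finite(combined))) {
    stop("Non-finite attack gradient.", call. = FALSE)
  }
  mu_g <- if (mean_over == "edges") mean(combined[x == 1])
          else mean(combined)
  structure(list(combined = combined, mu_g = mu_g,
                 loss = res$loss, mean_over = mean_over),
            class = "edge_gradient")
}

#' Edge-drop mask from sensitivity gradients
#'
#' An undirected edge `(i, j)` is dropped iff `mu_g > combined[i, j]`
#' (strictly): edges whose gradient sits below the mean sensitivity are
#' removed. Non-edges are never touched. A `flip = TRUE` ablation inverts
#' the comparison.
#'
#' @param grad an `edge_gradient` from [attack_gradients()].
#' @param graph the graph the gradient was computed on.
#' @param flip invert the drop rule (ablation).
#' @return symmetric logical n x n matrix (class `attack_mask`).
#' @export
edge_drop_mask <- function(grad, graph, flip = FALSE) {
  x <- adjacency_matrix(graph)
  drop <- matrix(FALSE, nrow(x), ncol(x))
  sel <- if (flip) grad$combined > grad$mu_g else grad$mu_g > grad$combined
  drop[x == 1 & sel] <- TRUE
  drop <- drop | t(drop)
  structure(drop, class = c("attack_mask", "matrix"))
}

#' Apply an edge-drop mask to a graph
#'
#' Removes masked edges (both directions) and their edge features; node
#' features and labels are untouched. Never adds edges.
#'
#' @param graph a [molecular_graph()].
#' @param mask an [edge_drop_mask()] result (n x n logical).
#' @return the attacked [molecular_graph()].
#' @export
apply_attack <- function(graph, mask) {
  stopifnot(nrow(mask) == n_nodes(graph))
  if (nrow(graph$edges) == 0 || !any(mask)) return(graph)
  keep <- !mask[graph$edges]
  molecular_graph(graph$node_features,
                  graph$edges[keep, , drop = FALSE],
                  graph$edge_features[keep, , drop = FALSE],
                  labels = graph$labels, smiles = graph$smiles)
}

#' Extract the spectral branch of a trained model as a backbone encoder
#'
#' The attack is white-box: it reuses the victim's own spectral weights.
#'
#' @param model a `dual_branch_model`.
#' @return an `encoder` object sharing the model's Chebyshev layers.
#' @export
model_backbone <- function(model) {
  structure(list(layers = model$spectral, dims = model$dims, K = 3L,
                 laplacian = model$laplacian,
                 fixed_lambda = model$fixed_lambda),
            class = "encoder")
}

#' Evaluate a model under the scheduled adversarial attack
#'
#' Runs the test set several times. Within each run, the sine-wave schedule
#' decides per sample whether to attack; attacked samples are perturbed via
#' [attack_gradients()] / [edge_drop_mask()] / [apply_attack()] before
#' prediction. Reports the clean metric, per-run attacked metrics and the
#' percentage decrease, plus a per-sample log of attack status and number of
#' dropped edges.
#'
#' @param model a trained `dual_branch_model`.
#' @param graphs test graphs.
#' @param labels B x k label matrix.
#' @param runs number of attacked test runs (the reference protocol averages
#'   5).
#' @param seed integer seed; run r uses seed + r.
#' @param schedule an [attack_schedule()].
#' @param backbone encoder used by the attack; defaults to the victim's own
#'   spectral branch.
#' @return list with `clean_metric`, `attacked_metrics` (one per run),
#'   `mean_attacked_metric`, `decrease_pct`, and `log` (data.frame).
#' @export
evaluate_under_attack <- function(model, graphs, labels, runs = 5L,
                                  seed = 1L, schedule = attack_schedule(),
                                  backbone = NULL) {
  labels <- matrix(as.numeric(labels), nrow = length(graphs))
  if (is.null(backbone)) backbone <- model_backbone(model)
  clean_pred <- predict(model, graphs)
  clean_metric <- roc_auc(labels, clean_pred)
  attacked <- numeric(runs)
  logs <- list()
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    preds <- matrix(NA_real_, length(graphs), model$k)
    for (i in seq_along(graphs)) {
      g <- graphs[[i]]
      fire <- should_attack(schedule) && nrow(g$edges) > 0
      dropped <- 0L
      if (fire) {
        grad <- attack_gradients(g, backbone)
        mask <- edge_drop_mask(grad, g)
        dropped <- sum(mask) / 2L
        g <- apply_attack(g, mask)
      }
      preds[i, ] <- predict(model, list(g))
      logs[[length(logs) + 1L]] <-
        data.frame(run = r, sample = i, attacked = fire,
                   edges_dropped = as.integer(dropped))
    }
    attacked[r] <- roc_auc(labels, preds)
  }
  list(clean_metric = clean_metric,
       attacked_metrics = attacked,
       mean_attacked_metric = mean(attacked),
       decrease_pct = 100 * (clean_metric - mean(attacked)) / clean_metric,
       log = do.call(rbind, logs))
}
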