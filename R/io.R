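# Dataset IO, synthetic task generation, metrics and checkpointing.

#' Read a MoleculeNet-style SMILES CSV
#'
#' The file must have a header with a `smiles` column; every remaining column
#' is treated as a task label. Empty cells become missing labels (NA), not 0.
#' Rows whose SMILES does not parse are dropped with a warning; the number of
#' drops is recorded in the `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @return data.frame with a `smiles` column and k label columns; attributes
#'   `k` (task count) and `n_dropped`.
#' @export
read_smiles_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  if (!"smiles" %in% names(df)) {
    stop("CSV has no 'smiles' column: ", path, call. = FALSE)
  }
  label_cols <- setdiff(names(df), "smiles")
  for (cl in label_cols) df[[cl]] <- as.numeric(df[[cl]])
  parsed <- parse_smiles(df$smiles)
  ok <- !vapply(parsed, is.null, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning("Dropped ", n_dropped, " row(s) with unparsable SMILES.",
            call. = FALSE)
  }
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k") <- length(label_cols)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Ring-membership label of a molecular graph
#'
#' The structural rule used by the synthetic classification task: 1 if any
#' atom of the graph sits in a ring (read off the in-ring slot of the node
#' features), else 0.
#'
#' @param graph a [molecular_graph()].
#' @export
ring_label <- function(graph) {
  as.numeric(any(graph$node_features[, 26] == 1))
}

# small vocabulary of acyclic substituents; attaching one never changes the
# ring label of the base molecule
.SUBSTITUENTS <- c("C", "CC", "CCC", "N", "CN", "CO", "CCO", "CC(C)", "COC")

#' Generate a synthetic ring-label classification dataset
#'
#' Samples fixture molecules (balanced over the ring/no-ring label) and
#' perturbs roughly half of them by attaching a random acyclic substituent
#' from a small vocabulary; candidates that fail to parse fall back to the
#' unmodified fixture. The binary label is the structural rule "contains a
#' ring", recomputable from any generated graph via [ring_label()], so the
#' task is learnable from the featurization by construction.
#'
#' @param n number of molecules (>= 10).
#' @param seed integer seed; the dataset is a deterministic function of
#'   `(n, seed)`.
#' @return data.frame with columns `smiles`, `label`; attributes `k = 1` and
#'   `task_mode = "classification"`.
#' @export
synthetic_classification_dataset <- function(n, seed = 1L) {
  stopifnot(n >= 10)
  set.seed(seed)
  fx <- fixture_molecules()
  ring_pool <- fx$smiles[fx$label == 1]
  chain_pool <- fx$smiles[fx$label == 0]
  want_ring <- stats::runif(n) < 0.5
  base <- ifelse(want_ring,
                 ring_pool[sample.int(length(ring_pool), n, replace = TRUE)],
                 chain_pool[sample.int(length(chain_pool), n, replace = TRUE)])
  perturb <- stats::runif(n) < 0.5
  sub <- .SUBSTITUENTS[sample.int(length(.SUBSTITUENTS), n, replace = TRUE)]
  candidate <- ifelse(perturb, paste0(sub, base), base)
  ok <- !vapply(parse_smiles(candidate), is.null, logical(1))
  smiles <- ifelse(ok, candidate, base)
  out <- data.frame(smiles = smiles, label = as.numeric(want_ring),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- 1L
  attr(out, "task_mode") <- "classification"
  out
}

#' Area under the ROC curve
#'
#' Pairwise (Mann-Whitney) definition: the probability that a uniformly
#' random positive outranks a uniformly random negative, ties counted 1/2.
#' Matrix inputs are macro-averaged over columns (tasks), skipping columns
#' without both classes; missing labels are ignored.
#'
#' @param labels binary vector, or matrix with NA for missing entries.
#' @param scores real vector or matrix matching `labels`.
#' @return real in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (is.matrix(labels) || is.matrix(scores)) {
    labels <- as.matrix(labels)
    scores <- as.matrix(scores)
    stopifnot(identical(dim(labels), dim(scores)))
    aucs <- vapply(seq_len(ncol(labels)), function(j) {
      obs <- !is.na(labels[, j])
      y <- labels[obs, j]
      if (length(unique(y)) < 2) return(NA_real_)
      roc_auc(y, scores[obs, j])
    }, numeric(1))
    if (all(is.na(aucs))) {
      stop("No task has both classes present.", call. = FALSE)
    }
    return(mean(aucs, na.rm = TRUE))
  }
  obs <- !is.na(labels)
  labels <- labels[obs]
  scores <- scores[obs]
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("ROC-AUC is undefined with a single class.", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

CHECKPOINT_FORMAT <- "molgraphnn_checkpoint"
CHECKPOINT_VERSION <- 1L

#' Write a model checkpoint
#'
#' Serialises an encoder or dual-branch model into a single versioned file;
#' the round trip through [read_checkpoint()] is bit-exact.
#'
#' @param object an `encoder` or `dual_branch_model`.
#' @param path destination file.
#' @param seed optional training seed to record.
#' @param config optional configuration list to record.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(object, path, seed = NULL, config = NULL) {
  payload <- list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
                  class = class(object)[1], object = object,
                  seed = seed, config = config)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path file written by [write_checkpoint()].
#' @return list with `object`, `class`, `seed`, `config`, `version`.
#' @export
read_checkpoint <- function(path) {
  stopifnot(file.exists(path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("Corrupt or unreadable checkpoint: ", path, " (", conditionMessage(e),
         ")", call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, CHECKPOINT_FORMAT)) {
    stop("Not a molgraphnn checkpoint: ", path, call. = FALSE)
  }
  if (!identical(payload$version, CHECKPOINT_VERSION)) {
    stop("Unsupported checkpoint version: ", payload$version, call. = FALSE)
  }
  payload
}

#' Seeded train/validation/test split
#'
#' @param n number of samples.
#' @param fractions length-3 nonnegative vector summing to 1.
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = ord[seq_len(n_train)],
       val = ord[n_train + seq_len(n_val)],
       test = ord[(n_train + n_val + 1):n])
}
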