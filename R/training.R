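#' Training configuration
#'
#' Class weights default to the published values (metal 8.9, nucleic 7.7,
#' small 4.4): they multiply the positive term of each class's binary
#' cross-entropy so that missing a rare binding residue costs more than
#' missing a non-binding one. The graph threshold defaults to the final
#' published cutoff, 17 Angstrom.
#'
#' @param class_weights positive length-3 vector (metal, nucleic, small).
#' @param graph_threshold distance cutoff in Angstrom used when building
#'   protein graphs for training/prediction.
#' @param learning_rate Adam step size.
#' @param l1 sparsifying L1 penalty on the weight matrices, applied as a
#'   proximal soft-threshold of `learning_rate * l1` after each Adam step.
#'   pLM embeddings are wide (768-2560 dimensions) and typically carry many
#'   dimensions uninformative for binding; with only hundreds of training
#'   proteins the input layers otherwise memorize those dimensions. The L1
#'   step zeroes their weights, acting as built-in feature selection.
#' @param weight_decay decoupled L2 weight decay per step (AdamW style),
#'   off by default; a milder alternative to `l1`.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience, in epochs without improvement
#'   of validation binary F1.
#' @param seed integer seed; fixes initialization, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(class_weights = c(metal = 8.9, nucleic = 7.7, small = 4.4),
                         graph_threshold = 17, learning_rate = 3e-3, l1 = 0.1,
                         weight_decay = 0, max_epochs = 200, patience = 20,
                         seed = 42) {
  assert_that(length(class_weights) == 3 && all(class_weights > 0),
              "class_weights must be 3 positive values")
  structure(list(class_weights = class_weights, graph_threshold = graph_threshold,
                 learning_rate = learning_rate, l1 = l1,
                 weight_decay = weight_decay, max_epochs = max_epochs,
                 patience = patience, seed = as.integer(seed)),
            class = "train_config")
}

#' Class-weighted multi-label binary cross-entropy
#'
#' Mean over residues and classes of
#' `-(w_c * y * log p + (1 - y) * log(1 - p))`: the weight touches only the
#' positive term, so with all-zero labels the loss is the plain negative
#' log of the non-binding probabilities (uniform 0.5 gives `log 2`).
#'
#' @param probs L x 3 probabilities in (0, 1).
#' @param labels L x 3 binary matrix.
#' @param weights positive length-3 class weights.
#' @return scalar loss (non-negative).
#' @export
weighted_loss <- function(probs, labels, weights = c(8.9, 7.7, 4.4)) {
  assert_that(all(dim(probs) == dim(labels)), "probs/labels shape mismatch")
  p <- clip_prob(probs)
  w <- matrix(weights, nrow(probs), 3, byrow = TRUE)
  mean(-(w * labels * log(p) + (1 - labels) * log(1 - p)))
}

## Gradient of weighted_loss w.r.t. the logits (probs = sigmoid(logits)):
## d/dz [-w y log p - (1-y) log(1-p)] = p (1 - y) - w y (1 - p), then / (L*3).
loss_logit_grad <- function(probs, labels, weights) {
  w <- matrix(weights, nrow(probs), 3, byrow = TRUE)
  (probs * (1 - labels) - w * labels * (1 - probs)) / length(probs)
}

## Adam over the nested param list ----------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

## Adam with decoupled weight decay (applied to weight matrices, not biases
## or attention vectors).
adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (ln in names(params)) {
    for (an in names(params[[ln]])) {
      g <- grads[[ln]][[an]]
      state$m[[ln]][[an]] <- beta1 * state$m[[ln]][[an]] + (1 - beta1) * g
      state$v[[ln]][[an]] <- beta2 * state$v[[ln]][[an]] + (1 - beta2) * g^2
      decay <- if (weight_decay > 0 && is.matrix(params[[ln]][[an]]))
        lr * weight_decay * params[[ln]][[an]] else 0
      params[[ln]][[an]] <- params[[ln]][[an]] - decay -
        lr * (state$m[[ln]][[an]] / corr1) /
        (sqrt(state$v[[ln]][[an]] / corr2) + eps)
    }
  }
  list(params = params, state = state)
}

## Proximal soft-threshold for the L1 penalty; weight matrices only (biases
## and attention vectors stay dense).
l1_prox <- function(params, thresh) {
  for (ln in names(params)) {
    for (an in names(params[[ln]])) {
      p <- params[[ln]][[an]]
      if (is.matrix(p)) {
        params[[ln]][[an]] <- sign(p) * pmax(abs(p) - thresh, 0)
      }
    }
  }
  params
}

## Micro-averaged binary F1 over a list of proteins at threshold 0.5.
validation_binary_f1 <- function(model, inputs, ops_list) {
  calls <- integer(0); truth <- integer(0)
  for (i in seq_along(inputs)) {
    x <- inputs[[i]]
    fw <- forward_model(model, x$embedding, x$graph, x$dssp,
                        training = FALSE, ops = ops_list[[i]])
    calls <- c(calls, to_binary(call_binding(fw$probs)))
    truth <- c(truth, as.integer(rowSums(x$labels) > 0))
  }
  metrics(confusion(calls, truth))$f1
}

#' Train one model on a train/validation split
#'
#' Full-graph gradient steps, one protein per step, epoch order reshuffled
#' from the seed; Adam optimizer; early stopping on validation binary F1
#' (micro-averaged over residues) with the configured patience. The
#' checkpoint with the best validation F1 is returned. Given the same seed
#' and inputs, the result is bit-reproducible.
#'
#' @param train,val lists of protein inputs, each element a list with
#'   `embedding` (L x d), `graph` (`residue_graph`), `labels` (L x 3) and
#'   optionally `dssp` (L x 20). See [prepare_inputs()].
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress?
#' @return list with `model` (best checkpoint), `history` (data.frame:
#'   epoch, loss, val_f1) and `best_epoch`.
#' @export
train_fold <- function(train, val, config, tc = train_config(), verbose = FALSE) {
  assert_that(length(train) > 0 && length(val) > 0, "empty split")
  set.seed(tc$seed)
  model <- build_model(config, seed = derive_seed(tc$seed, 1))
  state <- adam_init(model$params)
  ops_train <- lapply(train, function(x) graph_ops(x$graph, config$arch))
  ops_val <- lapply(val, function(x) graph_ops(x$graph, config$arch))
  best <- list(f1 = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), loss = numeric(0), val_f1 = numeric(0))
  for (epoch in seq_len(tc$max_epochs)) {
    order_idx <- sample(length(train))
    epoch_loss <- 0
    for (i in order_idx) {
      x <- train[[i]]
      fw <- forward_model(model, x$embedding, x$graph, x$dssp,
                          training = TRUE, ops = ops_train[[i]])
      epoch_loss <- epoch_loss +
        weighted_loss(fw$probs, x$labels, tc$class_weights)
      dlogits <- loss_logit_grad(fw$probs, x$labels, tc$class_weights)
      grads <- backward_model(model, fw$cache, dlogits)
      upd <- adam_step(model$params, grads, state, lr = tc$learning_rate,
                       weight_decay = tc$weight_decay %||% 0)
      model$params <- upd$params
      state <- upd$state
      if ((tc$l1 %||% 0) > 0) {
        model$params <- l1_prox(model$params, tc$learning_rate * tc$l1)
      }
    }
    f1 <- validation_binary_f1(model, val, ops_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = epoch_loss / length(train),
                                         val_f1 = f1))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val F1 %.4f", epoch,
                      epoch_loss / length(train), f1))
    }
    if (f1 > best$f1) {
      best <- list(f1 = f1, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= tc$patience) {
      break
    }
  }
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_f1 = best$f1)
}

#' Five-fold cross-training
#'
#' Fold k's model is trained on the other four folds and validated on fold
#' k, so every development protein is validated exactly once. Per-fold
#' validation metrics are aggregated with [evaluate_predictions()].
#'
#' @param dev named list of protein inputs (see [train_fold()]).
#' @param splits named vector protein_id -> fold ("1".."5"; "test" entries
#'   are ignored here).
#' @param config a [model_config()].
#' @param tc a [train_config()].
#' @param verbose print progress?
#' @return a `crossval_result`: list with `fold_models` (5 models),
#'   `fold_metrics` (per-fold metric sets) and `config`/`tc`.
#' @export
cross_validate <- function(dev, splits, config, tc = train_config(),
                           verbose = FALSE) {
  folds <- splits[names(dev)]
  assert_that(all(folds %in% as.character(1:5)),
              "every dev protein must be assigned to a fold 1-5")
  fold_models <- list()
  fold_metrics <- list()
  for (k in as.character(1:5)) {
    tr <- dev[names(folds)[folds != k]]
    va <- dev[names(folds)[folds == k]]
    tck <- tc
    tck$seed <- derive_seed(tc$seed, as.integer(k))
    fit <- train_fold(tr, va, config, tck, verbose = verbose)
    fold_models[[k]] <- fit$model
    probs <- predict_proteins(fit$model, va)
    fold_metrics[[k]] <- evaluate_predictions(probs,
                                              lapply(va, `[[`, "labels"))
    if (verbose) message(sprintf("fold %s: best val F1 %.4f", k, fit$best_val_f1))
  }
  structure(list(fold_models = fold_models, fold_metrics = fold_metrics,
                 config = config, tc = tc),
            class = "crossval_result")
}

#' Ensemble prediction from cross-validation models
#'
#' The final predictor is the arithmetic mean of the five fold models'
#' probability outputs (probabilities stay in (0, 1) by convexity).
#'
#' @param models a `crossval_result` or a plain list of `gnn_model`s.
#' @param inputs named list of protein inputs (see [train_fold()]).
#' @return named list of L x 3 probability matrices.
#' @export
ensemble_predict <- function(models, inputs) {
  if (inherits(models, "crossval_result")) models <- models$fold_models
  per_model <- lapply(models, predict_proteins, inputs = inputs)
  out <- lapply(seq_along(inputs), function(i) {
    Reduce(`+`, lapply(per_model, `[[`, i)) / length(per_model)
  })
  stats::setNames(out, names(inputs))
}

#' Assemble model-ready inputs from pipeline artifacts
#'
#' Builds the residue graph at the configured cutoff and bundles embedding,
#' labels and (optionally) normalized DSSP features per protein.
#'
#' @param coord_sets named list of `coordinate_set`s.
#' @param embeddings named list of L x d matrices.
#' @param labels named list of L x 3 matrices (optional for pure prediction).
#' @param dssp named list of L x 20 feature matrices (optional).
#' @param threshold graph distance cutoff in Angstrom (default 17).
#' @return named list of protein inputs.
#' @export
prepare_inputs <- function(coord_sets, embeddings, labels = NULL, dssp = NULL,
                           threshold = 17) {
  ids <- names(coord_sets)
  out <- lapply(ids, function(id) {
    g <- build_graph(compute_distance_map(coord_sets[[id]]$ca_coords), threshold)
    list(id = id,
         embedding = embeddings[[id]],
         graph = g,
         labels = labels[[id]],
         dssp = dssp[[id]],
         plddt = coord_sets[[id]]$plddt)
  })
  stats::setNames(out, ids)
}
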