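ARCHITECTURES <- c("sageconv", "gcnconv", "sageconvmlp", "sageconvgatmlp")

#' Model configuration
#'
#' Fixes an architecture and its dimensions. All four architectures map a
#' protein's L x d node-feature matrix plus its residue graph to an L x 3
#' matrix of per-residue, per-ligand-class binding probabilities
#' (independent sigmoids; multi-label calls are thresholded downstream).
#'
#' Architectures (hidden width 128, dropout 0.7 unless overridden):
#' * `sageconv` (the final published configuration): GraphSAGE(d -> 128),
#'   leaky-relu, dropout, GraphSAGE(128 -> 3). With DSSP features the 20
#'   columns are concatenated at the input (d + 20).
#' * `gcnconv`: GCN(d -> 128), relu, dropout, GCN(128 -> 3); DSSP at input.
#' * `sageconvmlp`: GraphSAGE(d -> 128), leaky-relu, then (optionally
#'   concatenate DSSP -> 148) two fully connected layers (-> 32, relu,
#'   dropout, -> 3).
#' * `sageconvgatmlp`: GraphSAGE(d -> 128) in parallel with a second
#'   GraphSAGE (from d, or from the 20 DSSP features when enabled) whose
#'   output feeds two GATv2 layers halving the width (128 -> 64 -> 32);
#'   concatenation gives 160 features, followed by two fully connected
#'   layers (160 -> 32 -> 3).
#'
#' @param arch one of `"sageconv"`, `"gcnconv"`, `"sageconvmlp"`,
#'   `"sageconvgatmlp"`.
#' @param input_dim embedding dimension d (768/1024/1536/2560 for the usual
#'   pLMs; any positive integer accepted).
#' @param hidden_dim graph-layer width (default 128).
#' @param n_classes number of ligand classes (default 3).
#' @param dropout dropout rate in \[0, 1) (default 0.7).
#' @param use_dssp concatenate the 20 normalized DSSP features?
#' @param dssp_dim width of the DSSP feature block (default 20).
#' @return a `model_config` list.
#' @export
model_config <- function(arch = "sageconv", input_dim = 1024, hidden_dim = 128,
                         n_classes = 3, dropout = 0.7, use_dssp = FALSE,
                         dssp_dim = 20) {
  arch <- match.arg(tolower(arch), ARCHITECTURES)
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(input_dim > 0 && hidden_dim > 0 && n_classes > 0,
              "dimensions must be positive")
  structure(list(arch = arch, input_dim = input_dim, hidden_dim = hidden_dim,
                 n_classes = n_classes, dropout = dropout,
                 use_dssp = isTRUE(use_dssp), dssp_dim = dssp_dim),
            class = "model_config")
}

## Effective width of the graph-layer input (DSSP concatenated at the input
## for the two plain graph architectures).
input_width <- function(config) {
  config$input_dim +
    if (config$use_dssp && config$arch %in% c("sageconv", "gcnconv"))
      config$dssp_dim else 0
}

#' Instantiate a model with freshly initialized weights
#'
#' @param config a [model_config()].
#' @param seed integer RNG seed for the Glorot initialization.
#' @return a `gnn_model`: list with `config` and `params` (named list of
#'   per-layer weight arrays).
#' @export
build_model <- function(config, seed = 1) {
  set.seed(seed)
  h <- config$hidden_dim
  k <- config$n_classes
  p <- switch(config$arch,
    sageconv = list(
      sage1 = init_sage(input_width(config), h),
      sage2 = init_sage(h, k)
    ),
    gcnconv = list(
      gcn1 = init_gcn(input_width(config), h),
      gcn2 = init_gcn(h, k)
    ),
    sageconvmlp = list(
      sage1 = init_sage(config$input_dim, h),
      fc1 = init_dense(h + if (config$use_dssp) config$dssp_dim else 0, 32),
      fc2 = init_dense(32, k)
    ),
    sageconvgatmlp = list(
      sage_a = init_sage(config$input_dim, h),
      sage_b = init_sage(if (config$use_dssp) config$dssp_dim else config$input_dim, h),
      gat1 = init_gatv2(h, h / 2),
      gat2 = init_gatv2(h / 2, h / 4),
      fc1 = init_dense(h + h / 4, 32),
      fc2 = init_dense(32, k)
    )
  )
  structure(list(config = config, params = p), class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  pc <- count_parameters(x$config)
  cat(sprintf("gnn_model <%s> input_dim=%d%s, %s trainable parameters\n",
              x$config$arch, x$config$input_dim,
              if (x$config$use_dssp) " (+DSSP)" else "",
              format(pc$total, big.mark = ",")))
  invisible(x)
}

## Graph operators an architecture needs, precomputed once per protein.
graph_ops <- function(graph, arch) {
  switch(arch,
    gcnconv = list(Ahat = gcn_norm_operator(graph)),
    sageconv = ,
    sageconvmlp = list(P = neighbor_mean_operator(graph)),
    sageconvgatmlp = list(P = neighbor_mean_operator(graph),
                          gat = gat_edges(graph))
  )
}

#' Deterministic forward pass
#'
#' Runs the configured architecture on one protein. Dropout is active only
#' with `training = TRUE`; inference is fully deterministic. Returns the
#' sigmoid probabilities, the pre-sigmoid logits and (for the training
#' loop) the caches needed by the backward pass.
#'
#' @param model a `gnn_model` from [build_model()] or a checkpoint.
#' @param h L x d embedding matrix.
#' @param graph `residue_graph` for the same protein.
#' @param dssp L x 20 normalized DSSP feature matrix; required iff the
#'   config has `use_dssp = TRUE`.
#' @param training enable dropout (training mode)?
#' @param ops optional precomputed [graph] operators (internal reuse).
#' @return list with `probs` (L x 3), `logits` and `cache`.
#' @export
forward_model <- function(model, h, graph, dssp = NULL, training = FALSE,
                          ops = NULL) {
  config <- model$config
  p <- model$params
  assert_that(is.matrix(h) && ncol(h) == config$input_dim,
              sprintf("h must be L x %d", config$input_dim))
  assert_that(nrow(h) == graph$n_nodes, "h rows must match graph nodes")
  if (config$use_dssp) {
    assert_that(!is.null(dssp) && nrow(dssp) == nrow(h) &&
                  ncol(dssp) == config$dssp_dim,
                "config uses DSSP features but no valid dssp matrix supplied")
  }
  if (is.null(ops)) ops <- graph_ops(graph, config$arch)
  cache <- list(ops = ops)

  run_head <- function(x, fc1, fc2) {
    f1 <- dense_forward(x, fc1); cache$fc1 <<- f1$cache
    r1 <- relu_forward(f1$out); cache$relu <<- r1$cache
    d1 <- dropout_forward(r1$out, config$dropout, training); cache$drop <<- d1$cache
    f2 <- dense_forward(d1$out, fc2); cache$fc2 <<- f2$cache
    f2$out
  }

  logits <- switch(config$arch,
    sageconv = {
      x <- if (config$use_dssp) cbind(h, dssp) else h
      s1 <- sage_forward(x, ops$P, p$sage1); cache$sage1 <- s1$cache
      a1 <- lrelu_forward(s1$out); cache$act1 <- a1$cache
      d1 <- dropout_forward(a1$out, config$dropout, training); cache$drop <- d1$cache
      s2 <- sage_forward(d1$out, ops$P, p$sage2); cache$sage2 <- s2$cache
      s2$out
    },
    gcnconv = {
      x <- if (config$use_dssp) cbind(h, dssp) else h
      g1 <- gcn_forward(x, ops$Ahat, p$gcn1); cache$gcn1 <- g1$cache
      a1 <- relu_forward(g1$out); cache$act1 <- a1$cache
      d1 <- dropout_forward(a1$out, config$dropout, training); cache$drop <- d1$cache
      g2 <- gcn_forward(d1$out, ops$Ahat, p$gcn2); cache$gcn2 <- g2$cache
      g2$out
    },
    sageconvmlp = {
      s1 <- sage_forward(h, ops$P, p$sage1); cache$sage1 <- s1$cache
      a1 <- lrelu_forward(s1$out); cache$act1 <- a1$cache
      x <- if (config$use_dssp) cbind(a1$out, dssp) else a1$out
      cache$concat_width <- ncol(x)
      run_head(x, p$fc1, p$fc2)
    },
    sageconvgatmlp = {
      sa <- sage_forward(h, ops$P, p$sage_a); cache$sage_a <- sa$cache
      aa <- lrelu_forward(sa$out); cache$act_a <- aa$cache
      hb <- if (config$use_dssp) dssp else h
      sb <- sage_forward(hb, ops$P, p$sage_b); cache$sage_b <- sb$cache
      ab <- lrelu_forward(sb$out); cache$act_b <- ab$cache
      g1 <- gatv2_forward(ab$out, ops$gat, p$gat1); cache$gat1 <- g1$cache
      a1 <- lrelu_forward(g1$out); cache$act_g1 <- a1$cache
      g2 <- gatv2_forward(a1$out, ops$gat, p$gat2); cache$gat2 <- g2$cache
      a2 <- lrelu_forward(g2$out); cache$act_g2 <- a2$cache
      x <- cbind(aa$out, a2$out)
      cache$concat_width <- ncol(x)
      run_head(x, p$fc1, p$fc2)
    }
  )
  list(probs = sigmoid(logits), logits = logits, cache = cache)
}

## Backward pass from the gradient w.r.t. the logits; returns grads with the
## same structure as model$params.
backward_model <- function(model, cache, dlogits) {
  config <- model$config
  p <- model$params
  grads <- list()

  back_head <- function(G) {
    b2 <- dense_backward(G, cache$fc2, p$fc2); grads$fc2 <<- b2$grads
    Gd <- dropout_backward(b2$dh, cache$drop)
    Gr <- relu_backward(Gd, cache$relu)
    b1 <- dense_backward(Gr, cache$fc1, p$fc1); grads$fc1 <<- b1$grads
    b1$dh
  }

  switch(config$arch,
    sageconv = {
      b2 <- sage_backward(dlogits, cache$sage2, p$sage2); grads$sage2 <- b2$grads
      Gd <- dropout_backward(b2$dh, cache$drop)
      Ga <- lrelu_backward(Gd, cache$act1)
      b1 <- sage_backward(Ga, cache$sage1, p$sage1); grads$sage1 <- b1$grads
    },
    gcnconv = {
      b2 <- gcn_backward(dlogits, cache$gcn2, p$gcn2); grads$gcn2 <- b2$grads
      Gd <- dropout_backward(b2$dh, cache$drop)
      Ga <- relu_backward(Gd, cache$act1)
      b1 <- gcn_backward(Ga, cache$gcn1, p$gcn1); grads$gcn1 <- b1$grads
    },
    sageconvmlp = {
      dx <- back_head(dlogits)
      h <- model$config$hidden_dim
      Ga <- lrelu_backward(dx[, seq_len(h), drop = FALSE], cache$act1)
      b1 <- sage_backward(Ga, cache$sage1, p$sage1); grads$sage1 <- b1$grads
    },
    sageconvgatmlp = {
      dx <- back_head(dlogits)
      h <- config$hidden_dim
      dA <- dx[, seq_len(h), drop = FALSE]
      dB <- dx[, (h + 1):ncol(dx), drop = FALSE]
      Ga <- lrelu_backward(dA, cache$act_a)
      ba <- sage_backward(Ga, cache$sage_a, p$sage_a); grads$sage_a <- ba$grads
      G2 <- lrelu_backward(dB, cache$act_g2)
      bg2 <- gatv2_backward(G2, cache$gat2, p$gat2); grads$gat2 <- bg2$grads
      G1 <- lrelu_backward(bg2$dh, cache$act_g1)
      bg1 <- gatv2_backward(G1, cache$gat1, p$gat1); grads$gat1 <- bg1$grads
      Gb <- lrelu_backward(bg1$dh, cache$act_b)
      bb <- sage_backward(Gb, cache$sage_b, p$sage_b); grads$sage_b <- bb$grads
    }
  )
  grads
}

#' Count trainable parameters of an architecture (closed form)
#'
#' Per-layer closed forms: GraphSAGE `2*in*out + out` (two weight matrices
#' plus bias), GCN and fully connected `in*out + out`, GATv2 single-head
#' `2*in*out + 2*out` (left/right transforms, attention vector, bias).
#' These equal the array sizes of a model built from the same config
#' (property-tested), so the count is architecture arithmetic, not an
#' empirical measurement.
#'
#' @param config a [model_config()].
#' @return list with `layers` (named integer vector) and `total`.
#' @export
count_parameters <- function(config) {
  h <- config$hidden_dim
  k <- config$n_classes
  n_sage <- function(nin, nout) 2 * nin * nout + nout
  n_lin <- function(nin, nout) nin * nout + nout
  n_gat <- function(nin, nout) 2 * nin * nout + 2 * nout
  layers <- switch(config$arch,
    sageconv = c(sage1 = n_sage(input_width(config), h), sage2 = n_sage(h, k)),
    gcnconv = c(gcn1 = n_lin(input_width(config), h), gcn2 = n_lin(h, k)),
    sageconvmlp = c(
      sage1 = n_sage(config$input_dim, h),
      fc1 = n_lin(h + if (config$use_dssp) config$dssp_dim else 0, 32),
      fc2 = n_lin(32, k)),
    sageconvgatmlp = c(
      sage_a = n_sage(config$input_dim, h),
      sage_b = n_sage(if (config$use_dssp) config$dssp_dim else config$input_dim, h),
      gat1 = n_gat(h, h / 2), gat2 = n_gat(h / 2, h / 4),
      fc1 = n_lin(h + h / 4, 32), fc2 = n_lin(32, k))
  )
  list(layers = layers, total = sum(layers))
}

#' Count parameters by enumerating a built model's weight arrays
#'
#' Independent of the closed forms in [count_parameters()]; used to verify
#' them.
#'
#' @param model a `gnn_model`.
#' @return integer total.
#' @export
count_model_parameters <- function(model) {
  sum(vapply(unlist(model$params, recursive = FALSE), length, integer(1)))
}

#' Parameter count of the reference two-layer sequence CNN
#'
#' The sequence-only state-of-the-art comparison method is a shallow CNN:
#' two 1-D convolutions along the sequence with kernel width 5 and biases,
#' channels `input_dim -> hidden -> n_classes`. Its parameter count is the
#' denominator of the headline ~60 % parameter-reduction figure.
#'
#' @param input_dim embedding dimension (default 1024).
#' @param hidden hidden channels (default 128).
#' @param n_classes output channels (default 3).
#' @param kernel_width convolution kernel width (default 5).
#' @return list with `layers` and `total` (1024/128/3/5 gives 657,411).
#' @export
count_reference_cnn_parameters <- function(input_dim = 1024, hidden = 128,
                                           n_classes = 3, kernel_width = 5) {
  layers <- c(conv1 = input_dim * hidden * kernel_width + hidden,
              conv2 = hidden * n_classes * kernel_width + n_classes)
  list(layers = layers, total = sum(layers))
}

#' Percent reduction in trainable parameters vs. the reference CNN
#'
#' @param n_model parameter count of the GNN.
#' @param n_reference parameter count of the reference CNN.
#' @return percentage, `100 * (1 - n_model / n_reference)`.
#' @export
parameter_reduction_pct <- function(n_model,
                                    n_reference = count_reference_cnn_parameters()$total) {
  100 * (1 - n_model / n_reference)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is two text files: `<prefix>.json` (versioned config
#' sidecar) and `<prefix>.weights.tsv`, a flat named-array table (array
#' name, dimensions, values at `%.17g`, which round-trips IEEE doubles
#' exactly). `load_checkpoint(save_checkpoint(m, p))` is bit-identical.
#'
#' @param model a `gnn_model`.
#' @param prefix path prefix (no extension).
#' @export
save_checkpoint <- function(model, prefix) {
  cfg <- model$config
  jsonlite::write_json(
    list(format = "resibind-checkpoint", version = 1L, config = unclass(cfg)),
    paste0(prefix, ".json"), auto_unbox = TRUE)
  rows <- character(0)
  for (ln in names(model$params)) {
    for (an in names(model$params[[ln]])) {
      x <- model$params[[ln]][[an]]
      d <- if (is.matrix(x)) dim(x) else length(x)
      rows <- c(rows, paste(paste(ln, an, sep = "."),
                            paste(d, collapse = ","),
                            paste(format_full(as.vector(x)), collapse = " "),
                            sep = "\t"))
    }
  }
  writeLines(rows, paste0(prefix, ".weights.tsv"))
  invisible(prefix)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  assert_that(identical(meta$format, "resibind-checkpoint"),
              "not a resibind checkpoint")
  cfg <- do.call(model_config, meta$config[c("arch", "input_dim", "hidden_dim",
                                             "n_classes", "dropout", "use_dssp",
                                             "dssp_dim")])
  params <- list()
  for (row in readLines(paste0(prefix, ".weights.tsv"))) {
    parts <- strsplit(row, "\t", fixed = TRUE)[[1]]
    nm <- strsplit(parts[1], ".", fixed = TRUE)[[1]]
    d <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    v <- as.numeric(strsplit(parts[3], " ", fixed = TRUE)[[1]])
    params[[nm[1]]][[nm[2]]] <- if (length(d) == 2) matrix(v, d[1], d[2]) else v
  }
  structure(list(config = cfg, params = params), class = "gnn_model")
}
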