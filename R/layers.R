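## Message-passing and dense layers with explicit forward/backward passes.
## Each forward returns list(out, cache); each backward takes the upstream
## gradient and returns list(grads = <same shape as params>, dh = input grad).
## Gradients are exact (checked against central differences in the tests).

## Glorot/Xavier uniform initialization.
init_mat <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

init_dense <- function(nin, nout) list(W = init_mat(nin, nout), b = rep(0, nout))

dense_forward <- function(h, p) {
  list(out = sweep(h %*% p$W, 2, p$b, `+`), cache = list(h = h))
}

dense_backward <- function(G, cache, p) {
  list(grads = list(W = crossprod(cache$h, G), b = colSums(G)),
       dh = G %*% t(p$W))
}

## GraphSAGE: out_i = W_self h_i + W_nbr m_i + b with m_i the edge-weighted
## mean of neighbor features (zero vector for isolated nodes). P is the
## row-normalized weighted adjacency from neighbor_mean_operator().
init_sage <- function(nin, nout) {
  list(W_self = init_mat(nin, nout), W_nbr = init_mat(nin, nout), b = rep(0, nout))
}

sage_forward <- function(h, P, p) {
  m <- as.matrix(P %*% h)
  list(out = sweep(h %*% p$W_self + m %*% p$W_nbr, 2, p$b, `+`),
       cache = list(h = h, m = m, P = P))
}

sage_backward <- function(G, cache, p) {
  list(grads = list(W_self = crossprod(cache$h, G),
                    W_nbr = crossprod(cache$m, G),
                    b = colSums(G)),
       dh = G %*% t(p$W_self) +
         as.matrix(Matrix::crossprod(cache$P, G %*% t(p$W_nbr))))
}

## GCN with symmetric normalization over the weighted adjacency plus unit
## self-loops: out = Ahat H W + b.
init_gcn <- init_dense

gcn_forward <- function(h, Ahat, p) {
  ah <- as.matrix(Ahat %*% h)
  list(out = sweep(ah %*% p$W, 2, p$b, `+`),
       cache = list(ah = ah, Ahat = Ahat))
}

gcn_backward <- function(G, cache, p) {
  list(grads = list(W = crossprod(cache$ah, G), b = colSums(G)),
       dh = as.matrix(Matrix::crossprod(cache$Ahat, G %*% t(p$W))))
}

## Single-head GATv2 attention over N(i) U {i}:
##   e_ij = a . LeakyReLU(W_l h_i + W_r h_j),  alpha = softmax_j over N(i)U{i},
##   out_i = sum_j alpha_ij (W_r h_j) + b.
## `edges` carries directed edges including self-loops (src, dst).
## The attention LeakyReLU uses the customary slope 0.2.
init_gatv2 <- function(nin, nout) {
  list(W_l = init_mat(nin, nout), W_r = init_mat(nin, nout),
       a = stats::runif(nout, -sqrt(6 / (nout + 1)), sqrt(6 / (nout + 1))),
       b = rep(0, nout))
}

gat_edges <- function(graph) {
  de <- directed_edges(graph)
  n <- graph$n_nodes
  list(src = c(de$src, seq_len(n)), dst = c(de$dst, seq_len(n)), n = n)
}

## rowsum over a grouping that is guaranteed to contain every node (each
## node has a self-loop), so results come back in node order 1..n.
group_sum <- function(x, g) rowsum(x, g)

gatv2_forward <- function(h, edges, p, att_slope = 0.2) {
  src <- edges$src; dst <- edges$dst; n <- edges$n
  Hl <- h %*% p$W_l
  Hr <- h %*% p$W_r
  U <- Hl[src, , drop = FALSE] + Hr[dst, , drop = FALSE]
  S <- leaky_relu(U, att_slope)
  e <- as.vector(S %*% p$a)
  emax <- as.numeric(tapply(e, factor(src, levels = seq_len(n)), max))
  ex <- exp(e - emax[src])
  Z <- as.vector(group_sum(ex, src))
  alpha <- as.numeric(ex / Z[src])
  M <- Matrix::sparseMatrix(i = src, j = seq_along(src), x = alpha,
                            dims = c(n, length(src)))
  out <- sweep(as.matrix(M %*% Hr[dst, , drop = FALSE]), 2, p$b, `+`)
  list(out = out,
       cache = list(h = h, Hl = Hl, Hr = Hr, U = U, S = S, alpha = alpha,
                    src = src, dst = dst, n = n, att_slope = att_slope))
}

gatv2_backward <- function(G, cache, p) {
  src <- cache$src; dst <- cache$dst
  z <- cache$Hr[dst, , drop = FALSE]
  Gsrc <- G[src, , drop = FALSE]
  dz_agg <- cache$alpha * Gsrc
  dalpha <- rowSums(Gsrc * z)
  sg <- as.vector(group_sum(cache$alpha * dalpha, src))
  de <- cache$alpha * (dalpha - sg[src])
  dS <- de %o% p$a
  da <- as.vector(crossprod(cache$S, de))
  dU <- dS * leaky_relu_grad(cache$U, cache$att_slope)
  dHl <- group_sum(dU, src)
  dHr <- group_sum(dU, dst) + group_sum(dz_agg, dst)
  list(grads = list(W_l = crossprod(cache$h, dHl),
                    W_r = crossprod(cache$h, dHr),
                    a = da, b = colSums(G)),
       dh = dHl %*% t(p$W_l) + dHr %*% t(p$W_r))
}

## Activations ------------------------------------------------------------

relu_forward <- function(h) list(out = relu(h), cache = list(h = h))
relu_backward <- function(G, cache) G * (cache$h > 0)

lrelu_forward <- function(h, slope = 0.01) {
  list(out = leaky_relu(h, slope), cache = list(h = h, slope = slope))
}
lrelu_backward <- function(G, cache) G * leaky_relu_grad(cache$h, cache$slope)

## Inverted dropout; identity at inference so predictions are deterministic.
dropout_forward <- function(h, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = h, cache = list(mask = NULL, rate = rate)))
  }
  mask <- matrix(stats::runif(length(h)) >= rate, nrow(h), ncol(h)) / (1 - rate)
  list(out = h * mask, cache = list(mask = mask, rate = rate))
}
dropout_backward <- function(G, cache) {
  if (is.null(cache$mask)) G else G * cache$mask
}
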