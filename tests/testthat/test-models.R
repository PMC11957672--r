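# scalar-feature params for hand-worked layer examples
scalar_sage <- function(w_self, w_nbr, b = 0) {
  list(W_self = matrix(w_self), W_nbr = matrix(w_nbr), b = b)
}

test_that("GraphSAGE layer computes self transform plus weighted neighbor mean", {
  # node 1 linked to nodes 2 and 3
  h <- matrix(c(0, 1, 3))

  g_eq <- manual_graph(3, c(1, 2, 1, 3), weights = c(1, 1))
  P <- resibind:::neighbor_mean_operator(g_eq)
  out <- resibind:::sage_forward(h, P, scalar_sage(0, 1))$out
  expect_equal(out[1], 2)  # unweighted mean of 1 and 3

  g_w <- manual_graph(3, c(1, 2, 1, 3), weights = c(3, 1))
  P <- resibind:::neighbor_mean_operator(g_w)
  out <- resibind:::sage_forward(h, P, scalar_sage(0, 1))$out
  expect_equal(out[1], (3 * 1 + 1 * 3) / 4)  # hand-computed weighted mean

  # explicit-loop oracle on a random case
  set.seed(2)
  L <- 7
  coords <- generate_chain(L, seed = 3)$ca_coords
  g <- build_graph(compute_distance_map(coords), 8)
  hh <- matrix(rnorm(L))
  P <- resibind:::neighbor_mean_operator(g)
  out <- resibind:::sage_forward(hh, P, scalar_sage(0, 1))$out
  for (i in seq_len(L)) {
    nb <- c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1])
    w <- c(g$weights[g$edges[, 1] == i], g$weights[g$edges[, 2] == i])
    expected <- if (length(nb)) sum(w * hh[nb]) / sum(w) else 0
    expect_equal(out[i], expected)
  }

  # isolated node: neighbor mean is the zero vector
  g_iso <- manual_graph(2, c(1, 2)[0], weights = numeric(0))
  P <- resibind:::neighbor_mean_operator(g_iso)
  out <- resibind:::sage_forward(matrix(c(5, -2)), P, scalar_sage(1, 9))$out
  expect_equal(as.vector(out), c(5, -2))
})

test_that("GCN layer applies symmetric normalization with self-loops", {
  # single node, no edges: A + I = 1, plain linear map
  g1 <- manual_graph(1, integer(0), numeric(0))
  Ahat <- resibind:::gcn_norm_operator(g1)
  out <- resibind:::gcn_forward(matrix(3), Ahat, list(W = matrix(2), b = 1))$out
  expect_equal(out[1], 7)

  # two nodes, one unit edge: each output is the mean of self and other
  g2 <- manual_graph(2, c(1, 2), weights = 1)
  Ahat <- resibind:::gcn_norm_operator(g2)
  h <- matrix(c(1, 3))
  out <- resibind:::gcn_forward(h, Ahat, list(W = matrix(1), b = 0))$out
  expect_equal(as.vector(out), c(2, 2))
  # dense-matrix oracle
  A <- matrix(c(1, 1, 1, 1), 2)  # A + I with w = 1
  Dm <- diag(1 / sqrt(rowSums(A)))
  expect_equal(unname(as.matrix(Ahat)), Dm %*% A %*% Dm)

  # no edges at all: layer degenerates to a per-node linear map
  g0 <- manual_graph(3, integer(0), numeric(0))
  Ahat <- resibind:::gcn_norm_operator(g0)
  h <- matrix(rnorm(3))
  out <- resibind:::gcn_forward(h, Ahat, list(W = matrix(2), b = 0.5))$out
  expect_equal(as.vector(out), as.vector(2 * h + 0.5))
})

test_that("GATv2 attention is a proper softmax over the closed neighborhood", {
  set.seed(3)
  L <- 6
  g <- build_graph(compute_distance_map(generate_chain(L, seed = 4)$ca_coords), 8)
  edges <- resibind:::gat_edges(g)
  p <- resibind:::init_gatv2(2, 2)
  h <- matrix(rnorm(L * 2), L, 2)

  # attention rows sum to 1 (checked against an explicit softmax oracle)
  fw <- resibind:::gatv2_forward(h, edges, p)
  sums <- tapply(fw$cache$alpha, fw$cache$src, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, L))

  # all logits equal (a = 0): uniform attention, output = mean of W_r h
  p0 <- p; p0$a <- c(0, 0); p0$b <- c(0, 0)
  out <- resibind:::gatv2_forward(h, edges, p0)$out
  Hr <- h %*% p0$W_r
  for (i in seq_len(L)) {
    nbh <- c(i, c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1]))
    expect_equal(out[i, ], colMeans(Hr[nbh, , drop = FALSE]))
  }

  # single node: alpha_ii = 1, output = W_r h + b
  g1 <- manual_graph(1, integer(0), numeric(0))
  out1 <- resibind:::gatv2_forward(matrix(c(1, 2), 1), resibind:::gat_edges(g1), p)$out
  expect_equal(as.vector(out1), as.vector(matrix(c(1, 2), 1) %*% p$W_r + p$b))
})

test_that("layer backward passes match central-difference gradients", {
  set.seed(10)
  L <- 6
  g <- build_graph(compute_distance_map(generate_chain(L, seed = 21)$ca_coords), 9)
  h <- matrix(rnorm(L * 4), L, 4)
  G <- matrix(rnorm(L * 3), L, 3)
  check <- function(fwd, bwd, params) {
    fw <- fwd(h, params)
    grads <- bwd(G, fw$cache, params)
    for (an in names(params)) {
      for (k in sample(length(params[[an]]), min(3, length(params[[an]])))) {
        eps <- 1e-6
        up <- params; up[[an]][k] <- up[[an]][k] + eps
        dn <- params; dn[[an]][k] <- dn[[an]][k] - eps
        num <- (sum(fwd(h, up)$out * G) - sum(fwd(h, dn)$out * G)) / (2 * eps)
        expect_equal(grads$grads[[an]][k], num, tolerance = 1e-5)
      }
    }
    # input gradient
    k <- sample(length(h), 1)
    eps <- 1e-6
    hu <- h; hu[k] <- hu[k] + eps
    hd <- h; hd[k] <- hd[k] - eps
    num <- (sum(fwd(hu, params)$out * G) - sum(fwd(hd, params)$out * G)) / (2 * eps)
    expect_equal(grads$dh[k], num, tolerance = 1e-5)
  }
  P <- resibind:::neighbor_mean_operator(g)
  check(function(h, p) resibind:::sage_forward(h, P, p),
        resibind:::sage_backward, resibind:::init_sage(4, 3))
  Ahat <- resibind:::gcn_norm_operator(g)
  check(function(h, p) resibind:::gcn_forward(h, Ahat, p),
        resibind:::gcn_backward, resibind:::init_gcn(4, 3))
  edges <- resibind:::gat_edges(g)
  # scale pre-activations away from the LeakyReLU kink for clean differences
  pg <- resibind:::init_gatv2(4, 3)
  pg$W_l <- pg$W_l * 3; pg$W_r <- pg$W_r * 3
  check(function(h, p) resibind:::gatv2_forward(h, edges, p),
        resibind:::gatv2_backward, pg)
  check(function(h, p) resibind:::dense_forward(h, p),
        function(G, cache, p) resibind:::dense_backward(G, cache, p),
        resibind:::init_dense(4, 3))
})

test_that("all architectures produce deterministic L x 3 probabilities", {
  L <- 12
  g <- build_graph(compute_distance_map(generate_chain(L, seed = 6)$ca_coords), 10)
  for (arch in c("sageconv", "gcnconv", "sageconvmlp", "sageconvgatmlp")) {
    for (use_dssp in c(FALSE, TRUE)) {
      cfg <- model_config(arch, input_dim = 16, hidden_dim = 8,
                          use_dssp = use_dssp, dssp_dim = 20)
      m <- build_model(cfg, seed = 2)
      h <- matrix(rnorm(L * 16), L, 16)
      dssp <- if (use_dssp) matrix(runif(L * 20), L, 20)
      p1 <- forward_model(m, h, g, dssp)$probs
      p2 <- forward_model(m, h, g, dssp)$probs
      expect_equal(dim(p1), c(L, 3))
      expect_true(all(p1 > 0 & p1 < 1))
      expect_identical(p1, p2)
    }
    cfg <- model_config(arch, input_dim = 16, hidden_dim = 8, use_dssp = TRUE)
    m <- build_model(cfg, seed = 2)
    expect_error(forward_model(m, matrix(rnorm(L * 16), L, 16), g), "dssp")
  }
})

test_that("architectures are equivariant under node relabeling", {
  set.seed(13)
  L <- 10
  coords <- generate_chain(L, seed = 14)$ca_coords
  perm <- sample(L)
  g <- build_graph(compute_distance_map(coords), 12)
  g_perm <- build_graph(compute_distance_map(coords[perm, ]), 12)
  h <- matrix(rnorm(L * 8), L, 8)
  dssp <- matrix(runif(L * 20), L, 20)
  for (arch in c("sageconv", "gcnconv", "sageconvmlp", "sageconvgatmlp")) {
    cfg <- model_config(arch, input_dim = 8, hidden_dim = 8, use_dssp = TRUE)
    m <- build_model(cfg, seed = 3)
    base <- forward_model(m, h, g, dssp)$probs
    permuted <- forward_model(m, h[perm, ], g_perm, dssp[perm, ])$probs
    expect_equal(permuted, base[perm, ], tolerance = 1e-10)
  }
})

test_that("published architecture widths are reproduced", {
  # DSSP concatenation grows the graph-layer input from 1024 to 1044
  cfg <- model_config("sageconv", input_dim = 1024, use_dssp = TRUE)
  m <- build_model(cfg, seed = 1)
  expect_equal(nrow(m$params$sage1$W_self), 1044)
  cfg_gcn <- model_config("gcnconv", input_dim = 1024, use_dssp = TRUE)
  expect_equal(nrow(build_model(cfg_gcn, seed = 1)$params$gcn1$W), 1044)

  # parallel-branch concatenation is 128 + 32 = 160 wide
  L <- 8
  g <- build_graph(compute_distance_map(generate_chain(L, seed = 2)$ca_coords), 10)
  cfg2 <- model_config("sageconvgatmlp", input_dim = 24)
  m2 <- build_model(cfg2, seed = 1)
  fw <- forward_model(m2, matrix(rnorm(L * 24), L, 24), g)
  expect_equal(fw$cache$concat_width, 160)
  expect_equal(nrow(m2$params$fc1$W), 160)

  # DSSP-augmented first fully connected layer of the MLP variant is 148 wide
  cfg3 <- model_config("sageconvmlp", input_dim = 1024, use_dssp = TRUE)
  expect_equal(nrow(build_model(cfg3, seed = 1)$params$fc1$W), 148)
})

test_that("closed-form parameter counts equal enumerated weight arrays", {
  for (arch in c("sageconv", "gcnconv", "sageconvmlp", "sageconvgatmlp")) {
    for (use_dssp in c(FALSE, TRUE)) {
      for (d in c(768, 1024)) {
        cfg <- model_config(arch, input_dim = d, use_dssp = use_dssp)
        expect_equal(count_parameters(cfg)$total,
                     count_model_parameters(build_model(cfg, seed = 1)),
                     info = paste(arch, use_dssp, d))
      }
    }
  }
})

test_that("the SAGEConv model cuts the reference CNN parameters by ~60 %", {
  sage <- count_parameters(model_config("sageconv", input_dim = 1024))
  expect_equal(sage$total, 263043)
  expect_equal(unname(sage$layers["sage1"]), 2 * 1024 * 128 + 128)
  cnn <- count_reference_cnn_parameters()
  expect_equal(cnn$total, 657411)
  expect_equal(parameter_reduction_pct(sage$total, cnn$total), 59.99,
               tolerance = 0.001)
})

test_that("checkpoints round-trip bit-exactly", {
  cfg <- model_config("sageconvgatmlp", input_dim = 12, hidden_dim = 8,
                      use_dssp = TRUE)
  m <- build_model(cfg, seed = 9)
  prefix <- file.path(withr::local_tempdir(), "ckpt")
  save_checkpoint(m, prefix)
  back <- load_checkpoint(prefix)
  expect_identical(back$params, m$params)
  expect_equal(unclass(back$config), unclass(m$config))
})
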