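# shared fixtures and independent oracles used across test files

# two rigid 2-atom fragments about one rotatable bond: the minimal torsion
chain4 <- function(coords = rbind(c(-0.5, 1, 0), c(0, 0, 0),
                                  c(1.5, 0, 0), c(2, 1, 0))) {
  list(conformer = conformer(rep("C", 4), coords),
       topology = dihedral_topology(
         bonds = list(c(1, 2), c(2, 3), c(3, 4)),
         dihedrals = list(c(1, 2, 3, 4)),
         fragments = list(c(1, 2), c(3, 4))))
}

# independent closed-form torsion: praxeolitic atan2 formula, written
# differently from the package implementation (explicit projection vectors)
reference_torsion <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1]) * w)
  (atan2(y, x) / pi * 180) %% 360
}

# brute-force clash scan: double loop over all eligible pairs
reference_clash <- function(conf, top, threshold = 2.1) {
  n <- nrow(conf$coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!top$clash_eligible[i, j]) next
    if (sqrt(sum((conf$coords[i, ] - conf$coords[j, ])^2)) < threshold)
      return(TRUE)
  }
  FALSE
}

# neuron-by-neuron forward pass with explicit loops (no matrix products)
reference_forward <- function(net, x, output = "linear") {
  h <- x
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- numeric(ncol(net$W[[l]]))
    for (j in seq_along(z)) {
      s <- net$b[[l]][j]
      for (i in seq_along(h)) s <- s + net$W[[l]][i, j] * h[i]
      z[j] <- s
    }
    h <- if (l < L || output == "logistic") 1 / (1 + exp(-z)) else z
  }
  h
}

# hand-built classifier ensemble whose members vote a fixed pattern
# (zero weights, output bias sign decides the vote), for gating tests
fixed_vote_classifier <- function(votes, n_d = 2,
                                  encoding = feature_encoding()) {
  p <- n_d * features_per_dihedral(encoding)
  member <- function(v) {
    list(net = list(W = list(matrix(0, p, 3), matrix(0, 3, 1)),
                    b = list(numeric(3), if (v) 5 else -5),
                    layer_sizes = c(p, 3L, 1L)),
         output = "logistic", hidden = 3L, seed = 0L,
         stopped_epoch = 0L, best_epoch = 0L, validation_loss = NA_real_)
  }
  structure(list(members = lapply(votes, member),
                 encoding = encoding,
                 feature_center = numeric(p), feature_scale = rep(1, p),
                 threshold_energy = 46, n_d = n_d, seed = 0L),
            class = "classifier_ensemble")
}

small_control <- function(max_epochs = 25L)
  training_control(max_epochs = max_epochs)
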