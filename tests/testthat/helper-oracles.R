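# Independent oracles and in-code fixtures shared across tests. These stay
# deliberately naive (loops, double loops) so they cannot share a defect
# with the vectorized implementations they check.

# Loop-based forward pass: one neuron at a time.
oracle_forward <- function(params, X) {
  act <- function(name) switch(name,
    tanh = tanh,
    logistic = function(z) 1 / (1 + exp(-z)),
    identity = function(z) z)
  f <- act(params$f_hidden); g <- act(params$f_output)
  n <- nrow(X); nh <- length(params$B1); no <- length(params$B2)
  out <- matrix(0, n, no)
  for (i in seq_len(n)) {
    h <- numeric(nh)
    for (j in seq_len(nh)) {
      h[j] <- f(sum(params$W1[j, ] * X[i, ]) + params$B1[j])
    }
    for (k in seq_len(no)) {
      out[i, k] <- g(sum(params$W2[k, ] * h) + params$B2[k])
    }
  }
  out
}

random_mlp <- function(n_in, n_hidden, n_out, f_hidden, f_output) {
  mlp_parameters(
    W1 = matrix(rnorm(n_hidden * n_in), n_hidden, n_in),
    B1 = rnorm(n_hidden),
    W2 = matrix(rnorm(n_out * n_hidden), n_out, n_hidden),
    B2 = rnorm(n_out),
    f_hidden = f_hidden, f_output = f_output)
}

# Double-loop dominance oracle (maximization in all columns).
oracle_pareto <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# Naive agglomerative clustering, complete linkage on Manhattan distances;
# returns the merge heights in order and the partition after each merge.
oracle_hclust <- function(m) {
  n <- nrow(m)
  manhattan <- function(a, b) sum(abs(a - b))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- max(vapply(clusters[[i]], function(a) {
          max(vapply(clusters[[j]], function(b) manhattan(m[a, ], m[b, ]),
                     numeric(1)))
        }, numeric(1)))
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    labels <- integer(n)
    for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition label vector, for comparison up to relabeling.
canonical_partition <- function(labels) match(labels, unique(labels))

# Synthetic TPC-like quadratic surface used by the recovery experiments: an
# interior maximum at (20 min, 50 C, 18 mL/g), spanning roughly the measured
# TPC range over the factor box, with the campaign's median replicate SD.
tpc_like_spec <- function(noise_sd = 0.224) {
  coef <- tibble::tribble(
    ~response, ~term, ~value,
    "TPC", "intercept", 16.5 - 0.02 * 400 - 0.0064 * 2500 - 0.028 * 324,
    "TPC", "time", 0.02 * 2 * 20,
    "TPC", "temperature", 0.0064 * 2 * 50,
    "TPC", "ratio", 0.028 * 2 * 18,
    "TPC", "time2", -0.02,
    "TPC", "temperature2", -0.0064,
    "TPC", "ratio2", -0.028)
  surface_spec(coef, noise_sd = c(TPC = noise_sd))
}

paper_levels <- function() {
  list(time = c(10, 20, 30), temperature = c(25, 50, 75),
       ratio = c(10, 15, 20))
}

# A hand-built monotone-increasing linear "surrogate": y = x1 + x2 + x3 in
# scaled space, increasing in every factor.
monotone_surrogate <- function() {
  box <- rbind(c(10, 25, 10), c(30, 75, 20))
  colnames(box) <- c("time", "temperature", "ratio")
  out <- matrix(c(0, 3), 2, 1, dimnames = list(NULL, "y"))
  structure(list(
    parameters = mlp_parameters(W1 = diag(3), B1 = rep(0, 3),
                                W2 = matrix(1, 1, 3), B2 = 0,
                                f_hidden = "identity", f_output = "identity"),
    hidden = 3, outputs = "y",
    input_scaler = fit_scaler(box, "minmax", c(0, 1)),
    output_scaler = fit_scaler(out, "minmax", c(0, 1)),
    split = NULL, performance = NULL, history = NULL, control = NULL),
    class = "uae_mlp")
}
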