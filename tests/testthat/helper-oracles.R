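# Independent oracles used across the suite. Deliberately brute-force and
# structured differently from the package implementation.

# Undecimated Haar transform by explicit periodic convolution with the
# level-l filters upsampled by 2^(l-1): h = (1, 1)/sqrt(2) at offsets
# {0, 2^(l-1)}, g = (1, -1)/sqrt(2). Double loop, no vectorised shifts.
oracle_swt <- function(x, j) {
  n <- length(x)
  a <- x
  details <- vector("list", j)
  for (l in seq_len(j)) {
    gap <- 2^(l - 1)
    h_tap <- c(0, gap)            # offsets of the two nonzero taps
    a_new <- numeric(n)
    d_new <- numeric(n)
    for (k in seq_len(n)) {
      sa <- 0
      sdl <- 0
      for (m in seq_along(h_tap)) {
        idx <- ((k - 1 + h_tap[m]) %% n) + 1
        coef_h <- 1 / sqrt(2)
        coef_g <- if (m == 1) 1 / sqrt(2) else -1 / sqrt(2)
        sa <- sa + coef_h * a[idx]
        sdl <- sdl + coef_g * a[idx]
      }
      a_new[k] <- sa
      d_new[k] <- sdl
    }
    details[[l]] <- d_new
    a <- a_new
  }
  list(details = details, approx = a)
}

# Direct O(N^2) DFT magnitude, one-sided, scaled by 1/fs.
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2) + 1
  mag <- numeric(half)
  for (k in seq_len(half)) {
    acc <- 0 + 0i
    for (m in seq_len(n)) {
      acc <- acc + x[m] * exp(-2i * pi * (k - 1) * (m - 1) / n)
    }
    mag[k] <- Mod(acc) / fs
  }
  mag
}

# Definition-level moment statistics (explicit sums).
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  cm <- function(p) sum((x - mu)^p) / n
  list(mean = mu,
       var = sum((x - mu)^2) / (n - 1),
       sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skew = cm(3) / cm(2)^1.5,
       kurt = cm(4) / cm(2)^2)
}

# Pearson's rho from the covariance definition.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  cov_xy <- sum((x - mx) * (y - my)) / (n - 1)
  cov_xy / (sqrt(sum((x - mx)^2) / (n - 1)) * sqrt(sum((y - my)^2) / (n - 1)))
}

# Gaussian class clusters with well-separated means: a table any sane
# classifier (including nearest-centroid) separates almost perfectly.
make_separable_table <- function(n_per_class = 60, n_feat = 5, sep = 3,
                                 sd = 1, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(1:3, function(cl) {
      m <- matrix(stats::rnorm(n_per_class * n_feat, mean = (cl - 1) * sep,
                               sd = sd),
                  nrow = n_per_class)
      df <- as.data.frame(m)
      names(df) <- paste0("f", seq_len(n_feat))
      df$class <- cl
      df
    })
    tibble::as_tibble(do.call(rbind, rows))
  })
}

# Nearest-centroid classifier, leave-one-out.
nearest_centroid_loo_accuracy <- function(tab) {
  feats <- setdiff(names(tab), "class")
  X <- as.matrix(tab[, feats])
  cls <- tab$class
  pred <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    cents <- vapply(sort(unique(cls)), function(k) {
      colMeans(X[cls == k & seq_len(nrow(X)) != i, , drop = FALSE])
    }, numeric(ncol(X)))
    d2 <- colSums((cents - X[i, ])^2)
    pred[i] <- sort(unique(cls))[which.min(d2)]
  }
  100 * mean(pred == cls)
}

# Feature-table fixture in which the five redundancy-prone features are
# exact affine images of retained ones (|rho| = 1) and the 18 retained
# features are mutually independent noise.
make_collinear_fixture <- function(n = 200, seed = 42) {
  withr::with_seed(seed, {
    cat23 <- feature_catalogue()
    retained <- cat23[1:18]
    tab <- as.data.frame(matrix(stats::rnorm(n * 18), nrow = n))
    names(tab) <- retained
    tab$sc_t_mean <- 2 * tab$sc_t_min + 1
    tab$sc_t_max <- -0.5 * tab$sc_t_range + 3
    tab$sc_t_median <- 1.2 * tab$sc_t_std
    tab$scl_t_mean <- 0.8 * tab$scl_t_min - 2
    tab$scl_t_max <- 3 * tab$scl_t_std + 0.5
    tab$class <- rep_len(1:3, n)
    tibble::as_tibble(tab[, c(cat23, "class")])
  })
}

rmse <- function(a, b) sqrt(mean((a - b)^2))
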