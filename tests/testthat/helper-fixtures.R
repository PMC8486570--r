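# fixture builders shared across test files

# small labeled Gaussian training set (not via the generator; for classifier
# unit tests that should not depend on the synthetic_data module)
gaussian_classes <- function(seed, n_classes = 3, n_per_class = 10,
                             n_features = 6, separation = 2, sd = 1) {
  set.seed(seed)
  x <- NULL; y <- character(0)
  for (k in seq_len(n_classes)) {
    mu <- rep(0, n_features)
    mu[((k - 1) %% n_features) + 1] <- separation
    xk <- matrix(stats::rnorm(n_per_class * n_features, 0, sd),
                 n_per_class, n_features)
    xk <- sweep(xk, 2, mu, "+")
    x <- rbind(x, xk)
    y <- c(y, rep(sprintf("C%02d", k), n_per_class))
  }
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  rownames(x) <- sprintf("s%03d", seq_len(nrow(x)))
  list(x = x, y = y)
}

# full generator -> classifier-ready feature pipeline
featurize <- function(m) {
  log_transform(exclude_mirnas(normalize_median(m)))
}

# reference cohort + featurized matrix + merged labels
training_fixture <- function(seed = 7, n_classes = 17, n_per_class = 5,
                             separation = 2.5) {
  cfg <- sim_config(seed = seed, n_per_class = n_per_class,
                    class_separation = separation)
  profiles <- make_class_profiles(n_classes, config = cfg)
  ref <- simulate_reference_cohort(profiles, cfg)
  fx <- featurize(ref$matrix)
  list(cfg = cfg, profiles = profiles, ref = ref, x = fx$values,
       y = ref$meta$class_label)
}
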