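# A cheap synthetic feature table: class structure planted in a couple of
# columns, everything else noise.
toy_features <- function(n_per_class, seed, classes = c("noMig", "mig12",
                                                        "mig21")) {
  set.seed(seed)
  k <- length(classes)
  n <- n_per_class * k
  df <- as.data.frame(matrix(rnorm(n * 31), n))
  colnames(df) <- feature_names()
  y <- rep(classes, each = n_per_class)
  shift <- (match(y, classes) - 1) * 4
  df$d_min <- df$d_min + shift
  df$Z_X <- df$Z_X - shift
  list(features = df, labels = y)
}
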