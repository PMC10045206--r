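# Shared fixtures built in code at test time.

# A small, fast phantom configuration (geometry unchanged, fewer slices).
tiny_phantom <- function(...) {
  args <- utils::modifyList(
    list(n_vessels = 8L, slices_per_vessel = 10L, grid_size = 48L),
    list(...))
  do.call(phantom_config, args)
}

# Synthetic feature table with independent Gaussian columns spread over the
# seven families, plus labels; optionally some columns get a mean shift in
# positive rows ("informative").
random_feature_table <- function(n = 30, per_family = 20, n_informative = 0,
                                 effect = 1.5, seed = 1,
                                 range_kind = "LOI") {
  set.seed(seed)
  fams <- c("shape", "firstorder", "glcm", "gldm", "glrlm", "glszm", "ngtdm")
  cols <- unlist(lapply(fams, function(f)
    sprintf("mean_%s_f%02d_8b", f, seq_len(per_family))))
  X <- matrix(rnorm(n * length(cols)), n, length(cols),
              dimnames = list(NULL, cols))
  y <- rep(c(TRUE, FALSE), length.out = n)
  y <- sample(y)
  if (n_informative > 0) {
    inf_cols <- sample(ncol(X), n_informative)
    X[y, inf_cols] <- X[y, inf_cols] + effect
    attr(X, "informative") <- colnames(X)[inf_cols]
  }
  ft <- feature_table(as.data.frame(X),
                      data.frame(vessel_id = sprintf("v%02d", seq_len(n)),
                                 tcfa = y, mc = y, tcfa_mc = y),
                      range_kind)
  attr(ft, "informative") <- attr(X, "informative")
  ft
}

# Disc mask of radius r pixels centred in an n x n grid.
disc_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+"))
  d <= r
}
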