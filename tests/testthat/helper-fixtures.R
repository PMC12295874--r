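# Shared fixtures, all built in code at test time.

# information-rich PWM: base cycle A,C,G,T with 0.94 on the consensus
consensus_pwm <- function(width = 8L, name = "CONS") {
  m <- matrix(0.02, 4, width)
  for (j in seq_len(width)) m[((j - 1) %% 4) + 1, j] <- 0.94
  pwm(m, name)
}

random_pwm <- function(width, name = "RND", seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::runif(4 * width), 4, width)
  pwm(sweep(m, 2, colSums(m), "/"), name)
}

random_sequence <- function(n, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# hand-built tree node tables for the RI / ID oracles
toy_tree_single_node <- function(ig = 1, n = 10) {
  data.frame(
    feature = c("g", NA, NA), threshold = c(0, NA, NA), ig = c(ig, 0, 0),
    n = c(n, n / 2, n / 2), left = c(2, 0, 0), right = c(3, 0, 0),
    parent = c(0, 1, 1), pred = NA, stringsAsFactors = FALSE
  )
}

# small two-class matrix with one perfectly separating feature
separable_data <- function(n = 60, p = 20, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
    dimnames = list(sprintf("s%03d", seq_len(n)), sprintf("f%03d", seq_len(p)))
  )
  y <- factor(rep(c("a", "b"), length.out = n))
  x[, 1] <- ifelse(y == "a", 1, 0) + rnorm(n, sd = 0.01)
  list(x = x, y = y)
}

# exhaustive search over all (feature, midpoint-threshold) splits
brute_force_best_split <- function(x, y, task = "classification") {
  best <- list(gain = 0, feature = NA, threshold = NA)
  for (j in seq_len(ncol(x))) {
    v <- sort(unique(x[, j]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      l <- x[, j] <= thr
      gain <- if (task == "classification") {
        information_gain(y, y[l], y[!l])
      } else {
        variance_reduction(y, list(y[l], y[!l]))
      }
      if (gain > best$gain + 1e-12) {
        best <- list(gain = gain, feature = colnames(x)[j], threshold = thr)
      }
    }
  }
  best
}

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_spec(
        n_cancer = 30, n_normal = 10, p_mrna = 60, p_mirna = 50,
        p_meth = 70, k_informative = 5, effect_size = 2, seed = 42
      ))
    }
    cache
  }
})
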