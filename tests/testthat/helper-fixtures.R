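# shared in-code fixtures

# small binary mutation profile with all four roles
toy_profile <- function() {
  w <- matrix(
    c(1, 1, 1, 0, 0,
      1, 1, 0, 1, 0,
      0, 1, 1, 1, 0,
      1, 0, 1, 1, 0,
      0, 0, 1, 1, 0),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("v", 1:5), c("T1", "L1", "D1", "D2", "N1"))
  )
  mutation_profile_set(
    "toy", w,
    c(T1 = "primary", L1 = "lymph_node", D1 = "distant", D2 = "distant",
      N1 = "normal")
  )
}

# independent JSD oracle: direct two-term KL summation
jsd_oracle <- function(p, q) {
  p <- unname(p); q <- unname(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log(a[i] / b[i])
    s
  }
  (kl(p, m) + kl(q, m)) / 2
}

# labelled symmetric matrix from a vector of upper-triangle entries
dist_mat <- function(labels, upper) {
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- upper
  d + t(d)
}

# small expression study built by hand: values per sample type
typed_study <- function(values, noise = NULL, design = default_array_design(),
                        genes = NULL) {
  x <- matrix(NA_real_, length(values[[1]]), nrow(design),
              dimnames = list(sprintf("g%03d", seq_along(values[[1]])),
                              design$sample_id))
  for (tp in names(values))
    x[, design$sample_type == tp] <- values[[tp]]
  if (!is.null(noise)) x <- x * noise
  expression_study(x, design, genes = genes)
}
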