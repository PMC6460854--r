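# Independent brute-force oracles, written as plain loops straight from the
# definitions. They deliberately share no code with the package internals.

oracle_screen_flags <- function(tpm, criteria = screen_criteria()) {
  out <- data.frame(gene_id = rownames(tpm), passes_I = NA, passes_II = NA,
                    passes_III = NA, passes_IV = NA, cv = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(tpm))) {
    v <- tpm[g, ]
    p1 <- TRUE
    for (x in v) if (!(x > criteria$min_tpm_exclusive)) p1 <- FALSE
    out$passes_I[g] <- p1
    if (!p1) next
    L <- log2(v)
    mu <- sum(L) / length(L)
    s <- sqrt(sum((L - mu)^2) / (length(L) - 1))
    dev <- max(abs(L - mu))
    out$passes_II[g] <- s < criteria$max_sd_log2
    out$passes_III[g] <- dev < criteria$max_abs_deviation_log2
    out$passes_IV[g] <- mu > criteria$min_mean_log2_exclusive
    out$cv[g] <- s / mu
  }
  out
}

# sample SD by the definition, loop form
oracle_sd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / (length(x) - 1))
}

oracle_genorm_M <- function(q) {
  n <- nrow(q)
  m <- numeric(n)
  for (j in seq_len(n)) {
    vs <- c()
    for (k in seq_len(n)) {
      if (k == j) next
      a <- log2(q[j, ] / q[k, ])
      vs <- c(vs, oracle_sd(a))
    }
    m[j] <- mean(vs)
  }
  names(m) <- rownames(q)
  m
}

oracle_genorm_exclusion <- function(q) {
  remaining <- rownames(q)
  order_out <- character(0)
  while (length(remaining) > 2) {
    m <- oracle_genorm_M(q[remaining, , drop = FALSE])
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[length(worst)]
    order_out <- c(order_out, worst)
    remaining <- setdiff(remaining, worst)
  }
  order_out
}

oracle_deltact <- function(ct) {
  n <- nrow(ct)
  stab <- numeric(n)
  for (i in seq_len(n)) {
    sds <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      sds <- c(sds, oracle_sd(ct[i, ] - ct[j, ]))
    }
    stab[i] <- mean(sds)
  }
  names(stab) <- rownames(ct)
  stab
}

oracle_normfinder_ungrouped <- function(ct, e = rep(1, nrow(ct))) {
  y <- -ct * log2(1 + e)
  n <- nrow(y)
  stab <- numeric(n)
  for (i in seq_len(n)) {
    z <- numeric(ncol(y))
    for (s in seq_len(ncol(y))) z[s] <- y[i, s] - mean(y[, s])
    stab[i] <- oracle_sd(z)
  }
  names(stab) <- rownames(ct)
  stab
}

oracle_normfinder_grouped <- function(ct, groups, e = rep(1, nrow(ct))) {
  y <- -ct * log2(1 + e)
  z <- y
  for (s in seq_len(ncol(y))) z[, s] <- y[, s] - mean(y[, s])
  gl <- unique(groups)
  stab <- numeric(nrow(y))
  for (i in seq_len(nrow(y))) {
    acc <- c()
    for (g in gl) {
      cols <- which(groups == g)
      d <- (mean(y[i, cols]) - mean(y[i, ])) - (mean(y[, cols]) - mean(y))
      s2 <- oracle_sd(z[i, cols])^2
      acc <- c(acc, abs(d) + sqrt(s2 / length(cols)))
    }
    stab[i] <- mean(acc)
  }
  names(stab) <- rownames(ct)
  stab
}

# upper-tail hypergeometric by explicit pmf summation
oracle_hyper_p <- function(overlap, term_size, universe_size, query_size) {
  upper <- min(term_size, query_size)
  total <- 0
  for (x in overlap:upper) {
    total <- total + exp(lchoose(term_size, x) +
                           lchoose(universe_size - term_size, query_size - x) -
                           lchoose(universe_size, query_size))
  }
  total
}

# random Ct matrix helper (values safely inside (0, 45])
random_ct <- function(n_genes, n_samples, seed, sd = 1) {
  set.seed(seed)
  ct <- matrix(stats::rnorm(n_genes * n_samples, 25, sd), n_genes, n_samples,
               dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                               sprintf("s%02d", seq_len(n_samples))))
  ct_matrix(pmin(pmax(ct, 5), 40))
}

# random strictly-positive TPM matrix
random_tpm <- function(n_genes, n_conditions, seed) {
  set.seed(seed)
  m <- matrix(2^stats::rnorm(n_genes * n_conditions, 6, 3),
              n_genes, n_conditions,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_conditions))))
  # sprinkle exact zeros so criterion I is exercised
  set.seed(seed + 1)
  m[sample(length(m), ceiling(length(m) / 20))] <- 0
  m
}

# write a FASTQ file from records given as list(name, seq, quals [ints])
write_test_fastq <- function(records, path = tempfile(fileext = ".fastq"),
                             offset = 33) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$name), r$seq, "+",
      intToUtf8(r$quals + offset, multiple = FALSE))
  }))
  writeLines(lines, path)
  path
}

make_read <- function(name, len = 20, q = 40, n_low = 0, q_low = 19,
                      with_N = FALSE) {
  seq <- paste(rep("A", len), collapse = "")
  if (with_N) substr(seq, 1, 1) <- "N"
  quals <- rep(q, len)
  if (n_low > 0) quals[seq_len(n_low)] <- q_low
  list(name = name, seq = seq, quals = quals)
}
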