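# Programmatic fixtures: small files written to tempdir at test time.

write_expr_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "expr_fixture.tsv")
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   gA = c(1.5, 2.5, 3.5), gB = c(10, 20, 30))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_maf_fixture <- function(records, dir = tempdir(),
                              name = "fixture.maf") {
  path <- file.path(dir, name)
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

random_mutation_matrix <- function(n, k, rate = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(as.numeric(rbinom(n * k, 1, rate)), n, k,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(k))))
  m
}

# exhaustive two-sided Mann-Whitney p-value by enumerating every group
# assignment; independent of the implementation under test
mwu_enum_p <- function(y1, y0) {
  y <- c(y1, y0)
  n1 <- length(y1)
  r <- rank(y)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y0) / 2
  combs <- combn(length(y), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
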